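# Seeded generator of desk-scale reaction datasets with known ground-truth
# mappings, controllable molecular symmetry and valence-legal edit lists.

# conservative valences for the generator palette: every molecule built
# within these limits passes validate_product by construction
.gen_valence <- c(C = 4, N = 3, O = 2, S = 2, F = 1, Cl = 1)

#' Generator configuration
#'
#' @param n_reactions number of reactions to generate
#' @param atom_range min/max heavy atoms per reactant molecule
#' @param edit_range min/max number of bond edits per reaction
#' @param symmetry_fraction probability that a molecule is grown with a
#'   mirrored fragment, guaranteeing a nontrivial equivalence class
#' @param element_palette elements to draw from (must have an entry in the
#'   generator valence model)
#' @param seed integer seed
#' @return object of class `"generator_config"`
#' @export
generator_config <- function(n_reactions = 1000L, atom_range = c(6L, 16L),
                             edit_range = c(1L, 3L),
                             symmetry_fraction = 0.4,
                             element_palette = c("C", "N", "O", "S", "F", "Cl"),
                             seed = 1L) {
  stopifnot(atom_range[1] <= atom_range[2], edit_range[1] <= edit_range[2],
            length(element_palette) > 0,
            symmetry_fraction >= 0, symmetry_fraction <= 1,
            all(element_palette %in% names(.gen_valence)))
  structure(list(n_reactions = as.integer(n_reactions),
                 atom_range = as.integer(atom_range),
                 edit_range = as.integer(edit_range),
                 symmetry_fraction = symmetry_fraction,
                 element_palette = element_palette,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# grow a random connected valence-legal tree, then close up to `max_rings`
# rings where both endpoints have spare valence
.grow_molecule <- function(n_atoms, palette, max_rings = 2L) {
  # carbon-rich draws keep molecules connected and growable
  w <- ifelse(palette == "C", 4, 1)
  repeat {
    sym <- sample(palette, n_atoms, replace = TRUE, prob = w)
    cap <- .gen_valence[sym]
    if (sum(cap) >= 2 * (n_atoms - 1L)) break   # enough valence for a tree
  }
  used <- numeric(n_atoms)
  bi <- integer(0); bj <- integer(0)
  open <- 1L     # atoms already placed
  for (a in seq_len(n_atoms)[-1]) {
    anchors <- which(seq_len(n_atoms) <= open & used < cap)
    anchors <- anchors[cap[anchors] - used[anchors] >= 1]
    if (!length(anchors)) return(NULL)          # dead end; caller retries
    p <- sample(rep(anchors, 2L), 1L)           # rep() guards length-1 sample
    bi <- c(bi, p); bj <- c(bj, a)
    used[p] <- used[p] + 1; used[a] <- used[a] + 1
    open <- a
  }
  # probabilistic ring closures
  n_rings <- sample.int(max_rings + 1L, 1L) - 1L
  if (n_rings > 0L) {
    adj <- matrix(FALSE, n_atoms, n_atoms)
    adj[cbind(bi, bj)] <- adj[cbind(bj, bi)] <- TRUE
    for (r in seq_len(n_rings)) {
      free <- which(used < cap)
      if (length(free) < 2L) break
      cand <- expand.grid(i = free, j = free)
      cand <- cand[cand$i < cand$j & !adj[cbind(cand$i, cand$j)], , drop = FALSE]
      if (!nrow(cand)) break
      k <- sample.int(nrow(cand), 1L)
      i <- cand$i[k]; j <- cand$j[k]
      bi <- c(bi, i); bj <- c(bj, j)
      adj[i, j] <- adj[j, i] <- TRUE
      used[i] <- used[i] + 1; used[j] <- used[j] + 1
    }
  }
  # unsaturation: upgrade bonds to double (or occasionally triple) where
  # both endpoints have spare valence, so the generated chemistry
  # exercises bond orders, sp/sp2 hybridization and conjugation
  order <- rep("single", length(bi))
  for (k in sample.int(length(bi))) {
    i <- bi[k]; j <- bj[k]
    spare_i <- cap[i] - used[i]; spare_j <- cap[j] - used[j]
    if (spare_i >= 2 && spare_j >= 2 && runif(1) < 0.05) {
      order[k] <- "triple"; used[i] <- used[i] + 2; used[j] <- used[j] + 2
    } else if (spare_i >= 1 && spare_j >= 1 && runif(1) < 0.3) {
      order[k] <- "double"; used[i] <- used[i] + 1; used[j] <- used[j] + 1
    }
  }
  list(symbols = sym, bonds = data.frame(i = bi, j = bj, order = order,
                                         stringsAsFactors = FALSE),
       used = used, cap = cap)
}

# mirror a random fragment: duplicate the subtree hanging off a random
# leaf-ish anchor so at least one nontrivial equivalence class exists
.grow_symmetric <- function(n_atoms, palette) {
  half <- max(2L, n_atoms %/% 2L)
  core <- .grow_molecule(half, palette, max_rings = 1L)
  if (is.null(core)) return(NULL)
  # pick an anchor with >= 2 spare valence to host two identical branches
  spare <- core$cap - core$used
  anchors <- which(spare >= 2)
  if (!length(anchors)) return(NULL)
  anchor <- sample(rep(anchors, 2L), 1L)
  branch_n <- max(1L, (n_atoms - half) %/% 2L)
  br <- .grow_molecule(branch_n, palette, max_rings = 0L)
  if (is.null(br)) return(NULL)
  if (br$cap[1] - br$used[1] < 1) return(NULL)  # branch root must bond
  sym <- core$symbols; bonds <- core$bonds
  for (copy in 1:2) {
    off <- length(sym)
    sym <- c(sym, br$symbols)
    if (nrow(br$bonds))
      bonds <- rbind(bonds, data.frame(i = br$bonds$i + off,
                                       j = br$bonds$j + off,
                                       order = br$bonds$order))
    bonds <- rbind(bonds, data.frame(i = anchor, j = off + 1L,
                                     order = "single"))
  }
  list(symbols = sym, bonds = bonds)
}

#' Generate a random valence-legal molecule
#'
#' Grows a connected molecule by random tree growth with probabilistic
#' ring closure (at most two rings).  With probability
#' `symmetry_fraction` the molecule is instead built by attaching two
#' identical copies of a random fragment to one anchor atom, which
#' guarantees at least one equivalence class of size two or more.
#' Hydrogens are filled implicitly up to each element's generator valence.
#'
#' @param config a [generator_config]
#' @return a [molgraph]
#' @export
generate_molecule <- function(config) {
  n_atoms <- sample(seq(config$atom_range[1], config$atom_range[2]), 1L)
  symmetric <- runif(1) < config$symmetry_fraction
  for (try in 1:50) {
    raw <- if (symmetric) .grow_symmetric(n_atoms, config$element_palette)
           else .grow_molecule(n_atoms, config$element_palette)
    if (!is.null(raw)) {
      cap <- .gen_valence[raw$symbols]
      used <- numeric(length(raw$symbols))
      for (k in seq_len(nrow(raw$bonds))) {
        o <- .bond_order_num[[raw$bonds$order[k]]]
        used[raw$bonds$i[k]] <- used[raw$bonds$i[k]] + o
        used[raw$bonds$j[k]] <- used[raw$bonds$j[k]] + o
      }
      if (any(used > cap)) next
      n_h <- as.integer(cap - used)
      return(molgraph(symbols = raw$symbols, bonds = raw$bonds, n_h = n_h,
                      map = seq_along(raw$symbols)))
    }
  }
  stop("molecule growth failed repeatedly; relax the configuration",
       call. = FALSE)
}

# sample a valence-legal edit set for a reactant graph.  Deleting a bond
# frees one valence on each endpoint, compensated by a gained hydrogen;
# adding a bond consumes a hydrogen from each endpoint.  Every edit is
# therefore hydrogen-balanced and the product stays valence-legal.
.sample_edits <- function(g, n_edits) {
  bonds <- g$bonds[, c("i", "j", "order")]
  n_h <- g$n_h
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  present <- key(bonds$i, bonds$j)
  deleted <- data.frame(i = integer(), j = integer())
  added <- data.frame(i = integer(), j = integer(), order = character())
  lost_h <- integer(0); gained_h <- integer(0)
  deleted_keys <- character(0)
  for (e in seq_len(n_edits)) {
    added_keys <- key(added$i, added$j)   # map == index in generator graphs
    # only single bonds are deletable: each endpoint is compensated with
    # exactly one hydrogen, keeping the edit hydrogen-balanced
    deletable <- which(bonds$order == "single" &
                       !(key(bonds$i, bonds$j) %in% added_keys))
    do_delete <- length(deletable) > 1L && runif(1) < 0.5
    if (do_delete) {
      # deleting a bridge splits the molecule: allowed (reactions may
      # fragment), but keep both endpoints hydrogen-compensated; bonds
      # introduced by an earlier edit are never re-deleted
      k <- deletable[sample.int(length(deletable), 1L)]
      i <- bonds$i[k]; j <- bonds$j[k]
      deleted <- rbind(deleted, data.frame(i = g$map[i], j = g$map[j]))
      deleted_keys <- c(deleted_keys, key(i, j))
      bonds <- bonds[-k, , drop = FALSE]
      n_h[i] <- n_h[i] + 1L; n_h[j] <- n_h[j] + 1L
      gained_h <- c(gained_h, g$map[i], g$map[j])
    } else {
      free <- which(n_h >= 1L)
      if (length(free) < 2L) next
      cand <- expand.grid(i = free, j = free)
      cand <- cand[cand$i < cand$j, , drop = FALSE]
      ck <- key(cand$i, cand$j)
      ok <- !(ck %in% present) & !(ck %in% key(added$i, added$j)) &
            !(ck %in% deleted_keys)
      cand <- cand[ok, , drop = FALSE]
      if (!nrow(cand)) next
      k <- sample.int(nrow(cand), 1L)
      i <- cand$i[k]; j <- cand$j[k]
      added <- rbind(added, data.frame(i = g$map[i], j = g$map[j],
                                       order = "single"))
      bonds <- rbind(bonds, data.frame(i = i, j = j, order = "single"))
      present <- c(present, key(i, j))
      n_h[i] <- n_h[i] - 1L; n_h[j] <- n_h[j] - 1L
      lost_h <- c(lost_h, g$map[i], g$map[j])
    }
  }
  reaction_edits(lost_h = lost_h, gained_h = gained_h,
                 deleted_bonds = deleted, added_bonds = added)
}

#' Generate one synthetic reaction
#'
#' Draws a reactant molecule, samples a valence-legal edit set, builds
#' the product by [apply_edits()], remaps both sides with seeded random
#' permutations to remove atom-position dependence, and serializes the
#' record.  The ground-truth correspondence is known by construction.
#'
#' @param config a [generator_config]
#' @param remap_seed seed for the atom-order remapping (default: drawn
#'   from the current RNG stream)
#' @return list with `record` (TSV line) and `reaction` (a [reaction])
#' @export
generate_reaction <- function(config,
                              remap_seed = sample.int(2^30, 1L)) {
  for (try in 1:50) {
    g <- generate_molecule(config)
    n_edits <- sample(seq(config$edit_range[1], config$edit_range[2]), 1L)
    edits <- .sample_edits(g, n_edits)
    prod <- apply_edits(g, edits)
    if (!validate_product(prod)$ok) next
    gt <- diag(g$atom_count)
    storage.mode(gt) <- "integer"
    rxn <- remap_reaction(reaction(g, prod, edits, gt), remap_seed)
    # normalize atom order through one serialization round so that the
    # record round-trips byte-identically through parse/format
    rxn <- reaction_from_record(format_reaction_record(rxn))
    return(list(record = format_reaction_record(rxn), reaction = rxn))
  }
  stop("failed to sample a legal reaction", call. = FALSE)
}

#' Generate a split synthetic dataset
#'
#' Generates `config$n_reactions` reactions and writes seeded 70/10/20
#' train/validation/test record files plus a JSON manifest (seed, config
#' echo, counts).
#'
#' @param config a [generator_config]
#' @param dir output directory (created if missing)
#' @return invisibly, a list with `reactions` (all generated reactions),
#'   `split` (index vectors) and `files` (paths written, `NULL` when
#'   `dir` is `NULL`)
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(config$n_reactions >= 10L)
  out <- with_seed(config$seed, {
    lapply(seq_len(config$n_reactions), function(k)
      generate_reaction(config, remap_seed = .sub_seed(config$seed, k)))
  })
  records <- vapply(out, `[[`, "", "record")
  reactions <- lapply(out, `[[`, "reaction")
  split <- split_dataset(config$n_reactions, .sub_seed(config$seed, 0L))
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- file.path(dir, c("train.tsv", "val.tsv", "test.tsv",
                              "manifest.json"))
    writeLines(records[split$train], files[1])
    writeLines(records[split$val], files[2])
    writeLines(records[split$test], files[3])
    manifest <- list(seed = config$seed,
                     config = unclass(config),
                     counts = list(train = length(split$train),
                                   val = length(split$val),
                                   test = length(split$test)))
    jsonlite::write_json(manifest, files[4], auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(reactions = reactions, records = records, split = split,
                 files = files))
}
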