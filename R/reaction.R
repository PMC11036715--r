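# Reaction records: parsing/writing the TSV record dialect, applying
# reaction edits to reactants, product validation, ground-truth
# correspondence matrices, remapping and dataset splits.
#
# Record dialect (one reaction per line, 5 tab-separated fields):
#   <reaction SMILES> \t <lost_h> \t <gained_h> \t <deleted_bonds> \t <added_bonds>
# where lost_h/gained_h are semicolon-separated atom-map numbers,
# deleted_bonds entries are "i-j" (map numbers) and added_bonds entries
# are "i-j" or "i-j-order" (order in {single,double,triple}; default
# single).  Empty lists are empty fields.

# maximum permitted valence per element for product validation; NA = no
# constraint (elements outside the simple organic valence model)
.max_valence <- c(B = 4, C = 4, N = 4, O = 3, P = 6, S = 6,
                  F = 1, Cl = 7, Br = 7, I = 7, Si = 4, Se = 6, Te = 6,
                  As = 5, Ge = 4, Sn = 4, Al = 4, Li = 1, Na = 1, K = 1,
                  Be = 2, Mg = 2, Ca = 2)

#' Reaction edit lists
#'
#' The four edit types that transform the reactant side into the product
#' side: atoms that lost a hydrogen, atoms that gained a hydrogen, deleted
#' bonds and added bonds.  Atoms are referenced by atom-map number.
#'
#' @param lost_h,gained_h integer vectors of atom-map numbers (repeats
#'   allowed: one entry per hydrogen)
#' @param deleted_bonds data frame with map-number columns `i`, `j`
#' @param added_bonds data frame with columns `i`, `j`, `order`
#' @return object of class `"reaction_edits"`
#' @export
reaction_edits <- function(lost_h = integer(0), gained_h = integer(0),
                           deleted_bonds = data.frame(i = integer(),
                                                      j = integer()),
                           added_bonds = data.frame(i = integer(),
                                                    j = integer(),
                                                    order = character())) {
  deleted_bonds <- as.data.frame(deleted_bonds)
  added_bonds <- as.data.frame(added_bonds)
  if (is.null(added_bonds$order)) added_bonds$order <- rep("single", nrow(added_bonds))
  if (nrow(deleted_bonds) && nrow(added_bonds)) {
    dk <- paste(pmin(deleted_bonds$i, deleted_bonds$j),
                pmax(deleted_bonds$i, deleted_bonds$j))
    ak <- paste(pmin(added_bonds$i, added_bonds$j),
                pmax(added_bonds$i, added_bonds$j))
    if (length(intersect(dk, ak)))
      stop("bond(s) both deleted and added: ",
           paste(intersect(dk, ak), collapse = "; "), call. = FALSE)
  }
  structure(list(lost_h = as.integer(lost_h),
                 gained_h = as.integer(gained_h),
                 deleted_bonds = deleted_bonds, added_bonds = added_bonds),
            class = "reaction_edits")
}

.edit_maps <- function(edits) {
  c(edits$lost_h, edits$gained_h,
    edits$deleted_bonds$i, edits$deleted_bonds$j,
    edits$added_bonds$i, edits$added_bonds$j)
}

#' Balanced reaction with ground-truth correspondence
#'
#' Bundles a reactant graph, a product graph, the edit lists and the
#' binary ground-truth correspondence matrix (a permutation matrix with
#' `gt_matrix[i, j] = 1` iff reactant atom i becomes product atom j).
#' The element multisets of the two sides must agree (balanced reaction).
#'
#' @param reactants,products [molgraph] objects
#' @param edits a [reaction_edits]
#' @param gt_matrix binary `|V_R| x |V_P|` permutation matrix
#' @return object of class `"reaction"`
#' @export
reaction <- function(reactants, products, edits = reaction_edits(),
                     gt_matrix) {
  if (!identical(element_multiset(reactants), element_multiset(products)))
    stop("reaction is not balanced: element multisets differ between ",
         "reactant and product sides", call. = FALSE)
  n <- reactants$atom_count
  if (!all(dim(gt_matrix) == c(n, products$atom_count)) ||
      any(rowSums(gt_matrix) != 1) || any(colSums(gt_matrix) != 1))
    stop("gt_matrix is not a permutation matrix of the right shape",
         call. = FALSE)
  structure(list(reactants = reactants, products = products, edits = edits,
                 gt_matrix = gt_matrix), class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  cat("<reaction> ", write_smiles(x$reactants), ">>",
      write_smiles(x$products), "\n", sep = "")
  cat("  ", x$reactants$atom_count, " heavy atoms/side; edits: ",
      length(x$edits$lost_h), " -H, ", length(x$edits$gained_h), " +H, ",
      nrow(x$edits$deleted_bonds), " deleted, ",
      nrow(x$edits$added_bonds), " added bonds\n", sep = "")
  invisible(x)
}

.parse_pair_list <- function(field, with_order = FALSE, line_no = NA) {
  if (!nzchar(field)) {
    return(if (with_order) data.frame(i = integer(), j = integer(),
                                      order = character())
           else data.frame(i = integer(), j = integer()))
  }
  items <- strsplit(field, ";", fixed = TRUE)[[1]]
  parts <- strsplit(items, "-", fixed = TRUE)
  bad <- lengths(parts) < 2L | lengths(parts) > (2L + with_order)
  if (any(bad))
    stop("malformed bond list entry '", items[bad][1], "'",
         if (!is.na(line_no)) paste0(" at line ", line_no), call. = FALSE)
  i <- as.integer(vapply(parts, `[`, "", 1L))
  j <- as.integer(vapply(parts, `[`, "", 2L))
  if (anyNA(i) || anyNA(j))
    stop("non-numeric map number in bond list '", field, "'",
         if (!is.na(line_no)) paste0(" at line ", line_no), call. = FALSE)
  if (with_order) {
    order <- vapply(parts, function(p) if (length(p) == 3L) p[3] else "single", "")
    data.frame(i = i, j = j, order = order, stringsAsFactors = FALSE)
  } else data.frame(i = i, j = j)
}

.parse_int_list <- function(field, line_no = NA) {
  if (!nzchar(field)) return(integer(0))
  v <- suppressWarnings(as.integer(strsplit(field, ";", fixed = TRUE)[[1]]))
  if (anyNA(v))
    stop("non-numeric atom-map number in '", field, "'",
         if (!is.na(line_no)) paste0(" at line ", line_no), call. = FALSE)
  v
}

#' Parse one reaction record
#'
#' Reads one line of the reaction-record TSV dialect: a reaction SMILES
#' (reactant side atom-mapped) followed by the four edit lists.  All map
#' numbers referenced by the edits must exist on the reactant side.
#'
#' @param line a single record line
#' @param line_no optional line number used in error messages
#' @return list with `rxn_smiles` (the SMILES field), `reactants`
#'   ([molgraph]), `edits` ([reaction_edits]) and, when the SMILES has a
#'   product side, the parsed `products`
#' @export
parse_reaction_record <- function(line, line_no = NA) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(fields) < 5L) fields <- c(fields, rep("", 5L - length(fields)))
  if (length(fields) != 5L)
    stop("record must have 5 tab-separated fields, got ", length(fields),
         if (!is.na(line_no)) paste0(" at line ", line_no), call. = FALSE)
  rxn <- parse_reaction_smiles(fields[1])
  edits <- reaction_edits(
    lost_h = .parse_int_list(fields[2], line_no),
    gained_h = .parse_int_list(fields[3], line_no),
    deleted_bonds = .parse_pair_list(fields[4], FALSE, line_no),
    added_bonds = .parse_pair_list(fields[5], TRUE, line_no)
  )
  known <- rxn$reactants$map[rxn$reactants$map > 0L]
  dangling <- setdiff(.edit_maps(edits), known)
  if (length(dangling))
    stop("edit references atom-map number(s) absent from the reactant ",
         "side: ", paste(sort(unique(dangling)), collapse = ", "),
         if (!is.na(line_no)) paste0(" at line ", line_no), call. = FALSE)
  list(rxn_smiles = fields[1], reactants = rxn$reactants,
       products = rxn$products, edits = edits)
}

#' Format a reaction as a record line
#'
#' Inverse of [parse_reaction_record()]: writes the reaction SMILES (both
#' sides atom-mapped so the map numbers carry the ground-truth
#' correspondence) and the four edit fields.
#'
#' @param rxn a [reaction]
#' @return a single TSV line (no trailing newline)
#' @export
format_reaction_record <- function(rxn) {
  fmt_pairs <- function(df, with_order = FALSE) {
    if (!nrow(df)) return("")
    if (with_order) paste(paste(df$i, df$j, df$order, sep = "-"),
                          collapse = ";")
    else paste(paste(df$i, df$j, sep = "-"), collapse = ";")
  }
  smiles <- paste0(write_smiles(rxn$reactants, with_maps = TRUE), ">>",
                   write_smiles(rxn$products, with_maps = TRUE))
  paste(smiles,
        paste(rxn$edits$lost_h, collapse = ";"),
        paste(rxn$edits$gained_h, collapse = ";"),
        fmt_pairs(rxn$edits$deleted_bonds),
        fmt_pairs(rxn$edits$added_bonds, TRUE),
        sep = "\t")
}

#' Apply reaction edits to a reactant graph
#'
#' Constructs the product graph by deleting/adding the listed bonds and
#' adjusting hydrogen counts.  Atom order, elements and charges are
#' unchanged, so the element multiset is conserved and the identity
#' correspondence maps the reactant onto the product.
#'
#' @param reactants a [molgraph] whose atoms carry the map numbers the
#'   edits reference (atoms with map 0 cannot be edited)
#' @param edits a [reaction_edits]
#' @return the product [molgraph]
#' @export
apply_edits <- function(reactants, edits) {
  g <- reactants
  map_to_idx <- function(m) {
    idx <- match(m, g$map)
    if (anyNA(idx))
      stop("edit references atom-map number(s) not present: ",
           paste(m[is.na(idx)], collapse = ", "), call. = FALSE)
    idx
  }
  # gains first: an atom may pass a hydrogen it only just received, and the
  # net count is order-independent
  n_h <- g$n_h
  for (a in map_to_idx(edits$gained_h)) n_h[a] <- n_h[a] + 1L
  for (a in map_to_idx(edits$lost_h)) {
    n_h[a] <- n_h[a] - 1L
    if (n_h[a] < 0L)
      stop("edit removes a hydrogen from atom with none (map ",
           g$map[a], ")", call. = FALSE)
  }

  bonds <- g$bonds[, c("i", "j", "order")]
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  bkey <- key(bonds$i, bonds$j)
  if (nrow(edits$deleted_bonds)) {
    di <- map_to_idx(edits$deleted_bonds$i)
    dj <- map_to_idx(edits$deleted_bonds$j)
    dk <- key(di, dj)
    missing <- !(dk %in% bkey)
    if (any(missing))
      stop("deleted bond not present between map numbers ",
           paste(paste(edits$deleted_bonds$i[missing],
                       edits$deleted_bonds$j[missing], sep = "-"),
                 collapse = ", "), call. = FALSE)
    bonds <- bonds[!(bkey %in% dk), , drop = FALSE]
    bkey <- key(bonds$i, bonds$j)
  }
  if (nrow(edits$added_bonds)) {
    ai <- map_to_idx(edits$added_bonds$i)
    aj <- map_to_idx(edits$added_bonds$j)
    ak <- key(ai, aj)
    if (any(ak %in% bkey) || anyDuplicated(ak))
      stop("added bond duplicates an existing bond", call. = FALSE)
    bonds <- rbind(bonds,
                   data.frame(i = ai, j = aj,
                              order = edits$added_bonds$order,
                              stringsAsFactors = FALSE))
  }
  # aromatic flags only survive where the aromatic system is untouched;
  # recompute from remaining aromatic bonds
  molgraph(symbols = g$atom_symbols, bonds = bonds, charge = g$charge,
           n_h = n_h, chirality = g$chirality, map = g$map)
}

#' Validate a product graph against valence limits
#'
#' A product fails validation iff some atom's explicit valence (total bond
#' order including hydrogens) exceeds the permitted maximum for its
#' element, adjusted by +1 for cationic atoms with a bondable charge.
#'
#' @param product a [molgraph]
#' @return list with `ok` (logical) and `reasons` (character vector, empty
#'   when valid)
#' @export
validate_product <- function(product) {
  reasons <- character(0)
  for (a in seq_len(product$atom_count)) {
    sym <- product$atom_symbols[a]
    vmax <- .max_valence[[sym]]
    if (is.null(vmax) || is.na(vmax)) next
    if (product$charge[a] > 0) vmax <- vmax + product$charge[a]
    if (product$valence[a] > vmax + 1e-9) {
      reasons <- c(reasons, paste0("atom ", a, " (", sym, ") has valence ",
                                   product$valence[a],
                                   " above the permitted maximum ", vmax))
    }
  }
  list(ok = !length(reasons), reasons = reasons)
}

# permute the atoms of a molgraph: atom old index i -> new index perm[i]
.permute_graph <- function(g, perm) {
  inv <- order(perm)   # new index -> old index
  bonds <- g$bonds[, c("i", "j", "order")]
  bonds$i <- perm[bonds$i]; bonds$j <- perm[bonds$j]
  molgraph(symbols = g$atom_symbols[inv], bonds = bonds,
           charge = g$charge[inv], n_h = g$n_h[inv],
           chirality = g$chirality[inv], map = g$map[inv],
           aromatic = g$aromatic[inv])
}

#' Remap a reaction to remove atom-position dependence
#'
#' Independently permutes the atom orders of the reactant and product
#' sides by seeded uniform random permutations and updates the
#' ground-truth matrix so it encodes the same chemical correspondence.
#' With the same seed the output is identical.
#'
#' @param rxn a [reaction]
#' @param seed integer seed
#' @return the remapped [reaction]
#' @export
remap_reaction <- function(rxn, seed) {
  n <- rxn$reactants$atom_count
  m <- rxn$products$atom_count
  perm_r <- with_seed(.sub_seed(seed, 1L), sample.int(n))  # old -> new
  perm_p <- with_seed(.sub_seed(seed, 2L), sample.int(m))
  gr <- .permute_graph(rxn$reactants, perm_r)
  gp <- .permute_graph(rxn$products, perm_p)
  gt <- matrix(0L, n, m)
  old_pairs <- which(rxn$gt_matrix == 1L, arr.ind = TRUE)
  gt[cbind(perm_r[old_pairs[, 1]], perm_p[old_pairs[, 2]])] <- 1L
  # edits reference map numbers, which travel with the atoms
  reaction(gr, gp, rxn$edits, gt)
}

#' Seeded train/validation/test split
#'
#' Deterministically splits `n` items into 70/10/20 train/validation/test
#' proportions (counts rounded, every item assigned exactly once).
#'
#' @param n number of items
#' @param seed integer seed
#' @param fractions length-3 numeric vector summing to 1
#' @return list with integer index vectors `train`, `val`, `test`
#' @export
split_dataset <- function(n, seed, fractions = c(0.7, 0.1, 0.2)) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, n >= 3L)
  perm <- with_seed(seed, sample.int(n))
  n_train <- round(n * fractions[1])
  n_val <- round(n * fractions[2])
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[(n_train + n_val + 1L):n]))
}

#' Read a reaction-record TSV file into reactions
#'
#' Parses every line with [parse_reaction_record()], reconstructs the
#' product side by applying the edits to the reactants, validates it and
#' builds the ground-truth matrix from the atom-map numbers on both sides
#' of the SMILES field (falling back to the identity correspondence when
#' the product side is unmapped).
#'
#' @param path file path
#' @return list of [reaction] objects
#' @export
read_reactions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(ln) reaction_from_record(lines[ln], ln))
}

#' @rdname read_reactions
#' @param line a single record line
#' @param line_no optional line number for error messages
#' @export
reaction_from_record <- function(line, line_no = NA) {
  rec <- parse_reaction_record(line, line_no = line_no)
  prod <- apply_edits(rec$reactants, rec$edits)
  val <- validate_product(prod)
  if (!val$ok)
    stop("invalid product", if (!is.na(line_no)) paste0(" at line ", line_no),
         ": ", paste(val$reasons, collapse = "; "), call. = FALSE)
  n <- rec$reactants$atom_count
  if (all(rec$products$map > 0L) && all(rec$reactants$map > 0L)) {
    # the record's own product atom order is authoritative; map numbers
    # on both sides encode the ground-truth correspondence
    reaction(rec$reactants, rec$products, rec$edits,
             diag_to_gt(rec$reactants, rec$products))
  } else {
    gt <- diag(n)
    storage.mode(gt) <- "integer"
    reaction(rec$reactants, prod, rec$edits, gt)
  }
}

# gt matrix between two mapped graphs: atoms correspond iff equal map number
diag_to_gt <- function(gr, gp) {
  tgt <- match(gr$map, gp$map)
  if (anyNA(tgt)) stop("map numbers do not align between sides", call. = FALSE)
  gt <- matrix(0L, gr$atom_count, gp$atom_count)
  gt[cbind(seq_along(tgt), tgt)] <- 1L
  gt
}
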