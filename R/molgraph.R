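#' Molecular graph with featurized atoms and bonds
#'
#' Constructs the graph representation used throughout the package: heavy
#' atoms are nodes, chemical bonds are undirected edges, and each atom and
#' bond carries the one-hot/scalar feature vector of [feature_schema()].
#' Ring membership is perceived from the graph (an atom/bond is in a ring
#' iff it lies on a cycle), hybridization is derived from multiple-bond
#' counts, and explicit valence is the total bond order including
#' hydrogens.
#'
#' @param symbols character vector of element symbols (heavy atoms only)
#' @param bonds data frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (`"single"`, `"double"`, `"triple"`, `"aromatic"`)
#' @param charge integer vector of formal charges (default all 0)
#' @param n_h integer vector of hydrogen counts (default all 0)
#' @param chirality character vector (`"unspecified"`, `"tet_cw"`,
#'   `"tet_ccw"`, `"other"`)
#' @param map integer vector of atom-map numbers (0 = unmapped)
#' @param aromatic logical vector of aromatic-atom flags
#' @return object of class `"molgraph"`: a list with fields `atom_count`,
#'   `atom_symbols`, `adjacency` (symmetric 0/1 matrix, zero diagonal),
#'   `atom_features` (atoms x 106), `bonds`, `bond_features` (one row per
#'   bond; see [bond_feature_rows()] for the ordered-pair view), plus the
#'   per-atom annotation vectors.
#' @examples
#' g <- mol_to_graph("CC")
#' g$adjacency
#' @export
molgraph <- function(symbols, bonds = data.frame(i = integer(), j = integer(),
                                                 order = character()),
                     charge = NULL, n_h = NULL, chirality = NULL,
                     map = NULL, aromatic = NULL) {
  n <- length(symbols)
  if (n == 0L) stop("molecule has no atoms", call. = FALSE)
  unknown <- setdiff(unique(symbols), .element_table$symbol)
  if (length(unknown))
    stop("element(s) not in the 64-slot vocabulary: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(charge)) charge <- integer(n)
  if (is.null(n_h)) n_h <- integer(n)
  if (is.null(chirality)) chirality <- rep("unspecified", n)
  if (is.null(map)) map <- integer(n)
  if (is.null(aromatic)) aromatic <- logical(n)
  stopifnot(length(charge) == n, length(n_h) == n, length(chirality) == n,
            length(map) == n, length(aromatic) == n)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  m <- nrow(bonds)
  if (m) {
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("bond references an atom index outside 1..", n, call. = FALSE)
    if (any(bonds$i == bonds$j)) stop("self-bond not allowed", call. = FALSE)
    bad <- setdiff(unique(bonds$order), names(.bond_order_num))
    if (length(bad))
      stop("unrecognized bond order(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond between the same atom pair",
                                 call. = FALSE)
  }
  adjacency <- matrix(0L, n, n)
  if (m) {
    adjacency[cbind(bonds$i, bonds$j)] <- 1L
    adjacency[cbind(bonds$j, bonds$i)] <- 1L
  }

  # ring perception: a bond is in a ring iff it is not a bridge.  A cheap
  # union-find pass first detects forests (every bond a bridge), the
  # common case; otherwise igraph does the bridge finding.
  bond_in_ring <- logical(m)
  if (m) {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    has_cycle <- FALSE
    for (k in seq_len(m)) {
      ri <- find(bonds$i[k]); rj <- find(bonds$j[k])
      if (ri == rj) { has_cycle <- TRUE; break }
      parent[ri] <- rj
    }
    if (has_cycle) {
      ig <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j),
                                        directed = FALSE)
      br <- igraph::bridges(ig)
      bond_in_ring <- !(seq_len(m) %in% as.integer(br))
    }
  }
  atom_in_ring <- logical(n)
  if (any(bond_in_ring)) {
    ring_bonds <- bonds[bond_in_ring, , drop = FALSE]
    atom_in_ring[unique(c(ring_bonds$i, ring_bonds$j))] <- TRUE
  }

  # bond-order bookkeeping per atom
  ord_num <- if (m) .bond_order_num[bonds$order] else numeric(0)
  bond_sum <- numeric(n); n_double <- integer(n); n_triple <- integer(n)
  n_arom <- integer(n); degree <- integer(n)
  for (k in seq_len(m)) {
    i <- bonds$i[k]; j <- bonds$j[k]
    bond_sum[i] <- bond_sum[i] + ord_num[k]
    bond_sum[j] <- bond_sum[j] + ord_num[k]
    degree[i] <- degree[i] + 1L; degree[j] <- degree[j] + 1L
    if (bonds$order[k] == "double") { n_double[i] <- n_double[i] + 1L; n_double[j] <- n_double[j] + 1L }
    if (bonds$order[k] == "triple") { n_triple[i] <- n_triple[i] + 1L; n_triple[j] <- n_triple[j] + 1L }
    if (bonds$order[k] == "aromatic") { n_arom[i] <- n_arom[i] + 1L; n_arom[j] <- n_arom[j] + 1L }
  }
  aromatic <- aromatic | n_arom > 0L
  valence <- round(bond_sum + n_h, 6)

  hybrid <- vapply(seq_len(n), function(a) {
    if (degree[a] + n_h[a] == 0L) return("s")
    if (aromatic[a]) return("sp2")
    if (n_triple[a] >= 1L || n_double[a] >= 2L) return("sp")
    if (n_double[a] >= 1L) return("sp2")
    sigma <- degree[a] + n_h[a]
    if (sigma >= 6L) return("sp3d2")
    if (sigma == 5L) return("sp3d")
    "sp3"
  }, character(1))

  # pi systems for conjugation: multiple/aromatic bonds give atoms pi character
  pi_count <- n_double + n_triple + n_arom
  conjugated <- logical(m)
  for (k in seq_len(m)) {
    i <- bonds$i[k]; j <- bonds$j[k]
    conjugated[k] <- if (bonds$order[k] == "aromatic") TRUE
    else if (bonds$order[k] == "single") pi_count[i] >= 1L && pi_count[j] >= 1L
    else pi_count[i] >= 2L || pi_count[j] >= 2L
  }

  # vectorized featurization (same layout as featurize_atom/featurize_bond)
  atom_features <- matrix(0, n, 106L)
  rows <- seq_len(n)
  slot <- function(offset, idx) cbind(rows, offset + idx)
  atom_features[slot(0L, match(symbols, .element_table$symbol))] <- 1
  atom_features[slot(64L, ifelse(degree > 4L, 6L, degree + 1L))] <- 1
  atom_features[slot(70L, ifelse(charge < -3L | charge > 3L, 8L,
                                 charge + 4L))] <- 1
  hyb_idx <- match(hybrid, .hybridizations)
  hyb_idx[is.na(hyb_idx)] <- 7L
  atom_features[slot(78L, hyb_idx)] <- 1
  atom_features[slot(85L, pmin(pmax(round(valence), 1L), 6L))] <- 1
  atom_features[, 92L] <- as.numeric(atom_in_ring)
  atom_features[, 93L] <- as.numeric(aromatic)
  atom_features[, 94L] <- .element_scaled[symbols, "mass"]
  atom_features[, 95L] <- .element_scaled[symbols, "vdw"]
  atom_features[, 96L] <- .element_scaled[symbols, "cov"]
  chir_idx <- match(chirality, .chirality_types)
  chir_idx[is.na(chir_idx)] <- 4L
  atom_features[slot(96L, chir_idx)] <- 1
  atom_features[slot(100L, ifelse(n_h > 4L, 6L, n_h + 1L))] <- 1
  bond_features <- matrix(0, m, 6L)
  if (m) {
    bond_features[cbind(seq_len(m), match(bonds$order, .bond_orders))] <- 1
    bond_features[, 5L] <- as.numeric(conjugated)
    bond_features[, 6L] <- as.numeric(bond_in_ring)
  }
  bonds$in_ring <- bond_in_ring
  bonds$conjugated <- conjugated

  structure(list(
    atom_count = n,
    atom_symbols = symbols,
    adjacency = adjacency,
    atom_features = atom_features,
    bonds = bonds,
    bond_features = bond_features,
    charge = charge, n_h = n_h, chirality = chirality, map = map,
    aromatic = aromatic, in_ring = atom_in_ring, degree = degree,
    valence = valence, hybridization = hybrid
  ), class = "molgraph")
}

#' Build a molecular graph from a SMILES string
#'
#' Parses the SMILES, fills implicit hydrogens, perceives rings and
#' hybridization, and featurizes atoms and bonds.
#'
#' @param smiles SMILES string
#' @return a [molgraph]
#' @examples
#' mol_to_graph("c1ccccc1")$in_ring
#' @export
mol_to_graph <- function(smiles) parse_smiles(smiles)

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", x$atom_count, " heavy atoms, ", nrow(x$bonds),
      " bonds: ", write_smiles(x), "\n", sep = "")
  invisible(x)
}

#' Bond features over ordered atom pairs
#'
#' The bond feature matrix is stored with one row per bond; this helper
#' exposes the ordered-pair view in which pair (i,j) and pair (j,i) carry
#' identical rows.  With `dense = TRUE` a full `n^2 x 6` matrix is
#' returned (rows indexed by `(i-1)*n + j`), zero rows for non-bonded
#' pairs.
#'
#' @param graph a [molgraph]
#' @param dense return the dense `n^2` view
#' @return a matrix; the sparse view has columns `i`, `j` then the 6
#'   feature columns, one row per ordered pair
#' @export
bond_feature_rows <- function(graph, dense = FALSE) {
  g <- graph
  m <- nrow(g$bonds)
  if (dense) {
    n <- g$atom_count
    out <- matrix(0, n * n, ncol(g$bond_features))
    for (k in seq_len(m)) {
      i <- g$bonds$i[k]; j <- g$bonds$j[k]
      out[(i - 1L) * n + j, ] <- g$bond_features[k, ]
      out[(j - 1L) * n + i, ] <- g$bond_features[k, ]
    }
    return(out)
  }
  if (!m) return(cbind(i = integer(0), j = integer(0),
                       matrix(0, 0, ncol(g$bond_features))))
  rbind(cbind(i = g$bonds$i, j = g$bonds$j, g$bond_features),
        cbind(i = g$bonds$j, j = g$bonds$i, g$bond_features))
}

#' Dump a molecular graph as TSV tables
#'
#' Writes two debugging tables: `<stem>.atoms.tsv` (index, symbol, charge,
#' hydrogens, ring/aromatic flags, valence, hybridization, map number) and
#' `<stem>.bonds.tsv` (i, j, order, conjugated, in_ring).
#'
#' @param graph a [molgraph]
#' @param stem output path stem
#' @return invisibly, the two file paths
#' @export
graph_to_tsv <- function(graph, stem) {
  g <- graph
  atoms <- data.frame(index = seq_len(g$atom_count), symbol = g$atom_symbols,
                      charge = g$charge, n_h = g$n_h, in_ring = g$in_ring,
                      aromatic = g$aromatic, valence = g$valence,
                      hybridization = g$hybridization, map = g$map)
  paths <- paste0(stem, c(".atoms.tsv", ".bonds.tsv"))
  write.table(atoms, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(g$bonds, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Element multiset of a molecular graph
#'
#' Counts atoms per element, used for checking that reactions are
#' balanced.  By default only heavy atoms are counted: the mapping model
#' covers non-hydrogen atoms, and hydrogen-transfer edits legitimately
#' change the implicit hydrogen totals of the written species.
#'
#' @param graph a [molgraph]
#' @param include_h also count implicit hydrogens (as an `"H"` entry)
#' @return named integer vector of counts, elements sorted
#' @export
element_multiset <- function(graph, include_h = FALSE) {
  tab <- table(graph$atom_symbols)
  out <- setNames(as.integer(tab), names(tab))
  if (include_h) {
    h <- sum(graph$n_h)
    if (h > 0) out <- c(out, H = h)
  }
  out[order(names(out))]
}
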