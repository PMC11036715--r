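# Shared fixtures and independent oracles used across the test files.

# random connected graph with element labels, as a molgraph with permissive
# hydrogen counts (structure-only tests; no valence semantics intended)
random_connected_graph <- function(n, extra_edges = 2L,
                                   symbols = c("C", "N", "O")) {
  sym <- sample(symbols, n, replace = TRUE)
  bonds <- data.frame(i = integer(0), j = integer(0), order = character(0))
  if (n > 1L) {
    parent <- vapply(2:n, function(k) sample.int(k - 1L, 1L), integer(1))
    bonds <- data.frame(i = parent, j = 2:n, order = "single")
  }
  for (e in seq_len(extra_edges)) {
    cand <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    have <- paste(bonds$i, bonds$j)
    cand <- cand[!(paste(cand[, 1], cand[, 2]) %in% have) &
                 !(paste(cand[, 2], cand[, 1]) %in% have), , drop = FALSE]
    if (!nrow(cand)) break
    k <- cand[sample.int(nrow(cand), 1L), ]
    bonds <- rbind(bonds, data.frame(i = k[1], j = k[2], order = "single"))
  }
  molgraph(symbols = sym, bonds = bonds, n_h = rep(0L, n))
}

# independent orbit oracle: automorphism-group generators from igraph's
# BLISS backend (vertex-colored by element), closed into orbits by
# union-find
automorphism_orbits <- function(graph) {
  n <- graph$atom_count
  ig <- igraph::graph_from_adjacency_matrix(graph$adjacency != 0,
                                            mode = "undirected")
  colors <- as.integer(factor(graph$atom_symbols))
  gens <- igraph::automorphism_group(ig, colors = colors)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
  }
  for (g in gens) {
    perm <- as.integer(g)
    for (v in seq_len(n)) union_(v, perm[v])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), roots))
}

# brute-force permutation automorphisms for tiny graphs (validates the
# enumeration path independently of igraph)
brute_force_automorphisms <- function(graph) {
  n <- graph$atom_count
  stopifnot(n <= 8L)
  A <- graph$adjacency
  sym <- graph$atom_symbols
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), , drop = FALSE]
  keep <- apply(perms, 1, function(p) {
    all(sym[p] == sym) && all(A[p, p] == A)
  })
  perms[keep, , drop = FALSE]
}

# a reaction whose reactant carries exactly two independent topologically
# equivalent pairs (methyls {1,3} on one carbon and {5,6} on another), so
# exactly four symmetry-compatible mappings exist: identity, each single
# methyl swap, and the double swap.  The edit migrates the chlorine from
# carbon 4 to carbon 2, which preserves both pairs on the product side.
two_pair_reaction <- function() {
  gr <- parse_smiles("[CH3:1][CH:2]([CH3:3])[C:4]([CH3:5])([CH3:6])[Cl:7]")
  edits <- reaction_edits(lost_h = 2L, gained_h = 4L,
                          deleted_bonds = data.frame(i = 4L, j = 7L),
                          added_bonds = data.frame(i = 2L, j = 7L,
                                                   order = "single"))
  gp <- apply_edits(gr, edits)
  gt <- diag(gr$atom_count)
  storage.mode(gt) <- "integer"
  reaction(gr, gp, edits, gt)
}

identity_reaction <- function(smiles) {
  g <- parse_smiles(smiles)
  g$map <- seq_len(g$atom_count)
  gt <- diag(g$atom_count)
  storage.mode(gt) <- "integer"
  reaction(g, g, reaction_edits(), gt)
}

# tiny deterministic training set for matcher tests
tiny_training_set <- function(n = 12L, seed = 303L) {
  cfg <- generator_config(n_reactions = 10L, atom_range = c(5L, 8L),
                          edit_range = c(1L, 2L), symmetry_fraction = 0.3,
                          seed = seed)
  with_seed(seed, lapply(seq_len(n), function(k)
    generate_reaction(cfg, remap_seed = k)$reaction))
}
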