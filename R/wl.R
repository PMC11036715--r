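# Adapted Weisfeiler-Lehman refinement for detecting topologically
# equivalent atoms, plus enumeration of symmetry-compatible atom mappings.

#' Weisfeiler-Lehman label refinement
#'
#' Iteratively refines per-atom labels: at iteration 0 every atom is
#' labelled by its element symbol; at iteration t+1 an atom's label is the
#' canonical combination of its current label with the sorted multiset of
#' its neighbors' labels.  Canonical strings are used instead of integer
#' hashes, so label equality is collision-free.  Two atoms with equal
#' labels after `iterations` rounds have indistinguishable
#' `iterations`-hop neighborhoods.
#'
#' @param graph a [molgraph]
#' @param iterations number of refinement rounds (>= 0)
#' @param use_bond_order include the bond order to each neighbor in the
#'   neighbor token (stricter equivalence); default `FALSE`: labels
#'   augment atomic symbols only
#' @return object of class `"wl_coloring"`: list with `labels`, a list of
#'   per-atom character vectors for t = 0..iterations, and `partition`,
#'   the partition induced by the final labels
#' @examples
#' wl_refine(mol_to_graph("CCCCC"), 1)$partition
#' @export
wl_refine <- function(graph, iterations = 3L, use_bond_order = FALSE) {
  stopifnot(iterations >= 0)
  n <- graph$atom_count
  nbrs <- lapply(seq_len(n), function(i) which(graph$adjacency[i, ] > 0))
  border <- NULL
  if (use_bond_order) {
    border <- matrix("", n, n)
    for (k in seq_len(nrow(graph$bonds))) {
      i <- graph$bonds$i[k]; j <- graph$bonds$j[k]
      border[i, j] <- border[j, i] <- graph$bonds$order[k]
    }
  }
  labels <- vector("list", iterations + 1L)
  cur <- graph$atom_symbols
  labels[[1]] <- cur
  t <- 0L
  while (t < iterations) {
    # compress labels to compact ids each round to keep strings short
    ids <- match(cur, sort(unique(cur)))
    nxt <- vapply(seq_len(n), function(i) {
      tok <- if (use_bond_order) {
        paste0(border[i, nbrs[[i]]], ids[nbrs[[i]]])
      } else as.character(ids[nbrs[[i]]])
      paste0(ids[i], "|", paste(sort(tok), collapse = ","))
    }, character(1))
    cur <- nxt
    t <- t + 1L
    labels[[t + 1L]] <- cur
  }
  part <- unname(split(seq_len(n), match(cur, unique(cur))))
  structure(list(labels = labels, partition = part), class = "wl_coloring")
}

#' Topological-equivalence classes of atoms
#'
#' Partitions the atoms of a molecule into classes of topologically
#' equivalent atoms: atoms with the same atomic symbol whose three-hop
#' neighborhoods are indistinguishable under Weisfeiler-Lehman refinement.
#' Every class is non-empty; singleton classes mark atoms with no
#' equivalent partner.
#'
#' @param graph a [molgraph]
#' @param iterations number of WL rounds (default 3, the three-hop
#'   equivalence radius)
#' @param use_bond_order passed to [wl_refine()]
#' @return object of class `"equivalence_partition"`: list with `classes`
#'   (list of disjoint integer index vectors covering all atoms) and
#'   `class_of` (integer vector mapping atom index to class number)
#' @examples
#' equivalence_classes(mol_to_graph("CC(C)C"))$classes
#' @export
equivalence_classes <- function(graph, iterations = 3L,
                                use_bond_order = FALSE) {
  col <- wl_refine(graph, iterations, use_bond_order)
  classes <- col$partition
  class_of <- integer(graph$atom_count)
  for (ci in seq_along(classes)) class_of[classes[[ci]]] <- ci
  structure(list(classes = classes, class_of = class_of),
            class = "equivalence_partition")
}

#' @export
print.equivalence_partition <- function(x, ...) {
  for (cl in x$classes) cat("{", paste(cl, collapse = ", "), "}\n")
  invisible(x)
}

# all adjacency-preserving permutations of `graph` that move atoms only
# within their equivalence classes (a subgroup-restricted automorphism
# search), returned as a list of integer permutations
.class_automorphisms <- function(graph, partition, cap = 1e4) {
  n <- graph$atom_count
  class_of <- partition$class_of
  sizes <- vapply(partition$classes, length, integer(1))
  n_perm <- prod(factorial(sizes))
  if (n_perm > cap)
    stop("symmetric-mapping enumeration would explore ", format(n_perm),
         " candidate permutations, above the cap of ", format(cap),
         call. = FALSE)
  A <- graph$adjacency
  perms <- list(integer(0))
  # build permutations atom by atom, pruning by adjacency consistency with
  # already-placed atoms
  for (i in seq_len(n)) {
    cand_pool <- partition$classes[[class_of[i]]]
    new_perms <- list()
    for (p in perms) {
      placed <- seq_len(i - 1L)
      for (c in setdiff(cand_pool, p)) {
        if (all(A[i, placed] == A[c, p[placed]])) {
          new_perms[[length(new_perms) + 1L]] <- c(p, c)
        }
      }
    }
    perms <- new_perms
    if (!length(perms)) break
  }
  perms
}

#' Enumerate symmetry-compatible atom mappings
#'
#' Given a reaction with one known valid mapping, enumerates all
#' one-to-one mappings obtainable by permuting atoms within
#' topological-equivalence classes while preserving adjacency on both
#' sides.  A reactant with two independent equivalent pairs yields four
#' mappings (identity, each single swap, both swaps).
#'
#' @param reaction a [reaction] object (with `gt_matrix`)
#' @param partition_r,partition_p equivalence partitions of the reactant
#'   and product atoms; computed with [equivalence_classes()] when `NULL`
#' @param cap abort if the within-class permutation count exceeds this
#'   (default `1e4`)
#' @return list of binary correspondence matrices, each a valid
#'   permutation matrix; the known mapping is always included
#' @export
enumerate_symmetric_mappings <- function(reaction, partition_r = NULL,
                                         partition_p = NULL, cap = 1e4) {
  if (is.null(partition_r)) partition_r <- equivalence_classes(reaction$reactants)
  if (is.null(partition_p)) partition_p <- equivalence_classes(reaction$products)
  gt <- reaction$gt_matrix
  perm_gt <- apply(gt, 1, which.max)          # reactant i -> product perm_gt[i]
  auts_r <- .class_automorphisms(reaction$reactants, partition_r, cap)
  auts_p <- .class_automorphisms(reaction$products, partition_p, cap)
  n <- reaction$reactants$atom_count
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (ar in auts_r) {
    base <- perm_gt[ar]                        # gt after reactant-side symmetry
    for (ap in auts_p) {
      m <- ap[base]                            # then product-side symmetry
      key <- paste(m, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        M <- matrix(0L, n, reaction$products$atom_count)
        M[cbind(seq_len(n), m)] <- 1L
        out[[length(out) + 1L]] <- M
      }
    }
  }
  out
}
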