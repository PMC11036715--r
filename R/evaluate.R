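# Symmetry-tolerant evaluation: per-atom top-k hits, per-reaction
# correctness, and dataset-level accuracies.

#' Top-k hit for a single reactant atom
#'
#' A hit is registered when any member of the ground-truth product atom's
#' equivalence class appears among the first `k` ranked candidates, so
#' predicting a topologically equivalent partner counts as correct.  Pass
#' a partition of all-singleton classes for the strict (exact-index)
#' criterion.
#'
#' @param ranking integer vector of product atom indices, best first
#' @param gt_atom ground-truth product atom index
#' @param product_classes an `equivalence_partition` of the product atoms
#' @param k ranking depth (>= 1)
#' @return logical flag
#' @export
atom_hit_at_k <- function(ranking, gt_atom, product_classes, k) {
  stopifnot(k >= 1)
  if (gt_atom < 1L || gt_atom > length(product_classes$class_of))
    stop("ground-truth atom ", gt_atom, " outside the product atom range",
         call. = FALSE)
  cls <- product_classes$classes[[product_classes$class_of[gt_atom]]]
  any(utils::head(ranking, k) %in% cls)
}

#' Reaction-level correctness at depth k
#'
#' A reaction is correctly mapped at depth `k` iff every reactant atom
#' registers a hit at `k`.
#'
#' @param hits logical vector of per-atom hits at depth `k`
#' @return logical flag
#' @export
reaction_correct_at_k <- function(hits) all(hits)

#' Average accuracy over a result set
#'
#' The mean over reactions of each reaction's per-atom top-1 hit rate,
#' expressed as a percentage (a reaction-mean, not a pooled per-atom
#' mean).
#'
#' @param atom_hits list of per-reaction logical hit vectors at k = 1
#' @return percentage in \[0, 100\]
#' @export
average_accuracy <- function(atom_hits) {
  if (!length(atom_hits)) stop("empty result set", call. = FALSE)
  100 * mean(vapply(atom_hits, mean, numeric(1)))
}

#' Evaluate a fitted matcher on a reaction set
#'
#' Runs [predict.atom_matcher()] on every reaction and aggregates
#' symmetry-tolerant and strict metrics: the percentage of correctly
#' mapped reactions at each depth in `ks`, the average accuracy
#' (reaction-mean of top-1 atom hit rates) and its pooled per-atom
#' variant.
#'
#' @param model a fitted `atom_matcher`
#' @param reactions list of [reaction] objects with ground truth
#' @param ks ranking depths reported (default 1, 3, 5, 10)
#' @param symmetry_aware tolerate topologically equivalent product atoms
#'   (default `TRUE`); `FALSE` scores exact indices only
#' @param reaction_threshold fraction of atoms that must hit for a
#'   reaction to count as correct (default 1: all atoms)
#' @return object of class `"eval_report"`: list with `avg_accuracy`,
#'   `atom_accuracy` (pooled), `topk_reaction_pct` (named by k) and
#'   `per_reaction` (data frame with hit counts and per-k flags)
#' @export
evaluate_matcher <- function(model, reactions, ks = c(1L, 3L, 5L, 10L),
                             symmetry_aware = TRUE,
                             reaction_threshold = 1) {
  stopifnot(length(reactions) > 0)
  per <- lapply(reactions, function(rxn) {
    pred <- predict(model, rxn)
    classes <- if (symmetry_aware) pred$product_classes else {
      np <- rxn$products$atom_count
      structure(list(classes = as.list(seq_len(np)),
                     class_of = seq_len(np)),
                class = "equivalence_partition")
    }
    gt <- apply(rxn$gt_matrix, 1, which.max)
    n <- length(gt)
    hits_k <- vapply(ks, function(k) {
      vapply(seq_len(n), function(i)
        atom_hit_at_k(pred$ranking[i, ], gt[i], classes, k), logical(1))
    }, logical(n))
    if (!is.matrix(hits_k)) hits_k <- matrix(hits_k, nrow = 1L)
    list(hits1 = hits_k[, 1], atoms = n,
         correct = colMeans(hits_k) >= reaction_threshold - 1e-12)
  })
  correct_mat <- do.call(rbind, lapply(per, `[[`, "correct"))
  topk <- 100 * colMeans(correct_mat)
  names(topk) <- paste0("top", ks)
  hits1 <- lapply(per, `[[`, "hits1")
  structure(list(
    avg_accuracy = average_accuracy(hits1),
    atom_accuracy = 100 * mean(unlist(hits1)),
    topk_reaction_pct = topk,
    ks = ks,
    symmetry_aware = symmetry_aware,
    per_reaction = data.frame(
      atoms = vapply(per, `[[`, integer(1), "atoms"),
      atom_hits = vapply(hits1, sum, numeric(1)),
      correct_mat)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", nrow(x$per_reaction), " reactions (",
      if (x$symmetry_aware) "symmetry-aware" else "strict", ")\n", sep = "")
  cat(sprintf("  average accuracy: %.1f%% (pooled per-atom: %.1f%%)\n",
              x$avg_accuracy, x$atom_accuracy))
  for (i in seq_along(x$ks))
    cat(sprintf("  reactions correct at top@%d: %.1f%%\n", x$ks[i],
                x$topk_reaction_pct[i]))
  invisible(x)
}
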