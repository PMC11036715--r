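# The learned core: shared-weight graph encoder, affinity computation,
# softmax normalization, symmetry pooling, negative log-likelihood loss,
# training loop and prediction.

#' Pairwise affinity between two embedding matrices
#'
#' `affinity_matrix(H_R, H_P)[i, j]` is the inner product of reactant-atom
#' embedding i with product-atom embedding j.
#'
#' @param h_r,h_p embedding matrices with equal column counts
#' @return the raw affinity matrix
#' @export
affinity_matrix <- function(h_r, h_p) {
  if (ncol(h_r) != ncol(h_p))
    stop("embedding widths differ: ", ncol(h_r), " vs ", ncol(h_p),
         call. = FALSE)
  h_r %*% t(h_p)
}

#' Softmax normalization of an affinity matrix
#'
#' Turns raw affinities into matching probabilities.  The default axis,
#' `"per_reactant_atom"`, makes each reactant atom's row a probability
#' distribution over product candidates (the distribution the loss and
#' the top-k evaluation read); `"per_product_atom"` normalizes each
#' column over reactant atoms instead.  Numerically stabilized by
#' max-subtraction.
#'
#' @param m_hat raw affinity matrix (finite entries)
#' @param axis `"per_reactant_atom"` or `"per_product_atom"`
#' @return matrix of probabilities; every slice along the chosen axis
#'   sums to 1
#' @examples
#' normalize_affinity(matrix(0, 2, 4))
#' @export
normalize_affinity <- function(m_hat, axis = c("per_reactant_atom",
                                               "per_product_atom")) {
  axis <- match.arg(axis)
  softmax_rows <- function(m) {
    e <- exp(m - apply(m, 1, max))
    e / rowSums(e)
  }
  if (axis == "per_reactant_atom") softmax_rows(m_hat)
  else t(softmax_rows(t(m_hat)))
}

#' Pool matching probabilities over product equivalence classes
#'
#' Aggregates the probability mass that a reactant atom assigns to all
#' topologically equivalent product atoms: `M[i, j]` becomes the sum of
#' `m_tilde[i, j']` over every `j'` in the class of `j`.  All members of
#' a class therefore share one pooled value per row, which is how the
#' model avoids being penalized for not distinguishing equivalent atoms.
#'
#' @param m_tilde probability matrix (reactant x product)
#' @param product_classes an `equivalence_partition` of the product atoms
#' @return the pooled matrix, entrywise no smaller than `m_tilde`
#' @export
symmetry_pool <- function(m_tilde, product_classes) {
  class_of <- product_classes$class_of
  if (length(class_of) != ncol(m_tilde))
    stop("partition does not cover the product atoms: ", length(class_of),
         " classes entries vs ", ncol(m_tilde), " columns", call. = FALSE)
  n_cl <- length(product_classes$classes)
  # sum columns within each class, then broadcast back to members
  cl_mass <- matrix(0, nrow(m_tilde), n_cl)
  for (ci in seq_len(n_cl)) {
    cols <- product_classes$classes[[ci]]
    cl_mass[, ci] <- rowSums(m_tilde[, cols, drop = FALSE])
  }
  cl_mass[, class_of, drop = FALSE]
}

#' Negative log-likelihood of the ground-truth correspondence
#'
#' `-sum_i log M[i, gt(i)]`, the training objective.  Probabilities are
#' clamped at `eps` before the log (a warning reports any clamped cell).
#'
#' @param m probability matrix (possibly symmetry-pooled)
#' @param gt integer vector: `gt[i]` is the product atom of reactant atom
#'   i, or a binary permutation matrix
#' @param eps clamp for zero probabilities
#' @return nonnegative scalar; 0 iff every ground-truth probability is 1
#' @export
matcher_nll <- function(m, gt, eps = 1e-12) {
  if (is.matrix(gt)) gt <- apply(gt, 1, which.max)
  p <- m[cbind(seq_len(nrow(m)), gt)]
  if (any(p < eps)) {
    warning("clamped ", sum(p < eps), " zero probability cell(s) at eps = ",
            eps, call. = FALSE)
    p <- pmax(p, eps)
  }
  -sum(log(p))
}

# forward pass for one reaction: embeddings, affinity, probabilities,
# pooled matrix and loss; returns everything needed for the reverse pass
.reaction_forward <- function(prep, params, cfg) {
  fr <- .encode(prep$gc_r, params, cfg$mp_layers, cfg$aggregate,
                cfg$jumping_knowledge)
  fp <- .encode(prep$gc_p, params, cfg$mp_layers, cfg$aggregate,
                cfg$jumping_knowledge)
  m_hat <- affinity_matrix(fr$H, fp$H)
  m_tilde <- normalize_affinity(m_hat, cfg$normalization_axis)
  pooled <- if (cfg$use_symmetry) symmetry_pool(m_tilde, prep$classes_p)
            else m_tilde
  p <- pooled[cbind(seq_len(nrow(pooled)), prep$gt_perm)]
  loss <- -sum(log(pmax(p, 1e-12)))
  list(fr = fr, fp = fp, m_hat = m_hat, m_tilde = m_tilde, pooled = pooled,
       loss = loss)
}

# gradient of the loss w.r.t. the raw affinity matrix, through pooling and
# the softmax on the configured axis
.affinity_grad <- function(fwd, prep, cfg) {
  m_tilde <- fwd$m_tilde
  n <- nrow(m_tilde)
  d_tilde <- matrix(0, n, ncol(m_tilde))
  p <- fwd$pooled[cbind(seq_len(n), prep$gt_perm)]
  p <- pmax(p, 1e-12)
  if (cfg$use_symmetry) {
    class_of <- prep$classes_p$class_of
    gt_class <- class_of[prep$gt_perm]
    # d loss / d m_tilde[i, j'] = -1/p_i for every j' in the gt class of i
    for (i in seq_len(n)) {
      cols <- which(class_of == gt_class[i])
      d_tilde[i, cols] <- -1 / p[i]
    }
  } else {
    d_tilde[cbind(seq_len(n), prep$gt_perm)] <- -1 / p
  }
  softmax_bwd_rows <- function(dy, y) y * (dy - rowSums(dy * y))
  if (cfg$normalization_axis == "per_reactant_atom") {
    softmax_bwd_rows(d_tilde, m_tilde)
  } else {
    t(softmax_bwd_rows(t(d_tilde), t(m_tilde)))
  }
}

# full reverse pass for one reaction, accumulating into `grads`
.reaction_backward <- function(fwd, prep, params, grads, cfg) {
  d_hat <- .affinity_grad(fwd, prep, cfg)
  dH_r <- d_hat %*% fwd$fp$H
  dH_p <- crossprod(d_hat, fwd$fr$H)
  grads <- .encode_bwd(dH_r, fwd$fr, prep$gc_r, params, grads,
                       cfg$mp_layers, cfg$aggregate, cfg$jumping_knowledge)
  .encode_bwd(dH_p, fwd$fp, prep$gc_p, params, grads,
              cfg$mp_layers, cfg$aggregate, cfg$jumping_knowledge)
}

.prep_reaction <- function(rxn, wl_iterations) {
  list(gc_r = .graph_cache(rxn$reactants),
       gc_p = .graph_cache(rxn$products),
       classes_p = equivalence_classes(rxn$products, wl_iterations),
       classes_r = equivalence_classes(rxn$reactants, wl_iterations),
       gt_perm = apply(rxn$gt_matrix, 1, which.max),
       reaction = rxn)
}

.mean_loss <- function(preps, params, cfg) {
  mean(vapply(preps, function(pr) {
    .reaction_forward(pr, params, cfg)$loss / pr$gc_r$n
  }, numeric(1)))
}

#' Fit the atom matching model
#'
#' Trains a shared-weight graph isomorphism network encoder so that the
#' softmax-normalized inner products of reactant and product atom
#' embeddings recover the ground-truth atom correspondence.  The loss is
#' the negative log-likelihood of the ground-truth cells of the
#' correspondence matrix after pooling probability mass over classes of
#' topologically equivalent product atoms (disable with
#' `use_symmetry = FALSE` to train the symmetry-blind variant).
#' Optimization is Adam with a fixed learning rate, per-minibatch updates
#' and early stopping on validation loss; the returned parameters are
#' those of the best validation epoch.  Training is deterministic given
#' `seed`.
#'
#' @param train list of [reaction] objects
#' @param val optional validation list; defaults to `train` (early
#'   stopping then monitors training loss)
#' @param embed_dim embedding width per layer (desk-scale default 64; 512
#'   reproduces the full-scale setting)
#' @param mp_layers number of message-passing layers (default 3)
#' @param learning_rate Adam learning rate (default 1e-4)
#' @param epochs maximum number of epochs
#' @param batch_size reactions per parameter update
#' @param patience early-stopping patience in epochs
#' @param min_delta minimum validation-loss improvement counted as progress
#' @param aggregate neighbor aggregation: `"sum"` (default), `"mean"` or
#'   `"max"`
#' @param normalization_axis see [normalize_affinity()]
#' @param jumping_knowledge concatenate embeddings from all layers
#'   (default `TRUE`); otherwise only the last layer is used
#' @param use_symmetry pool over product equivalence classes in the loss
#' @param wl_iterations WL rounds defining equivalence (default 3)
#' @param seed integer seed controlling init and batch order
#' @param verbose print per-epoch losses
#' @return an object of class `"atom_matcher"` with elements `params`,
#'   `config`, `history` (data frame of per-epoch train/val loss) and
#'   `best_epoch`
#' @seealso [predict.atom_matcher()], [evaluate_matcher()]
#' @export
fit_atom_matcher <- function(train, val = NULL, embed_dim = 64L,
                             mp_layers = 3L, learning_rate = 1e-4,
                             epochs = 50L, batch_size = 16L,
                             patience = 10L, min_delta = 1e-4,
                             aggregate = c("sum", "mean", "max"),
                             normalization_axis = c("per_reactant_atom",
                                                    "per_product_atom"),
                             jumping_knowledge = TRUE, use_symmetry = TRUE,
                             wl_iterations = 3L, seed = 1L,
                             verbose = FALSE) {
  stopifnot(length(train) > 0, embed_dim >= 1L, mp_layers >= 1L,
            learning_rate > 0)
  cfg <- list(embed_dim = as.integer(embed_dim),
              mp_layers = as.integer(mp_layers),
              learning_rate = learning_rate,
              aggregate = match.arg(aggregate),
              normalization_axis = match.arg(normalization_axis),
              jumping_knowledge = jumping_knowledge,
              use_symmetry = use_symmetry,
              wl_iterations = as.integer(wl_iterations),
              batch_size = as.integer(batch_size),
              patience = as.integer(patience), min_delta = min_delta,
              seed = as.integer(seed))
  schema <- feature_schema()
  params <- .init_params(schema$atom_len, schema$bond_len, cfg$embed_dim,
                         cfg$mp_layers, .sub_seed(seed, 17L))
  preps <- lapply(train, .prep_reaction, wl_iterations = cfg$wl_iterations)
  vpreps <- if (is.null(val)) preps
            else lapply(val, .prep_reaction, wl_iterations = cfg$wl_iterations)
  state <- .adam_state(params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = params, epoch = 0L)
  stall <- 0L
  for (ep in seq_len(epochs)) {
    ord <- with_seed(.sub_seed(seed, ep), sample.int(length(preps)))
    ep_loss <- 0
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      batch <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      grads <- .zero_like(params)
      for (bi in batch) {
        pr <- preps[[bi]]
        fwd <- .reaction_forward(pr, params, cfg)
        if (!is.finite(fwd$loss))
          stop("training diverged: non-finite loss at epoch ", ep,
               " (reaction ", bi, ")", call. = FALSE)
        ep_loss <- ep_loss + fwd$loss / pr$gc_r$n
        grads <- .reaction_backward(fwd, pr, params, grads, cfg)
      }
      grads <- lapply(grads, function(g) g / length(batch))
      upd <- .adam_step(params, grads, state, cfg$learning_rate)
      params <- upd$params; state <- upd$state
    }
    train_loss <- ep_loss / length(preps)
    val_loss <- if (is.null(val)) train_loss else .mean_loss(vpreps, params, cfg)
    history <- rbind(history, data.frame(epoch = ep, train_loss = train_loss,
                                         val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep, train_loss,
                      val_loss))
    if (val_loss < best$loss - min_delta) {
      best <- list(loss = val_loss, params = params, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  structure(list(params = best$params, config = cfg, history = history,
                 best_epoch = best$epoch, best_val_loss = best$loss),
            class = "atom_matcher")
}

#' Embed one molecular graph with a trained (or given) parameter set
#'
#' @param graph a [molgraph]
#' @param params parameter list as stored in an `atom_matcher`
#' @param config matcher configuration list (fields `mp_layers`,
#'   `aggregate`, `jumping_knowledge`)
#' @return embedding matrix, one row per atom; with jumping knowledge the
#'   width is `(mp_layers + 1) * embed_dim`
#' @export
embed_graph <- function(graph, params, config) {
  if (ncol(params$W_in) != config$embed_dim ||
      nrow(params$W_in) != ncol(graph$atom_features))
    stop("parameter shapes do not match the configuration", call. = FALSE)
  .encode(.graph_cache(graph), params, config$mp_layers, config$aggregate,
          config$jumping_knowledge)$H
}

#' Predict the atom mapping of a reaction
#'
#' Computes the correspondence probabilities for one reaction and derives
#' (i) the per-reactant-atom ranking of product candidates (descending
#' probability, ties broken by ascending atom index) and (ii) a one-to-one
#' mapping, by default the greedy highest-probability assignment without
#' column reuse, or the optimal linear assignment with
#' `assignment = "optimal"`.
#'
#' @param object a fitted `atom_matcher`
#' @param reaction a [reaction] (its `gt_matrix` is not consulted)
#' @param assignment `"greedy"` or `"optimal"`
#' @param ... unused
#' @return list with `probabilities` (the normalized matrix), `affinity`,
#'   `pooled`, `ranking` (|V_R| x |V_P| matrix of product indices, best
#'   first) and `mapping` (integer vector: reactant atom i -> product
#'   atom `mapping[i]`)
#' @export
predict.atom_matcher <- function(object, reaction,
                                 assignment = c("greedy", "optimal"), ...) {
  assignment <- match.arg(assignment)
  cfg <- object$config
  h_r <- embed_graph(reaction$reactants, object$params, cfg)
  h_p <- embed_graph(reaction$products, object$params, cfg)
  m_hat <- affinity_matrix(h_r, h_p)
  m_tilde <- normalize_affinity(m_hat, cfg$normalization_axis)
  classes_p <- equivalence_classes(reaction$products, cfg$wl_iterations)
  pooled <- symmetry_pool(m_tilde, classes_p)
  ranking <- t(apply(m_tilde, 1, function(row)
    order(-row, seq_along(row))))
  if (!is.matrix(ranking)) ranking <- matrix(ranking, nrow = 1L)
  mapping <- if (assignment == "greedy") .greedy_assign(m_tilde)
             else .optimal_assign(m_tilde)
  list(probabilities = m_tilde, affinity = m_hat, pooled = pooled,
       ranking = ranking, mapping = mapping, product_classes = classes_p)
}

# greedy global assignment: repeatedly take the highest remaining cell
.greedy_assign <- function(m) {
  n <- nrow(m); p <- ncol(m)
  mapping <- integer(n)
  work <- m
  for (step in seq_len(min(n, p))) {
    k <- which.max(work)
    i <- (k - 1L) %% n + 1L
    j <- (k - 1L) %/% n + 1L
    mapping[i] <- j
    work[i, ] <- -Inf
    work[, j] <- -Inf
  }
  mapping
}

# optimal linear assignment (maximize total probability) via the Hungarian
# shortest-augmenting-path algorithm on the negated square matrix
.optimal_assign <- function(m) {
  n <- nrow(m); p <- ncol(m)
  stopifnot(n <= p)
  cost <- -m
  u <- numeric(n + 1L); v <- numeric(p + 1L)
  way <- integer(p + 1L)
  match_col <- integer(p + 1L)   # column -> row
  for (i in seq_len(n)) {
    match_col[p + 1L] <- i
    j0 <- p + 1L
    minv <- rep(Inf, p); used <- logical(p + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- match_col[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(p)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(p + 1L)) {
        if (used[j]) {
          if (match_col[j] > 0L) u[match_col[j]] <- u[match_col[j]] + delta
          v[j] <- v[j] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (match_col[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      match_col[j0] <- match_col[j1]
      j0 <- j1
      if (j0 == p + 1L) break
    }
  }
  mapping <- integer(n)
  for (j in seq_len(p)) if (match_col[j] > 0L) mapping[match_col[j]] <- j
  mapping
}

#' @export
print.atom_matcher <- function(x, ...) {
  cfg <- x$config
  cat("<atom_matcher> GIN encoder, ", cfg$mp_layers, " layers x ",
      cfg$embed_dim, " dims",
      if (cfg$jumping_knowledge) " (jumping knowledge)", "\n", sep = "")
  cat("  symmetry pooling: ", if (cfg$use_symmetry) "on" else "off",
      "; normalization: ", cfg$normalization_axis, "\n", sep = "")
  cat("  trained ", nrow(x$history), " epochs; best epoch ", x$best_epoch,
      " (val loss ", format(x$best_val_loss, digits = 5), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.atom_matcher <- function(object, ...) {
  n_par <- sum(vapply(object$params, length, numeric(1)))
  cat("Atom matching model\n")
  print(object)
  cat("  parameters: ", n_par, "\n", sep = "")
  cat("  final train loss ",
      format(utils::tail(object$history$train_loss, 1), digits = 5),
      ", final val loss ",
      format(utils::tail(object$history$val_loss, 1), digits = 5), "\n",
      sep = "")
  invisible(object)
}

#' @export
coef.atom_matcher <- function(object, ...) object$params

#' @export
plot.atom_matcher <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "mean per-atom NLL", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}

#' Save / load a matcher checkpoint
#'
#' Serializes the configuration, weights and training history to a
#' versioned JSON file (plain text, portable across platforms).
#'
#' @param model an `atom_matcher`
#' @param path output path
#' @return `save_matcher`: invisibly, `path`; `load_matcher`: the
#'   restored `atom_matcher`
#' @export
save_matcher <- function(model, path) {
  payload <- list(schema_version = 1L,
                  config = model$config,
                  history = model$history,
                  best_epoch = model$best_epoch,
                  best_val_loss = model$best_val_loss,
                  params = lapply(model$params, function(p) {
                    list(dim = if (is.matrix(p)) dim(p) else integer(0),
                         data = as.numeric(p))
                  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_matcher
#' @export
load_matcher <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$schema_version) || payload$schema_version != 1L)
    stop("unsupported checkpoint schema", call. = FALSE)
  params <- lapply(payload$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1], p$dim[2]) else p$data
  })
  structure(list(params = params, config = as.list(payload$config),
                 history = as.data.frame(payload$history),
                 best_epoch = payload$best_epoch,
                 best_val_loss = payload$best_val_loss),
            class = "atom_matcher")
}
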