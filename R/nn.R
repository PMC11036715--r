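# Internal neural-network machinery for the atom matcher: a shared-weight
# graph isomorphism network (GIN) encoder with an additive learned
# transform of bond features in the neighbor messages, jumping-knowledge
# concatenation across layers, and a hand-rolled reverse pass with Adam.
# All maths is plain base-R matrix algebra; molecules are small, so dense
# operations are the fast path.

.glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -s, s), n_in, n_out)
}

# parameter container: input projection + per-layer GIN blocks
.init_params <- function(feat_len, edge_len, embed_dim, mp_layers, seed) {
  with_seed(seed, {
    p <- list(W_in = .glorot(feat_len, embed_dim), b_in = numeric(embed_dim))
    for (l in seq_len(mp_layers)) {
      p[[paste0("We", l)]] <- .glorot(edge_len, embed_dim)
      p[[paste0("W1", l)]] <- .glorot(embed_dim, embed_dim)
      p[[paste0("b1", l)]] <- numeric(embed_dim)
      p[[paste0("W2", l)]] <- .glorot(embed_dim, embed_dim)
      p[[paste0("b2", l)]] <- numeric(embed_dim)
    }
    p
  })
}

.zero_like <- function(params) lapply(params, function(p) p * 0)

# per-graph constants reused across epochs
.graph_cache <- function(g) {
  n <- g$atom_count
  Re <- matrix(0, n, ncol(g$bond_features))
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    Re[i, ] <- Re[i, ] + g$bond_features[k, ]
    Re[j, ] <- Re[j, ] + g$bond_features[k, ]
  }
  deg <- pmax(g$degree, 1L)
  nbrs <- lapply(seq_len(n), function(i) which(g$adjacency[i, ] > 0))
  list(X = g$atom_features, A = g$adjacency * 1, Re = Re, deg = deg,
       nbrs = nbrs, n = n)
}

.aggregate_fwd <- function(h, gc, aggregate) {
  if (aggregate == "sum") return(list(m = gc$A %*% h, arg = NULL))
  if (aggregate == "mean") return(list(m = (gc$A %*% h) / gc$deg, arg = NULL))
  # max: per-atom componentwise max over neighbor embeddings (0 if none)
  n <- gc$n; d <- ncol(h)
  m <- matrix(0, n, d); arg <- matrix(0L, n, d)
  for (i in seq_len(n)) {
    nb <- gc$nbrs[[i]]
    if (!length(nb)) next
    sub <- h[nb, , drop = FALSE]
    w <- max.col(t(sub), ties.method = "first")
    m[i, ] <- sub[cbind(w, seq_len(d))]
    arg[i, ] <- nb[w]
  }
  list(m = m, arg = arg)
}

.aggregate_bwd <- function(dz, gc, aggregate, arg) {
  if (aggregate == "sum") return(gc$A %*% dz)          # A symmetric
  if (aggregate == "mean") return(gc$A %*% (dz / gc$deg))
  n <- gc$n; d <- ncol(dz)
  out <- matrix(0, n, d)
  for (i in seq_len(n)) {
    a <- arg[i, ]
    live <- which(a > 0L)
    for (k in live) out[a[k], k] <- out[a[k], k] + dz[i, k]
  }
  out
}

# forward pass through the encoder; returns the jumping-knowledge
# concatenation (or the last layer only) plus the cache for backprop
.encode <- function(gc, params, mp_layers, aggregate, jumping_knowledge) {
  h <- sweep(gc$X %*% params$W_in, 2, params$b_in, "+")
  hs <- list(h)
  cache <- list()
  for (l in seq_len(mp_layers)) {
    agg <- .aggregate_fwd(h, gc, aggregate)
    z <- h + agg$m + gc$Re %*% params[[paste0("We", l)]]
    a <- sweep(z %*% params[[paste0("W1", l)]], 2, params[[paste0("b1", l)]], "+")
    r <- pmax(a, 0)
    h <- sweep(r %*% params[[paste0("W2", l)]], 2, params[[paste0("b2", l)]], "+")
    cache[[l]] <- list(z = z, a = a, r = r, arg = agg$arg)
    hs[[l + 1L]] <- h
  }
  H <- if (jumping_knowledge) do.call(cbind, hs) else h
  list(H = H, hs = hs, cache = cache)
}

# reverse pass; accumulates parameter gradients into `grads` and returns it
.encode_bwd <- function(dH, fwd, gc, params, grads, mp_layers, aggregate,
                        jumping_knowledge) {
  d <- ncol(params$W_in)
  if (jumping_knowledge) {
    dhs <- lapply(seq_len(mp_layers + 1L), function(l)
      dH[, ((l - 1L) * d + 1L):(l * d), drop = FALSE])
  } else {
    dhs <- c(rep(list(matrix(0, gc$n, d)), mp_layers), list(dH))
  }
  g <- dhs[[mp_layers + 1L]]
  for (l in rev(seq_len(mp_layers))) {
    cc <- fwd$cache[[l]]
    grads[[paste0("W2", l)]] <- grads[[paste0("W2", l)]] + crossprod(cc$r, g)
    grads[[paste0("b2", l)]] <- grads[[paste0("b2", l)]] + colSums(g)
    dr <- g %*% t(params[[paste0("W2", l)]])
    da <- dr * (cc$a > 0)
    grads[[paste0("W1", l)]] <- grads[[paste0("W1", l)]] + crossprod(cc$z, da)
    grads[[paste0("b1", l)]] <- grads[[paste0("b1", l)]] + colSums(da)
    dz <- da %*% t(params[[paste0("W1", l)]])
    grads[[paste0("We", l)]] <- grads[[paste0("We", l)]] + crossprod(gc$Re, dz)
    g <- dhs[[l]] + dz + .aggregate_bwd(dz, gc, aggregate, cc$arg)
  }
  grads$W_in <- grads$W_in + crossprod(gc$X, g)
  grads$b_in <- grads$b_in + colSums(g)
  grads
}

.adam_state <- function(params) {
  list(m = .zero_like(params), v = .zero_like(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}
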