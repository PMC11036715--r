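test_that("affinity matrix equals the scalar-product oracle", {
  set.seed(1)
  h_r <- matrix(rnorm(5 * 7), 5)
  h_p <- matrix(rnorm(6 * 7), 6)
  m <- affinity_matrix(h_r, h_p)
  oracle <- matrix(0, 5, 6)
  for (i in 1:5) for (j in 1:6) oracle[i, j] <- sum(h_r[i, ] * h_p[j, ])
  expect_equal(m, oracle, tolerance = 1e-12)
  # orthonormal rows give the identity
  q <- qr.Q(qr(matrix(rnorm(16), 4)))
  expect_equal(affinity_matrix(q, q), diag(4), tolerance = 1e-12)
  # identical embeddings give a symmetric Gram matrix
  expect_true(isSymmetric(affinity_matrix(h_r, h_r)))
  expect_error(affinity_matrix(h_r, matrix(0, 3, 4)), "widths differ")
})

test_that("softmax normalization matches closed forms and invariances", {
  m <- normalize_affinity(matrix(0, 3, 4))
  expect_equal(m, matrix(0.25, 3, 4))
  # shift invariance per slice
  set.seed(2)
  raw <- matrix(rnorm(12), 3)
  shifted <- raw + 5
  expect_equal(normalize_affinity(raw), normalize_affinity(shifted),
               tolerance = 1e-12)
  # hand-computed 2x2 softmax
  m2 <- normalize_affinity(matrix(c(log(2), 0, 0, log(2)), 2, byrow = TRUE))
  expect_equal(m2, matrix(c(2 / 3, 1 / 3, 1 / 3, 2 / 3), 2, byrow = TRUE),
               tolerance = 1e-12)
  # every slice sums to 1 for arbitrary finite input, both axes
  for (rep in 1:10) {
    raw <- matrix(rnorm(35, sd = 10), 5)
    expect_equal(rowSums(normalize_affinity(raw)), rep(1, 5),
                 tolerance = 1e-6)
    expect_equal(colSums(normalize_affinity(raw, "per_product_atom")),
                 rep(1, 7), tolerance = 1e-6)
  }
})

test_that("symmetry pooling aggregates class mass and conserves row sums", {
  singles <- structure(list(classes = as.list(1:4), class_of = 1:4),
                       class = "equivalence_partition")
  m <- matrix(runif(12), 3)
  expect_equal(symmetry_pool(m, singles), m, ignore_attr = TRUE)

  part <- structure(list(classes = list(c(1L, 2L), 3L, 4L),
                         class_of = c(1L, 1L, 2L, 3L)),
                    class = "equivalence_partition")
  u <- matrix(0.25, 2, 4)
  pooled <- symmetry_pool(u, part)
  expect_equal(pooled[, 1], c(0.5, 0.5))
  expect_equal(pooled[, 2], c(0.5, 0.5))
  # pooled never smaller than the raw probabilities
  expect_true(all(pooled >= u - 1e-12))
  # mass aggregated per class representative equals the original row sums
  reps <- vapply(part$classes, `[`, integer(1), 1)
  expect_equal(rowSums(pooled[, reps, drop = FALSE]), rowSums(u))
  # the split-mass ambiguity collapses to certainty at the true class
  split_mass <- matrix(c(0.5, 0.5, 0, 0), 1)
  expect_equal(symmetry_pool(split_mass, part)[1, 1], 1.0)
  expect_error(symmetry_pool(matrix(0, 2, 5), part), "partition")
})

test_that("negative log-likelihood matches its closed forms", {
  gt <- 1:4
  perm <- diag(4)
  expect_equal(matcher_nll(perm, gt), 0)
  u <- matrix(0.25, 4, 4)
  expect_equal(matcher_nll(u, gt), 4 * log(4), tolerance = 1e-9)
  # increasing a ground-truth cell (renormalized) strictly decreases loss
  m <- matrix(0.25, 4, 4)
  m[1, ] <- c(0.4, 0.2, 0.2, 0.2)
  expect_lt(matcher_nll(m, gt), matcher_nll(u, gt))
  # zero cells are clamped with a warning
  z <- diag(4); z[1, 1] <- 0
  expect_warning(l <- matcher_nll(z, gt), "clamp")
  expect_true(is.finite(l))
})

test_that("encoder gradients agree with finite differences", {
  rxn <- tiny_training_set(1)[[1]]
  prep <- atommatch:::.prep_reaction(rxn, 3L)
  cfg <- list(embed_dim = 4L, mp_layers = 2L, aggregate = "sum",
              normalization_axis = "per_reactant_atom",
              jumping_knowledge = TRUE, use_symmetry = TRUE,
              wl_iterations = 3L)
  schema <- feature_schema()
  params <- atommatch:::.init_params(schema$atom_len, schema$bond_len,
                                     4L, 2L, seed = 11L)
  fwd <- atommatch:::.reaction_forward(prep, params, cfg)
  grads <- atommatch:::.reaction_backward(fwd, prep, params,
                                          atommatch:::.zero_like(params), cfg)
  eps <- 1e-6
  set.seed(3)
  for (k in names(params)) {
    for (ii in sample(length(params[[k]]), min(3, length(params[[k]])))) {
      p2 <- params
      p2[[k]][ii] <- p2[[k]][ii] + eps
      lp <- atommatch:::.reaction_forward(prep, p2, cfg)$loss
      p2[[k]][ii] <- p2[[k]][ii] - 2 * eps
      lm <- atommatch:::.reaction_forward(prep, p2, cfg)$loss
      expect_equal(grads[[k]][ii], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("the encoder is equivariant under atom permutation", {
  g <- mol_to_graph("CC(N)C(=O)OCC1CC1Cl")
  schema <- feature_schema()
  cfg <- list(embed_dim = 8L, mp_layers = 3L, aggregate = "sum",
              jumping_knowledge = TRUE)
  params <- atommatch:::.init_params(schema$atom_len, schema$bond_len,
                                     8L, 3L, seed = 4L)
  h <- embed_graph(g, params, cfg)
  set.seed(8)
  for (rep in 1:3) {
    perm <- sample.int(g$atom_count)
    hp <- embed_graph(atommatch:::.permute_graph(g, perm), params, cfg)
    expect_lt(max(abs(hp[perm, ] - h)), 1e-5)
  }
  # and for mean/max aggregation too
  for (agg in c("mean", "max")) {
    cfg$aggregate <- agg
    h <- embed_graph(g, params, cfg)
    perm <- sample.int(g$atom_count)
    hp <- embed_graph(atommatch:::.permute_graph(g, perm), params, cfg)
    expect_lt(max(abs(hp[perm, ] - h)), 1e-5)
  }
})

test_that("topologically equivalent atoms get identical embeddings and slices", {
  g <- mol_to_graph("CC(C)C")   # methyls 1, 3, 4 equivalent
  schema <- feature_schema()
  cfg <- list(embed_dim = 8L, mp_layers = 3L, aggregate = "sum",
              jumping_knowledge = TRUE,
              normalization_axis = "per_reactant_atom")
  params <- atommatch:::.init_params(schema$atom_len, schema$bond_len,
                                     8L, 3L, seed = 5L)
  h <- embed_graph(g, params, cfg)
  part <- equivalence_classes(g)
  for (cl in part$classes[lengths(part$classes) > 1]) {
    for (other in cl[-1]) {
      expect_equal(h[cl[1], ], h[other, ], tolerance = 1e-10)
    }
  }
  # hence identical rows/columns of the probability matrix: the mechanism
  # behind the split-mass ambiguity on symmetric molecules
  m <- normalize_affinity(affinity_matrix(h, h))
  cl <- part$classes[lengths(part$classes) > 1][[1]]
  expect_equal(m[cl[1], ], m[cl[2], ], tolerance = 1e-10)
  expect_equal(m[, cl[1]], m[, cl[2]], tolerance = 1e-10)
})

test_that("training is deterministic, converges on a tiny set, and stops early", {
  rxn <- tiny_training_set(1, seed = 404L)[[1]]
  train <- rep(list(rxn), 50)
  m1 <- fit_atom_matcher(train, embed_dim = 16L, mp_layers = 2L,
                         learning_rate = 1e-3, epochs = 40L,
                         batch_size = 16L, seed = 9L)
  m2 <- fit_atom_matcher(train, embed_dim = 16L, mp_layers = 2L,
                         learning_rate = 1e-3, epochs = 40L,
                         batch_size = 16L, seed = 9L)
  expect_identical(m1$history, m2$history)
  # training loss decreases over the first epochs and overfits to < 0.1
  expect_true(all(diff(m1$history$train_loss[1:5]) < 0))
  expect_lt(min(m1$history$train_loss), 0.1)
  # identity prediction on the overfitted reaction, up to equivalence
  pred <- predict(m1, rxn)
  gt <- apply(rxn$gt_matrix, 1, which.max)
  cls <- pred$product_classes$class_of
  expect_equal(cls[pred$mapping], cls[gt])
})

test_that("shape mismatches and divergence guards raise errors", {
  schema <- feature_schema()
  params <- atommatch:::.init_params(schema$atom_len, schema$bond_len,
                                     4L, 2L, seed = 1L)
  g <- mol_to_graph("CCO")
  expect_error(embed_graph(g, params, list(embed_dim = 8L, mp_layers = 2L,
                                           aggregate = "sum",
                                           jumping_knowledge = TRUE)),
               "shapes")
})

test_that("rankings are complete and assignments match the brute-force optimum", {
  set.seed(12)
  rxn <- tiny_training_set(1, seed = 505L)[[1]]
  m <- fit_atom_matcher(list(rxn), embed_dim = 8L, mp_layers = 2L,
                        epochs = 2L, seed = 2L)
  pred <- predict(m, rxn)
  np <- rxn$products$atom_count
  expect_equal(dim(pred$ranking), c(rxn$reactants$atom_count, np))
  for (i in seq_len(nrow(pred$ranking))) {
    expect_setequal(pred$ranking[i, ], seq_len(np))
  }
  # optimal assignment equals exhaustive search over permutations (small n)
  brute_best <- function(p) {
    n <- nrow(p)
    perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    perms <- perms[apply(perms, 1, function(q) !anyDuplicated(q)), ,
                   drop = FALSE]
    scores <- apply(perms, 1, function(q) sum(p[cbind(seq_len(n), q)]))
    max(scores)
  }
  for (rep in 1:5) {
    p <- matrix(runif(25), 5)
    got <- atommatch:::.optimal_assign(p)
    expect_equal(sum(p[cbind(1:5, got)]), brute_best(p), tolerance = 1e-10)
  }
  # greedy agrees with optimal on diagonally dominant matrices
  for (rep in 1:5) {
    p <- matrix(runif(36, 0, 0.1), 6)
    d <- sample.int(6)
    p[cbind(1:6, d)] <- 0.5 + runif(6, 0, 0.4)
    expect_equal(atommatch:::.greedy_assign(p), atommatch:::.optimal_assign(p))
  }
})

test_that("checkpoints round-trip through the JSON schema", {
  rxn <- tiny_training_set(1, seed = 606L)[[1]]
  m <- fit_atom_matcher(list(rxn), embed_dim = 6L, mp_layers = 2L,
                        epochs = 3L, seed = 3L)
  path <- tempfile(fileext = ".json")
  save_matcher(m, path)
  m2 <- load_matcher(path)
  expect_equal(m2$params, m$params, tolerance = 1e-12)
  expect_equal(m2$config$embed_dim, m$config$embed_dim)
  p1 <- predict(m, rxn)$probabilities
  p2 <- predict(m2, rxn)$probabilities
  expect_equal(p1, p2, tolerance = 1e-12)
})
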