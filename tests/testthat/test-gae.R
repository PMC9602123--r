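# Graph auto-encoder: initialization, the worked 1x1 forward example,
# aggregation, decoder symmetry, the loss closed forms, negative sampling,
# the finite-difference gradient check, and training behaviour.

# All-ones parameters for hand-worked forward passes.
unit_params <- function(config, n_m, n_d) {
  p <- gae_init_params(config, n_m, n_d, seed = 1)
  p$W_m[] <- 1; p$W_d[] <- 1; p$Q[] <- 1
  for (l in seq_len(config$L)) {
    p$layers_m[[l]]$W[] <- 1; p$layers_m[[l]]$b[] <- 0
    p$layers_d[[l]]$W[] <- 1; p$layers_d[[l]]$b[] <- 0
  }
  p
}

named_square <- function(vals, ids) {
  S <- matrix(vals, length(ids), length(ids), dimnames = list(ids, ids))
  S
}

test_that("initialization is seed-deterministic with the right shapes", {
  cfg <- gae_config(E = 3, L = 2)
  p1 <- gae_init_params(cfg, 5, 4, seed = 9)
  p2 <- gae_init_params(cfg, 5, 4, seed = 9)
  expect_identical(p1, p2)
  p3 <- gae_init_params(cfg, 5, 4, seed = 10)
  expect_false(identical(p1$W_m, p3$W_m))

  expect_equal(dim(p1$W_m), c(3L, 5L))
  expect_equal(dim(p1$W_d), c(3L, 4L))
  expect_equal(dim(p1$Q), c(3L, 3L))
  expect_length(p1$layers_m, 2L)
  expect_equal(dim(p1$layers_m[[1]]$W), c(3L, 6L))
  expect_length(p1$layers_m[[1]]$b, 3L)
  expect_equal(unname(p1$layers_m[[1]]$b), rep(0, 3))

  cfg1 <- gae_config(E = 1, L = 1)
  pmin <- gae_init_params(cfg1, 1, 1, seed = 1)
  expect_equal(dim(pmin$layers_m[[1]]$W), c(1L, 2L))
})

test_that("the 1-miRNA/1-disease unit forward pass reproduces the hand result", {
  cfg <- gae_config(E = 1, L = 1)
  p <- unit_params(cfg, 1, 1)
  msim <- named_square(1, "m1"); dsim <- named_square(1, "d1")
  A <- matrix(1, 1, 1, dimnames = list("m1", "d1"))
  emb <- gae_encode(p, msim, dsim, A, cfg)
  expect_equal(unname(emb$H_m[1, 1]), 2)  # 1 (self) + 1 (aggregate)
  expect_equal(unname(emb$H_d[1, 1]), 2)
  sc <- gae_decode(p, emb$H_m, emb$H_d)
  expect_equal(unname(sc[1, 1]), plogis(4))  # sigmoid(2 * 1 * 2)
})

test_that("neighbour aggregation is the degree-normalized sum", {
  Nm <- mirgae:::degree_normalized(matrix(c(1, 1), 1, 2))
  Hd <- rbind(c(1, 2), c(3, 4))
  expect_equal(unname(Nm %*% Hd), matrix(c(2, 3), 1, 2))
  # degree-0 node aggregates to the zero vector
  N0 <- mirgae:::degree_normalized(matrix(0, 1, 2))
  expect_equal(unname(N0 %*% Hd), matrix(0, 1, 2))
})

test_that("zero weights give zero embeddings and all-0.5 scores", {
  cfg <- gae_config(E = 2, L = 2)
  p <- gae_init_params(cfg, 3, 2, seed = 1)
  p <- mirgae:::map_params(function(x) x * 0, p)
  msim <- random_similarity(paste0("m", 1:3), 1)
  dsim <- random_similarity(paste0("d", 1:2), 2)
  A <- matrix(rbinom(6, 1, 0.5), 3, 2, dimnames = list(rownames(msim), rownames(dsim)))
  emb <- gae_encode(p, msim, dsim, A, cfg)
  expect_true(all(emb$H_m == 0) && all(emb$H_d == 0))
  expect_true(all(gae_decode(p, emb$H_m, emb$H_d) == 0.5))
})

test_that("negating Q maps every score s to 1 - s", {
  cfg <- gae_config(E = 3, L = 1)
  p <- gae_init_params(cfg, 4, 3, seed = 2)
  H_m <- matrix(rnorm(12), 4, 3)
  H_d <- matrix(rnorm(9), 3, 3)
  s1 <- gae_decode(p, H_m, H_d)
  p$Q <- -p$Q
  expect_equal(gae_decode(p, H_m, H_d), 1 - s1)
  expect_true(all(s1 > 0 & s1 < 1))
})

test_that("weighted cross-entropy matches its closed forms", {
  n <- 4L
  samples <- tibble::tibble(i = rep(1:n, 2), j = rep(c(1L, 2L), each = n),
                            label = rep(c(1L, 0L), each = n))
  half <- matrix(0.5, n, 2)
  expect_equal(weighted_bce_loss(half, samples, 1), 2 * n * log(2))

  # perfect scores: bounded by the clip floor
  perfect <- matrix(0, n, 2)
  perfect[, 1] <- 1  # the positive column
  expect_lt(weighted_bce_loss(perfect, samples, 2), 2 * n * 1e-6)

  # pos_weight scales only the positive terms (two-term hand sum)
  two <- tibble::tibble(i = c(1L, 2L), j = c(1L, 1L), label = c(1L, 0L))
  sc <- matrix(c(0.8, 0.3), 2, 1)
  expect_equal(weighted_bce_loss(sc, two, 2),
               -(2 * log(0.8) + log(0.7)))
  expect_error(weighted_bce_loss(half, samples[0, ], 1), regexp = "empty")
})

test_that("negative sampling is uniform over allowed zeros and seed-deterministic", {
  A <- matrix(0, 5, 4, dimnames = list(paste0("m", 1:5), paste0("d", 1:4)))
  A[1, 1] <- A[2, 2] <- 1
  s1 <- sample_negatives(A, 6, seed = 3)
  s2 <- sample_negatives(A, 6, seed = 3)
  expect_identical(s1, s2)
  expect_true(all(A[cbind(s1$i, s1$j)] == 0))
  expect_false(identical(s1, sample_negatives(A, 6, seed = 4)))

  # excluding all zero cells but k forces exactly those k
  zeros <- which(A == 0, arr.ind = TRUE)
  keep <- zeros[1:3, , drop = FALSE]
  excl <- tibble::tibble(i = zeros[-(1:3), 1], j = zeros[-(1:3), 2])
  forced <- sample_negatives(A, 3, seed = 1, exclude = excl)
  expect_setequal(paste(forced$i, forced$j), paste(keep[, 1], keep[, 2]))
  expect_error(sample_negatives(A, 19, seed = 1), regexp = "zero cells")
})

test_that("analytic gradients match central finite differences (4x3, E=2, L=2)", {
  cfg <- gae_config(E = 2, L = 2)
  set.seed(42)
  msim <- random_similarity(paste0("m", 1:4), 31)
  dsim <- random_similarity(paste0("d", 1:3), 32)
  A <- matrix(rbinom(12, 1, 0.5), 4, 3, dimnames = list(rownames(msim), rownames(dsim)))
  A[1, 1] <- 1
  params <- gae_init_params(cfg, 4, 3, seed = 7)
  samples <- tibble::tibble(i = c(1L, 2L, 3L, 4L, 1L, 2L),
                            j = c(1L, 2L, 3L, 1L, 2L, 3L),
                            label = c(1L, 1L, 0L, 0L, 1L, 0L))
  lg <- mirgae:::gae_loss_grads(params, msim, dsim, A, samples, cfg)

  h <- 1e-5
  max_rel <- 0
  check <- function(get, set, grad) {
    for (k in seq_along(grad)) {
      pp <- params; v <- get(pp); v[k] <- v[k] + h
      l1 <- mirgae:::gae_loss_grads(set(pp, v), msim, dsim, A, samples, cfg)$loss
      pp <- params; v <- get(pp); v[k] <- v[k] - h
      l2 <- mirgae:::gae_loss_grads(set(pp, v), msim, dsim, A, samples, cfg)$loss
      num <- (l1 - l2) / (2 * h)
      rel <- abs(num - grad[k]) / max(1e-8, abs(num) + abs(grad[k]))
      max_rel <<- max(max_rel, rel)
    }
  }
  check(function(p) p$W_m, function(p, v) { p$W_m[] <- v; p }, lg$grads$W_m)
  check(function(p) p$W_d, function(p, v) { p$W_d[] <- v; p }, lg$grads$W_d)
  check(function(p) p$Q, function(p, v) { p$Q[] <- v; p }, lg$grads$Q)
  for (l in 1:2) {
    check(function(p) p$layers_m[[l]]$W,
          function(p, v) { p$layers_m[[l]]$W[] <- v; p }, lg$grads$layers_m[[l]]$W)
    check(function(p) p$layers_m[[l]]$b,
          function(p, v) { p$layers_m[[l]]$b[] <- v; p }, lg$grads$layers_m[[l]]$b)
    check(function(p) p$layers_d[[l]]$W,
          function(p, v) { p$layers_d[[l]]$W[] <- v; p }, lg$grads$layers_d[[l]]$W)
    check(function(p) p$layers_d[[l]]$b,
          function(p, v) { p$layers_d[[l]]$b[] <- v; p }, lg$grads$layers_d[[l]]$b)
  }
  expect_lt(max_rel, 1e-4)
})

test_that("the forward pass stays finite and shape-valid across L = 1..8", {
  set.seed(6)
  msim <- random_similarity(paste0("m", 1:5), 61)
  dsim <- random_similarity(paste0("d", 1:4), 62)
  A <- matrix(rbinom(20, 1, 0.4), 5, 4, dimnames = list(rownames(msim), rownames(dsim)))
  for (L in 1:8) {
    cfg <- gae_config(E = 4, L = L)
    p <- gae_init_params(cfg, 5, 4, seed = L)
    emb <- gae_encode(p, msim, dsim, A, cfg)
    expect_equal(dim(emb$H_m), c(5L, 4L))
    expect_equal(dim(emb$H_d), c(4L, 4L))
    expect_true(all(is.finite(emb$H_m)) && all(is.finite(emb$H_d)))
  }
})

test_that("relabelling nodes permutes scores identically", {
  cfg <- gae_config(E = 3, L = 2)
  set.seed(15)
  msim <- random_similarity(paste0("m", 1:5), 71)
  dsim <- random_similarity(paste0("d", 1:4), 72)
  A <- matrix(rbinom(20, 1, 0.4), 5, 4, dimnames = list(rownames(msim), rownames(dsim)))
  p <- gae_init_params(cfg, 5, 4, seed = 3)
  emb <- gae_encode(p, msim, dsim, A, cfg)
  S <- gae_decode(p, emb$H_m, emb$H_d)

  pm <- sample(5); pd <- sample(4)
  pp <- p
  pp$W_m <- p$W_m[, pm]  # permute feature axis with the nodes
  pp$W_d <- p$W_d[, pd]
  emb2 <- gae_encode(pp, msim[pm, pm], dsim[pd, pd], A[pm, pd], cfg)
  S2 <- gae_decode(pp, emb2$H_m, emb2$H_d)
  expect_equal(unname(S2), unname(S[pm, pd]))
})

test_that("training reduces the loss, is seed-deterministic, and flags divergence", {
  fix <- make_fixture("tiny", seed = 2)
  msim <- random_similarity(rownames(fix$associations), 81)
  dsim <- random_similarity(colnames(fix$associations), 82)
  pos <- association_pairs(fix$associations)
  cfg <- quick_config()
  fit <- gae_train(cfg, msim, dsim, pos, seed = 5)
  expect_lt(fit$history$loss[nrow(fit$history)], fit$history$loss[1])
  expect_equal(nrow(fit$history), cfg$epochs)

  fit2 <- gae_train(cfg, msim, dsim, pos, seed = 5)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params, fit2$params)

  S <- predict(fit)
  expect_equal(dim(S), dim(fix$associations))
  expect_true(all(S > 0 & S < 1))

  expect_error(gae_train(cfg, msim, dsim, pos[0, ], seed = 1), regexp = "positives")
  expect_error(gae_config(epochs = 0))
})

test_that("tidy, glance and autoplot expose the fit", {
  fix <- make_fixture("tiny", seed = 3)
  msim <- random_similarity(rownames(fix$associations), 91)
  dsim <- random_similarity(colnames(fix$associations), 92)
  fit <- gae_train(quick_config(), msim, dsim, association_pairs(fix$associations),
                   seed = 1)
  td <- tidy(fit)
  expect_named(td, c("epoch", "loss"))
  gl <- glance(fit)
  expect_equal(gl$n_mirna, 12L)
  expect_lt(gl$final_loss, gl$first_loss)
  expect_s3_class(autoplot(fit), "ggplot")
})
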