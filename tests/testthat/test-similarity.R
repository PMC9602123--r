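# Similarity construction: metric micro-examples, DAG semantic similarity,
# GIP kernels, integration, and the matrix invariants on random fixtures.

test_that("feature similarity reproduces hand-computed pairs", {
  X <- rbind(a = c(1, 0), b = c(1, 1))
  expect_equal(feature_similarity(X, "cosine")["a", "b"], 1 / sqrt(2))

  X <- rbind(a = c(1, 2, 3), b = c(3, 2, 1))
  expect_equal(feature_similarity(X, "pearson")["a", "b"], -1)

  X <- rbind(a = c(0, 0), b = c(3, 4))
  expect_equal(feature_similarity(X, "euclidean")["a", "b"], 1 / 6)

  X <- rbind(a = c(2, 5, 1), b = c(2, 5, 1))
  for (m in c("cosine", "euclidean", "pearson")) {
    expect_equal(feature_similarity(X, m)["a", "b"], 1)
  }
})

test_that("zero-norm and constant rows give similarity 0, never NaN", {
  X <- rbind(a = c(0, 0, 0), b = c(1, 2, 3))
  suppressMessages({
    expect_equal(feature_similarity(X, "cosine")["a", "b"], 0)
    expect_equal(feature_similarity(X, "pearson")["a", "b"], 0)
  })
  Xc <- rbind(a = c(2, 2, 2), b = c(1, 2, 3))  # constant row under pearson
  suppressMessages(expect_equal(feature_similarity(Xc, "pearson")["a", "b"], 0))
  expect_true(all(is.finite(suppressMessages(feature_similarity(X, "cosine")))))
})

test_that("feature similarity matches the per-pair loop oracle on random inputs", {
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(2:6, 1); d <- sample(2:10, 1)
    X <- matrix(rnorm(n * d), n, d, dimnames = list(paste0("m", 1:n), NULL))
    for (metric in c("cosine", "euclidean", "pearson")) {
      got <- feature_similarity(X, metric)
      want <- oracle_similarity(X, metric)
      expect_lt(max(abs(unname(got) - want)), 1e-12)
    }
  }
})

test_that("similarity matrices satisfy symmetry, diagonal and range invariants", {
  set.seed(9)
  # non-negative rows (the descriptor encoders emit frequencies)
  X <- matrix(runif(40), 5, 8, dimnames = list(paste0("m", 1:5), NULL))
  for (metric in c("cosine", "euclidean", "pearson")) {
    S <- feature_similarity(X, metric)
    expect_symmetric_unit_diag(S)
    if (metric == "pearson") {
      expect_true(all(S >= -1 - 1e-12 & S <= 1 + 1e-12))
    } else {
      expect_true(all(S >= -1e-12 & S <= 1 + 1e-12))
    }
  }
  # arbitrary real features still give finite symmetric matrices
  Xr <- matrix(rnorm(40), 5, 8, dimnames = list(paste0("m", 1:5), NULL))
  for (metric in c("cosine", "euclidean", "pearson")) {
    expect_symmetric_unit_diag(feature_similarity(Xr, metric))
  }
})

test_that("semantic contributions follow the attenuated best-path rule", {
  chain <- disease_dag(list(g = "R", p = "R.1", d = "R.1.1"))
  sc <- semantic_contribution(chain, "d")
  expect_equal(sort(unname(sc$contribution), decreasing = TRUE), c(1, 0.5, 0.25))
  expect_equal(sc$dv, 1.75)

  solo <- disease_dag(list(x = "Z"))
  sc <- semantic_contribution(solo, "x")
  expect_equal(unname(sc$contribution), 1)
  expect_equal(sc$dv, 1)

  # diamond: ancestor reachable at depths 1 and 2 takes the max, 0.5
  diamond <- disease_dag(list(d = c("A.1", "A.2.3")))
  sc <- semantic_contribution(diamond, "d")
  expect_equal(unname(sc$contribution["A"]), 0.5)

  expect_error(semantic_contribution(chain, "nope"), class = "mirgae_key_error")
})

test_that("semantic contribution equals exhaustive path enumeration on random DAGs", {
  set.seed(21)
  for (rep in 1:15) {
    n <- sample(3:10, 1)
    codes <- replicate(n, paste(sample(1:3, sample(1:4, 1), replace = TRUE),
                                collapse = "."))
    dag <- disease_dag(setNames(as.list(codes), paste0("d", 1:n)))
    for (dis in dag$disease_ids) {
      sc <- semantic_contribution(dag, dis)
      own <- dag$tree_numbers[[dis]]
      for (nd in names(sc$contribution)) {
        # exhaustive: delta^(min hops from any of the disease's own codes)
        hops <- integer(0)
        for (code in own) {
          cur <- code; h <- 0
          repeat {
            if (cur == nd) { hops <- c(hops, h); break }
            cur <- mirgae:::code_parent(cur)
            h <- h + 1
            if (is.na(cur)) break
          }
        }
        expect_equal(unname(sc$contribution[nd]), 0.5^min(hops))
      }
    }
  }
})

test_that("sibling diseases under one parent have semantic similarity 1/3", {
  dag <- disease_dag(list(A = "P.1", B = "P.2"))
  S <- semantic_similarity(dag)
  expect_equal(S["A", "B"], 1 / 3)
  expect_equal(unname(diag(S)), c(1, 1))

  disjoint <- disease_dag(list(A = "P.1", B = "Q.1"))
  expect_equal(semantic_similarity(disjoint)["A", "B"], 0)
})

test_that("GIP kernel matches hand-computed bandwidth and distances", {
  A <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("m1", "m2"), c("d1", "d2")))
  S <- gip_similarity(A, "mirna")
  expect_equal(S["m1", "m2"], exp(-2))  # sigma = 1, squared distance 2
  expect_equal(unname(diag(S)), c(1, 1))

  # identical profiles
  A2 <- matrix(c(1, 1, 0, 0), 2, 2, dimnames = list(c("m1", "m2"), c("d1", "d2")))
  expect_equal(gip_similarity(A2, "mirna")["m1", "m2"], 1)

  # appending all-zero disease columns changes nothing
  A3 <- cbind(A, matrix(0, 2, 3, dimnames = list(NULL, c("z1", "z2", "z3"))))
  expect_equal(unname(gip_similarity(A3, "mirna")), unname(S), ignore_attr = TRUE)

  expect_error(gip_similarity(A * 0, "mirna"), class = "mirgae_degenerate_error")
})

test_that("GIP kernel is equivariant under simultaneous row/column permutation", {
  set.seed(13)
  A <- matrix(rbinom(48, 1, 0.3), 6, 8,
              dimnames = list(paste0("m", 1:6), paste0("d", 1:8)))
  A[1, 1] <- 1
  pm <- sample(6); pd <- sample(8)
  for (axis in c("mirna", "disease")) {
    S <- gip_similarity(A, axis)
    Sp <- gip_similarity(A[pm, pd], axis)
    perm <- if (axis == "mirna") pm else pd
    expect_equal(unname(Sp), unname(S[perm, perm]), ignore_attr = TRUE)
  }
})

test_that("integration takes the primary entry only when both ids have data", {
  ids <- c("x", "y", "z")
  P <- random_similarity(ids, seed = 1)
  G <- random_similarity(ids, seed = 2)
  attr(G, "source_tag") <- "mgsm"
  expect_equal(unname(integrate_similarity(P, G, rep(TRUE, 3))), unname(P),
               ignore_attr = TRUE)
  expect_equal(unname(integrate_similarity(P, G, rep(FALSE, 3))), unname(G),
               ignore_attr = TRUE)

  S <- integrate_similarity(P, G, c(TRUE, FALSE, TRUE))
  expect_equal(S["x", "z"], P["x", "z"])
  expect_equal(S["x", "y"], G["x", "y"])
  expect_equal(S["y", "z"], G["y", "z"])
  expect_symmetric_unit_diag(S)

  G2 <- random_similarity(rev(ids), seed = 3)
  expect_error(integrate_similarity(P, G2), class = "mirgae_alignment_error")
})

test_that("five encoders by three metrics yield 15 distinct similarity products", {
  cat <- mssm_catalog()
  expect_equal(nrow(cat), 15L)
  expect_equal(length(unique(cat$tag)), 15L)
  expect_setequal(unique(cat$encoder),
                  c("kmer", "cksnap", "moran", "geary", "nmbroto"))
})
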