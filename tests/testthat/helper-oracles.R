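# Independent brute-force oracles and small in-code fixtures shared by the
# test files. Oracles are deliberately naive (explicit loops, exhaustive
# enumeration) and share no code with the package implementation.

RNA <- c("A", "C", "G", "U")

random_rna <- function(n) paste(sample(RNA, n, replace = TRUE), collapse = "")

# -- descriptor oracles ------------------------------------------------------

oracle_kmer <- function(seq) {
  n <- nchar(seq)
  out <- numeric(0)
  for (a in RNA) for (b in RNA) for (ch in RNA) {
    kmer <- paste0(a, b, ch)
    cnt <- 0
    for (i in seq_len(n - 2)) {
      if (substr(seq, i, i + 2) == kmer) cnt <- cnt + 1
    }
    out[kmer] <- cnt / n
  }
  out
}

oracle_cksnap <- function(seq, kmax = 5) {
  s <- chartr("U", "T", seq)
  L <- nchar(s)
  dna <- c("A", "C", "G", "T")
  out <- numeric(0)
  for (g in 0:kmax) {
    for (a in dna) for (b in dna) {
      cnt <- 0
      for (i in seq_len(L)) {
        jj <- i + g + 1
        if (jj <= L && substr(s, i, i) == a && substr(s, jj, jj) == b) cnt <- cnt + 1
      }
      out[paste0(a, b, ".gap", g)] <- cnt / (L - g - 1)
    }
  }
  out
}

# Per-position standardized property profile of a sequence.
oracle_profile <- function(seq, table, prop) {
  n <- nchar(seq) - 1
  vapply(seq_len(n), function(i) {
    di <- substr(seq, i, i + 1)
    table$values[prop, di]
  }, numeric(1))
}

oracle_moran <- function(m, d) {
  n <- length(m)
  mbar <- sum(m) / n
  den <- sum((m - mbar)^2) / n
  if (den == 0) return(0)
  num <- 0
  for (i in seq_len(n - d)) num <- num + (m[i] - mbar) * (m[i + d] - mbar)
  (num / (n - d)) / den
}

oracle_geary <- function(m, d) {
  n <- length(m)
  mbar <- sum(m) / n
  den <- sum((m - mbar)^2) / (n - 1)
  if (den == 0) return(0)
  num <- 0
  for (i in seq_len(n - d)) num <- num + (m[i] - m[i + d])^2
  (num / (2 * (n - d))) / den
}

oracle_nmbroto <- function(m, d) {
  n <- length(m)
  num <- 0
  for (i in seq_len(n - d)) num <- num + m[i] * m[i + d]
  num / (n - d)
}

# -- similarity oracles ------------------------------------------------------

oracle_similarity <- function(X, metric) {
  n <- nrow(X)
  S <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    x <- X[a, ]; y <- X[b, ]
    S[a, b] <- switch(metric,
      cosine = {
        den <- sqrt(sum(x^2)) * sqrt(sum(y^2))
        if (den == 0) 0 else sum(x * y) / den
      },
      pearson = {
        xc <- x - mean(x); yc <- y - mean(y)
        den <- sqrt(sum(xc^2)) * sqrt(sum(yc^2))
        if (den == 0) 0 else sum(xc * yc) / den
      },
      euclidean = 1 / (1 + sqrt(sum((x - y)^2)))
    )
  }
  diag(S) <- 1
  S
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# -- small in-code fixtures --------------------------------------------------

# A synthetic standardized property table with `k` properties over the 16
# RNA dinucleotides (seeded), exercising the autocorrelation encoders
# without touching the packaged default values.
synthetic_property_table <- function(k = 3, seed = 1) {
  dinucs <- as.vector(outer(RNA, RNA, paste0))
  dinucs <- dinucs[order(dinucs)]
  set.seed(seed)
  vals <- matrix(rnorm(k * 16), k, 16,
                 dimnames = list(paste0("prop", seq_len(k)), dinucs))
  std <- t(apply(vals, 1, function(v) (v - mean(v)) / sd(v)))
  dimnames(std) <- dimnames(vals)
  structure(
    list(properties = rownames(vals), dinucleotides = dinucs,
         raw = vals, values = std, standardized = TRUE),
    class = "rna_property_table"
  )
}

# Square symmetric unit-diagonal matrix with random entries (seeded).
random_similarity <- function(ids, seed = 1) {
  n <- length(ids)
  set.seed(seed)
  S <- matrix(runif(n * n), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  S
}

# A small config that keeps training fast in unit tests.
quick_config <- function(...) {
  gae_config(E = 8, L = 2, epochs = 40, ...)
}

expect_symmetric_unit_diag <- function(S, tol = 1e-9) {
  expect_lt(max(abs(S - t(S))), tol)
  expect_equal(unname(diag(S)), rep(1, nrow(S)))
  expect_true(all(is.finite(S)))
}
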