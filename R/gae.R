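# Bipartite graph auto-encoder: linear feature projection, L rounds of
# degree-normalized neighbour aggregation through LeakyReLU perceptron
# layers (Jacobi-style simultaneous update on both sides), a bilinear
# sigmoid decoder, and cost-sensitive cross-entropy trained with Adam.
# Forward pass and analytic gradients are written out by hand and verified
# against finite differences in the test suite.

#' Graph auto-encoder configuration
#'
#' @param E Projection (embedding) dimension, default 64.
#' @param L Number of encoder layers, default 6.
#' @param leaky_slope Negative-side slope of LeakyReLU, default 0.01.
#' @param learning_rate Adam step size, default 1e-3.
#' @param epochs Full-graph gradient steps, default 200.
#' @param pos_weight Weight of the positive-class loss term (>= 1), default 1
#'   (negative sampling is already balanced).
#' @param neg_ratio Negatives sampled per positive, default 1.
#' @param clip_norm Global gradient-norm ceiling per step (default 5000,
#'   roughly the 90th percentile of healthy full-graph gradient norms at
#'   this scale); `Inf` disables clipping. Guards against the late-training
#'   oscillation the unbounded bilinear logits can trigger.
#' @param threshold Classification threshold on decoder scores, default 0.5.
#' @param feature,metric Encoder tag and similarity metric used when a
#'   pipeline builds the sequence-similarity input from FASTA.
#' @param nlag,kmax Sequence-encoder tuning.
#' @return A `gae_config` list.
#' @export
gae_config <- function(E = 64L, L = 6L, leaky_slope = 0.01,
                       learning_rate = 1e-3, epochs = 200L,
                       pos_weight = 1, neg_ratio = 1, clip_norm = 5000,
                       threshold = 0.5,
                       feature = "cksnap", metric = "pearson",
                       nlag = 3L, kmax = 5L) {
  stopifnot(E >= 1L, L >= 1L, epochs >= 1L, leaky_slope >= 0,
            learning_rate > 0, pos_weight >= 1, neg_ratio > 0,
            clip_norm > 0, threshold > 0, threshold < 1)
  structure(
    list(E = as.integer(E), L = as.integer(L), leaky_slope = leaky_slope,
         learning_rate = learning_rate, epochs = as.integer(epochs),
         pos_weight = pos_weight, neg_ratio = neg_ratio,
         clip_norm = clip_norm, threshold = threshold,
         feature = feature, metric = metric,
         nlag = as.integer(nlag), kmax = as.integer(kmax)),
    class = "gae_config"
  )
}

#' Read a gae_config from a JSON file
#'
#' Keys absent from the file keep their defaults.
#'
#' @param path JSON file path.
#' @return A `gae_config`.
#' @export
read_gae_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(gae_config))
  unknown <- setdiff(names(vals), c(known, "seed"))
  if (length(unknown) > 0L) {
    abort_format("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(gae_config, vals[intersect(names(vals), known)])
}

glorot <- function(nrow, ncol) {
  b <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -b, b), nrow, ncol)
}

#' Initialize graph auto-encoder parameters
#'
#' Weights are drawn from a zero-mean scaled uniform scheme (bounds
#' +/- sqrt(6 / (fan_in + fan_out))), biases start at zero; draws are fully
#' determined by `seed`.
#'
#' @param config A [gae_config()].
#' @param n_m,n_d Numbers of miRNA and disease nodes.
#' @param seed Integer seed.
#' @return A `gae_params` list: projections `W_m` (E x n_m) and `W_d`
#'   (E x n_d), per-side per-layer perceptron weights (E x 2E) and biases,
#'   and the bilinear decoder matrix `Q` (E x E).
#' @export
gae_init_params <- function(config, n_m, n_d, seed = 1L) {
  stopifnot(inherits(config, "gae_config"), n_m >= 1L, n_d >= 1L)
  E <- config$E
  with_seed(seed, {
    layers <- function() {
      lapply(seq_len(config$L), function(l)
        list(W = glorot(E, 2L * E), b = numeric(E)))
    }
    structure(
      list(
        W_m = glorot(E, n_m),
        W_d = glorot(E, n_d),
        layers_m = layers(),
        layers_d = layers(),
        Q = glorot(E, E)
      ),
      class = "gae_params"
    )
  })
}

lrelu <- function(x, slope) ifelse(x > 0, x, slope * x)
dlrelu <- function(x, slope) ifelse(x > 0, 1, slope)

# Row-degree-normalized adjacency: row i is A[i, ] / deg(i); zero-degree
# rows stay zero so isolated nodes aggregate to the zero vector.
degree_normalized <- function(A) {
  deg <- rowSums(A)
  A / pmax(deg, 1)
}

#' Encode miRNA and disease nodes
#'
#' Node features are the rows of the integrated similarity matrices. After
#' linear projection into the embedding space, each of the `L` layers
#' aggregates every node's training-graph neighbours (degree-normalized
#' sum), concatenates the aggregate with the node's own embedding, and
#' applies that layer's affine map followed by LeakyReLU. Both sides update
#' simultaneously from the pre-round embeddings.
#'
#' @param params A `gae_params`.
#' @param msim,dsim Integrated similarity matrices (node features).
#' @param A_train Training-fold association matrix (the message graph).
#' @param config A [gae_config()].
#' @return List with embeddings `H_m` (n_m x E) and `H_d` (n_d x E).
#' @export
gae_encode <- function(params, msim, dsim, A_train, config) {
  gae_forward(params, msim, dsim, A_train, config)[c("H_m", "H_d")]
}

# Forward pass keeping the per-layer cache needed for backprop.
gae_forward <- function(params, msim, dsim, A_train, config) {
  check_square(msim, "msim"); check_square(dsim, "dsim")
  n_m <- nrow(msim); n_d <- nrow(dsim)
  if (!identical(dim(A_train), c(n_m, n_d))) {
    rlang::abort("A_train shape does not match similarity matrices")
  }
  if (ncol(params$W_m) != n_m || ncol(params$W_d) != n_d) {
    rlang::abort("parameter shapes do not match graph sizes")
  }
  E <- config$E; slope <- config$leaky_slope
  Nm <- degree_normalized(A_train)       # n_m x n_d
  Nd <- degree_normalized(t(A_train))    # n_d x n_m
  Hm <- vector("list", config$L + 1L)
  Hd <- vector("list", config$L + 1L)
  Zm <- Zd <- Xm <- Xd <- vector("list", config$L)
  Hm[[1]] <- msim %*% t(params$W_m)
  Hd[[1]] <- dsim %*% t(params$W_d)
  for (l in seq_len(config$L)) {
    agg_m <- Nm %*% Hd[[l]]
    agg_d <- Nd %*% Hm[[l]]
    Xm[[l]] <- cbind(Hm[[l]], agg_m)
    Xd[[l]] <- cbind(Hd[[l]], agg_d)
    Zm[[l]] <- Xm[[l]] %*% t(params$layers_m[[l]]$W) +
      matrix(params$layers_m[[l]]$b, n_m, E, byrow = TRUE)
    Zd[[l]] <- Xd[[l]] %*% t(params$layers_d[[l]]$W) +
      matrix(params$layers_d[[l]]$b, n_d, E, byrow = TRUE)
    Hm[[l + 1L]] <- lrelu(Zm[[l]], slope)
    Hd[[l + 1L]] <- lrelu(Zd[[l]], slope)
  }
  list(H_m = Hm[[config$L + 1L]], H_d = Hd[[config$L + 1L]],
       Hm = Hm, Hd = Hd, Zm = Zm, Zd = Zd, Xm = Xm, Xd = Xd,
       Nm = Nm, Nd = Nd, Fm = msim, Fd = dsim)
}

#' Decode embeddings into association scores
#'
#' `score(i, j) = sigmoid(h_d(j) Q h_m(i)^T)`: the logistic of the bilinear
#' form between the disease and miRNA embeddings through `Q`.
#'
#' @param params A `gae_params`.
#' @param H_m,H_d Final embeddings from [gae_encode()].
#' @return An n_m x n_d score matrix, entries in (0, 1).
#' @export
gae_decode <- function(params, H_m, H_d) {
  logits <- H_m %*% t(params$Q) %*% t(H_d)
  S <- stats::plogis(logits)
  dimnames(S) <- list(rownames(H_m), rownames(H_d))
  S
}

BCE_EPS <- 1e-7

#' Cost-sensitive binary cross-entropy over sampled pairs
#'
#' `-sum(pos_weight * y * log(s) + (1 - y) * log(1 - s))` over the sampled
#' positive and negative pairs, with scores clipped to
#' `[1e-7, 1 - 1e-7]` inside the loss.
#'
#' @param scores Score matrix from [gae_decode()].
#' @param samples Tibble with integer columns `i`, `j` and `label` (0/1).
#' @param pos_weight Weight of positive terms (>= 1).
#' @return The scalar loss.
#' @export
weighted_bce_loss <- function(scores, samples, pos_weight = 1) {
  stopifnot(is.data.frame(samples), all(c("i", "j", "label") %in% names(samples)))
  if (nrow(samples) == 0L) rlang::abort("empty sample list")
  s <- pmin(pmax(scores[cbind(samples$i, samples$j)], BCE_EPS), 1 - BCE_EPS)
  y <- samples$label
  -sum(pos_weight * y * log(s) + (1 - y) * log(1 - s))
}

#' Sample negative pairs from the unknown cells of an association matrix
#'
#' Uniform without replacement over the zero cells of `A`, minus an optional
#' exclusion set; deterministic in `seed`.
#'
#' @param A Binary association matrix.
#' @param count Number of negatives to draw.
#' @param seed Integer seed.
#' @param exclude Optional data frame of pairs to exclude, with either id
#'   columns (`mirna`, `disease`) or index columns (`i`, `j`).
#' @return A tibble with columns `mirna`, `disease`, `i`, `j`, `label` (0).
#' @export
sample_negatives <- function(A, count, seed = 1L, exclude = NULL) {
  stopifnot(is.matrix(A), count >= 0)
  zero_idx <- which(A == 0)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    if (all(c("i", "j") %in% names(exclude))) {
      drop <- (exclude$j - 1L) * nrow(A) + exclude$i
    } else {
      drop <- (match(exclude$disease, colnames(A)) - 1L) * nrow(A) +
        match(exclude$mirna, rownames(A))
    }
    zero_idx <- setdiff(zero_idx, drop)
  }
  if (count > length(zero_idx)) {
    rlang::abort(sprintf("requested %d negatives but only %d zero cells available",
                         count, length(zero_idx)))
  }
  picked <- with_seed(seed, sample(zero_idx, count))
  i <- ((picked - 1L) %% nrow(A)) + 1L
  j <- ((picked - 1L) %/% nrow(A)) + 1L
  tibble::tibble(
    mirna = rownames(A)[i], disease = colnames(A)[j],
    i = i, j = j, label = 0L
  )
}

# Loss and analytic gradients of the full model on the sampled pairs.
gae_loss_grads <- function(params, msim, dsim, A_train, samples, config) {
  fw <- gae_forward(params, msim, dsim, A_train, config)
  Hm <- fw$H_m; Hd <- fw$H_d
  logits <- Hm %*% t(params$Q) %*% t(Hd)
  p <- stats::plogis(logits[cbind(samples$i, samples$j)])
  pc <- pmin(pmax(p, BCE_EPS), 1 - BCE_EPS)
  y <- samples$label
  w <- ifelse(y == 1, config$pos_weight, 1)
  loss <- -sum(w * (y * log(pc) + (1 - y) * log(1 - pc)))
  # d loss / d logit; zero where the score hit the clip bounds.
  dlogit <- ifelse(p > BCE_EPS & p < 1 - BCE_EPS, w * (p - y), 0)
  G <- matrix(0, nrow(Hm), nrow(Hd))
  G[cbind(samples$i, samples$j)] <- G[cbind(samples$i, samples$j)] + dlogit
  dQ <- t(Hd) %*% t(G) %*% Hm
  dHm <- G %*% (Hd %*% params$Q)
  dHd <- t(G) %*% (Hm %*% t(params$Q))
  E <- config$E; slope <- config$leaky_slope
  g_layers_m <- vector("list", config$L)
  g_layers_d <- vector("list", config$L)
  for (l in rev(seq_len(config$L))) {
    dZm <- dHm * dlrelu(fw$Zm[[l]], slope)
    dZd <- dHd * dlrelu(fw$Zd[[l]], slope)
    g_layers_m[[l]] <- list(W = t(dZm) %*% fw$Xm[[l]], b = colSums(dZm))
    g_layers_d[[l]] <- list(W = t(dZd) %*% fw$Xd[[l]], b = colSums(dZd))
    dXm <- dZm %*% params$layers_m[[l]]$W
    dXd <- dZd %*% params$layers_d[[l]]$W
    dHm <- dXm[, 1:E, drop = FALSE] + t(fw$Nd) %*% dXd[, (E + 1):(2 * E), drop = FALSE]
    dHd <- dXd[, 1:E, drop = FALSE] + t(fw$Nm) %*% dXm[, (E + 1):(2 * E), drop = FALSE]
  }
  grads <- list(
    W_m = t(dHm) %*% fw$Fm,
    W_d = t(dHd) %*% fw$Fd,
    layers_m = g_layers_m,
    layers_d = g_layers_d,
    Q = dQ
  )
  list(loss = loss, grads = grads)
}

# Global L2 norm over a nested list of numeric arrays.
param_global_norm <- function(g) {
  total <- 0
  rec <- function(x) {
    if (is.list(x)) lapply(x, rec) else total <<- total + sum(x^2)
    invisible(NULL)
  }
  rec(g)
  sqrt(total)
}

# Recursively apply f over parallel nested lists of numeric arrays.
map_params <- function(f, ...) {
  dots <- list(...)
  if (is.list(dots[[1]]) && !is.data.frame(dots[[1]])) {
    out <- Map(function(...) map_params(f, ...), ...)
    attributes(out) <- attributes(dots[[1]])
    out
  } else {
    do.call(f, dots)
  }
}

#' Train the graph auto-encoder
#'
#' Builds the training adjacency from the supplied positive pairs only,
#' draws a balanced negative sample once, and minimizes the cost-sensitive
#' cross-entropy with full-graph Adam steps.
#'
#' @param config A [gae_config()].
#' @param msim,dsim Integrated similarity matrices.
#' @param train_pos Data frame of training positives (`mirna`, `disease`
#'   ids matching the similarity dimnames).
#' @param seed Integer seed governing initialization and negative sampling.
#' @return A `gae_fit`: final parameters, per-epoch loss history, the
#'   training sample, config and inputs.
#' @export
gae_train <- function(config, msim, dsim, train_pos, seed = 1L) {
  stopifnot(inherits(config, "gae_config"), is.data.frame(train_pos))
  if (nrow(train_pos) == 0L) rlang::abort("no training positives")
  mids <- rownames(msim); dids <- rownames(dsim)
  i <- match(train_pos$mirna, mids); j <- match(train_pos$disease, dids)
  if (anyNA(i) || anyNA(j)) rlang::abort("training pair id not present in similarity matrices")
  A_train <- matrix(0, length(mids), length(dids), dimnames = list(mids, dids))
  A_train[cbind(i, j)] <- 1
  pos <- tibble::tibble(mirna = train_pos$mirna, disease = train_pos$disease,
                        i = i, j = j, label = 1L)
  pos <- dplyr::distinct(pos)
  neg <- sample_negatives(A_train, round(config$neg_ratio * nrow(pos)),
                          seed = derive_seed(seed, "negatives"))
  samples <- dplyr::bind_rows(pos, neg)
  params <- gae_init_params(config, length(mids), length(dids),
                            seed = derive_seed(seed, "init"))
  m_state <- map_params(function(x) x * 0, params)
  v_state <- map_params(function(x) x * 0, params)
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  lr <- config$learning_rate
  history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    lg <- gae_loss_grads(params, msim, dsim, A_train, samples, config)
    if (!is.finite(lg$loss)) {
      rlang::abort(sprintf("training diverged: non-finite loss at epoch %d", epoch),
                   class = "mirgae_divergence_error")
    }
    history[epoch] <- lg$loss
    grads <- lg$grads
    gn <- param_global_norm(grads)
    if (is.finite(config$clip_norm) && gn > config$clip_norm) {
      grads <- map_params(function(g) g * config$clip_norm / gn, grads)
    }
    m_state <- map_params(function(m, g) beta1 * m + (1 - beta1) * g, m_state, grads)
    v_state <- map_params(function(v, g) beta2 * v + (1 - beta2) * g^2, v_state, grads)
    bc1 <- 1 - beta1^epoch; bc2 <- 1 - beta2^epoch
    params <- map_params(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + adam_eps),
                         params, m_state, v_state)
  }
  structure(
    list(params = params, config = config,
         history = tibble::tibble(epoch = seq_len(config$epochs), loss = history),
         samples = samples, msim = msim, dsim = dsim, A_train = A_train,
         seed = seed),
    class = "gae_fit"
  )
}

#' Predict association scores from a trained model
#'
#' Encodes all nodes over the training graph and decodes the full score
#' matrix, held-out pairs included.
#'
#' @param object A `gae_fit`.
#' @param ... Unused.
#' @return An n_m x n_d score matrix with dimnames, entries in (0, 1).
#' @export
predict.gae_fit <- function(object, ...) {
  emb <- gae_encode(object$params, object$msim, object$dsim,
                    object$A_train, object$config)
  H_m <- emb$H_m; H_d <- emb$H_d
  rownames(H_m) <- rownames(object$msim)
  rownames(H_d) <- rownames(object$dsim)
  gae_decode(object$params, H_m, H_d)
}

#' @export
print.gae_fit <- function(x, ...) {
  cat(sprintf(
    "<gae_fit> E=%d L=%d | %d miRNAs x %d diseases | %d pos + %d neg samples\n",
    x$config$E, x$config$L, nrow(x$msim), nrow(x$dsim),
    sum(x$samples$label == 1), sum(x$samples$label == 0)))
  cat(sprintf("  loss: %.4f (epoch 1) -> %.4f (epoch %d)\n",
              x$history$loss[1], x$history$loss[nrow(x$history)],
              nrow(x$history)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training trajectory of a fitted graph auto-encoder
#'
#' @param x A `gae_fit`.
#' @param ... Unused.
#' @return Tibble with columns `epoch`, `loss`.
#' @exportS3Method generics::tidy
tidy.gae_fit <- function(x, ...) x$history

#' One-row summary of a fitted graph auto-encoder
#'
#' @param x A `gae_fit`.
#' @param ... Unused.
#' @return One-row tibble with sizes, sample counts and first/final loss.
#' @exportS3Method generics::glance
glance.gae_fit <- function(x, ...) {
  tibble::tibble(
    n_mirna = nrow(x$msim), n_disease = nrow(x$dsim),
    E = x$config$E, L = x$config$L, epochs = x$config$epochs,
    n_pos = sum(x$samples$label == 1), n_neg = sum(x$samples$label == 0),
    first_loss = x$history$loss[1],
    final_loss = x$history$loss[nrow(x$history)]
  )
}

#' Loss-curve plot of a fitted graph auto-encoder
#'
#' @param object A `gae_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gae_fit <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "Epoch", y = "Weighted cross-entropy loss",
                  title = "Graph auto-encoder training trajectory") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
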