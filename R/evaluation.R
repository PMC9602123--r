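# Model evaluation: seeded stratified folds, threshold metrics, rank-based
# ROC-AUC, leakage-safe 5-fold cross-validation, and leave-disease-out
# top-k ranking.

#' Split positive pairs into k seeded, near-equal folds
#'
#' @param pairs Data frame of positive pairs (`mirna`, `disease`).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return The input tibble with an integer `fold` column; fold sizes
#'   differ by at most 1 and every pair lands in exactly one fold.
#' @export
stratified_folds <- function(pairs, k = 5L, seed = 1L) {
  stopifnot(is.data.frame(pairs))
  if (k < 2L) rlang::abort("need at least 2 folds")
  n <- nrow(pairs)
  if (n < k) rlang::abort(sprintf("only %d pairs for %d folds", n, k))
  perm <- with_seed(seed, sample(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), length.out = n)
  dplyr::mutate(tibble::as_tibble(pairs), fold = fold)
}

#' Confusion-matrix metrics at a score threshold
#'
#' Accuracy, precision, recall and F1 with the usual zero-denominator
#' convention (0, with a warning) when no prediction or no positive exists.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels of the same length.
#' @param threshold `score >= threshold` predicts the positive class
#'   (default 0.5).
#' @return One-row tibble with `acc`, `prec`, `recall`, `f1` (proportions).
#' @export
binary_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0L) rlang::abort("empty input")
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  acc <- (tp + tn) / length(labels)
  prec <- if (tp + fp == 0) { warning("no positive predictions; precision set to 0"); 0 } else tp / (tp + fp)
  recall <- if (tp + fn == 0) { warning("no positive labels; recall set to 0"); 0 } else tp / (tp + fn)
  f1 <- if (prec + recall == 0) 0 else 2 * prec * recall / (prec + recall)
  tibble::tibble(acc = acc, prec = prec, recall = recall, f1 = f1)
}

#' Rank-based ROC-AUC
#'
#' The probability that a random positive outscores a random negative,
#' ties counted one half (Mann-Whitney formulation; exact and tie-robust).
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return The AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    rlang::abort("both classes must be present to compute AUC")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Stepwise ROC curve points (fpr, tpr), from (0,0) to (1,1).
roc_points <- function(scores, labels) {
  ord <- order(-scores)
  tp <- cumsum(labels[ord] == 1)
  fp <- cumsum(labels[ord] == 0)
  tibble::tibble(
    fpr = c(0, fp / max(sum(labels == 0), 1)),
    tpr = c(0, tp / max(sum(labels == 1), 1))
  )
}

#' Leakage-safe k-fold cross-validation of the full pipeline
#'
#' Positive pairs are split into `k` seeded folds. For each fold the
#' training adjacency is rebuilt without the test positives, the GIP
#' kernels (and hence the integrated similarities) are recomputed from the
#' training adjacency only, the auto-encoder is trained, and the test
#' positives plus an equal-size seeded sample of never-used negative pairs
#' are scored. Metrics are reported per fold and as mean +/- sd, in
#' percent.
#'
#' @param A Binary association matrix (the full id universe).
#' @param msim Sequence-similarity matrix over the miRNAs of `A` (or `NULL`
#'   to use the GIP kernel alone).
#' @param dsim_sem Semantic similarity matrix over the diseases of `A` (or
#'   `NULL` to use the GIP kernel alone).
#' @param config A [gae_config()].
#' @param seed Master seed: folds, per-fold training and test negatives all
#'   draw from derived streams.
#' @param k Number of folds (default 5).
#' @param mirna_available,disease_available Logical flags per id: does the
#'   entity have sequence / MeSH data? Defaults to all `TRUE` when the
#'   corresponding matrix is supplied.
#' @return A `cv_report`.
#' @export
cross_validate <- function(A, msim = NULL, dsim_sem = NULL,
                           config = gae_config(), seed = 1L, k = 5L,
                           mirna_available = NULL, disease_available = NULL) {
  stopifnot(is.matrix(A))
  pos <- association_pairs(A)
  assignments <- stratified_folds(pos, k = k, seed = derive_seed(seed, "folds"))
  folds <- vector("list", k)
  roc <- vector("list", k)
  fold_train <- vector("list", k)
  for (f in seq_len(k)) {
    test_pos <- dplyr::filter(assignments, .data$fold == f)
    train_pos <- dplyr::filter(assignments, .data$fold != f)
    fold_train[[f]] <- train_pos[, c("mirna", "disease")]
    A_train <- A
    A_train[cbind(test_pos$mirna, test_pos$disease)] <- 0
    mgsm <- gip_similarity(A_train, "mirna")
    dgsm <- gip_similarity(A_train, "disease")
    MSim <- if (is.null(msim)) mgsm else
      integrate_similarity(msim, mgsm, mirna_available)
    DSim <- if (is.null(dsim_sem)) dgsm else
      integrate_similarity(dsim_sem, dgsm, disease_available)
    fit <- gae_train(config, MSim, DSim, train_pos,
                     seed = derive_seed(seed, paste0("train-fold", f)))
    S <- predict(fit)
    test_neg <- sample_negatives(
      A, nrow(test_pos),
      seed = derive_seed(seed, paste0("testneg-fold", f)),
      exclude = dplyr::filter(fit$samples, .data$label == 0L)
    )
    scores <- c(S[cbind(test_pos$mirna, test_pos$disease)],
                S[cbind(test_neg$mirna, test_neg$disease)])
    labels <- c(rep(1L, nrow(test_pos)), rep(0L, nrow(test_neg)))
    bm <- binary_metrics(scores, labels, config$threshold)
    folds[[f]] <- tibble::tibble(
      fold = f,
      auc = 100 * roc_auc(scores, labels),
      acc = 100 * bm$acc, prec = 100 * bm$prec,
      recall = 100 * bm$recall, f1 = 100 * bm$f1,
      first_loss = fit$history$loss[1],
      final_loss = fit$history$loss[nrow(fit$history)],
      gip_norm_mirna = norm(mgsm, "F"),
      gip_norm_disease = norm(dgsm, "F")
    )
    roc[[f]] <- dplyr::mutate(roc_points(scores, labels), fold = f)
  }
  folds <- dplyr::bind_rows(folds)
  metrics <- c("auc", "acc", "prec", "recall", "f1")
  summary <- tibble::tibble(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(folds[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(folds[[m]]), numeric(1))
  )
  structure(
    list(folds = folds, summary = summary, assignments = assignments,
         fold_train = fold_train, roc = dplyr::bind_rows(roc),
         config = config, seed = seed, k = k,
         protocol = "balanced seeded negative sample; per-fold GIP recomputation"),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold cross-validation (seed %s)\n", x$k, x$seed))
  for (r in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-7s %6.2f +/- %.2f %%\n", toupper(x$summary$metric[r]),
                x$summary$mean[r], x$summary$sd[r]))
  }
  invisible(x)
}

#' Per-fold metrics of a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble of per-fold metrics (percentages).
#' @exportS3Method generics::tidy
tidy.cv_report <- function(x, ...) x$folds

#' One-row mean +/- sd summary of a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return One-row tibble: `<metric>_mean` and `<metric>_sd` in percent.
#' @exportS3Method generics::glance
glance.cv_report <- function(x, ...) {
  wide <- c(stats::setNames(x$summary$mean, paste0(x$summary$metric, "_mean")),
            stats::setNames(x$summary$sd, paste0(x$summary$metric, "_sd")))
  tibble::as_tibble(as.list(wide))
}

#' ROC curves of a cross-validation report
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object with one stepwise ROC curve per fold.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_report <- function(object, ...) {
  auc_mean <- object$summary$mean[object$summary$metric == "auc"]
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = factor(.data$fold))) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = "Fold",
                  title = sprintf("ROC per fold (mean AUC %.2f%%)", auc_mean)) +
    ggplot2::theme_minimal()
}

#' Leave-disease-out top-k miRNA ranking
#'
#' Removes every association of the target disease from the training data,
#' retrains the model, and ranks candidate miRNAs for that disease by
#' descending score (ties broken by miRNA id).
#'
#' @param disease Target disease id.
#' @param A Binary association matrix.
#' @param msim,dsim_sem Similarity matrices as in [cross_validate()].
#' @param config A [gae_config()].
#' @param seed Integer seed.
#' @param top_k Number of miRNAs to return (default 50).
#' @param mirna_available,disease_available Availability flags as in
#'   [cross_validate()].
#' @return Tibble with columns `rank`, `mirna`, `disease`, `score`.
#' @export
rank_disease <- function(disease, A, msim = NULL, dsim_sem = NULL,
                         config = gae_config(), seed = 1L, top_k = 50L,
                         mirna_available = NULL, disease_available = NULL) {
  stopifnot(is.matrix(A))
  if (!disease %in% colnames(A)) {
    rlang::abort(paste0("unknown disease: '", disease, "'"),
                 class = "mirgae_key_error")
  }
  if (top_k > nrow(A)) rlang::abort("top_k exceeds the number of miRNAs")
  A_train <- A
  A_train[, disease] <- 0
  train_pos <- association_pairs(A_train)
  mgsm <- gip_similarity(A_train, "mirna")
  dgsm <- gip_similarity(A_train, "disease")
  MSim <- if (is.null(msim)) mgsm else integrate_similarity(msim, mgsm, mirna_available)
  DSim <- if (is.null(dsim_sem)) dgsm else
    integrate_similarity(dsim_sem, dgsm, disease_available)
  fit <- gae_train(config, MSim, DSim, train_pos,
                   seed = derive_seed(seed, paste0("rank-", disease)))
  S <- predict(fit)
  candidates <- rownames(A)[A_train[, disease] == 0]
  cand_scores <- S[candidates, disease]
  out <- tibble::tibble(mirna = candidates, disease = disease,
                        score = unname(cand_scores))
  out <- out[order(-out$score, out$mirna, method = "radix"), ]
  out <- utils::head(out, top_k)
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
}
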