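# Similarity matrices: feature-space similarity under three metrics,
# MeSH-DAG semantic similarity, Gaussian interaction-profile (GIP) kernels,
# and the sequence/semantic-with-GIP-fallback integration.

as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    stopifnot("id" %in% names(features))
    X <- as.matrix(features[, setdiff(names(features), "id"), drop = FALSE])
    rownames(X) <- features$id
  } else if (is.matrix(features)) {
    X <- features
    if (is.null(rownames(X))) rlang::abort("feature matrix needs row names")
  } else {
    rlang::abort("`features` must be a data frame or a matrix")
  }
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) abort_state("non-finite feature values")
  X
}

finalize_similarity <- function(S, tag) {
  S <- (S + t(S)) / 2
  diag(S) <- 1
  attr(S, "source_tag") <- tag
  S
}

#' Pairwise similarity of feature vectors
#'
#' Computes a square symmetric similarity matrix over the rows of a feature
#' table. `cosine` is the inner product over the norm product; `pearson` is
#' the centred cosine (kept raw in `[-1, 1]`); `euclidean` is the distance
#' `d` transformed to `1/(1 + d)` so it lands in `(0, 1]`. The diagonal is
#' forced to exactly 1. All-zero (or, for Pearson, constant) rows get
#' similarity 0 to every other row rather than NaN.
#'
#' @param features Feature tibble from [encode_features()] (or a numeric
#'   matrix with row names).
#' @param metric One of `"cosine"`, `"euclidean"`, `"pearson"`.
#' @return A symmetric similarity matrix with a `source_tag` attribute.
#' @export
feature_similarity <- function(features, metric = c("cosine", "euclidean", "pearson")) {
  metric <- match.arg(metric)
  X <- as_feature_matrix(features)
  if (nrow(X) < 2L) rlang::abort("need at least 2 feature rows")
  S <- switch(metric,
    cosine = {
      nrm <- sqrt(rowSums(X^2))
      G <- X %*% t(X)
      denom <- outer(nrm, nrm)
      out <- ifelse(denom > 0, G / ifelse(denom > 0, denom, 1), 0)
      if (any(nrm == 0)) message("zero-norm feature row(s): cosine similarity set to 0")
      out
    },
    pearson = {
      Xc <- X - rowMeans(X)
      nrm <- sqrt(rowSums(Xc^2))
      G <- Xc %*% t(Xc)
      denom <- outer(nrm, nrm)
      out <- ifelse(denom > 0, G / ifelse(denom > 0, denom, 1), 0)
      if (any(nrm == 0)) message("constant feature row(s): Pearson similarity set to 0")
      out
    },
    euclidean = {
      D <- as.matrix(stats::dist(X))
      1 / (1 + D)
    }
  )
  dimnames(S) <- list(rownames(X), rownames(X))
  enc <- attr(features, "encoder")
  tag <- if (is.null(enc)) paste0("mssm::", metric) else
    paste0("mssm:", enc, ":", metric)
  finalize_similarity(S, tag)
}

#' Raw Euclidean distance matrix of feature vectors
#'
#' Audit companion to the `euclidean` similarity transform.
#'
#' @inheritParams feature_similarity
#' @return A symmetric distance matrix.
#' @export
feature_distance <- function(features) {
  X <- as_feature_matrix(features)
  as.matrix(stats::dist(X))
}

# Ancestor closure (all prefixes of all codes) of one disease.
disease_nodes <- function(dag, disease) {
  codes <- dag$tree_numbers[[disease]]
  if (is.null(codes)) {
    rlang::abort(paste0("unknown disease: '", disease, "'"),
                 class = "mirgae_key_error")
  }
  unique(unlist(lapply(codes, code_prefixes), use.names = FALSE))
}

#' Semantic contribution of DAG ancestors to a disease
#'
#' The disease's own tree-number nodes contribute 1; every ancestor node
#' contributes `delta` raised to its generation distance, taking the best
#' (max) path when a node is reachable at several depths. The semantic
#' value `dv` is the sum of contributions over the disease's DAG.
#'
#' @param dag A [disease_dag()].
#' @param disease Disease id.
#' @param delta Per-generation attenuation factor (default 0.5).
#' @return List with `disease`, named `contribution` vector over DAG nodes,
#'   and `dv`.
#' @export
semantic_contribution <- function(dag, disease, delta = 0.5) {
  stopifnot(inherits(dag, "disease_dag"), delta > 0, delta <= 1)
  nodes <- disease_nodes(dag, disease)
  own <- dag$tree_numbers[[disease]]
  contrib <- vapply(nodes, function(nd) {
    nd_len <- length(strsplit(nd, ".", fixed = TRUE)[[1]])
    depths <- vapply(own, function(code) {
      if (nd == code || startsWith(code, paste0(nd, "."))) {
        length(strsplit(code, ".", fixed = TRUE)[[1]]) - nd_len
      } else NA_integer_
    }, integer(1))
    delta^min(depths, na.rm = TRUE)
  }, numeric(1))
  list(disease = disease, contribution = contrib, dv = sum(contrib))
}

#' Disease-disease semantic similarity matrix
#'
#' Entry `(i, j)` sums, over the DAG nodes shared by the two diseases, the
#' two semantic contributions, divided by the sum of the two semantic
#' values. Diseases sharing no node score 0; the diagonal is 1.
#'
#' @param dag A [disease_dag()].
#' @param diseases Ordered disease ids (default: all diseases in the DAG).
#' @param delta Attenuation factor (default 0.5).
#' @return A symmetric similarity matrix tagged `"dssm"`.
#' @export
semantic_similarity <- function(dag, diseases = NULL, delta = 0.5) {
  stopifnot(inherits(dag, "disease_dag"))
  if (is.null(diseases)) diseases <- dag$disease_ids
  scores <- lapply(diseases, function(d) semantic_contribution(dag, d, delta))
  names(scores) <- diseases
  n <- length(diseases)
  S <- diag(1, n)
  dimnames(S) <- list(diseases, diseases)
  if (n >= 2L) {
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        ca <- scores[[a]]$contribution
        cb <- scores[[b]]$contribution
        shared <- intersect(names(ca), names(cb))
        S[a, b] <- S[b, a] <- if (length(shared) == 0L) 0 else
          sum(ca[shared] + cb[shared]) / (scores[[a]]$dv + scores[[b]]$dv)
      }
    }
  }
  finalize_similarity(S, "dssm")
}

#' Gaussian interaction-profile kernel similarity
#'
#' Interaction profiles are the rows (`axis = "mirna"`) or columns
#' (`axis = "disease"`) of the association matrix. The kernel bandwidth is
#' the reference bandwidth (1) divided by the mean squared profile norm,
#' and the similarity of two entities is `exp(-sigma * ||IP_i - IP_j||^2)`.
#'
#' @param A Binary association matrix.
#' @param axis `"mirna"` or `"disease"`.
#' @param bandwidth Reference bandwidth (default 1).
#' @return A symmetric similarity matrix tagged `"mgsm"` or `"dgsm"`.
#' @export
gip_similarity <- function(A, axis = c("mirna", "disease"), bandwidth = 1) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(A))
  if (sum(A) == 0) {
    rlang::abort("association matrix has no positives: GIP bandwidth undefined",
                 class = "mirgae_degenerate_error")
  }
  P <- if (axis == "mirna") A else t(A)
  n2 <- rowSums(P^2)
  sigma <- bandwidth / mean(n2)
  D2 <- outer(n2, n2, "+") - 2 * P %*% t(P)
  D2[D2 < 0] <- 0  # numerical noise
  S <- exp(-sigma * D2)
  dimnames(S) <- list(rownames(P), rownames(P))
  finalize_similarity(S, if (axis == "mirna") "mgsm" else "dgsm")
}

#' Integrate a primary similarity with its GIP fallback
#'
#' Entry `(i, j)` is taken from the primary (sequence or semantic) matrix
#' when both entities have the required source data, and from the GIP
#' kernel otherwise.
#'
#' @param primary Sequence or semantic similarity matrix.
#' @param gip GIP similarity matrix over the same ids in the same order.
#' @param available Logical vector (one flag per id): does the entity have
#'   primary source data? Default: all `TRUE`.
#' @return A symmetric similarity matrix tagged `"msim"` or `"dsim"`.
#' @export
integrate_similarity <- function(primary, gip, available = NULL) {
  check_square(primary, "primary")
  check_square(gip, "gip")
  if (!identical(rownames(primary), rownames(gip))) {
    rlang::abort("id order mismatch between primary and GIP matrices",
                 class = "mirgae_alignment_error")
  }
  n <- nrow(primary)
  if (is.null(available)) available <- rep(TRUE, n)
  stopifnot(is.logical(available), length(available) == n)
  mask <- outer(available, available, "&")
  S <- ifelse(mask, primary, gip)
  dimnames(S) <- dimnames(primary)
  tag <- if (identical(attr(gip, "source_tag"), "dgsm")) "dsim" else "msim"
  finalize_similarity(S, tag)
}

#' Source tags of all single-encoder sequence-similarity products
#'
#' Crossing the five descriptor encoders with the three metrics yields the
#' 15 distinct miRNA sequence-similarity matrices the pipeline can build.
#'
#' @return A tibble with columns `encoder`, `metric`, `tag`.
#' @export
mssm_catalog <- function() {
  g <- expand.grid(metric = c("cosine", "euclidean", "pearson"),
                   encoder = ENCODER_NAMES, stringsAsFactors = FALSE)
  tibble::tibble(
    encoder = g$encoder,
    metric = g$metric,
    tag = paste0("mssm:", g$encoder, ":", g$metric)
  )
}
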