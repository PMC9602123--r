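# Internal helpers shared across modules.

#' Derive an independent seed for a named consumer of randomness
#'
#' One user-facing seed governs fold splits, negative sampling, parameter
#' initialization and the synthetic generators; each consumer draws from its
#' own derived stream so changing one stage never shifts another's draws.
#'
#' @param seed Integer master seed.
#' @param tag Character label of the consumer (e.g. `"folds"`, `"init"`).
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483629)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Locale-independent lexicographic sort for identifiers.
sort_ids <- function(x) sort(x, method = "radix")

# Canonical identifier form: trimmed, lower-cased (case-insensitive matching).
normalize_id <- function(x) tolower(trimws(x))

abort_format <- function(msg, ...) {
  rlang::abort(paste0(msg, ...), class = "mirgae_format_error")
}

abort_state <- function(msg, ...) {
  rlang::abort(paste0(msg, ...), class = "mirgae_state_error")
}

# Is `x` a square numeric matrix with matching dimnames?
check_square <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x) || nrow(x) != ncol(x)) {
    rlang::abort(sprintf("`%s` must be a square numeric matrix", what))
  }
  if (is.null(rownames(x)) || is.null(colnames(x)) ||
      !identical(rownames(x), colnames(x))) {
    rlang::abort(sprintf("`%s` must carry identical row/column names", what))
  }
  invisible(x)
}
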