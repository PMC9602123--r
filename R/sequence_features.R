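# The five miRNA sequence descriptor encoders: 3-mer composition, CKSNAP
# (composition of k-spaced nucleotide pairs), and Moran / Geary / normalized
# Moreau-Broto autocorrelation over dinucleotide physicochemical indices.

RNA_ALPHABET <- c("A", "C", "G", "U")
DNA_ALPHABET <- c("A", "C", "G", "T")

# Lexicographic 3-mers over {A,C,G,U}: AAA, AAC, ..., UUU.
kmer3_names <- function() {
  g <- expand.grid(c3 = RNA_ALPHABET, c2 = RNA_ALPHABET, c1 = RNA_ALPHABET,
                   stringsAsFactors = FALSE)
  paste0(g$c1, g$c2, g$c3)
}

# The 16 ordered nucleotide pairs in the field's T-spelled order: AA..TT.
pair16_names <- function() {
  g <- expand.grid(c2 = DNA_ALPHABET, c1 = DNA_ALPHABET, stringsAsFactors = FALSE)
  paste0(g$c1, g$c2)
}

# RNA-spelled dinucleotides AA..UU (property-table column order).
dinuc16_names <- function() chartr("T", "U", pair16_names())

check_rna_seq <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    abort_format("sequence must be a single non-empty string")
  }
  if (grepl("[^ACGU]", seq)) {
    abort_format("sequence contains characters outside {A,C,G,U}: '", seq, "'")
  }
  seq
}

#' 3-mer composition of an RNA sequence
#'
#' Counts every length-3 window (step 1) and divides by the sequence length
#' `N`, so the 64 components sum to `(N - 2)/N`.
#'
#' @param seq RNA string over `{A,C,G,U}`.
#' @return Named numeric vector of length 64 (lexicographic 3-mers).
#' @export
#' @examples
#' encode_kmer("ACGACG")[c("ACG", "CGA", "GAC")]
encode_kmer <- function(seq) {
  check_rna_seq(seq)
  n <- nchar(seq)
  if (n < 3L) abort_format("sequence shorter than 3 nt: cannot form a 3-mer")
  windows <- substring(seq, 1:(n - 2L), 3:n)
  counts <- table(factor(windows, levels = kmer3_names()))
  stats::setNames(as.numeric(counts) / n, kmer3_names())
}

#' Composition of k-spaced nucleotide pairs (CKSNAP)
#'
#' For each gap `g` in `0..kmax` and each of the 16 ordered pairs, the
#' component is the count of positions `(i, i + g + 1)` forming that pair
#' divided by `L - g - 1`, so each per-gap block of 16 sums to 1. Pairs are
#' named in the conventional T-spelled alphabet (`U` mapped to `T`); both
#' RNA- and DNA-spelled inputs are accepted.
#'
#' @param seq RNA string over `{A,C,G,U}`.
#' @param kmax Largest gap (default 5, giving 96 components).
#' @return Named numeric vector of length `16 * (kmax + 1)`.
#' @export
encode_cksnap <- function(seq, kmax = 5L) {
  check_rna_seq(seq)
  stopifnot(kmax >= 0L)
  L <- nchar(seq)
  if (L < kmax + 2L) {
    abort_format(sprintf("sequence of length %d too short for gap %d (needs >= %d)",
                         L, kmax, kmax + 2L))
  }
  chars <- strsplit(chartr("U", "T", seq), "")[[1]]
  pairs <- pair16_names()
  out <- numeric(0)
  for (g in 0:kmax) {
    i <- seq_len(L - g - 1L)
    obs <- paste0(chars[i], chars[i + g + 1L])
    block <- as.numeric(table(factor(obs, levels = pairs))) / (L - g - 1L)
    names(block) <- paste0(pairs, ".gap", g)
    out <- c(out, block)
  }
  out
}

# Autocorrelation kernels over a per-position property profile `m` at lag d.
# Zero-variance profiles yield 0 for Moran/Geary (information-free input).
moran_stat <- function(m, d) {
  n <- length(m)
  mbar <- mean(m)
  denom <- sum((m - mbar)^2) / n
  if (denom == 0) return(0)
  num <- sum((m[1:(n - d)] - mbar) * (m[(1 + d):n] - mbar)) / (n - d)
  num / denom
}

geary_stat <- function(m, d) {
  n <- length(m)
  denom <- sum((m - mean(m))^2) / (n - 1)
  if (denom == 0) return(0)
  num <- sum((m[1:(n - d)] - m[(1 + d):n])^2) / (2 * (n - d))
  num / denom
}

nmbroto_stat <- function(m, d) {
  n <- length(m)
  sum(m[1:(n - d)] * m[(1 + d):n]) / (n - d)
}

#' Autocorrelation descriptor of an RNA sequence
#'
#' Maps the sequence to a per-position profile of standardized dinucleotide
#' property values (the dinucleotide starting at position `i`, giving
#' `N - 1` positions) and summarizes each property at lags `1..nlag` with
#' the chosen autocorrelation statistic.
#'
#' @param seq RNA string over `{A,C,G,U}`.
#' @param table An [rna_property_table()] (must be standardized).
#' @param kind One of `"moran"`, `"geary"`, `"nmbroto"`.
#' @param nlag Maximum lag (default 3).
#' @return Named numeric vector of length `n_properties * nlag`,
#'   property-major (`<property>.lag<d>`).
#' @export
encode_autocorrelation <- function(seq, table = rna_property_table(),
                                   kind = c("moran", "geary", "nmbroto"),
                                   nlag = 3L) {
  kind <- match.arg(kind)
  check_rna_seq(seq)
  if (!inherits(table, "rna_property_table")) {
    abort_state("`table` must be an rna_property_table")
  }
  if (!isTRUE(table$standardized)) {
    abort_state("property table must be standardized before autocorrelation")
  }
  n_pos <- nchar(seq) - 1L
  if (n_pos <= nlag) {
    abort_format(sprintf(
      "sequence gives %d dinucleotide positions; need more than nlag = %d",
      n_pos, nlag))
  }
  dinucs <- substring(seq, seq_len(n_pos), seq_len(n_pos) + 1L)
  idx <- match(dinucs, table$dinucleotides)
  stat <- switch(kind, moran = moran_stat, geary = geary_stat, nmbroto = nmbroto_stat)
  out <- numeric(nrow(table$values) * nlag)
  nm <- character(length(out))
  k <- 0L
  for (p in seq_len(nrow(table$values))) {
    m <- table$values[p, idx]
    for (d in seq_len(nlag)) {
      k <- k + 1L
      out[k] <- stat(m, d)
      nm[k] <- paste0(table$properties[p], ".lag", d)
    }
  }
  stats::setNames(out, nm)
}

#' Load the dinucleotide physicochemical property table
#'
#' Reads a TSV with a `property` column and 16 dinucleotide columns
#' (`AA..UU`) and z-scores each property across the 16 dinucleotides (mean
#' 0, unit standard deviation), the standard Moreau-Broto normalization.
#' Without a path, the packaged default table of 22 indices (helical step
#' geometry, nearest-neighbour thermodynamics, hydrophilicity and
#' composition indicators) is used.
#'
#' @param path Optional TSV path; `NULL` loads the packaged default.
#' @return An `rna_property_table`: property names, dinucleotide order,
#'   raw and standardized value matrices.
#' @export
rna_property_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rna_dinucleotide_properties.tsv",
                        package = "mirgae", mustWork = TRUE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  expected <- dinuc16_names()
  missing <- setdiff(expected, names(raw))
  if (length(missing) > 0L) {
    abort_format("property table missing dinucleotide column(s): ",
                 paste(missing, collapse = ", "))
  }
  vals <- as.matrix(raw[, expected, drop = FALSE])
  if (any(!is.finite(vals))) abort_format("non-finite value in property table")
  rownames(vals) <- raw[[1]]
  std <- t(apply(vals, 1, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  dimnames(std) <- dimnames(vals)
  structure(
    list(
      properties = raw[[1]],
      dinucleotides = expected,
      raw = vals,
      values = std,
      standardized = TRUE
    ),
    class = "rna_property_table"
  )
}

#' @export
print.rna_property_table <- function(x, ...) {
  cat(sprintf("<rna_property_table> %d properties x %d dinucleotides (standardized)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

ENCODER_NAMES <- c("kmer", "cksnap", "moran", "geary", "nmbroto")

encode_one <- function(seq, encoder, table, nlag, kmax) {
  switch(encoder,
    kmer = encode_kmer(seq),
    cksnap = encode_cksnap(seq, kmax = kmax),
    moran = encode_autocorrelation(seq, table, "moran", nlag = nlag),
    geary = encode_autocorrelation(seq, table, "geary", nlag = nlag),
    nmbroto = encode_autocorrelation(seq, table, "nmbroto", nlag = nlag)
  )
}

#' Encode a set of miRNA sequences as a feature table
#'
#' Applies one or more descriptor encoders to every sequence and
#' concatenates their components column-wise (combined-feature models are
#' concatenations of the named encoders' vectors).
#'
#' @param seqs Tibble with columns `id` and `seq` (see [read_mirna_fasta()]).
#' @param encoders Character vector drawn from
#'   `c("kmer", "cksnap", "moran", "geary", "nmbroto")`.
#' @param table Property table for the autocorrelation encoders.
#' @param nlag,kmax Encoder tuning (defaults 3 and 5).
#' @return A tibble with `id` plus one numeric column per feature component;
#'   attribute `encoder` holds the `"+"`-joined encoder tag.
#' @export
#' @examples
#' seqs <- tibble::tibble(id = c("m1", "m2"),
#'                        seq = c("ACGUACGUACGU", "GGGCCCAAAUUU"))
#' dim(encode_features(seqs, "kmer"))
encode_features <- function(seqs, encoders = "cksnap", table = NULL,
                            nlag = 3L, kmax = 5L) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  if (nrow(seqs) == 0L) abort_format("empty sequence set")
  bad <- setdiff(encoders, ENCODER_NAMES)
  if (length(bad) > 0L || length(encoders) == 0L) {
    abort_format("unknown encoder(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(seqs$id)) abort_format("duplicate sequence ids in input")
  needs_table <- any(encoders %in% c("moran", "geary", "nmbroto"))
  if (needs_table && is.null(table)) table <- rna_property_table()
  rows <- lapply(seq_len(nrow(seqs)), function(k) {
    tryCatch(
      unlist(lapply(encoders, function(e)
        encode_one(seqs$seq[k], e, table, nlag, kmax))),
      error = function(e) {
        rlang::abort(sprintf("encoding failed for sequence '%s': %s",
                             seqs$id[k], conditionMessage(e)),
                     class = "mirgae_format_error")
      }
    )
  })
  M <- do.call(rbind, rows)
  if (any(!is.finite(M))) abort_state("non-finite feature value produced")
  out <- tibble::as_tibble(as.data.frame(M, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(id = seqs$id), out)
  attr(out, "encoder") <- paste(encoders, collapse = "+")
  out
}

#' Feature-table dimensionality of an encoder tag
#'
#' @param encoders Character vector of encoder names.
#' @param nlag,kmax Encoder tuning.
#' @return Integer total number of feature components.
#' @export
encoder_dim <- function(encoders, nlag = 3L, kmax = 5L) {
  n_prop <- nrow(rna_property_table()$values)
  dims <- c(kmer = 64L, cksnap = 16L * (kmax + 1L),
            moran = n_prop * nlag, geary = n_prop * nlag,
            nmbroto = n_prop * nlag)
  bad <- setdiff(encoders, names(dims))
  if (length(bad) > 0L) abort_format("unknown encoder(s): ", paste(bad, collapse = ", "))
  sum(dims[encoders])
}
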