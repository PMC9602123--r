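# Seeded generators for planted-structure inputs: miRNA sequence families,
# block-structured association matrices, and a random disease DAG whose
# subtrees align with the association blocks. Every stage of the pipeline
# is testable from these without external databases.

#' Generate miRNA sequence families around random consensi
#'
#' One uniform-random consensus per family; members are consensus copies
#' with independent per-position substitution probability `mut_rate`. Ids
#' encode the family (`mir-f<family>-<member>`) for test introspection.
#'
#' @param n_families,per_family Family count and members per family.
#' @param length Sequence length in nt (default 22, mature-miRNA scale).
#' @param mut_rate Per-position substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `seq`, `family`.
#' @export
gen_family_sequences <- function(n_families, per_family, length = 22L,
                                 mut_rate = 0.08, seed = 1L) {
  stopifnot(n_families >= 1L, per_family >= 1L, length >= 1L,
            mut_rate >= 0, mut_rate < 1)
  wf <- nchar(as.character(n_families))
  wm <- nchar(as.character(per_family))
  with_seed(seed, {
    rows <- lapply(seq_len(n_families), function(f) {
      consensus <- sample(RNA_ALPHABET, length, replace = TRUE)
      seqs <- vapply(seq_len(per_family), function(m) {
        s <- consensus
        hit <- stats::runif(length) < mut_rate
        if (any(hit)) {
          s[hit] <- vapply(s[hit], function(base)
            sample(setdiff(RNA_ALPHABET, base), 1), character(1))
        }
        paste(s, collapse = "")
      }, character(1))
      tibble::tibble(
        id = sprintf("mir-f%0*d-%0*d", wf, f, wm, seq_len(per_family)),
        seq = seqs,
        family = f
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate a planted-block association matrix
#'
#' miRNA families are paired with disease blocks; a cell is positive with
#' probability `p_in` when the miRNA's family matches the disease's block
#' and `p_out` otherwise, drawn independently under `seed`.
#'
#' @param mirna_ids,disease_ids Entity ids (define matrix order).
#' @param families,blocks Integer assignment per miRNA / disease. Defaults
#'   to round-robin over `n_blocks`.
#' @param n_blocks Number of family/block pairs (used for the defaults).
#' @param p_in,p_out In-block and out-of-block association probabilities;
#'   the degenerate `p_in == p_out` case is rejected.
#' @param seed Integer seed.
#' @return List with `associations` (binary matrix), `truth` (the
#'   structural block mask), `families`, `blocks`.
#' @export
gen_block_associations <- function(mirna_ids, disease_ids,
                                   families = NULL, blocks = NULL,
                                   n_blocks = 4L, p_in = 0.35, p_out = 0.02,
                                   seed = 1L) {
  n_m <- length(mirna_ids); n_d <- length(disease_ids)
  stopifnot(n_m >= 1L, n_d >= 1L, p_out >= 0, p_in <= 1, p_out <= p_in)
  if (p_in == p_out) {
    rlang::abort("degenerate block model: p_in equals p_out",
                 class = "mirgae_degenerate_error")
  }
  if (is.null(families)) families <- rep(seq_len(n_blocks), length.out = n_m)
  if (is.null(blocks)) blocks <- rep(seq_len(n_blocks), length.out = n_d)
  stopifnot(length(families) == n_m, length(blocks) == n_d)
  mask <- outer(families, blocks, "==")
  P <- ifelse(mask, p_in, p_out)
  A <- with_seed(seed, (matrix(stats::runif(n_m * n_d), n_m, n_d) < P) * 1)
  dimnames(A) <- list(mirna_ids, disease_ids)
  truth <- mask * 1
  dimnames(truth) <- dimnames(A)
  list(associations = A, truth = truth,
       families = stats::setNames(families, mirna_ids),
       blocks = stats::setNames(blocks, disease_ids))
}

#' Generate a random disease DAG from a rooted code tree
#'
#' Tree-number codes are sampled as distinct leaf paths of a complete
#' `branching`-ary tree of the given depth. When `blocks` is supplied, each
#' block is anchored to its own internal subtree so same-block diseases
#' share code prefixes (making semantic similarity informative about the
#' planted structure).
#'
#' @param disease_ids Disease ids.
#' @param blocks Optional integer block assignment per disease.
#' @param depth,branching Tree shape; capacity `branching^depth` must cover
#'   the diseases (and each block must fit inside one subtree).
#' @param seed Integer seed.
#' @return A [disease_dag()] with one code per disease.
#' @export
gen_random_dag <- function(disease_ids, blocks = NULL, depth = 3L,
                           branching = 3L, seed = 1L) {
  n <- length(disease_ids)
  stopifnot(n >= 1L, depth >= 1L, branching >= 1L)
  if (branching^depth < n) {
    rlang::abort(sprintf("tree capacity %d < %d diseases", branching^depth, n))
  }
  paths_under <- function(prefix, levels) {
    if (levels == 0L) return(paste(prefix, collapse = "."))
    g <- expand.grid(rep(list(seq_len(branching)), levels))[, rev(seq_len(levels)), drop = FALSE]
    apply(g, 1, function(r) paste(c(prefix, r), collapse = "."))
  }
  codes <- with_seed(seed, {
    if (is.null(blocks)) {
      leaves <- paths_under(integer(0), depth)
      sample(leaves, n)
    } else {
      stopifnot(length(blocks) == n)
      n_blocks <- max(blocks)
      sizes <- table(factor(blocks, levels = seq_len(n_blocks)))
      lev <- NA_integer_
      for (l in seq_len(depth - 1L)) {
        if (branching^l >= n_blocks && branching^(depth - l) >= max(sizes)) {
          lev <- l; break
        }
      }
      if (is.na(lev)) {
        rlang::abort("tree cannot anchor every block in its own subtree; increase depth or branching")
      }
      anchors <- paths_under(integer(0), lev)
      out <- character(n)
      for (b in seq_len(n_blocks)) {
        members <- which(blocks == b)
        sub_leaves <- paths_under(strsplit(anchors[b], ".", fixed = TRUE)[[1]],
                                  depth - lev)
        out[members] <- sample(sub_leaves, length(members))
      }
      out
    }
  })
  disease_dag(stats::setNames(as.list(codes), disease_ids))
}

FIXTURE_PROFILES <- c("tiny", "default", "null")

#' Build a complete planted fixture
#'
#' Profiles: `tiny` (12 miRNAs x 8 diseases, 4 families/blocks; unit
#' tests), `default` (120 x 80, 6 families/blocks, p_in 0.35 / p_out 0.02;
#' full evaluation), and `null` (default sizes with a uniform association
#' probability equal to the default profile's expected density, 0.075 - a
#' no-signal control with an empty truth mask). Signal is planted in both
#' channels the model uses: sequence families align with association
#' blocks, and same-block diseases share DAG subtrees.
#'
#' @param profile One of `"tiny"`, `"default"`, `"null"`.
#' @param seed Master seed; generators draw from derived streams.
#' @return A `planted_fixture`: `sequences`, `associations`, `dag`,
#'   `truth`, `families`, `blocks`, `profile`, `seed`.
#' @export
make_fixture <- function(profile = c("tiny", "default", "null"), seed = 1L) {
  profile <- match.arg(profile)
  spec <- switch(profile,
    tiny = list(n_fam = 4L, per_fam = 3L, n_d = 8L, p_in = 0.6, p_out = 0.05,
                depth = 3L, branching = 3L),
    default = list(n_fam = 6L, per_fam = 20L, n_d = 80L, p_in = 0.35, p_out = 0.02,
                   depth = 4L, branching = 4L),
    null = list(n_fam = 6L, per_fam = 20L, n_d = 80L, p = 0.075,
                depth = 4L, branching = 4L)
  )
  seqs <- gen_family_sequences(spec$n_fam, spec$per_fam,
                               seed = derive_seed(seed, "sequences"))
  wd <- nchar(as.character(spec$n_fam))
  blocks <- rep(seq_len(spec$n_fam), length.out = spec$n_d)
  disease_ids <- sprintf("disease-b%0*d-%02d", wd, blocks,
                         stats::ave(blocks, blocks, FUN = seq_along))
  ord <- order(disease_ids, method = "radix")
  disease_ids <- disease_ids[ord]; blocks <- blocks[ord]
  if (profile == "null") {
    A <- with_seed(derive_seed(seed, "associations"),
                   (matrix(stats::runif(nrow(seqs) * spec$n_d),
                           nrow(seqs), spec$n_d) < spec$p) * 1)
    dimnames(A) <- list(seqs$id, disease_ids)
    truth <- A * 0
    families <- stats::setNames(seqs$family, seqs$id)
    blocks_named <- stats::setNames(blocks, disease_ids)
    assoc <- list(associations = A, truth = truth,
                  families = families, blocks = blocks_named)
  } else {
    assoc <- gen_block_associations(
      seqs$id, disease_ids, families = seqs$family, blocks = blocks,
      p_in = spec$p_in, p_out = spec$p_out,
      seed = derive_seed(seed, "associations")
    )
  }
  dag <- gen_random_dag(disease_ids, blocks = blocks, depth = spec$depth,
                        branching = spec$branching,
                        seed = derive_seed(seed, "dag"))
  structure(
    list(sequences = seqs, associations = assoc$associations,
         dag = dag, truth = assoc$truth, families = assoc$families,
         blocks = assoc$blocks, profile = profile, seed = seed),
    class = "planted_fixture"
  )
}

#' @export
print.planted_fixture <- function(x, ...) {
  cat(sprintf("<planted_fixture> profile '%s' | %d miRNAs x %d diseases | %d positives (seed %s)\n",
              x$profile, nrow(x$associations), ncol(x$associations),
              sum(x$associations), x$seed))
  invisible(x)
}

#' Write a fixture to disk in the pipeline's input formats
#'
#' Emits `sequences.fasta`, `associations.tsv`, `mesh.tsv`, `truth.csv`
#' and `manifest.json` (generator parameters and seed) under `dir`.
#'
#' @param fixture A [make_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "planted_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mirna_fasta(fixture$sequences, file.path(dir, "sequences.fasta"))
  pairs <- association_pairs(fixture$associations)
  utils::write.table(pairs, file.path(dir, "associations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = c("mirna", "disease"))
  mesh <- data.frame(
    disease = fixture$dag$disease_ids,
    codes = vapply(fixture$dag$tree_numbers, paste, character(1), collapse = ";")
  )
  utils::write.table(mesh, file.path(dir, "mesh.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = c("disease", "codes"))
  write_table(fixture$truth, file.path(dir, "truth.csv"), kind = "matrix")
  manifest <- list(
    profile = fixture$profile, seed = fixture$seed,
    n_mirna = nrow(fixture$associations), n_disease = ncol(fixture$associations),
    n_positive = sum(fixture$associations),
    files = c("sequences.fasta", "associations.tsv", "mesh.tsv", "truth.csv")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
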