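#' Identity-times-coverage similarity between two protein sequences
#'
#' Locally aligns the query `seq_a` against the subject `seq_b`
#' (Smith-Waterman with affine gaps; BLOSUM62, gap open 11 / extend 1 by
#' default) and reports `identity` (identical columns / alignment columns),
#' `coverage` (alignment columns / query length, capped at 1) and their
#' product `score`, the similarity measure used to cap train/test homology.
#' When nothing aligns with positive score, all three are 0. With
#' `symmetrize = TRUE` the query/subject orderings are both evaluated and the
#' larger score (with its identity/coverage) is returned, so the measure no
#' longer depends on direction.
#'
#' @param seq_a query amino-acid sequence.
#' @param seq_b subject amino-acid sequence.
#' @param submat substitution matrix: a name known to Biostrings (e.g.
#'   `"BLOSUM62"`) or a numeric matrix with residue dimnames.
#' @param gap_open,gap_ext affine gap penalties (positive numbers).
#' @param symmetrize take the max over both query orderings.
#' @return A one-row data frame: `identity`, `coverage`, `score`.
#' @export
pairwise_similarity <- function(seq_a, seq_b, submat = "BLOSUM62",
                                gap_open = 11, gap_ext = 1,
                                symmetrize = FALSE) {
  stopifnot(nchar(seq_a) > 0L, nchar(seq_b) > 0L)
  if (is.character(submat)) {
    e <- new.env()
    utils::data(list = submat, package = "Biostrings", envir = e)
    submat <- get(submat, envir = e)
  }
  one <- function(q, s) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(q), Biostrings::AAString(s), type = "local",
      substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_ext)
    ncols <- Biostrings::nchar(aln)
    if (Biostrings::score(aln) <= 0 || ncols == 0L)
      return(c(identity = 0, coverage = 0, score = 0))
    identity <- Biostrings::nmatch(aln) / ncols
    coverage <- min(1, ncols / nchar(q))
    c(identity = identity, coverage = coverage, score = identity * coverage)
  }
  res <- one(seq_a, seq_b)
  if (symmetrize) {
    res2 <- one(seq_b, seq_a)
    if (res2[["score"]] > res[["score"]]) res <- res2
  }
  as.data.frame(as.list(res))
}

#' All-against-all symmetrized similarity scores for a record collection
#'
#' Computes [pairwise_similarity()] (symmetrized) for every unordered pair of
#' records, for use by [split_by_similarity()]. Quadratic in the number of
#' records; intended for benchmark-construction scale, with precomputed
#' external score tables accepted as a drop-in wherever this output is.
#'
#' @param records a [protein_records] data frame.
#' @param ... passed to [pairwise_similarity()].
#' @return Data frame with columns `id_a`, `id_b`, `identity`, `coverage`,
#'   `score`, one row per unordered pair.
#' @export
similarity_scores <- function(records, ...) {
  n <- nrow(records)
  pairs <- if (n >= 2L) utils::combn(n, 2L) else matrix(integer(), 2L, 0L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i <- pairs[1L, j]; k <- pairs[2L, j]
    s <- pairwise_similarity(records$sequence[i], records$sequence[k],
                             symmetrize = TRUE, ...)
    cbind(data.frame(id_a = records$id[i], id_b = records$id[k],
                     stringsAsFactors = FALSE), s)
  })
  if (!length(rows))
    return(data.frame(id_a = character(), id_b = character(),
                      identity = numeric(), coverage = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Read / write a pairwise score table
#'
#' Plain TSV with columns `id_a`, `id_b`, `identity`, `coverage`, `score`,
#' interchangeable with externally computed (e.g. BLASTP-derived) scores.
#'
#' @param scores score data frame as from [similarity_scores()].
#' @param path file path.
#' @return `write_scores_tsv`: `path` invisibly; `read_scores_tsv`: the data
#'   frame.
#' @export
write_scores_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores_tsv
#' @export
read_scores_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id_a", "id_b", "identity", "coverage", "score")
  if (!all(need %in% names(df)))
    stop("score table must have columns: ", paste(need, collapse = ", "))
  df[need]
}
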