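#' Read a protein FASTA file into protein records
#'
#' The first whitespace-delimited token of each header becomes the record id,
#' the remainder of the line its description. Sequences are uppercased and
#' characters outside the 20 standard residue letters are mapped to `X`.
#'
#' @param path path to a (multi-record, optionally line-wrapped) FASTA file.
#' @return A [protein_records] data frame.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 trimws(sub("^\\S+\\s+", "", headers)), "")
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  protein_records(id = id, sequence = as.character(set), description = desc)
}

#' Write protein records to a FASTA file
#'
#' Header is `>id description` (description omitted when empty); sequences are
#' written unwrapped.
#'
#' @param records a [protein_records] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  hdr <- ifelse(nzchar(records$description),
                paste(records$id, records$description), records$id)
  lines <- character(2L * nrow(records))
  if (nrow(records)) {
    lines[c(TRUE, FALSE)] <- paste0(">", hdr)
    lines[c(FALSE, TRUE)] <- records$sequence
  }
  writeLines(lines, path)
  invisible(path)
}

#' Translate a coding sequence under the standard genetic code
#'
#' Frame-0 translation of a nucleotide string. Translation stops at the first
#' stop codon (which is not emitted); codons containing `N` translate to `X`;
#' a trailing partial codon is ignored.
#'
#' @param nucleotides a DNA string over the alphabet `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive).
#' @return The amino-acid string.
#' @examples
#' translate_cds("ATGAAACAAAAT")  # "MKQN"
#' translate_cds("ATGTAAAAA")     # "M" (stop terminates)
#' @export
translate_cds <- function(nucleotides) {
  nt <- toupper(as.character(nucleotides))
  if (length(nt) != 1L || is.na(nt)) stop("expected a single nucleotide string")
  if (nchar(nt) < 3L) stop("coding sequence shorter than one codon")
  if (grepl("[^ACGTN]", nt)) stop("invalid nucleotide character in coding sequence")
  nt <- substr(nt, 1L, 3L * (nchar(nt) %/% 3L))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           if.fuzzy.codon = "X"))
  sub("\\*.*$", "", aa)
}

#' Reverse-complement a nucleotide string
#'
#' @param nucleotides a DNA string over `A`, `C`, `G`, `T`, `N`.
#' @return The reverse complement, uppercase.
#' @export
reverse_complement <- function(nucleotides) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(toupper(as.character(nucleotides)))))
}

#' Write annotation predictions to a TSV file
#'
#' Tab-separated with header `id`, `pvp_call`, `pvp_confidence`, `category`,
#' `category_confidence`; confidences rendered with 4 decimals; absent
#' categories written as `NA`.
#'
#' @param results an annotation result data frame as returned by
#'   [annotate_proteins()] (columns `id`, `pvp_call`, `pvp_confidence`,
#'   `category`, `category_confidence`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(results, path) {
  fmt4 <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))
  out <- data.frame(
    id = results$id,
    pvp_call = results$pvp_call,
    pvp_confidence = fmt4(results$pvp_confidence),
    category = ifelse(is.na(results$category), "NA", results$category),
    category_confidence = fmt4(results$category_confidence),
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
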