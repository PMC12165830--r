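#' The seven functional categories of phage virion proteins
#'
#' Fixed, ordered set of structural-protein categories used by the multi-class
#' annotation head. The order defines the class-index mapping of the
#' classifier, so it must not be changed between training and prediction.
#'
#' @format Character vector of length 7.
#' @export
PVP_CATEGORIES <- c(
  "portal", "major capsid", "minor capsid",
  "major tail", "minor tail", "baseplate", "tail fiber"
)

#' Valid binary labels for a protein record
#' @keywords internal
BINARY_LABELS <- c("PVP", "nonPVP", "unlabeled")

# The 20 standard amino-acid one-letter codes; everything else is mapped to X.
AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a collection of protein records
#'
#' A protein record collection is a plain `data.frame` with one row per
#' protein and columns `id`, `sequence`, `description`, `release_date`
#' (a `Date` or `NA`), `binary_label` (one of `"PVP"`, `"nonPVP"`,
#' `"unlabeled"`) and `category` (one of [PVP_CATEGORIES] or `NA`). It is the
#' unit that flows through labeling, splitting and embedding.
#'
#' @param id character vector of unique, non-empty protein identifiers.
#' @param sequence character vector of amino-acid sequences; uppercased, and
#'   any character outside the 20 standard residue letters is replaced by `X`.
#' @param description free-text annotation lines (default `""`).
#' @param release_date `Date` vector (or coercible), `NA` allowed.
#' @param binary_label one of `"PVP"`, `"nonPVP"`, `"unlabeled"`.
#' @param category one of [PVP_CATEGORIES], or `NA`. A category may only be
#'   present on records labeled `"PVP"`.
#' @return A `data.frame` of class `protein_records`.
#' @examples
#' protein_records(c("p1", "p2"), c("MKQN", "mavt*"),
#'                 description = c("major capsid protein", "hypothetical protein"))
#' @export
protein_records <- function(id, sequence, description = "",
                            release_date = as.Date(NA),
                            binary_label = "unlabeled", category = NA_character_) {
  id <- as.character(id)
  sequence <- clean_aa(as.character(sequence))
  n <- length(id)
  if (n == 0L) {
    df <- data.frame(id = character(), sequence = character(),
                     description = character(),
                     release_date = as.Date(character()),
                     binary_label = character(), category = character(),
                     stringsAsFactors = FALSE)
    class(df) <- c("protein_records", "data.frame")
    return(df)
  }
  df <- data.frame(
    id = id,
    sequence = sequence,
    description = rep_len(as.character(description), n),
    release_date = rep_len(as.Date(release_date), n),
    binary_label = rep_len(as.character(binary_label), n),
    category = rep_len(as.character(category), n),
    stringsAsFactors = FALSE
  )
  validate_protein_records(df)
}

#' @keywords internal
validate_protein_records <- function(df) {
  if (anyNA(df$id) || any(!nzchar(df$id)))
    stop("protein ids must be non-empty")
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup))
    stop("duplicate protein id(s): ", paste(dup, collapse = ", "))
  if (any(!nzchar(df$sequence)))
    stop("empty sequence for id(s): ",
         paste(df$id[!nzchar(df$sequence)], collapse = ", "))
  bad <- !(df$binary_label %in% BINARY_LABELS)
  if (any(bad))
    stop("invalid binary_label: ", paste(unique(df$binary_label[bad]), collapse = ", "))
  badc <- !is.na(df$category) & !(df$category %in% PVP_CATEGORIES)
  if (any(badc))
    stop("invalid category: ", paste(unique(df$category[badc]), collapse = ", "))
  stray <- !is.na(df$category) & df$binary_label != "PVP"
  if (any(stray))
    stop("category present on non-PVP record(s): ",
         paste(df$id[stray], collapse = ", "))
  class(df) <- unique(c("protein_records", class(df)))
  rownames(df) <- NULL
  df
}

#' Normalize an amino-acid string
#'
#' Uppercases and maps every character outside the 20 standard one-letter
#' residue codes (including `B`, `Z`, `U`, `*`, gaps) to `X`.
#'
#' @param x character vector of sequences.
#' @return character vector of cleaned sequences.
#' @export
clean_aa <- function(x) {
  x <- toupper(x)
  gsub(sprintf("[^%sX]", paste(AA_STANDARD, collapse = "")), "X", x)
}

#' @export
print.protein_records <- function(x, ...) {
  cat(sprintf("protein_records: %d record(s)\n", nrow(x)))
  if (nrow(x)) {
    tab <- table(factor(x$binary_label, levels = BINARY_LABELS))
    cat(sprintf("  labels: PVP=%d nonPVP=%d unlabeled=%d\n",
                tab[["PVP"]], tab[["nonPVP"]], tab[["unlabeled"]]))
    print(utils::head(as.data.frame(x), 6L), ...)
    if (nrow(x) > 6L) cat(sprintf("  ... and %d more\n", nrow(x) - 6L))
  }
  invisible(x)
}
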