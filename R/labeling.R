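#' Default keyword rule set for labeling RefSeq-style annotation lines
#'
#' Builds the rule set used to derive binary (virion / non-virion) labels and
#' functional categories from free-text protein descriptions. Structural
#' keywords select virion proteins (PVP); non-structural keywords, together
#' with any whitespace-delimited word ending in the enzyme suffix `"ase"`,
#' select non-PVPs. Category phrases map a structural description onto one of
#' the seven functional categories and are matched longest phrase first, so
#' `"major capsid"` wins over the generic `"capsid"`.
#'
#' @param structural_keywords character vector of phrases whose presence marks
#'   a structural (virion) protein.
#' @param nonstructural_keywords phrases marking known non-structural proteins.
#' @param enzyme_suffix suffix (matched at a word boundary) marking enzymes.
#' @param category_keywords named character vector mapping a phrase to a
#'   functional category; every value must be one of [PVP_CATEGORIES].
#' @return A list of class `label_rules`.
#' @export
label_rules <- function(
    structural_keywords = c("portal", "capsid", "tail", "fiber",
                            "tape measure", "baseplate", "structural"),
    nonstructural_keywords = c("transcription", "holin", "lysin", "regulator"),
    enzyme_suffix = "ase",
    category_keywords = stats::setNames(PVP_CATEGORIES, PVP_CATEGORIES)) {
  category_keywords <- category_keywords[order(-nchar(names(category_keywords)))]
  if (!all(category_keywords %in% PVP_CATEGORIES))
    stop("category_keywords values must be one of: ",
         paste(PVP_CATEGORIES, collapse = ", "))
  # every category phrase must imply a structural match, or PVP records could
  # carry a category without being structural
  implied <- vapply(names(category_keywords), function(ph) {
    any(vapply(structural_keywords,
               function(s) grepl(s, ph, fixed = TRUE), logical(1)))
  }, logical(1))
  if (!all(implied))
    stop("category phrase(s) not covered by a structural keyword: ",
         paste(names(category_keywords)[!implied], collapse = ", "))
  structure(list(structural_keywords = structural_keywords,
                 nonstructural_keywords = nonstructural_keywords,
                 enzyme_suffix = enzyme_suffix,
                 category_keywords = category_keywords),
            class = "label_rules")
}

#' Label protein records from their description lines
#'
#' Applies the keyword rules to each record's description. A structural
#' keyword match labels the record `PVP` (structural matching takes precedence
#' over enzyme-suffix matching, so e.g. "capsid maturation protease" is PVP);
#' otherwise a non-structural keyword, or any word ending in the enzyme
#' suffix, labels it `nonPVP`; otherwise it stays `unlabeled`. PVP records
#' additionally receive the first (longest-phrase-first) matching functional
#' category, or no category when only a generic structural keyword matched.
#' Matching is case-insensitive; labeling is deterministic and idempotent.
#'
#' @param records a [protein_records] data frame with descriptions.
#' @param rules a [label_rules] object.
#' @return The records with `binary_label` and `category` filled in.
#' @examples
#' r <- protein_records(c("a", "b", "c"), c("MK", "MK", "MK"),
#'                      description = c("major capsid protein",
#'                                      "DNA polymerase", "hypothetical protein"))
#' label_records(r)$binary_label  # "PVP" "nonPVP" "unlabeled"
#' @export
label_records <- function(records, rules = label_rules()) {
  stopifnot(inherits(rules, "label_rules"))
  desc <- tolower(records$description)
  has_any <- function(d, phrases) {
    out <- rep(FALSE, length(d))
    for (p in phrases) out <- out | grepl(p, d, fixed = TRUE)
    out
  }
  structural <- has_any(desc, tolower(rules$structural_keywords))
  nonstruct <- has_any(desc, tolower(rules$nonstructural_keywords)) |
    grepl(paste0("[[:alpha:]]*", tolower(rules$enzyme_suffix), "\\b"), desc)
  records$binary_label <- ifelse(structural, "PVP",
                                 ifelse(nonstruct, "nonPVP", "unlabeled"))
  cat_phrases <- tolower(names(rules$category_keywords))  # longest first
  records$category <- NA_character_
  for (i in seq_along(cat_phrases)) {
    hit <- structural & is.na(records$category) &
      grepl(cat_phrases[i], desc, fixed = TRUE)
    records$category[hit] <- unname(rules$category_keywords[i])
  }
  validate_protein_records(records)
}
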