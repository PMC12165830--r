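#' Two-stage annotation of proteins
#'
#' Stage 1 classifies every protein as virion (PVP) or not with the binary
#' model; stage 2 assigns one of the seven functional categories, with a
#' softmax confidence, to the proteins called PVP. The category confidence is
#' banded as `"high"` when it exceeds `high_conf` and `"moderate_low"`
#' otherwise — low confidence is surfaced rather than suppressed, so proteins
#' outside the seven trained categories show up as cautious calls instead of
#' being silently dropped.
#'
#' @param records a [protein_records] data frame.
#' @param binary_model trained 2-class `pvp_model` whose class levels are
#'   `PVP` / `nonPVP`.
#' @param multi_model trained 7-class `pvp_model` over [PVP_CATEGORIES].
#' @param backend the [embedder_backend] shared by both models.
#' @param high_conf category-confidence threshold separating the `high` band
#'   (default 0.997).
#' @return Data frame of class `annotation_result`, one row per input record
#'   in input order: `id`, `pvp_call`, `pvp_confidence`, `category`,
#'   `category_confidence`, `confidence_band`.
#' @export
annotate_proteins <- function(records, binary_model, multi_model, backend,
                              high_conf = 0.997) {
  stopifnot(inherits(binary_model, "pvp_model"),
            inherits(multi_model, "pvp_model"),
            inherits(backend, "embedder_backend"))
  if (binary_model$config$input_dim != backend$dim ||
      multi_model$config$input_dim != backend$dim)
    stop("models and backend disagree on embedding dimension")
  if (!setequal(binary_model$meta$class_levels, c("PVP", "nonPVP")))
    stop("binary model must be trained on PVP/nonPVP labels")

  out <- data.frame(id = records$id, pvp_call = NA_character_,
                    pvp_confidence = NA_real_, category = NA_character_,
                    category_confidence = NA_real_,
                    confidence_band = NA_character_,
                    stringsAsFactors = FALSE)
  if (!nrow(records)) {
    class(out) <- c("annotation_result", "data.frame")
    return(out)
  }
  table <- embed_proteins(records, backend)
  p1 <- predict_table(binary_model, table)
  out$pvp_call <- p1$class
  out$pvp_confidence <- p1$confidence

  is_pvp <- out$pvp_call == "PVP"
  if (any(is_pvp)) {
    sub <- subset_table(table, records$id[is_pvp])
    p2 <- predict_table(multi_model, sub)
    out$category[is_pvp] <- p2$class
    out$category_confidence[is_pvp] <- p2$confidence
    out$confidence_band[is_pvp] <-
      ifelse(p2$confidence > high_conf, "high", "moderate_low")
  }
  class(out) <- c("annotation_result", "data.frame")
  out
}

#' Filter annotation results by functional category
#'
#' Returns exactly the results annotated with the given category, in input
#' order — e.g. the tail-fiber extraction feeding phage-host prediction.
#'
#' @param results an `annotation_result` data frame.
#' @param category one of [PVP_CATEGORIES].
#' @return The matching subset, same columns and order.
#' @export
filter_by_category <- function(results, category) {
  if (!(category %in% PVP_CATEGORIES))
    stop("unknown category '", category, "'; valid categories: ",
         paste(PVP_CATEGORIES, collapse = ", "))
  out <- results[!is.na(results$category) & results$category == category, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an ORF table
#'
#' Tab-separated with columns `id`, `contig`, `start`, `end`, `strand`,
#' `sequence` (nucleotides) — the shape produced by external gene callers'
#' coordinate + sequence outputs. Coordinates are 1-based inclusive.
#'
#' @param path TSV path.
#' @return Data frame with those columns.
#' @export
read_orf_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "contig", "start", "end", "strand", "sequence")
  if (!all(need %in% names(df)))
    stop("ORF table must have columns: ", paste(need, collapse = ", "))
  df[need]
}

#' Annotate called ORFs from a genome
#'
#' Translates each ORF (reverse-complementing minus-strand entries first),
#' runs the two-stage annotation, and optionally writes a predictions TSV and
#' a GFF3 file with one CDS feature per protein carrying the call, category
#' and confidences as attributes.
#'
#' @param orfs ORF table as from [read_orf_table()]: `id`, `contig`, `start`,
#'   `end` (1-based inclusive), `strand` (`+`/`-`), `sequence` (nucleotides).
#' @param binary_model,multi_model,backend as in [annotate_proteins()].
#' @param gff_path,tsv_path optional output paths.
#' @param high_conf see [annotate_proteins()].
#' @return List with `results` (the `annotation_result`) and `proteins` (the
#'   translated [protein_records]).
#' @export
annotate_genome <- function(orfs, binary_model, multi_model, backend,
                            gff_path = NULL, tsv_path = NULL,
                            high_conf = 0.997) {
  stopifnot(all(c("id", "contig", "start", "end", "strand", "sequence")
                %in% names(orfs)))
  span <- orfs$end - orfs$start + 1L
  bad <- span != nchar(orfs$sequence)
  if (any(bad))
    stop("ORF coordinate span and sequence length disagree for: ",
         paste(orfs$id[bad], collapse = ", "))
  if (!all(orfs$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")

  aa <- vapply(seq_len(nrow(orfs)), function(i) {
    nt <- orfs$sequence[i]
    if (orfs$strand[i] == "-") nt <- reverse_complement(nt)
    translate_cds(nt)
  }, character(1))
  proteins <- protein_records(orfs$id, aa,
                              description = sprintf("ORF %s:%d-%d(%s)",
                                                    orfs$contig, orfs$start,
                                                    orfs$end, orfs$strand))
  results <- annotate_proteins(proteins, binary_model, multi_model, backend,
                               high_conf = high_conf)
  if (!is.null(tsv_path)) write_predictions_tsv(results, tsv_path)
  if (!is.null(gff_path)) write_annotation_gff3(results, orfs, gff_path)
  list(results = results, proteins = proteins)
}

#' Write annotation results as GFF3
#'
#' One `CDS` feature per ORF, 1-based inclusive coordinates, with
#' `ID`, `pvp_call`, `category` and the confidences as attributes
#' (URL-escaped by the writer); round-trips through standard GFF3 parsers.
#'
#' @param results an `annotation_result` aligned with `orfs` by `id`.
#' @param orfs the ORF table the results were computed from.
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(results, orfs, path) {
  i <- match(results$id, orfs$id)
  if (anyNA(i)) stop("results contain ids absent from the ORF table")
  gr <- GenomicRanges::GRanges(
    seqnames = orfs$contig[i],
    ranges = IRanges::IRanges(start = orfs$start[i], end = orfs$end[i]),
    strand = orfs$strand[i])
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "pvpanno", type = "CDS", phase = 0L,
    ID = results$id,
    pvp_call = results$pvp_call,
    pvp_confidence = sprintf("%.4f", results$pvp_confidence),
    category = ifelse(is.na(results$category), "NA", results$category),
    category_confidence = ifelse(is.na(results$category_confidence), "NA",
                                 sprintf("%.4f", results$category_confidence)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
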