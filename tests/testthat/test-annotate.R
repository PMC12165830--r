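# Shared two-stage fixture: a deterministic k-mer backend plus binary and
# 7-class models trained on embedded synthetic protein families. Built once
# per test run.
annotate_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    backend <- kmer_hash_backend(dim = 48, k = 3, seed = 5)
    fams <- gen_protein_families(9, 12, length = 120, mutation_rate = 0.05,
                                 seed = 13)
    fam_of <- sub("_m\\d+$", "", fams$id)
    # families 1-7 carry the seven categories; 8-9 are non-virion
    cats <- PVP_CATEGORIES[match(fam_of, paste0("fam", 1:7))]
    binary <- ifelse(is.na(cats), "nonPVP", "PVP")
    tab <- embed_proteins(fams, backend)
    mc <- function(C, seed) classifier_config(input_dim = 48,
                                              conv_filters = 4,
                                              hidden_units = 16,
                                              n_classes = C, seed = seed)
    bin_model <- train(tab, binary, model_config = mc(2, 1),
                       train_cfg = train_config(seed = 1, max_epochs = 30,
                                                batch_size = 32))
    pvp_idx <- which(binary == "PVP")
    multi_model <- train(subset_table(tab, fams$id[pvp_idx]), cats[pvp_idx],
                         model_config = mc(7, 2),
                         train_cfg = train_config(seed = 2, max_epochs = 30,
                                                  batch_size = 32))
    cache <<- list(backend = backend, records = fams, truth_binary = binary,
                   truth_cat = cats, bin_model = bin_model,
                   multi_model = multi_model)
    cache
  }
})

test_that("two-stage annotation conserves counts and the category rule", {
  fx <- annotate_fixture()
  res <- annotate_proteins(fx$records, fx$bin_model, fx$multi_model,
                           fx$backend)
  expect_equal(nrow(res), nrow(fx$records))
  expect_equal(res$id, fx$records$id)
  expect_true(all(res$pvp_call %in% c("PVP", "nonPVP")))
  # category present iff called PVP
  expect_identical(is.na(res$category), res$pvp_call == "nonPVP")
  expect_identical(is.na(res$category_confidence), res$pvp_call == "nonPVP")
  expect_true(all(is.na(res$category) | res$category %in% PVP_CATEGORIES))
  # the families are easy: the learned two-stage calls track the truth
  expect_gte(mean(res$pvp_call == fx$truth_binary), 0.9)
})

test_that("confidence bands split exactly at the threshold", {
  fx <- annotate_fixture()
  res <- annotate_proteins(fx$records, fx$bin_model, fx$multi_model,
                           fx$backend, high_conf = 0.6)
  pvp <- res[res$pvp_call == "PVP", ]
  expect_identical(pvp$confidence_band == "high",
                   pvp$category_confidence > 0.6)
  # threshold 0 makes every PVP high-confidence
  res0 <- annotate_proteins(fx$records, fx$bin_model, fx$multi_model,
                            fx$backend, high_conf = 0)
  expect_true(all(res0$confidence_band[res0$pvp_call == "PVP"] == "high"))
})

test_that("category filtering partitions the PVP calls", {
  fx <- annotate_fixture()
  res <- annotate_proteins(fx$records, fx$bin_model, fx$multi_model,
                           fx$backend)
  parts <- lapply(PVP_CATEGORIES, function(cc) filter_by_category(res, cc))
  expect_equal(sum(vapply(parts, nrow, integer(1))),
               sum(res$pvp_call == "PVP"))
  tf <- filter_by_category(res, "tail fiber")
  expect_true(all(tf$category == "tail fiber"))
  expect_equal(nrow(filter_by_category(res[0, ], "portal")), 0)
  expect_error(filter_by_category(res, "tailfiber"), "valid categories")
})

test_that("mismatched embedder and model dimensions are refused", {
  fx <- annotate_fixture()
  wrong <- kmer_hash_backend(dim = 32, seed = 1)
  expect_error(annotate_proteins(fx$records, fx$bin_model, fx$multi_model,
                                 wrong), "dimension")
})

make_orfs <- function(proteins, revcomp_idx = integer()) {
  nt <- vapply(seq_len(nrow(proteins)), function(i) {
    codons <- c("GCT", "TGC", "GAT", "GAA", "TTT", "GGT", "CAT", "ATT",
                "AAA", "TTA", "ATG", "AAT", "CCT", "CAA", "CGT", "TCT",
                "ACT", "GTT", "TGG", "TAT")
    names(codons) <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    paste(codons[strsplit(proteins$sequence[i], "")[[1]]], collapse = "")
  }, character(1))
  strand <- rep("+", nrow(proteins))
  for (i in revcomp_idx) {
    nt[i] <- reverse_complement(nt[i])
    strand[i] <- "-"
  }
  start <- cumsum(c(1, head(nchar(nt), -1) + 50))
  data.frame(id = proteins$id, contig = "toy_genome", start = start,
             end = start + nchar(nt) - 1L, strand = strand, sequence = nt,
             stringsAsFactors = FALSE)
}

test_that("genome annotation translates both strands and emits GFF3", {
  fx <- annotate_fixture()
  prot <- fx$records[1:15, ]
  orfs <- make_orfs(prot, revcomp_idx = c(2, 9))
  gff <- withr::local_tempfile(fileext = ".gff3")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  out <- annotate_genome(orfs, fx$bin_model, fx$multi_model, fx$backend,
                         gff_path = gff, tsv_path = tsv)
  expect_equal(out$proteins$sequence, prot$sequence)  # incl. minus strand
  expect_equal(nrow(out$results), 15)
  # GFF3 round trip through a standard parser
  gr <- rtracklayer::import(gff)
  expect_length(gr, 15)
  expect_equal(as.character(GenomicRanges::strand(gr))[c(2, 9)], c("-", "-"))
  expect_equal(BiocGenerics::start(gr), orfs$start)
  expect_equal(BiocGenerics::end(gr), orfs$end)
  expect_equal(gr$pvp_call, out$results$pvp_call)
  # TSV written with one row per ORF
  expect_equal(length(readLines(tsv)), 16)
})

test_that("coordinate/sequence disagreements name the offending ORF", {
  fx <- annotate_fixture()
  orfs <- make_orfs(fx$records[1:3, ])
  orfs$end[2] <- orfs$end[2] + 3L
  expect_error(annotate_genome(orfs, fx$bin_model, fx$multi_model,
                               fx$backend), orfs$id[2])
  orfs$end[2] <- orfs$end[2] - 3L
  orfs$strand[1] <- "?"
  expect_error(annotate_genome(orfs, fx$bin_model, fx$multi_model,
                               fx$backend), "strand")
})

test_that("the pipeline is deterministic end to end", {
  fx <- annotate_fixture()
  orfs <- make_orfs(fx$records[1:10, ], revcomp_idx = 4)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  g1 <- withr::local_tempfile(fileext = ".gff3")
  g2 <- withr::local_tempfile(fileext = ".gff3")
  annotate_genome(orfs, fx$bin_model, fx$multi_model, fx$backend,
                  gff_path = g1, tsv_path = f1)
  annotate_genome(orfs, fx$bin_model, fx$multi_model, fx$backend,
                  gff_path = g2, tsv_path = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(g1), readLines(g2))
})

test_that("ORF tables round-trip from disk", {
  fx <- annotate_fixture()
  orfs <- make_orfs(fx$records[1:4, ])
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(orfs, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_orf_table(f)
  expect_equal(back, orfs)
  writeLines("id\tcontig", f)
  expect_error(read_orf_table(f), "columns")
})
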