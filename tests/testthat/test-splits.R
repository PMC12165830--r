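make_dated_records <- function(dates, labels = NULL) {
  n <- length(dates)
  protein_records(sprintf("d%03d", seq_len(n)), strrep("MKQNLV", 5),
                  release_date = as.Date(dates),
                  binary_label = if (is.null(labels)) "unlabeled" else labels)
}

test_that("time split partitions strictly at the cutoff date", {
  rec <- make_dated_records(c("2019-05-01", "2021-03-01", "2020-12-01",
                              "2020-11-30"))
  sp <- split_by_time(rec, as.Date("2020-12-01"))
  expect_setequal(sp$train_ids, c("d001", "d004"))
  expect_setequal(sp$test_ids, c("d002", "d003"))  # cutoff day itself -> test
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
})

test_that("time split warns when one side is empty and errors on missing dates", {
  rec <- make_dated_records(c("2018-01-01", "2019-01-01"))
  expect_warning(split_by_time(rec), "empty test")
  rec$release_date[2] <- NA
  expect_error(split_by_time(rec), "d002")
})

test_that("binary balancing down-samples the majority class to parity", {
  rec <- make_dated_records(
    rep(c("2019-06-01", "2021-06-01"), c(40, 20)),
    labels = c(rep(c("PVP", "nonPVP"), c(10, 30)),
               rep(c("PVP", "nonPVP"), c(5, 15))))
  sp <- split_by_time(rec, balance_binary = TRUE, seed = 3)
  lab <- function(ids) table(rec$binary_label[match(ids, rec$id)])
  expect_equal(as.integer(lab(sp$train_ids)[c("PVP", "nonPVP")]), c(10L, 10L))
  expect_equal(as.integer(lab(sp$test_ids)[c("PVP", "nonPVP")]), c(5L, 5L))
  # reproducible under the seed; train+test union unchanged across seeds
  sp2 <- split_by_time(rec, balance_binary = TRUE, seed = 3)
  expect_identical(sp$train_ids, sp2$train_ids)
})

test_that("similarity split keeps near-duplicates on one side", {
  set.seed(3)
  s <- rand_aa(1, 60)
  rec <- protein_records(c("a", "b", "c", "d"),
                         c(s, s, rand_aa(1, 60), rand_aa(1, 55)))
  sp <- split_by_similarity(rec, threshold = 0.9, test_fraction = 0.34,
                            seed = 1)
  same_side <- ("a" %in% sp$train_ids) == ("b" %in% sp$train_ids)
  expect_true(same_side)
})

test_that("with no similar pairs the per-class test count rounds up", {
  set.seed(6)
  rec <- protein_records(sprintf("u%02d", 1:10), rand_aa(10, 12))
  scores <- similarity_scores(rec)
  scores$score <- 0
  sp <- split_by_similarity(rec, threshold = 0.4, scores = scores,
                            test_fraction = 0.2, seed = 2)
  expect_length(sp$test_ids, 2)
  expect_length(sp$train_ids, 8)
})

test_that("whole families co-segregate and the cross-split cap holds", {
  rec <- gen_protein_families(3, 5, length = 80, mutation_rate = 0.03,
                              seed = 11)
  scores <- similarity_scores(rec)
  sp <- split_by_similarity(rec, threshold = 0.4, scores = scores,
                            test_fraction = 0.33, seed = 4)
  expect_length(sp$test_ids, 5)  # exactly one family of five
  fams <- unique(sub("_m\\d+$", "", sp$test_ids))
  expect_length(fams, 1)
  expect_lte(max_cross_split_score(sp, scores), 0.4)
})

test_that("an unsplittable giant component is reported with advice", {
  rec <- gen_protein_families(1, 8, length = 60, mutation_rate = 0.02,
                              seed = 9)
  expect_error(split_by_similarity(rec, threshold = 0.4,
                                   test_fraction = 0.2, seed = 1),
               "raise the threshold")
})

test_that("imbalance split reproduces the balance factor in both partitions", {
  set.seed(41)
  rec <- protein_records(sprintf("i%04d", 1:1000), strrep("MK", 10),
                         binary_label = rep(c("PVP", "nonPVP"), c(100, 900)))
  sp <- split_by_imbalance(rec, 3, train_fraction = 0.8, seed = 2)
  cnt <- function(ids) table(rec$binary_label[match(ids, rec$id)])
  expect_equal(as.integer(cnt(sp$train_ids)[c("PVP", "nonPVP")]), c(80L, 240L))
  expect_equal(as.integer(cnt(sp$test_ids)[c("PVP", "nonPVP")]), c(20L, 60L))
  # r = 1 gives equal counts; r = 9 uses all 900 nonPVP
  sp1 <- split_by_imbalance(rec, 1, seed = 5)
  c1 <- cnt(sp1$train_ids)
  expect_equal(unname(c1[["PVP"]]), unname(c1[["nonPVP"]]))
  sp9 <- split_by_imbalance(rec, 9, seed = 5)
  expect_equal(length(sp9$train_ids) + length(sp9$test_ids), 1000L)
  expect_error(split_by_imbalance(rec, 10, seed = 1), "maximum feasible")
})

test_that("imbalance ratio deviates by at most r in every partition", {
  set.seed(43)
  rec <- protein_records(sprintf("j%04d", 1:800), strrep("ML", 8),
                         binary_label = rep(c("PVP", "nonPVP"), c(70, 730)))
  for (r in c(1, 3, 5, 9)) {
    sp <- split_by_imbalance(rec, r, train_fraction = 0.8, seed = r)
    for (ids in list(sp$train_ids, sp$test_ids)) {
      tab <- table(rec$binary_label[match(ids, rec$id)])
      expect_lte(abs(tab[["nonPVP"]] - r * tab[["PVP"]]), r)
    }
  }
})

test_that("split manifests round-trip through TSV + JSON sidecar", {
  rec <- make_dated_records(c("2019-05-01", "2021-03-01", "2019-07-01"))
  sp <- split_by_time(rec)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_split(sp, f)
  back <- read_split(f)
  expect_identical(back$train_ids, sp$train_ids)
  expect_identical(back$test_ids, sp$test_ids)
  expect_equal(back$protocol, "time")
  expect_equal(back$params$cutoff_date, as.Date("2020-12-01"))
})

test_that("splitters are pure functions of their seed", {
  set.seed(51)
  rec <- protein_records(sprintf("k%03d", 1:60), rand_aa(60, 15),
                         binary_label = rep(c("PVP", "nonPVP"), c(20, 40)))
  a <- split_by_imbalance(rec, 2, seed = 7)
  b <- split_by_imbalance(rec, 2, seed = 7)
  d <- split_by_imbalance(rec, 2, seed = 8)
  expect_identical(a$train_ids, b$train_ids)
  expect_false(identical(a$train_ids, d$train_ids))
})
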