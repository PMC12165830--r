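#' @keywords internal
dataset_split <- function(train_ids, test_ids, protocol, params, seed) {
  if (length(intersect(train_ids, test_ids)))
    stop("train and test sets overlap")
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 protocol = protocol, params = params, seed = seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset_split [%s]: %d train / %d test (seed %s)\n",
              x$protocol, length(x$train_ids), length(x$test_ids),
              format(x$seed)))
  invisible(x)
}

# seeded sampling that leaves the caller's RNG state untouched
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Split records into train and test by release date
#'
#' Records released strictly before the cutoff form the training set; all
#' others form the test set, emulating prospective discovery of unknown
#' proteins. With `balance_binary = TRUE` the majority binary class is
#' down-sampled (uniformly, seeded) to the minority count, separately within
#' train and test, as used for the balanced binary benchmark; the multi-class
#' task keeps the original distribution.
#'
#' @param records a labeled [protein_records] data frame; every record must
#'   carry a release date.
#' @param cutoff_date the cutoff (default the benchmark's 2020-12-01).
#' @param balance_binary down-sample the majority binary class to parity.
#' @param seed integer seed for the balancing subsample.
#' @return A `dataset_split`.
#' @export
split_by_time <- function(records, cutoff_date = as.Date("2020-12-01"),
                          balance_binary = FALSE, seed = 1L) {
  cutoff_date <- as.Date(cutoff_date)
  miss <- is.na(records$release_date)
  if (any(miss))
    stop("missing release_date for id(s): ",
         paste(records$id[miss], collapse = ", "))
  in_train <- records$release_date < cutoff_date
  train_ids <- records$id[in_train]
  test_ids <- records$id[!in_train]
  if (!length(test_ids)) warning("empty test set: all records predate cutoff")
  if (!length(train_ids)) warning("empty training set: no records predate cutoff")
  if (balance_binary) {
    balance <- function(ids) {
      lab <- records$binary_label[match(ids, records$id)]
      pvp <- ids[lab == "PVP"]; non <- ids[lab == "nonPVP"]
      m <- min(length(pvp), length(non))
      sort(c(sample(pvp, m), sample(non, m)))
    }
    with_seed(seed, {
      train_ids <- balance(train_ids)
      test_ids <- balance(test_ids)
    })
  }
  dataset_split(train_ids, test_ids, "time",
                list(cutoff_date = cutoff_date,
                     balance_binary = balance_binary), seed)
}

#' Homology-aware split capping train/test similarity
#'
#' Builds a graph over records connecting every pair whose symmetrized
#' identity-times-coverage score exceeds the threshold `t`, takes its
#' connected components, and assigns whole components to the test set
#' (components in seeded random order, stratified by the component's majority
#' class) until each class's test fraction is met or first exceeded. Because
#' no edge crosses the partition, every train/test pair is guaranteed to have
#' score at most `t`.
#'
#' @param records a [protein_records] data frame.
#' @param threshold maximum allowed cross-split similarity `t` (the benchmark
#'   uses 0.4 to 0.9).
#' @param scores pairwise score table as from [similarity_scores()]; computed
#'   on demand when `NULL`.
#' @param test_fraction target fraction of each class in the test set.
#' @param seed integer seed for the component order.
#' @param class_of which record column defines the stratification class
#'   (`"binary_label"` or `"category"`).
#' @return A `dataset_split`.
#' @export
split_by_similarity <- function(records, threshold, scores = NULL,
                                test_fraction = 0.2, seed = 1L,
                                class_of = c("binary_label", "category")) {
  stopifnot(threshold > 0, threshold <= 1,
            test_fraction > 0, test_fraction < 1)
  class_of <- match.arg(class_of)
  if (is.null(scores)) scores <- similarity_scores(records)
  cls <- records[[class_of]]
  cls[is.na(cls)] <- "(none)"

  g <- igraph::make_empty_graph(n = nrow(records), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = records$id)
  edges <- scores[scores$score > threshold, c("id_a", "id_b")]
  if (nrow(edges))
    g <- igraph::add_edges(g, t(as.matrix(edges)))
  comp <- igraph::components(g)$membership  # named by record id
  comp <- comp[records$id]

  # per-component class tallies and majority class
  comp_ids <- split(records$id, comp)
  comp_major <- vapply(comp_ids, function(ids) {
    names(which.max(table(cls[match(ids, records$id)])))
  }, character(1))

  class_n <- table(cls)
  target <- ceiling(test_fraction * class_n)
  # a component holding more than (1 - test_fraction) of a class cannot leave
  # enough of that class for training
  for (k in seq_along(comp_ids)) {
    tab <- table(cls[match(comp_ids[[k]], records$id)])
    too_big <- tab > (1 - test_fraction) * class_n[names(tab)]
    if (any(too_big))
      stop("a single similarity component holds more than ",
           sprintf("%.0f%%", 100 * (1 - test_fraction)),
           " of class '", names(tab)[too_big][1],
           "'; raise the threshold t")
  }

  test_comps <- character(0)
  with_seed(seed, {
    for (cl in names(class_n)) {
      members <- names(comp_major)[comp_major == cl]
      members <- sample(members)
      got <- 0L
      for (k in members) {
        if (got >= target[[cl]]) break
        test_comps <- c(test_comps, k)
        got <- got + sum(cls[match(comp_ids[[k]], records$id)] == cl)
      }
    }
  })
  in_test <- as.character(comp) %in% test_comps
  dataset_split(records$id[!in_test], records$id[in_test], "similarity",
                list(threshold = threshold, test_fraction = test_fraction),
                seed)
}

#' Verify the cross-split similarity guarantee
#'
#' Asserts that no train/test pair has symmetrized score above the threshold;
#' returns the maximum cross-split score.
#'
#' @param split a `dataset_split` from [split_by_similarity()].
#' @param scores the pairwise score table used (or an exhaustive one).
#' @return The maximum cross-split score (0 when no pair is scored).
#' @export
max_cross_split_score <- function(split, scores) {
  crosses <- (scores$id_a %in% split$train_ids & scores$id_b %in% split$test_ids) |
    (scores$id_b %in% split$train_ids & scores$id_a %in% split$test_ids)
  if (!any(crosses)) return(0)
  max(scores$score[crosses])
}

#' Construct a binary dataset with a fixed class-imbalance ratio
#'
#' Retains all PVP records plus a uniform seeded subsample of non-PVP records
#' such that nonPVP:PVP equals the balance factor `r`, then splits both
#' classes by `train_fraction` so train and test preserve the ratio exactly.
#'
#' @param records a labeled [protein_records] data frame (binary labels).
#' @param balance_factor desired nonPVP/PVP ratio `r >= 1` (the benchmark
#'   uses 1, 3, 5, 7, 9).
#' @param train_fraction fraction of each class assigned to training.
#' @param seed integer seed.
#' @return A `dataset_split`.
#' @export
split_by_imbalance <- function(records, balance_factor, train_fraction = 0.8,
                               seed = 1L) {
  stopifnot(balance_factor >= 1, train_fraction > 0, train_fraction < 1)
  pvp <- records$id[records$binary_label == "PVP"]
  non <- records$id[records$binary_label == "nonPVP"]
  need <- round(balance_factor * length(pvp))
  if (length(non) < need)
    stop(sprintf(
      "only %d nonPVP records for %d PVP: maximum feasible balance factor is %d",
      length(non), length(pvp), length(non) %/% max(1L, length(pvp))))
  with_seed(seed, {
    non_keep <- sample(non, need)
    train_p <- sample(pvp, round(train_fraction * length(pvp)))
    train_n <- sample(non_keep, balance_factor * length(train_p))
  })
  dataset_split(sort(c(train_p, train_n)),
                sort(c(setdiff(pvp, train_p), setdiff(non_keep, train_n))),
                "imbalance",
                list(balance_factor = balance_factor,
                     train_fraction = train_fraction), seed)
}

#' Write / read a split manifest
#'
#' Two-column TSV (`id`, `partition`) plus a JSON sidecar (`<path>.json`)
#' recording protocol, parameters and seed.
#'
#' @param split a `dataset_split`.
#' @param path TSV path.
#' @return `write_split`: `path` invisibly; `read_split`: the `dataset_split`.
#' @export
write_split <- function(split, path) {
  df <- data.frame(
    id = c(split$train_ids, split$test_ids),
    partition = rep(c("train", "test"),
                    c(length(split$train_ids), length(split$test_ids))),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  params <- split$params
  if (!is.null(params$cutoff_date))
    params$cutoff_date <- format(params$cutoff_date)
  jsonlite::write_json(list(protocol = split$protocol, params = params,
                            seed = split$seed),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  params <- meta$params
  if (!is.null(params$cutoff_date))
    params$cutoff_date <- as.Date(params$cutoff_date)
  dataset_split(df$id[df$partition == "train"], df$id[df$partition == "test"],
                meta$protocol, params, meta$seed)
}
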