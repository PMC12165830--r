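#' Read a pipeline configuration file
#'
#' A YAML file with optional sections `loss`, `model`, `train` and
#' `embedder`, whose keys mirror the arguments of [asl_config()],
#' [classifier_config()], [train_config()] and [kmer_hash_backend()] /
#' [plm_backend()]. Missing sections and keys fall back to the package
#' defaults, so a file needs to state only what it overrides:
#'
#' ```yaml
#' loss:
#'   gamma_pos: 0
#'   gamma_neg: 4
#'   mode: standard
#' model:
#'   n_classes: 7
#' train:
#'   lr: 0.001
#'   max_epochs: 50
#' embedder:
#'   backend: kmer_hash
#'   dim: 1024
#' ```
#'
#' @param path path to the YAML file.
#' @return A list with elements `loss` ([asl_config]), `model`
#'   ([classifier_config]), `train` ([train_config]) and `backend` (an
#'   [embedder_backend], or `NULL` when `embedder.backend` is `plm` — the
#'   adapter needs a user-supplied encoder and cannot be built from a file).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  take <- function(section, fun, drop = character()) {
    given <- as.list(cfg[[section]])
    given <- given[setdiff(names(given), drop)]
    unknown <- setdiff(names(given), names(formals(fun)))
    if (length(unknown))
      stop(sprintf("unknown key(s) in [%s]: %s", section,
                   paste(unknown, collapse = ", ")))
    do.call(fun, given)
  }
  backend <- NULL
  emb <- as.list(cfg$embedder)
  kind <- if (is.null(emb$backend)) "kmer_hash" else emb$backend
  if (kind == "kmer_hash") {
    args <- emb[intersect(names(emb), names(formals(kmer_hash_backend)))]
    backend <- do.call(kmer_hash_backend, args)
  } else if (kind != "plm") {
    stop("embedder.backend must be 'kmer_hash' or 'plm'")
  }
  list(loss = take("loss", asl_config),
       model = take("model", classifier_config),
       train = take("train", train_config),
       backend = backend)
}
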