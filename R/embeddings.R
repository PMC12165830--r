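#' Mean-pool a matrix of residue embeddings into one protein vector
#'
#' Element-wise arithmetic mean over the rows (residue positions) of an
#' `L x dim` matrix, giving the fixed-length per-protein feature vector.
#'
#' @param residue_matrix numeric matrix, one row per residue.
#' @return numeric vector of length `ncol(residue_matrix)`.
#' @export
mean_pool <- function(residue_matrix) {
  if (!is.matrix(residue_matrix) || nrow(residue_matrix) < 1L)
    stop("residue matrix must have at least one row")
  if (!all(is.finite(residue_matrix)))
    stop("non-finite entry in residue matrix")
  colMeans(residue_matrix)
}

#' Construct an embedder backend
#'
#' An embedder backend is a named, deterministic function from an amino-acid
#' sequence to an `L x dim` matrix of residue embeddings; [embed_proteins()]
#' mean-pools that matrix into the per-protein vector.
#'
#' @param name backend name.
#' @param dim embedding dimensionality (1024 for the reference setup).
#' @param residue_fun `function(sequence)` returning an `L x dim` matrix.
#' @param max_len sequences longer than this are truncated (with a warning)
#'   before embedding, mirroring transformer context limits.
#' @return An object of class `embedder_backend`.
#' @export
embedder_backend <- function(name, dim, residue_fun, max_len = 4000L) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(dim), dim >= 1, is.function(residue_fun))
  structure(list(name = name, dim = as.integer(dim),
                 residue_fun = residue_fun, max_len = as.integer(max_len)),
            class = "embedder_backend")
}

#' Deterministic k-mer hashing embedder backend
#'
#' An offline stand-in for a protein language model: each residue's embedding
#' row is a fixed pseudo-random unit vector determined by the k-mer window
#' centred on it (and the backend seed). Because edit-similar sequences share
#' most of their k-mer windows, their mean-pooled vectors are close, giving
#' the backend the locality that classifier and splitter tests rely on. It
#' makes no claim to imitate the geometry of real language-model embeddings.
#'
#' @param dim embedding dimensionality (default 1024).
#' @param k k-mer window width (default 3).
#' @param seed integer seed fixing the k-mer-to-vector map.
#' @param max_len truncation length for long sequences.
#' @return An `embedder_backend`.
#' @examples
#' b <- kmer_hash_backend(dim = 16, seed = 1)
#' m <- b$residue_fun("MKQN")  # 4 x 16 matrix
#' @export
kmer_hash_backend <- function(dim = 1024L, k = 3L, seed = 0L, max_len = 4000L) {
  stopifnot(dim >= 1, k >= 1)
  dim <- as.integer(dim); k <- as.integer(k); seed <- as.integer(seed)
  cache <- new.env(parent = emptyenv())
  left <- (k - 1L) %/% 2L
  residue_fun <- function(sequence) {
    chars <- strsplit(as.character(sequence), "")[[1]]
    L <- length(chars)
    padded <- c(rep("-", left), chars, rep("-", k - 1L - left))
    out <- matrix(0, nrow = L, ncol = dim)
    for (i in seq_len(L)) {
      kmer <- paste(padded[i:(i + k - 1L)], collapse = "")
      v <- cache[[kmer]]
      if (is.null(v)) {
        v <- hashed_unit_vector(kmer, dim, seed)
        cache[[kmer]] <- v
      }
      out[i, ] <- v
    }
    out
  }
  embedder_backend(sprintf("kmer_hash(k=%d,seed=%d)", k, seed), dim,
                   residue_fun, max_len = max_len)
}

# FNV-1a string hash folded into a valid 32-bit R seed; the vector for a k-mer
# is drawn from R's RNG under that seed, with the caller's RNG state restored.
#' @keywords internal
hashed_unit_vector <- function(key, dim, seed) {
  bytes <- utf8ToInt(paste0(key, "|", seed))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(h))
  v <- stats::rnorm(dim)
  v / sqrt(sum(v^2))
}

#' Adapter slot for a real protein-language-model backend
#'
#' The package's classifier consumes 1024-dimensional mean-pooled embeddings
#' regardless of their source. Users with access to a transformer encoder can
#' plug it in here by supplying `residue_fun`; the package itself ships no
#' model weights and no inference code.
#'
#' @param residue_fun `function(sequence)` returning an `L x dim` matrix of
#'   last-layer residue embeddings.
#' @param dim embedding dimensionality of the model (default 1024).
#' @param name backend label recorded in embedding tables.
#' @param max_len truncation length for long sequences.
#' @return An `embedder_backend`.
#' @export
plm_backend <- function(residue_fun = NULL, dim = 1024L, name = "plm",
                        max_len = 4000L) {
  if (is.null(residue_fun))
    stop("plm_backend requires a user-supplied residue embedding function; ",
         "for an offline backend use kmer_hash_backend()")
  embedder_backend(name, dim, residue_fun, max_len = max_len)
}

#' Embed protein records into an embedding table
#'
#' Runs the backend on every record (in input order) and mean-pools the
#' residue matrices into per-protein vectors.
#'
#' @param records a [protein_records] data frame.
#' @param backend an [embedder_backend].
#' @return An `embedding_table`: list with `ids`, `backend`, `dim` and the
#'   `n x dim` numeric matrix `values` (rownames = ids).
#' @export
embed_proteins <- function(records, backend) {
  stopifnot(inherits(backend, "embedder_backend"))
  n <- nrow(records)
  values <- matrix(0, nrow = n, ncol = backend$dim)
  for (i in seq_len(n)) {
    seq_i <- records$sequence[i]
    if (nchar(seq_i) > backend$max_len) {
      warning(sprintf("sequence %s truncated to %d residues",
                      records$id[i], backend$max_len))
      seq_i <- substr(seq_i, 1L, backend$max_len)
    }
    m <- tryCatch(backend$residue_fun(seq_i), error = function(e)
      stop(sprintf("backend '%s' failed on id %s: %s",
                   backend$name, records$id[i], conditionMessage(e))))
    if (!is.matrix(m) || ncol(m) != backend$dim)
      stop(sprintf("backend '%s' returned wrong shape for id %s",
                   backend$name, records$id[i]))
    values[i, ] <- mean_pool(m)
  }
  embedding_table(records$id, values, backend$name)
}

#' Construct an embedding table
#'
#' @param ids unique protein ids.
#' @param values `n x dim` numeric matrix of pooled embeddings.
#' @param backend_name label of the backend that produced the vectors.
#' @return An object of class `embedding_table`.
#' @export
embedding_table <- function(ids, values, backend_name = "unknown") {
  ids <- as.character(ids)
  if (!is.matrix(values)) values <- matrix(values, nrow = length(ids))
  if (length(ids) != nrow(values)) stop("ids and values disagree in length")
  if (anyDuplicated(ids)) stop("duplicate ids in embedding table")
  if (nrow(values) && !all(is.finite(values)))
    stop("non-finite embedding values")
  rownames(values) <- ids
  structure(list(ids = ids, backend = backend_name,
                 dim = ncol(values), values = values),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("embedding_table: %d vector(s) x %d dims (backend %s)\n",
              length(x$ids), x$dim, x$backend))
  invisible(x)
}

#' Subset an embedding table by id
#'
#' @param table an `embedding_table`.
#' @param ids ids to keep, in the order given.
#' @return The subset `embedding_table`.
#' @export
subset_table <- function(table, ids) {
  missing <- setdiff(ids, table$ids)
  if (length(missing))
    stop("ids not in embedding table: ", paste(missing, collapse = ", "))
  embedding_table(ids, table$values[ids, , drop = FALSE], table$backend)
}

#' Save / load an embedding table
#'
#' The on-disk format is a self-describing TSV: a first comment line holding a
#' JSON header (backend name, dimension, count), then one row per protein
#' (`id` followed by `dim` values at full precision). The round trip is
#' lossless.
#'
#' @param table an `embedding_table`.
#' @param path file path.
#' @return `save_table`: `path` invisibly; `load_table`: the table.
#' @export
save_table <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  hdr <- jsonlite::toJSON(list(format = "pvpanno_embedding_table",
                               backend = table$backend, dim = table$dim,
                               n = length(table$ids)), auto_unbox = TRUE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  if (length(table$ids)) {
    rows <- vapply(seq_along(table$ids), function(i)
      paste(c(table$ids[i], sprintf("%.17g", table$values[i, ])),
            collapse = "\t"), character(1))
    writeLines(rows, con)
  }
  invisible(path)
}

#' @rdname save_table
#' @export
load_table <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop("not an embedding table file (missing JSON header): ", path)
  hdr <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  if (!identical(hdr$format, "pvpanno_embedding_table"))
    stop("not an embedding table file: ", path)
  body <- lines[-1]
  if (length(body) != hdr$n)
    stop(sprintf("truncated embedding table: header says %d rows, found %d",
                 hdr$n, length(body)))
  if (hdr$n == 0L)
    return(embedding_table(character(), matrix(0, 0, hdr$dim), hdr$backend))
  parts <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(parts)
  if (any(widths != hdr$dim + 1L))
    stop(sprintf("row width mismatch: expected %d values per row", hdr$dim))
  ids <- vapply(parts, `[[`, character(1), 1L)
  values <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                     numeric(hdr$dim)))
  if (hdr$dim == 1L) values <- matrix(values, ncol = 1L)
  embedding_table(ids, values, hdr$backend)
}
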