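#' Output length of a 1-D convolution or pooling layer
#'
#' `floor((L + 2*padding - kernel) / stride) + 1`, the standard sliding-window
#' arithmetic. In the default architecture this gives 1024 -> 1022 for the
#' convolution (kernel 3, stride 1) and 1022 -> 510 for the max pool
#' (kernel 3, stride 2).
#'
#' @param L input length.
#' @param kernel window width.
#' @param stride step between windows.
#' @param padding zero padding added at both ends (default 0).
#' @return Integer output length.
#' @examples
#' conv_out_len(1024, 3, 1)  # 1022
#' conv_out_len(1022, 3, 2)  # 510
#' @export
conv_out_len <- function(L, kernel, stride, padding = 0L) {
  stopifnot(kernel >= 1, stride >= 1, padding >= 0)
  if (L + 2 * padding < kernel)
    stop("input length ", L, " (+padding) shorter than kernel ", kernel)
  as.integer((L + 2 * padding - kernel) %/% stride + 1L)
}

#' Configuration of the convolutional classifier
#'
#' The reference architecture reshapes each 1024-dimensional embedding to one
#' channel, applies a 1-D convolution (32 filters, kernel 3, stride 1), batch
#' normalization, ReLU, max pooling (kernel 3, stride 2), flattens to
#' 32 x 510 = 16320 features, then dense(64) -> batch norm -> ReLU ->
#' dense(`n_classes`) producing logits (the loss applies the softmax). The
#' width of the first dense layer is inferred from the flattened size at build
#' time, so non-default `input_dim` works unchanged.
#'
#' @param input_dim embedding dimensionality (default 1024).
#' @param conv_filters,conv_kernel,conv_stride convolution geometry.
#' @param pool_kernel,pool_stride max-pool geometry.
#' @param hidden_units width of the dense layer (default 64).
#' @param n_classes 2 for the binary head, 7 for the functional head.
#' @param activation `"relu"` (default) or `"identity"`.
#' @param seed integer seed for parameter initialization.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(input_dim = 1024L, conv_filters = 32L,
                              conv_kernel = 3L, conv_stride = 1L,
                              pool_kernel = 3L, pool_stride = 2L,
                              hidden_units = 64L, n_classes = 2L,
                              activation = c("relu", "identity"),
                              seed = 1L) {
  activation <- match.arg(activation)
  cfg <- list(input_dim = as.integer(input_dim),
              conv_filters = as.integer(conv_filters),
              conv_kernel = as.integer(conv_kernel),
              conv_stride = as.integer(conv_stride),
              pool_kernel = as.integer(pool_kernel),
              pool_stride = as.integer(pool_stride),
              hidden_units = as.integer(hidden_units),
              n_classes = as.integer(n_classes),
              activation = activation, seed = as.integer(seed))
  stopifnot(all(unlist(cfg[1:8]) > 0L), cfg$n_classes >= 2L)
  class(cfg) <- "classifier_config"
  cfg
}

#' @keywords internal
model_shapes <- function(config) {
  conv_len <- conv_out_len(config$input_dim, config$conv_kernel,
                           config$conv_stride)
  pool_len <- conv_out_len(conv_len, config$pool_kernel, config$pool_stride)
  list(conv_len = conv_len, pool_len = pool_len,
       flat_dim = pool_len * config$conv_filters)
}

#' Build a classifier with seeded initial parameters
#'
#' Allocates and initializes all parameters of the architecture described in
#' [classifier_config()] (He-scaled Gaussian weights, zero biases, unit batch
#' norm scale). The same seed always yields bit-identical parameters.
#'
#' @param config a [classifier_config].
#' @return A `pvp_model`: parameters, batch-norm running statistics and
#'   training metadata.
#' @export
build_model <- function(config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  sh <- model_shapes(config)
  F <- config$conv_filters; K <- config$conv_kernel
  H <- config$hidden_units; C <- config$n_classes
  params <- with_seed(config$seed, list(
    conv_w = matrix(stats::rnorm(F * K, sd = sqrt(2 / K)), nrow = F),
    conv_b = numeric(F),
    bn1_gamma = rep(1, F), bn1_beta = numeric(F),
    fc1_w = matrix(stats::rnorm(sh$flat_dim * H, sd = sqrt(2 / sh$flat_dim)),
                   nrow = sh$flat_dim),
    fc1_b = numeric(H),
    bn2_gamma = rep(1, H), bn2_beta = numeric(H),
    fc2_w = matrix(stats::rnorm(H * C, sd = sqrt(2 / H)), nrow = H),
    fc2_b = numeric(C)
  ))
  structure(list(
    config = config, shapes = sh, params = params,
    buffers = list(bn1_mean = numeric(F), bn1_var = rep(1, F),
                   bn2_mean = numeric(H), bn2_var = rep(1, H)),
    meta = list(epochs_run = 0L, best_val_loss = NA_real_,
                class_levels = NULL)
  ), class = "pvp_model")
}

#' @export
print.pvp_model <- function(x, ...) {
  cat(sprintf(
    "pvp_model: %d-dim input -> conv(%d,k=%d) -> pool(k=%d,s=%d) -> %d -> %d -> %d classes\n",
    x$config$input_dim, x$config$conv_filters, x$config$conv_kernel,
    x$config$pool_kernel, x$config$pool_stride, x$shapes$flat_dim,
    x$config$hidden_units, x$config$n_classes))
  if (!is.null(x$meta$class_levels))
    cat("  classes:", paste(x$meta$class_levels, collapse = ", "), "\n")
  invisible(x)
}

# Row index of element (n, t) in the (N*len) x filters layout used throughout:
# rows are ordered n fastest, position t slowest.
#' @keywords internal
window_rows <- function(N, starts, offset) {
  rep(seq_len(N), times = length(starts)) +
    (rep(starts + offset, each = N) - 1L) * N
}

#' @keywords internal
relu <- function(x) x * (x > 0)

#' @keywords internal
bn_eps <- 1e-5

# Full forward pass. training = TRUE normalizes with batch statistics,
# returns the cache needed by the backward pass, and reports updated running
# statistics; training = FALSE uses the stored running statistics.
#
# Conv-stage tensors are held channel-major (filters x N*positions, columns
# ordered sample-fastest) so that per-channel bias/batch-norm broadcasts are
# plain vector recycling instead of sweep()/aperm() copies.
#' @keywords internal
model_forward_full_r <- function(model, X, training = FALSE, momentum = 0.1) {
  cfg <- model$config; sh <- model$shapes; p <- model$params
  b <- model$buffers
  N <- nrow(X)
  if (ncol(X) != cfg$input_dim)
    stop(sprintf("input width %d does not match model input_dim %d",
                 ncol(X), cfg$input_dim))
  act <- if (cfg$activation == "relu") relu else identity

  # rows of batch-norm helper = channels/features, columns = observations
  bn <- function(Zt, gamma, beta, run_mean, run_var) {
    if (training) {
      mu <- rowMeans(Zt)
      va <- rowMeans(Zt^2) - mu^2
      m <- ncol(Zt)
      unbiased <- if (m > 1L) va * m / (m - 1L) else va
      run_mean <- (1 - momentum) * run_mean + momentum * mu
      run_var <- (1 - momentum) * run_var + momentum * unbiased
    } else {
      mu <- run_mean; va <- run_var
    }
    invstd <- 1 / sqrt(va + bn_eps)
    xhat <- (Zt - mu) * invstd
    out <- xhat * gamma + beta
    list(out = out, xhat = xhat, invstd = invstd,
         run_mean = run_mean, run_var = run_var)
  }

  conv_starts <- seq(1L, by = cfg$conv_stride, length.out = sh$conv_len)
  Xw <- matrix(0, N * sh$conv_len, cfg$conv_kernel)
  for (s in seq_len(cfg$conv_kernel))
    Xw[, s] <- as.vector(X[, conv_starts + (s - 1L), drop = FALSE])
  Z1 <- p$conv_w %*% t(Xw) + p$conv_b           # filters x (N*conv_len)

  bn1 <- bn(Z1, p$bn1_gamma, p$bn1_beta, b$bn1_mean, b$bn1_var)
  A1 <- act(bn1$out)

  pool_starts <- seq(1L, by = cfg$pool_stride, length.out = sh$pool_len)
  idx <- lapply(seq_len(cfg$pool_kernel) - 1L,
                function(off) window_rows(N, pool_starts, off))
  P <- A1[, idx[[1L]], drop = FALSE]            # filters x (N*pool_len)
  which_s <- matrix(1L, nrow(P), ncol(P))
  for (s in seq_len(cfg$pool_kernel)[-1L]) {
    As <- A1[, idx[[s]], drop = FALSE]
    better <- As > P
    P[better] <- As[better]
    which_s[better] <- s
  }
  # flatten to N x (pool_len*filters); feature order: position fastest
  flat <- matrix(t(P), nrow = N)

  Hpre <- t(flat %*% p$fc1_w) + p$fc1_b         # hidden x N
  bn2 <- bn(Hpre, p$bn2_gamma, p$bn2_beta, b$bn2_mean, b$bn2_var)
  A2 <- act(bn2$out)
  logits <- t(p$fc2_w) %*% A2 + p$fc2_b         # classes x N
  logits <- t(logits)

  list(logits = logits,
       cache = if (training)
         list(Xw = Xw, bn1 = bn1, A1 = A1, idx = idx, which_s = which_s,
              flat = flat, bn2 = bn2, A2 = A2, N = N) else NULL,
       buffers = list(bn1_mean = bn1$run_mean, bn1_var = bn1$run_var,
                      bn2_mean = bn2$run_mean, bn2_var = bn2$run_var))
}

#' Evaluate the classifier on a batch of embeddings
#'
#' Evaluation-mode forward pass (batch-norm uses the stored running
#' statistics), a pure function of the parameters and the input.
#'
#' @param model a `pvp_model`.
#' @param X `N x input_dim` numeric matrix.
#' @return `N x n_classes` matrix of logits.
#' @export
model_forward <- function(model, X) {
  stopifnot(inherits(model, "pvp_model"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  model_forward_full(model, X, training = FALSE)$logits
}

# Gradients of the batch loss w.r.t. every parameter, given the gradient
# d loss / d logits. Batch-norm backward uses the standard closed form.
#' @keywords internal
model_backward_r <- function(model, cache, dlogits) {
  cfg <- model$config; p <- model$params
  g <- list()
  # channel-major batch-norm backward (rows = channels)
  bn_back <- function(dy, bnc, gamma) {
    m <- ncol(dy)
    dgamma <- rowSums(dy * bnc$xhat)
    dbeta <- rowSums(dy)
    dxhat <- dy * gamma
    t1 <- rowSums(dxhat)
    t2 <- rowSums(dxhat * bnc$xhat)
    dx <- (dxhat - t1 / m - bnc$xhat * (t2 / m)) * bnc$invstd
    list(dx = dx, dgamma = dgamma, dbeta = dbeta)
  }
  relu_mask <- function(pre_out) pre_out > 0

  dlogits_t <- t(dlogits)                         # classes x N
  g$fc2_w <- cache$A2 %*% dlogits                 # hidden x classes
  g$fc2_b <- rowSums(dlogits_t)
  dA2 <- p$fc2_w %*% dlogits_t                    # hidden x N
  if (cfg$activation == "relu") dA2 <- dA2 * relu_mask(cache$bn2$out)
  b2 <- bn_back(dA2, cache$bn2, p$bn2_gamma)
  g$bn2_gamma <- b2$dgamma; g$bn2_beta <- b2$dbeta
  dHpre <- b2$dx                                  # hidden x N
  g$fc1_w <- t(cache$flat) %*% t(dHpre)           # flat_dim x hidden
  g$fc1_b <- rowSums(dHpre)
  dflat <- t(dHpre) %*% t(p$fc1_w)                # N x flat_dim
  dP <- t(matrix(as.vector(dflat), ncol = nrow(cache$which_s)))
  dA1 <- matrix(0, nrow(cache$A1), ncol(cache$A1))
  for (s in seq_along(cache$idx)) {
    contrib <- dP * (cache$which_s == s)
    cols <- cache$idx[[s]]
    dA1[, cols] <- dA1[, cols] + contrib
  }
  if (cfg$activation == "relu") dA1 <- dA1 * relu_mask(cache$bn1$out)
  b1 <- bn_back(dA1, cache$bn1, p$bn1_gamma)
  g$bn1_gamma <- b1$dgamma; g$bn1_beta <- b1$dbeta
  dZ1 <- b1$dx                                    # filters x (N*conv_len)
  g$conv_w <- dZ1 %*% cache$Xw                    # filters x kernel
  g$conv_b <- rowSums(dZ1)
  g
}

#' Save / load a classifier checkpoint
#'
#' The checkpoint is self-describing (configuration, parameters, batch-norm
#' buffers, training metadata) and reloads bit-identically: forward outputs
#' before and after a round trip are equal.
#'
#' @param model a `pvp_model`.
#' @param path file path.
#' @return `save_model`: `path` invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pvp_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pvp_model")) stop("not a pvp_model checkpoint: ", path)
  model
}

# C++-backed forward pass (the production path); the pure-R twin
# model_forward_full_r is kept as an independent reference implementation and
# the two are compared in the test suite.
#' @keywords internal
model_forward_full <- function(model, X, training = FALSE, momentum = 0.1) {
  cfg <- model$config
  if (ncol(X) != cfg$input_dim)
    stop(sprintf("input width %d does not match model input_dim %d",
                 ncol(X), cfg$input_dim))
  .cpp_forward(model$params, model$buffers, X, training, momentum,
               cfg$activation == "relu", cfg$conv_stride, cfg$pool_kernel,
               cfg$pool_stride)
}

# X is the same batch the forward cache was computed from (the window matrix
# is rebuilt from it rather than cached).
#' @keywords internal
model_backward <- function(model, cache, dlogits, X) {
  cfg <- model$config
  .cpp_backward(model$params, cache, dlogits, X, cfg$activation == "relu",
                cfg$conv_stride, cfg$pool_kernel, cfg$pool_stride)
}
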