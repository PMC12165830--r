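#' Training configuration
#'
#' Optimization settings for [train()]. The defaults (Adam, learning rate
#' 1e-3, batch 128, up to 100 epochs with early stopping at patience 10 on
#' validation loss, 10% stratified validation split) are robust desk-scale
#' choices; all are configurable.
#'
#' @param optimizer only `"adam"` is implemented.
#' @param lr learning rate.
#' @param batch_size mini-batch size.
#' @param max_epochs maximum number of epochs.
#' @param patience epochs without validation-loss improvement before stopping.
#' @param val_fraction fraction of the training data held out (stratified)
#'   for validation; must be in (0, 0.5).
#' @param restore_best return the parameters with the best validation loss
#'   (default); `FALSE` keeps the final-epoch parameters, as used for
#'   fixed-schedule comparisons between loss functions.
#' @param seed integer seed governing initialization, the validation split and
#'   batch shuffling; the whole of training is a pure function of it.
#' @return An object of class `train_config`.
#' @export
train_config <- function(optimizer = "adam", lr = 1e-3, batch_size = 128L,
                         max_epochs = 100L, patience = 10L,
                         val_fraction = 0.1, restore_best = TRUE, seed = 1L) {
  stopifnot(identical(optimizer, "adam"), lr > 0, batch_size >= 1,
            max_epochs >= 1, patience >= 1,
            val_fraction > 0, val_fraction < 0.5, is.logical(restore_best))
  structure(list(optimizer = optimizer, lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 restore_best = isTRUE(restore_best),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' @keywords internal
one_hot <- function(labels, levels) {
  idx <- match(labels, levels)
  if (anyNA(idx)) stop("label outside class set: ",
                       paste(unique(labels[is.na(idx)]), collapse = ", "))
  m <- matrix(0, length(labels), length(levels))
  m[cbind(seq_along(idx), idx)] <- 1
  colnames(m) <- levels
  m
}

#' Train the classifier on an embedding table
#'
#' Mini-batch gradient descent (Adam) on the asymmetric loss. A stratified
#' validation subset is carved from the training data; the parameters with
#' the best validation loss are retained and training stops early when the
#' validation loss has not improved for `patience` epochs. Given the seed,
#' training is fully reproducible.
#'
#' @param table an `embedding_table` of training vectors.
#' @param labels character/factor vector of class labels aligned with
#'   `table$ids` (at least 2 classes present).
#' @param model_config a [classifier_config]; by default one matching the
#'   table dimension and the number of label classes, seeded from
#'   `train_cfg$seed`.
#' @param loss_config an [asl_config] (default standard mode,
#'   `gamma_pos = 0`, `gamma_neg = 4`).
#' @param train_cfg a [train_config].
#' @return A trained `pvp_model`; `meta$history` holds the per-epoch
#'   train/validation losses, `meta$class_levels` the label order used for
#'   the logit columns.
#' @export
train <- function(table, labels, model_config = NULL,
                  loss_config = asl_config(), train_cfg = train_config()) {
  stopifnot(inherits(table, "embedding_table"))
  labels <- as.character(labels)
  if (length(labels) != length(table$ids))
    stop("labels must align with the embedding table")
  levels <- sort(unique(labels))
  if (length(levels) < 2L) stop("training requires at least 2 classes")
  if (is.null(model_config))
    model_config <- classifier_config(input_dim = table$dim,
                                      n_classes = length(levels),
                                      seed = train_cfg$seed)
  if (model_config$n_classes != length(levels))
    stop("model n_classes does not match the number of label classes")
  X <- table$values
  Y <- one_hot(labels, levels)
  n <- nrow(X)

  model <- build_model(model_config)
  model$meta$class_levels <- levels

  adam <- new.env(parent = emptyenv())
  adam$t <- 0L
  adam$m <- lapply(model$params, function(p) p * 0)
  adam$v <- lapply(model$params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = model$params, buffers = model$buffers,
               epoch = 0L)

  with_seed(train_cfg$seed, {
    # stratified validation split
    val_idx <- unlist(lapply(split(seq_len(n), labels), function(ix) {
      k <- max(1L, round(train_cfg$val_fraction * length(ix)))
      if (length(ix) <= 1L) integer() else sample(ix, min(k, length(ix) - 1L))
    }), use.names = FALSE)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (!length(val_idx)) stop("training set too small for a validation split")

    since_best <- 0L
    for (epoch in seq_len(train_cfg$max_epochs)) {
      order_idx <- sample(tr_idx)
      batches <- split(order_idx,
                       ceiling(seq_along(order_idx) / train_cfg$batch_size))
      epoch_loss <- 0
      for (bi in batches) {
        if (length(bi) < 2L) next  # batch norm needs >= 2 rows
        fw <- model_forward_full(model, X[bi, , drop = FALSE],
                                 training = TRUE)
        model$buffers <- fw$buffers
        loss <- asl_loss(fw$logits, Y[bi, , drop = FALSE], loss_config)
        if (!is.finite(loss))
          stop(sprintf("non-finite loss at epoch %d (batch of %d); %s",
                       epoch, length(bi),
                       "check inputs or lower the learning rate"))
        epoch_loss <- epoch_loss + loss * length(bi)
        dlogits <- asl_loss_grad(fw$logits, Y[bi, , drop = FALSE],
                                 loss_config)
        grads <- model_backward(model, fw$cache, dlogits,
                                X[bi, , drop = FALSE])
        adam$t <- adam$t + 1L
        corr1 <- 1 - beta1^adam$t
        corr2 <- 1 - beta2^adam$t
        for (nm in names(grads)) {
          adam$m[[nm]] <- beta1 * adam$m[[nm]] + (1 - beta1) * grads[[nm]]
          adam$v[[nm]] <- beta2 * adam$v[[nm]] + (1 - beta2) * grads[[nm]]^2
          model$params[[nm]] <- model$params[[nm]] -
            train_cfg$lr * (adam$m[[nm]] / corr1) /
            (sqrt(adam$v[[nm]] / corr2) + eps)
        }
      }
      train_loss <- epoch_loss / length(order_idx)
      val_logits <- model_forward_full(model, X[val_idx, , drop = FALSE],
                                       training = FALSE)$logits
      val_loss <- asl_loss(val_logits, Y[val_idx, , drop = FALSE],
                           loss_config)
      history[nrow(history) + 1L, ] <- list(epoch, train_loss, val_loss)
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = model$params,
                     buffers = model$buffers, epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= train_cfg$patience) break
      }
    }
  })

  if (train_cfg$restore_best) {
    model$params <- best$params
    model$buffers <- best$buffers
  }
  model$meta$epochs_run <- nrow(history)
  model$meta$best_epoch <- best$epoch
  model$meta$best_val_loss <- best$loss
  model$meta$history <- history
  model
}

#' Predict classes and confidences for an embedding table
#'
#' Evaluation-mode forward pass followed by a softmax; the predicted class is
#' the argmax and the per-class confidences sum to 1.
#'
#' @param model a trained `pvp_model` (with `meta$class_levels` set).
#' @param table an `embedding_table` (same dimension as the model input).
#' @return A `pvp_predictions` object: data frame with `id`, `class_index`,
#'   `class`, `confidence` (probability of the predicted class), plus the
#'   full `N x C` probability matrix in `attr(, "probs")`.
#' @export
predict_table <- function(model, table) {
  stopifnot(inherits(model, "pvp_model"), inherits(table, "embedding_table"))
  if (table$dim != model$config$input_dim)
    stop(sprintf("embedding dim %d does not match model input_dim %d",
                 table$dim, model$config$input_dim))
  logits <- model_forward(model, table$values)
  probs <- softmax(logits)
  levels <- model$meta$class_levels
  if (is.null(levels)) levels <- paste0("class", seq_len(ncol(probs)))
  colnames(probs) <- levels
  rownames(probs) <- table$ids
  idx <- max.col(probs, ties.method = "first")
  out <- data.frame(id = table$ids, class_index = idx,
                    class = levels[idx],
                    confidence = probs[cbind(seq_along(idx), idx)],
                    stringsAsFactors = FALSE)
  attr(out, "probs") <- probs
  class(out) <- c("pvp_predictions", "data.frame")
  out
}
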