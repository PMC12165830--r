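#' Classification metric suite
#'
#' Accuracy, precision, recall, F1 and the Matthews correlation coefficient
#' (MCC) from predicted and true labels. With `averaging = "binary"` the
#' `positive` class (default `"PVP"`) defines the positive counts. For
#' multi-class input the default is support-weighted averaging of the
#' per-class scores, under which weighted recall is identically the accuracy;
#' `"macro"` averages per-class scores unweighted. Per-class precision or
#' recall that is undefined (zero denominator) is set to 0 with a warning.
#' MCC uses the binary formula for two classes and the correlation-coefficient
#' generalization over the full confusion matrix otherwise (0 when its
#' denominator vanishes).
#'
#' @param predicted character vector of predicted labels.
#' @param truth character vector of true labels (same length).
#' @param averaging `"weighted"`, `"macro"`, or `"binary"`.
#' @param positive positive class for binary averaging.
#' @return A `metrics_report`: list with `accuracy`, `precision`, `recall`,
#'   `f1`, `mcc`, `per_class_f1` and `averaging`.
#' @export
compute_metrics <- function(predicted, truth,
                            averaging = c("weighted", "macro", "binary"),
                            positive = "PVP") {
  averaging <- match.arg(averaging)
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth))
    stop("predicted and truth differ in length")
  levels <- sort(union(predicted, truth))
  cm <- table(factor(truth, levels = levels),
              factor(predicted, levels = levels))  # rows = truth
  total <- sum(cm)
  accuracy <- sum(diag(cm)) / total

  tp <- diag(cm)
  pred_n <- colSums(cm)
  true_n <- rowSums(cm)
  zero_warn <- FALSE
  safe_div <- function(num, den) {
    out <- ifelse(den == 0, 0, num / den)
    if (any(den == 0)) zero_warn <<- TRUE
    out
  }
  prec_c <- safe_div(tp, pred_n)
  rec_c <- safe_div(tp, true_n)
  f1_c <- safe_div(2 * prec_c * rec_c, prec_c + rec_c)
  names(f1_c) <- levels

  if (averaging == "binary") {
    if (length(levels) > 2L)
      stop("binary averaging requires at most 2 classes")
    if (!(positive %in% levels))
      stop("positive class '", positive, "' absent from labels")
    precision <- prec_c[[positive]]
    recall <- rec_c[[positive]]
    f1 <- f1_c[[positive]]
  } else if (averaging == "macro") {
    precision <- mean(prec_c); recall <- mean(rec_c); f1 <- mean(f1_c)
  } else {
    w <- true_n / total
    precision <- sum(w * prec_c); recall <- sum(w * rec_c)
    f1 <- sum(w * f1_c)
  }
  if (zero_warn)
    warning("undefined per-class precision/recall set to 0 (empty class)")

  mcc <- if (length(levels) == 2L) {
    pos <- if (positive %in% levels) positive else levels[2L]
    neg <- setdiff(levels, pos)
    TP <- cm[pos, pos]; TN <- cm[neg, neg]
    FP <- cm[neg, pos]; FN <- cm[pos, neg]
    den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
    if (den == 0) 0 else (TP * TN - FP * FN) / den
  } else {
    s <- total; c_tr <- sum(diag(cm))
    pk <- colSums(cm); tk <- rowSums(cm)
    den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
    if (den == 0) 0 else (c_tr * s - sum(pk * tk)) / den
  }

  structure(list(accuracy = accuracy, precision = unname(precision),
                 recall = unname(recall), f1 = unname(f1), mcc = mcc,
                 per_class_f1 = f1_c, averaging = averaging),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics (%s): ACC %.4f  P %.4f  R %.4f  F1 %.4f  MCC %.4f\n",
              x$averaging, x$accuracy, x$precision, x$recall, x$f1, x$mcc))
  invisible(x)
}

#' Sweep asymmetric-loss focusing exponents
#'
#' Trains one seeded model per `(gamma_pos, gamma_neg)` configuration on
#' identical data and splits, evaluates on the test table, and tabulates
#' per-class F1 alongside the summary metrics. The default grid is the five
#' benchmark configurations (0,1), (0,4), (0,6), (1,1), (2,0).
#'
#' @param train_table,train_labels training embedding table and labels.
#' @param test_table,test_labels evaluation embedding table and labels.
#' @param gammas list of 2-vectors `c(gamma_pos, gamma_neg)`.
#' @param mode loss interpretation, see [asl_config()].
#' @param model_config optional shared [classifier_config].
#' @param train_cfg a [train_config] reused (same seed) for every
#'   configuration.
#' @param averaging metric averaging, see [compute_metrics()].
#' @return Data frame, one row per configuration: `gamma_pos`, `gamma_neg`,
#'   `accuracy`, `precision`, `recall`, `f1`, `mcc`, then one `f1.<class>`
#'   column per class.
#' @export
gamma_sweep <- function(train_table, train_labels, test_table, test_labels,
                        gammas = list(c(0, 1), c(0, 4), c(0, 6),
                                      c(1, 1), c(2, 0)),
                        mode = "standard", model_config = NULL,
                        train_cfg = train_config(),
                        averaging = "weighted") {
  stopifnot(length(gammas) >= 1L)
  rows <- lapply(gammas, function(g) {
    cfg <- asl_config(gamma_pos = g[1L], gamma_neg = g[2L], mode = mode)
    model <- train(train_table, train_labels, model_config = model_config,
                   loss_config = cfg, train_cfg = train_cfg)
    pred <- predict_table(model, test_table)
    m <- compute_metrics(pred$class, test_labels, averaging = averaging)
    row <- data.frame(gamma_pos = g[1L], gamma_neg = g[2L],
                      accuracy = m$accuracy, precision = m$precision,
                      recall = m$recall, f1 = m$f1, mcc = m$mcc)
    f1s <- as.list(m$per_class_f1)
    names(f1s) <- paste0("f1.", names(m$per_class_f1))
    cbind(row, as.data.frame(f1s, check.names = FALSE))
  })
  do.call(rbind, rows)
}
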