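# small, well-separated two-class problem reused across training tests
small_gaussians <- function(sep = 8, n = 60, dim = 32, seed = 5,
                            labels = c("nonPVP", "PVP")) {
  gen_gaussian_embeddings(c(n, n), dim = dim, separation = sep, seed = seed,
                          class_labels = labels)
}

test_that("training is a pure function of its seed", {
  g <- small_gaussians()
  tc <- train_config(seed = 11, max_epochs = 4, batch_size = 32)
  mc <- classifier_config(input_dim = 32, conv_filters = 4,
                          hidden_units = 8, seed = 11)
  f1 <- train(g$table, g$labels, model_config = mc, train_cfg = tc)
  f2 <- train(g$table, g$labels, model_config = mc, train_cfg = tc)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$meta$history, f2$meta$history)
})

test_that("a separable problem is learned; an unlearnable one is not", {
  g <- small_gaussians(sep = 10, n = 80, seed = 7)
  ids <- g$table$ids
  test_idx <- seq(1, 160, by = 4)
  tr <- subset_table(g$table, ids[-test_idx])
  te <- subset_table(g$table, ids[test_idx])
  mc <- classifier_config(input_dim = 32, conv_filters = 4,
                          hidden_units = 8, seed = 7)
  fit <- train(tr, g$labels[-test_idx], model_config = mc,
               train_cfg = train_config(seed = 7, max_epochs = 30,
                                        batch_size = 32))
  acc <- mean(predict_table(fit, te)$class == g$labels[test_idx])
  expect_gte(acc, 0.95)

  g0 <- small_gaussians(sep = 0, n = 80, seed = 7)
  tr0 <- subset_table(g0$table, ids[-test_idx])
  te0 <- subset_table(g0$table, ids[test_idx])
  fit0 <- train(tr0, g0$labels[-test_idx], model_config = mc,
                train_cfg = train_config(seed = 7, max_epochs = 10,
                                         batch_size = 32))
  acc0 <- mean(predict_table(fit0, te0)$class == g0$labels[test_idx])
  expect_gte(acc0, 0.3)
  expect_lte(acc0, 0.7)
})

test_that("training rejects degenerate label sets", {
  g <- small_gaussians()
  expect_error(train(g$table, rep("PVP", length(g$labels))), "2 classes")
  expect_error(train(g$table, g$labels[-1]), "align")
})

test_that("early stopping keeps the best-validation parameters", {
  g <- small_gaussians(sep = 3, n = 50, seed = 9)
  fit <- train(g$table, g$labels,
               model_config = classifier_config(input_dim = 32,
                                                conv_filters = 4,
                                                hidden_units = 8, seed = 9),
               train_cfg = train_config(seed = 9, max_epochs = 15,
                                        batch_size = 32, patience = 3))
  h <- fit$meta$history
  expect_lte(nrow(h), 15)
  expect_equal(fit$meta$best_val_loss, min(h$val_loss))
  expect_equal(h$val_loss[fit$meta$best_epoch], min(h$val_loss))
})

test_that("prediction confidences are softmax probabilities", {
  m <- build_model(classifier_config(input_dim = 32, conv_filters = 4,
                                     hidden_units = 8, seed = 1))
  m$meta$class_levels <- c("nonPVP", "PVP")
  # zero network with fixed logit bias (1, -1): constant sigmoid confidence
  for (nm in names(m$params)) m$params[[nm]][] <- 0
  m$params$fc2_b <- c(1, -1)
  tab <- embedding_table(c("a", "b"), matrix(rnorm(2 * 32), 2), "test")
  pred <- predict_table(m, tab)
  probs <- attr(pred, "probs")
  expect_equal(rowSums(probs), c(a = 1, b = 1))
  expect_equal(unname(probs[, "nonPVP"]), rep(1 / (1 + exp(-2)), 2))
  expect_equal(pred$class, c("nonPVP", "nonPVP"))
  expect_equal(pred$confidence, unname(probs[, 1]))
  # uniform logits give 0.5/0.5
  m$params$fc2_b <- c(0, 0)
  expect_equal(unname(attr(predict_table(m, tab), "probs")[1, ]), c(0.5, 0.5))
  expect_error(predict_table(m, embedding_table("x", matrix(0, 1, 5), "t")),
               "dim")
})

test_that("metric suite matches the confusion-matrix oracle", {
  set.seed(91)
  for (i in 1:200) {
    C <- sample(c(2, 7), 1)
    n <- sample(10:60, 1)
    classes <- if (C == 2) c("nonPVP", "PVP") else paste0("c", 1:7)
    truth <- sample(classes, n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.6, truth, sample(classes, n, replace = TRUE))
    for (avg in c("weighted", "macro")) {
      got <- suppressWarnings(compute_metrics(pred, truth, averaging = avg))
      want <- metrics_oracle(pred, truth, averaging = avg)
      expect_equal(got$accuracy, want$accuracy)
      expect_equal(got$precision, want$precision)
      expect_equal(got$recall, want$recall)
      expect_equal(got$f1, want$f1)
      expect_equal(got$mcc, want$mcc)
    }
  }
})

test_that("weighted recall is identically the accuracy", {
  set.seed(97)
  for (i in 1:30) {
    classes <- paste0("k", 1:sample(2:7, 1))
    truth <- sample(classes, 40, replace = TRUE)
    pred <- sample(classes, 40, replace = TRUE)
    m <- suppressWarnings(compute_metrics(pred, truth, averaging = "weighted"))
    expect_equal(m$recall, m$accuracy)
  }
})

test_that("metric edge cases behave as documented", {
  truth <- rep(c("PVP", "nonPVP"), c(12, 8))
  perfect <- compute_metrics(truth, truth, averaging = "binary")
  expect_equal(perfect$accuracy, 1); expect_equal(perfect$f1, 1)
  expect_equal(perfect$mcc, 1)
  # all 12 positives recovered: recall 1 regardless of false positives
  pred <- rep("PVP", 20)
  m <- suppressWarnings(compute_metrics(pred, truth, averaging = "binary"))
  expect_equal(m$recall, 1)
  # constant predictor on a balanced set: MCC 0
  bal <- rep(c("PVP", "nonPVP"), 10)
  m0 <- suppressWarnings(compute_metrics(rep("PVP", 20), bal,
                                         averaging = "binary"))
  expect_equal(m0$mcc, 0)
  expect_error(compute_metrics("PVP", c("PVP", "PVP")), "length")
})

test_that("binary MCC equals the multi-class generalization for C = 2", {
  set.seed(101)
  for (i in 1:20) {
    truth <- sample(c("PVP", "nonPVP"), 30, replace = TRUE)
    pred <- sample(c("PVP", "nonPVP"), 30, replace = TRUE)
    m <- suppressWarnings(compute_metrics(pred, truth, averaging = "binary"))
    expect_equal(m$mcc, metrics_oracle(pred, truth)$mcc)
  }
})

test_that("gamma sweep tabulates one seeded run per configuration", {
  g <- small_gaussians(sep = 6, n = 40, seed = 3)
  ids <- g$table$ids
  test_idx <- seq(2, 80, by = 4)
  tr <- subset_table(g$table, ids[-test_idx])
  te <- subset_table(g$table, ids[test_idx])
  mc <- classifier_config(input_dim = 32, conv_filters = 4,
                          hidden_units = 8, seed = 3)
  tc <- train_config(seed = 3, max_epochs = 5, batch_size = 32)
  tab <- gamma_sweep(tr, g$labels[-test_idx], te, g$labels[test_idx],
                     gammas = list(c(0, 4), c(1, 1)),
                     model_config = mc, train_cfg = tc)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("f1.PVP", "f1.nonPVP") %in% names(tab)))
  # a single-config sweep equals the direct train + evaluate route
  one <- gamma_sweep(tr, g$labels[-test_idx], te, g$labels[test_idx],
                     gammas = list(c(0, 4)), model_config = mc,
                     train_cfg = tc)
  fit <- train(tr, g$labels[-test_idx], model_config = mc,
               loss_config = asl_config(0, 4), train_cfg = tc)
  m <- compute_metrics(predict_table(fit, te)$class, g$labels[test_idx])
  expect_equal(one$f1, m$f1)
  expect_equal(one$accuracy, m$accuracy)
})

test_that("default sweep grid covers the five printed configurations", {
  expect_equal(eval(formals(gamma_sweep)$gammas),
               list(c(0, 1), c(0, 4), c(0, 6), c(1, 1), c(2, 0)))
})
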