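# Independent oracles used across the suite. These are deliberately naive
# (quadratic DP, explicit confusion-matrix counting, term-by-term scalar
# evaluation) and share no code with the implementation they check.

# Brute-force Smith-Waterman with per-symbol scoring and linear gap costs.
# Returns the best local score plus identity (matches / alignment columns)
# and coverage (alignment columns / query length) from a full traceback.
sw_oracle <- function(query, subject, match = 1, mismatch = -10, gap = -10) {
  a <- strsplit(query, "")[[1]]
  b <- strsplit(subject, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  ptr <- matrix(0L, n + 1, m + 1)  # 1 diag, 2 up (gap in subject), 3 left
  best <- 0; bi <- 1L; bj <- 1L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- H[i, j] + if (a[i] == b[j]) match else mismatch
      del <- H[i, j + 1] + gap
      ins <- H[i + 1, j] + gap
      v <- max(0, sub, del, ins)
      H[i + 1, j + 1] <- v
      ptr[i + 1, j + 1] <- if (v == 0) 0L else which.max(c(sub, del, ins))
      if (v > best) { best <- v; bi <- i + 1L; bj <- j + 1L }
    }
  }
  if (best <= 0) return(list(score = 0, identity = 0, coverage = 0,
                             simscore = 0))
  cols <- 0L; matches <- 0L
  i <- bi; j <- bj
  while (i > 1L && j > 1L && H[i, j] > 0) {
    p <- ptr[i, j]
    cols <- cols + 1L
    if (p == 1L) {
      if (a[i - 1L] == b[j - 1L]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (p == 2L) i <- i - 1L else j <- j - 1L
  }
  identity <- matches / cols
  coverage <- min(1, cols / n)
  list(score = best, identity = identity, coverage = coverage,
       simscore = identity * coverage)
}

# Scoring matrix over the 20 residues matching sw_oracle's match/mismatch.
simple_submat <- function(match = 1, mismatch = -10) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  m <- matrix(mismatch, 20, 20, dimnames = list(aa, aa))
  diag(m) <- match
  m
}

# Confusion-matrix metrics by explicit counting over label pairs.
metrics_oracle <- function(pred, truth, averaging = "weighted",
                           positive = "PVP") {
  levels <- sort(union(pred, truth))
  per <- lapply(levels, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p = p, r = r, f = f, support = sum(truth == cl))
  })
  tab <- do.call(rbind, per)
  acc <- mean(pred == truth)
  if (averaging == "binary") {
    k <- match(positive, levels)
    out <- list(accuracy = acc, precision = tab[k, "p"],
                recall = tab[k, "r"], f1 = tab[k, "f"])
  } else if (averaging == "macro") {
    out <- list(accuracy = acc, precision = mean(tab[, "p"]),
                recall = mean(tab[, "r"]), f1 = mean(tab[, "f"]))
  } else {
    w <- tab[, "support"] / length(truth)
    out <- list(accuracy = acc, precision = sum(w * tab[, "p"]),
                recall = sum(w * tab[, "r"]), f1 = sum(w * tab[, "f"]))
  }
  # MCC by direct covariance over indicator vectors
  s <- length(truth)
  cm <- table(factor(truth, levels = levels), factor(pred, levels = levels))
  ctr <- sum(diag(cm)); pk <- colSums(cm); tk <- rowSums(cm)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  out$mcc <- if (den == 0) 0 else (ctr * s - sum(pk * tk)) / den
  out
}

# Term-by-term scalar evaluation of the asymmetric loss of one sample under
# the standard (per-class binary) reading; probabilities from the definition
# of the softmax with no stabilization tricks.
asl_scalar_oracle <- function(logits, true_class, gamma_pos, gamma_neg,
                              floor = 1e-8) {
  p <- exp(logits) / sum(exp(logits))
  p <- pmin(pmax(p, floor), 1 - floor)
  total <- 0
  for (c in seq_along(logits)) {
    y <- as.numeric(c == true_class)
    total <- total - y * (1 - p[c])^gamma_pos * log(p[c]) -
      (1 - y) * p[c]^gamma_neg * log(1 - p[c])
  }
  total
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

rand_aa <- function(n, len) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i)
    paste(sample(aa, len, replace = TRUE), collapse = ""), character(1))
}
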