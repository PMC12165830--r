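#' Generate class-structured Gaussian embedding fixtures
#'
#' Draws each class from an isotropic Gaussian with unit within-class
#' standard deviation; class means are placed along random orthonormal
#' directions (scaled so that every pair of means is exactly `separation`
#' apart, in within-class sigma units), so the class signal is distributed
#' across all embedding coordinates the way trained language-model features
#' are, rather than concentrated in a few positions. This emulates the one
#' property of language-model embeddings the classifier relies on — classes
#' forming clusters of controllable separation and size — and nothing else
#' about their geometry.
#'
#' @param n_per_class integer vector of per-class counts.
#' @param dim embedding dimensionality (default 1024, must be >= number of
#'   classes).
#' @param separation distance between class means in sigma units.
#' @param seed integer seed; the output is a pure function of the spec.
#' @param class_labels optional class names (default `class1`, `class2`, ...).
#' @return List with `table` (an `embedding_table`) and `labels` (character
#'   vector aligned with `table$ids`).
#' @examples
#' g <- gen_gaussian_embeddings(c(20, 20), dim = 16, separation = 6, seed = 1)
#' table(g$labels)
#' @export
gen_gaussian_embeddings <- function(n_per_class, dim = 1024L, separation = 5,
                                    seed = 1L, class_labels = NULL) {
  k <- length(n_per_class)
  stopifnot(k >= 1L, all(n_per_class >= 1L), dim >= max(2L, k),
            separation >= 0)
  if (is.null(class_labels)) class_labels <- paste0("class", seq_len(k))
  stopifnot(length(class_labels) == k)
  n <- sum(n_per_class)
  lab <- rep(class_labels, n_per_class)
  # class means at (separation / sqrt(2)) * q_c for orthonormal directions
  # q_c: every pairwise inter-mean distance is exactly `separation`
  values <- with_seed(seed, {
    q <- qr.Q(qr(matrix(stats::rnorm(dim * k), dim, k)))
    means <- t(q) * separation / sqrt(2)
    noise <- matrix(stats::rnorm(n * dim), n, dim)
    noise + means[rep(seq_len(k), n_per_class), , drop = FALSE]
  })
  ids <- sprintf("emb%04d", seq_len(n))
  list(table = embedding_table(ids, values,
                               sprintf("gaussian(sep=%g,seed=%d)",
                                       separation, seed)),
       labels = lab)
}

#' Generate toy protein families with controlled divergence
#'
#' One random ancestor per family (uniform over the 20 residues); each member
#' is an independent per-site mutant of its ancestor (substitutions uniform
#' over the other 19 residues). `mutation_rate` parameterizes the expected
#' divergence *between members*: each member mutates at `mutation_rate / 2`
#' relative to the ancestor, so two members differ at close to
#' `mutation_rate` of their sites and within-family identity sits near
#' `1 - mutation_rate`. Between families there is essentially no similarity,
#' which is what the homology-aware splitter tests exercise.
#'
#' @param n_families number of families.
#' @param members_per_family members per family.
#' @param length sequence length (>= 10).
#' @param mutation_rate per-site substitution probability in `[0, 1)`.
#' @param seed integer seed.
#' @return A [protein_records] data frame; ids `famF_mM`, descriptions tag the
#'   family.
#' @export
gen_protein_families <- function(n_families, members_per_family, length = 300L,
                                 mutation_rate = 0.05, seed = 1L) {
  stopifnot(n_families >= 1L, members_per_family >= 1L, length >= 10L,
            mutation_rate >= 0, mutation_rate < 1)
  with_seed(seed, {
    ids <- character(0); seqs <- character(0); desc <- character(0)
    for (f in seq_len(n_families)) {
      anc <- sample(AA_STANDARD, length, replace = TRUE)
      for (m in seq_len(members_per_family)) {
        member <- anc
        hit <- stats::runif(length) < mutation_rate / 2
        if (any(hit))
          member[hit] <- vapply(anc[hit], function(a)
            sample(setdiff(AA_STANDARD, a), 1L), character(1))
        ids <- c(ids, sprintf("fam%d_m%d", f, m))
        seqs <- c(seqs, paste(member, collapse = ""))
        desc <- c(desc, sprintf("synthetic family %d member %d", f, m))
      }
    }
    protein_records(ids, seqs, description = desc)
  })
}

#' Generate a labeled annotation-line corpus for labeler tests
#'
#' Builds records whose descriptions are drawn from the keyword vocabulary of
#' the default [label_rules()] — the seven category phrases plus generic
#' structural terms for virion proteins, enzyme/non-structural phrases for
#' non-virion proteins, and `"hypothetical protein"` distractors — with the
#' ground-truth labels attached in columns `true_binary` / `true_category`,
#' so the labeler can be checked for exact agreement.
#'
#' @param n_per_category records per functional category.
#' @param n_nonpvp number of non-structural records.
#' @param n_distractor number of unlabeled distractor records.
#' @param seed integer seed (random sequences only; descriptions are fixed
#'   templates).
#' @return A [protein_records] data frame with extra truth columns.
#' @export
gen_annotation_corpus <- function(n_per_category = 2L, n_nonpvp = 6L,
                                  n_distractor = 2L, seed = 1L) {
  stopifnot(n_per_category >= 1L, n_nonpvp >= 0L, n_distractor >= 0L)
  cat_desc <- paste(PVP_CATEGORIES, "protein")
  nonpvp_pool <- c("DNA polymerase", "terminase large subunit", "putative holin",
                   "endolysin", "transcription factor", "repressor regulator",
                   "DNA ligase", "exonuclease")
  desc <- c(rep(cat_desc, each = n_per_category),
            rep_len(nonpvp_pool, n_nonpvp),
            rep("hypothetical protein", n_distractor))
  true_binary <- c(rep("PVP", 7L * n_per_category),
                   rep("nonPVP", n_nonpvp),
                   rep("unlabeled", n_distractor))
  true_category <- c(rep(PVP_CATEGORIES, each = n_per_category),
                     rep(NA_character_, n_nonpvp + n_distractor))
  n <- length(desc)
  seqs <- with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(AA_STANDARD, 60L, replace = TRUE), collapse = ""),
    character(1)))
  rec <- protein_records(sprintf("corpus%03d", seq_len(n)), seqs,
                         description = desc)
  rec$true_binary <- true_binary
  rec$true_category <- true_category
  rec
}
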