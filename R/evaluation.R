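#' Statistical evaluation layer
#'
#' The survey sample-size formula, inter-rater agreement, chi-square
#' association with Pearson residuals, Bonferroni-corrected group contrasts
#' with one-way ANOVA, emotion-channel correlation screens, and the
#' stratified cross-validation protocol for the fused classifier.
#'
#' @name evaluation
NULL

#' Finite-population survey sample size
#'
#' `n0 = z^2 p (1-p) / e^2`, corrected for a finite population of size `N`:
#' `n = n0 / (1 + n0 / N)`.
#'
#' @param N population size (may be `Inf`).
#' @param z z-score of the confidence level (1.96 for 95 percent).
#' @param p anticipated proportion (0.5 is conservative).
#' @param e margin of error.
#' @return list: `n` (unrounded), `n_ceiling`, `n_infinite` (the uncorrected
#'   `n0`).
#' @export
sample_size <- function(N, z = 1.96, p = 0.5, e = 0.05) {
  if (N <= 0 || p <= 0 || p >= 1 || e <= 0) {
    stopf("need N > 0, 0 < p < 1, e > 0")
  }
  n0 <- z^2 * p * (1 - p) / e^2
  n <- n0 / (1 + n0 / N)
  list(n = n, n_ceiling = ceiling(n), n_infinite = n0)
}

#' Cohen's kappa inter-rater agreement
#'
#' `(p_o - p_e) / (1 - p_e)` from two aligned label vectors or a square
#' contingency table. When chance agreement is 1, kappa is undefined and
#' returned as `NA`.
#'
#' @param a,b label vectors, or `a` a square table with `b` missing.
#' @return kappa in \[-1, 1\], or `NA` for the degenerate case.
#' @export
cohens_kappa <- function(a, b = NULL) {
  tab <- if (is.null(b)) as.matrix(a) else {
    lev <- sort(union(unique(as.character(a)), unique(as.character(b))))
    table(factor(a, lev), factor(b, lev))
  }
  if (nrow(tab) != ncol(tab)) stopf("agreement table must be square")
  n <- sum(tab)
  if (n < 2) stopf("need at least 2 rated items")
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Chi-square test of association with Pearson residuals
#'
#' Standard (uncorrected) chi-square statistic on an r x c count table, with
#' the per-cell Pearson residuals `(O - E) / sqrt(E)` whose squares sum to
#' the statistic.
#'
#' @param tab matrix/table of non-negative counts; all expected counts must
#'   be positive.
#' @return list: `statistic`, `p_value`, `df`, `residuals`, `expected`.
#' @export
chi_square_association <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stopf("counts must be non-negative")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0)) stopf("zero expected count: table is degenerate")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = unname(ht$parameter), residuals = ht$residuals,
       expected = ht$expected)
}

#' Group contrasts with Bonferroni-corrected significance
#'
#' For every feature column: a two-sample pooled-variance t-test with the
#' 95 percent confidence interval of the mean difference when there are
#' exactly two groups (Welch behind `var_equal = FALSE`), and a one-way
#' ANOVA F for any number of groups. Stars are assigned at alpha = 0.05 and
#' at the Bonferroni level 0.05 / m, with `m` defaulting to the study-wide
#' feature count of 223.
#'
#' @param features data.frame or matrix of numeric feature columns.
#' @param group grouping vector (2 or more levels, each with n >= 2).
#' @param m_total number of comparisons for the Bonferroni correction.
#' @param var_equal pooled-variance t (default TRUE).
#' @return data.frame, one row per feature.
#' @export
group_tests <- function(features, group, m_total = 223, var_equal = TRUE) {
  features <- as.data.frame(features)
  group <- factor(group)
  if (nlevels(group) < 2 || any(table(group) < 2)) {
    stopf("need at least 2 groups with n >= 2 each")
  }
  two <- nlevels(group) == 2
  rows <- lapply(names(features), function(f) {
    v <- features[[f]]
    degenerate <- all(tapply(v, group, function(g) stats::var(g) < 1e-24))
    tt <- list(statistic = NA_real_, conf.int = c(NA_real_, NA_real_), p.value = NA_real_)
    if (two && !degenerate) {
      tt <- stats::t.test(v ~ group, var.equal = var_equal)
    }
    Fv <- NA_real_; pF <- NA_real_
    if (!degenerate) {
      an <- stats::oneway.test(v ~ group, var.equal = TRUE)
      Fv <- unname(an$statistic); pF <- unname(an$p.value)
    }
    p <- if (two) tt$p.value else pF
    data.frame(feature = f,
               t_stat = unname(tt$statistic),
               ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
               f_stat = Fv, p_value = p, p_anova = pF,
               sig_05 = !is.na(p) & p < 0.05,
               sig_bonferroni = !is.na(p) & p < 0.05 / m_total,
               degenerate = degenerate)
  })
  do.call(rbind, rows)
}

#' Correlation screen between two feature channels
#'
#' Pearson correlation of every (face-emotion, text-emotion) feature pair
#' with a significance mask: pairs whose correlation is not significant at
#' p < 0.05 (or undefined because a column is constant) are masked.
#'
#' @param face,text aligned numeric matrices/data.frames (rows = users).
#' @return list: `r`, `p`, `masked` (logical).
#' @export
emotion_text_correlation <- function(face, text) {
  face <- as.matrix(face); text <- as.matrix(text)
  if (nrow(face) != nrow(text) || nrow(face) < 3) {
    stopf("need aligned rows, n >= 3")
  }
  r <- matrix(NA_real_, ncol(face), ncol(text),
              dimnames = list(colnames(face), colnames(text)))
  p <- r
  for (i in seq_len(ncol(face))) {
    for (j in seq_len(ncol(text))) {
      xi <- face[, i]; yj <- text[, j]
      ok <- stats::complete.cases(xi, yj)
      if (sum(ok) >= 3 && stats::sd(xi[ok]) > 0 && stats::sd(yj[ok]) > 0) {
        ct <- stats::cor.test(xi[ok], yj[ok])
        r[i, j] <- unname(ct$estimate)
        p[i, j] <- ct$p.value
      }
    }
  }
  list(r = r, p = p, masked = is.na(p) | p >= 0.05)
}

#' Classification metrics with the depressed class positive
#'
#' @param truth,predicted 0/1 vectors (1 = depressed).
#' @return named vector: specificity, sensitivity, f1, accuracy.
#' @export
classifier_metrics <- function(truth, predicted) {
  tp <- sum(truth == 1 & predicted == 1); fn <- sum(truth == 1 & predicted == 0)
  fp <- sum(truth == 0 & predicted == 1); tn <- sum(truth == 0 & predicted == 0)
  sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  c(specificity = spec, sensitivity = sens, f1 = f1,
    accuracy = (tp + tn) / length(truth))
}

# deterministic stratified fold assignment
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the fused classifier
#'
#' Everything that learns from data — fusion standardization/imputation,
#' optional shadow-feature selection, and the booster — is fitted inside
#' each training fold only; held-out rows are transformed with the training
#' moments and scored once.
#'
#' @param blocks named list of modality blocks (see [cohort_feature_blocks()]).
#' @param labels named 0/1 vector keyed by user id.
#' @param params booster hyperparameters.
#' @param k folds (default 10); must not exceed the minority class count.
#' @param seed integer seed for the fold assignment (and selection RNG).
#' @param select run [boruta_select()] per fold and keep confirmed features
#'   (falling back to all features if none confirm).
#' @param select_iter iterations for the per-fold selector.
#' @return list of class `cv_result`: `mean` (specificity, sensitivity, f1,
#'   accuracy), `folds` (per-fold metric matrix), `k`.
#' @export
cross_validate <- function(blocks, labels, params = booster_params(), k = 10,
                           seed = 1, select = FALSE, select_iter = 20) {
  ids <- names(labels)
  y <- as.numeric(labels)
  if (k > min(table(y))) stopf("k = %d exceeds the minority class count", k)
  with_seed(derive_seed(seed, "cv"), {
    fold <- stratified_folds(y, k)
    per_fold <- lapply(seq_len(k), function(f) {
      train_ids <- ids[fold != f]
      fm <- early_fusion(blocks, train_ids = train_ids)
      x <- fm$x[ids, , drop = FALSE]
      tr <- fold != f
      keep <- colnames(x)
      if (select) {
        sel <- boruta_select(x[tr, , drop = FALSE], y[tr], n_iter = select_iter)
        conf <- sel$feature[sel$decision == "confirmed"]
        if (length(conf) >= 2) keep <- conf
      }
      model <- fit_booster(x[tr, keep, drop = FALSE], y[tr], params)
      pred <- predict(model, x[!tr, keep, drop = FALSE], type = "class")
      classifier_metrics(y[!tr], pred)
    })
    folds <- do.call(rbind, per_fold)
    structure(list(mean = colMeans(folds, na.rm = TRUE), folds = folds, k = k),
              class = "cv_result")
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", x$k, "folds:",
      paste(sprintf("%s %.3f", names(x$mean), x$mean), collapse = ", "), "\n")
  invisible(x)
}
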