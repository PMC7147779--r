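#' Early fusion of modality feature blocks
#'
#' Concatenates per-modality blocks column-wise into one user-by-feature
#' matrix, tracking which block each column came from and which cells were
#' missing. Columns are z-score standardized with moments fitted on the
#' training rows only (pass `train_ids` inside cross-validation folds to keep
#' the transform leakage-free); missing cells are imputed with the training
#' column mean and each block contributes a 0/1 missingness indicator column.
#'
#' @param blocks named list of data.frames, each with a `user_id` column and
#'   numeric feature columns; feature names must be unique across blocks.
#' @param train_ids user ids used to fit moments/imputation (default: all).
#' @param standardize z-score the feature columns (default TRUE).
#' @return object of class `feature_matrix`: list with `x` (numeric matrix,
#'   rownames = user ids), `mask` (logical missingness matrix), `block`
#'   (named character: column -> block), `center`, `scale`, `train_ids`.
#' @export
early_fusion <- function(blocks, train_ids = NULL, standardize = TRUE) {
  stopifnot(is.list(blocks), length(blocks) > 0, !is.null(names(blocks)))
  feat_names <- unlist(lapply(blocks, function(b) setdiff(names(b), "user_id")))
  if (anyDuplicated(feat_names)) {
    stopf("duplicate feature names across blocks: %s",
          paste(unique(feat_names[duplicated(feat_names)]), collapse = ", "))
  }
  merged <- Reduce(function(a, b) merge(a, b, by = "user_id", all = TRUE), blocks)
  ids <- merged$user_id
  x <- as.matrix(merged[, setdiff(names(merged), "user_id"), drop = FALSE])
  rownames(x) <- ids
  block_of <- stats::setNames(
    rep(names(blocks), vapply(blocks, function(b) ncol(b) - 1L, integer(1))),
    feat_names
  )[colnames(x)]
  mask <- is.na(x)
  train_ids <- train_ids %||% ids
  tr <- ids %in% train_ids
  if (!any(tr)) stopf("no training rows among the supplied ids")

  center <- rep(0, ncol(x)); scale_ <- rep(1, ncol(x))
  names(center) <- names(scale_) <- colnames(x)
  for (j in seq_len(ncol(x))) {
    tv <- x[tr, j][!mask[tr, j]]
    mu <- if (length(tv)) mean(tv) else 0
    x[mask[, j], j] <- mu
    if (standardize) {
      sd_ <- if (length(tv) > 1) stats::sd(tv) else 0
      center[j] <- mu
      scale_[j] <- if (is.na(sd_) || sd_ < 1e-12) 1 else sd_
      x[, j] <- (x[, j] - center[j]) / scale_[j]
    }
  }
  # one missingness indicator per block (1 = block absent for the user)
  ind <- sapply(names(blocks), function(b) {
    cols <- which(block_of == b)
    as.numeric(rowSums(!mask[, cols, drop = FALSE]) == 0)
  })
  colnames(ind) <- paste0("missing_", names(blocks))
  x <- cbind(x, ind)
  block_of <- c(block_of, stats::setNames(names(blocks), colnames(ind)))
  structure(list(x = x, mask = mask, block = block_of, center = center,
                 scale = scale_, train_ids = train_ids),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix>", nrow(x$x), "users x", ncol(x$x), "features (",
      length(unique(x$block)), "blocks )\n")
  invisible(x)
}

#' Augment a feature matrix with shadow features
#'
#' Appends one row-permuted copy of every column (`shadow_<name>`). The
#' permutation breaks any feature-label association while preserving each
#' column's marginal distribution — the importance null used by the
#' shadow-feature selector.
#'
#' @param x numeric matrix.
#' @return matrix of doubled width.
#' @export
shadow_augment <- function(x) {
  stopifnot(is.matrix(x), nrow(x) > 0, ncol(x) > 0)
  sh <- apply(x, 2, function(col) col[sample.int(length(col))])
  colnames(sh) <- paste0("shadow_", colnames(x))
  cbind(x, sh)
}

#' Shadow-feature (all-relevant) selection
#'
#' Ensemble feature selection: on each iteration the shadow columns are
#' re-permuted, a random forest is fitted on the extended matrix, and a
#' feature scores a "hit" when its importance exceeds the maximum shadow
#' importance. Hits over `n_iter` iterations are referred to an exact
#' two-sided Binomial(n_iter, 1/2) test: features with significantly more
#' than half hits are confirmed, significantly fewer are rejected, the rest
#' stay tentative.
#'
#' @param x numeric feature matrix (rows = users).
#' @param y 0/1 labels.
#' @param n_iter iterations (at least 20).
#' @param alpha significance level of the binomial decision test.
#' @param importance importance oracle `function(x, y) -> named numeric`;
#'   default: ranger impurity importance.
#' @param num_trees trees per forest for the default oracle.
#' @return data.frame of class `boruta_result`: feature, hits, p_value,
#'   decision.
#' @export
boruta_select <- function(x, y, n_iter = 50, alpha = 0.05,
                          importance = NULL, num_trees = 100) {
  if (n_iter < 20) stopf("n_iter must be at least 20 (got %d)", n_iter)
  if (length(unique(y)) < 2) stopf("labels are constant")
  importance <- importance %||% function(xx, yy) {
    fit <- ranger::ranger(x = xx, y = factor(yy), num.trees = num_trees,
                          importance = "impurity",
                          num.threads = 1, verbose = FALSE)
    fit$variable.importance
  }
  hits <- stats::setNames(integer(ncol(x)), colnames(x))
  for (it in seq_len(n_iter)) {
    ext <- shadow_augment(x)
    imp <- importance(ext, y)
    max_shadow <- max(imp[grepl("^shadow_", names(imp))])
    real <- imp[colnames(x)]
    hits <- hits + as.integer(real > max_shadow)
  }
  p <- vapply(hits, function(h) stats::binom.test(h, n_iter, 0.5)$p.value, numeric(1))
  decision <- ifelse(p < alpha & hits > n_iter / 2, "confirmed",
                     ifelse(p < alpha & hits < n_iter / 2, "rejected", "tentative"))
  out <- data.frame(feature = colnames(x), hits = as.integer(hits),
                    p_value = p, decision = decision, row.names = NULL)
  attr(out, "n_iter") <- n_iter
  attr(out, "alpha") <- alpha
  class(out) <- c("boruta_result", "data.frame")
  out
}
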