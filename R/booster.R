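#' Second-order gradient-boosted trees, from the objective up
#'
#' Binary classifier built directly from the boosted-ensemble equations:
#' logistic loss with per-example first/second derivatives g = p - y and
#' h = p(1 - p); regularizer phi(f) = lambda/2 * sum w_j^2 + gamma * k over a
#' tree's k leaves; optimal leaf weight w_j = -G_j / (H_j + lambda); greedy
#' exact split search maximizing the structure-score gain
#' 1/2 \[G_L^2/(H_L+lambda) + G_R^2/(H_R+lambda) - (G_L+G_R)^2/(H_L+H_R+lambda)\] - gamma,
#' splitting only on positive gain; leaves shrunk by eta. Equal-gain ties
#' break to the lowest feature index, then lowest threshold, so builds are
#' deterministic. An optional L1 term soft-thresholds the leaf numerator.
#'
#' @name booster
NULL

#' Booster hyperparameters
#'
#' @param eta learning rate (shrinkage) applied to every leaf weight.
#' @param max_depth maximum tree depth (a stump has depth 1).
#' @param nrounds number of boosting rounds (trees).
#' @param lambda L2 penalty on leaf weights.
#' @param gamma per-leaf complexity penalty (minimum split gain).
#' @param alpha optional L1 penalty on leaf weights (0 = off).
#' @return named list of parameters.
#' @export
booster_params <- function(eta = 0.1, max_depth = 3, nrounds = 100,
                           lambda = 1, gamma = 0, alpha = 0) {
  stopifnot(eta > 0, max_depth >= 1, nrounds >= 0, lambda >= 0, gamma >= 0, alpha >= 0)
  list(eta = eta, max_depth = max_depth, nrounds = nrounds,
       lambda = lambda, gamma = gamma, alpha = alpha)
}

#' Optimal leaf weight
#'
#' `w = -G / (H + lambda)` from the second-order expansion of the loss; with
#' an L1 penalty the numerator is soft-thresholded first.
#'
#' @param G sum of first derivatives over the leaf.
#' @param H sum of second derivatives over the leaf.
#' @param lambda L2 penalty.
#' @param alpha L1 penalty (default 0).
#' @return leaf weight.
#' @export
leaf_weight <- function(G, H, lambda, alpha = 0) {
  if (H + lambda <= 0) stopf("H + lambda must be positive (got %g)", H + lambda)
  num <- if (alpha > 0) sign(G) * max(0, abs(G) - alpha) else G
  -num / (H + lambda)
}

# structure-score term G^2/(H + lambda)
score_term <- function(G, H, lambda) G^2 / (H + lambda)

# recursive exact greedy tree builder on gradient/hessian targets
build_tree <- function(x, g, h, idx, depth, params) {
  G <- sum(g[idx]); H <- sum(h[idx])
  value <- params$eta * leaf_weight(G, H, params$lambda, params$alpha)
  node <- list(value = value, cover = H, n = length(idx))
  if (depth >= params$max_depth || length(idx) < 2) {
    node$leaf <- TRUE
    return(node)
  }
  best <- list(gain = 0)
  parent_term <- score_term(G, H, params$lambda)
  for (j in seq_len(ncol(x))) {
    xv <- x[idx, j]
    ord <- order(xv)
    xs <- xv[ord]; gs <- g[idx][ord]; hs <- h[idx][ord]
    cg <- cumsum(gs); ch <- cumsum(hs)
    # candidate split after each position where the value changes
    cut <- which(diff(xs) > 0)
    if (length(cut) == 0) next
    for (kk in cut) {
      gl <- cg[kk]; hl <- ch[kk]
      gain <- 0.5 * (score_term(gl, hl, params$lambda) +
                     score_term(G - gl, H - hl, params$lambda) -
                     parent_term) - params$gamma
      if (gain > best$gain + 1e-12) {
        best <- list(gain = gain, feature = j,
                     threshold = (xs[kk] + xs[kk + 1]) / 2)
      }
    }
  }
  if (best$gain <= 0 || is.null(best$feature)) {
    node$leaf <- TRUE
    return(node)
  }
  left_idx <- idx[x[idx, best$feature] < best$threshold]
  right_idx <- idx[x[idx, best$feature] >= best$threshold]
  node$leaf <- FALSE
  node$feature <- colnames(x)[best$feature]
  node$feature_index <- best$feature
  node$threshold <- best$threshold
  node$gain <- best$gain
  node$left <- build_tree(x, g, h, left_idx, depth + 1, params)
  node$right <- build_tree(x, g, h, right_idx, depth + 1, params)
  node
}

tree_predict_row <- function(node, xrow) {
  while (!node$leaf) {
    node <- if (xrow[node$feature_index] < node$threshold) node$left else node$right
  }
  node$value
}

logloss <- function(y, p) -mean(y * log(pmax(p, 1e-15)) + (1 - y) * log(pmax(1 - p, 1e-15)))

#' Fit the gradient-boosted classifier
#'
#' @param x numeric feature matrix (rows = examples, named columns).
#' @param y 0/1 labels, both classes present at least twice.
#' @param params see [booster_params()].
#' @return object of class `depscreen_booster`: trees, params, feature
#'   names, `base_score` (log-odds of the class prior) and the per-round
#'   training log-loss trace.
#' @export
fit_booster <- function(x, y, params = booster_params()) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (!all(y %in% c(0, 1))) stopf("labels must be 0/1")
  if (sum(y == 0) < 2 || sum(y == 1) < 2) stopf("need at least 2 examples of each class")
  base <- stats::qlogis(mean(y))
  pred <- rep(base, nrow(x))
  trees <- vector("list", params$nrounds)
  trace <- numeric(params$nrounds)
  idx <- seq_len(nrow(x))
  for (t in seq_len(params$nrounds)) {
    p <- stats::plogis(pred)
    g <- p - y
    h <- p * (1 - p)
    tree <- build_tree(x, g, h, idx, 0, params)
    trees[[t]] <- tree
    pred <- pred + vapply(idx, function(i) tree_predict_row(tree, x[i, ]), numeric(1))
    trace[t] <- logloss(y, stats::plogis(pred))
  }
  structure(list(trees = trees, params = params, feature_names = colnames(x),
                 base_score = base, train_logloss = trace),
            class = "depscreen_booster")
}

#' @export
print.depscreen_booster <- function(x, ...) {
  cat("<depscreen_booster>", length(x$trees), "trees, depth <=",
      x$params$max_depth, ", eta", x$params$eta, "\n")
  invisible(x)
}

#' Predict log-odds and probabilities
#'
#' `log-odds = base_score + sum_t f_t(x)`; `probability = plogis(log-odds)`.
#'
#' @param object fitted `depscreen_booster`.
#' @param newdata numeric matrix with (at least) the model's feature columns.
#' @param type `"prob"`, `"logodds"` or `"class"`.
#' @param ... unused.
#' @return numeric vector (or 0/1 for `"class"`).
#' @export
predict.depscreen_booster <- function(object, newdata, type = c("prob", "logodds", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing) > 0) {
    stopf("newdata lacks model features: %s", paste(missing, collapse = ", "))
  }
  newdata <- newdata[, object$feature_names, drop = FALSE]
  lo <- vapply(seq_len(nrow(newdata)), function(i) {
    object$base_score + sum(vapply(object$trees, tree_predict_row,
                                   numeric(1), xrow = newdata[i, ]))
  }, numeric(1))
  switch(type, logodds = lo, prob = stats::plogis(lo),
         class = as.numeric(stats::plogis(lo) > 0.5))
}

#' Additive log-odds explanation of one prediction
#'
#' Deterministic path attribution: walking each tree, the change in node
#' value (the regularized Newton estimate -G/(H+lambda), shrunk by eta) at
#' every traversed split is credited to the split feature; contributions are
#' summed across trees. By construction
#' `base + sum(deltas) == predicted log-odds` exactly, where `base` is the
#' prior log-odds plus each tree's root value.
#'
#' @param model fitted `depscreen_booster`.
#' @param xrow single named feature vector (or 1-row matrix).
#' @return object of class `booster_explanation`: `base`, `deltas` (named,
#'   sorted by absolute impact), `logodds`, `probability`.
#' @export
explain_booster <- function(model, xrow) {
  if (is.matrix(xrow)) xrow <- xrow[1, ]
  xrow <- xrow[model$feature_names]
  deltas <- stats::setNames(numeric(length(model$feature_names)), model$feature_names)
  base <- model$base_score
  for (tree in model$trees) {
    base <- base + tree$value
    node <- tree
    while (!node$leaf) {
      child <- if (xrow[node$feature_index] < node$threshold) node$left else node$right
      deltas[node$feature] <- deltas[node$feature] + (child$value - node$value)
      node <- child
    }
  }
  lo <- base + sum(deltas)
  structure(list(base = base,
                 deltas = deltas[order(-abs(deltas))],
                 logodds = lo,
                 probability = stats::plogis(lo)),
            class = "booster_explanation")
}

#' @export
print.booster_explanation <- function(x, ...) {
  cat(sprintf("log-odds %.3f (probability %.1f%%), base %.3f\n",
              x$logodds, 100 * x$probability, x$base))
  top <- x$deltas[seq_len(min(8, length(x$deltas)))]
  for (nm in names(top)) cat(sprintf("  %+0.4f  %s\n", top[[nm]], nm))
  invisible(x)
}

#' Serialize / restore a booster as JSON
#'
#' @param model fitted `depscreen_booster`.
#' @param path file path.
#' @return `path` (write) or the restored model (read).
#' @export
booster_to_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname booster_to_json
#' @export
booster_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  fix <- function(node) {
    node$leaf <- isTRUE(node$leaf)
    if (!node$leaf) {
      node$left <- fix(node$left)
      node$right <- fix(node$right)
    }
    node
  }
  raw$trees <- lapply(raw$trees, fix)
  raw$feature_names <- unlist(raw$feature_names)
  structure(raw, class = "depscreen_booster")
}
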