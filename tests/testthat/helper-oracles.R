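# Independent brute-force oracles, kept deliberately naive: per-pixel loops,
# textbook DP, adjacency-matrix arithmetic. They never call the package's
# vectorized paths.

bf_image_stats <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  n <- h * w
  rs <- gs <- bs <- 0
  rg <- yb <- numeric(n)
  lum <- sat <- numeric(n)
  k <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    k <- k + 1
    r <- img[i, j, 1] * 255; g <- img[i, j, 2] * 255; b <- img[i, j, 3] * 255
    rs <- rs + r; gs <- gs + g; bs <- bs + b
    rg[k] <- r - g
    yb[k] <- (r + g) / 2 - b
    lum[k] <- (0.299 * r + 0.587 * g + 0.114 * b) / 255
    mx <- max(r, g, b)
    sat[k] <- if (mx == 0) 0 else (mx - min(r, g, b)) / mx
  }
  m_rg <- sum(rg) / n; m_yb <- sum(yb) / n
  v_rg <- sum((rg - m_rg)^2) / n; v_yb <- sum((yb - m_yb)^2) / n
  m_lum <- sum(lum) / n
  m_sat <- sum(sat) / n
  list(
    red_mean = rs / n, green_mean = gs / n, blue_mean = bs / n,
    avg_rgb = (rs + gs + bs) / (3 * n),
    colorfulness = sqrt(v_rg + v_yb) + 0.3 * sqrt(m_rg^2 + m_yb^2),
    grayscale_mean = m_lum,
    contrast = sqrt(sum((lum - m_lum)^2) / n),
    saturation_mean = m_sat,
    saturation_var = sum((sat - m_sat)^2) / n
  )
}

bf_levenshtein <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  d <- matrix(0, length(a) + 1, length(b) + 1)
  d[, 1] <- 0:length(a); d[1, ] <- 0:length(b)
  for (i in seq_along(a)) for (j in seq_along(b)) {
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1, d[i + 1, j] + 1,
                           d[i, j] + (a[i] != b[j]))
  }
  d[length(a) + 1, length(b) + 1]
}

# ego metrics from scratch on an adjacency representation
bf_ego_metrics <- function(u, edges) {
  nodes_all <- unique(c(edges$from, edges$to, u))
  A <- matrix(0, length(nodes_all), length(nodes_all),
              dimnames = list(nodes_all, nodes_all))
  for (r in seq_len(nrow(edges))) {
    if (edges$count[r] > 0) {
      A[edges$from[r], edges$to[r]] <- A[edges$from[r], edges$to[r]] + edges$count[r]
    }
  }
  U <- (A + t(A)) > 0   # undirected adjacency
  n1 <- nodes_all[U[u, ]]
  n2 <- unique(nodes_all[colSums(U[n1, , drop = FALSE]) > 0])
  keep <- unique(c(u, n1, n2))
  Us <- U[keep, keep, drop = FALSE]
  n <- length(keep)
  out_p <- nodes_all[A[u, ] > 0]; in_p <- nodes_all[A[, u] > 0]
  either <- union(out_p, in_p)
  reciprocity <- if (length(either) == 0) 0 else
    length(intersect(out_p, in_p)) / length(either)
  prestige <- sum(A[, u]) / max(1, sum(A[u, ]))
  density <- if (n < 2) 0 else sum(Us) / (n * (n - 1))
  nu <- keep[Us[u, ]]
  deg <- length(nu)
  clustering <- if (deg < 2) 0 else {
    links <- 0
    for (a in nu) for (b in nu) if (a < b && Us[a, b]) links <- links + 1
    links / (deg * (deg - 1) / 2)
  }
  emb <- if (deg == 0) 0 else mean(sapply(nu, function(v) {
    nv <- keep[Us[v, ]]
    length(intersect(nu, nv)) / length(union(nu, nv))
  }))
  rest <- setdiff(keep, u)
  comp <- 0
  if (length(rest) > 0) {
    seen <- character(0)
    for (s in rest) {
      if (s %in% seen) next
      comp <- comp + 1
      frontier <- s
      while (length(frontier) > 0) {
        seen <- union(seen, frontier)
        nxt <- unique(unlist(lapply(frontier, function(v) rest[Us[v, rest]])))
        frontier <- setdiff(nxt, seen)
      }
    }
  }
  list(reciprocity = reciprocity, prestige_ratio = prestige,
       graph_density = density, clustering_coefficient = clustering,
       embeddedness = emb, ego_components = comp, two_hop_size = n - 1)
}

random_image <- function(h = 8, w = 8) {
  array(runif(h * w * 3), dim = c(h, w, 3))
}

make_test_cohort <- function(nd = 40, nc = 50, seed = 11, ...) {
  generate_cohort(cohort_config(n_depressed = nd, n_control = nc, seed = seed, ...))
}

# exhaustive oracle: scan every feature and every midpoint threshold,
# scoring the regularized structure gain directly from the definitions
oracle_stump <- function(x, y, lambda, gamma, eta, base) {
  p <- plogis(rep(base, length(y)))
  g <- p - y; h <- p * (1 - p)
  G <- sum(g); H <- sum(h)
  best <- list(gain = 0, feature = NA, threshold = NA)
  for (j in seq_len(ncol(x))) {
    for (t in sort(unique(x[, j]))[-1]) {
      thr <- mean(c(max(x[x[, j] < t, j]), t))
      L <- x[, j] < thr
      gl <- sum(g[L]); hl <- sum(h[L])
      gain <- 0.5 * (gl^2 / (hl + lambda) + (G - gl)^2 / (H - hl + lambda) -
                     G^2 / (H + lambda)) - gamma
      if (gain > best$gain + 1e-12) best <- list(gain = gain, feature = j, threshold = thr)
    }
  }
  if (is.na(best$feature)) return(NULL)
  L <- x[, best$feature] < best$threshold
  best$w_left <- -eta * sum(g[L]) / (sum(h[L]) + lambda)
  best$w_right <- -eta * sum(g[!L]) / (sum(h[!L]) + lambda)
  best
}

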