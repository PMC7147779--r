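#' Calibrated target sets for synthetic imagery
#'
#' Per-class, per-context aesthetic targets the image synthesizer steers
#' toward, taken from the study's printed class means: colorfulness,
#' naturalness, saturation mean, and a gray-level target (profile images carry
#' an average-RGB target, shared media a normalized grayscale-mean target).
#' Features not listed (hue variance, saturation variance, channel means) are
#' emergent properties of the composition, not steered.
#'
#' @param class "depressed" or "control".
#' @param context "profile" or "shared".
#' @return named list of targets.
#' @export
image_calibration_targets <- function(class = c("depressed", "control"),
                                      context = c("profile", "shared")) {
  class <- match.arg(class)
  context <- match.arg(context)
  tab <- list(
    depressed = list(
      profile = list(colorfulness = 108.05, avg_rgb = 134.39,
                     naturalness = 0.37, saturation_mean = 0.21),
      shared = list(colorfulness = 106.12, gray_mean = 0.54,
                    naturalness = 0.486, saturation_mean = 0.198)
    ),
    control = list(
      profile = list(colorfulness = 118.85, avg_rgb = 139.00,
                     naturalness = 0.61, saturation_mean = 0.31),
      shared = list(colorfulness = 122.37, gray_mean = 0.49,
                    naturalness = 0.651, saturation_mean = 0.289)
    )
  )
  tab[[class]][[context]]
}

# continuous HSV -> RGB (h in degrees, s/v in [0,1]); no 8-bit quantization
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  c_ <- v * s
  x <- c_ * (1 - abs(h %% 2 - 1))
  m <- v - c_
  i <- floor(h) %% 6
  sel <- function(a) a[cbind(seq_along(i), i + 1)]
  zero <- 0 * x
  rr <- cbind(c_, x, zero, zero, x, c_)
  gg <- cbind(x, c_, c_, x, zero, zero)
  bb <- cbind(zero, zero, x, c_, c_, x)
  cbind(r = sel(rr) + m, g = sel(gg) + m, b = sel(bb) + m)
}

# luminance of a unit-value HSV color
lum_factor <- function(h, s) {
  rgb <- hsv_to_rgb(h, s, 1)
  as.numeric(rgb %*% c(0.299, 0.587, 0.114))
}

#' Synthesize an image matching aesthetic targets
#'
#' Composes an image from four pixel populations: a memory-color "band"
#' population (sky-band hue, saturation solved in closed form so the band's
#' naturalness score equals the target), a high-chroma blue/yellow pair that
#' carries opponent-channel dispersion (its size is solved by binary search so
#' the measured colorfulness matches the target), near-gray filler whose value
#' is solved linearly for the gray-level target, with population fractions
#' chosen so the saturation mean matches exactly. The blue/yellow pixels sit
#' outside the naturalness qualifying luminance range by construction, so the
#' colorfulness and naturalness knobs do not interact. Re-measuring the
#' emitted image with the feature operators recovers the (jittered) targets to
#' within about one colorfulness unit and 1e-6 on saturation mean.
#'
#' @param targets list with \code{colorfulness}, \code{saturation_mean}, and
#'   optionally \code{naturalness} and \code{gray_mean} (luminance in \[0,1\])
#'   or \code{avg_rgb} (0-255). See [image_calibration_targets()].
#' @param seed optional integer; when given the draw is reproducible.
#' @param dim image height/width (default 32 x 32).
#' @param jitter logical; when TRUE (default) targets receive small random
#'   perturbations (4 percent relative; 0.02 absolute on naturalness) so
#'   repeated draws emulate a population of images whose mean recovers the
#'   targets. Set FALSE for an exact single image.
#' @return numeric array \code{h x w x 3} in \[0, 1\].
#' @export
synthesize_image <- function(targets, seed = NULL, dim = c(32, 32), jitter = TRUE) {
  run <- function() synthesize_image_impl(targets, dim, jitter)
  if (is.null(seed)) run() else with_seed(seed, run())
}

synthesize_image_impl <- function(targets, dim, jitter) {
  cf_t <- targets$colorfulness %||% stopf("targets$colorfulness is required")
  s_t <- targets$saturation_mean %||% stopf("targets$saturation_mean is required")
  nat_t <- targets$naturalness %||% NA_real_
  gray_t <- targets$gray_mean %||% NA_real_
  avg_t <- targets$avg_rgb %||% NA_real_
  if (cf_t < 0) stopf("infeasible target: colorfulness %.3f < 0", cf_t)
  if (s_t < 0 || s_t > 1) stopf("infeasible target: saturation_mean %.3f outside [0,1]", s_t)
  if (!is.na(nat_t) && (nat_t < 0 || nat_t > 1)) {
    stopf("infeasible target: naturalness %.3f outside [0,1]", nat_t)
  }

  if (jitter) {
    cf_t <- max(0, cf_t * clamp(1 + stats::rnorm(1, 0, 0.04), 0.92, 1.08))
    s_t <- clamp(s_t * (1 + stats::rnorm(1, 0, 0.04)), 0, 0.95)
    if (!is.na(nat_t) && nat_t > 0) nat_t <- clamp(nat_t + stats::rnorm(1, 0, 0.02), 0.02, 0.98)
    if (!is.na(gray_t)) gray_t <- clamp(gray_t * (1 + stats::rnorm(1, 0, 0.04)), 0.05, 0.95)
    if (!is.na(avg_t)) avg_t <- clamp(avg_t * (1 + stats::rnorm(1, 0, 0.04)), 15, 240)
  }

  n <- prod(dim)
  s_gray <- if (s_t < 0.01) 0 else 0.02

  # band saturation from the naturalness target (closed form on the sky band)
  use_band <- !is.na(nat_t) && nat_t > 0 && s_t >= 0.12
  if (!is.na(nat_t) && nat_t > 0 && s_t < 0.12) {
    stopf("infeasible target: naturalness %.3f requires saturation_mean >= 0.12 (got %.3f)",
          nat_t, s_t)
  }
  s_band <- NA_real_
  if (use_band) {
    sky <- cni_bands()[cni_bands()$band == "sky", ]
    q <- sqrt(-2 * log(nat_t))
    cand <- c(sky$mu - sky$sigma * q, sky$mu + sky$sigma * q)
    cand <- cand[cand > 0.115 & cand < 0.98]
    if (length(cand) == 0) {
      stopf("infeasible target: naturalness %.3f has no admissible band saturation", nat_t)
    }
    # prefer the high-saturation candidate: it needs the smallest band
    # fraction for a given saturation budget, leaving headroom for the
    # chroma pair and gray filler
    s_band <- max(cand)
  }

  # per-image population hues/values (shared by all pixels of a population).
  # The chroma quartet carries the opponent-channel energy: yellow/blue span
  # the yb axis outside the naturalness qualifying-luminance range; orange/
  # magenta span the rg axis on hues outside every memory-color band.
  hue_band <- if (jitter) stats::runif(1, 185, 235) else 210
  hue_y <- if (jitter) stats::runif(1, 57, 64) else 60
  hue_b <- if (jitter) stats::runif(1, 238, 250) else 243
  hue_o <- if (jitter) stats::runif(1, 5, 16) else 10
  hue_m <- if (jitter) stats::runif(1, 295, 315) else 305
  v_chroma <- c(y = 0.99, b = 0.99, o = 1, m = 1)
  v_band <- if (use_band) min(1, 0.5 / lum_factor(hue_band, s_band)) else NA_real_

  compose <- function(n_c) {
    n4 <- n_c %/% 4
    rem <- n_c - 4 * n4
    n_y <- n4 + (rem >= 1)
    n_b <- n4 + (rem >= 2)
    n_o <- n4 + (rem >= 3)
    n_m <- n4
    f_c <- n_c / n
    if (use_band) {
      f_band <- (s_t - f_c * 1 - (1 - f_c) * s_gray) / (s_band - s_gray)
      if (f_band < -1e-9) return(NULL)  # chroma already exceeds saturation budget
      f_band <- clamp(f_band, 0, 1 - f_c)
      n_band <- max(1L, round(f_band * n))
      n_band <- min(n_band, n - n_c)
    } else {
      n_band <- 0L
    }
    n_g <- n - n_c - n_band
    # gray saturation trimmed so the overall saturation mean is exact
    s_g_eff <- if (n_g > 0) {
      clamp((s_t * n - n_c - n_band * ifelse(use_band, s_band, 0)) / n_g, 0, 0.1)
    } else 0
    pops <- list(
      list(n = n_y, h = hue_y, s = 1, v = v_chroma[["y"]]),
      list(n = n_b, h = hue_b, s = 1, v = v_chroma[["b"]]),
      list(n = n_o, h = hue_o, s = 1, v = v_chroma[["o"]]),
      list(n = n_m, h = hue_m, s = 1, v = v_chroma[["m"]]),
      list(n = n_band, h = hue_band, s = if (use_band) s_band else 0, v = v_band),
      list(n = n_g, h = 0, s = s_g_eff, v = NA_real_)  # v solved below
    )
    # solve gray value against the gray-level target
    coef <- if (!is.na(gray_t)) c(0.299, 0.587, 0.114) else rep(1 / 3, 3)
    t_g <- if (!is.na(gray_t)) gray_t else if (!is.na(avg_t)) avg_t / 255 else NA_real_
    fixed <- 0
    for (p in pops[1:5]) {
      if (p$n > 0) fixed <- fixed + p$n * sum(hsv_to_rgb(p$h, p$s, 1) * coef) * p$v
    }
    v_g <- if (is.na(t_g)) 0.5 else {
      gl <- sum(hsv_to_rgb(0, pops[[6]]$s, 1) * coef)  # ~1 for near-gray
      vg <- if (n_g > 0) (t_g * n - fixed) / (n_g * gl) else 0.5
      if (vg < -0.08 || vg > 1.08) {
        stopf("infeasible target: gray level %.3f needs gray value %.2f outside [0,1]", t_g, vg)
      }
      clamp(vg, 0.02, 0.98)
    }
    pops[[6]]$v <- v_g
    px <- do.call(rbind, lapply(pops, function(p) {
      if (p$n == 0) NULL else hsv_to_rgb(rep(p$h, p$n), rep(p$s, p$n), rep(p$v, p$n))
    }))
    clamp(px, 0, 1)
  }

  measure_cf <- function(px) {
    r <- px[, 1] * 255; g <- px[, 2] * 255; b <- px[, 3] * 255
    rg <- r - g; yb <- 0.5 * (r + g) - b
    sqrt(pop_var(rg) + pop_var(yb)) + 0.3 * sqrt(mean(rg)^2 + mean(yb)^2)
  }

  # binary search on the chroma-pair pixel count for the colorfulness target
  n_c_max <- floor(n * clamp((s_t - s_gray) / (1 - s_gray), 0, 1))
  while (n_c_max > 0 && is.null(compose(n_c_max))) n_c_max <- n_c_max - 1
  cf_lo <- measure_cf(compose(0))
  cf_hi <- if (n_c_max > 0) measure_cf(compose(n_c_max)) else cf_lo
  # a jittered draw may brush the feasible boundary; saturate it there rather
  # than fail, provided the requested (pre-jitter) target itself is reachable
  slack <- if (jitter) 0.10 * max(cf_t, 10) else 1.5
  if (cf_lo > cf_t + slack) {
    stopf("infeasible target: colorfulness %.2f below the %.2f floor implied by the naturalness/saturation targets",
          cf_t, cf_lo)
  }
  if (cf_hi < cf_t - slack) {
    stopf("infeasible target: colorfulness %.2f exceeds the %.2f ceiling implied by saturation_mean %.3f",
          cf_t, cf_hi, s_t)
  }
  cf_t <- clamp(cf_t, cf_lo, cf_hi)
  lo <- 0L; hi <- n_c_max
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (measure_cf(compose(mid)) < cf_t) lo <- mid else hi <- mid
  }
  n_c <- if (abs(measure_cf(compose(lo)) - cf_t) <= abs(measure_cf(compose(hi)) - cf_t)) lo else hi
  px <- compose(n_c)
  px <- px[sample.int(nrow(px)), , drop = FALSE]
  array(c(px[, 1], px[, 2], px[, 3]), dim = c(dim[1], dim[2], 3L))
}

#' Write an RGB array to a PNG file
#'
#' @param img RGB array in \[0,1\].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(as_rgb_image(img), path)
  invisible(path)
}
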