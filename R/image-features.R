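#' Computational aesthetic image features
#'
#' Per-image descriptors used throughout the pipeline: RGB channel means,
#' luminance brightness/contrast, HSV moments (circular hue statistics,
#' linear saturation statistics), opponent-channel colorfulness, a memory-color
#' naturalness index, and Laplacian sharpness. Images are numeric arrays
#' \code{h x w x 3} with values in \[0, 1\] (the convention of
#' \code{png::readPNG}); grayscale matrices are broadcast to three channels and
#' an alpha channel, when present, is dropped.
#'
#' @name image_features
NULL

#' Coerce input to an RGB array
#'
#' @param img numeric array \code{h x w x 3} (or \code{h x w}, or
#'   \code{h x w x 4}) with values in \[0, 1\].
#' @return numeric array \code{h x w x 3}.
#' @export
as_rgb_image <- function(img) {
  if (is.character(img) && length(img) == 1) img <- read_image(img)
  if (!is.numeric(img)) stopf("image must be a numeric array, got %s", class(img)[1])
  if (length(img) == 0) stopf("image has no pixels")
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3L))
  if (length(dim(img)) != 3) stopf("image must have 2 or 3 dimensions")
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] != 3) stopf("image must have 1, 3 or 4 channels, got %d", dim(img)[3])
  if (anyNA(img) || min(img) < -1e-9 || max(img) > 1 + 1e-9) {
    stopf("image values must lie in [0, 1]")
  }
  img
}

#' Read a PNG image as an RGB array
#'
#' @param path path to a PNG file.
#' @return numeric array \code{h x w x 3} in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!grepl("\\.png$", tolower(path))) {
    stopf("unsupported image format for '%s' (PNG only)", basename(path))
  }
  as_rgb_image(png::readPNG(path))
}

# Rec.601 luminance in [0,1]
luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# HSV per pixel: hue in degrees [0,360), s and v in [0,1]
image_hsv <- function(img) {
  m <- grDevices::rgb2hsv(rbind(
    as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3])
  ), maxColorValue = 1)
  list(h = m[1, ] * 360, s = m[2, ], v = m[3, ])
}

#' Opponent-channel colorfulness
#'
#' Hasler-Suesstrunk metric on the 0-255 scale: with opponent channels
#' \code{rg = R - G} and \code{yb = (R + G)/2 - B},
#' \code{sqrt(sd_rg^2 + sd_yb^2) + 0.3 * sqrt(mu_rg^2 + mu_yb^2)}.
#' A uniform gray image scores exactly 0. Standard deviations use the
#' population (n) divisor so a single pixel is well defined.
#'
#' @param img RGB image (see [as_rgb_image()]).
#' @return non-negative scalar.
#' @export
colorfulness <- function(img) {
  img <- as_rgb_image(img)
  r <- as.vector(img[, , 1]) * 255
  g <- as.vector(img[, , 2]) * 255
  b <- as.vector(img[, , 3]) * 255
  rg <- r - g
  yb <- 0.5 * (r + g) - b
  sqrt(pop_var(rg) + pop_var(yb)) + 0.3 * sqrt(mean(rg)^2 + mean(yb)^2)
}

#' Memory-color naturalness constants
#'
#' Hue bands (degrees) and saturation prototypes (mean, sd) for the three
#' memory-color families. These constants are this package's documented
#' choice of a colorfulness-naturalness-index parameterization; see the
#' methods vignette.
#'
#' @return data.frame with one row per band.
#' @export
cni_bands <- function() {
  data.frame(
    band = c("skin", "grass", "sky"),
    hue_lo = c(20, 70, 170),
    hue_hi = c(70, 170, 260),
    mu = c(0.55, 0.44, 0.43),
    sigma = c(0.19, 0.16, 0.15)
  )
}

#' Naturalness index
#'
#' Pixels with Rec.601 luminance in \[20, 80\] (0-100 scale) and saturation
#' above 0.1 qualify; qualifying pixels are classified by hue into the
#' skin/grass/sky memory-color bands of [cni_bands()]. Each non-empty band
#' scores \code{exp(-0.5 * ((S_bar - mu)/sigma)^2)} where \code{S_bar} is the
#' band's mean saturation, and the index is the pixel-count-weighted average
#' of band scores. Returns 0 when no pixel is classified.
#'
#' @param img RGB image.
#' @return scalar in \[0, 1\].
#' @export
naturalness <- function(img) {
  img <- as_rgb_image(img)
  hsv <- image_hsv(img)
  lum <- as.vector(luminance(img)) * 100
  qual <- lum >= 20 & lum <= 80 & hsv$s > 0.1
  bands <- cni_bands()
  w <- numeric(nrow(bands))
  score <- numeric(nrow(bands))
  for (i in seq_len(nrow(bands))) {
    idx <- qual & hsv$h >= bands$hue_lo[i] & hsv$h < bands$hue_hi[i]
    w[i] <- sum(idx)
    if (w[i] > 0) {
      sbar <- mean(hsv$s[idx])
      score[i] <- exp(-0.5 * ((sbar - bands$mu[i]) / bands$sigma[i])^2)
    }
  }
  if (sum(w) == 0) return(0)
  sum(w * score) / sum(w)
}

# variance of the 3x3 Laplacian of luminance; 0 for images smaller than 3x3
laplacian_sharpness <- function(lum) {
  d <- dim(lum)
  if (d[1] < 3 || d[2] < 3) return(0)
  i <- 2:(d[1] - 1)
  j <- 2:(d[2] - 1)
  lap <- lum[i - 1, j] + lum[i + 1, j] + lum[i, j - 1] + lum[i, j + 1] - 4 * lum[i, j]
  pop_var(as.vector(lap))
}

#' Full per-image aesthetic feature vector
#'
#' Channel means and the grand RGB mean are on the 0-255 scale;
#' \code{grayscale_mean} and \code{brightness} are the (identical) normalized
#' Rec.601 luminance mean, kept as two named fields for downstream tables;
#' \code{contrast} is the luminance standard deviation; hue statistics are
#' circular (mean in radians, variance = 1 - mean resultant length);
#' saturation statistics are linear; \code{sharpness} is the variance of the
#' 3x3 Laplacian of luminance. Every statistic except \code{sharpness} is
#' invariant to pixel permutation.
#'
#' @param img RGB image.
#' @return named numeric vector of class-free features.
#' @export
image_features <- function(img) {
  img <- as_rgb_image(img)
  r <- as.vector(img[, , 1]) * 255
  g <- as.vector(img[, , 2]) * 255
  b <- as.vector(img[, , 3]) * 255
  lum <- luminance(img)
  hsv <- image_hsv(img)
  rad <- hsv$h * pi / 180
  c1 <- mean(cos(rad)); s1 <- mean(sin(rad))
  hue_mean <- atan2(s1, c1) %% (2 * pi)
  hue_var <- 1 - sqrt(c1^2 + s1^2)
  c(
    red_mean = mean(r),
    green_mean = mean(g),
    blue_mean = mean(b),
    avg_rgb = mean(c(r, g, b)),
    grayscale_mean = mean(lum),
    brightness = mean(lum),
    contrast = pop_sd(as.vector(lum)),
    hue_mean = hue_mean,
    hue_var = hue_var,
    saturation_mean = mean(hsv$s),
    saturation_var = pop_var(hsv$s),
    colorfulness = colorfulness(img),
    naturalness = naturalness(img),
    sharpness = laplacian_sharpness(lum)
  )
}

#' Aggregate per-image features to user level
#'
#' Shared-media features are the arithmetic mean over the user's shared
#' images; the profile block comes from the single profile image. An absent
#' modality yields an all-\code{NA} block (absence is preserved, not coded as
#' zero) together with a missingness flag.
#'
#' @param profile named feature vector for the profile image, or \code{NULL}.
#' @param media list of named feature vectors for shared images (possibly empty).
#' @return named numeric vector with \code{profile_*} and \code{shared_*}
#'   fields plus \code{profile_missing} / \code{shared_missing} indicators.
#' @export
aggregate_user_images <- function(profile = NULL, media = list()) {
  template <- names(image_features(array(0.5, dim = c(2, 2, 3))))
  prof <- if (is.null(profile)) {
    stats::setNames(rep(NA_real_, length(template)), template)
  } else profile[template]
  shared <- if (length(media) == 0) {
    stats::setNames(rep(NA_real_, length(template)), template)
  } else {
    colMeans(do.call(rbind, lapply(media, function(f) f[template])))
  }
  out <- c(
    stats::setNames(prof, paste0("profile_", template)),
    stats::setNames(shared, paste0("shared_", template)),
    profile_missing = as.numeric(is.null(profile)),
    shared_missing = as.numeric(length(media) == 0)
  )
  out
}
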