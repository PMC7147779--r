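#' Facial affect pooling and presence statistics
#'
#' Per-face emotion vectors follow the six-emotion basic-affect model
#' (anger, disgust, fear, joy, sadness, surprise), each intensity in \[0, 1\].
#' Face detection itself is pluggable: any detector that annotates each image
#' with a list of six-float vectors can feed these functions; the synthetic
#' cohort supplies such annotations directly.
#'
#' @name facial_affect
NULL

EMOTIONS <- c("anger", "disgust", "fear", "joy", "sadness", "surprise")
POSITIVE_EMOTIONS <- c("joy", "surprise")
NEGATIVE_EMOTIONS <- c("anger", "disgust", "fear", "sadness")

#' Pool per-face emotion vectors into user-level affect features
#'
#' Component-wise mean over all faces across a user's images, plus polarity
#' scores: positive = mean of the pooled joy and surprise components,
#' negative = mean of the pooled anger, disgust, fear and sadness components.
#' An empty face list yields an all-missing block (absence is not zero).
#'
#' @param faces list of numeric length-6 vectors (or an n x 6 matrix), one per
#'   detected face; component order as in `EMOTIONS`.
#' @return named list: `emotions` (named 6-vector), `positive`, `negative`,
#'   `n_faces`, `missing`.
#' @export
pool_face_emotions <- function(faces) {
  if (is.matrix(faces)) faces <- asplit(faces, 1)
  if (length(faces) == 0) {
    return(list(
      emotions = stats::setNames(rep(NA_real_, 6), EMOTIONS),
      positive = NA_real_, negative = NA_real_, n_faces = 0L, missing = TRUE
    ))
  }
  m <- do.call(rbind, lapply(faces, function(f) {
    f <- as.numeric(f)
    if (length(f) != 6) stopf("emotion vector must have 6 components, got %d", length(f))
    if (anyNA(f) || any(f < 0) || any(f > 1)) {
      stopf("emotion intensities must lie in [0, 1]")
    }
    f
  }))
  pooled <- stats::setNames(colMeans(m), EMOTIONS)
  list(
    emotions = pooled,
    positive = mean(pooled[POSITIVE_EMOTIONS]),
    negative = mean(pooled[NEGATIVE_EMOTIONS]),
    n_faces = nrow(m),
    missing = FALSE
  )
}

#' Facial-presence rates by class with chi-square association
#'
#' For each context (profile image, shared media) a user counts as "present"
#' when at least one face was annotated in that context; `not_found` users
#' have no face anywhere. Rates are computed over all users of a class
#' (not only users with images). Each context row gets a 2x2 chi-square
#' association test (class x presence) via [chi_square_association()];
#' degenerate tables (an empty margin) are flagged instead of tested.
#'
#' @param cohort a cohort bundle (see [generate_cohort()]) or a list of user
#'   records with `label`, `face_annotations$profile` and
#'   `face_annotations$media` fields.
#' @return data.frame with one row per context: rates per class (percent),
#'   chi-square statistic, p-value and a degeneracy flag.
#' @export
facial_presence_stats <- function(cohort) {
  users <- if (!is.null(cohort$users)) cohort$users else cohort
  if (length(users) == 0) stopf("cohort has no users")
  label <- vapply(users, function(u) u$label, character(1))
  has_face <- function(ann) any(vapply(ann, function(im) length(im) > 0, logical(1)))
  prof <- vapply(users, function(u) has_face(u$face_annotations$profile), logical(1))
  media <- vapply(users, function(u) has_face(u$face_annotations$media), logical(1))
  rows <- list(media = media, profile = prof, not_found = !(prof | media))
  out <- lapply(names(rows), function(ctx) {
    pres <- rows[[ctx]]
    tab <- table(factor(label, levels = c("depressed", "control")),
                 factor(pres, levels = c(FALSE, TRUE)))
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    chi <- if (degenerate) list(statistic = NA_real_, p_value = NA_real_) else
      chi_square_association(tab)
    data.frame(
      context = ctx,
      rate_depressed = 100 * mean(pres[label == "depressed"]),
      rate_control = 100 * mean(pres[label == "control"]),
      chi_square = unname(chi$statistic),
      p_value = unname(chi$p_value),
      degenerate = degenerate
    )
  })
  do.call(rbind, out)
}
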