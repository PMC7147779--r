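#' Configuration for the synthetic cohort generator
#'
#' All calibration parameters of the generator in one validated object:
#' class sizes, per-class age/gender disclosure rates (set from the study's
#' printed counts, 822/3981 and 239/4789 for age), right-skewed age
#' distributions with class medians 17 and 19, per-class image-aesthetic
#' targets, facial-presence rates per context, social-count means with a
#' fixed coefficient of variation of 1, the face/text emotion-channel
#' correlation, and egocentric-network density parameters giving two-hop
#' neighborhood means of about 84 (depressed) and 154 (control).
#'
#' @param n_depressed,n_control class sizes (defaults 3981 / 4789).
#' @param seed integer master seed; every sub-generator derives its own
#'   stream from it, so a fixed seed reproduces the cohort bit for bit.
#' @param age_disclosure,gender_disclosure named per-class rates in \[0,1\].
#' @param age_median per-class target median of disclosed (integer) ages.
#' @param age_sdlog log-scale sd of the truncated log-normal age model.
#' @param female_share per-class probability that a user's latent gender is
#'   female.
#' @param face_presence_profile,face_presence_media per-class probability
#'   that a user shows at least one face in that context.
#' @param social_count_means list of named per-class mean vectors for the six
#'   engagement counts.
#' @param social_count_cv coefficient of variation of the log-normal count
#'   model (dispersion is not printed in the source tables; 1 is documented
#'   in the methods vignette).
#' @param emotion_text_corr latent correlation in \[-1,1\] coupling the
#'   facial-emotion and text-emotion channels (Gaussian copula).
#' @param ego per-class list of `k1` (mean partner count), `k2` (mean
#'   partners-per-partner) and `tri` (probability that two of the ego's
#'   partners are themselves connected).
#' @param media_images_mean Poisson mean of per-user shared-image counts.
#' @param profile_image_rate probability a user has a profile image.
#' @param collection_year calendar year stamped on records (birth-year
#'   arithmetic uses it).
#' @param image_dim height/width of synthesized images.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_depressed = 3981L,
                          n_control = 4789L,
                          seed = 1L,
                          age_disclosure = c(depressed = 822 / 3981, control = 239 / 4789),
                          gender_disclosure = c(depressed = 937 / 3981, control = 527 / 4789),
                          age_median = c(depressed = 17, control = 19),
                          age_sdlog = 0.45,
                          female_share = c(depressed = 0.70, control = 0.55),
                          face_presence_profile = c(depressed = 0.04, control = 0.12),
                          face_presence_media = c(depressed = 0.72, control = 0.81),
                          social_count_means = list(
                            depressed = c(friends_count = 610.196, followers_count = 589.47,
                                          statuses_count = 3722, favourites_count = 2021,
                                          avg_tweet_favorite_count = 0.22,
                                          avg_tweet_retweet_count = 876.75),
                            control = c(friends_count = 1380.25, followers_count = 1340.83,
                                        statuses_count = 7766, favourites_count = 5199.67,
                                        avg_tweet_favorite_count = 0.67,
                                        avg_tweet_retweet_count = 2720)
                          ),
                          social_count_cv = 1.0,
                          emotion_text_corr = 0.6,
                          ego = list(depressed = list(k1 = 12, k2 = 6, tri = 0.25),
                                     control = list(k1 = 14, k2 = 10, tri = 0.18)),
                          media_images_mean = 3,
                          profile_image_rate = 0.95,
                          collection_year = 2017L,
                          image_dim = c(32L, 32L)) {
  if (!is_count(n_depressed) || !is_count(n_control)) {
    stopf("class sizes must be non-negative integers")
  }
  for (r in list(age_disclosure, gender_disclosure, female_share,
                 face_presence_profile, face_presence_media,
                 profile_image_rate)) {
    if (!is_rate(r)) stopf("all rates must lie in [0, 1]")
  }
  if (!is.numeric(emotion_text_corr) || abs(emotion_text_corr) > 1) {
    stopf("emotion_text_corr must lie in [-1, 1]")
  }
  if (age_sdlog <= 0 || social_count_cv <= 0 || media_images_mean < 0) {
    stopf("dispersion parameters must be positive")
  }
  cfg <- list(
    n_depressed = as.integer(n_depressed), n_control = as.integer(n_control),
    seed = as.integer(seed),
    age_disclosure = age_disclosure, gender_disclosure = gender_disclosure,
    age_median = age_median, age_sdlog = age_sdlog,
    female_share = female_share,
    face_presence_profile = face_presence_profile,
    face_presence_media = face_presence_media,
    social_count_means = social_count_means,
    social_count_cv = social_count_cv,
    emotion_text_corr = emotion_text_corr,
    ego = ego,
    media_images_mean = media_images_mean,
    profile_image_rate = profile_image_rate,
    collection_year = as.integer(collection_year),
    image_dim = as.integer(image_dim)
  )
  # solve the truncated log-normal location so the *integer* age median hits
  # the target: aim the continuous median slightly above target so rounding
  # cannot tip it to target + 1
  cfg$age_meanlog <- vapply(cfg$age_median, function(med) {
    target <- med + 0.2
    f <- function(ml) {
      lo <- stats::plnorm(AGE_MIN, ml, age_sdlog)
      hi <- stats::plnorm(AGE_MAX, ml, age_sdlog)
      stats::qlnorm((lo + hi) / 2, ml, age_sdlog) - target
    }
    stats::uniroot(f, c(log(5), log(59)))$root
  }, numeric(1))
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>", x$n_depressed, "depressed /", x$n_control,
      "control users, seed", x$seed, "\n")
  invisible(x)
}
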