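#' Modality feature blocks for a cohort
#'
#' Each extractor returns a data.frame keyed by `user_id`, one block per
#' modality, ready for [early_fusion()]. Absent modalities (no images, no
#' faces) yield `NA` rows; the fusion layer turns those into imputed values
#' plus missingness indicators.
#'
#' @name cohort_features
NULL

#' @rdname cohort_features
#' @param cohort a `cohort` bundle.
#' @return data.frame of per-user image-aesthetic features (profile block and
#'   shared-media means).
#' @export
cohort_image_features <- function(cohort) {
  rows <- lapply(cohort$users, function(u) {
    prof <- if (!is.na(u$image_seeds$profile)) {
      image_features(cohort_image(cohort, u$user_id, "profile"))
    } else NULL
    media <- lapply(seq_along(u$image_seeds$media), function(k) {
      image_features(cohort_image(cohort, u$user_id, k))
    })
    cbind(data.frame(user_id = u$user_id),
          as.data.frame(t(aggregate_user_images(prof, media))))
  })
  do.call(rbind, rows)
}

#' @rdname cohort_features
#' @export
cohort_face_features <- function(cohort) {
  rows <- lapply(cohort$users, function(u) {
    faces <- c(unlist(u$face_annotations$profile, recursive = FALSE),
               unlist(u$face_annotations$media, recursive = FALSE))
    faces <- lapply(faces, function(f) as.numeric(unlist(f)))
    pooled <- pool_face_emotions(faces)
    cbind(data.frame(user_id = u$user_id),
          as.data.frame(t(c(pooled$emotions,
                            face_positive = pooled$positive,
                            face_negative = pooled$negative,
                            n_faces = as.numeric(pooled$n_faces)))))
  })
  do.call(rbind, rows)
}

#' @rdname cohort_features
#' @param lexicon category lexicon (default: bundled).
#' @param terms depression-term lexicon for screen-name similarity.
#' @param include_description concatenate the profile description with the
#'   tweets before scoring (default TRUE).
#' @export
cohort_text_features <- function(cohort,
                                 lexicon = depscreen_lexicon("category_lexicon"),
                                 terms = depscreen_lexicon("depression_terms"),
                                 include_description = TRUE) {
  rows <- lapply(cohort$users, function(u) {
    txt <- unlist(u$tweets)
    if (include_description) txt <- c(txt, u$description)
    tokens <- tokenize_text(txt)
    rates <- category_rates(tokens, lexicon)
    cbind(data.frame(user_id = u$user_id),
          as.data.frame(t(rates)),
          screen_name_dist = screen_name_similarity(u$screen_name, terms))
  })
  do.call(rbind, rows)
}

#' @rdname cohort_features
#' @param age_lexicon,gender_lexicon weighted lexica (default: bundled).
#' @export
cohort_demo_features <- function(cohort,
                                 age_lexicon = depscreen_lexicon("age_lexicon"),
                                 gender_lexicon = depscreen_lexicon("gender_lexicon"),
                                 include_description = TRUE) {
  rows <- lapply(cohort$users, function(u) {
    txt <- unlist(u$tweets)
    if (include_description) txt <- c(txt, u$description)
    tokens <- tokenize_text(txt)
    data.frame(
      user_id = u$user_id,
      age_score = infer_demographic(tokens, age_lexicon),
      gender_score = infer_demographic(tokens, gender_lexicon),
      age_disclosed = as.numeric(!is.na(u$disclosed_age)),
      gender_disclosed = as.numeric(!is.na(u$disclosed_gender))
    )
  })
  do.call(rbind, rows)
}

#' @rdname cohort_features
#' @export
cohort_social_features <- function(cohort) {
  fields <- c("friends_count", "followers_count", "statuses_count",
              "favourites_count", "avg_tweet_favorite_count",
              "avg_tweet_retweet_count")
  rows <- lapply(cohort$users, function(u) {
    cbind(data.frame(user_id = u$user_id),
          as.data.frame(as.list(stats::setNames(
            vapply(fields, function(f) as.numeric(u[[f]]), numeric(1)), fields))))
  })
  do.call(rbind, rows)
}

#' @rdname cohort_features
#' @param images include the (costly) image block (default TRUE).
#' @return named list of modality blocks for [early_fusion()].
#' @export
cohort_feature_blocks <- function(cohort, images = TRUE) {
  blocks <- list(
    face = cohort_face_features(cohort),
    text = cohort_text_features(cohort),
    demo = cohort_demo_features(cohort),
    network = network_features(cohort),
    social = cohort_social_features(cohort)
  )
  if (images) blocks <- c(list(image = cohort_image_features(cohort)), blocks)
  blocks
}

#' Class labels of a cohort
#'
#' @param cohort a `cohort` bundle.
#' @return named 0/1 vector (1 = depressed), names are user ids.
#' @export
cohort_labels <- function(cohort) {
  stats::setNames(
    as.numeric(vapply(cohort$users, function(u) u$label, character(1)) == "depressed"),
    vapply(cohort$users, function(u) u$user_id, character(1))
  )
}
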