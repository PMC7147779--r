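#' Synthetic cohort generation
#'
#' Emulates the statistical structure of an annotated Twitter depression
#' cohort with no real data: per-class disclosure rates, right-skewed ages,
#' engagement counts, templated tweets and descriptions carrying plantable
#' age/gender/affect signal, face-emotion annotations at the configured
#' presence rates, lazily materialized images calibrated to the per-class
#' aesthetic targets, and an @-reply interaction edge list with class-specific
#' ego-network density. Determinism: every user and every sub-generator draws
#' from a seed derived from the master seed, so identical configurations
#' reproduce identical cohorts (and identical bytes when written).
#'
#' @name synthetic_cohort
NULL

# word pools for templated tweet/description text; pool membership is aligned
# with the bundled lexica so lexicon features recover the planted signal
word_pools <- function() {
  list(
    old = c("work", "office", "meeting", "taxes", "coffee", "news", "morning", "budget"),
    young = c("lol", "omg", "school", "homework", "lmao", "literally", "snap", "idk"),
    neutral = c("today", "weather", "watching", "movie", "music", "walking",
                "dinner", "photo", "weekend", "street", "river", "book", "tea",
                "garden", "cloud", "train", "the", "a", "i", "my", "me"),
    posemo = c("happy", "love", "great", "joy", "excited", "smile", "good",
               "amazing", "hope", "fun"),
    negemo = c("sad", "cry", "hate", "tired", "pain", "alone", "depressed",
               "awful", "anxious", "worthless", "empty", "hurt"),
    female = c("cute", "hair", "bestie", "makeup", "dress", "nails", "mascara"),
    male = c("game", "bro", "team", "beard", "football", "truck", "gym"),
    depressed_phrases = c("self-harm", "anxiety", "depression", "cant sleep",
                          "i feel like a failure", "i am depressed",
                          "0 energy to do anything", "people hate me",
                          "i just want be skinny"),
    control_phrases = c("coffee lover", "sports fan", "love old movies",
                        "travel addict", "music is life", "dog person",
                        "amateur photographer", "weekend hiker")
  )
}

# truncated log-normal age, rounded to whole years
sample_age <- function(n, meanlog, sdlog) {
  lo <- stats::plnorm(AGE_MIN, meanlog, sdlog)
  hi <- stats::plnorm(AGE_MAX, meanlog, sdlog)
  u <- stats::runif(n, lo, hi)
  pmin(AGE_MAX, pmax(AGE_MIN, round(stats::qlnorm(u, meanlog, sdlog))))
}

# correlated standard-normal pair (Gaussian copula driver for the
# face-emotion / text-emotion coupling)
copula_pair <- function(n, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(z1, z2)
}

#' Synthesize a profile description
#'
#' When an age is given it is embedded through exactly one of the three
#' disclosure patterns ("I am X years old" / "Born in X" / "X years old",
#' X a year for the second rule), chosen at random unless forced; the rest of
#' the string is drawn from class-flavoured phrase pools that contain no age
#' pattern, so [extract_age()] round-trips exactly.
#'
#' @param age integer age in \[11, 60\] or `NA`.
#' @param gender "F", "M" or `NA`.
#' @param label "depressed" or "control".
#' @param collection_year calendar year (birth-year arithmetic).
#' @param rule force disclosure rule 1, 2 or 3 (default: random).
#' @return character scalar.
#' @export
synthesize_description <- function(age = NA, gender = NA, label = "control",
                                   collection_year = 2017, rule = NULL) {
  if (!is.na(age) && (age < AGE_MIN || age > AGE_MAX)) {
    stopf("age must lie in [%d, %d]", AGE_MIN, AGE_MAX)
  }
  pools <- word_pools()
  parts <- character(0)
  if (!is.na(age)) {
    rule <- rule %||% sample(1:3, 1)
    parts <- c(parts, switch(rule,
      sprintf("I am %d years old", age),
      sprintf("Born in %d", collection_year - age),
      sprintf("%d years old", age)
    ))
  }
  if (!is.na(gender)) {
    parts <- c(parts, if (gender == "F") sample(c("she/her", "girl here"), 1)
               else sample(c("he/him", "boy here"), 1))
  }
  phrases <- if (label == "depressed") pools$depressed_phrases else pools$control_phrases
  parts <- c(parts, sample(phrases, sample(2:3, 1)))
  paste(parts, collapse = ", ")
}

# templated tweets: each word drawn from emotion / gender / age-mix pools
# with user-specific probabilities (see methods vignette for the mixture)
synthesize_tweets <- function(n_tweets, age, gender, p_neg) {
  pools <- word_pools()
  w <- (age - AGE_MIN) / (AGE_MAX - AGE_MIN)
  p_old <- 0.05 + 0.35 * w
  p_young <- 0.40 - 0.35 * w
  is_f <- isTRUE(unname(gender) == "F")
  own <- if (is_f) pools$female else pools$male
  other <- if (is_f) pools$male else pools$female

  nw <- sample(6:10, n_tweets, replace = TRUE)
  total <- sum(nw)
  u <- stats::runif(total)
  words <- character(total)
  pick <- function(mask, pool) {
    if (any(mask)) words[mask] <<- sample(pool, sum(mask), replace = TRUE)
  }
  emo <- u < 0.15
  neg <- emo & stats::runif(total) < p_neg
  pick(neg, pools$negemo)
  pick(emo & !neg, pools$posemo)
  gen <- !emo & u < 0.23
  ownish <- stats::runif(total) < 0.8
  pick(gen & ownish, own)
  pick(gen & !ownish, other)
  rest <- !emo & !gen
  v <- stats::runif(total)
  pick(rest & v < p_old, pools$old)
  pick(rest & v >= p_old & v < p_old + p_young, pools$young)
  pick(rest & v >= p_old + p_young, pools$neutral)
  vapply(split(words, rep(seq_len(n_tweets), nw)), paste, character(1),
         collapse = " ", USE.NAMES = FALSE)
}

random_screen_name <- function(label, terms) {
  syll <- c("ka", "lo", "mi", "ra", "ve", "zu", "ne", "ta", "pol", "dra", "sky", "lun")
  base <- paste(sample(syll, sample(2:3, 1), replace = TRUE), collapse = "")
  if (label == "depressed" && stats::runif(1) < 0.15) {
    base <- sample(terms, 1)
  }
  paste0(base, if (stats::runif(1) < 0.5) "_" else "", sample(0:999, 1))
}

# one face-emotion vector: Dirichlet with the negative components carrying
# `neg_share` of the concentration mass
sample_emotion_vector <- function(neg_share, concentration = 8) {
  a <- stats::setNames(numeric(6), EMOTIONS)
  a[NEGATIVE_EMOTIONS] <- concentration * neg_share / 4
  a[POSITIVE_EMOTIONS] <- concentration * (1 - neg_share) / 2
  g <- stats::rgamma(6, shape = pmax(a, 1e-3))
  as.list(stats::setNames(g / sum(g), EMOTIONS))
}

# Stage 1: all fixed-arity per-user quantities, drawn vectorized from one
# seeded stream. (One stream per sub-generator, never one per user: freshly
# seeded generators with related seeds have correlated opening draws, which
# would bias small-probability indicators like disclosure.)
draw_core <- function(labels, cfg) {
  n <- length(labels)
  dep <- labels == "depressed"
  with_seed(derive_seed(cfg$seed, "core"), {
    z <- copula_pair(n, cfg$emotion_text_corr)
    ml <- cfg$age_meanlog[labels]
    lo <- stats::plnorm(AGE_MIN, ml, cfg$age_sdlog)
    hi <- stats::plnorm(AGE_MAX, ml, cfg$age_sdlog)
    age <- unname(pmin(AGE_MAX, pmax(AGE_MIN, round(
      stats::qlnorm(stats::runif(n, lo, hi), ml, cfg$age_sdlog)))))
    gender <- unname(ifelse(stats::runif(n) < cfg$female_share[labels], "F", "M"))
    disclose_age <- unname(stats::runif(n) < cfg$age_disclosure[labels])
    disclose_gender <- unname(stats::runif(n) < cfg$gender_disclosure[labels])
    sdlog <- sqrt(log(1 + cfg$social_count_cv^2))
    mns <- do.call(rbind, cfg$social_count_means)[ifelse(dep, "depressed", "control"), ,
                                                 drop = FALSE]
    counts <- matrix(stats::rlnorm(length(mns), log(mns) - sdlog^2 / 2, sdlog),
                     nrow = n, dimnames = list(NULL, colnames(mns)))
    whole <- c("friends_count", "followers_count", "statuses_count", "favourites_count")
    counts[, whole] <- round(counts[, whole])
    prof_face <- unname(stats::runif(n) < cfg$face_presence_profile[labels])
    media_face <- unname(stats::runif(n) < cfg$face_presence_media[labels])
    has_profile_img <- prof_face | stats::runif(n) < cfg$profile_image_rate
    n_media <- stats::rpois(n, cfg$media_images_mean)
    n_media[media_face & n_media == 0] <- 1L
    list(
      z_face = z[, 1], z_text = z[, 2], age = age, gender = gender,
      disclose_age = disclose_age, disclose_gender = disclose_gender,
      counts = counts, prof_face = prof_face, media_face = media_face,
      has_profile_img = has_profile_img, n_media = n_media,
      p_neg = stats::plogis(stats::qlogis(ifelse(dep, 0.65, 0.35)) + 0.9 * z[, 2]),
      face_neg = stats::plogis(stats::qlogis(ifelse(dep, 0.60, 0.30)) + 0.9 * z[, 1])
    )
  })
}

assemble_user <- function(i, label, cfg, core, txt, ann) {
  id <- sprintf("u%05d", i)
  n_media <- core$n_media[i]
  list(
    user_id = id,
    label = label,
    screen_name = txt$screen_name,
    description = txt$description,
    tweets = as.list(txt$tweets),
    friends_count = core$counts[i, "friends_count"],
    followers_count = core$counts[i, "followers_count"],
    statuses_count = core$counts[i, "statuses_count"],
    favourites_count = core$counts[i, "favourites_count"],
    avg_tweet_favorite_count = core$counts[i, "avg_tweet_favorite_count"],
    avg_tweet_retweet_count = core$counts[i, "avg_tweet_retweet_count"],
    profile_image = if (core$has_profile_img[i]) {
      file.path("profiles", paste0(id, ".png"))
    } else NA,
    media_images = if (n_media > 0) {
      as.list(file.path("media", sprintf("%s_%02d.png", id, seq_len(n_media))))
    } else list(),
    face_annotations = ann,
    disclosed_age = if (core$disclose_age[i]) core$age[i] else NA,
    disclosed_gender = if (core$disclose_gender[i]) core$gender[i] else NA,
    collection_year = cfg$collection_year,
    latent = list(age = core$age[i], gender = core$gender[i],
                  z_face = core$z_face[i], z_text = core$z_text[i],
                  face_neg = core$face_neg[i], p_neg = core$p_neg[i]),
    image_seeds = list(
      profile = if (core$has_profile_img[i]) derive_seed(cfg$seed, paste0("imgp", id)) else NA,
      media = if (n_media > 0) {
        vapply(seq_len(n_media), function(k) {
          derive_seed(cfg$seed, paste0("imgm", id, "_", k))
        }, integer(1))
      } else integer(0)
    )
  )
}

#' Synthesize the @-reply interaction edge list
#'
#' Each user receives an independent ego neighborhood of off-cohort partner
#' accounts: `k1` one-hop partners (some reciprocating), each with a Poisson
#' `k2` partners of their own, plus partner-partner edges with probability
#' `tri` per pair. Expected two-hop size is `k1 * (1 + k2)` — about 84 for
#' depressed and 154 for control users under the defaults. A cohort with
#' fewer than two users has no interactions to export and yields an empty
#' edge list.
#'
#' @param users list of user records.
#' @param cfg a `cohort_config`.
#' @return data.frame `from`, `to`, `count`.
#' @export
synthesize_ego_interactions <- function(users, cfg) {
  empty <- data.frame(from = character(0), to = character(0), count = integer(0))
  if (length(users) < 2) return(empty)
  rows <- with_seed(derive_seed(cfg$seed, "net"), lapply(users, function(u) {
    p <- cfg$ego[[u$label]]
    {
      # per-user overdispersion: sociability varies a lot between accounts,
      # so partner rates get unit-mean gamma multipliers (cv 0.5) and the
      # partner-interconnection probability a beta draw around the class mean
      m1 <- stats::rgamma(1, shape = 4, rate = 4)
      m2 <- stats::rgamma(1, shape = 4, rate = 4)
      tri_u <- stats::rbeta(1, p$tri * 8, (1 - p$tri) * 8)
      k1 <- max(1L, stats::rpois(1, p$k1 * m1))
      nb <- sprintf("x%s_%02d", u$user_id, seq_len(k1))
      back <- stats::runif(k1) < 0.6
      k2 <- stats::rpois(k1, p$k2 * m2)
      second_from <- rep(nb, k2)
      second_to <- if (length(second_from)) {
        sprintf("%s_%02d", second_from, sequence(k2))
      } else character(0)
      tri_a <- tri_b <- character(0)
      if (k1 >= 2) {
        pairs <- utils::combn(nb, 2)
        hit <- stats::runif(ncol(pairs)) < tri_u
        tri_a <- pairs[1, hit]; tri_b <- pairs[2, hit]
      }
      list(
        from = c(rep(u$user_id, k1), nb[back], second_from, tri_a),
        to = c(nb, rep(u$user_id, sum(back)), second_to, tri_b),
        count = c(1L + stats::rpois(k1, 0.7), 1L + stats::rpois(sum(back), 0.5),
                  rep(1L, length(second_from) + length(tri_a)))
      )
    }
  }))
  data.frame(
    from = unlist(lapply(rows, `[[`, "from")),
    to = unlist(lapply(rows, `[[`, "to")),
    count = unlist(lapply(rows, `[[`, "count"))
  )
}

#' Generate a synthetic cohort
#'
#' @param cfg a [cohort_config()].
#' @return list of class `cohort` with `users` (list of user records),
#'   `interactions` (edge data.frame) and `config`. Images are lazy: each
#'   record carries image seeds, and [cohort_image()] (or [write_cohort()])
#'   materializes the pixels deterministically.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  terms <- depscreen_lexicon("depression_terms")
  n <- cfg$n_depressed + cfg$n_control
  labels <- rep(c("depressed", "control"), c(cfg$n_depressed, cfg$n_control))
  if (n == 0) {
    return(structure(list(users = list(),
                          interactions = synthesize_ego_interactions(list(), cfg),
                          config = cfg), class = "cohort"))
  }
  core <- draw_core(labels, cfg)
  txt <- with_seed(derive_seed(cfg$seed, "text"), {
    lapply(seq_len(n), function(i) {
      list(
        screen_name = random_screen_name(labels[i], terms),
        description = synthesize_description(
          age = if (core$disclose_age[i]) core$age[i] else NA,
          gender = if (core$disclose_gender[i]) core$gender[i] else NA,
          label = labels[i], collection_year = cfg$collection_year
        ),
        tweets = synthesize_tweets(10 + stats::rpois(1, 5), core$age[i],
                                   core$gender[i], core$p_neg[i])
      )
    })
  })
  ann <- with_seed(derive_seed(cfg$seed, "faces"), {
    lapply(seq_len(n), function(i) {
      prof <- if (core$has_profile_img[i]) {
        list(if (core$prof_face[i]) list(sample_emotion_vector(core$face_neg[i])) else list())
      } else list()
      media <- if (core$n_media[i] > 0) {
        faces_per <- stats::rpois(core$n_media[i], 0.8)
        if (core$media_face[i] && sum(faces_per) == 0) faces_per[1] <- 1L
        if (!core$media_face[i]) faces_per[] <- 0L
        lapply(faces_per, function(k) {
          if (k == 0) list() else {
            lapply(seq_len(k), function(j) sample_emotion_vector(core$face_neg[i]))
          }
        })
      } else list()
      list(profile = prof, media = media)
    })
  })
  users <- lapply(seq_len(n), function(i) {
    assemble_user(i, labels[i], cfg, core, txt[[i]], ann[[i]])
  })
  structure(list(
    users = users,
    interactions = synthesize_ego_interactions(users, cfg),
    config = cfg
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  lab <- vapply(x$users, function(u) u$label, character(1))
  cat("<cohort>", sum(lab == "depressed"), "depressed /", sum(lab == "control"),
      "control users,", nrow(x$interactions), "interaction edges\n")
  invisible(x)
}

#' Materialize one of a user's images
#'
#' @param cohort a `cohort` bundle.
#' @param user_id user id.
#' @param which `"profile"` or a shared-image index.
#' @return RGB array, or `NULL` when the image is absent.
#' @export
cohort_image <- function(cohort, user_id, which = "profile") {
  ids <- vapply(cohort$users, function(u) u$user_id, character(1))
  u <- cohort$users[[match(user_id, ids)]]
  dim <- cohort$config$image_dim
  if (identical(which, "profile")) {
    if (is.na(u$image_seeds$profile)) return(NULL)
    targets <- image_calibration_targets(u$label, "profile")
    synthesize_image(targets, seed = u$image_seeds$profile, dim = dim)
  } else {
    k <- as.integer(which)
    if (k > length(u$image_seeds$media)) return(NULL)
    targets <- image_calibration_targets(u$label, "shared")
    synthesize_image(targets, seed = u$image_seeds$media[k], dim = dim)
  }
}

#' Write a cohort to disk
#'
#' Writes `users.jsonl` (one record per line), `interactions.tsv`,
#' `config.json`, and (optionally) every profile/media image as PNG under
#' `profiles/` and `media/`. Output bytes are a pure function of the
#' configuration.
#'
#' @param cohort a `cohort` bundle.
#' @param dir output directory (created if needed).
#' @param images materialize PNGs (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, images = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "users.jsonl"), open = "wb")
  for (u in cohort$users) {
    rec <- u[setdiff(names(u), "image_seeds")]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null",
                                na = "null"), con)
  }
  close(con)
  utils::write.table(cohort$interactions, file.path(dir, "interactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (images && length(cohort$users) > 0) {
    dir.create(file.path(dir, "profiles"), showWarnings = FALSE)
    dir.create(file.path(dir, "media"), showWarnings = FALSE)
    for (u in cohort$users) {
      if (!is.na(u$image_seeds$profile)) {
        write_image(cohort_image(cohort, u$user_id, "profile"),
                    file.path(dir, u$profile_image))
      }
      for (k in seq_along(u$image_seeds$media)) {
        write_image(cohort_image(cohort, u$user_id, k),
                    file.path(dir, u$media_images[[k]]))
      }
    }
  }
  invisible(dir)
}
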