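co <- make_test_cohort()  # 40 depressed / 50 control, seed 11
labels <- cohort_labels(co)

test_that("cohort has the configured composition", {
  expect_length(co$users, 90)
  expect_equal(sum(labels == 1), 40)
  expect_equal(sum(labels == 0), 50)
  expect_s3_class(co$config, "cohort_config")

  empty <- generate_cohort(cohort_config(n_depressed = 0, n_control = 0))
  expect_length(empty$users, 0)
  expect_equal(nrow(empty$interactions), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_depressed = -1), "non-negative")
  expect_error(cohort_config(age_disclosure = c(depressed = 1.2, control = 0.1)),
               "rates")
  expect_error(cohort_config(emotion_text_corr = 2), "emotion_text_corr")
})

test_that("identical configuration reproduces identical bytes on disk", {
  cfg <- cohort_config(n_depressed = 3, n_control = 3, seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  expect_gt(length(f1), 5)  # jsonl, tsv, config, and several PNGs
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_equal(unname(h1), unname(h2))
})

test_that("descriptions embed ages that extract_age recovers exactly", {
  for (u in co$users) {
    got <- extract_age(u$description, u$collection_year)
    if (is.na(u$disclosed_age)) {
      expect_true(is.na(got), label = u$description)
    } else {
      expect_equal(got, as.integer(u$disclosed_age), label = u$description)
    }
  }
})

test_that("the three disclosure rules produce their canonical phrasings", {
  set.seed(2)
  expect_match(synthesize_description(17, NA, "depressed", rule = 3),
               "^17 years old, ")
  expect_match(synthesize_description(23, NA, "control", 2017, rule = 2),
               "Born in 1994")
  expect_match(synthesize_description(30, NA, "control", rule = 1),
               "I am 30 years old")
  no_age <- synthesize_description(NA, "F", "control")
  expect_true(is.na(extract_age(no_age)))
})

test_that("class calibration is recovered within sampling tolerance", {
  big <- make_test_cohort(nd = 700, nc = 800, seed = 5)
  lab <- cohort_labels(big)
  users <- big$users

  dis <- vapply(users, function(u) !is.na(u$disclosed_age), logical(1))
  p_dep <- 822 / 3981
  se <- sqrt(p_dep * (1 - p_dep) / 700)
  expect_lt(abs(mean(dis[lab == 1]) - p_dep), 3 * se)

  med <- vapply(users, function(u) u$latent$age, numeric(1))
  expect_equal(median(med[lab == 1]), 17, tolerance = 0.51)
  expect_equal(median(med[lab == 0]), 19, tolerance = 0.51)

  fr <- vapply(users, function(u) u$friends_count, numeric(1))
  for (cl in c(1, 0)) {
    mu <- if (cl == 1) 610.196 else 1380.25
    n <- sum(lab == cl)
    expect_lt(abs(mean(fr[lab == cl]) - mu), 3 * mu / sqrt(n))  # cv = 1
  }

  fp <- facial_presence_stats(big)
  med_row <- fp[fp$context == "media", ]
  expect_lt(abs(med_row$rate_depressed - 72), 3 * 100 * sqrt(0.72 * 0.28 / 700))
  expect_lt(abs(med_row$rate_control - 81), 3 * 100 * sqrt(0.81 * 0.19 / 800))
})

test_that("cohort images are lazy, deterministic and class-calibrated", {
  u <- Find(function(u) !is.na(u$image_seeds$profile) && u$label == "depressed",
            co$users)
  img <- cohort_image(co, u$user_id, "profile")
  expect_identical(img, cohort_image(co, u$user_id, "profile"))
  expect_equal(dim(img), c(32, 32, 3))

  dep_prof <- Filter(function(u) u$label == "depressed" && !is.na(u$image_seeds$profile),
                     co$users)
  nat <- vapply(dep_prof, function(u) naturalness(cohort_image(co, u$user_id)),
                numeric(1))
  expect_equal(mean(nat), 0.37, tolerance = 0.03)
})

test_that("interaction networks separate the classes as configured", {
  nf <- network_features(co)
  expect_true(all(nf$graph_density >= 0 & nf$graph_density <= 1))
  m_dep <- mean(nf$two_hop_size[labels == 1])
  m_ctl <- mean(nf$two_hop_size[labels == 0])
  expect_lt(m_dep, m_ctl)
  expect_equal(m_dep, 84, tolerance = 0.15)
  expect_equal(m_ctl, 154, tolerance = 0.15)

  single <- generate_cohort(cohort_config(n_depressed = 1, n_control = 0))
  expect_equal(nrow(single$interactions), 0)

  i1 <- synthesize_ego_interactions(co$users, co$config)
  i2 <- synthesize_ego_interactions(co$users, co$config)
  expect_identical(i1, i2)
})

test_that("the emotion copula couples face and text channels at the configured rho", {
  set.seed(1)
  z <- depscreen:::copula_pair(5000, 0.6)
  expect_equal(cor(z[, 1], z[, 2]), 0.6, tolerance = 0.05)
  z0 <- depscreen:::copula_pair(5000, 0)
  expect_lt(abs(cor(z0[, 1], z0[, 2])), 0.05)
})
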