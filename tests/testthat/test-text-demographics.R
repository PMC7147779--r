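lex_cat <- depscreen:::depscreen_lexicon("category_lexicon")

test_that("category rates are token percentages, invariant to duplication", {
  toks <- c("i", "me", "my", "sad")
  r <- category_rates(toks, lex_cat)
  expect_equal(unname(r["self_ref"]), 75)
  expect_equal(unname(r["negemo"]), 25)
  expect_equal(r, category_rates(c(toks, toks), lex_cat))

  long <- category_rates(c("wonderful", "xy"), lex_cat)
  expect_equal(unname(long["sixltr"]), 50)

  empty_lex <- data.frame(term = character(0), category = character(0))
  class(empty_lex) <- c("category_lexicon", "data.frame")
  r0 <- category_rates(toks, empty_lex)
  expect_true(all(r0[setdiff(names(r0), "sixltr")] == 0))

  r_none <- category_rates(character(0), lex_cat)
  expect_true(all(r_none == 0))
  expect_true(isTRUE(attr(r_none, "degenerate")))
})

test_that("tokenizer lowercases, splits and keeps emoticons", {
  toks <- tokenize_text("I'm SAD today :( lol <3")
  expect_true(all(c("i'm", "sad", "today", "lol") %in% toks))
  expect_true(":(" %in% toks)
  expect_true("<3" %in% toks)
})

test_that("screen-name distance is the normalized Levenshtein minimum", {
  expect_equal(screen_name_similarity("kitten", terms = "sitting"), 3 / 7)
  expect_equal(screen_name_similarity("anxiety_2004", terms = c("anxiety", "zzz")), 0)
  expect_error(screen_name_similarity("abc", terms = character(0)), "empty")
  expect_error(screen_name_similarity("_1999_"), "empty after cleaning")

  set.seed(4)
  pool <- c("sad", "kitten", "sitting", "hope", "despair", "abcdef")
  for (i in 1:10) {
    a <- sample(pool, 1); b <- sample(pool, 1)
    d <- bf_levenshtein(a, b)
    expect_equal(d, bf_levenshtein(b, a))            # symmetry
    expect_equal(screen_name_similarity(a, terms = b), d / max(nchar(a), nchar(b)))
    cpool <- sample(pool, 1)                          # triangle inequality
    expect_lte(d, bf_levenshtein(a, cpool) + bf_levenshtein(cpool, b))
  }
  s <- screen_name_similarity("zzzz", terms = pool)
  expect_true(s >= 0 && s <= 1)
})

test_that("age extraction applies the three rules with plausibility filtering", {
  expect_equal(extract_age("17 years old, self-harm, anxiety, depression"), 17L)
  expect_equal(extract_age("Born in 1994", 2017), 23L)
  expect_equal(extract_age("I am 19 years old and fine"), 19L)
  expect_equal(extract_age("i'm 21 years old"), 21L)
  expect_true(is.na(extract_age("love old movies")))
  expect_true(is.na(extract_age("8 years old")))       # below support
  expect_true(is.na(extract_age("99 years old")))      # above support
  expect_true(is.na(extract_age("Born in 2015", 2017)))  # not a valid birth year
  expect_equal(extract_age("Born in 1960", 2017), 57L)
})

test_that("weighted-lexicon score is relative frequency times weight", {
  lex <- data.frame(term = c("a", "b"), weight = c(3, -1))
  attr(lex, "intercept") <- 0
  class(lex) <- c("weighted_lexicon", "data.frame")

  expect_equal(infer_demographic(c("a", "b", "a"), lex), 5 / 3)
  expect_equal(infer_demographic(c("x", "y"), lex), 0)  # no term occurs
  doc <- c("a", "b", "a", "z")
  expect_equal(infer_demographic(doc, lex), infer_demographic(c(doc, doc), lex))
  expect_error(infer_demographic(character(0), lex), "empty")

  # linearity in the weights
  lex2 <- lex; lex2$weight <- c(1, 4); attr(lex2, "intercept") <- 0
  lex_sum <- lex; lex_sum$weight <- lex$weight + lex2$weight
  expect_equal(infer_demographic(doc, lex_sum),
               infer_demographic(doc, lex) + infer_demographic(doc, lex2))
})

test_that("bundled lexica recover planted demographic signal", {
  co <- make_test_cohort(nd = 60, nc = 60, seed = 21)
  demo <- cohort_demo_features(co)
  lat_age <- vapply(co$users, function(u) u$latent$age, numeric(1))
  lat_gen <- vapply(co$users, function(u) u$latent$gender, character(1))
  expect_gt(cor(demo$age_score, lat_age), 0.5)
  sc <- split(demo$gender_score, lat_gen)
  expect_gt(mean(sc$F), 0)
  expect_lt(mean(sc$M), 0)
  expect_gt(mean(sc$F > 0), 0.8)
})

test_that("adult-development bins follow the left-closed convention", {
  expect_equal(as.character(assign_age_group(c(17, 19, 22, 23, 45, 59))),
               c("[11,19)", "[19,23)", "[19,23)", "[23,34)", "[34,46)", "[46,60)"))
  expect_error(assign_age_group(10), "\\[11, 60\\)")
  expect_error(assign_age_group(60), "\\[11, 60\\)")
})

test_that("one-vs-rest group metrics match hand arithmetic", {
  truth <- c("A", "A", "B", "B", "B", "C")
  pred <- c("A", "B", "B", "B", "C", "C")
  m <- evaluate_group_predictions(truth, pred)
  a <- m[m$group == "A", ]
  expect_equal(a$sensitivity, 1 / 2)
  expect_equal(a$specificity, 4 / 4)
  expect_equal(a$accuracy, 5 / 6)
  b <- m[m$group == "B", ]
  expect_equal(b$sensitivity, 2 / 3)
  expect_equal(b$specificity, 2 / 3)

  perfect <- evaluate_group_predictions(truth, truth)
  expect_true(all(perfect$sensitivity == 1) && all(perfect$specificity == 1))

  all_a <- evaluate_group_predictions(truth, rep("A", 6))
  expect_equal(all_a$specificity[all_a$group == "A"], 0)
  expect_true(is.na(evaluate_group_predictions(c("A", "A"), c("A", "B"))$sensitivity[2]))
})
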