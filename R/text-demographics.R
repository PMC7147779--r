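#' Lexicon-based text features and demographic inference
#'
#' The text layer is fully open: a category lexicon (term -> categories)
#' stands in for closed-vocabulary psycholinguistic dictionaries, and small
#' weighted lexica (term -> weight, optional intercept) drive continuous age
#' and signed gender scores. Proprietary summary composites (analytic
#' thinking, clout, authenticity, tone) have unpublished formulas and are
#' accepted only as precomputed optional columns, never re-derived.
#'
#' @name text_demographics
NULL

# emoticons are kept as verbatim tokens; everything else is lowercased and
# split on non-alphanumerics
EMOTICON_RE <- "[;:=8][-o^']?[)(\\[\\]dpDP/\\\\|]|<3|</3"

#' Tokenize text
#'
#' Lowercases, preserves common emoticons as single tokens, and splits the
#' remainder on non-alphanumeric characters.
#'
#' @param x character vector (concatenated before tokenization).
#' @return character vector of tokens.
#' @export
tokenize_text <- function(x) {
  txt <- tolower(paste(x, collapse = " "))
  emo <- regmatches(txt, gregexpr(EMOTICON_RE, txt, perl = TRUE))[[1]]
  txt <- gsub(EMOTICON_RE, " ", txt, perl = TRUE)
  words <- regmatches(txt, gregexpr("[a-z0-9']+", txt))[[1]]
  words <- gsub("^'+|'+$", "", words)
  c(words[nchar(words) > 0], emo)
}

#' Read a category lexicon (term,category CSV)
#'
#' @param path CSV with columns `term` and `category`; a term may appear on
#'   several rows (one per category).
#' @return data.frame of class `category_lexicon`.
#' @export
read_category_lexicon <- function(path) {
  lex <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("term", "category") %in% names(lex))) {
    stopf("category lexicon needs 'term' and 'category' columns")
  }
  lex$term <- tolower(lex$term)
  class(lex) <- c("category_lexicon", "data.frame")
  lex
}

#' Read a weighted lexicon (term,weight CSV)
#'
#' An optional row with term `_intercept` supplies the additive intercept.
#'
#' @param path CSV with columns `term` and `weight`.
#' @return data.frame of class `weighted_lexicon` with an `intercept` attribute.
#' @export
read_weighted_lexicon <- function(path) {
  lex <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("term", "weight") %in% names(lex))) {
    stopf("weighted lexicon needs 'term' and 'weight' columns")
  }
  if (any(!is.finite(lex$weight))) stopf("lexicon weights must be finite")
  lex$term <- tolower(lex$term)
  icpt <- lex$weight[lex$term == "_intercept"]
  lex <- lex[lex$term != "_intercept", , drop = FALSE]
  attr(lex, "intercept") <- if (length(icpt)) icpt[1] else 0
  class(lex) <- c("weighted_lexicon", "data.frame")
  lex
}

# bundled lexica shipped under inst/extdata
depscreen_lexicon <- function(name) {
  path <- system.file("extdata", paste0(name, ".csv"), package = "depscreen")
  if (path == "") path <- file.path("inst", "extdata", paste0(name, ".csv"))
  switch(name,
    category_lexicon = read_category_lexicon(path),
    depression_terms = tolower(utils::read.csv(path, stringsAsFactors = FALSE)$term),
    read_weighted_lexicon(path)
  )
}

#' Per-category token rates
#'
#' For each lexicon category, 100 x (matching tokens) / (total tokens), plus
#' `sixltr`, the percentage of tokens longer than six letters. An empty token
#' list yields all-zero rates with a `degenerate` attribute set.
#'
#' @param tokens character vector of (lowercased) tokens.
#' @param lexicon a `category_lexicon` (see [read_category_lexicon()]).
#' @return named numeric vector of percentages.
#' @export
category_rates <- function(tokens, lexicon) {
  cats <- sort(unique(lexicon$category))
  n <- length(tokens)
  rates <- vapply(cats, function(cc) {
    terms <- lexicon$term[lexicon$category == cc]
    if (n == 0) 0 else 100 * sum(tokens %in% terms) / n
  }, numeric(1))
  out <- c(rates, sixltr = if (n == 0) 0 else 100 * sum(nchar(tokens) > 6) / n)
  if (n == 0) attr(out, "degenerate") <- TRUE
  out
}

#' Screen-name similarity to a depression lexicon
#'
#' Minimum normalized Levenshtein distance between the cleaned screen name
#' (lowercased, digits and underscores stripped) and any lexicon term:
#' `min_t lev(name, t) / max(nchar(name), nchar(t))`, in \[0, 1\].
#'
#' @param screen_name character scalar.
#' @param terms character vector of depression-indicative terms (default:
#'   the bundled mini-lexicon).
#' @return scalar in \[0, 1\].
#' @export
screen_name_similarity <- function(screen_name, terms = depscreen_lexicon("depression_terms")) {
  if (length(terms) == 0) stopf("depression lexicon is empty")
  name <- gsub("[0-9_]+", "", tolower(screen_name))
  if (nchar(name) == 0) stopf("screen name '%s' is empty after cleaning", screen_name)
  d <- as.vector(utils::adist(name, tolower(terms)))
  min(d / pmax(nchar(name), nchar(terms)))
}

AGE_MIN <- 11
AGE_MAX <- 60

#' Extract a disclosed age from a profile description
#'
#' Applies three patterns in order: "I am X years old", "Born in X", and
#' "X years old", where X is an age or a 4-digit year. A year in
#' \[1900, collection_year - 11\] is treated as a birth year
#' (age = collection_year - year). Ages outside \[11, 60\] are rejected as
#' implausible. Absence is a value (`NA`), not an error.
#'
#' @param description raw description string.
#' @param collection_year calendar year the profile was collected.
#' @return integer age or `NA`.
#' @export
extract_age <- function(description, collection_year = 2017) {
  txt <- tolower(description)
  num_from <- function(pattern) {
    m <- regmatches(txt, regexpr(pattern, txt, perl = TRUE))
    if (length(m) == 0) return(NA_real_)
    as.numeric(regmatches(m, regexpr("[0-9]+", m)))
  }
  x <- num_from("\\bi\\s*(am|'m)\\s+[0-9]{1,4}\\s+years?\\s+old\\b")
  if (is.na(x)) x <- num_from("\\bborn\\s+in\\s+[0-9]{2,4}\\b")
  if (is.na(x)) x <- num_from("\\b[0-9]{1,4}\\s+years?\\s+old\\b")
  if (is.na(x)) return(NA_integer_)
  if (x >= 1900 && x <= collection_year - AGE_MIN) x <- collection_year - x
  if (x < AGE_MIN || x > AGE_MAX) return(NA_integer_)
  as.integer(x)
}

#' Weighted-lexicon demographic score
#'
#' The relative-frequency lexicon score
#' `score = sum_term weight(term) * freq(term, doc) / wordcount(doc)` plus the
#' lexicon intercept. For the age lexicon the score is a continuous age
#' estimate; for the gender lexicon the sign carries the prediction
#' (positive = female, the bundled lexicon's convention).
#'
#' @param tokens document tokens (see [tokenize_text()]); must be non-empty.
#' @param lexicon a `weighted_lexicon`.
#' @return numeric scalar.
#' @export
infer_demographic <- function(tokens, lexicon) {
  wc <- length(tokens)
  if (wc == 0) stopf("cannot score an empty document")
  freq <- table(tokens)
  idx <- match(lexicon$term, names(freq))
  hit <- !is.na(idx)
  score <- sum(lexicon$weight[hit] * as.numeric(freq[idx[hit]])) / wc
  score + attr(lexicon, "intercept")
}

AGE_BREAKS <- c(11, 19, 23, 34, 46, 60)

#' Assign an adult-development age group
#'
#' Left-closed, right-open bins \[11,19), \[19,23), \[23,34), \[34,46),
#' \[46,60) partitioning \[11, 60).
#'
#' @param age numeric vector of ages in \[11, 60).
#' @return factor of group labels.
#' @export
assign_age_group <- function(age) {
  if (any(is.na(age)) || any(age < AGE_MIN) || any(age >= AGE_MAX)) {
    stopf("age must lie in [%d, %d)", AGE_MIN, AGE_MAX)
  }
  labels <- paste0("[", AGE_BREAKS[-length(AGE_BREAKS)], ",", AGE_BREAKS[-1], ")")
  cut(age, breaks = AGE_BREAKS, right = FALSE, labels = labels)
}

#' One-vs-rest group prediction metrics
#'
#' Per group: sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy.
#' A group with zero positives has undefined sensitivity, reported `NA`.
#'
#' @param truth,predicted aligned label vectors (factors or characters).
#' @return data.frame with one row per group present in either vector.
#' @export
evaluate_group_predictions <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stopf("label vectors must align")
  groups <- sort(unique(c(as.character(truth), as.character(predicted))))
  out <- lapply(groups, function(gr) {
    tp <- sum(truth == gr & predicted == gr)
    fn <- sum(truth == gr & predicted != gr)
    fp <- sum(truth != gr & predicted == gr)
    tn <- sum(truth != gr & predicted != gr)
    data.frame(
      group = gr,
      sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
      specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
      accuracy = (tp + tn) / length(truth)
    )
  })
  do.call(rbind, out)
}
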