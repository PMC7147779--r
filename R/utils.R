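# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a base seed and a stage label
#'
#' The cohort generator runs several sub-generators (descriptions, images,
#' interactions, ...). Each draws from its own seeded stream so that one stage
#' can be regenerated without disturbing the others. Seeds stay below 2^31-1.
#'
#' @param seed integer base seed.
#' @param tag character stage label.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 8191) %% 2147483563L) + 1L
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  # discard the opening draws: freshly seeded Mersenne-Twister streams with
  # related seeds start out cross-correlated
  stats::runif(32)
  force(code)
}

# population variance / sd (n divisor): well-defined for a single pixel
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)

is_rate <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0 & x <= 1)
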