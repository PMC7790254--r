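#' Default item-to-trait key map
#'
#' Assigns the 15 items to the five traits in blocks of three (items 1-3
#' neuroticism, 4-6 extraversion, 7-9 openness, 10-12 agreeableness, 13-15
#' conscientiousness). The short inventory's actual item wording and keying
#' are instrument-specific, so the default direction (no reverse-keyed
#' items) is declaredly arbitrary; supply your own map for real data.
#'
#' @param reverse_keyed Integer item indices to mark as reverse-keyed.
#' @param likert_levels Number of response levels (used to flip reversed
#'   items as `levels + 1 - value`).
#' @return data.frame with columns `item`, `trait`, `reversed` and the
#'   attribute `likert_levels`.
#' @export
default_keymap <- function(reverse_keyed = integer(0), likert_levels = 7L) {
  km <- data.frame(
    item = 1:15,
    trait = rep(big_five_traits(), each = 3L),
    reversed = FALSE
  )
  km$reversed[reverse_keyed] <- TRUE
  attr(km, "likert_levels") <- as.integer(likert_levels)
  km
}

validate_keymap <- function(keymap) {
  if (!is.data.frame(keymap) ||
      !all(c("item", "trait", "reversed") %in% names(keymap)))
    stopf("keymap must be a data.frame with columns item, trait, reversed")
  if (!setequal(keymap$item, 1:15))
    stopf("keymap must cover exactly items 1..15")
  counts <- table(keymap$trait)
  if (!setequal(names(counts), big_five_traits()) || any(counts != 3L))
    stopf("keymap must assign exactly 3 items to each of the five traits")
  if (is.null(attr(keymap, "likert_levels")))
    attr(keymap, "likert_levels") <- 7L
  keymap
}

item_matrix_ <- function(items) {
  cols <- grep("^item_", names(items), value = TRUE)
  if (length(cols) != 15L)
    stopf("expected 15 item_* columns, found %d", length(cols))
  m <- as.matrix(items[, cols])
  storage.mode(m) <- "double"
  m
}

# Flip reverse-keyed items, return the keyed n x 15 matrix.
keyed_items_ <- function(items, keymap) {
  keymap <- validate_keymap(keymap)
  m <- item_matrix_(items)
  lev <- attr(keymap, "likert_levels")
  rev_idx <- keymap$item[keymap$reversed]
  if (length(rev_idx)) m[, rev_idx] <- (lev + 1) - m[, rev_idx]
  m
}

#' Score items to Big Five trait means
#'
#' Trait score = mean of the available keyed items of that trait
#' (reverse-keyed items flipped first). A person with one missing item on a
#' trait is scored on the remaining two; a trait with all three items
#' missing is missing.
#'
#' @param items data.frame with `person_id` and `item_01`..`item_15`.
#' @param keymap An item-to-trait key map, see [default_keymap()].
#' @return data.frame `person_id` plus five trait-score columns.
#' @export
score_traits <- function(items, keymap = default_keymap()) {
  m <- keyed_items_(items, keymap)
  keymap <- validate_keymap(keymap)
  scores <- sapply(big_five_traits(), function(tr) {
    idx <- keymap$item[keymap$trait == tr]
    rowMeans(m[, idx, drop = FALSE], na.rm = TRUE)
  })
  if (!is.matrix(scores))  # single-person input collapses to a vector
    scores <- matrix(scores, nrow = 1L,
                     dimnames = list(NULL, big_five_traits()))
  scores[is.nan(scores)] <- NA_real_
  out <- data.frame(person_id = items$person_id, scores)
  rownames(out) <- NULL
  out
}

# Mean over traits of the within-trait population variance (denominator 3)
# of the available items; traits with fewer than 2 available items are
# skipped. NA when no trait has a computable variance.
intradim_variance_ <- function(keyed, keymap) {
  vars <- sapply(big_five_traits(), function(tr) {
    idx <- keymap$item[keymap$trait == tr]
    x <- keyed[, idx, drop = FALSE]
    n_ok <- rowSums(!is.na(x))
    mu <- rowMeans(x, na.rm = TRUE)
    v <- rowMeans((x - mu)^2, na.rm = TRUE)
    v[n_ok < 2L] <- NA_real_
    v
  })
  if (!is.matrix(vars))
    vars <- matrix(vars, nrow = 1L)
  rowMeans(vars, na.rm = TRUE)
}

#' Apply the missing-answer and answer-variance exclusion rules
#'
#' A person is excluded when they have more than one missing item answer,
#' or when their intradimensional answer variance (mean over traits of the
#' within-trait variance of the trait's items) is strictly greater than
#' `multiplier` times the sample average of that statistic. The sample
#' average is computed over all persons with a computable variance,
#' *before* any exclusion.
#'
#' @param items data.frame with `person_id` and `item_01`..`item_15`.
#' @param keymap Item-to-trait key map.
#' @param multiplier Variance-rule multiplier (default 4).
#' @return data.frame of class `exclusion_report`: `person_id`,
#'   `n_missing`, `intradim_variance`, `excluded`, `reason`; attribute
#'   `sample_mean_variance`.
#' @export
apply_exclusions <- function(items, keymap = default_keymap(),
                             multiplier = 4) {
  keymap <- validate_keymap(keymap)
  keyed <- keyed_items_(items, keymap)
  n_missing <- rowSums(is.na(keyed))
  iv <- intradim_variance_(keyed, keymap)
  sample_mean <- mean(iv, na.rm = TRUE)
  miss_flag <- n_missing > 1L
  var_flag <- !is.na(iv) & iv > multiplier * sample_mean
  excluded <- miss_flag | var_flag
  if (all(excluded))
    stopf("all %d persons excluded: degenerate sample", nrow(items))
  reason <- rep(NA_character_, length(excluded))
  reason[miss_flag] <- "missing"
  reason[var_flag] <- "variance"
  reason[miss_flag & var_flag] <- "missing+variance"
  out <- data.frame(person_id = items$person_id, n_missing = n_missing,
                    intradim_variance = iv, excluded = excluded,
                    reason = reason)
  attr(out, "sample_mean_variance") <- sample_mean
  attr(out, "multiplier") <- multiplier
  class(out) <- c("exclusion_report", class(out))
  out
}

#' Z-standardize trait scores
#'
#' Standardizes each trait with its own sample moments, or with supplied
#' reference moments (used when projecting a later assessment wave into the
#' derivation wave's z-space). The moments actually used are attached so
#' the transform can be inverted.
#'
#' @param traits data.frame from [score_traits()] (or numeric matrix).
#' @param reference Optional moments: a list with numeric 5-vectors `mean`
#'   and `sd`, e.g. the `moments` attribute of a previous call.
#' @return Standardized object of the same shape, with attribute `moments`.
#' @export
zstandardize <- function(traits, reference = NULL) {
  z <- as_trait_matrix(traits)
  if (is.null(reference)) {
    mu <- colMeans(z, na.rm = TRUE)
    sd_ <- apply(z, 2L, stats::sd, na.rm = TRUE)
  } else {
    stopifnot(is.list(reference), !is.null(reference$mean),
              !is.null(reference$sd))
    mu <- reference$mean
    sd_ <- reference$sd
  }
  zero <- which(sd_ <= 0 | !is.finite(sd_))
  if (length(zero))
    stopf("zero standard deviation for trait(s): %s",
          paste(colnames(z)[zero], collapse = ", "))
  zs <- sweep(sweep(z, 2L, mu, "-"), 2L, sd_, "/")
  moments <- list(mean = mu, sd = sd_)
  if (is.data.frame(traits)) {
    out <- traits
    out[, colnames(z)] <- zs
  } else {
    out <- zs
  }
  attr(out, "moments") <- moments
  attr(out, "standardized") <- TRUE
  out
}

#' Invert a z-standardization
#'
#' @param z Standardized traits (matrix or data.frame).
#' @param moments Moments list (`mean`, `sd`); defaults to the `moments`
#'   attribute of `z`.
#' @return Raw-scale object of the same shape.
#' @export
unstandardize <- function(z, moments = attr(z, "moments")) {
  stopifnot(!is.null(moments))
  m <- as_trait_matrix(z)
  raw <- sweep(sweep(m, 2L, moments$sd, "*"), 2L, moments$mean, "+")
  if (is.data.frame(z)) {
    out <- z
    out[, colnames(m)] <- raw
    attr(out, "moments") <- NULL
    attr(out, "standardized") <- NULL
    out
  } else raw
}

#' One-call preprocessing: score, exclude, standardize
#'
#' @inheritParams apply_exclusions
#' @param reference Optional reference moments passed to [zstandardize()].
#' @return list with `z` (standardized trait data.frame of included,
#'   fully-scored persons), `traits` (raw scores, all persons),
#'   `exclusions` (the [apply_exclusions()] report).
#' @export
preprocess_items <- function(items, keymap = default_keymap(),
                             multiplier = 4, reference = NULL) {
  excl <- apply_exclusions(items, keymap, multiplier)
  traits <- score_traits(items, keymap)
  keep <- !excl$excluded & stats::complete.cases(traits)
  z <- zstandardize(traits[keep, , drop = FALSE], reference)
  list(z = z, traits = traits, exclusions = excl)
}
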