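#' Default planted prototype profiles
#'
#' Trait profiles of the five canonical personality prototypes, at a
#' configurable magnitude. These are synthetic stand-ins for
#' literature-derived profiles: the patterns follow the standard verbal
#' descriptions of the types — resilients combine low neuroticism with high
#' values on all other traits; overcontrollers high neuroticism with low
#' extraversion and openness; undercontrollers slightly elevated
#' neuroticism, slightly depressed extraversion and openness, and low
#' agreeableness and conscientiousness; reserveds below-average
#' neuroticism, extraversion and openness with high agreeableness and
#' conscientiousness; vulnerable-resilients elevated on every trait
#' including neuroticism — while the magnitude is a free parameter because
#' published type profiles vary from study to study. The default magnitude
#' (0.8 z) and the fractional entries are calibrated together so that the
#' planted mixture is recoverable by k-means at the generator's default
#' within-component spread while coarser merged solutions face genuinely
#' ambiguous merge choices, the regime in which split-half replication
#' discriminates between cluster counts; see the methods vignette.
#'
#' @param magnitude Absolute z-score of the full-strength entries
#'   (default 0.8); fractional entries scale proportionally.
#' @return A 5 x 5 numeric matrix, rows named by prototype, columns by trait
#'   in [big_five_traits()] order.
#' @export
default_prototype_means <- function(magnitude = 0.8) {
  stopifnot(is.numeric(magnitude), length(magnitude) == 1L, magnitude >= 0)
  m <- magnitude
  out <- m * rbind(
    resilient              = c(-1,     1,     1,     1,  1),
    overcontroller         = c( 1,    -1,    -1,     0,  0),
    undercontroller        = c( 0.25, -0.25, -0.25, -1, -1),
    reserved               = c(-0.5,  -1,    -1,     1,  1),
    `vulnerable-resilient` = c( 1,     1,     1,     1,  1)
  )
  colnames(out) <- big_five_traits()
  out
}

#' Default mixing proportions of the five planted prototypes
#'
#' Cluster share of the resilient, overcontroller, undercontroller, reserved
#' and vulnerable-resilient components (14.4, 17.3, 24.6, 22.5 and 21.2
#' percent respectively), matching the prototype prevalences reported for
#' the large German panel sample these defaults emulate.
#'
#' @return Named numeric 5-vector summing to 1.
#' @export
default_mixing_proportions <- function() {
  c(resilient = 0.144, overcontroller = 0.173, undercontroller = 0.246,
    reserved = 0.225, `vulnerable-resilient` = 0.212)
}

#' Configuration for the synthetic Big Five panel generator
#'
#' Bundles and validates every knob of the generator: a Gaussian mixture over
#' trait z-space with named prototype components, the trait-to-item mapping
#' noise, Likert discretization, reverse-keyed items, and response
#' pathologies (careless responders, missing answers).
#'
#' @param n_persons Number of persons to simulate.
#' @param prototype_means Matrix of component means (prototypes x 5 traits).
#' @param mixing_proportions Numeric vector of component weights, summing
#'   to 1, one per row of `prototype_means`.
#' @param within_sd Within-component standard deviation in trait z-space;
#'   scalar or one value per trait.
#' @param item_noise_sd Standard deviation of the Gaussian noise added to
#'   each item before rounding.
#' @param likert_levels Number of Likert response levels (default 7).
#' @param reverse_keyed Integer indices (in 1..15) of reverse-keyed items.
#' @param missing_rate Probability that a non-careless cell is set missing.
#' @param careless_rate Probability that a person answers all items
#'   uniformly at random.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_persons = 4000L,
                             prototype_means = default_prototype_means(),
                             mixing_proportions = default_mixing_proportions(),
                             within_sd = 0.5,
                             item_noise_sd = 0.5,
                             likert_levels = 7L,
                             reverse_keyed = integer(0),
                             missing_rate = 0,
                             careless_rate = 0,
                             seed = 1L) {
  stopifnot(is.numeric(n_persons), length(n_persons) == 1L, n_persons >= 1)
  prototype_means <- as.matrix(prototype_means)
  if (ncol(prototype_means) != 5L)
    stopf("prototype_means must have 5 trait columns, got %d",
          ncol(prototype_means))
  if (is.null(rownames(prototype_means)))
    rownames(prototype_means) <- paste0("component_", seq_len(nrow(prototype_means)))
  if (length(mixing_proportions) != nrow(prototype_means))
    stopf("need one mixing proportion per prototype (%d), got %d",
          nrow(prototype_means), length(mixing_proportions))
  if (any(mixing_proportions < 0))
    stopf("mixing proportions must be non-negative")
  if (abs(sum(mixing_proportions) - 1) > 1e-12)
    stopf("mixing proportions must sum to 1 (got %.15f)",
          sum(mixing_proportions))
  if (!length(within_sd) %in% c(1L, 5L) || any(within_sd < 0))
    stopf("within_sd must be a non-negative scalar or 5-vector")
  stopifnot(item_noise_sd >= 0, likert_levels >= 2)
  if (length(reverse_keyed) &&
      (any(reverse_keyed < 1) || any(reverse_keyed > 15)))
    stopf("reverse_keyed indices must lie in 1..15")
  for (r in c(missing_rate = missing_rate, careless_rate = careless_rate))
    if (r < 0 || r > 1) stopf("rates must lie in [0, 1]")
  structure(list(
    n_persons = as.integer(n_persons),
    prototype_means = prototype_means,
    mixing_proportions = as.numeric(mixing_proportions),
    within_sd = rep(as.numeric(within_sd), length.out = 5L),
    item_noise_sd = as.numeric(item_noise_sd),
    likert_levels = as.integer(likert_levels),
    reverse_keyed = as.integer(reverse_keyed),
    missing_rate = as.numeric(missing_rate),
    careless_rate = as.numeric(careless_rate),
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Map trait z-scores to the Likert scale: midpoint + z * (levels - 1) / 6,
# so that +/-3 z spans the full response range before rounding.
likert_rescale <- function(z, levels) {
  (levels + 1) / 2 + z * (levels - 1) / 6
}

#' Generate a synthetic Big Five item-response population
#'
#' Draws persons from the configured Gaussian mixture in trait z-space,
#' maps each trait to its three items (linear rescale to the Likert
#' midpoint/range, additive Gaussian item noise, reverse-key flip, round and
#' clip), and returns the item matrix together with the true component
#' labels. Response pathologies are *not* applied here; see
#' [inject_missing_and_careless()].
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_population` with elements
#'   `items` (data.frame `person_id`, `item_01`..`item_15`),
#'   `traits_true` (n x 5 matrix of latent trait z-scores),
#'   `true_labels` (integer components), `prototype` (component names) and
#'   `config`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_persons
  k <- nrow(config$prototype_means)
  with_seed_(config$seed, {
    comp <- sample.int(k, n, replace = TRUE, prob = config$mixing_proportions)
    traits <- config$prototype_means[comp, , drop = FALSE] +
      matrix(stats::rnorm(n * 5L), n, 5L) %*% diag(config$within_sd)
    colnames(traits) <- big_five_traits()
    # item j of trait t carries the trait value plus item-specific noise
    items <- matrix(NA_real_, n, 15L)
    for (t in 1:5) {
      for (j in 1:3) {
        col <- (t - 1L) * 3L + j
        items[, col] <- likert_rescale(traits[, t], config$likert_levels) +
          stats::rnorm(n, sd = config$item_noise_sd)
      }
    }
    if (length(config$reverse_keyed))
      items[, config$reverse_keyed] <-
        (config$likert_levels + 1) - items[, config$reverse_keyed]
    items <- pmin(pmax(round(items), 1L), config$likert_levels)
    storage.mode(items) <- "integer"
    df <- data.frame(person_id = sprintf("p%05d", seq_len(n)), items)
    names(df)[-1L] <- sprintf("item_%02d", 1:15)
    structure(list(items = df, traits_true = traits,
                   true_labels = as.integer(comp),
                   prototype = rownames(config$prototype_means)[comp],
                   config = config),
              class = "synthetic_population")
  })
}

#' Inject careless responders and MCAR missingness
#'
#' A `careless_rate` fraction of persons have all 15 answers replaced by
#' uniform draws over the Likert range (the mechanism that maximally
#' inflates within-trait answer variance); afterwards each cell of the
#' remaining (non-careless) persons is independently set missing with
#' probability `missing_rate`. Flags are recorded so tests can measure the
#' exclusion rules' sensitivity.
#'
#' @param pop A `synthetic_population` from [generate_population()], or a
#'   bare item data.frame.
#' @param config The [generator_config()]; defaults to `pop$config`.
#' @return The input object with pathologies applied; gains logical vectors
#'   `careless` (per person) and `missing_mask` (n x 15).
#' @export
inject_missing_and_careless <- function(pop, config = NULL) {
  if (inherits(pop, "synthetic_population")) {
    if (is.null(config)) config <- pop$config
    items <- pop$items
  } else {
    items <- pop
    stopifnot(!is.null(config))
  }
  stopifnot(inherits(config, "generator_config"))
  item_cols <- grep("^item_", names(items))
  n <- nrow(items)
  with_seed_(config$seed + 1L, {
    careless <- stats::runif(n) < config$careless_rate
    if (any(careless)) {
      repl <- matrix(sample.int(config$likert_levels,
                                sum(careless) * length(item_cols),
                                replace = TRUE),
                     nrow = sum(careless))
      items[careless, item_cols] <- repl
    }
    miss <- matrix(stats::runif(n * length(item_cols)) < config$missing_rate,
                   n, length(item_cols))
    miss[careless, ] <- FALSE
    for (j in seq_along(item_cols))
      items[miss[, j], item_cols[j]] <- NA_integer_
  })
  if (inherits(pop, "synthetic_population")) {
    pop$items <- items
    pop$careless <- careless
    pop$missing_mask <- miss
    pop
  } else {
    structure(items, careless = careless, missing_mask = miss)
  }
}

#' Specify a criterion variable by its target trait correlations
#'
#' A criterion is generated as a linear combination of the five trait
#' z-scores plus Gaussian noise, with coefficients solved so that the
#' *population* correlation of the criterion with each trait equals
#' `trait_correlations` under the empirical trait covariance. The implied
#' R-squared (`r' %*% solve(R) %*% r` with `R` the trait correlation
#' matrix) must not exceed 1, otherwise the target vector is infeasible.
#'
#' @param name Criterion name.
#' @param trait_correlations Numeric 5-vector of target correlations in
#'   (-1, 1), trait order as [big_five_traits()].
#' @return An object of class `criterion_spec`.
#' @export
criterion_spec <- function(name, trait_correlations) {
  stopifnot(is.character(name), length(name) == 1L,
            length(trait_correlations) == 5L)
  if (any(abs(trait_correlations) >= 1))
    stopf("target correlations must lie strictly inside (-1, 1)")
  structure(list(name = name,
                 trait_correlations = as.numeric(trait_correlations)),
            class = "criterion_spec")
}

#' Generate criterion variables with planted trait correlations
#'
#' @param traits Matrix or data.frame of z-scored trait values (n x 5).
#' @param specs A single [criterion_spec()] or a list of them.
#' @param seed Integer seed.
#' @return data.frame with `person_id` (when available) and one column per
#'   criterion; attribute `coefficients` holds the solved loadings.
#' @export
generate_criteria <- function(traits, specs, seed = 1L) {
  z <- as_trait_matrix(traits)
  stopifnot(ncol(z) == 5L)
  if (inherits(specs, "criterion_spec")) specs <- list(specs)
  R <- stats::cor(z)
  out <- vector("list", length(specs))
  coefs <- vector("list", length(specs))
  with_seed_(seed, {
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      stopifnot(inherits(sp, "criterion_spec"))
      b <- solve(R, sp$trait_correlations)
      r2 <- drop(crossprod(sp$trait_correlations, b))
      if (r2 > 1 + 1e-12)
        stopf("criterion '%s': implied R-squared %.3f exceeds 1 (infeasible)",
              sp$name, r2)
      noise_sd <- sqrt(max(0, 1 - r2))
      # scale() so loadings apply to unit-variance traits even if the caller
      # passed raw z-scores whose SDs deviate slightly from 1
      y <- drop(scale(z) %*% b) + stats::rnorm(nrow(z), sd = noise_sd)
      out[[i]] <- y
      coefs[[i]] <- b
    }
  })
  names(out) <- vapply(specs, `[[`, "", "name")
  df <- as.data.frame(out, check.names = FALSE)
  if (is.data.frame(traits) && "person_id" %in% names(traits))
    df <- cbind(person_id = traits$person_id, df)
  else if (!is.null(rownames(z)))
    df <- cbind(person_id = rownames(z), df)
  attr(df, "coefficients") <- stats::setNames(coefs, names(out))
  df
}

#' Write / read the generator's delimited-text interface
#'
#' `write_item_csv` stores the item table as plain CSV (missing cells
#' empty) plus a JSON sidecar with the true labels and the configuration;
#' `read_item_csv` reads such a table back; `read_generator_config` builds a
#' [generator_config()] from a YAML file whose keys mirror the constructor
#' arguments.
#'
#' @param pop A `synthetic_population`.
#' @param path CSV output path (sidecar written next to it as
#'   `<path>.meta.json`).
#' @return `write_item_csv` returns `path` invisibly; `read_item_csv` a
#'   data.frame; `read_generator_config` a `generator_config`.
#' @export
write_item_csv <- function(pop, path) {
  stopifnot(inherits(pop, "synthetic_population"))
  utils::write.csv(pop$items, path, row.names = FALSE, na = "")
  meta <- list(true_labels = pop$true_labels, prototype = pop$prototype,
               config = unclass(pop$config))
  meta$config$prototype_means <- as.data.frame(pop$config$prototype_means)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_item_csv
#' @export
read_item_csv <- function(path) {
  utils::read.csv(path, na.strings = c("", "NA"))
}

#' @rdname write_item_csv
#' @param yaml_path Path to a YAML generator configuration.
#' @export
read_generator_config <- function(yaml_path) {
  y <- yaml::read_yaml(yaml_path)
  if (!is.null(y$prototype_means)) {
    pm <- do.call(rbind, lapply(y$prototype_means, as.numeric))
    rownames(pm) <- names(y$prototype_means)
    colnames(pm) <- big_five_traits()
    y$prototype_means <- pm
  }
  if (!is.null(y$mixing_proportions))
    y$mixing_proportions <- unlist(y$mixing_proportions)
  do.call(generator_config, y)
}
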