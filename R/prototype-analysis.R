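#' Profile similarity D between two trait profiles
#'
#' Cronbach-Gleser profile distance: the Euclidean distance between two
#' z-score profiles, `sqrt(sum((a - b)^2))`. Zero if and only if the
#' profiles coincide.
#'
#' @param a,b Numeric 5-vectors (trait order as [big_five_traits()]).
#' @return Non-negative scalar.
#' @export
profile_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (anyNA(a) || anyNA(b))
    stopf("profile distance requires complete profiles")
  sqrt(sum((a - b)^2))
}

#' All pairwise profile distances between two profile matrices
#'
#' @param A,B Numeric matrices with one profile per row and the same
#'   number of trait columns.
#' @return `nrow(A)` x `nrow(B)` distance matrix.
#' @export
profile_distance_matrix <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(ncol(A) == ncol(B))
  if (anyNA(A) || anyNA(B))
    stopf("profile distance requires complete profiles")
  # direct differences (not the quadratic expansion) so identical profiles
  # give exact zeros
  out <- matrix(0, nrow(A), nrow(B),
                dimnames = list(rownames(A), rownames(B)))
  for (j in seq_len(nrow(B)))
    out[, j] <- sqrt(rowSums(sweep(A, 2L, B[j, ])^2))
  out
}

#' Default reference prototype table
#'
#' Five canonical personality-type profiles (resilient, overcontroller,
#' undercontroller, reserved, vulnerable-resilient) as sign-pattern z-score
#' profiles at magnitude 0.6. These are synthetic stand-ins marked
#' non-canonical: published literature profiles are not reproduced here, so
#' users wishing to label clusters against the literature should supply
#' their own table via [read_reference_prototypes()].
#'
#' @param magnitude Absolute z-score of the non-zero entries.
#' @return Matrix prototypes x 5 traits with a `provenance` attribute.
#' @export
reference_prototypes <- function(magnitude = 0.6) {
  out <- default_prototype_means(magnitude)
  attr(out, "provenance") <-
    paste("synthetic sign-pattern profiles derived from standard verbal",
          "type descriptions; magnitudes arbitrary, not literature values")
  out
}

#' Read a reference prototype table from CSV
#'
#' Expected columns: `prototype`, then the five traits in
#' [big_five_traits()] order.
#'
#' @param path CSV path.
#' @return Matrix prototypes x 5 traits.
#' @export
read_reference_prototypes <- function(path) {
  df <- utils::read.csv(path)
  need <- c("prototype", big_five_traits())
  if (!all(need %in% names(df)))
    stopf("reference table must have columns: %s",
          paste(need, collapse = ", "))
  m <- as.matrix(df[, big_five_traits()])
  rownames(m) <- df$prototype
  if (anyNA(m)) stopf("reference table contains missing values")
  if (anyDuplicated(rownames(m))) stopf("prototype names must be unique")
  if (nrow(m) < 2L) stopf("need at least 2 reference prototypes")
  m
}

#' Label cluster centers against reference prototypes
#'
#' Each cluster center is named after its nearest reference prototype in
#' 5-dimensional z-space (profile-similarity D). With
#' `one_to_one = TRUE` (default) the labeling is the optimal one-to-one
#' assignment minimizing total D, and any cluster whose independently
#' nearest prototype differs from its assigned one is flagged in
#' `conflicts`. Exact ties on the nearest prototype are resolved toward the
#' lexicographically first name and reported.
#'
#' @param centers k x 5 matrix of cluster mean z-profiles.
#' @param reference Reference prototype matrix (see
#'   [reference_prototypes()]).
#' @param one_to_one Require each prototype name to be used at most once.
#' @return data.frame with `cluster`, `prototype`, `D`, `nearest`,
#'   `nearest_D`; attribute `conflicts`.
#' @export
label_prototypes <- function(centers, reference = reference_prototypes(),
                             one_to_one = TRUE) {
  centers <- as.matrix(centers)
  if (is.null(reference) || !nrow(reference))
    stopf("empty reference prototype table")
  # lexicographic name order makes tie-breaking deterministic
  reference <- reference[order(rownames(reference)), , drop = FALSE]
  D <- profile_distance_matrix(centers, reference)
  nearest_idx <- max.col(-D, ties.method = "first")
  ties <- vapply(seq_len(nrow(D)), function(i)
    sum(abs(D[i, ] - D[i, nearest_idx[i]]) <= 1e-12) > 1L, TRUE)
  if (one_to_one) {
    if (nrow(centers) > nrow(reference))
      stopf("more clusters (%d) than reference prototypes (%d); %s",
            nrow(centers), nrow(reference),
            "use one_to_one = FALSE or extend the reference table")
    pad <- cbind(D, matrix(max(D) + 1, nrow(D),
                           max(0, nrow(D) - ncol(D))))
    assignment <- as.integer(clue::solve_LSAP(pad))
    assigned <- pmin(assignment, ncol(D))
  } else {
    assigned <- nearest_idx
  }
  out <- data.frame(
    cluster = seq_len(nrow(centers)),
    prototype = rownames(reference)[assigned],
    D = D[cbind(seq_len(nrow(D)), assigned)],
    nearest = rownames(reference)[nearest_idx],
    nearest_D = D[cbind(seq_len(nrow(D)), nearest_idx)])
  conflicts <- which(out$prototype != out$nearest | ties)
  attr(out, "conflicts") <- conflicts
  attr(out, "tied") <- which(ties)
  out
}

#' Person-level similarity to every prototype
#'
#' Computes the profile-similarity D of every person's trait z-profile to
#' every prototype, and a monotone-decreasing "inverse distance" similarity
#' used as a continuous type-membership measure: the default is the negated
#' distance `-D` (which preserves all correlational structure up to sign),
#' with `1 / (1 + D)` available as an alternative.
#'
#' @param z Trait z-score matrix or data.frame (same z-space as the
#'   prototypes).
#' @param prototypes Matrix prototypes x 5 (e.g. labeled cluster centers).
#' @param transform `"negate"` (default) or `"inverse"`.
#' @return list of class `similarity_profile` with matrices `D` and
#'   `similarity` (persons x prototypes), the `transform` used, and
#'   `incomplete` (persons with missing traits, excluded row-wise as NA).
#' @export
participant_similarity <- function(z, prototypes,
                                   transform = c("negate", "inverse")) {
  transform <- match.arg(transform)
  m <- as_trait_matrix(z)
  prototypes <- as.matrix(prototypes)
  if (is.null(rownames(prototypes)))
    rownames(prototypes) <- paste0("prototype_", seq_len(nrow(prototypes)))
  incomplete <- which(!stats::complete.cases(m))
  D <- matrix(NA_real_, nrow(m), nrow(prototypes),
              dimnames = list(rownames(m), rownames(prototypes)))
  ok <- setdiff(seq_len(nrow(m)), incomplete)
  D[ok, ] <- profile_distance_matrix(m[ok, , drop = FALSE],
                                     as.matrix(prototypes))
  sim <- switch(transform, negate = -D, inverse = 1 / (1 + D))
  structure(list(D = D, similarity = sim, transform = transform,
                 incomplete = incomplete),
            class = "similarity_profile")
}

cor_with_p_ <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(c(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x[ok], y[ok])
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  c(r = r, p = p, n = n)
}

#' Predictive-validity correlation tables
#'
#' Pairwise-complete Pearson correlations of each criterion variable with
#' (a) the similarity to each prototype and (b) each raw trait z-score,
#' with two-sided p-values and a significance flag at the chosen level.
#'
#' @param similarity A [participant_similarity()] object (or a numeric
#'   persons x prototypes similarity matrix).
#' @param traits Trait z-score matrix or data.frame.
#' @param criteria data.frame of criterion variables (non-numeric columns
#'   such as `person_id` are ignored); rows must correspond to the same
#'   persons as `similarity` and `traits`.
#' @param alpha Flagging level (default 0.001).
#' @return list of class `predictive_validity` with data.frames
#'   `by_prototype` and `by_trait` (long format: criterion, target, r, p,
#'   n, significant).
#' @export
predictive_validity <- function(similarity, traits, criteria,
                                alpha = 0.001) {
  sim <- if (inherits(similarity, "similarity_profile"))
    similarity$similarity else as.matrix(similarity)
  z <- as_trait_matrix(traits)
  crit <- criteria[, vapply(criteria, is.numeric, TRUE), drop = FALSE]
  stopifnot(nrow(sim) == nrow(z), nrow(z) == nrow(crit))
  if (nrow(z) < 30L)
    stopf("need at least 30 overlapping persons, got %d", nrow(z))
  long <- function(targets) {
    rows <- expand.grid(criterion = names(crit),
                        target = colnames(targets),
                        stringsAsFactors = FALSE)
    res <- t(mapply(function(cr, tg)
      cor_with_p_(crit[[cr]], targets[, tg]),
      rows$criterion, rows$target))
    out <- cbind(rows, as.data.frame(res))
    out$significant <- !is.na(out$p) & out$p <= alpha
    rownames(out) <- NULL
    out
  }
  structure(list(by_prototype = long(sim), by_trait = long(z),
                 alpha = alpha),
            class = "predictive_validity")
}

#' Write predictive-validity tables as CSV
#'
#' Emits one CSV per table in criterion x target layout; cells whose
#' p-value exceeds the flagging level are left blank, mirroring the
#' convention of reporting only correlations significant at that level.
#'
#' @param pv A [predictive_validity()] object.
#' @param path_prototype,path_trait Output CSV paths.
#' @param blank_nonsignificant Blank cells with `p > alpha` (default TRUE).
#' @return Invisibly, the two paths.
#' @export
write_predictive_validity <- function(pv, path_prototype, path_trait,
                                      blank_nonsignificant = TRUE) {
  widen <- function(df) {
    vals <- df
    if (blank_nonsignificant) vals$r[!vals$significant] <- NA_real_
    wide <- stats::reshape(vals[, c("criterion", "target", "r")],
                           direction = "wide", idvar = "criterion",
                           timevar = "target")
    names(wide) <- sub("^r\\.", "", names(wide))
    wide
  }
  utils::write.csv(widen(pv$by_prototype), path_prototype,
                   row.names = FALSE, na = "")
  utils::write.csv(widen(pv$by_trait), path_trait, row.names = FALSE,
                   na = "")
  invisible(c(path_prototype, path_trait))
}

#' Per-cluster trait profiles and membership proportions
#'
#' @param z Trait z-score matrix or data.frame.
#' @param partition Integer cluster labels.
#' @param groups Optional data.frame of pass-through grouping variables
#'   (e.g. demographics) summarized per cluster for external reporting.
#' @return list with `centers` (k x 5 trait means), `sizes`,
#'   `proportions`, and optionally `groups` (split by cluster).
#' @export
cluster_profiles <- function(z, partition, groups = NULL) {
  m <- as_trait_matrix(z)
  partition <- as.integer(partition)
  stopifnot(length(partition) == nrow(m))
  k <- max(partition)
  sizes <- tabulate(partition, k)
  if (any(sizes == 0L)) stopf("empty cluster in partition")
  centers <- cluster_centers_(m, partition, k)
  out <- list(centers = centers, sizes = sizes,
              proportions = sizes / length(partition))
  if (!is.null(groups))
    out$groups <- split(groups, partition)
  out
}
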