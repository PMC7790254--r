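#' @name validity_indices
#' @title Internal cluster validity indices
#'
#' @description
#' Exact implementations of the distance-based internal validity battery:
#' C-index, Baker-Hubert Gamma and G+, generalized Dunn index GDI31,
#' point-biserial correlation, mean silhouette width, S_Dbw, and a
#' classification-likelihood AIC/BIC for hard partitions. All indices use
#' Euclidean distance on the supplied profile space. Each function accepts
#' either a raw data matrix or a precomputed `dist` object.
#'
#' The optimization direction of every index (whether smaller or larger
#' values indicate a better partition) is available from
#' [index_directions()].
NULL

#' Optimization directions of all validity indices
#'
#' @return Named character vector, `"min"` or `"max"` per index.
#' @export
index_directions <- function() {
  c(c_index = "min", gdi31 = "max", gamma = "max", g_plus = "min",
    point_biserial = "max", silhouette = "max", s_dbw = "min",
    aic = "min", bic = "min",
    kappa = "max", rand = "max", adjusted_rand = "max")
}

as_dist_ <- function(data) {
  if (inherits(data, "dist")) data else stats::dist(as_trait_matrix(data))
}

# distance values + within-pair indicator, in stats::dist pair order
pair_setup_ <- function(data, partition) {
  d <- as_dist_(data)
  n <- attr(d, "Size")
  stopifnot(length(partition) == n)
  within <- as.vector(stats::dist(as.numeric(partition))) == 0
  list(d = as.vector(d), within = within, n = n)
}

#' Within/between pair-distance comparison counts
#'
#' Compares every within-cluster pair distance against every
#' between-cluster pair distance: `s_plus` counts comparisons where the
#' within distance is strictly smaller, `s_minus` where it is strictly
#' larger; ties count in neither. Computed by sorting rather than the
#' O(n_w * n_b) double loop, but exactly equivalent to it.
#'
#' @param data Numeric matrix or `dist` object.
#' @param partition Integer cluster labels.
#' @return Object of class `pair_counts`: list with `s_plus`, `s_minus`,
#'   `n_w`, `n_b`, `n_t`.
#' @export
pair_counts <- function(data, partition) {
  ps <- pair_setup_(data, partition)
  dw <- ps$d[ps$within]
  db <- sort(ps$d[!ps$within])
  n_w <- length(dw)
  n_b <- length(db)
  stopifnot(ps$n >= 2)
  # counts of between distances <= / < each within distance
  n_le <- as.numeric(findInterval(dw, db))
  n_lt <- as.numeric(findInterval(dw, db, left.open = TRUE))
  structure(list(s_plus = sum(n_b - n_le), s_minus = sum(n_lt),
                 n_w = as.numeric(n_w), n_b = as.numeric(n_b),
                 n_t = as.numeric(n_w + n_b)),
            class = "pair_counts")
}

#' Baker-Hubert Gamma and G+ indices
#'
#' `gamma = (s_plus - s_minus) / (s_plus + s_minus)` (larger is better);
#' `g_plus = 2 * s_minus / (n_t * (n_t - 1))` (smaller is better). With all
#' comparisons tied, gamma is undefined and reported as `NA`.
#'
#' @param pc A [pair_counts()] object (or data for which to compute one
#'   with `partition`).
#' @param partition Cluster labels, when `pc` is raw data.
#' @return list with `gamma` and `g_plus`.
#' @export
gamma_gplus <- function(pc, partition = NULL) {
  if (!inherits(pc, "pair_counts")) pc <- pair_counts(pc, partition)
  denom <- pc$s_plus + pc$s_minus
  gamma <- if (denom > 0) (pc$s_plus - pc$s_minus) / denom else NA_real_
  g_plus <- 2 * pc$s_minus / (pc$n_t * (pc$n_t - 1))
  list(gamma = gamma, g_plus = g_plus)
}

#' C-index
#'
#' `(S - S_min) / (S_max - S_min)`, where `S` is the sum of within-cluster
#' pair distances and `S_min`/`S_max` are the sums of the `n_w` smallest /
#' largest pairwise distances overall. Ranges in `[0, 1]`, smaller is
#' better. When every pairwise distance is equal the index is defined as 0.
#'
#' @inheritParams pair_counts
#' @return Numeric scalar.
#' @export
c_index <- function(data, partition) {
  ps <- pair_setup_(data, partition)
  dw <- ps$d[ps$within]
  n_w <- length(dw)
  stopifnot(n_w >= 1)
  d_sorted <- sort(ps$d)
  s <- sum(dw)
  s_min <- sum(d_sorted[seq_len(n_w)])
  s_max <- sum(d_sorted[seq.int(length(d_sorted) - n_w + 1L,
                                length(d_sorted))])
  if (s_max == s_min) return(0)
  (s - s_min) / (s_max - s_min)
}

#' Generalized Dunn index GDI31
#'
#' Ratio of the minimum (over cluster pairs) mean between-cluster point
#' distance to the maximum (over clusters) intra-cluster diameter. Larger
#' is better. Singleton clusters have diameter 0; if *all* clusters are
#' singletons the index is undefined (`NA`).
#'
#' @inheritParams pair_counts
#' @return Numeric scalar (or `NA`).
#' @export
gdi31 <- function(data, partition) {
  d <- as.matrix(as_dist_(data))
  partition <- as.integer(factor(partition))
  k <- max(partition)
  stopifnot(k >= 2)
  idx <- split(seq_along(partition), partition)
  diam <- vapply(idx, function(ii) {
    if (length(ii) < 2L) 0 else max(d[ii, ii])
  }, 0)
  if (max(diam) == 0) return(NA_real_)
  sep <- Inf
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    sep <- min(sep, mean(d[idx[[i]], idx[[j]]]))
  }
  sep / max(diam)
}

#' Point-biserial index
#'
#' Pearson correlation between the vector of pairwise distances and the
#' between-cluster indicator, computed in closed form:
#' `(mean_between - mean_within) * sqrt(n_w * n_b / n_t^2) / sd(d)` with the
#' population standard deviation of all pairwise distances. Larger is
#' better. Undefined (`NA`) when the distances have zero variance.
#'
#' @inheritParams pair_counts
#' @return Numeric scalar (or `NA`).
#' @export
point_biserial <- function(data, partition) {
  ps <- pair_setup_(data, partition)
  dw <- ps$d[ps$within]
  db <- ps$d[!ps$within]
  stopifnot(length(dw) >= 1, length(db) >= 1)
  n_t <- as.numeric(length(ps$d))
  sd_pop <- sqrt(mean((ps$d - mean(ps$d))^2))
  if (sd_pop == 0) return(NA_real_)
  (mean(db) - mean(dw)) *
    sqrt(as.numeric(length(dw)) * as.numeric(length(db)) / n_t^2) / sd_pop
}

#' Mean silhouette width
#'
#' For each point, `s = (b - a) / max(a, b)` with `a` the mean distance to
#' its own cluster (excluding itself) and `b` the smallest mean distance to
#' another cluster; singleton points score 0. Returns the mean over all
#' points. Larger is better.
#'
#' @inheritParams pair_counts
#' @return Numeric scalar in `[-1, 1]`.
#' @export
silhouette_mean <- function(data, partition) {
  d <- as.matrix(as_dist_(data))
  partition <- as.integer(factor(partition))
  k <- max(partition)
  stopifnot(k >= 2)
  n <- nrow(d)
  sizes <- tabulate(partition, k)
  # mean distance of every point to every cluster
  sums <- vapply(seq_len(k), function(j)
    rowSums(d[, partition == j, drop = FALSE]), numeric(n))
  own <- cbind(seq_len(n), partition)
  a <- sums[own] / pmax(sizes[partition] - 1L, 1L)
  means <- sweep(sums, 2L, sizes, "/")
  means[own] <- Inf
  b <- apply(means, 1L, min)
  s <- (b - a) / pmax(a, b)
  s[!is.finite(s)] <- 0
  s[sizes[partition] == 1L] <- 0
  mean(s)
}

#' S_Dbw index
#'
#' Halkidi-Vazirgiannis validity index: average normalized cluster scatter
#' plus an inter-cluster density term evaluated at cluster-pair midpoints,
#' with the standard average-standard-deviation neighborhood radius.
#' Smaller is better. Undefined (`NA`) when the total scatter is zero.
#'
#' @param data Numeric data matrix (not a `dist`; the index needs
#'   coordinates).
#' @param partition Integer cluster labels.
#' @return Numeric scalar (or `NA`).
#' @export
s_dbw <- function(data, partition) {
  x <- as_trait_matrix(data)
  partition <- as.integer(factor(partition))
  k <- max(partition)
  stopifnot(k >= 2)
  pop_var <- function(m) colMeans(sweep(m, 2L, colMeans(m))^2)
  sigma_all <- sqrt(sum(pop_var(x)^2))
  if (sigma_all == 0) return(NA_real_)
  idx <- split(seq_len(nrow(x)), partition)
  centers <- cluster_centers_(x, partition, k)
  sigma_cl <- vapply(idx, function(ii)
    sqrt(sum(pop_var(x[ii, , drop = FALSE])^2)), 0)
  scat <- mean(sigma_cl) / sigma_all
  stdev <- sqrt(sum(sigma_cl)) / k
  dens <- function(points, u) {
    dd <- sqrt(rowSums(sweep(points, 2L, u)^2))
    sum(dd <= stdev)
  }
  total <- 0
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    pts <- x[c(idx[[i]], idx[[j]]), , drop = FALSE]
    d_i <- dens(pts, centers[i, ])
    d_j <- dens(pts, centers[j, ])
    d_u <- dens(pts, (centers[i, ] + centers[j, ]) / 2)
    m <- max(d_i, d_j)
    total <- total + if (m > 0) d_u / m else 0
  }
  dens_bw <- 2 * total / (k * (k - 1L))
  scat + dens_bw
}

#' AIC and BIC of a cluster solution
#'
#' For latent-profile solutions the mixture log-likelihood and parameter
#' count of the fitted covariance family are used directly. For hard
#' partitions (`ward_kmeans`, `spectral`) a classification likelihood is
#' evaluated: Gaussian components at the cluster means with a shared
#' spherical variance equal to the pooled within-cluster variance, and
#' `p = d*k + 1 + (k - 1)` parameters (means, variance, mixing
#' proportions).
#'
#' @param data Numeric data matrix (ignored for lpa solutions, which carry
#'   their own likelihood).
#' @param solution A [cluster_solution()].
#' @return list with `aic`, `bic`, `loglik`, `df`.
#' @export
partition_aic_bic <- function(data, solution) {
  stopifnot(inherits(solution, "cluster_solution"))
  n <- length(solution$labels)
  if (solution$algorithm == "lpa" &&
      !is.null(solution$fit_extras$loglik)) {
    ll <- solution$fit_extras$loglik
    p <- solution$fit_extras$df
  } else {
    x <- as_trait_matrix(data)
    stopifnot(nrow(x) == n)
    k <- solution$k
    d <- ncol(x)
    resid2 <- rowSums((x - solution$centers[solution$labels, , drop = FALSE])^2)
    sigma2 <- sum(resid2) / (n * d)
    if (sigma2 <= 0)
      stopf("pooled within-cluster variance is zero (degenerate partition)")
    prop <- solution$sizes / n
    ll <- sum(log(prop[solution$labels])) -
      n * d / 2 * log(2 * pi * sigma2) - sum(resid2) / (2 * sigma2)
    p <- d * k + 1 + (k - 1)
  }
  list(aic = -2 * ll + 2 * p, bic = -2 * ll + p * log(n),
       loglik = ll, df = p)
}

#' Optimal one-to-one alignment of two partitions' labels
#'
#' Solves the linear assignment problem on the contingency table (padded
#' square when the cluster counts differ) to find the label mapping that
#' maximizes total agreement.
#'
#' @param a,b Integer label vectors over the same persons.
#' @return list with `b_to_a` (integer vector: `b_to_a[j]` is the a-label
#'   matched to b-label `j`; values above `max(a)` are padded labels),
#'   `agreement` (matched count), and `b_aligned` (b relabeled into a's
#'   label space).
#' @export
align_labels <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.integer(a); b <- as.integer(b)
  ka <- max(a); kb <- max(b)
  k <- max(ka, kb)
  tab <- matrix(0, k, k)
  tt <- table(factor(a, levels = seq_len(k)), factor(b, levels = seq_len(k)))
  tab[] <- as.numeric(tt)
  assignment <- clue::solve_LSAP(tab, maximum = TRUE)
  b_to_a <- integer(k)
  b_to_a[as.integer(assignment)] <- seq_len(k)  # column j -> row
  agreement <- sum(tab[cbind(seq_len(k), as.integer(assignment))])
  list(b_to_a = b_to_a, agreement = as.integer(agreement),
       b_aligned = b_to_a[b])
}

#' Cohen's kappa between two partitions
#'
#' `(p_o - p_e) / (1 - p_e)` with expected agreement from the marginal
#' products. Partitions from independent clusterings carry arbitrary label
#' identities, so set `align = TRUE` to first apply the optimal-assignment
#' alignment of [align_labels()]; leave it `FALSE` when the labels already
#' share provenance (e.g. classifier predictions trained on the reference
#' labels).
#'
#' @param a,b Integer label vectors over the same persons.
#' @param align Apply optimal label alignment first (default `FALSE`).
#' @return Numeric scalar in `[-1, 1]`.
#' @export
cohen_kappa <- function(a, b, align = FALSE) {
  stopifnot(length(a) == length(b))
  if (align) b <- align_labels(a, b)$b_aligned
  lev <- sort(unique(c(a, b)))
  ta <- factor(a, levels = lev)
  tb <- factor(b, levels = lev)
  tab <- table(ta, tb) / length(a)
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (1 - p_e < .Machine$double.eps) {
    # single shared category: kappa degenerates; define by identity
    return(if (all(a == b)) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

contingency_pairs_ <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) sum(x * (x - 1) / 2)
  list(n_pairs = n * (n - 1) / 2, nij = ch2(tab),
       ai = ch2(rowSums(tab)), bj = ch2(colSums(tab)))
}

#' Rand index
#'
#' Fraction of person pairs on which two partitions agree (both together or
#' both apart). Label-permutation invariant.
#'
#' @param a,b Integer label vectors over the same persons (`n >= 2`).
#' @return Numeric scalar in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2) stopf("rand_index requires n >= 2")
  cp <- contingency_pairs_(a, b)
  (cp$n_pairs - cp$ai - cp$bj + 2 * cp$nij) / cp$n_pairs
}

#' Hubert-Arabie adjusted Rand index
#'
#' Chance-corrected pair agreement; 0 expected under independent random
#' labelings, 1 for identical partitions, negative for worse-than-chance
#' agreement. When the correction denominator is zero (e.g. both
#' partitions are a single cluster) the index is defined as 1 for
#' identical partitions and 0 otherwise.
#'
#' @inheritParams rand_index
#' @return Numeric scalar `<= 1`.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  cp <- contingency_pairs_(a, b)
  expected <- cp$ai * cp$bj / cp$n_pairs
  denom <- (cp$ai + cp$bj) / 2 - expected
  if (abs(denom) < .Machine$double.eps) {
    return(if (identical(as.integer(factor(a)), as.integer(factor(b)))) 1 else 0)
  }
  (cp$nij - expected) / denom
}

#' Compute the full validity battery for one or more solutions
#'
#' Evaluates the nine internal indices (and, when a comparison partition is
#' supplied, the three external agreement criteria) for each solution.
#'
#' @param solutions A [cluster_solution()] or list of them, all fit on the
#'   same data.
#' @param data Optional data matrix / `dist`; defaults to the solutions'
#'   own stored data.
#' @param comparison Optional partition to compare each solution against
#'   (kappa computed after optimal alignment).
#' @return data.frame of class `validity_report`: one row per solution,
#'   columns `algorithm`, `k` and one per index; attribute `directions`.
#' @export
validity_report <- function(solutions, data = NULL, comparison = NULL) {
  if (inherits(solutions, "cluster_solution")) solutions <- list(solutions)
  rows <- lapply(solutions, function(sol) {
    stopifnot(inherits(sol, "cluster_solution"))
    x <- if (is.null(data)) sol$data else data
    d <- as_dist_(x)
    lab <- sol$labels
    pc <- pair_counts(d, lab)
    gg <- gamma_gplus(pc)
    ab <- partition_aic_bic(x, sol)
    row <- data.frame(
      algorithm = sol$algorithm, k = sol$k,
      c_index = c_index(d, lab),
      gdi31 = gdi31(d, lab),
      gamma = gg$gamma, g_plus = gg$g_plus,
      point_biserial = point_biserial(d, lab),
      silhouette = silhouette_mean(d, lab),
      s_dbw = s_dbw(x, lab),
      aic = ab$aic, bic = ab$bic
    )
    if (!is.null(comparison)) {
      row$kappa <- cohen_kappa(comparison, lab, align = TRUE)
      row$rand <- rand_index(comparison, lab)
      row$adjusted_rand <- adjusted_rand(comparison, lab)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "directions") <- index_directions()[
    intersect(names(index_directions()), names(out))]
  class(out) <- c("validity_report", class(out))
  out
}

#' Serialize a validity report
#'
#' Writes the report as CSV in indices-by-solutions layout plus a JSON
#' variant carrying the optimization directions.
#'
#' @param report A [validity_report()].
#' @param path CSV path (JSON written as `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_validity_report <- function(report, path) {
  idx_cols <- setdiff(names(report), c("algorithm", "k"))
  wide <- t(as.matrix(report[, idx_cols]))
  colnames(wide) <- sprintf("%s_k%d", report$algorithm, report$k)
  out <- data.frame(index = rownames(wide),
                    direction = unname(attr(report, "directions")[rownames(wide)]),
                    wide, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  jsonlite::write_json(
    list(directions = as.list(attr(report, "directions")),
         solutions = report),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
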