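#' Construct / validate a cluster solution
#'
#' Uniform container returned by all three engines. Centers are always
#' recomputed from the data, never trusted from the fitting backend, and
#' every cluster must be non-empty.
#'
#' @param algorithm One of `"ward_kmeans"`, `"lpa"`, `"spectral"`.
#' @param k Number of clusters.
#' @param labels Integer vector in `1..k`, one per person.
#' @param data Numeric matrix the solution was fit on (rows = persons).
#' @param fit_extras Algorithm-specific list (log-likelihood and family for
#'   lpa, inertia for ward_kmeans, embedding dimension for spectral).
#' @return Object of class `cluster_solution` with fields `algorithm`,
#'   `k`, `labels`, `centers`, `sizes`, `data`, `fit_extras`.
#' @export
cluster_solution <- function(algorithm, k, labels, data, fit_extras = list()) {
  algorithm <- match.arg(algorithm, c("ward_kmeans", "lpa", "spectral"))
  labels <- as.integer(labels)
  data <- as_trait_matrix(data)
  stopifnot(length(labels) == nrow(data), k >= 1L)
  if (!all(labels %in% seq_len(k)))
    stopf("labels must lie in 1..%d", k)
  sizes <- tabulate(labels, nbins = k)
  if (any(sizes == 0L))
    stopf("cluster(s) %s are empty", paste(which(sizes == 0L), collapse = ","))
  centers <- cluster_centers_(data, labels, k)
  structure(list(algorithm = algorithm, k = as.integer(k), labels = labels,
                 centers = centers, sizes = sizes, data = data,
                 fit_extras = fit_extras),
            class = "cluster_solution")
}

cluster_centers_ <- function(data, labels, k) {
  centers <- matrix(NA_real_, k, ncol(data),
                    dimnames = list(NULL, colnames(data)))
  for (j in seq_len(k))
    centers[j, ] <- colMeans(data[labels == j, , drop = FALSE])
  centers
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> %s, k = %d, n = %d\n",
              x$algorithm, x$k, length(x$labels)))
  cat("sizes:", paste(x$sizes, collapse = " "), "\n")
  invisible(x)
}

# Lloyd iterations from fixed starting centers. Empty clusters are repaired
# by promoting the point farthest from its current center to a singleton
# center (recorded in the `repairs` attribute).
lloyd_kmeans_ <- function(data, centers, tol = 1e-6, max_iter = 300L) {
  n <- nrow(data)
  k <- nrow(centers)
  repairs <- 0L
  sq <- rowSums(data^2)
  for (iter in seq_len(max_iter)) {
    # squared distances to centers via the expansion ||x||^2 - 2 x.c + ||c||^2
    d2 <- outer(sq, rowSums(centers^2), "+") - 2 * data %*% t(centers)
    labels <- max.col(-d2, ties.method = "first")
    sizes <- tabulate(labels, nbins = k)
    while (any(sizes == 0L)) {
      empty <- which(sizes == 0L)[1L]
      own_d2 <- d2[cbind(seq_len(n), labels)]
      # only points from clusters of size >= 2 may be promoted
      own_d2[sizes[labels] < 2L] <- -Inf
      far <- which.max(own_d2)
      labels[far] <- empty
      sizes <- tabulate(labels, nbins = k)
      repairs <- repairs + 1L
    }
    new_centers <- cluster_centers_(data, labels, k)
    move <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (move < tol) break
  }
  d2 <- outer(sq, rowSums(centers^2), "+") - 2 * data %*% t(centers)
  inertia <- sum(d2[cbind(seq_len(n), labels)])
  list(labels = labels, centers = centers, inertia = max(0, inertia),
       iterations = iter, repairs = repairs)
}

#' Ward-initialized k-means clustering
#'
#' Ward agglomeration on Euclidean distances is cut at `k` clusters; the
#' resulting cluster means are the single initialization for Lloyd's
#' k-means, iterated to convergence (center movement below `tol`, at most
#' `max_iter` sweeps).
#'
#' @param z Trait z-score matrix (or data.frame with `person_id`).
#' @param k Number of clusters (`2 <= k <= n`).
#' @param seed Unused by this deterministic engine; accepted for interface
#'   uniformity.
#' @param tree Optional precomputed `hclust` object (method `ward.D2` on
#'   Euclidean distances) to reuse across several `k`.
#' @param tol,max_iter Lloyd convergence controls.
#' @return A [cluster_solution()].
#' @export
ward_kmeans <- function(z, k, seed = NULL, tree = NULL, tol = 1e-6,
                        max_iter = 300L) {
  data <- as_trait_matrix(z)
  stopifnot(k >= 2L, nrow(data) > k)
  if (is.null(tree)) tree <- stats::hclust(stats::dist(data),
                                           method = "ward.D2")
  init_labels <- stats::cutree(tree, k = k)
  init_centers <- cluster_centers_(data, init_labels, k)
  fit <- lloyd_kmeans_(data, init_centers, tol = tol, max_iter = max_iter)
  cluster_solution("ward_kmeans", k, fit$labels, data,
                   fit_extras = list(inertia = fit$inertia,
                                     iterations = fit$iterations,
                                     repairs = fit$repairs))
}

lpa_families_ <- c("spherical-equal" = "EII", "spherical-varying" = "VII",
                   "diagonal" = "VVI", "full" = "VVV")

#' Latent profile analysis (Gaussian mixture model)
#'
#' Fits a Gaussian finite mixture by expectation-maximization for each
#' requested covariance family and retains the family with the best BIC;
#' persons are assigned to the component with the largest posterior
#' probability. Backed by \pkg{mclust}.
#'
#' @param z Trait z-score matrix.
#' @param k Number of mixture components (`k >= 1`).
#' @param families Subset of `"spherical-equal"` (equal-volume spherical),
#'   `"spherical-varying"`, `"diagonal"`, `"full"`.
#' @param seed Integer seed (used only when `init_subset` sampling applies).
#' @param init_subset Optional size of a random subset used for the
#'   agglomerative EM initialization, a standard speed-up for large n.
#' @return A [cluster_solution()] whose `fit_extras` exposes `loglik`,
#'   `df`, `family`, `bic` and the posterior matrix `z_posterior`.
#' @export
lpa_fit <- function(z, k, families = names(lpa_families_), seed = NULL,
                    init_subset = NULL) {
  data <- as_trait_matrix(z)
  stopifnot(k >= 1L)
  families <- match.arg(families, names(lpa_families_), several.ok = TRUE)
  models <- unname(lpa_families_[families])
  init <- NULL
  fit <- with_seed_(seed, {
    if (!is.null(init_subset) && init_subset < nrow(data))
      init <- list(subset = sample.int(nrow(data), init_subset))
    mclust::Mclust(data, G = k, modelNames = models, verbose = FALSE,
                   initialization = init)
  })
  if (is.null(fit) || length(unique(fit$classification)) < k) {
    # degenerate EM (collapsing variance / empty component): refit under a
    # regularizing conjugate prior, which acts as a variance floor
    fit <- with_seed_(seed,
      mclust::Mclust(data, G = k, modelNames = models, verbose = FALSE,
                     initialization = init,
                     prior = mclust::priorControl()))
  }
  if (is.null(fit))
    stopf("EM failed for all requested families at k = %d", k)
  labels <- as.integer(fit$classification)
  if (length(unique(labels)) < k)
    stopf("EM at k = %d produced empty components (degenerate fit)", k)
  cluster_solution("lpa", k, labels, data,
                   fit_extras = list(
                     loglik = fit$loglik,
                     df = fit$df,
                     family = names(lpa_families_)[match(fit$modelName,
                                                         lpa_families_)],
                     model_name = fit$modelName,
                     bic = -fit$bic,  # mclust reports 2*loglik - penalty
                     z_posterior = fit$z))
}

#' Spectral embedding of a similarity graph
#'
#' Builds a Gaussian (RBF) affinity matrix `exp(-d^2 / (2 h^2))` with
#' bandwidth `h` = median pairwise distance by default, forms the symmetric
#' normalized Laplacian and returns its eigendecomposition so that
#' [spectral_cluster()] can be evaluated at several `k` without repeating
#' the O(n^3) work.
#'
#' @param z Trait z-score matrix.
#' @param bandwidth RBF bandwidth; default median pairwise distance.
#' @return list with `vectors`, `values` (eigenpairs of the normalized
#'   affinity, decreasing), `bandwidth`, `n`.
#' @export
spectral_embedding <- function(z, bandwidth = NULL) {
  data <- as_trait_matrix(z)
  n <- nrow(data)
  d <- as.matrix(stats::dist(data))
  if (is.null(bandwidth)) bandwidth <- stats::median(d[upper.tri(d)])
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stopf("non-positive bandwidth; supply one explicitly")
  A <- exp(-d^2 / (2 * bandwidth^2))
  diag(A) <- 0
  if (!graph_connected_(A > .Machine$double.xmin))
    stopf(paste("similarity graph is disconnected; increase the bandwidth",
                "or modify the graph construction"))
  deg <- rowSums(A)
  inv_sqrt <- 1 / sqrt(deg)
  M <- A * tcrossprod(inv_sqrt)        # D^{-1/2} A D^{-1/2}
  e <- eigen(M, symmetric = TRUE)
  list(vectors = e$vectors, values = e$values, bandwidth = bandwidth, n = n)
}

# Breadth-first connectivity check on a logical adjacency matrix.
graph_connected_ <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}

#' Normalized spectral clustering
#'
#' Ng-Jordan-Weiss variant: the first `k` eigenvectors of the symmetric
#' normalized Laplacian (equivalently, the top-k eigenvectors of the
#' normalized affinity) are row-normalized to the unit sphere and clustered
#' with k-means (10 random restarts).
#'
#' @inheritParams spectral_embedding
#' @param k Number of clusters.
#' @param seed Integer seed for the k-means restarts.
#' @param embedding Optional precomputed [spectral_embedding()].
#' @param n_restarts k-means restarts on the embedding (default 10).
#' @return A [cluster_solution()].
#' @export
spectral_cluster <- function(z, k, seed = NULL, bandwidth = NULL,
                             embedding = NULL, n_restarts = 10L) {
  data <- as_trait_matrix(z)
  stopifnot(k >= 2L, nrow(data) > k)
  if (is.null(embedding)) embedding <- spectral_embedding(data, bandwidth)
  U <- embedding$vectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(U^2))
  nrm[nrm == 0] <- 1
  U <- U / nrm
  km <- with_seed_(seed, stats::kmeans(U, centers = k, nstart = n_restarts,
                                       iter.max = 100L))
  cluster_solution("spectral", k, km$cluster, data,
                   fit_extras = list(embedding_dim = k,
                                     bandwidth = embedding$bandwidth,
                                     embedding_inertia = km$tot.withinss))
}
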