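#' Configuration of the split-half replication protocol
#'
#' @param n_resamples Number of resampled permutations of the full sample
#'   (default 20).
#' @param k_range Candidate cluster counts (default 3..10).
#' @param algorithms Subset of `"ward_kmeans"`, `"lpa"`, `"spectral"`.
#' @param kappa_gate Cross-algorithm average kappa below which a cluster
#'   count is discarded (default 0.6).
#' @param sample_fraction Fraction of the full sample drawn per resample
#'   before halving (default 1: a random permutation of everyone).
#' @param svm List of SVM hyperparameters: `kernel`, `cost`, `gamma`
#'   (`NULL` gamma = `1 / (d * mean feature variance)` of the training
#'   half).
#' @param lpa_init_subset Size of the random subset used to initialize the
#'   mixture EM on each half (keeps the agglomerative initialization
#'   affordable at panel-scale n).
#' @param seed Integer master seed.
#' @return Object of class `protocol_config`.
#' @export
protocol_config <- function(n_resamples = 20L,
                            k_range = 3:10,
                            algorithms = c("ward_kmeans", "lpa", "spectral"),
                            kappa_gate = 0.6,
                            sample_fraction = 1,
                            svm = list(kernel = "radial", cost = 1,
                                       gamma = NULL),
                            lpa_init_subset = 500L,
                            seed = 1L) {
  algorithms <- match.arg(algorithms,
                          c("ward_kmeans", "lpa", "spectral"),
                          several.ok = TRUE)
  stopifnot(n_resamples >= 1L, all(k_range >= 2L),
            kappa_gate >= 0, kappa_gate <= 1,
            sample_fraction > 0, sample_fraction <= 1)
  structure(list(n_resamples = as.integer(n_resamples),
                 k_range = as.integer(k_range),
                 algorithms = algorithms,
                 kappa_gate = kappa_gate,
                 sample_fraction = sample_fraction,
                 svm = svm,
                 lpa_init_subset = as.integer(lpa_init_subset),
                 seed = as.integer(seed)),
            class = "protocol_config")
}

svm_gamma_ <- function(train_z, svm_config) {
  if (!is.null(svm_config$gamma)) return(svm_config$gamma)
  1 / (ncol(train_z) * mean(apply(train_z, 2L, stats::var)))
}

#' Reclassify persons with one-vs-rest SVM classifiers
#'
#' Trains a soft-margin SVM (RBF kernel by default) for every cluster of
#' the training half's solution and assigns each test person to the cluster
#' whose classifier yields the largest decision value. This transfers a
#' partition across halves without forcing spherical, evenly shaped
#' clusters the way nearest-centroid allocation does. When any training
#' cluster has fewer than 2 members (too small to train a classifier on),
#' the whole allocation falls back to nearest-centroid so all decision
#' values stay on one scale; the triggering clusters are recorded in the
#' `fallback` attribute.
#'
#' @param train_z Training-half feature matrix.
#' @param train_labels Integer cluster labels of the training half.
#' @param test_z Test-half feature matrix.
#' @param svm_config List with `kernel`, `cost`, optional `gamma`.
#' @return Integer vector of predicted labels (training label space), with
#'   attribute `decision_values`.
#' @export
svm_reclassify <- function(train_z, train_labels, test_z,
                           svm_config = list(kernel = "radial", cost = 1,
                                             gamma = NULL)) {
  train_z <- as_trait_matrix(train_z)
  test_z <- as_trait_matrix(test_z)
  stopifnot(nrow(train_z) == length(train_labels),
            ncol(train_z) == ncol(test_z))
  ks <- sort(unique(as.integer(train_labels)))
  gamma <- svm_gamma_(train_z, svm_config)
  dec <- matrix(NA_real_, nrow(test_z), length(ks))
  fallback <- ks[vapply(ks, function(k) sum(train_labels == k) < 2L, TRUE)]
  if (length(fallback)) {
    # a cluster too small to train on: SVM decision values and distances
    # are not on a common scale, so allocate everyone by nearest centroid
    for (i in seq_along(ks)) {
      centroid <- colMeans(train_z[train_labels == ks[i], , drop = FALSE])
      dec[, i] <- -sqrt(rowSums(sweep(test_z, 2L, centroid)^2))
    }
    out <- ks[max.col(dec, ties.method = "first")]
    attr(out, "decision_values") <- dec
    attr(out, "fallback") <- fallback
    attr(out, "gamma") <- gamma
    return(out)
  }
  for (i in seq_along(ks)) {
    member <- train_labels == ks[i]
    y <- factor(ifelse(member, "in", "out"), levels = c("in", "out"))
    fit <- e1071::svm(train_z, y,
                      kernel = svm_config$kernel %||% "radial",
                      cost = svm_config$cost %||% 1,
                      gamma = gamma, scale = FALSE)
    pred <- stats::predict(fit, test_z, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    # orient so that larger values favor membership ("in")
    if (colnames(dv)[1L] == "out/in") dv <- -dv
    dec[, i] <- dv[, 1L]
  }
  out <- ks[max.col(dec, ties.method = "first")]
  attr(out, "decision_values") <- dec
  attr(out, "fallback") <- fallback
  attr(out, "gamma") <- gamma
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fit one algorithm on one half at every k, reusing the expensive
# per-half structures (Ward tree, spectral embedding) across k.
fit_half_ <- function(z, algorithm, k_range, seed, config) {
  pre <- switch(algorithm,
    ward_kmeans = stats::hclust(stats::dist(z), method = "ward.D2"),
    spectral = spectral_embedding(z),
    lpa = NULL)
  out <- vector("list", length(k_range))
  names(out) <- as.character(k_range)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    out[[i]] <- tryCatch(switch(algorithm,
      ward_kmeans = ward_kmeans(z, k, tree = pre),
      spectral = spectral_cluster(z, k, seed = seed + k, embedding = pre),
      lpa = lpa_fit(z, k, seed = seed + k,
                    init_subset = config$lpa_init_subset)),
      error = function(e) e)
  }
  out
}

#' Run the resampled split-half replication protocol
#'
#' For each of `n_resamples` random permutations of the sample: split into
#' two halves, fit every requested algorithm at every `k` on both halves,
#' reclassify each half's members with one-vs-rest SVMs trained on the
#' *opposite* half's solution, and score the agreement between each half's
#' own labels and its SVM-predicted labels with Cohen's kappa (after
#' optimal label alignment), the Rand index and the Hubert-Arabie adjusted
#' Rand index. Values are averaged per resample (over the two halves) and
#' then across resamples.
#'
#' @param z Trait z-score matrix (or data.frame) of the full included
#'   sample.
#' @param config A [protocol_config()].
#' @return Object of class `replication_result`: list with `summary`
#'   (per algorithm x k averaged kappa/rand/adjusted_rand and the number of
#'   half-comparisons contributing), `raw` (per resample x half values),
#'   `failures` (engine errors, if any) and `config`.
#' @export
run_replication <- function(z, config = protocol_config()) {
  stopifnot(inherits(config, "protocol_config"))
  z <- as_trait_matrix(z)
  n <- nrow(z)
  if (n < 40L * max(config$k_range))
    stopf("need n >= 40 * max(k_range) = %d persons, got %d",
          40L * max(config$k_range), n)
  raw <- list()
  failures <- list()
  for (r in seq_len(config$n_resamples)) {
    rs <- config$seed + 1000L * r
    idx <- with_seed_(rs, sample.int(n, floor(n * config$sample_fraction)))
    half_size <- floor(length(idx) / 2)
    halves <- list(idx[seq_len(half_size)],
                   idx[seq.int(half_size + 1L, 2L * half_size)])
    for (alg in config$algorithms) {
      fits <- lapply(halves, function(h)
        fit_half_(z[h, , drop = FALSE], alg, config$k_range, rs, config))
      for (k in config$k_range) {
        kk <- as.character(k)
        sols <- list(fits[[1L]][[kk]], fits[[2L]][[kk]])
        bad <- vapply(sols, inherits, TRUE, "error")
        if (any(bad)) {
          failures[[length(failures) + 1L]] <- data.frame(
            resample = r, algorithm = alg, k = k,
            message = conditionMessage(sols[[which(bad)[1L]]]))
          next
        }
        for (h in 1:2) {
          other <- 3L - h
          pred <- svm_reclassify(z[halves[[other]], , drop = FALSE],
                                 sols[[other]]$labels,
                                 z[halves[[h]], , drop = FALSE],
                                 config$svm)
          own <- sols[[h]]$labels
          raw[[length(raw) + 1L]] <- data.frame(
            resample = r, half = h, algorithm = alg, k = k,
            kappa = cohen_kappa(own, pred, align = TRUE),
            rand = rand_index(own, pred),
            adjusted_rand = adjusted_rand(own, pred))
        }
      }
    }
  }
  raw <- do.call(rbind, raw)
  # mean over the two halves within each resample, then across resamples
  per_sample <- stats::aggregate(
    raw[, c("kappa", "rand", "adjusted_rand")],
    by = raw[, c("resample", "algorithm", "k")], FUN = mean)
  summary <- stats::aggregate(
    per_sample[, c("kappa", "rand", "adjusted_rand")],
    by = per_sample[, c("algorithm", "k")], FUN = mean)
  counts <- stats::aggregate(list(n_comparisons = raw$kappa),
                             by = raw[, c("algorithm", "k")], FUN = length)
  summary <- merge(summary, counts, by = c("algorithm", "k"))
  summary <- summary[order(summary$algorithm, summary$k), ]
  rownames(summary) <- NULL
  structure(list(summary = summary, raw = raw,
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL,
                 config = config),
            class = "replication_result")
}

#' @export
print.replication_result <- function(x, ...) {
  cat(sprintf("<replication_result> %d resamples, k in %s\n",
              x$config$n_resamples,
              paste(range(x$config$k_range), collapse = "..")))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Screen cluster counts by the averaged-kappa gate
#'
#' Averages kappa across algorithms for each `k` and retains the cluster
#' counts whose cross-algorithm average meets the gate. If nothing
#' survives, the single best `k` is returned with a warning.
#'
#' @param result A [run_replication()] result, or its `summary`
#'   data.frame.
#' @param gate Kappa threshold (default from the result's config, else
#'   0.6).
#' @return list with `retained_k` (integer vector), `by_k` (data.frame of
#'   cross-algorithm mean kappa per k) and `retained` (the algorithm x k
#'   rows of the summary that survive).
#' @export
screen_by_kappa <- function(result, gate = NULL) {
  if (inherits(result, "replication_result")) {
    if (is.null(gate)) gate <- result$config$kappa_gate
    summary <- result$summary
  } else {
    summary <- result
    if (is.null(gate)) gate <- 0.6
  }
  by_k <- stats::aggregate(list(kappa = summary$kappa),
                           by = list(k = summary$k), FUN = mean)
  retained_k <- by_k$k[by_k$kappa >= gate]
  if (!length(retained_k)) {
    warning("no cluster count reaches the kappa gate; ",
            "falling back to the best single k")
    retained_k <- by_k$k[which.max(by_k$kappa)]
  }
  list(retained_k = sort(retained_k), by_k = by_k,
       retained = summary[summary$k %in% retained_k, , drop = FALSE])
}

#' Vote-count model selection over a validity report
#'
#' For every index, the best solution *within* each algorithm's retained
#' candidates receives a within-algorithm vote, and the single best
#' solution overall receives a between-algorithm vote. The winner is the
#' solution with the most between-algorithm votes; ties are broken by
#' within-algorithm votes, then by the smaller `k`. Indices with missing
#' values abstain from the affected comparisons.
#'
#' @param report A [validity_report()] over the retained solutions (at
#'   least 2 rows).
#' @return list with `votes` (per-solution data.frame with `within_votes`
#'   and `between_votes`), `per_index` (which solution each index voted
#'   for), and `winner` (row index into `votes`).
#' @export
vote_count <- function(report) {
  stopifnot(nrow(report) >= 2L)
  directions <- attr(report, "directions")
  idx_names <- intersect(names(directions), names(report))
  within <- integer(nrow(report))
  between <- integer(nrow(report))
  per_index <- data.frame(index = idx_names, between_winner = NA_integer_)
  for (m in seq_along(idx_names)) {
    nm <- idx_names[m]
    v <- report[[nm]]
    v_cmp <- if (directions[[nm]] == "min") v else -v
    if (all(is.na(v_cmp))) next
    best <- which.min(v_cmp)           # NAs never win
    between[best] <- between[best] + 1L
    per_index$between_winner[m] <- best
    for (alg in unique(report$algorithm)) {
      rows <- which(report$algorithm == alg)
      if (all(is.na(v_cmp[rows]))) next
      b <- rows[which.min(v_cmp[rows])]
      within[b] <- within[b] + 1L
    }
  }
  votes <- data.frame(algorithm = report$algorithm, k = report$k,
                      within_votes = within, between_votes = between)
  ord <- order(-votes$between_votes, -votes$within_votes, votes$k)
  list(votes = votes, per_index = per_index, winner = ord[1L])
}

#' Cross-wave stability of a cluster solution
#'
#' Clusters a new assessment wave with the reference solution's engine and
#' `k`, matches the new prototypes to the reference prototypes by minimal
#' total profile-similarity D (optimal one-to-one assignment), allocates
#' the new wave's members to the reference types with SVMs trained on the
#' reference solution, and reports overall kappa / Rand / adjusted Rand
#' between the matched new-wave clustering and the SVM allocation, plus a
#' one-vs-rest kappa per personality type.
#'
#' @param solution_ref Reference [cluster_solution()] (carries its data).
#' @param z_new New-wave trait z-score matrix (ideally standardized with
#'   the reference wave's moments; see [zstandardize()]).
#' @param engine_config Optional list: `seed`, `svm` (as in
#'   [protocol_config()]), `k` override.
#' @return list with `solution_new`, `matching` (data.frame: reference
#'   type, matched new cluster, profile distance D), `overall` (kappa,
#'   rand, adjusted_rand), `per_type` (one-vs-rest kappa per reference
#'   type) and `svm_labels`.
#' @export
stability_compare <- function(solution_ref, z_new, engine_config = list()) {
  stopifnot(inherits(solution_ref, "cluster_solution"))
  z_new <- as_trait_matrix(z_new)
  k_ref <- solution_ref$k
  k_new <- engine_config$k %||% k_ref
  seed <- engine_config$seed %||% 1L
  sol_new <- switch(solution_ref$algorithm,
    ward_kmeans = ward_kmeans(z_new, k_new),
    spectral = spectral_cluster(z_new, k_new, seed = seed),
    lpa = lpa_fit(z_new, k_new, seed = seed))
  k_match <- min(k_ref, k_new)
  if (k_ref != k_new)
    warning(sprintf("k mismatch between waves (%d vs %d); matching on %d",
                    k_ref, k_new, k_match))
  D <- profile_distance_matrix(solution_ref$centers, sol_new$centers)
  assignment <- clue::solve_LSAP(D[seq_len(k_match), seq_len(k_match),
                                   drop = FALSE])
  matching <- data.frame(
    reference_cluster = seq_len(k_match),
    new_cluster = as.integer(assignment),
    D = D[cbind(seq_len(k_match), as.integer(assignment))])
  # relabel the new wave's clusters into the reference label space
  new_to_ref <- rep(NA_integer_, k_new)
  new_to_ref[matching$new_cluster] <- matching$reference_cluster
  labels_new <- new_to_ref[sol_new$labels]
  svm_labels <- svm_reclassify(solution_ref$data, solution_ref$labels,
                               z_new, engine_config$svm %||%
                                 list(kernel = "radial", cost = 1,
                                      gamma = NULL))
  ok <- !is.na(labels_new)
  overall <- list(kappa = cohen_kappa(labels_new[ok], svm_labels[ok]),
                  rand = rand_index(labels_new[ok], svm_labels[ok]),
                  adjusted_rand = adjusted_rand(labels_new[ok],
                                                svm_labels[ok]))
  per_type <- vapply(seq_len(k_match), function(t)
    cohen_kappa(as.integer(labels_new[ok] == t) + 1L,
                as.integer(svm_labels[ok] == t) + 1L), 0)
  list(solution_new = sol_new, matching = matching, overall = overall,
       per_type = data.frame(reference_cluster = seq_len(k_match),
                             kappa = per_type),
       svm_labels = svm_labels)
}

#' Write the replication summary in cluster-count-by-algorithm layout
#'
#' @param result A [run_replication()] result.
#' @param path CSV path.
#' @param metric Which metric to tabulate (default `"kappa"`).
#' @return `path`, invisibly.
#' @export
write_replication_summary <- function(result, path, metric = "kappa") {
  s <- result$summary
  wide <- stats::reshape(s[, c("algorithm", "k", metric)],
                         direction = "wide", idvar = "algorithm",
                         timevar = "k")
  names(wide) <- sub(paste0("^", metric, "\\."), "k_", names(wide))
  means <- c(algorithm = "mean",
             as.list(colMeans(wide[, -1L, drop = FALSE])))
  wide <- rbind(wide, means)
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
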