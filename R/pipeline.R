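#' Full model-selection pipeline: replicate, gate, score, vote
#'
#' Runs the split-half replication protocol, screens cluster counts by the
#' averaged-kappa gate, refits every retained (algorithm, k) pair on the
#' full sample, evaluates the internal validity battery on those solutions,
#' and selects the winner by vote counting.
#'
#' @param z Trait z-score matrix (or data.frame) of the included sample.
#' @param config A [protocol_config()].
#' @return list with `replication` ([run_replication()] result), `screen`
#'   ([screen_by_kappa()] result), `solutions` (retained full-sample
#'   [cluster_solution()]s), `report` ([validity_report()]), `votes`
#'   ([vote_count()] result) and `winner` (the winning solution).
#' @export
select_prototype_solution <- function(z, config = protocol_config()) {
  z <- as_trait_matrix(z)
  replication <- run_replication(z, config)
  screen <- screen_by_kappa(replication)
  solutions <- list()
  for (alg in config$algorithms) {
    pre <- switch(alg,
      ward_kmeans = stats::hclust(stats::dist(z), method = "ward.D2"),
      spectral = spectral_embedding(z),
      lpa = NULL)
    for (k in screen$retained_k) {
      sol <- tryCatch(switch(alg,
        ward_kmeans = ward_kmeans(z, k, tree = pre),
        spectral = spectral_cluster(z, k, seed = config$seed + k,
                                    embedding = pre),
        lpa = lpa_fit(z, k, seed = config$seed + k,
                      init_subset = config$lpa_init_subset)),
        error = function(e) NULL)
      if (!is.null(sol))
        solutions[[sprintf("%s_k%d", alg, k)]] <- sol
    }
  }
  if (length(solutions) < 2L)
    stopf("fewer than 2 retained solutions; cannot vote")
  report <- validity_report(solutions, data = z)
  votes <- vote_count(report)
  list(replication = replication, screen = screen, solutions = solutions,
       report = report, votes = votes,
       winner = solutions[[votes$winner]])
}
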