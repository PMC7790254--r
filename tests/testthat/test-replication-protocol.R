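test_that("SVM self-reclassification reproduces its training labels", {
  pt <- planted_traits(n = 1000, within_sd = 0.4, seed = 3)
  sol <- ward_kmeans(pt$z, 5)
  pred <- svm_reclassify(pt$z, sol$labels, pt$z)
  expect_gte(cohen_kappa(sol$labels, pred), 0.99)
})

test_that("SVM and nearest-centroid agree on linearly separable blobs", {
  set.seed(6)
  b <- make_blobs(100, rbind(c(0, 0), c(8, 8)), sd = 0.4)
  half <- c(1:50, 101:150)
  pred_svm <- svm_reclassify(b$x[half, ], b$labels[half], b$x[-half, ])
  centers <- rbind(colMeans(b$x[half[1:50], ]),
                   colMeans(b$x[half[51:100], ]))
  d2 <- outer(rowSums(b$x[-half, ]^2), rowSums(centers^2), "+") -
    2 * b$x[-half, ] %*% t(centers)
  pred_cen <- max.col(-d2)
  expect_equal(as.integer(pred_svm), pred_cen)
})

test_that("SVM reallocation preserves ring structure where centroids cannot", {
  set.seed(30)
  r <- make_rings(200)
  sol <- spectral_cluster(r$x, 2, seed = 1, bandwidth = 0.5)
  pred_svm <- svm_reclassify(r$x, sol$labels, r$x)
  kappa_svm <- cohen_kappa(sol$labels, pred_svm)
  centers <- rbind(colMeans(r$x[sol$labels == 1, ]),
                   colMeans(r$x[sol$labels == 2, ]))
  d2 <- outer(rowSums(r$x^2), rowSums(centers^2), "+") -
    2 * r$x %*% t(centers)
  kappa_cen <- cohen_kappa(sol$labels, max.col(-d2))
  expect_lt(kappa_cen, 1)
  expect_gt(kappa_svm, kappa_cen)
  expect_gte(kappa_svm, 0.99)
})

test_that("singleton training clusters fall back to nearest centroid", {
  x <- rbind(c(0, 0), c(0.2, 0), c(10, 10))
  pred <- svm_reclassify(x, c(1, 1, 2), rbind(c(0.1, 0), c(9, 9)))
  expect_equal(as.integer(pred), c(1L, 2L))
  expect_equal(attr(pred, "fallback"), 2L)
})

test_that("replication bookkeeping and determinism", {
  pt <- planted_traits(n = 800, seed = 5)
  cfg <- protocol_config(n_resamples = 2, k_range = 3:5,
                         algorithms = "ward_kmeans", seed = 11)
  res <- run_replication(pt$z, cfg)
  # 2 resamples x 2 halves x 3 k x 1 algorithm
  expect_equal(nrow(res$raw), 2 * 2 * 3)
  expect_equal(res$summary$n_comparisons, rep(4L, 3))
  res2 <- run_replication(pt$z, cfg)
  expect_equal(res$summary, res2$summary)
  expect_true(all(res$summary$kappa >= -1 & res$summary$kappa <= 1))
})

test_that("too-small samples are rejected", {
  expect_error(run_replication(matrix(rnorm(100), 20, 5),
                               protocol_config(k_range = 3:10)),
               "40")
})

test_that("kappa gate screens cluster counts as on the published mean row", {
  # cross-algorithm averaged kappas for k = 3..10 shaped like the panel
  # study's: gate 0.6 retains only k in {3, 4, 5}
  summary <- data.frame(
    algorithm = "ward_kmeans", k = 3:10,
    kappa = c(0.78, 0.66, 0.70, 0.54, 0.56, 0.56, 0.55, 0.50),
    rand = NA, adjusted_rand = NA)
  sc <- screen_by_kappa(summary, gate = 0.6)
  expect_equal(sc$retained_k, 3:5)
  expect_equal(nrow(sc$retained), 3)
})

test_that("kappa gate is monotone and has a non-empty fallback", {
  summary <- data.frame(algorithm = "a", k = 3:6,
                        kappa = c(0.7, 0.65, 0.5, 0.4))
  gates <- c(0, 0.6, 0.66, 0.9)
  sizes <- sapply(gates, function(g)
    length(suppressWarnings(screen_by_kappa(summary, gate = g))$retained_k))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[1], 4)  # vacuous gate retains everything
  expect_warning(sc <- screen_by_kappa(summary, gate = 0.9), "falling back")
  expect_equal(sc$retained_k, 3)
})

test_that("vote counting: dominance, majorities and tie-breaks", {
  dirs <- index_directions()[c("c_index", "gamma", "silhouette")]
  mk_report <- function(vals) {
    df <- cbind(data.frame(algorithm = c("ward_kmeans", "ward_kmeans",
                                         "spectral"),
                           k = c(4, 5, 5)), vals)
    attr(df, "directions") <- dirs
    class(df) <- c("validity_report", class(df))
    df
  }
  # row 2 dominates every index
  rep1 <- mk_report(data.frame(c_index = c(0.5, 0.1, 0.4),
                               gamma = c(0.2, 0.9, 0.5),
                               silhouette = c(0.1, 0.8, 0.4)))
  vc1 <- vote_count(rep1)
  expect_equal(vc1$winner, 2L)
  expect_equal(vc1$votes$between_votes, c(0L, 3L, 0L))
  expect_equal(vc1$votes$within_votes, c(0L, 3L, 3L))
  # majority: row 3 best on 2 of 3 indices
  rep2 <- mk_report(data.frame(c_index = c(0.1, 0.5, 0.4),
                               gamma = c(0.2, 0.5, 0.9),
                               silhouette = c(0.1, 0.4, 0.8)))
  vc2 <- vote_count(rep2)
  expect_equal(vc2$winner, 3L)
  expect_equal(vc2$votes$between_votes, c(1L, 0L, 2L))
  # between-vote tie with unequal within votes: more within votes wins
  rep3 <- mk_report(data.frame(c_index = c(0.1, 0.5, 0.2),
                               gamma = c(0.2, 0.4, 0.9),
                               silhouette = c(NA, NA, NA)))
  vc3 <- vote_count(rep3)
  expect_equal(vc3$votes$between_votes, c(1L, 0L, 1L))
  expect_equal(vc3$votes$within_votes, c(1L, 1L, 2L))
  expect_equal(vc3$winner, 3L)
  # full tie on between and within votes: smaller k wins
  rep4 <- mk_report(data.frame(c_index = c(0.1, 0.5, 0.2),
                               gamma = c(0.9, 0.4, 0.95),
                               silhouette = c(NA, NA, NA)))
  vc4 <- vote_count(rep4)
  expect_equal(vc4$votes$between_votes, c(1L, 0L, 1L))
  expect_equal(vc4$votes$within_votes, c(2L, 0L, 2L))
  expect_equal(vc4$winner, 1L)   # k = 4 beats k = 5 on the final tie-break
})

test_that("missing index values abstain from voting", {
  dirs <- index_directions()["silhouette"]
  df <- cbind(data.frame(algorithm = "ward_kmeans", k = c(4, 5)),
              data.frame(silhouette = c(NA_real_, NA_real_)))
  attr(df, "directions") <- dirs
  class(df) <- c("validity_report", class(df))
  vc <- vote_count(df)
  expect_equal(sum(vc$votes$between_votes), 0L)
})

test_that("replication kappa is maximal at the planted k on clean data", {
  pt <- planted_traits(n = 1200, within_sd = 0.4, seed = 19)
  cfg <- protocol_config(n_resamples = 3, k_range = 4:6,
                         algorithms = "ward_kmeans", seed = 23)
  res <- run_replication(pt$z, cfg)
  kap <- res$summary$kappa[order(res$summary$k)]
  expect_equal(which.max(kap), 2L)   # k = 5 among 4..6
})

test_that("structureless data favors small k (the known small-k bias)", {
  set.seed(41)
  z <- matrix(rnorm(600 * 5), 600, 5)
  cfg <- protocol_config(n_resamples = 3, k_range = c(3, 8),
                         algorithms = "ward_kmeans", seed = 7)
  res <- run_replication(z, cfg)
  kap <- res$summary$kappa[order(res$summary$k)]
  expect_gt(kap[1], kap[2])
})

test_that("stability_compare on the same wave is near-perfect", {
  pt <- planted_traits(n = 1000, within_sd = 0.4, seed = 29)
  sol <- ward_kmeans(pt$z, 5)
  st <- stability_compare(sol, pt$z)
  expect_equal(st$matching$D, rep(0, 5), tolerance = 1e-12)
  expect_gte(st$overall$kappa, 0.99)
  expect_gte(st$overall$rand, 0.99)
  expect_true(all(st$per_type$kappa >= 0.98))
})

test_that("stability matching recovers a planted label permutation", {
  pt <- planted_traits(n = 1000, within_sd = 0.4, seed = 37)
  sol <- ward_kmeans(pt$z, 5)
  perm <- c(3L, 5L, 4L, 1L, 2L)
  permuted <- cluster_solution("ward_kmeans", 5, perm[sol$labels], pt$z)
  D <- profile_distance_matrix(sol$centers, permuted$centers)
  assignment <- as.integer(clue::solve_LSAP(D))
  expect_equal(assignment, perm)
  expect_equal(D[cbind(1:5, perm)], rep(0, 5))
})

test_that("a fresh same-config wave replicates the reference solution", {
  pt_a <- planted_traits(n = 1500, within_sd = 0.5, seed = 51)
  pt_b <- planted_traits(n = 1500, within_sd = 0.5, seed = 52)
  sol <- ward_kmeans(pt_a$z, 5)
  st <- stability_compare(sol, pt_b$z)
  expect_gte(st$overall$kappa, 0.6)
  expect_true(all(st$matching$D < 0.3))
})

test_that("replication summary CSV mirrors the k-by-algorithm layout", {
  pt <- planted_traits(n = 800, seed = 5)
  cfg <- protocol_config(n_resamples = 1, k_range = 3:4,
                         algorithms = c("ward_kmeans", "spectral"), seed = 2)
  res <- run_replication(pt$z, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_replication_summary(res, path)
  tab <- read.csv(path)
  expect_equal(tab$algorithm, c("spectral", "ward_kmeans", "mean"))
  expect_true(all(c("k_3", "k_4") %in% names(tab)))
})
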