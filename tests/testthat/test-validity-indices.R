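# canonical 1-D toy instance: clusters {0,1} and {10,11}
toy_x <- matrix(c(0, 1, 10, 11), 4, 1)
toy_lab <- c(1, 1, 2, 2)

test_that("pair counts on the 1-D toy instance enumerate correctly", {
  pc <- pair_counts(toy_x, toy_lab)
  expect_equal(pc$n_w, 2)
  expect_equal(pc$n_b, 4)
  expect_equal(pc$s_plus, 8)
  expect_equal(pc$s_minus, 0)
})

test_that("all-identical points yield only ties", {
  x <- matrix(1, 6, 2)
  pc <- pair_counts(x, rep(1:2, 3))
  expect_equal(pc$s_plus, 0)
  expect_equal(pc$s_minus, 0)
  gg <- gamma_gplus(pc)
  expect_true(is.na(gg$gamma))
  expect_equal(gg$g_plus, 0)
})

test_that("gamma and G+ follow their closed forms", {
  pc <- structure(list(s_plus = 8, s_minus = 0, n_w = 2, n_b = 4, n_t = 6),
                  class = "pair_counts")
  gg <- gamma_gplus(pc)
  expect_equal(gg$gamma, 1)
  expect_equal(gg$g_plus, 0)
  pc$s_minus <- 8
  expect_equal(gamma_gplus(pc)$gamma, 0)
})

test_that("C-index: best and worst configurations attain the bounds", {
  expect_equal(c_index(toy_x, toy_lab), 0)
  # worst case: the single within pair is the largest distance
  expect_equal(c_index(matrix(c(0, 1, 10), 3, 1), c(1, 2, 1)), 1)
})

test_that("GDI31 on the toy instance and under scaling", {
  expect_equal(gdi31(toy_x, toy_lab), 10)
  expect_equal(gdi31(toy_x * 3.7, toy_lab), 10)
  # all-singleton partition is undefined
  expect_true(is.na(gdi31(matrix(1:3, 3, 1), 1:3)))
})

test_that("point-biserial equals the distance/indicator correlation", {
  expect_equal(point_biserial(toy_x, toy_lab),
               oracle_point_biserial(toy_x, toy_lab))
  expect_gt(point_biserial(toy_x, toy_lab), 0)
  # a partition whose within pairs span the gap scores negative
  expect_lt(point_biserial(toy_x, c(1, 2, 1, 2)), 0)
  expect_equal(point_biserial(toy_x, c(1, 2, 1, 2)),
               oracle_point_biserial(toy_x, c(1, 2, 1, 2)))
})

test_that("silhouette on the toy instance matches hand computation", {
  # per point: s = (b - a)/max(a, b); e.g. point 0 has a = 1,
  # b = mean(10, 11) = 10.5; point 1 has b = mean(9, 10) = 9.5
  expect_equal(silhouette_mean(toy_x, toy_lab),
               mean(c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5)))
  # fully coincident points: a = b = 0 handled as s = 0
  expect_equal(silhouette_mean(matrix(1, 8, 2), rep(1:2, 4)), 0)
  # two large interleaved clusters from one distribution: mean near 0
  set.seed(5)
  x <- matrix(rnorm(400), 200, 2)
  expect_lt(abs(silhouette_mean(x, rep(1:2, 100))), 0.02)
})

test_that("pair-based indices match brute-force oracles on random instances", {
  set.seed(101)
  for (rep in 1:30) {
    n <- sample(8:25, 1)
    k <- sample(2:4, 1)
    inst <- random_instance(n, k)
    pc <- pair_counts(inst$x, inst$labels)
    opc <- oracle_pair_counts(inst$x, inst$labels)
    expect_equal(pc$s_plus, opc$s_plus)
    expect_equal(pc$s_minus, opc$s_minus)
    expect_equal(c_index(inst$x, inst$labels),
                 oracle_c_index(inst$x, inst$labels), tolerance = 1e-10)
    expect_equal(gdi31(inst$x, inst$labels),
                 oracle_gdi31(inst$x, inst$labels), tolerance = 1e-10)
    expect_equal(point_biserial(inst$x, inst$labels),
                 oracle_point_biserial(inst$x, inst$labels),
                 tolerance = 1e-10)
    expect_equal(silhouette_mean(inst$x, inst$labels),
                 oracle_silhouette(inst$x, inst$labels), tolerance = 1e-10)
  }
})

test_that("silhouette agrees with the cluster package on a larger instance", {
  set.seed(55)
  inst <- random_instance(120, 4, d = 5)
  ours <- silhouette_mean(inst$x, inst$labels)
  ref <- mean(cluster::silhouette(inst$labels, dist(inst$x))[, "sil_width"])
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("S_Dbw behaves as a density-aware index", {
  set.seed(21)
  b <- make_blobs(40, rbind(c(0, 0), c(50, 50)), sd = 0.05)
  v_true <- s_dbw(b$x, b$labels)
  expect_lt(v_true, 0.05)
  # merging the two real clusters under a random split increases the index
  v_bad <- s_dbw(b$x, sample(rep(1:2, 40)))
  expect_gt(v_bad, v_true)
  # translation invariance
  expect_equal(s_dbw(b$x + 100, b$labels), v_true)
  # zero total scatter is undefined
  expect_true(is.na(s_dbw(matrix(1, 6, 2), rep(1:2, 3))))
})

test_that("classification AIC/BIC arithmetic and planted-k minimum", {
  set.seed(33)
  b <- make_blobs(30, default_prototype_means(3), sd = 0.25)
  # doubling n with the same fit shifts BIC - AIC by p * (log(2n) - 2)
  sol <- ward_kmeans(b$x, 5)
  ab <- partition_aic_bic(b$x, sol)
  x2 <- rbind(b$x, b$x)
  sol2 <- cluster_solution("ward_kmeans", 5, rep(sol$labels, 2), x2)
  ab2 <- partition_aic_bic(x2, sol2)
  p <- 5 * 5 + 1 + 4
  expect_equal(ab$bic - ab$aic, p * (log(nrow(b$x)) - 2))
  expect_equal(ab2$bic - ab2$aic, p * (log(2 * nrow(b$x)) - 2))
  # BIC across k = 3..8 is minimized at the planted k = 5
  bics <- sapply(3:8, function(k)
    partition_aic_bic(b$x, ward_kmeans(b$x, k))$bic)
  expect_equal((3:8)[which.min(bics)], 5)
})

test_that("label alignment maximizes agreement on the contingency table", {
  a <- c(rep(1, 10), rep(2, 10))
  b <- c(rep(1, 8), rep(2, 2), rep(1, 1), rep(2, 9))  # contingency [[8,2],[1,9]]
  al <- align_labels(a, b)
  expect_equal(al$agreement, 17L)
  expect_equal(al$b_to_a, c(1L, 2L))   # identity beats the swap (9 < 17)
  # a relabeling is recovered exactly
  a2 <- sample(1:4, 50, replace = TRUE)
  perm <- c(3L, 1L, 4L, 2L)
  al2 <- align_labels(a2, perm[a2])
  expect_equal(al2$agreement, 50L)
  expect_equal(al2$b_aligned, a2)
  # unequal cluster counts: padded labels absorb the surplus
  a3 <- c(1, 1, 2, 2, 3, 3)
  b3 <- c(1, 1, 2, 2, 2, 2)
  al3 <- align_labels(a3, b3)
  expect_equal(al3$agreement, 4L)
})

test_that("Cohen's kappa matches hand computation and axioms", {
  expect_equal(cohen_kappa(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  # confusion [[2,1],[1,2]] on n = 6: p_o = 4/6, p_e = 1/2, kappa = 1/3
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 1, 2, 2)
  expect_equal(cohen_kappa(a, b), 1 / 3)
  # degenerate single shared category
  expect_equal(cohen_kappa(rep(1, 5), rep(1, 5)), 1)
})

test_that("Rand and adjusted Rand follow their definitions", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 2 / 6)
  expect_equal(rand_index(1:4, rep(1, 4)), 0)
  expect_error(rand_index(1, 1), "n >= 2")
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_lt(adjusted_rand(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  expect_equal(adjusted_rand(rep(1, 4), rep(1, 4)), 1)
  # cross-check against an established implementation
  set.seed(77)
  for (i in 1:10) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
    expect_equal(rand_index(a, b),
                 e1071::classAgreement(table(a, b))$rand,
                 tolerance = 1e-12)
  }
})

test_that("partition indices are invariant to label permutation and row order", {
  set.seed(88)
  inst <- random_instance(40, 3, d = 5)
  perm_lab <- c(2L, 3L, 1L)[inst$labels]
  ord <- sample(40)
  for (f in list(c_index, gdi31, point_biserial, silhouette_mean, s_dbw)) {
    v <- f(inst$x, inst$labels)
    expect_equal(f(inst$x, perm_lab), v, tolerance = 1e-12)
    expect_equal(f(inst$x[ord, ], inst$labels[ord]), v, tolerance = 1e-10)
  }
  expect_equal(rand_index(inst$labels, perm_lab), 1)
  expect_equal(adjusted_rand(inst$labels, perm_lab), 1)
  expect_equal(cohen_kappa(inst$labels, perm_lab, align = TRUE), 1)
})

test_that("every index prefers the true k on planted separated blobs", {
  set.seed(44)
  b <- make_blobs(50, default_prototype_means(3), sd = 0.2)
  merged <- b$labels
  merged[merged == 5] <- 4   # force a wrong merged solution
  d <- dist(b$x)
  dirs <- index_directions()
  vals <- function(lab) {
    gg <- gamma_gplus(pair_counts(d, lab))
    c(c_index = c_index(d, lab), gdi31 = gdi31(d, lab), gamma = gg$gamma,
      g_plus = gg$g_plus, point_biserial = point_biserial(d, lab),
      silhouette = silhouette_mean(d, lab), s_dbw = s_dbw(b$x, lab))
  }
  v_true <- vals(b$labels)
  v_merged <- vals(merged)
  for (nm in names(v_true)) {
    if (dirs[[nm]] == "min") expect_lt(v_true[[nm]], v_merged[[nm]])
    else expect_gt(v_true[[nm]], v_merged[[nm]])
  }
})

test_that("validity_report assembles all indices with directions", {
  set.seed(66)
  pt <- planted_traits(n = 400, seed = 9)
  sols <- list(ward_kmeans(pt$z, 4), ward_kmeans(pt$z, 5))
  rep_ <- validity_report(sols, comparison = pt$labels)
  expect_s3_class(rep_, "validity_report")
  expect_equal(nrow(rep_), 2)
  expect_true(all(c("c_index", "gamma", "s_dbw", "aic", "kappa") %in%
                    names(rep_)))
  expect_gt(rep_$kappa[rep_$k == 5], rep_$kappa[rep_$k == 4])
  path <- withr::local_tempfile(fileext = ".csv")
  write_validity_report(rep_, path)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(back$index[1], "c_index")
  expect_true("ward_kmeans_k5" %in% names(back))
  expect_true(file.exists(paste0(path, ".json")))
})
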