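# Independent brute-force oracles for the distance-based validity indices.
# These enumerate pairs (and pairs of pairs) directly and are O(n^2)-O(n^4);
# they exist only to check the package's implementations on small instances.

pairs_of_ <- function(n) {
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

oracle_pair_counts <- function(x, labels) {
  d <- as.matrix(dist(x))
  p <- pairs_of_(nrow(x))
  dd <- d[p]
  within <- labels[p[, 1]] == labels[p[, 2]]
  dw <- dd[within]; db <- dd[!within]
  s_plus <- 0; s_minus <- 0
  for (w in dw) for (b in db) {
    if (w < b) s_plus <- s_plus + 1
    else if (w > b) s_minus <- s_minus + 1
  }
  list(s_plus = s_plus, s_minus = s_minus, n_w = length(dw),
       n_b = length(db), n_t = length(dd))
}

oracle_c_index <- function(x, labels) {
  d <- as.matrix(dist(x))
  p <- pairs_of_(nrow(x))
  dd <- d[p]
  within <- labels[p[, 1]] == labels[p[, 2]]
  nw <- sum(within)
  s <- sum(dd[within])
  srt <- sort(dd)
  (s - sum(head(srt, nw))) / (sum(tail(srt, nw)) - sum(head(srt, nw)))
}

oracle_gdi31 <- function(x, labels) {
  d <- as.matrix(dist(x))
  ks <- sort(unique(labels))
  diam <- sapply(ks, function(k) {
    ii <- which(labels == k)
    if (length(ii) < 2) 0 else max(d[ii, ii])
  })
  seps <- c()
  for (i in seq_along(ks)) for (j in seq_along(ks)) {
    if (i < j)
      seps <- c(seps, mean(d[labels == ks[i], labels == ks[j]]))
  }
  min(seps) / max(diam)
}

oracle_point_biserial <- function(x, labels) {
  d <- as.matrix(dist(x))
  p <- pairs_of_(nrow(x))
  dd <- d[p]
  between <- as.numeric(labels[p[, 1]] != labels[p[, 2]])
  cor(dd, between)
}

oracle_silhouette <- function(x, labels) {
  d <- as.matrix(dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(sapply(setdiff(unique(labels), labels[i]),
                    function(k) mean(d[i, labels == k])))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Random instance with guaranteed-nonempty clusters.
random_instance <- function(n, k, d = 2) {
  labels <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
  x <- matrix(rnorm(n * d), n, d) + labels
  list(x = x, labels = labels)
}

make_blobs <- function(n_per, centers, sd = 0.1) {
  k <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(j)
    sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), n_per), 2,
          centers[j, ], "+")))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

make_rings <- function(n_per, radii = c(1, 4), noise = 0.08) {
  x <- do.call(rbind, lapply(radii, function(r) {
    th <- runif(n_per, 0, 2 * pi)
    cbind(r * cos(th), r * sin(th)) + matrix(rnorm(2 * n_per, sd = noise),
                                             n_per)
  }))
  list(x = x, labels = rep(seq_along(radii), each = n_per))
}

# Planted five-prototype trait data in z-space (clean latent traits).
planted_traits <- function(n = 2000, within_sd = 0.4, seed = 1) {
  cfg <- generator_config(n_persons = n, within_sd = within_sd,
                          item_noise_sd = 0, seed = seed)
  pop <- generate_population(cfg)
  list(z = scale(pop$traits_true), labels = pop$true_labels, pop = pop)
}
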