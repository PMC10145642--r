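# Independent oracles and small fixture generators used across the suite.
# Everything here is computed from first principles (plain sums over the
# histogram), deliberately not reusing the package's cumulative-sum path.

# Random two-population grayscale image with a dense, overlapping histogram
# (no empty-bin plateaus around the optimum).
rand_bimodal_image <- function(seed, n = 64L) {
  set.seed(seed)
  m1 <- runif(1, 50, 100); m2 <- runif(1, 150, 220); s <- runif(1, 15, 30)
  v <- round(c(rnorm(n * n / 2, m1, s), rnorm(n * n / 2, m2, s)))
  matrix(pmin(pmax(as.integer(v), 0L), 255L), n, n)
}

rand_histogram <- function(seed, levels = 256L) {
  set.seed(seed)
  counts <- as.integer(rpois(levels, lambda = runif(levels, 0, 20)))
  if (sum(counts) == 0L) counts[1L] <- 1L
  structure(list(counts = counts, prob = counts / sum(counts),
                 levels = as.integer(levels)),
            class = "intensity_histogram")
}

# Exhaustive single-threshold Otsu by direct summation; contiguous ties are
# resolved to the plateau midpoint (the classical averaged-optimum rule).
brute_otsu_scan <- function(h) {
  P <- h$counts / sum(h$counts)
  lev <- seq_along(P) - 1
  muT <- sum(lev * P)
  f1 <- vapply(seq_len(h$levels - 1L), function(t) {
    w0 <- sum(P[seq_len(t)]); w1 <- 1 - w0
    m0 <- if (w0 > 0) sum(lev[seq_len(t)] * P[seq_len(t)]) / w0 else 0
    m1 <- if (w1 > 0) sum(lev[-seq_len(t)] * P[-seq_len(t)]) / w1 else 0
    w0 * (m0 - muT)^2 + w1 * (m1 - muT)^2
  }, numeric(1))
  ties <- which(abs(f1 - max(f1)) < 1e-12)
  as.integer(round(mean(range(ties))))
}

# Kapur objective by direct double summation.
brute_kapur <- function(h, tv) {
  P <- h$counts / sum(h$counts)
  bounds <- c(0L, as.integer(tv), h$levels)
  total <- 0
  for (r in seq_len(length(tv) + 1L)) {
    idx <- seq.int(bounds[r] + 1L, bounds[r + 1L])
    w <- sum(P[idx])
    if (w <= 0) next
    for (p in P[idx]) {
      if (p > 0) total <- total - (p / w) * log(p / w)
    }
  }
  total
}

# O(n^2) mutual non-dominance scan of a fitness matrix (maximisation).
is_mutually_nondominated <- function(F) {
  n <- nrow(F)
  if (n <= 1L) return(TRUE)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && all(F[j, ] >= F[i, ]) && any(F[j, ] > F[i, ])) return(FALSE)
    }
  }
  TRUE
}

sort_rows_ref <- function(X) cbind(pmin(X[, 1], X[, 2]), pmax(X[, 1], X[, 2]))

# Small swarm configuration for fast unit tests (full defaults are used in
# the acceptance suite).
quick_swarm <- function(n_particles = 40L, n_iterations = 60L, ...) {
  swarm_config(n_particles = n_particles, n_iterations = n_iterations, ...)
}
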