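#' Intensity histogram of a grayscale image
#'
#' @param img Integer matrix with values in \[0, levels - 1\].
#' @param levels Number of intensity levels (default 256).
#' @return Object of class `intensity_histogram`: a list with `counts`
#'   (length `levels`), `prob` (normalised counts) and `levels`.
#' @export
intensity_histogram <- function(img, levels = 256L) {
  v <- as.vector(img)
  if (length(v) == 0L) stop("empty image")
  if (any(v < 0 | v > levels - 1L)) stop("intensities outside [0, levels - 1]")
  counts <- tabulate(v + 1L, nbins = levels)
  structure(
    list(counts = counts, prob = counts / sum(counts), levels = as.integer(levels)),
    class = "intensity_histogram"
  )
}

#' Rebin a histogram to fewer intensity levels
#'
#' Aggregates adjacent bins so a 256-level histogram becomes, e.g., a
#' 64-level one; used for small-instance exhaustive searches.
#'
#' @param h An `intensity_histogram`.
#' @param levels Target number of levels; must divide `h$levels`.
#' @return An `intensity_histogram` with `levels` bins.
#' @export
downsample_histogram <- function(h, levels) {
  stopifnot(inherits(h, "intensity_histogram"))
  if (h$levels %% levels != 0L) stop("`levels` must divide h$levels")
  f <- h$levels %/% levels
  counts <- as.vector(rowsum(h$counts, rep(seq_len(levels), each = f)))
  structure(
    list(counts = counts, prob = counts / sum(counts), levels = as.integer(levels)),
    class = "intensity_histogram"
  )
}

check_thresholds <- function(h, tv) {
  tv <- as.integer(tv)
  if (length(tv) < 1L) stop("at least one threshold required")
  if (is.unsorted(tv, strictly = FALSE)) stop("thresholds must be sorted ascending")
  if (any(tv < 1L) || any(tv > h$levels - 1L)) {
    stop(sprintf("thresholds must lie in [1, %d]", h$levels - 1L))
  }
  tv
}

#' Per-region probability masses and mean intensities
#'
#' `k` thresholds split the intensity range into `k + 1` regions; region `r`
#' covers levels `[t[r-1], t[r] - 1]` with `t[0] = 0` and the last region
#' ending at `levels - 1`. Returns the region probability masses `omega`,
#' region means `mu` (0 for empty regions), and the global mean `mu_total`.
#' The identities `sum(omega) == 1` and `sum(omega * mu) == mu_total` hold
#' exactly.
#'
#' @param h An `intensity_histogram`.
#' @param tv Sorted integer thresholds in `[1, levels - 1]`.
#' @return List with `omega`, `mu` (length `k + 1`) and `mu_total`.
#' @export
region_stats <- function(h, tv) {
  tv <- check_thresholds(h, tv)
  P <- h$prob
  lev <- seq_len(h$levels) - 1
  bounds <- c(0L, tv, h$levels)
  k1 <- length(tv) + 1L
  omega <- numeric(k1); mu <- numeric(k1)
  for (r in seq_len(k1)) {
    idx <- seq.int(bounds[r] + 1L, bounds[r + 1L])  # 1-based over [t_{r-1}, t_r - 1]
    if (bounds[r] >= bounds[r + 1L]) next
    omega[r] <- sum(P[idx])
    if (omega[r] > 0) mu[r] <- sum(lev[idx] * P[idx]) / omega[r]
  }
  list(omega = omega, mu = mu, mu_total = sum(lev * P))
}

#' Otsu between-class variance objective
#'
#' `f1 = sum_r omega_r * (mu_r - mu_T)^2`, to be maximised. Empty regions
#' contribute 0.
#'
#' @inheritParams region_stats
#' @return Non-negative scalar.
#' @export
otsu_objective <- function(h, tv) {
  rs <- region_stats(h, tv)
  sum(rs$omega * (rs$mu - rs$mu_total)^2)
}

#' Kapur between-class entropy objective
#'
#' Sum over regions of the Shannon entropy of the region-normalised
#' intensity distribution: `KH_r = -sum_i (P_i/omega_r) ln(P_i/omega_r)`.
#' Zero-probability levels and empty regions contribute 0.
#'
#' @inheritParams region_stats
#' @return Scalar entropy sum (natural log).
#' @export
kapur_objective <- function(h, tv) {
  tv <- check_thresholds(h, tv)
  P <- h$prob
  bounds <- c(0L, tv, h$levels)
  total <- 0
  for (r in seq_len(length(tv) + 1L)) {
    if (bounds[r] >= bounds[r + 1L]) next
    p <- P[seq.int(bounds[r] + 1L, bounds[r + 1L])]
    w <- sum(p)
    if (w <= 0) next
    q <- p[p > 0] / w
    total <- total - sum(q * log(q))
  }
  total
}

#' Renyi entropy objective
#'
#' Sum over regions of `RH_r = (1/(1 - alpha)) * ln sum_i (P_i/omega_r)^alpha`,
#' the one-parameter generalisation of Shannon entropy; as `alpha -> 1` it
#' converges to the Kapur objective. Empty regions contribute 0.
#'
#' @inheritParams region_stats
#' @param alpha Renyi order, > 0 and != 1. Default 2.
#' @return Scalar entropy sum (natural log).
#' @export
renyi_objective <- function(h, tv, alpha = 2) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("`alpha` must be a positive number")
  }
  if (alpha == 1) stop("alpha == 1 is Shannon entropy; use kapur_objective()")
  tv <- check_thresholds(h, tv)
  P <- h$prob
  bounds <- c(0L, tv, h$levels)
  total <- 0
  for (r in seq_len(length(tv) + 1L)) {
    if (bounds[r] >= bounds[r + 1L]) next
    p <- P[seq.int(bounds[r] + 1L, bounds[r + 1L])]
    w <- sum(p)
    if (w <= 0) next
    total <- total + log(sum((p[p > 0] / w)^alpha)) / (1 - alpha)
  }
  total
}

#' Evaluate all three objectives for one threshold vector
#'
#' @inheritParams renyi_objective
#' @return Named numeric vector `c(otsu = , kapur = , renyi = )`.
#' @export
evaluate_objectives <- function(h, tv, alpha = 2) {
  c(otsu = otsu_objective(h, tv),
    kapur = kapur_objective(h, tv),
    renyi = renyi_objective(h, tv, alpha))
}

# Precompute cumulative tables so each (region, objective) evaluation is O(1).
# Used by the swarm engine and by exhaustive grid searches.
precompute_objectives <- function(h, alpha = 2) {
  P <- h$prob
  lev <- seq_len(h$levels) - 1
  plogp <- ifelse(P > 0, P * log(P), 0)
  list(
    levels = h$levels,
    mu_total = sum(lev * P),
    csP = c(0, cumsum(P)),
    csIP = c(0, cumsum(lev * P)),
    csPlogP = c(0, cumsum(plogp)),
    csPalpha = c(0, cumsum(P^alpha)),
    alpha = alpha
  )
}

# Vectorised fitness for a matrix of integer threshold vectors (n x k, each
# row sorted, values in [1, levels - 1]; equal adjacent thresholds denote an
# empty region). Returns an n x 3 matrix (otsu, kapur, renyi).
eval_fitness_matrix <- function(pre, T, objectives = c("otsu", "kapur", "renyi")) {
  T <- matrix(as.integer(T), nrow = NROW(T))
  n <- nrow(T); k <- ncol(T)
  L <- pre$levels
  lower <- cbind(matrix(0L, n, 1L), T)        # region starts t_{r-1}
  upper <- cbind(T, matrix(L, n, 1L))         # region ends are upper - 1
  f1 <- numeric(n); f2 <- numeric(n); f3 <- numeric(n)
  a1 <- pre$alpha
  for (r in seq_len(k + 1L)) {
    a <- lower[, r]; b <- upper[, r]
    w <- pre$csP[b + 1L] - pre$csP[a + 1L]
    pos <- w > 0
    if ("otsu" %in% objectives) {
      sIP <- pre$csIP[b + 1L] - pre$csIP[a + 1L]
      mu <- ifelse(pos, sIP / pmax(w, .Machine$double.xmin), 0)
      f1 <- f1 + ifelse(pos, w * (mu - pre$mu_total)^2, 0)
    }
    if ("kapur" %in% objectives) {
      sPlogP <- pre$csPlogP[b + 1L] - pre$csPlogP[a + 1L]
      f2 <- f2 + ifelse(pos, -sPlogP / pmax(w, .Machine$double.xmin) + log(pmax(w, .Machine$double.xmin)), 0)
    }
    if ("renyi" %in% objectives) {
      sPa <- pre$csPalpha[b + 1L] - pre$csPalpha[a + 1L]
      f3 <- f3 + ifelse(pos,
                        (log(pmax(sPa, .Machine$double.xmin)) -
                           a1 * log(pmax(w, .Machine$double.xmin))) / (1 - a1),
                        0)
    }
  }
  out <- cbind(otsu = f1, kapur = f2, renyi = f3)
  out[, objectives, drop = FALSE]
}
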