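#' Exhaustive multilevel threshold search
#'
#' Enumerates every strictly increasing threshold vector of length `k` over
#' the histogram's levels, scores each on the requested objectives, and
#' returns the vector maximising the Euclidean distance of the fitness
#' vector from the objective-space origin (for a single objective this is
#' simply the objective's maximum, e.g. classical exhaustive Otsu). Feasible
#' for small `k` or downsampled histograms; the swarm search exists because
#' this enumeration explodes combinatorially.
#'
#' @param h An `intensity_histogram`.
#' @param k Number of thresholds.
#' @param objectives Character subset of `c("otsu", "kapur", "renyi")`.
#' @param alpha Renyi order.
#' @return List with `thresholds`, `fitness` and `distance`.
#' @export
exhaustive_thresholds <- function(h, k = 2L,
                                  objectives = c("otsu", "kapur", "renyi"),
                                  alpha = 2) {
  stopifnot(inherits(h, "intensity_histogram"))
  L <- h$levels
  T <- as.matrix(do.call(expand.grid, rep(list(seq_len(L - 1L)), k)))
  if (k > 1L) {
    ok <- rep(TRUE, nrow(T))
    for (j in seq_len(k - 1L)) ok <- ok & T[, j] < T[, j + 1L]
    T <- T[ok, , drop = FALSE]
  }
  pre <- precompute_objectives(h, alpha)
  F <- eval_fitness_matrix(pre, T, objectives)
  d <- sqrt(rowSums(F^2))
  i <- which.max(d)
  tv <- center_tie_plateau(pre, as.integer(T[i, ]), objectives)
  list(thresholds = tv, fitness = F[i, ], distance = d[i])
}
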