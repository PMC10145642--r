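#' Synthetic H&E-like nuclei image with exact ground truth
#'
#' Generates a histology-like RGB fixture: dark, purple-tinted elliptical
#' "nuclei" on a brighter pink-tinted "stroma" background, with Gaussian
#' texture noise, plus the exact binary ground-truth mask and the nucleus
#' centres. Nuclei are placed without overlap by rejection sampling.
#' Intensity defaults emulate a well-stained, high-contrast H&E field:
#' hematoxylin-dark nuclei (mode 80) on eosin-bright stroma (mode 190).
#'
#' @param shape `c(H, W)` image size. Default `c(128, 128)`.
#' @param n_nuclei Number of nuclei. Default 12.
#' @param radius_range Ellipse semi-axis range in pixels. Default `c(6, 12)`.
#' @param nucleus_mode,nucleus_sd Nucleus intensity mode and spread.
#' @param background_mode,background_sd Background intensity mode and spread.
#' @param noise_sd Additive Gaussian texture noise.
#' @param nucleus_tint,background_tint RGB chroma multipliers (internally
#'   normalised to preserve luminance) giving the purple/pink cast.
#' @param seed Integer seed; fixtures are fully deterministic under it.
#' @param max_attempts Rejection-sampling cap for non-overlapping placement.
#' @return List with `image` (`H x W x 3` integer array), `mask` (logical
#'   ground truth), `centres` (matrix of row/col centres).
#' @export
make_nuclei_image <- function(shape = c(128L, 128L), n_nuclei = 12L,
                              radius_range = c(6, 12),
                              nucleus_mode = 80, nucleus_sd = 10,
                              background_mode = 190, background_sd = 10,
                              noise_sd = 5,
                              nucleus_tint = c(1.05, 0.75, 1.55),
                              background_tint = c(1.25, 0.9, 0.85),
                              seed = NULL, max_attempts = 2000L) {
  stopifnot(length(shape) == 2L, all(shape >= 8L), n_nuclei >= 0,
            nucleus_mode >= 0, nucleus_mode <= 255,
            background_mode >= 0, background_mode <= 255)
  if (nucleus_mode >= background_mode) {
    stop("nuclei must be darker than the background (nucleus_mode < background_mode)")
  }
  if (!is.null(seed)) set.seed(seed)
  H <- shape[1L]; W <- shape[2L]
  mask <- matrix(FALSE, H, W)
  centres <- matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("row", "col")))
  params <- list()
  attempts <- 0L
  while (nrow(centres) < n_nuclei) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("could not place all nuclei without overlap; use fewer or smaller nuclei")
    }
    a <- stats::runif(1, radius_range[1L], radius_range[2L])
    b <- stats::runif(1, radius_range[1L], radius_range[2L])
    cx <- stats::runif(1, a + 1, H - a - 1)
    cy <- stats::runif(1, b + 1, W - b - 1)
    theta <- stats::runif(1, 0, pi)
    ok <- TRUE
    for (q in params) {
      if (sqrt((cx - q$cx)^2 + (cy - q$cy)^2) < (max(a, b) + max(q$a, q$b) + 1)) {
        ok <- FALSE; break
      }
    }
    if (!ok) next
    params[[length(params) + 1L]] <- list(cx = cx, cy = cy, a = a, b = b, theta = theta)
    centres <- rbind(centres, c(cx, cy))
  }
  X <- matrix(rep(seq_len(H), W), H, W)
  Y <- matrix(rep(seq_len(W), each = H), H, W)
  for (q in params) {
    dx <- X - q$cx; dy <- Y - q$cy
    u <- dx * cos(q$theta) + dy * sin(q$theta)
    v <- -dx * sin(q$theta) + dy * cos(q$theta)
    mask <- mask | ((u / q$a)^2 + (v / q$b)^2 <= 1)
  }
  gray <- matrix(stats::rnorm(H * W, background_mode, background_sd), H, W)
  if (any(mask)) gray[mask] <- stats::rnorm(sum(mask), nucleus_mode, nucleus_sd)
  gray <- gray + stats::rnorm(H * W, 0, noise_sd)
  lum <- c(0.299, 0.587, 0.114)
  tint_n <- nucleus_tint / sum(lum * nucleus_tint)
  tint_b <- background_tint / sum(lum * background_tint)
  img <- array(0, c(H, W, 3L))
  for (ch in 1:3) {
    tint <- ifelse(mask, tint_n[ch], tint_b[ch])
    img[, , ch] <- gray * tint
  }
  img <- round(img); img[img < 0] <- 0; img[img > 255] <- 255
  storage.mode(img) <- "integer"
  list(image = img, mask = mask, centres = centres)
}

# Intersection of two Gaussian densities w1 N(m1, s1) and w2 N(m2, s2)
# between their means: the optimal decision boundary of the mixture.
gaussian_valley <- function(m1, s1, w1, m2, s2, w2) {
  if (s1 == s2) {
    return((m1 + m2) / 2 + s1^2 * log(w1 / w2) / (m2 - m1))
  }
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log((w1 * s2) / (w2 * s1))
  roots <- Re(polyroot(c(cc, b, a)))
  roots[roots > m1 & roots < m2][1L]
}

#' Synthetic trimodal grayscale image with analytic valley thresholds
#'
#' Pixels are drawn i.i.d. from a three-component Gaussian mixture and
#' clamped to \[0, 255\]. Used to test threshold recovery: the analytic
#' between-mode decision boundaries (density intersections; midpoints for
#' equal spreads and weights) are returned as the recovery targets. The
#' default size of 10^6 pixels is chosen so the empirical histogram
#' populates the inter-mode tails well enough to localise the valleys.
#'
#' @param modes Three strictly increasing intensity modes.
#' @param sigmas Component spreads (scalar or length 3).
#' @param weights Mixture weights (normalised internally).
#' @param shape `c(H, W)`. Default `c(1000, 1000)`.
#' @param seed Integer seed.
#' @return List with `image` (integer matrix) and `valleys` (two analytic
#'   thresholds).
#' @export
make_trimodal_image <- function(modes = c(40, 128, 215), sigmas = 8,
                                weights = c(1, 1, 1) / 3,
                                shape = c(1000L, 1000L), seed = NULL) {
  if (length(modes) != 3L || is.unsorted(modes, strictly = TRUE)) {
    stop("`modes` must be three strictly increasing intensities")
  }
  sigmas <- rep_len(sigmas, 3L)
  weights <- rep_len(weights, 3L); weights <- weights / sum(weights)
  if (any(diff(modes) < 4 * pmax(sigmas[-3L], sigmas[-1L]))) {
    stop("modes overlap: separation must be at least 4 sigma")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- shape[1L] * shape[2L]
  comp <- sample.int(3L, n, replace = TRUE, prob = weights)
  v <- stats::rnorm(n, modes[comp], sigmas[comp])
  v <- round(v); v[v < 0] <- 0; v[v > 255] <- 255
  img <- matrix(as.integer(v), shape[1L], shape[2L])
  valleys <- c(
    gaussian_valley(modes[1L], sigmas[1L], weights[1L], modes[2L], sigmas[2L], weights[2L]),
    gaussian_valley(modes[2L], sigmas[2L], weights[2L], modes[3L], sigmas[3L], weights[3L])
  )
  list(image = img, valleys = valleys)
}
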