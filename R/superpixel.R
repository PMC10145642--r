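#' Superpixel configuration
#'
#' Parameters of the SLIC-style local clustering stage. `n_superpixels` is
#' the expected cluster count; the default 1000 suits whole-slide crops
#' where individual nuclei are small relative to the frame. `compactness`
#' (p) weights the spatial term of the combined distance
#' `Dm = dRGB + (p/S) * dXY`: larger values give more compact, grid-like
#' clusters.
#'
#' @param n_superpixels Expected number of clusters (nc).
#' @param compactness Compactness weight p (> 0), on the 0-255 colour scale.
#' @param max_iter Iteration cap for the assign/update loop.
#' @param e_tol Residual-error stopping threshold: iteration stops once the
#'   summed centre displacement E drops to `e_tol` or below.
#' @return Object of class `superpixel_config`.
#' @export
superpixel_config <- function(n_superpixels = 1000L, compactness = 10,
                              max_iter = 10L, e_tol = 1) {
  stopifnot(n_superpixels >= 1, compactness > 0, max_iter >= 1, e_tol >= 0)
  structure(
    list(n_superpixels = as.integer(n_superpixels), compactness = compactness,
         max_iter = as.integer(max_iter), e_tol = e_tol),
    class = "superpixel_config"
  )
}

#' Initial superpixel centres on a regular grid
#'
#' Places centres with spacing `S = sqrt(np / nc)` (so each cluster is
#' expected to hold `np / nc` pixels), each seeded with the colour and
#' coordinates of the pixel at its grid point.
#'
#' @param img `H x W x 3` integer RGB array.
#' @param nc Expected number of superpixels; at most the pixel count.
#' @return List with `centers` (matrix with columns R, G, B, X, Y; X = row,
#'   Y = column) and spacing `S`.
#' @export
init_centers <- function(img, nc) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  np <- H * W
  if (nc > np) stop("`nc` exceeds the number of pixels")
  S <- sqrt(np / nc)
  # floor(H/S) * floor(W/S) <= H*W/S^2 = nc, so the centre count never
  # exceeds the requested nc
  nx <- max(1L, floor(H / S)); ny <- max(1L, floor(W / S))
  xs <- unique(pmin(pmax(round((seq_len(nx) - 0.5) * H / nx), 1L), H))
  ys <- unique(pmin(pmax(round((seq_len(ny) - 0.5) * W / ny), 1L), W))
  gr <- expand.grid(X = xs, Y = ys)
  centers <- cbind(
    R = img[cbind(gr$X, gr$Y, 1L)],
    G = img[cbind(gr$X, gr$Y, 2L)],
    B = img[cbind(gr$X, gr$Y, 3L)],
    X = gr$X, Y = gr$Y
  )
  list(centers = centers, S = S)
}

#' Assign pixels to superpixel centres
#'
#' Each pixel is assigned to the centre, among those whose `2S x 2S`
#' neighbourhood contains it, minimising `Dm = dRGB + (p/S) * dXY`, where
#' dRGB is the Euclidean colour distance and dXY the Euclidean spatial
#' distance. A pixel covered by no window falls back to the globally
#' nearest centre under the same distance.
#'
#' @param img `H x W x 3` integer RGB array.
#' @param centers Centre matrix (columns R, G, B, X, Y).
#' @param S Grid spacing.
#' @param p Compactness weight.
#' @param window If FALSE, search all centres for every pixel (the
#'   exhaustive reference used to validate the windowed search).
#' @return `H x W` integer label matrix with values in `[1, nrow(centers)]`.
#' @export
assign_pixels <- function(img, centers, S, p, window = TRUE) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  R <- img[, , 1L]; G <- img[, , 2L]; B <- img[, , 3L]
  Xc <- matrix(rep(seq_len(H), W), H, W)
  Yc <- matrix(rep(seq_len(W), each = H), H, W)
  best <- matrix(Inf, H, W)
  labels <- matrix(0L, H, W)
  rad <- if (window) S else Inf
  for (j in seq_len(nrow(centers))) {
    cj <- centers[j, ]
    x0 <- max(1L, ceiling(cj["X"] - rad)); x1 <- min(H, floor(cj["X"] + rad))
    y0 <- max(1L, ceiling(cj["Y"] - rad)); y1 <- min(W, floor(cj["Y"] + rad))
    if (x0 > x1 || y0 > y1) next
    xi <- x0:x1; yi <- y0:y1
    dRGB <- sqrt((R[xi, yi, drop = FALSE] - cj["R"])^2 +
                 (G[xi, yi, drop = FALSE] - cj["G"])^2 +
                 (B[xi, yi, drop = FALSE] - cj["B"])^2)
    dXY <- sqrt((Xc[xi, yi, drop = FALSE] - cj["X"])^2 +
                (Yc[xi, yi, drop = FALSE] - cj["Y"])^2)
    D <- dRGB + (p / S) * dXY
    upd <- D < best[xi, yi, drop = FALSE]
    if (any(upd)) {
      bsub <- best[xi, yi, drop = FALSE]; lsub <- labels[xi, yi, drop = FALSE]
      bsub[upd] <- D[upd]; lsub[upd] <- j
      best[xi, yi] <- bsub; labels[xi, yi] <- lsub
    }
  }
  if (any(labels == 0L)) {
    # pixels outside every window: global nearest-centre fallback
    miss <- which(labels == 0L)
    for (i in miss) {
      x <- Xc[i]; y <- Yc[i]
      d <- sqrt((centers[, "R"] - R[i])^2 + (centers[, "G"] - G[i])^2 +
                (centers[, "B"] - B[i])^2) +
           (p / S) * sqrt((centers[, "X"] - x)^2 + (centers[, "Y"] - y)^2)
      labels[i] <- which.min(d)
    }
  }
  labels
}

#' Recompute superpixel centres from an assignment
#'
#' New centres are the component-wise means of member pixels in
#' (R, G, B, X, Y); clusters that lost every pixel are dropped (which is how
#' the realised cluster count nc' falls below nc). The residual error E is
#' the sum over surviving clusters of the Euclidean distance between old and
#' new centre vectors.
#'
#' @param img `H x W x 3` integer RGB array.
#' @param labels `H x W` integer label matrix.
#' @param old_centers Previous centre matrix (rows indexed by label).
#' @return List with `centers`, `E`, and `relabel` (map old -> new labels).
#' @export
update_centers <- function(img, labels, old_centers) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  lv <- as.vector(labels)
  feat <- cbind(
    R = as.vector(img[, , 1L]), G = as.vector(img[, , 2L]),
    B = as.vector(img[, , 3L]),
    X = rep(seq_len(H), W), Y = rep(seq_len(W), each = H)
  )
  sums <- rowsum(feat, lv)
  cnt <- as.vector(table(factor(lv, levels = sort(unique(lv)))))
  centers <- sums / cnt
  surviving <- as.integer(rownames(sums))
  E <- sum(sqrt(rowSums((centers - old_centers[surviving, , drop = FALSE])^2)))
  relabel <- integer(nrow(old_centers))
  relabel[surviving] <- seq_along(surviving)
  colnames(centers) <- colnames(old_centers)
  list(centers = centers, E = E, relabel = relabel)
}

#' SLIC-style superpixel clustering
#'
#' Local k-means in joint colour-space coordinates: centres start on a
#' regular grid with spacing `S = sqrt(np/nc)`, pixels are assigned within
#' `2S x 2S` windows by the combined distance `Dm = dRGB + (p/S) dXY`, and
#' centres are recomputed until the summed centre displacement E reaches
#' `e_tol` or `max_iter` passes. No connectivity enforcement is applied.
#'
#' @param img `H x W x 3` integer RGB array.
#' @param cfg A [superpixel_config()].
#' @return Object of class `superpixel_result`: `labels` (`H x W` integers
#'   in `[1, nc_actual]`), `centers`, `nc_actual`, `S`, `iterations`, `E`.
#' @export
run_superpixel <- function(img, cfg = superpixel_config()) {
  stopifnot(inherits(cfg, "superpixel_config"))
  ini <- init_centers(img, cfg$n_superpixels)
  centers <- ini$centers
  S <- ini$S
  labels <- NULL
  E <- Inf
  it <- 0L
  while (it < cfg$max_iter && E > cfg$e_tol) {
    it <- it + 1L
    labels <- assign_pixels(img, centers, S, cfg$compactness)
    up <- update_centers(img, labels, centers)
    labels <- matrix(up$relabel[labels], nrow(labels), ncol(labels))
    centers <- up$centers
    E <- up$E
  }
  structure(
    list(labels = labels, centers = centers, nc_actual = nrow(centers),
         S = S, iterations = it, E = E),
    class = "superpixel_result"
  )
}

#' Threshold-guided cluster refinement
#'
#' Keeps exactly those superpixels whose mean pre-processed intensity is
#' below the dark threshold `t1` from the swarm search: the output mask
#' starts all-zero and each qualifying cluster contributes all of its
#' pixels, so the mask is always a union of whole clusters.
#'
#' @param sp A `superpixel_result`.
#' @param ipre Pre-processed grayscale image, same shape as the labels.
#' @param t1 Dark threshold from the swarm search.
#' @return Logical mask (`H x W`).
#' @export
refine_clusters <- function(sp, ipre, t1) {
  stopifnot(inherits(sp, "superpixel_result"))
  if (!all(dim(sp$labels) == dim(ipre))) {
    stop("label map and image shapes differ")
  }
  means <- as.vector(rowsum(as.vector(ipre), as.vector(sp$labels))) /
    as.vector(table(factor(as.vector(sp$labels), levels = seq_len(sp$nc_actual))))
  keep <- means < t1
  matrix(keep[sp$labels], nrow(ipre), ncol(ipre))
}

#' @export
print.superpixel_result <- function(x, ...) {
  cat(sprintf("Superpixel clustering: %d clusters (%d x %d labels), %d iterations, E = %.3f\n",
              x$nc_actual, nrow(x$labels), ncol(x$labels), x$iterations, x$E))
  invisible(x)
}
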