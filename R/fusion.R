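#' Merge the threshold map with the refined superpixel map
#'
#' Pixelwise union: the whole-cluster support from the superpixel route is
#' added to the dark-class threshold map, smoothing ragged ROI borders.
#'
#' @param i1 Logical mask from the threshold route (dark class I1).
#' @param ithresh Logical mask from superpixel refinement.
#' @return Logical mask, the union.
#' @export
merge_maps <- function(i1, ithresh) {
  if (!all(dim(i1) == dim(ithresh))) stop("mask shapes differ")
  i1 | ithresh
}

#' 8-connected component labelling of a binary mask
#'
#' @param mask Logical matrix.
#' @return Integer matrix; 0 for background, components numbered from 1.
#' @export
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  off_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  cur <- 0L
  todo <- which(mask)
  for (seed in todo) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    frontier <- seed
    lab[seed] <- cur
    while (length(frontier)) {
      r <- (frontier - 1L) %% H + 1L
      c <- (frontier - 1L) %/% H + 1L
      nr <- rep(r, times = 8L) + rep(off_r, each = length(r))
      nc <- rep(c, times = 8L) + rep(off_c, each = length(r))
      ok <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
      nb <- unique((nc[ok] - 1L) * H + nr[ok])
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

#' Post-processing configuration
#'
#' @param min_roi_area Connected components smaller than this (pixels) are
#'   removed. Default 30.
#' @param smooth_radius Disk radius (pixels) for the morphological
#'   opening-then-closing that smooths ROI edges; 0 disables smoothing.
#'   Default 2.
#' @param fill_holes Fill background holes enclosed by foreground.
#' @return Object of class `postprocess_config`.
#' @export
postprocess_config <- function(min_roi_area = 30L, smooth_radius = 2L,
                               fill_holes = TRUE) {
  stopifnot(min_roi_area >= 0, smooth_radius >= 0)
  structure(
    list(min_roi_area = as.integer(min_roi_area),
         smooth_radius = as.integer(smooth_radius),
         fill_holes = isTRUE(fill_holes)),
    class = "postprocess_config"
  )
}

#' Clean a merged segmentation mask
#'
#' In order: (1) fill holes enclosed by foreground, (2) smooth edges by
#' morphological opening then closing with a disk structuring element,
#' (3) remove 8-connected components with area below `min_roi_area`.
#'
#' @param mask Logical matrix.
#' @param cfg A [postprocess_config()].
#' @return Logical matrix of the same shape.
#' @export
postprocess_mask <- function(mask, cfg = postprocess_config()) {
  stopifnot(is.matrix(mask))
  m <- mask
  if (cfg$fill_holes) {
    m <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(m * 1)))) ) > 0.5
  }
  if (cfg$smooth_radius > 0) {
    brush <- EBImage::makeBrush(2L * cfg$smooth_radius + 1L, shape = "disc")
    e <- EBImage::Image(t(m * 1))
    e <- EBImage::closing(EBImage::opening(e, brush), brush)
    m <- t(EBImage::imageData(e)) > 0.5
  }
  if (cfg$min_roi_area > 0 && any(m)) {
    lab <- label_components(m)
    areas <- tabulate(lab[lab > 0L])
    small <- which(areas < cfg$min_roi_area)
    if (length(small)) m[lab %in% small] <- FALSE
  }
  m
}

#' Full segmentation pipeline
#'
#' Runs the two routes and fuses them: (route 1) grayscale + CLAHE
#' pre-processing, multiobjective swarm threshold search, dark-class map I1;
#' (route 2) SLIC-style superpixels on the RGB image, refined by the dark
#' threshold t1. The union of the two maps is morphologically
#' post-processed into the final mask.
#'
#' @param img `H x W x 3` integer RGB array (or a path readable by
#'   [read_image()]).
#' @param swarm_cfg A [swarm_config()].
#' @param sp_cfg A [superpixel_config()].
#' @param pp_cfg A [postprocess_config()].
#' @param clip_limit,tile_grid CLAHE parameters, see [enhance_contrast()].
#' @param seed Integer seed governing all randomness in the run; identical
#'   seeds give identical masks.
#' @return Object of class `mmpsos_segmentation`: `mask` (final logical
#'   mask), `thresholds`, intermediate maps `i1`, `ithresh`, `imerge`, the
#'   `superpixels` result, and a `report` list.
#' @export
run_pipeline <- function(img, swarm_cfg = swarm_config(),
                         sp_cfg = superpixel_config(),
                         pp_cfg = postprocess_config(),
                         clip_limit = 0.01, tile_grid = c(8, 8),
                         seed = NULL) {
  if (is.character(img)) img <- read_image(img)
  if (!is.null(seed)) set.seed(seed)
  swarm_cfg$seed <- NULL  # one seed governs the whole run
  t0 <- proc.time()[["elapsed"]]

  ipre <- tryCatch(preprocess_image(img, clip_limit, tile_grid),
                   error = function(e) stop("imageprep: ", conditionMessage(e)))
  res <- tryCatch(run_mmpso(ipre, swarm_cfg),
                  error = function(e) stop("mopso: ", conditionMessage(e)))
  t1 <- res$thresholds[1L]; t2 <- res$thresholds[length(res$thresholds)]
  maps <- apply_thresholds(ipre, t1, t2)
  t_swarm <- proc.time()[["elapsed"]]

  sp <- tryCatch(run_superpixel(img, sp_cfg),
                 error = function(e) stop("superpixel: ", conditionMessage(e)))
  ithresh <- refine_clusters(sp, ipre, t1)
  t_sp <- proc.time()[["elapsed"]]

  imerge <- merge_maps(maps$I1, ithresh)
  mask <- postprocess_mask(imerge, pp_cfg)
  t_end <- proc.time()[["elapsed"]]

  structure(
    list(mask = mask, thresholds = c(t1 = t1, t2 = t2),
         i1 = maps$I1, i2 = maps$I2, i3 = maps$I3,
         ithresh = ithresh, imerge = imerge,
         superpixels = sp, swarm = res, ipre = ipre,
         report = list(
           thresholds = c(t1 = t1, t2 = t2),
           best_fitness = res$fitness,
           archive_size = archive_size(res$archive),
           nc_actual = sp$nc_actual,
           seconds = c(thresholding = t_swarm - t0,
                       superpixel = t_sp - t_swarm,
                       fusion = t_end - t_sp,
                       total = t_end - t0)
         )),
    class = "mmpsos_segmentation"
  )
}

#' @export
print.mmpsos_segmentation <- function(x, ...) {
  r <- x$report
  cat("MMPSO-S segmentation\n")
  cat(sprintf("  thresholds: t1 = %d, t2 = %d\n", r$thresholds[["t1"]], r$thresholds[["t2"]]))
  cat(sprintf("  superpixels: %d clusters\n", r$nc_actual))
  cat(sprintf("  archive size: %d\n", r$archive_size))
  cat(sprintf("  foreground: %d px (%.1f%%)\n", sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}
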