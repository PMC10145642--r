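#' Swarm configuration
#'
#' Bundles the particle-swarm parameters. The defaults are the tuned values
#' for H&E histopathology thresholding: 150 particles, 150 iterations, k = 2
#' thresholds, inertia 1.3, acceleration coefficients 0.5/0.5, mutation rate
#' 0.1, archive capacity 30 and a 7-division adaptive grid. Positions live in
#' \[0, 255\] (or \[0, levels - 1\]) and velocities are clamped to \[-5, 5\].
#'
#' @param n_particles Swarm size (Npar).
#' @param n_iterations Number of iterations (Nite).
#' @param n_thresholds Number of thresholds k (k + 1 regions).
#' @param inertia Inertia weight on the previous velocity.
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param mutation_rate Mutation rate mu governing the decreasing
#'   non-uniform mutation schedule `pm(t) = (1 - (t-1)/(Nite-1))^(5/mu)`.
#' @param archive_max Pareto archive capacity (Amax).
#' @param grid_size Adaptive-grid divisions per objective (Gsize).
#' @param grid_x Numerator of the hypercube fitness `x / occupancy`; any
#'   value > 1 gives the same roulette probabilities.
#' @param v_max Velocity bound; velocities are clamped to `[-v_max, v_max]`.
#' @param alpha Renyi entropy order.
#' @param objectives Character subset of `c("otsu", "kapur", "renyi")`.
#' @param seed Optional integer seed; when non-NULL the run is reproducible.
#' @return Object of class `swarm_config`.
#' @export
swarm_config <- function(n_particles = 150L, n_iterations = 150L,
                         n_thresholds = 2L, inertia = 1.3, c1 = 0.5, c2 = 0.5,
                         mutation_rate = 0.1, archive_max = 30L, grid_size = 7L,
                         grid_x = 10, v_max = 5, alpha = 2,
                         objectives = c("otsu", "kapur", "renyi"),
                         seed = NULL) {
  stopifnot(n_particles >= 1, n_iterations >= 1, n_thresholds >= 1,
            archive_max >= 1, grid_size >= 2, grid_x > 1, v_max > 0,
            mutation_rate > 0)
  objectives <- match.arg(objectives, c("otsu", "kapur", "renyi"), several.ok = TRUE)
  structure(
    list(n_particles = as.integer(n_particles),
         n_iterations = as.integer(n_iterations),
         n_thresholds = as.integer(n_thresholds),
         inertia = inertia, c1 = c1, c2 = c2,
         mutation_rate = mutation_rate,
         archive_max = as.integer(archive_max),
         grid_size = as.integer(grid_size), grid_x = grid_x,
         v_max = v_max, alpha = alpha, objectives = objectives,
         seed = seed),
    class = "swarm_config"
  )
}

#' Pareto dominance (maximisation)
#'
#' `a` dominates `b` when `a` is at least as good in every objective and
#' strictly better in at least one.
#'
#' @param a,b Numeric fitness vectors of equal length.
#' @return Logical scalar.
#' @export
dominates <- function(a, b) {
  all(a >= b) && any(a > b)
}

# Row indices of the mutually non-dominated subset of a fitness matrix.
nondominated_rows <- function(F) {
  n <- nrow(F)
  if (n <= 1L) return(seq_len(n))
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    geq <- rowSums(F >= matrix(F[i, ], n, ncol(F), byrow = TRUE)) == ncol(F)
    gt  <- rowSums(F >  matrix(F[i, ], n, ncol(F), byrow = TRUE)) > 0
    if (any(geq & gt & keep)) keep[i] <- FALSE
  }
  which(keep)
}

new_archive <- function(capacity, grid_size) {
  structure(
    list(positions = NULL, fitness = NULL,
         capacity = as.integer(capacity), grid_size = as.integer(grid_size)),
    class = "pareto_archive"
  )
}

archive_size <- function(arch) if (is.null(arch$fitness)) 0L else nrow(arch$fitness)

#' Hypercube index of each archive member
#'
#' Partitions the occupied bounding box of the archive's fitness values into
#' `grid_size` divisions per objective and assigns each member to one
#' hypercube, encoded as a single integer.
#'
#' @param arch A `pareto_archive`.
#' @return Integer vector of cube codes, one per member.
#' @export
archive_grid <- function(arch) {
  F <- arch$fitness
  if (is.null(F)) return(integer(0))
  g <- arch$grid_size
  codes <- integer(nrow(F))
  for (j in seq_len(ncol(F))) {
    lo <- min(F[, j]); hi <- max(F[, j])
    if (hi > lo) {
      b <- pmin(g, floor((F[, j] - lo) / (hi - lo) * g) + 1L)
    } else {
      b <- rep(1L, nrow(F))
    }
    codes <- codes * g + (b - 1L)
  }
  codes
}

#' Insert a candidate into a Pareto archive
#'
#' Applies the four archive rules: an empty archive accepts the candidate; a
#' candidate dominated by any member is discarded; a non-dominated candidate
#' is inserted (evicting any members it dominates); and when the archive is
#' full, one member of the most crowded hypercube is removed first.
#' Candidates with fitness identical to an existing member are discarded to
#' avoid duplicate accumulation.
#'
#' @param arch A `pareto_archive`.
#' @param position Numeric position vector of the candidate.
#' @param fitness Numeric fitness vector of the candidate.
#' @return The updated archive.
#' @export
update_archive <- function(arch, position, fitness) {
  n <- archive_size(arch)
  if (n == 0L) {
    arch$positions <- matrix(position, 1L)
    arch$fitness <- matrix(fitness, 1L)
    return(arch)
  }
  F <- arch$fitness
  m <- ncol(F)
  fm <- matrix(fitness, n, m, byrow = TRUE)
  memb_geq <- rowSums(F >= fm) == m
  memb_gt  <- rowSums(F >  fm) > 0
  if (any(memb_geq & memb_gt) || any(memb_geq & rowSums(F <= fm) == m)) {
    return(arch)  # dominated by, or identical to, an existing member
  }
  cand_dom <- (rowSums(fm >= F) == m) & (rowSums(fm > F) > 0)
  if (any(cand_dom)) {
    keep <- !cand_dom
    arch$positions <- arch$positions[keep, , drop = FALSE]
    arch$fitness <- arch$fitness[keep, , drop = FALSE]
  }
  if (archive_size(arch) >= arch$capacity) {
    codes <- archive_grid(arch)
    occ <- table(codes)
    crowded <- as.integer(names(occ)[which.max(occ)])
    members <- which(codes == crowded)
    drop_i <- if (length(members) == 1L) members else members[sample.int(length(members), 1L)]
    keep <- setdiff(seq_len(archive_size(arch)), drop_i)
    arch$positions <- arch$positions[keep, , drop = FALSE]
    arch$fitness <- arch$fitness[keep, , drop = FALSE]
  }
  arch$positions <- rbind(arch$positions, position)
  arch$fitness <- rbind(arch$fitness, fitness)
  rownames(arch$positions) <- NULL; rownames(arch$fitness) <- NULL
  arch
}

#' Select swarm leaders from the archive by hypercube roulette
#'
#' Each occupied hypercube receives fitness `x / occupancy`; a cube is drawn
#' by roulette wheel on these fitnesses and a member of the chosen cube is
#' drawn uniformly. Sparse cubes are therefore favoured, pushing the swarm
#' toward under-explored parts of the Pareto front.
#'
#' @param arch A non-empty `pareto_archive`.
#' @param n Number of leaders to draw.
#' @return Integer vector of `n` member indices.
#' @export
select_leader <- function(arch, n = 1L) {
  sz <- archive_size(arch)
  if (sz == 0L) stop("cannot select a leader from an empty archive")
  if (sz == 1L) return(rep(1L, n))
  codes <- archive_grid(arch)
  occ <- as.vector(table(codes)[as.character(codes)])
  # member weight = P(cube) * P(member | cube) = (x/occ / sum_cubes) * (1/occ)
  w <- (1 / occ) * (1 / occ)
  sample.int(sz, n, replace = TRUE, prob = w)
}

#' Distance-to-origin best particle of an archive
#'
#' Returns the archive member whose fitness vector has the largest Euclidean
#' distance `d(O, i) = sqrt(f1^2 + f2^2 + f3^2)` from the origin of objective
#' space; ties are broken by the first index.
#'
#' @param arch A non-empty `pareto_archive`.
#' @return List with `position`, `fitness` and `distance`.
#' @export
best_particle <- function(arch) {
  if (archive_size(arch) == 0L) stop("archive is empty")
  d <- sqrt(rowSums(arch$fitness^2))
  i <- which.max(d)
  list(position = arch$positions[i, ], fitness = arch$fitness[i, ], distance = d[i])
}

# Sort threshold components of each row ascending (keeps (x1, x2) a valid
# threshold pair after velocity updates).
sort_rows <- function(X) {
  if (ncol(X) == 2L) {
    cbind(pmin(X[, 1L], X[, 2L]), pmax(X[, 1L], X[, 2L]))
  } else if (ncol(X) == 1L) {
    X
  } else {
    t(apply(X, 1L, sort))
  }
}

# Round real-valued positions to a valid sorted integer threshold vector in
# [1, L - 1]; collapsed components are nudged apart.
round_thresholds <- function(x, levels) {
  tv <- sort(as.integer(round(x)))
  tv <- pmin(pmax(tv, 1L), levels - 1L)
  for (i in seq_along(tv)[-1]) {
    if (tv[i] <= tv[i - 1L]) tv[i] <- tv[i - 1L] + 1L
  }
  if (any(tv > levels - 1L)) {
    tv <- pmin(tv, levels - 1L)
    for (i in rev(seq_along(tv)[-length(tv)])) {
      if (tv[i] >= tv[i + 1L]) tv[i] <- tv[i + 1L] - 1L
    }
  }
  if (any(tv < 1L) || is.unsorted(tv, strictly = TRUE)) {
    stop("cannot form a strictly increasing threshold vector")
  }
  tv
}

# Resolve fitness ties across empty-bin plateaus: when shifting one
# threshold leaves the fitness vector exactly unchanged (the moved levels
# carry no probability mass), every such position is an equally optimal
# cut and the midpoint is the maximum-margin choice — the same convention
# as averaging tied optima in classical Otsu thresholding. Scans each
# component while holding the others fixed.
center_tie_plateau <- function(pre, tv, objectives) {
  L <- pre$levels
  k <- length(tv)
  f0 <- eval_fitness_matrix(pre, matrix(tv, 1L), objectives)
  for (j in seq_len(k)) {
    lo_bound <- if (j == 1L) 1L else tv[j - 1L] + 1L
    hi_bound <- if (j == k) L - 1L else tv[j + 1L] - 1L
    lo <- tv[j]
    while (lo > lo_bound) {
      cand <- tv; cand[j] <- lo - 1L
      if (!identical(as.vector(eval_fitness_matrix(pre, matrix(cand, 1L), objectives)),
                     as.vector(f0))) break
      lo <- lo - 1L
    }
    hi <- tv[j]
    while (hi < hi_bound) {
      cand <- tv; cand[j] <- hi + 1L
      if (!identical(as.vector(eval_fitness_matrix(pre, matrix(cand, 1L), objectives)),
                     as.vector(f0))) break
      hi <- hi + 1L
    }
    tv[j] <- as.integer(round((lo + hi) / 2))
  }
  tv
}

#' Non-uniform mutation probability schedule
#'
#' `pm(t) = (1 - (t - 1)/(Nite - 1))^(5/mu)`: the whole swarm is eligible
#' for mutation at the first iteration, the probability decays
#' monotonically, and no particle mutates at the final iteration. This
#' keeps exploration high early without disturbing late convergence.
#'
#' @param t Iteration index in `[1, n_iterations]`.
#' @param n_iterations Total iterations (Nite).
#' @param mutation_rate Mutation rate mu.
#' @return Mutation probability in \[0, 1\].
#' @export
mutation_prob <- function(t, n_iterations, mutation_rate) {
  if (n_iterations <= 1L) return(0)
  (1 - (t - 1) / (n_iterations - 1))^(5 / mutation_rate)
}

#' One velocity/position update of the swarm
#'
#' Applies `V' = w V + c1 r1 (pbest - X) + c2 r2 (leader - X)` followed by
#' `X' = X + V'`, clamping velocities to `[-v_max, v_max]` and positions to
#' `[0, levels - 1]`, and sorting each particle's components ascending so
#' they always form a valid threshold vector.
#'
#' @param X,V,pbest,leader `n x k` matrices of positions, velocities,
#'   personal bests and per-particle leader positions.
#' @param cfg A [swarm_config()].
#' @param r1,r2 Per-particle uniform draws in (0, 1), length `n`.
#' @param levels Number of intensity levels (positions live in
#'   `[0, levels - 1]`).
#' @return List with updated `X` and `V`.
#' @export
update_particles <- function(X, V, pbest, leader, cfg, r1, r2, levels = 256L) {
  V <- cfg$inertia * V + cfg$c1 * r1 * (pbest - X) + cfg$c2 * r2 * (leader - X)
  V <- pmin(pmax(V, -cfg$v_max), cfg$v_max)
  X <- sort_rows(pmin(pmax(X + V, 0), levels - 1))
  list(X = X, V = V)
}

#' Run the multiobjective swarm threshold search on a histogram
#'
#' The engine behind [run_mmpso()]: evolves a particle swarm over threshold
#' vectors, scoring each particle on the enabled objectives (Otsu, Kapur,
#' Renyi), maintaining an external Pareto archive with an adaptive hypercube
#' grid, selecting leaders by roulette over cube fitness, applying a
#' decreasing non-uniform mutation, and finally extracting the archive
#' member farthest from the objective-space origin.
#'
#' @param h An `intensity_histogram`.
#' @param cfg A [swarm_config()].
#' @param keep_history If TRUE, per-iteration archive fitness snapshots are
#'   returned in `$history` (for auditing archive invariants).
#' @return List of class `mmpso_result` with `thresholds` (sorted integers),
#'   `position` (real-valued best position), `fitness`, `distance`,
#'   `archive`, and optionally `history`.
#' @export
mmpso_histogram <- function(h, cfg = swarm_config(), keep_history = FALSE) {
  stopifnot(inherits(h, "intensity_histogram"))
  if (sum(h$counts > 0) < 2L) {
    stop("degenerate image: fewer than two distinct intensity levels; no meaningful thresholds exist")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  L <- h$levels
  n <- cfg$n_particles
  k <- cfg$n_thresholds
  nobj <- length(cfg$objectives)
  pre <- precompute_objectives(h, cfg$alpha)
  eval_pos <- function(X) {
    T <- matrix(0L, nrow(X), k)
    for (i in seq_len(nrow(X))) T[i, ] <- round_thresholds(X[i, ], L)
    eval_fitness_matrix(pre, T, cfg$objectives)
  }

  X <- sort_rows(matrix(stats::runif(n * k, 0, L - 1), n, k))
  V <- matrix(0, n, k)
  F <- eval_pos(X)
  pbX <- X
  pbF <- F

  arch <- new_archive(cfg$archive_max, cfg$grid_size)
  for (i in nondominated_rows(F)) arch <- update_archive(arch, X[i, ], F[i, ])

  history <- if (keep_history) vector("list", cfg$n_iterations) else NULL

  for (t in seq_len(cfg$n_iterations)) {
    leaders <- select_leader(arch, n)
    lX <- arch$positions[leaders, , drop = FALSE]
    r1 <- stats::runif(n); r2 <- stats::runif(n)
    up <- update_particles(X, V, pbX, lX, cfg, r1, r2, L)
    X <- up$X; V <- up$V
    F <- eval_pos(X)

    # pBest: replace when dominated by the new position; coin flip on mutual
    # non-dominance.
    geq_new <- rowSums(F >= pbF) == nobj
    gt_new  <- rowSums(F >  pbF) > 0
    new_dom <- geq_new & gt_new
    old_dom <- (rowSums(pbF >= F) == nobj) & (rowSums(pbF > F) > 0)
    tie <- !new_dom & !old_dom
    replace <- new_dom | (tie & stats::runif(n) < 0.5)
    pbX[replace, ] <- X[replace, , drop = FALSE]
    pbF[replace, ] <- F[replace, , drop = FALSE]

    for (i in nondominated_rows(F)) arch <- update_archive(arch, X[i, ], F[i, ])

    pm <- mutation_prob(t, cfg$n_iterations, cfg$mutation_rate)
    if (pm > 0) {
      hit <- stats::runif(n) < pm
      if (any(hit)) {
        idx <- which(hit)
        dims <- sample.int(k, length(idx), replace = TRUE)
        half <- pm * (L - 1) / 2
        for (jj in seq_along(idx)) {
          i <- idx[jj]; j <- dims[jj]
          lo <- max(0, X[i, j] - half); hi <- min(L - 1, X[i, j] + half)
          X[i, j] <- stats::runif(1, lo, hi)
        }
        X[idx, ] <- sort_rows(X[idx, , drop = FALSE])
        Fm <- eval_pos(X[idx, , drop = FALSE])
        F[idx, ] <- Fm
        geq_new <- rowSums(Fm >= pbF[idx, , drop = FALSE]) == nobj
        gt_new  <- rowSums(Fm >  pbF[idx, , drop = FALSE]) > 0
        new_dom <- geq_new & gt_new
        old_dom <- (rowSums(pbF[idx, , drop = FALSE] >= Fm) == nobj) &
                   (rowSums(pbF[idx, , drop = FALSE] >  Fm) > 0)
        tie <- !new_dom & !old_dom
        repl <- idx[new_dom | (tie & stats::runif(length(idx)) < 0.5)]
        pbX[repl, ] <- X[repl, , drop = FALSE]
        pbF[repl, ] <- F[repl, , drop = FALSE]
      }
    }
    if (keep_history) {
      history[[t]] <- arch$fitness
    }
  }

  bp <- best_particle(arch)
  tv <- center_tie_plateau(pre, round_thresholds(bp$position, L), cfg$objectives)
  structure(
    list(thresholds = tv,
         position = bp$position, fitness = bp$fitness, distance = bp$distance,
         archive = arch, history = history, config = cfg, levels = L),
    class = "mmpso_result"
  )
}

#' Swarm threshold search on a pre-processed grayscale image
#'
#' Builds the 256-bin intensity histogram of `ipre` and runs the
#' multiobjective swarm ([mmpso_histogram()]) to find the optimal threshold
#' vector, by default the pair `(t1, t2)` splitting the image into dark
#' (ROI), intermediate and bright classes.
#'
#' @param ipre Pre-processed grayscale image (`H x W` integer matrix in
#'   \[0, 255\]), e.g. from [preprocess_image()].
#' @param cfg A [swarm_config()].
#' @param ... Passed to [mmpso_histogram()].
#' @return An `mmpso_result`; `$thresholds` holds the sorted integer
#'   thresholds.
#' @export
run_mmpso <- function(ipre, cfg = swarm_config(), ...) {
  mmpso_histogram(intensity_histogram(ipre), cfg, ...)
}

#' Partition an image into threshold-class binary maps
#'
#' For thresholds `t1 < t2`, map I1 holds pixels with intensity in
#' `[0, t1 - 1]` (the dark class containing the ROIs), I2 pixels in
#' `[t1, t2 - 1]`, and I3 pixels in `[t2, 255]`. The three maps partition
#' the image: every pixel is set in exactly one of them.
#'
#' @param ipre Grayscale image (`H x W` integer matrix).
#' @param t1,t2 Integer thresholds with `0 < t1 < t2 <= 255`.
#' @return List of logical matrices `I1`, `I2`, `I3`.
#' @export
apply_thresholds <- function(ipre, t1, t2) {
  stopifnot(is.matrix(ipre))
  if (!(t1 > 0 && t2 > t1 && t2 <= 255)) {
    stop("invalid thresholds: need 0 < t1 < t2 <= 255")
  }
  list(I1 = ipre < t1,
       I2 = ipre >= t1 & ipre < t2,
       I3 = ipre >= t2)
}

#' @export
print.mmpso_result <- function(x, ...) {
  cat("Multiobjective swarm threshold search\n")
  cat(sprintf("  thresholds: %s\n", paste(x$thresholds, collapse = ", ")))
  cat(sprintf("  best fitness (%s): %s\n",
              paste(colnames(x$archive$fitness), collapse = ", "),
              paste(signif(x$fitness, 6), collapse = ", ")))
  cat(sprintf("  archive size: %d\n", archive_size(x$archive)))
  invisible(x)
}
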