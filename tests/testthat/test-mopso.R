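test_that("Pareto dominance is strict and handles mutual non-dominance", {
  expect_true(dominates(c(2, 2, 2), c(1, 1, 1)))
  expect_false(dominates(c(1, 1, 1), c(2, 2, 2)))
  expect_false(dominates(c(2, 1, 1), c(1, 2, 1)))
  expect_false(dominates(c(1, 2, 1), c(2, 1, 1)))
  expect_false(dominates(c(1, 1, 1), c(1, 1, 1)))
  expect_true(dominates(c(1, 1, 2), c(1, 1, 1)))
})

test_that("archive rules: empty insert, dominated discard, dominator eviction, capacity bound", {
  arch <- mmpsos:::new_archive(5L, 7L)
  arch <- update_archive(arch, c(10, 20), c(1, 1, 1))
  expect_equal(mmpsos:::archive_size(arch), 1L)

  # dominated candidate discarded
  arch2 <- update_archive(arch, c(30, 40), c(0.5, 0.5, 0.5))
  expect_identical(arch2$fitness, arch$fitness)

  # dominating candidate evicts members it dominates
  arch3 <- update_archive(arch, c(5, 6), c(2, 2, 2))
  expect_equal(mmpsos:::archive_size(arch3), 1L)
  expect_equal(unname(arch3$fitness[1, ]), c(2, 2, 2))

  # fill to capacity with mutually non-dominated members, then insert one
  # more: size stays at capacity and the most crowded cube loses a member
  set.seed(9)
  arch <- mmpsos:::new_archive(5L, 2L)
  fits <- cbind(c(10, 8, 6, 4, 2), c(2, 4, 6, 8, 10), 1)
  for (i in 1:5) arch <- update_archive(arch, c(i, i + 1), fits[i, ])
  expect_equal(mmpsos:::archive_size(arch), 5L)
  before <- table(archive_grid(arch))
  arch <- update_archive(arch, c(9, 9), c(9, 9, 1.5))
  expect_lte(mmpsos:::archive_size(arch), 5L)
  expect_true(is_mutually_nondominated(arch$fitness))
})

test_that("archive members stay mutually non-dominated under random candidate streams", {
  set.seed(21)
  arch <- mmpsos:::new_archive(10L, 4L)
  for (i in 1:200) {
    arch <- update_archive(arch, runif(2, 0, 255), runif(3, 0, 10))
    expect_lte(mmpsos:::archive_size(arch), 10L)
  }
  expect_true(is_mutually_nondominated(arch$fitness))
})

test_that("leader roulette favours sparse hypercubes as x/occupancy", {
  # one member alone in a cube vs nine sharing a cube: cube probabilities
  # x/1 : x/9, i.e. 0.9 : 0.1
  arch <- mmpsos:::new_archive(30L, 2L)
  arch$positions <- matrix(runif(20), 10, 2)
  # member 1 in the high-f1 cube, members 2..10 clustered in the low-f1 cube;
  # f2 descending keeps all mutually non-dominated
  arch$fitness <- cbind(c(10, seq(1, 0.2, length.out = 9)),
                        c(1, seq(10, 18, length.out = 9)),
                        rep(1, 10))
  expect_true(is_mutually_nondominated(arch$fitness))
  codes <- archive_grid(arch)
  expect_equal(length(unique(codes)), 2L)
  expect_equal(sort(as.vector(table(codes))), c(1L, 9L))

  set.seed(4)
  draws <- select_leader(arch, 20000L)
  p_solo <- mean(draws == 1L)
  expect_equal(p_solo, 0.9, tolerance = 0.02)

  solo <- mmpsos:::new_archive(5L, 7L)
  solo <- update_archive(solo, c(1, 2), c(1, 2, 3))
  expect_true(all(select_leader(solo, 50L) == 1L))
  expect_error(select_leader(mmpsos:::new_archive(5L, 7L)), "empty")
})

test_that("particle updates follow the velocity equation with clamping and sorted components", {
  cfg <- swarm_config(inertia = 1.3, c1 = 0.5, c2 = 0.5, v_max = 5)

  # stationary fixed point
  X <- matrix(c(100, 200), 1, 2)
  up <- update_particles(X, matrix(0, 1, 2), X, X, cfg, 1, 1)
  expect_equal(up$X, X)
  expect_equal(up$V, matrix(0, 1, 2))

  # hand-computed step with r1 = r2 = 1:
  # V' = 1.3*1 + 0.5*(120-100) + 0.5*(90-100) = 1.3 + 10 - 5 = 6.3 -> clamp 5
  up <- update_particles(matrix(100, 1, 1), matrix(1, 1, 1),
                         matrix(120, 1, 1), matrix(90, 1, 1), cfg, 1, 1)
  expect_equal(up$V[1, 1], 5)
  expect_equal(up$X[1, 1], 105)

  # bounds hold under random updates, components sorted
  set.seed(2)
  for (i in 1:50) {
    X <- matrix(runif(20, 0, 255), 10, 2)
    V <- matrix(runif(20, -5, 5), 10, 2)
    up <- update_particles(sort_rows_ref(X), V, matrix(runif(20, 0, 255), 10, 2),
                           matrix(runif(20, 0, 255), 10, 2), cfg,
                           runif(10), runif(10))
    expect_true(all(up$V >= -5 & up$V <= 5))
    expect_true(all(up$X >= 0 & up$X <= 255))
    expect_true(all(up$X[, 1] <= up$X[, 2]))
  }
})

test_that("mutation schedule covers the swarm early and vanishes at the last iteration", {
  expect_equal(mutation_prob(1, 150, 0.1), 1)
  expect_equal(mutation_prob(150, 150, 0.1), 0)
  pm <- vapply(1:150, mutation_prob, numeric(1), n_iterations = 150, mutation_rate = 0.1)
  expect_true(all(diff(pm) <= 0))
  expect_true(all(pm >= 0 & pm <= 1))
})

test_that("best particle maximises distance from the objective-space origin", {
  arch <- mmpsos:::new_archive(10L, 7L)
  arch$positions <- matrix(1:4, 2, 2)
  arch$fitness <- rbind(c(3, 0, 0), c(0, 4, 0))
  bp <- best_particle(arch)
  expect_equal(unname(bp$fitness), c(0, 4, 0))
  expect_equal(bp$distance, 4)

  set.seed(13)
  arch$positions <- matrix(runif(40), 20, 2)
  arch$fitness <- matrix(runif(60, 0, 100), 20, 3)
  bp <- best_particle(arch)
  expect_equal(bp$distance, max(sqrt(rowSums(arch$fitness^2))))
  expect_error(best_particle(mmpsos:::new_archive(3L, 7L)), "empty")
})

test_that("swarm search is deterministic under a fixed seed and initialises velocities at zero", {
  img <- rand_bimodal_image(1)
  h <- intensity_histogram(img)
  r1 <- mmpso_histogram(h, quick_swarm(seed = 42))
  r2 <- mmpso_histogram(h, quick_swarm(seed = 42))
  expect_identical(r1$thresholds, r2$thresholds)
  expect_identical(r1$archive$fitness, r2$archive$fitness)
  r3 <- mmpso_histogram(h, quick_swarm(seed = 43))
  expect_s3_class(r3, "mmpso_result")
})

test_that("single-objective search matches exhaustive Otsu scan", {
  for (s in 1:5) {
    img <- rand_bimodal_image(s)
    h <- intensity_histogram(img)
    res <- mmpso_histogram(h, quick_swarm(n_thresholds = 1L, objectives = "otsu", seed = s))
    expect_equal(res$thresholds, brute_otsu_scan(h))
  }
})

test_that("degenerate single-intensity images are rejected", {
  expect_error(run_mmpso(matrix(7L, 10, 10)), "degenerate")
})

test_that("instrumented runs expose a valid archive at every iteration", {
  img <- rand_bimodal_image(3)
  res <- mmpso_histogram(intensity_histogram(img),
                         quick_swarm(n_iterations = 30L, seed = 5),
                         keep_history = TRUE)
  expect_length(res$history, 30L)
  for (F in res$history) {
    expect_lte(nrow(F), 30L)
    expect_true(is_mutually_nondominated(F))
  }
})

test_that("threshold maps partition the image and respect the half-open region convention", {
  set.seed(6)
  img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  maps <- apply_thresholds(img, 80, 170)
  expect_length(maps, 3L)
  expect_true(all(maps$I1 + maps$I2 + maps$I3 == 1))
  expect_true(all(img[maps$I1] < 80))
  expect_true(all(img[maps$I2] >= 80 & img[maps$I2] < 170))
  expect_true(all(img[maps$I3] >= 170))

  cimg <- matrix(0L, 5, 5)
  maps0 <- apply_thresholds(cimg, 10, 20)
  expect_true(all(maps0$I1))
  expect_false(any(maps0$I2 | maps0$I3))

  expect_error(apply_thresholds(img, 170, 80), "invalid threshold")
  expect_error(apply_thresholds(img, 80, 80), "invalid threshold")
})
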