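# Four solid colour quadrants: cluster structure known by construction.
quadrant_image <- function(n = 40L) {
  img <- array(0L, c(n, n, 3L))
  half <- n / 2
  img[1:half, 1:half, 1] <- 200L
  img[1:half, (half + 1):n, 2] <- 200L
  img[(half + 1):n, 1:half, 3] <- 200L
  img[(half + 1):n, (half + 1):n, ] <- 150L
  img
}

test_that("initial centres form a grid with spacing sqrt(np/nc), never exceeding nc", {
  img <- array(100L, c(100, 100, 3))
  ini <- init_centers(img, 100)
  expect_equal(ini$S, 10)
  expect_equal(nrow(ini$centers), 100L)
  xs <- sort(unique(ini$centers[, "X"]))
  expect_length(xs, 10L)

  ini1 <- init_centers(img, 1)
  expect_equal(nrow(ini1$centers), 1L)
  expect_true(abs(ini1$centers[1, "X"] - 50) <= 1 && abs(ini1$centers[1, "Y"] - 50) <= 1)

  for (nc in c(3, 17, 250)) {
    expect_lte(nrow(init_centers(img, nc)$centers), nc)
  }
  expect_error(init_centers(array(0L, c(4, 4, 3)), 17), "exceeds")
})

test_that("pixel assignment follows the combined colour-spatial distance", {
  # identical colours: the spatially closer centre wins
  img <- array(100L, c(10, 10, 3))
  centers <- rbind(c(100, 100, 100, 2, 5), c(100, 100, 100, 9, 5))
  colnames(centers) <- c("R", "G", "B", "X", "Y")
  lab <- assign_pixels(img, centers, S = 5, p = 10, window = FALSE)
  expect_true(all(lab[1:5, ] == 1L))
  expect_true(all(lab[7:10, ] == 2L))

  # very large compactness approaches a spatial Voronoi partition
  # (centres at rows 3 and 10 so no pixel row is spatially equidistant)
  set.seed(8)
  img2 <- array(sample(0:255, 12 * 12 * 3, replace = TRUE), c(12, 12, 3))
  centers2 <- cbind(R = c(0, 255), G = c(0, 255), B = c(0, 255), X = c(3, 10), Y = c(6, 6))
  lab_p <- assign_pixels(img2, centers2, S = 6, p = 1e6, window = FALSE)
  rows <- row(matrix(0, 12, 12))
  vor <- ifelse(abs(rows - 3) < abs(rows - 10), 1L, 2L)
  expect_identical(lab_p, vor)
})

test_that("windowed assignment equals exhaustive assignment when windows cover the image", {
  # S larger than the image diameter makes every 2S x 2S window cover the
  # whole frame, so windowing must change nothing
  set.seed(12)
  img <- array(sample(0:255, 20 * 20 * 3, replace = TRUE), c(20, 20, 3))
  centers <- cbind(R = sample(0:255, 5), G = sample(0:255, 5), B = sample(0:255, 5),
                   X = c(3, 8, 12, 17, 10), Y = c(4, 16, 9, 3, 12))
  lab_w <- assign_pixels(img, centers, S = 30, p = 10, window = TRUE)
  lab_e <- assign_pixels(img, centers, S = 30, p = 10, window = FALSE)
  expect_identical(lab_w, lab_e)
})

test_that("centre updates are means of members with zero residual at a fixed point", {
  img <- quadrant_image(20L)
  ini <- init_centers(img, 4)
  lab <- assign_pixels(img, ini$centers, ini$S, p = 10)
  up1 <- update_centers(img, lab, ini$centers)
  expect_gt(up1$E, 0)
  up2 <- update_centers(img, lab, up1$centers)
  expect_equal(up2$E, 0, tolerance = 1e-9)

  # single cluster: centre is the global mean pixel vector
  lab1 <- matrix(1L, 20, 20)
  up <- update_centers(img, lab1, ini$centers[1, , drop = FALSE])
  expect_equal(unname(up$centers[1, c("X", "Y")]), c(mean(1:20), mean(1:20)))
  expect_equal(unname(up$centers[1, "R"]), mean(img[, , 1]))
})

test_that("superpixel clustering recovers solid colour quadrants and honours nc' <= nc", {
  img <- quadrant_image(40L)
  sp <- run_superpixel(img, superpixel_config(n_superpixels = 4, compactness = 1))
  expect_lte(sp$nc_actual, 4L)
  # each quadrant should be (almost) one label
  q <- list(sp$labels[1:20, 1:20], sp$labels[1:20, 21:40],
            sp$labels[21:40, 1:20], sp$labels[21:40, 21:40])
  agree <- mean(unlist(lapply(q, function(m) mean(m == as.integer(names(which.max(table(m)))))))
  )
  expect_gte(agree, 0.99)

  # label maps are total and contiguous in [1, nc']
  set.seed(31)
  for (i in 1:5) {
    img <- array(sample(0:255, 24 * 24 * 3, replace = TRUE), c(24, 24, 3))
    sp <- run_superpixel(img, superpixel_config(n_superpixels = 9))
    expect_lte(sp$nc_actual, 9L)
    expect_setequal(unique(as.vector(sp$labels)), seq_len(sp$nc_actual))
    # centres equal member means at convergence/output
    for (ch in 1:3) {
      means <- as.vector(tapply(as.vector(img[, , ch]), as.vector(sp$labels), mean))
      expect_equal(unname(sp$centers[, ch]), means, tolerance = 1e-6)
    }
  }
})

test_that("constant-colour images cluster on space alone into compact regions", {
  img <- array(120L, c(20, 20, 3))
  sp <- run_superpixel(img, superpixel_config(n_superpixels = 4))
  expect_lte(sp$nc_actual, 4L)
  expect_gte(sp$nc_actual, 1L)
  expect_true(all(sp$labels >= 1))
})

test_that("cluster refinement keeps exactly the dark clusters, as whole clusters", {
  # two-region fixture: left half dark (mean 40), right half bright (mean 200)
  img <- array(0L, c(10, 20, 3))
  img[, 1:10, ] <- 40L; img[, 11:20, ] <- 200L
  sp <- run_superpixel(img, superpixel_config(n_superpixels = 2, compactness = 1))
  expect_equal(sp$nc_actual, 2L)
  ipre <- matrix(0L, 10, 20); ipre[, 1:10] <- 40L; ipre[, 11:20] <- 200L
  m <- refine_clusters(sp, ipre, t1 = 100)
  expect_identical(m, ipre < 100)

  expect_true(all(refine_clusters(sp, ipre, 255)))   # every cluster mean < 255
  expect_false(any(refine_clusters(sp, ipre, 1)))    # no cluster mean < 1

  # union-of-whole-clusters invariant on random images
  set.seed(14)
  img <- array(sample(0:255, 24 * 24 * 3, replace = TRUE), c(24, 24, 3))
  sp <- run_superpixel(img, superpixel_config(n_superpixels = 16))
  ipre <- to_grayscale(img)
  m <- refine_clusters(sp, ipre, 128)
  for (lbl in seq_len(sp$nc_actual)) {
    vals <- m[sp$labels == lbl]
    expect_true(all(vals) || !any(vals))
  }

  expect_error(refine_clusters(sp, ipre[1:10, 1:10], 128), "shape")
})
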