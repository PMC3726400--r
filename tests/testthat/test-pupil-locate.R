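test_that("oriented masks are zero-mean, deterministic, and orientation-selective", {
  for (sz in c(9, 15, 45)) for (th in c(0, 37.5, 90, 160)) {
    expect_lt(abs(sum(oriented_mask(sz, th))), 1e-9)
  }
  expect_identical(oriented_mask(21, 0), oriented_mask(21, 0))
  expect_error(oriented_mask(20, 0), class = "pex_config_error")
  expect_error(oriented_mask(21, 180), class = "pex_config_error")

  # brute-force response sweep on ideal step edges: the winning mask
  # orientation must match the edge orientation within one angular step
  step <- 5
  thetas <- seq(0, 180 - step, by = step)
  for (phi in c(0, 20, 45, 90, 135, 160)) {
    img <- edge_image(41, 41, phi)
    resp <- vapply(thetas, function(th) {
      m <- oriented_mask(21, th)
      abs(sum(m * img[11:31, 11:31]))
    }, numeric(1))
    win <- thetas[which.max(resp)]
    derr <- min(abs(win - phi), 180 - abs(win - phi))   # circular in [0,180)
    expect_lte(derr, step)
  }
})

test_that("direction field responds to edges with the local tangent orientation", {
  expect_equal(max(direction_field(matrix(0.5, 64, 64), 15, 10)$response), 0,
               tolerance = 1e-8)

  img <- disc_image(96, 96, c(48.5, 48.5), 30)
  df <- direction_field(img, 15, 5)
  strong <- which(df$response > quantile(df$response, 0.95))
  rr <- (strong - 1) %% 96 + 1
  cc <- (strong - 1) %/% 96 + 1
  phi <- (atan2(-(rr - 48.5), cc - 48.5) * 180 / pi) %% 360
  tangent <- (phi + 90) %% 180
  derr <- abs(df$theta[strong] - tangent)
  derr <- pmin(derr, 180 - derr)
  expect_lte(median(derr), 5)
  # curved edge + 5-degree quantization: allow two steps in the upper tail
  expect_lte(quantile(derr, 0.9), 10)

  # a coarser angular sweep can never beat a finer one by more than numerics
  df10 <- direction_field(img, 15, 10)
  expect_true(all(df10$response <= df$response + 1e-8))
})

test_that("centre voting recovers disc centres and radii, matching circle-fit and Hough oracles", {
  img <- disc_image(128, 128, c(60.2, 70.6), 35)
  df <- direction_field(img, 15, 5)
  acc <- vote_center(df, 0.95, r_min = 3, r_max = 60)
  expect_lt(sqrt(sum((acc$center - c(60.2, 70.6))^2)), 2)
  expect_lt(abs(acc$pupil_radius - 35) / 35, 0.05)
  expect_false(acc$low_confidence)

  # oracle 1: algebraic circle fit to thresholded edge pixels
  g <- df$response
  ed <- which(g > quantile(g, 0.95))
  fit <- circle_fit_lsq((ed - 1) %% 128 + 1, (ed - 1) %/% 128 + 1)
  expect_lt(sqrt(sum((acc$center - fit$center)^2)), 2)

  # oracle 2: brute-force Hough circle transform on a small instance
  img64 <- disc_image(64, 64, c(33.4, 30.8), 16)
  df64 <- direction_field(img64, 11, 5)
  acc64 <- vote_center(df64, 0.93, r_min = 3, r_max = 30)
  hc <- hough_circle_center(img64, 0.95, r_min = 5, r_max = 30)
  expect_lt(sqrt(sum((acc64$center - hc)^2)), 2)
  expect_lt(sqrt(sum((acc64$center - c(33.4, 30.8))^2)), 2)
})

test_that("voting is invariant under affine brightness changes", {
  img <- disc_image(96, 96, c(50.5, 45.5), 28)
  df1 <- direction_field(img, 15, 5)
  df2 <- direction_field(0.6 * img + 0.2, 15, 5)
  a1 <- vote_center(df1, 0.95, 3, 45)
  a2 <- vote_center(df2, 0.95, 3, 45)
  expect_identical(a1$center_int, a2$center_int)
  expect_equal(a1$center, a2$center, tolerance = 0.05)
  # FFT convolution perturbs responses at the threshold boundary by ~1e-10,
  # so one or two pixels sitting exactly at the vote quantile may flip and
  # each drags its whole vote line with it; the decision and the peak must
  # nevertheless be unchanged
  expect_lte(max(abs(a1$votes - a2$votes)), 5)
  expect_equal(a1$pupil_radius, a2$pupil_radius, tolerance = 2e-3)
})

test_that("rotating the image by 90 degrees rotates the detected centre", {
  img <- disc_image(96, 96, c(40.5, 60.5), 22)
  rot <- t(img)[, 96:1]                      # 90 degree rotation
  a1 <- vote_center(direction_field(img, 15, 5), 0.95, 3, 45)
  a2 <- vote_center(direction_field(rot, 15, 5), 0.95, 3, 45)
  # centre (r, c) maps to (c, 97 - r) under this rotation
  expect_lt(sqrt(sum((a2$center - c(a1$center[2], 97 - a1$center[1]))^2)), 2)
})

test_that("degenerate voting geometries are flagged or rejected", {
  # constant image: nothing exceeds the response threshold
  df <- direction_field(matrix(0.5, 64, 64), 15, 10)
  expect_error(vote_center(df, 0.98, 3, 30), class = "pex_no_pupil")

  # one straight edge: parallel normals never intersect in a point
  img <- edge_image(96, 96, 30)
  dfl <- direction_field(img, 15, 5)
  accl <- vote_center(dfl, 0.98, 3, 45)
  expect_true(accl$low_confidence)

  # two identical disjoint discs: the winner is one of the two true centres
  img2 <- pmin(disc_image(96, 192, c(48.5, 48.5), 20),
               disc_image(96, 192, c(48.5, 144.5), 20))
  acc2 <- vote_center(direction_field(img2, 15, 5), 0.95, 3, 45)
  d1 <- sqrt(sum((acc2$center - c(48.5, 48.5))^2))
  d2 <- sqrt(sum((acc2$center - c(48.5, 144.5))^2))
  expect_lt(min(d1, d2), 2)
})
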