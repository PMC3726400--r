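test_that("polar resampling has the expected geometry", {
  set.seed(3)
  img <- matrix(runif(96 * 96), 96, 96)
  ctr <- c(48.5, 48.5)
  pol <- to_polar(img, ctr, 40)
  # the r = 0 row replicates the (interpolated) centre value at every angle
  expect_equal(pol$pixels[1, ], rep(pol$pixels[1, 1], 360), tolerance = 1e-12)
  expect_equal(ncol(pol$pixels), 360)
  expect_true(all(pol$valid))

  # concentric rings: intensity depends on radius only, so all angular
  # columns must agree up to interpolation error
  dr <- matrix(seq_len(96) - ctr[1], 96, 96)
  dc <- matrix(seq_len(96) - ctr[2], 96, 96, byrow = TRUE)
  rings <- 0.5 + 0.4 * cos(sqrt(dr^2 + dc^2) / 3)
  polr <- to_polar(rings, ctr, 40)
  spread <- apply(polr$pixels, 1, function(x) diff(range(x)))
  expect_lt(max(spread), 0.02)

  expect_error(to_polar(img, c(-3, 50), 40), class = "pex_input_error")
  expect_error(to_polar(img, ctr, 4), class = "pex_config_error")
})

test_that("polar -> Cartesian round trip reconstructs smooth images accurately", {
  x <- matrix(seq_len(96), 96, 96)
  smooth <- 0.5 + 0.25 * sin(x / 11) * cos(t(x) / 13)
  ctr <- c(48.5, 48.5)
  pol <- to_polar(smooth, ctr, 45)
  back <- from_polar(pol, c(96, 96))
  ok <- !is.na(back)
  expect_gt(mean(ok), 0.5)
  rmse <- sqrt(mean((back[ok] - smooth[ok])^2))
  expect_lt(rmse, 0.02)
})

test_that("rotating the image about the centre circularly shifts polar columns", {
  img <- disc_image(97, 97, c(49, 49), 30) +
    0.05 * edge_image(97, 97, 40)            # break rotational symmetry
  rot <- t(img)[, 97:1]                      # exact 90-degree rotation about (49,49)
  p1 <- to_polar(img, c(49, 49), 40)
  p2 <- to_polar(rot, c(49, 49), 40)
  shifted <- cbind(p1$pixels[, 91:360], p1$pixels[, 1:90])
  expect_equal(p2$pixels, shifted, tolerance = 0.02, ignore_attr = TRUE)
})

test_that("mean intensity is preserved between polar and disc-restricted Cartesian domains", {
  set.seed(9)
  base <- matrix(runif(96 * 96), 96, 96)
  smooth <- .f <- NULL
  sm <- base
  for (i in 1:5) sm <- (sm +
    sm[c(1, 1:95), ] + sm[c(2:96, 96), ] + sm[, c(1, 1:95)] + sm[, c(2:96, 96)]) / 5
  ctr <- c(48.5, 48.5)
  pol <- to_polar(sm, ctr, 40)
  dr <- matrix(seq_len(96) - ctr[1], 96, 96)
  dc <- matrix(seq_len(96) - ctr[2], 96, 96, byrow = TRUE)
  disc <- sqrt(dr^2 + dc^2) <= 39
  # per-(r, theta) sampling (no area weighting): compare against the
  # radius-profile mean of the Cartesian disc, computed independently
  cart_mean <- mean(sm[disc])
  d <- sqrt(dr^2 + dc^2)[disc]
  prof <- tapply(sm[disc], round(d), mean)
  polar_like_mean <- mean(prof)
  expect_lt(abs(mean(pol$pixels) - polar_like_mean) /
              max(polar_like_mean, 1e-9), 0.02)
  expect_lt(abs(mean(pol$pixels) - cart_mean) / cart_mean, 0.1)
})
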