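polar_of <- function(img, ctr, rmax = 45) to_polar(img, ctr, rmax)

test_that("pupil contour recovers discs, fills holes, and matches the analytic ellipse", {
  ctr <- c(48.5, 48.5)
  img <- disc_image(96, 96, ctr, 25)
  Kz <- pupil_contour(polar_of(img, ctr))
  expect_true(all(abs(Kz$radius - 25) <= 1))

  # a bright specular hole strictly inside the pupil must not change K_z
  hole <- img
  dr <- matrix(seq_len(96) - 44, 96, 96)
  dc <- matrix(seq_len(96) - 52, 96, 96, byrow = TRUE)
  hole[sqrt(dr^2 + dc^2) < 4] <- 1
  Kzh <- pupil_contour(polar_of(hole, ctr))
  expect_equal(Kzh$radius, Kz$radius, tolerance = 0.01)

  # elliptical pupil: compare to the closed-form polar radius of an ellipse
  a <- 28; b <- 20
  dr <- matrix(seq_len(96) - ctr[1], 96, 96)
  dc <- matrix(seq_len(96) - ctr[2], 96, 96, byrow = TRUE)
  inside <- (dc / a)^2 + (dr / b)^2        # semi-axis a along columns
  ell <- 0.9 + (0.1 - 0.9) * pmin(pmax((1 - sqrt(inside)) * 15 + 0.5, 0), 1)
  Ke <- pupil_contour(polar_of(ell, ctr), poly_degree = 6)
  th <- Ke$angles * pi / 180
  r_true <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  expect_lt(max(abs(Ke$radius - r_true)), 2)

  # no dark region at the centre -> hard failure
  expect_error(pupil_contour(polar_of(1 - img, ctr)), class = "pex_no_pupil")
})

test_that("harmonic pupil fit residual is non-increasing in the degree", {
  ctr <- c(48.5, 48.5)
  set.seed(12)
  th <- seq(0, 359) * pi / 180
  rho <- 24 + 2 * sin(2 * th) + 1.2 * cos(5 * th)
  dr <- matrix(seq_len(96) - ctr[1], 96, 96)
  dc <- matrix(seq_len(96) - ctr[2], 96, 96, byrow = TRUE)
  phid <- (atan2(-dr, dc) * 180 / pi) %% 360
  rho_pix <- rho[pmin(floor(phid) + 1, 360)]
  img <- 0.9 + (0.1 - 0.9) *
    pmin(pmax((rho_pix - sqrt(dr^2 + dc^2)) / 1.2 + 0.5, 0), 1)
  pol <- polar_of(img, ctr)
  res <- vapply(0:6, function(deg) {
    K <- pupil_contour(pol, deg)
    raw <- attr(K, "raw_radius")
    ok <- !is.na(raw)
    sum((K$radius[ok] - raw[ok])^2)
  }, numeric(1))
  expect_true(all(diff(res) <= 1e-6))
})

test_that("the radial snake locks onto edges and respects its search band", {
  ctr <- c(48.5, 48.5)
  pol <- polar_of(disc_image(96, 96, ctr, 30, dark = 0.3, bright = 0.85), ctr)
  K <- radial_active_contour(pol, 10, 42, smoothness = 5, "dark_to_light")
  expect_true(all(abs(K$radius - 30) <= 1))

  # two concentric steps; a band excluding the inner one must lock outward
  img2 <- disc_image(96, 96, ctr, 35, dark = 0.5, bright = 0.9) *
    disc_image(96, 96, ctr, 18, dark = 0.3, bright = 1)
  pol2 <- polar_of(img2, ctr)
  K2 <- radial_active_contour(pol2, 25, 42, smoothness = 5, "dark_to_light")
  expect_true(all(abs(K2$radius - 35) <= 1))

  # sinusoidally modulated boundary is recovered within 2 px
  th <- seq(0, 359) * pi / 180
  rho <- 28 + 3 * sin(3 * th)
  dr <- matrix(seq_len(96) - ctr[1], 96, 96)
  dc <- matrix(seq_len(96) - ctr[2], 96, 96, byrow = TRUE)
  phid <- (atan2(-dr, dc) * 180 / pi) %% 360
  rho_pix <- rho[pmin(floor(phid) + 1, 360)]
  img3 <- 0.85 + (0.25 - 0.85) *
    pmin(pmax((rho_pix - sqrt(dr^2 + dc^2)) / 1.2 + 0.5, 0), 1)
  K3 <- radial_active_contour(polar_of(img3, ctr), 18, 40, smoothness = 1,
                              "dark_to_light")
  expect_lt(max(abs(K3$radius - rho)), 2)

  expect_error(radial_active_contour(pol, 40, 10, 2, "dark_to_light"),
               class = "pex_config_error")
})

test_that("circular DP cost equals exhaustive enumeration on toy grids", {
  set.seed(42)
  cases <- list(c(5, 6), c(4, 8), c(6, 5), c(3, 12), c(20, 4), c(2, 12))
  for (cs in cases) {
    nR <- cs[1]; C <- cs[2]
    for (lam in c(0, 0.7, 2)) {
      E <- matrix(rnorm(nR * C), nR, C)
      dp <- pexquant:::.snake_dp(E, lam)
      expect_equal(dp$cost, enum_snake_min(E, lam), tolerance = 1e-12)
      # the returned path must realize the returned cost
      pc <- sum(E[cbind(dp$path, seq_len(C))]) +
        lam * sum(abs(diff(c(dp$path, dp$path[1]))))
      expect_equal(pc, dp$cost, tolerance = 1e-12)
    }
  }
})

test_that("full contour extraction respects ordering and matches phantom ground truth", {
  ph <- render_phantom(test_phantom_spec(seed = 21, noise_var = 0))
  gray <- preprocess(ph$image)
  pol <- to_polar(gray, ph$spec$center, floor(96))
  Kz <- pupil_contour(pol)
  ct <- extract_contours(pol, Kz)
  expect_true(all(Kz$radius <= ct$pex$radius + 1e-9))
  expect_true(all(ct$pex$radius <= ct$iris$radius + 1e-9))
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(ct$pex$radius - ph$truth$pex$radius), 3)
  expect_lt(rms(ct$iris$radius - ph$truth$iris$radius), 3)
})

test_that("a missing PEX band collapses onto the pupil margin and flags unreliable", {
  # uniform iris with no deposit: K_P has no edge to find
  spec <- test_phantom_spec(seed = 31, noise_var = 0)
  spec$pex_profile <- rep(spec$pupil_radius, 360)   # rim hidden at pupil edge
  ph <- render_phantom(spec)
  m <- measure_phantom(ph)
  expect_false(m$result$reliable)
  expect_lt(mean(m$result$contours$pex$radius - m$result$contours$pupil$radius), 6)
})
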