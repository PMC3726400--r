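test_that("phantom rendering is deterministic and internally consistent", {
  spec <- test_phantom_spec(seed = 17, noise_var = 0.01)
  p1 <- render_phantom(spec)
  p2 <- render_phantom(spec)
  expect_identical(p1$image, p2$image)

  # generator/metric closure: the ground-truth contours reproduce the
  # analytic severity through the same statistic the pipeline uses
  w <- compute_wpex(p1$truth$pex, p1$truth$iris)
  expect_equal(as.numeric(w), p1$truth$w_pex_true, tolerance = 1e-6)

  expect_equal(dim(p1$image), c(192L, 192L, 3L))
  expect_true(all(p1$image >= 0 & p1$image <= 1))
})

test_that("the additive noise has the configured variance", {
  base <- eye_phantom_spec(size = c(320, 320), pupil_radius = 56,
                           iris_radius = 144, seed = 23, noise_var = 0)
  noisy <- base
  noisy$noise_var <- 0.05
  i0 <- render_phantom(base, clip = FALSE)$image
  i1 <- render_phantom(noisy, clip = FALSE)$image
  dv <- var(as.vector(i1 - i0))
  expect_gt(length(i0), 1e5)
  expect_lt(abs(dv - 0.05) / 0.05, 0.05)
})

test_that("random PEX profiles are range-bounded and band-limited", {
  expect_equal(random_pex_profile(1, 30, 80, 3, amplitude = 0),
               rep(55, 360))
  for (seed in 1:20) {
    p <- random_pex_profile(seed, 30, 80, 3, amplitude = 0.8)
    expect_true(min(p) > 30)
    expect_true(max(p) <= 80)
  }
  # discrete spectrum: no energy above the configured harmonic
  p <- random_pex_profile(99, 30, 80, n_harmonics = 4, amplitude = 0.5)
  sp <- Mod(fft(p - mean(p)))[2:180]         # harmonics 1..179
  expect_gt(sum(sp[1:4]), 1e-6)
  expect_lt(max(sp[5:179]), 1e-8 * max(sp[1:4]))
})

test_that("invalid phantom specifications are rejected", {
  expect_error(eye_phantom_spec(size = c(40, 192), pupil_radius = 10,
                                iris_radius = 15), class = "pex_config_error")
  expect_error(eye_phantom_spec(pupil_radius = 50, iris_radius = 40),
               class = "pex_config_error")
  expect_error(eye_phantom_spec(pupil_radius = 30, iris_radius = 200),
               class = "pex_config_error")
  expect_error(eye_phantom_spec(pupil_radius = 30, iris_radius = 80,
                                noise_var = 0.2), class = "pex_config_error")
  expect_error(eye_phantom_spec(pupil_radius = 30, iris_radius = 80,
                                pex_profile = rep(90, 360)),
               class = "pex_config_error")
})

test_that("the phantom suite spans the severity range and pupil regimes", {
  specs <- phantom_suite(12, seed = 3, noise_var = 0)
  meta <- attr(specs, "meta")
  expect_equal(nrow(meta), 12)
  expect_equal(range(meta$w_true), c(5, 60))
  expect_setequal(unique(meta$regime), c(0.60, 0.35, 0.10))
  for (i in seq_along(specs)) {
    tr <- render_phantom(specs[[i]])$truth
    expect_equal(tr$w_pex_true, meta$w_true[i], tolerance = 0.02)
    expect_equal(2 * specs[[i]]$pupil_radius / specs[[i]]$size[1],
                 meta$regime[i], tolerance = 1e-9)
  }
})
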