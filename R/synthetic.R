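#' Specification of a synthetic anterior-segment phantom
#'
#' Describes a synthetic eye image with known geometry: a dark near-circular
#' pupil, a textured iris annulus, an irregular grayish PEX deposit band
#' between the pupil edge and the iris border, a bright sclera, optional
#' specular highlight discs, and additive Gaussian noise. The geometry gives
#' exact ground-truth contours for validating the measurement pipeline.
#'
#' The PEX profile may touch the pupil radius (`r_p(theta) = r_z`), which
#' models a PEX rim hidden at the pupil margin — the situation the
#' reliability flag must detect.
#'
#' @param size Image size `c(M, N)` in pixels (each >= 64).
#' @param center Pupil centre `(row, col)`; default the image midpoint.
#' @param pupil_radius Pupil radius `r_z` in pixels.
#' @param iris_radius Iris outer radius `r_i`; must satisfy
#'   `r_z < r_i <= 0.5 * min(M, N)`.
#' @param pex_profile Per-angle PEX rim radius on the 1-degree grid (length
#'   360), with `r_z <= r_p(theta) <= r_i`; default halfway between pupil
#'   and iris.
#' @param levels Named intensities in `[0, 1]` for `pupil`, `iris`, `pex`,
#'   `sclera`.
#' @param highlights List of specular highlights, each
#'   `list(center = c(row, col), radius, intensity)`.
#' @param noise_var Variance of the additive zero-mean Gaussian noise, in
#'   `[0, 0.05]`.
#' @param seed Integer seed; rendering is fully deterministic given the spec.
#' @return Object of class `eye_phantom_spec`.
#' @export
eye_phantom_spec <- function(size = c(192L, 192L), center = NULL,
                             pupil_radius, iris_radius, pex_profile = NULL,
                             levels = c(pupil = 0.05, iris = 0.45,
                                        pex = 0.62, sclera = 0.92),
                             highlights = list(), noise_var = 0, seed = 1L) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 64L))
    .pex_error("size must be c(M, N) with both >= 64", "pex_config_error")
  if (is.null(center)) center <- (size + 1) / 2
  if (is.null(pex_profile))
    pex_profile <- rep((pupil_radius + iris_radius) / 2, 360L)
  if (length(pex_profile) != 360L)
    .pex_error("pex_profile must have length 360 (1-degree grid)", "pex_config_error")
  if (!(pupil_radius > 0 && pupil_radius < iris_radius &&
        iris_radius <= 0.5 * min(size)))
    .pex_error("need 0 < pupil_radius < iris_radius <= 0.5 * min(size)",
               "pex_config_error")
  if (any(pex_profile < pupil_radius - 1e-9) || any(pex_profile > iris_radius + 1e-9))
    .pex_error("pex_profile must satisfy r_z <= r_p(theta) <= r_i", "pex_config_error")
  if (!all(c("pupil", "iris", "pex", "sclera") %in% names(levels)) ||
      any(levels < 0) || any(levels > 1))
    .pex_error("levels must name pupil, iris, pex, sclera in [0,1]", "pex_config_error")
  if (!is.finite(noise_var) || noise_var < 0 || noise_var > 0.05)
    .pex_error("noise_var must lie in [0, 0.05]", "pex_config_error")
  structure(list(size = size, center = as.numeric(center),
                 pupil_radius = as.numeric(pupil_radius),
                 iris_radius = as.numeric(iris_radius),
                 pex_profile = as.numeric(pex_profile), levels = levels,
                 highlights = highlights, noise_var = as.numeric(noise_var),
                 seed = as.integer(seed)),
            class = "eye_phantom_spec")
}

#' Random band-limited PEX rim profile
#'
#' Draws a smooth periodic radius profile from `n_harmonics` random Fourier
#' harmonics, rescaled so the profile stays inside `(r_z, r_i]` by
#' construction (no clipping, so the spectrum is exactly band-limited).
#'
#' @param seed Integer seed.
#' @param r_z,r_i Pupil and iris radii bounding the profile.
#' @param n_harmonics Highest harmonic used (default 3).
#' @param amplitude Fraction in `[0, 1)` of the available room used by the
#'   modulation; 0 gives a constant profile.
#' @param mean_radius Mean of the profile; default midway between `r_z` and
#'   `r_i`. Useful for targeting a specific true severity, since
#'   `w_true = (1 - mean_radius / r_i) * 100` for a band-limited profile.
#' @return Numeric vector of length 360 (1-degree grid).
#' @export
random_pex_profile <- function(seed, r_z, r_i, n_harmonics = 3L,
                               amplitude = 0.35, mean_radius = (r_z + r_i) / 2) {
  if (!is.finite(amplitude) || amplitude < 0 || amplitude >= 1)
    .pex_error("amplitude must lie in [0, 1)", "pex_config_error")
  if (!(mean_radius > r_z && mean_radius <= r_i))
    .pex_error("mean_radius must lie in (r_z, r_i]", "pex_config_error")
  th <- seq(0, 359) * pi / 180
  if (amplitude == 0 || n_harmonics < 1)
    return(rep(mean_radius, 360L))
  raw <- .with_seed(seed, {
    out <- numeric(360L)
    for (h in seq_len(n_harmonics)) {
      ab <- stats::rnorm(2L, 0, 1 / h)
      out <- out + ab[1L] * cos(h * th) + ab[2L] * sin(h * th)
    }
    out
  })
  mx <- max(abs(raw))
  if (mx < 1e-12) return(rep(mean_radius, 360L))
  room <- min(r_i - mean_radius, mean_radius - r_z)
  mean_radius + amplitude * room * raw / mx
}

#' Render a synthetic eye phantom
#'
#' Deterministically renders the phantom described by `spec`: regions are
#' composited from the outside in (sclera, iris with low-amplitude fibre
#' texture, PEX band with mild mottling, pupil, specular highlights) with
#' smooth ~1-pixel anti-aliased boundaries, converted to three slightly
#' tinted colour channels, and finally corrupted with additive Gaussian
#' noise of the configured variance.
#'
#' @param spec An [eye_phantom_spec()].
#' @param clip Clip the noisy image into `[0, 1]` (default `TRUE`). Setting
#'   `FALSE` exposes the unclipped values, e.g. to verify the noise variance.
#' @return Object of class `eye_phantom`: list with `image` (`M x N x 3`
#'   array), `truth` (ground-truth contours on the 1-degree grid plus the
#'   analytic `w_pex_true`), and `spec`.
#' @export
render_phantom <- function(spec, clip = TRUE) {
  stopifnot(inherits(spec, "eye_phantom_spec"))
  M <- spec$size[1]; N <- spec$size[2]
  cm <- spec$center[1]; cn <- spec$center[2]
  dr <- matrix(seq_len(M) - cm, M, N)
  dc <- matrix(seq_len(N) - cn, M, N, byrow = TRUE)
  d <- sqrt(dr^2 + dc^2)
  thdeg <- (atan2(-dr, dc) * 180 / pi) %% 360
  # periodic linear interpolation of the rim profile at each pixel's angle
  i0 <- floor(thdeg)
  fr <- thdeg - i0
  prof <- spec$pex_profile
  rp <- prof[i0 + 1L] * (1 - fr) + prof[(i0 + 1L) %% 360L + 1L] * fr
  dim(rp) <- dim(d)

  w <- 1.2                                  # anti-aliasing edge width (px)
  soft <- function(x) pmin(pmax(x / w + 0.5, 0), 1)
  lv <- spec$levels
  img1 <- .with_seed(spec$seed, {
    ph <- stats::runif(6L, 0, 2 * pi)
    nfib <- sample(18:28, 1L)
    thr <- thdeg * pi / 180
    # textures modulate along the angle only (radial factors vary slowly):
    # real iris fibres and deposit flakes are angular structures, and sharp
    # radially periodic texture would create spurious ring edges
    iris_tex <- lv[["iris"]] +
      0.035 * sin(nfib * thr + ph[1L]) * cos(2 * pi * d / 40 + ph[2L])
    pex_tex <- lv[["pex"]] +
      0.03 * sin(5 * thr + ph[3L]) + 0.015 * sin(11 * thr + ph[4L])
    base <- matrix(lv[["sclera"]], M, N)
    base <- base + (iris_tex - base) * soft(spec$iris_radius - d)
    base <- base + (pex_tex - base) * soft(rp - d)
    base <- base + (lv[["pupil"]] - base) * soft(spec$pupil_radius - d)
    for (hgl in spec$highlights) {
      dh <- sqrt((matrix(seq_len(M), M, N) - hgl$center[1])^2 +
                   (matrix(seq_len(N), M, N, byrow = TRUE) - hgl$center[2])^2)
      base <- base + (hgl$intensity - base) * soft(hgl$radius - dh)
    }
    gains <- c(1.02, 1.00, 0.96)
    img <- array(0, c(M, N, 3L))
    for (k in 1:3) img[, , k] <- pmin(pmax(base * gains[k], 0), 1)
    if (spec$noise_var > 0)
      img <- img + array(stats::rnorm(M * N * 3L, 0, sqrt(spec$noise_var)),
                         c(M, N, 3L))
    img
  })
  if (clip) {
    img1[img1 < 0] <- 0
    img1[img1 > 1] <- 1
  }
  ang <- seq(0, 359)
  truth <- list(
    pupil = radial_contour(rep(spec$pupil_radius, 360L), "pupil", angles = ang),
    pex = radial_contour(pmax(prof, 1e-6), "pex", angles = ang),
    iris = radial_contour(rep(spec$iris_radius, 360L), "iris", angles = ang),
    w_pex_true = mean((spec$iris_radius - prof) / spec$iris_radius) * 100)
  structure(list(image = img1, truth = truth, spec = spec),
            class = "eye_phantom")
}

#' Build a suite of phantom specifications spanning severities and pupil sizes
#'
#' Creates `n` phantom specs with true severities uniformly spaced over
#' `w_range` and three pupil-size regimes (pupil diameter covering roughly
#' 60%, 35% and 10% of the frame height, emulating high, medium and low
#' magnification). Low severities are assigned to the large-pupil regime and
#' high severities to the small-pupil regime, since a large pupil leaves
#' little radial room for an extensive deposit.
#'
#' @param n Number of phantoms (default 30).
#' @param seed Base seed; every phantom derives its own seed from it.
#' @param size Frame side in pixels (square frames, default 192).
#' @param noise_var Gaussian noise variance applied to every phantom.
#' @param w_range True severity range in percent (default `c(5, 60)`).
#' @param regimes Pupil-diameter fractions of the frame height for the three
#'   regimes, matched to ascending severity thirds.
#' @return List of `eye_phantom_spec` objects; attribute `meta` is a
#'   data.frame with per-phantom `w_true`, `regime` and `seed`.
#' @export
phantom_suite <- function(n = 30L, seed = 42L, size = 192L,
                          noise_var = 0.005, w_range = c(5, 60),
                          regimes = c(0.60, 0.35, 0.10)) {
  stopifnot(n >= 3L, length(regimes) == 3L)
  w <- seq(w_range[1], w_range[2], length.out = n)
  grp <- cut(seq_len(n), 3L, labels = FALSE)
  specs <- vector("list", n)
  meta <- data.frame(id = seq_len(n), w_true = w,
                     regime = regimes[grp], seed = seed + 7919L * seq_len(n))
  for (i in seq_len(n)) {
    frac <- regimes[grp[i]]
    r_z <- frac * size / 2
    r_i <- if (frac >= 0.5) 0.48 * size else 0.45 * size
    mean_radius <- r_i * (1 - w[i] / 100)
    if (mean_radius <= r_z + 2)
      .pex_error(sprintf("severity %.1f%% infeasible for pupil regime %.2f",
                         w[i], frac), "pex_config_error")
    prof <- random_pex_profile(meta$seed[i], r_z, r_i, n_harmonics = 3L,
                               amplitude = 0.35, mean_radius = mean_radius)
    jit <- .with_seed(meta$seed[i] + 1L, round(stats::runif(2L, -3, 3)))
    ctr <- c((size + 1) / 2 + jit[1L], (size + 1) / 2 + jit[2L])
    hl <- list(list(center = ctr + c(-0.3, 0.25) * r_z,
                    radius = max(2, 0.12 * r_z), intensity = 1.0))
    specs[[i]] <- eye_phantom_spec(size = c(size, size), center = ctr,
                                   pupil_radius = r_z, iris_radius = r_i,
                                   pex_profile = prof, highlights = hl,
                                   noise_var = noise_var, seed = meta$seed[i])
  }
  attr(specs, "meta") <- meta
  specs
}
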