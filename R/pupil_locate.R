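#' Build an oriented step-edge mask
#'
#' Constructs the square zero-mean convolution mask used to compute the
#' direction field. The base template is a smoothed step edge: weights change
#' sign across the orientation axis (a `tanh` profile in the perpendicular
#' direction) and are tapered by an isotropic Gaussian envelope. Masks at
#' other orientations are obtained by rotating the base template with
#' bilinear resampling and re-enforcing the zero mean, so the response on any
#' constant region is exactly zero.
#'
#' Angles are measured in degrees from the image row axis, counter-clockwise;
#' the direction vector of orientation `theta` is `(-sin theta, cos theta)`
#' in (row, col) coordinates. This convention is shared with [to_polar()].
#'
#' @param size Odd mask size in pixels (the single instrument parameter;
#'   45 suits a full-resolution slit-lamp frame).
#' @param theta Orientation in degrees, in `[0, 180)`.
#' @return `size x size` numeric matrix with zero sum.
#' @export
oriented_mask <- function(size, theta) {
  size <- .stopifnot_odd(size, "mask size")
  if (!is.finite(theta) || theta < 0 || theta >= 180)
    .pex_error("theta must lie in [0, 180)", "pex_config_error")
  h <- (size - 1L) / 2
  dr <- matrix(-h:h, size, size)           # row offsets
  dc <- matrix(-h:h, size, size, byrow = TRUE)
  sigma <- size / 4.5
  tau <- 1.5                               # edge softness in pixels
  base <- tanh(-dr / tau) * exp(-(dr^2 + dc^2) / (2 * sigma^2))
  base <- base - mean(base)
  if (theta == 0) return(base)
  # rotate: sample the base template at coordinates rotated by -theta
  th <- theta * pi / 180
  sr <- cos(th) * dr + sin(th) * dc
  sc <- -sin(th) * dr + cos(th) * dc
  rr <- sr + h + 1
  cc <- sc + h + 1
  inside <- rr >= 1 & rr <= size & cc >= 1 & cc <= size
  rot <- matrix(0, size, size)
  rot[inside] <- .bilinear(base, rr[inside], cc[inside])
  rot - mean(rot)
}

#' Compute the direction field of a grayscale image
#'
#' Convolves the image with the oriented mask rotated over the angular range
#' `[0, 180)` in steps of `theta_step` degrees and records, per pixel, the
#' maximum absolute response `L_m` and the winning orientation `L_theta`
#' (ties broken by the smallest angle). Strong `L_m` values trace edges; the
#' orientation is the local edge direction.
#'
#' @param gray `M x N` matrix of gray levels.
#' @param mask_size Odd oriented-mask size (default 45).
#' @param theta_step Angular increment in degrees; must divide 180
#'   (1, 5 or 10 are typical; smaller is slower and more accurate).
#' @return Object of class `direction_field`: list with `response` (`L_m`),
#'   `theta` (`L_theta`, degrees in `[0, 180)`), `mask_size`, `theta_step`.
#' @export
direction_field <- function(gray, mask_size = 45L, theta_step = 5) {
  if (!is.matrix(gray) || !all(is.finite(gray)))
    .pex_error("gray must be a finite numeric matrix", "pex_input_error")
  mask_size <- .stopifnot_odd(mask_size, "mask_size")
  if (mask_size > min(dim(gray)))
    .pex_error("mask is larger than the image", "pex_config_error")
  if (!is.finite(theta_step) || theta_step <= 0 || 180 %% theta_step != 0)
    .pex_error("theta_step must be a positive divisor of 180", "pex_config_error")
  thetas <- seq(0, 180 - theta_step, by = theta_step)
  Lm <- matrix(-Inf, nrow(gray), ncol(gray))
  Lth <- matrix(0, nrow(gray), ncol(gray))
  for (th in thetas) {
    resp <- abs(.filter2r(gray, oriented_mask(mask_size, th)))
    upd <- resp > Lm                       # strict: ties keep the smaller angle
    Lm[upd] <- resp[upd]
    Lth[upd] <- th
  }
  structure(list(response = Lm, theta = Lth,
                 mask_size = mask_size, theta_step = theta_step),
            class = "direction_field")
}

#' Localize the pupil centre by perpendicular-line voting
#'
#' Every strong direction-field pixel casts votes along the straight line
#' perpendicular to its edge orientation (slope `L_theta + 90` degrees),
#' rasterized in both directions over the distance range
#' `[r_min, r_max]`. For a circular boundary all perpendiculars pass through
#' the centre, so the vote accumulator `L_T` peaks there. The centre is the
#' argmax of a 5 x 5 smoothed `L_T` (lexicographic tie-break: smallest row,
#' then smallest column).
#'
#' The accumulator also tracks `L_r`, the running mean distance from voters
#' to each cell. Because all circular structures of the eye (pupil rim, PEX
#' rim, iris/sclera border) are concentric and vote through the same centre,
#' the pupil radius `r_z` is estimated from the *innermost* strong peak of
#' the perimeter-normalized distance histogram of the voters whose line
#' passes through the detected centre, rather than from the overall mean.
#'
#' @param field A [direction_field()] result.
#' @param vote_quantile Fraction in (0, 1); only pixels with `L_m` above this
#'   quantile vote (default 0.98). Because the threshold is quantile-based,
#'   voting is invariant under affine brightness changes.
#' @param r_min,r_max Vote distance range in pixels, `0 <= r_min < r_max`.
#' @return Object of class `center_accumulator`: list with `votes` (`L_T`),
#'   `radius_mean` (`L_r`), `center` (row, col; sub-pixel refined),
#'   `center_int` (the raw accumulator argmax), `pupil_radius` (`r_z`),
#'   `low_confidence` flag, and `n_voters`.
#' @export
vote_center <- function(field, vote_quantile = 0.98, r_min, r_max) {
  stopifnot(inherits(field, "direction_field"))
  if (!is.finite(vote_quantile) || vote_quantile <= 0 || vote_quantile >= 1)
    .pex_error("vote_quantile must be in (0, 1)", "pex_config_error")
  if (!(r_min >= 0 && r_min < r_max))
    .pex_error("need 0 <= r_min < r_max", "pex_config_error")
  Lm <- field$response
  M <- nrow(Lm); N <- ncol(Lm)
  thr <- stats::quantile(Lm, vote_quantile, names = FALSE)
  voters <- which(Lm > thr & Lm > 1e-12)
  if (length(voters) == 0L)
    .pex_error("no pupil found: no edge response above the vote threshold",
               "pex_no_pupil")
  vr <- (voters - 1L) %% M + 1L
  vc <- (voters - 1L) %/% M + 1L
  psi <- ((field$theta[voters] + 90) %% 180) * pi / 180
  ur <- -sin(psi)                          # unit direction of the normal line
  uc <- cos(psi)

  tt <- seq(ceiling(r_min), floor(r_max))
  tt <- c(tt, -tt)                         # both directions along the normal
  nv <- length(voters)
  RR <- round(matrix(vr, nv, length(tt)) + outer(ur, tt))
  CC <- round(matrix(vc, nv, length(tt)) + outer(uc, tt))
  DD <- matrix(abs(tt), nv, length(tt), byrow = TRUE)
  keep <- RR >= 1 & RR <= M & CC >= 1 & CC <= N
  idx <- (CC[keep] - 1L) * M + RR[keep]
  cnt <- tabulate(idx, nbins = M * N)
  dsum <- numeric(M * N)
  ds <- rowsum(DD[keep], group = idx)
  dsum[as.integer(rownames(ds))] <- ds
  L_T <- matrix(cnt, M, N)
  L_r <- matrix(ifelse(cnt > 0, dsum / pmax(cnt, 1L), 0), M, N)

  sm <- .filter2r(L_T, matrix(1 / 25, 5, 5))
  mx <- max(sm)
  cand <- which(sm >= mx - 1e-9)
  cr <- (cand - 1L) %% M + 1L
  cc2 <- (cand - 1L) %/% M + 1L
  o <- order(cr, cc2)[1L]
  center_int <- c(cr[o], cc2[o])
  # sub-pixel peak refinement (quadratic interpolation of the smoothed
  # accumulator); matters most for small pupils where a half-pixel centre
  # error is a sizeable fraction of the radius
  center <- center_int
  qoff <- function(a, b, cc) {
    den <- a - 2 * b + cc
    if (!is.finite(den) || den >= 0) return(0)
    min(max(0.5 * (a - cc) / den, -0.5), 0.5)
  }
  if (all(center_int > 1) && center_int[1] < M && center_int[2] < N) {
    i <- center_int[1]; j <- center_int[2]
    center <- c(i + qoff(sm[i - 1, j], sm[i, j], sm[i + 1, j]),
                j + qoff(sm[i, j - 1], sm[i, j], sm[i, j + 1]))
  }

  # distance histogram of voters whose perpendicular passes near the centre
  vdr <- center[1] - vr
  vdc <- center[2] - vc
  tstar <- vdr * ur + vdc * uc
  off <- sqrt((vdr - tstar * ur)^2 + (vdc - tstar * uc)^2)
  sel <- off <= 1.5 & abs(tstar) >= r_min & abs(tstar) <= r_max
  d <- abs(tstar[sel])
  dw <- Lm[voters][sel]                    # response-weighted evidence
  low_conf <- length(d) < 0.05 * nv
  if (length(d) < 5L) {
    r_z <- if (length(d)) mean(d) else NA_real_
    low_conf <- TRUE
  } else {
    b0 <- max(1L, floor(r_min))
    bins <- tabulate(pmax(round(d) - b0 + 1L, 1L), nbins = ceiling(r_max) - b0 + 1L)
    w <- bins / pmax(b0:(b0 + length(bins) - 1L), 1L)  # votes per unit perimeter
    w <- as.numeric(stats::filter(c(0, 0, w, 0, 0), c(1, 2, 3, 2, 1) / 9,
                                  sides = 2))[3:(length(w) + 2L)]
    pk <- which(w >= c(-Inf, w[-length(w)]) & w >= c(w[-1], -Inf) &
                  w >= 0.25 * max(w))
    if (length(pk) == 0L) {
      r_z <- mean(d); low_conf <- TRUE
    } else {
      r_pk <- pk[1L] + b0 - 1L             # innermost strong peak
      inpk <- abs(d - r_pk) <= 2.5
      r_z <- sum(d[inpk] * dw[inpk]) / sum(dw[inpk])
    }
  }
  structure(list(votes = L_T, radius_mean = L_r, center = center,
                 center_int = center_int, pupil_radius = r_z,
                 low_confidence = low_conf, n_voters = nv,
                 vote_threshold = thr),
            class = "center_accumulator")
}
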