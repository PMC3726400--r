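#' Resample a grayscale image into polar coordinates
#'
#' Samples the image on a polar grid about `center`: radii `0, 1, ...,
#' r_max_polar - 1` (rows) and angles `0, angular_step, ..., 360 -
#' angular_step` degrees (columns). The Cartesian position of the sample at
#' radius `r` and angle `theta` is `row = center_row - r * sin(theta)`,
#' `col = center_col + r * cos(theta)` (angles counter-clockwise from the
#' row axis, matching [oriented_mask()]). Sampling is bilinear by default;
#' samples falling outside the image are filled with the nearest valid pixel
#' and flagged `FALSE` in the validity mask.
#'
#' @param gray `M x N` matrix of gray levels in `[0, 1]`.
#' @param center Numeric `(row, col)`, inside the image.
#' @param r_max_polar Number of radial samples (>= 8).
#' @param angular_step Angular step in degrees; must divide 360 (default 1).
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return Object of class `polar_image`: list with `pixels`
#'   (`r_max_polar x 360/angular_step` matrix), `valid` (logical mask),
#'   `center`, `angles` (degrees), `angular_step`.
#' @export
to_polar <- function(gray, center, r_max_polar, angular_step = 1,
                     method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (!is.matrix(gray)) .pex_error("gray must be a matrix", "pex_input_error")
  M <- nrow(gray); N <- ncol(gray)
  if (length(center) != 2L || center[1] < 1 || center[1] > M ||
      center[2] < 1 || center[2] > N)
    .pex_error("center must lie inside the image", "pex_input_error")
  if (!is.finite(r_max_polar) || r_max_polar < 8)
    .pex_error("r_max_polar must be >= 8", "pex_config_error")
  if (!is.finite(angular_step) || angular_step <= 0 || 360 %% angular_step != 0)
    .pex_error("angular_step must divide 360", "pex_config_error")
  angles <- seq(0, 360 - angular_step, by = angular_step)
  arad <- angles * pi / 180
  r <- seq.int(0L, r_max_polar - 1L)
  RW <- center[1] - outer(r, sin(arad))
  CL <- center[2] + outer(r, cos(arad))
  valid <- RW >= 1 & RW <= M & CL >= 1 & CL <= N
  P <- if (method == "bilinear") {
    matrix(.bilinear(gray, as.vector(RW), as.vector(CL)), length(r))
  } else {
    rr <- pmin(pmax(round(RW), 1), M)
    cc <- pmin(pmax(round(CL), 1), N)
    matrix(gray[(cc - 1) * M + rr], length(r))
  }
  structure(list(pixels = P, valid = valid, center = center,
                 angles = angles, angular_step = angular_step),
            class = "polar_image")
}

#' Resample a polar image back onto a Cartesian grid
#'
#' Inverse of [to_polar()], mainly used to verify the fidelity of the polar
#' transform. Pixels outside the sampled disc are `NA`.
#'
#' @param polar A [to_polar()] result.
#' @param dim Output dimension `c(M, N)`.
#' @return `M x N` matrix with `NA` outside the sampled disc.
#' @export
from_polar <- function(polar, dim) {
  stopifnot(inherits(polar, "polar_image"))
  M <- dim[1]; N <- dim[2]
  P <- polar$pixels
  nr <- nrow(P); nc <- ncol(P)
  # append the first angular column so interpolation wraps at 360 degrees
  Pw <- cbind(P, P[, 1L])
  dr <- matrix(seq_len(M) - polar$center[1], M, N)
  dc <- matrix(seq_len(N) - polar$center[2], M, N, byrow = TRUE)
  d <- sqrt(dr^2 + dc^2)
  th <- (atan2(-dr, dc) * 180 / pi) %% 360
  out <- matrix(NA_real_, M, N)
  ok <- d <= nr - 1
  out[ok] <- .bilinear(Pw, d[ok] + 1, th[ok] / polar$angular_step + 1)
  out
}
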