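#' Radial contour constructor
#'
#' A radial contour is a closed curve in polar space: one radius (in pixels
#' from the pupil centre) per angular sample, with a per-angle validity flag.
#'
#' @param radius Numeric vector of radii (> 0 at valid angles).
#' @param label One of `"pupil"`, `"pex"`, `"iris"`.
#' @param angles Angular grid in degrees.
#' @param valid Logical vector (default all `TRUE`).
#' @return Object of class `radial_contour`.
#' @export
radial_contour <- function(radius, label = c("pupil", "pex", "iris"),
                           angles = seq(0, 360 - 360 / length(radius),
                                        length.out = length(radius)),
                           valid = rep(TRUE, length(radius))) {
  label <- match.arg(label)
  if (length(valid) != length(radius) || length(angles) != length(radius))
    .pex_error("radius, angles and valid must have equal length", "pex_input_error")
  if (any(!is.finite(radius[valid])) || any(radius[valid] <= 0))
    .pex_error("radii must be finite and positive at valid angles", "pex_input_error")
  structure(list(radius = as.numeric(radius), label = label,
                 angles = as.numeric(angles), valid = as.logical(valid)),
            class = "radial_contour")
}

# periodic least-squares fit in a harmonic (Fourier) basis; degree = number
# of cos/sin pairs. A power-basis polynomial in theta would not close at
# 0/360 degrees, so the fit is done in the harmonic basis.
.fit_harmonic <- function(theta_rad, y, degree) {
  X <- matrix(1, length(y), 1L)
  if (degree > 0) {
    for (h in seq_len(degree))
      X <- cbind(X, cos(h * theta_rad), sin(h * theta_rad))
  }
  cf <- stats::lm.fit(X, y)$coefficients
  cf[!is.finite(cf)] <- 0
  function(th) {
    Xp <- matrix(1, length(th), 1L)
    if (degree > 0) {
      for (h in seq_len(degree))
        Xp <- cbind(Xp, cos(h * th), sin(h * th))
    }
    as.numeric(Xp %*% cf)
  }
}

#' Extract the pupil contour from a polar image
#'
#' Binarizes the polar image with Otsu's threshold, keeps the dark (pupil)
#' class, fills enclosed holes (e.g. specular highlights inside the pupil) by
#' morphological reconstruction, reads off the raw pupil edge per angular
#' column as the end of the dark run that starts at radius 0, and smooths the
#' edge with a periodic harmonic least-squares fit.
#'
#' @param polar A [to_polar()] result.
#' @param poly_degree Number of harmonic pairs in the periodic fit
#'   (default 4; 0 fits a circle).
#' @return A `radial_contour` labelled `"pupil"`, with attributes
#'   `otsu_threshold` and `raw_radius` (the per-column edge before fitting,
#'   `NA` where no dark run starts at the centre).
#' @export
pupil_contour <- function(polar, poly_degree = 4L) {
  stopifnot(inherits(polar, "polar_image"))
  if (!is.finite(poly_degree) || poly_degree < 0)
    .pex_error("poly_degree must be >= 0", "pex_config_error")
  P <- polar$pixels
  thr <- EBImage::otsu(EBImage::Image(P), range = c(0, 1))
  B <- P < thr
  # hole filling must respect polar topology: pad a foreground row at r = 0
  # (a highlight overlapping the origin touches that border and would not
  # count as enclosed) and tile three times along the angle (a blob crossing
  # the 0/360-degree seam would touch the lateral borders); keep the middle
  # tile
  nc0 <- ncol(B)
  Bp <- rbind(TRUE, B)
  Bt <- cbind(Bp, Bp, Bp)
  Bt <- EBImage::imageData(EBImage::fillHull(EBImage::Image(Bt * 1))) > 0.5
  B <- Bt[-1L, (nc0 + 1L):(2L * nc0), drop = FALSE]
  nc <- ncol(B)
  raw <- rep(NA_real_, nc)
  for (j in seq_len(nc)) {
    v <- B[, j]
    if (!v[1L]) next                        # centre is not dark in this column
    k <- match(FALSE, v)                    # first background row
    if (is.na(k)) next                      # dark all the way out: unusable
    raw[j] <- k - 1.5                       # midpoint of the dark->light step
  }
  ok <- !is.na(raw) & raw > 0
  if (mean(ok) < 0.5)
    .pex_error("pupil not found at centre: dark region missing in most polar columns",
               "pex_no_pupil")
  # robust two-pass fit: noise speckle fused with the pupil produces gross
  # outliers in single columns, which a plain least-squares harmonic fit
  # would swing around; trim against the first fit and refit
  arad <- polar$angles * pi / 180
  fit <- .fit_harmonic(arad[ok], raw[ok], poly_degree)
  resid <- raw[ok] - fit(arad[ok])
  tol <- max(3 * stats::mad(resid), 1.5)
  keep <- abs(resid) <= tol
  if (sum(keep) >= max(8, 2 * (2 * poly_degree + 1)) && !all(keep))
    fit <- .fit_harmonic(arad[ok][keep], raw[ok][keep], poly_degree)
  Kz <- pmax(fit(arad), 1)
  out <- radial_contour(Kz, "pupil", angles = polar$angles)
  attr(out, "otsu_threshold") <- as.numeric(thr)
  attr(out, "raw_radius") <- raw
  out
}

# exact min_{j} (D[j] + lam * |i - j|) for all i, by a forward/backward sweep
.l1_min_vec <- function(D, lam) {
  n <- length(D)
  for (i in 2:n) D[i] <- min(D[i], D[i - 1L] + lam)
  for (i in (n - 1L):1) D[i] <- min(D[i], D[i + 1L] + lam)
  D
}

# same transform applied down the rows of a matrix (one column per DP start)
.l1_min_mat <- function(D, lam) {
  n <- nrow(D)
  for (i in 2:n) D[i, ] <- pmin(D[i, ], D[i - 1L, ] + lam)
  for (i in (n - 1L):1) D[i, ] <- pmin(D[i, ], D[i + 1L, ] + lam)
  D
}

# globally optimal circular path through an energy matrix E (rows = states,
# columns = angular positions): minimizes sum_j E[path_j, j] +
# lam * sum_j |path_{j+1} - path_j| with periodic closure, by an exact sweep
# over all candidate start states followed by a backtracked fixed-start DP
.snake_dp <- function(E, lam) {
  nR <- nrow(E); C <- ncol(E)
  if (nR == 1L) return(list(path = rep(1L, C), cost = sum(E)))
  D <- matrix(Inf, nR, nR)
  diag(D) <- E[, 1L]
  if (C > 1L) for (j in 2:C) {
    D <- .l1_min_mat(D, lam)
    D <- D + E[, j]
  }
  if (C > 1L) D <- .l1_min_mat(D, lam)      # closing transition back to start
  total <- diag(D)
  s_star <- which.min(total)

  CT <- matrix(Inf, nR, C)
  v <- rep(Inf, nR); v[s_star] <- E[s_star, 1L]
  CT[, 1L] <- v
  if (C > 1L) for (j in 2:C) {
    v <- .l1_min_vec(v, lam)
    v <- v + E[, j]
    CT[, j] <- v
  }
  path <- integer(C)
  states <- seq_len(nR)
  path[C] <- which.min(CT[, C] + if (C > 1L) lam * abs(states - s_star) else 0)
  if (C > 1L) for (j in (C - 1L):1L)
    path[j] <- which.min(CT[, j] + lam * abs(path[j + 1L] - states))
  list(path = path, cost = total[s_star])
}

#' Radial active contour by circular dynamic programming
#'
#' Extracts one closed boundary from a polar image as a "radial snake": one
#' radius per angular column, minimizing the sum of a per-column edge energy
#' (the negative signed radial intensity gradient, sign set by `polarity`)
#' and a smoothness penalty `smoothness * |r(j+1) - r(j)|` between adjacent
#' columns, including the wrap-around between the last and first column. The
#' optimum is found exactly by dynamic programming with a sweep over all
#' candidate radii in the first column, so the returned path is the global
#' minimum of the energy, deterministically.
#'
#' The search is restricted per column to `[r_lo, r_hi]` (scalars or
#' per-column vectors). A small inward bias (`radial_bias` per pixel of
#' radius) makes the contour collapse to its lower band edge when no edge
#' evidence is present, which downstream reliability checks rely on.
#'
#' @param polar A [to_polar()] result.
#' @param r_lo,r_hi Search band per column (pixels from centre).
#' @param smoothness Non-negative weight of the `|delta r|` penalty, in units
#'   of the normalized edge energy per pixel.
#' @param polarity `"dark_to_light"` for boundaries where intensity rises
#'   with radius (iris to sclera), `"light_to_dark"` for boundaries where it
#'   falls (PEX deposit rim to iris).
#' @param radial_bias Small inward pull per radius pixel (default 1e-4).
#' @param subpixel Refine each radius by quadratic interpolation of the edge
#'   energy (default `TRUE`).
#' @param label Contour label for the result.
#' @return A `radial_contour` with attributes `path_cost` (the integer-grid
#'   optimal cost) and `path_int` (the integer path).
#' @export
radial_active_contour <- function(polar, r_lo, r_hi, smoothness = 2,
                                  polarity = c("dark_to_light", "light_to_dark"),
                                  radial_bias = 1e-4, subpixel = TRUE,
                                  label = "pex") {
  stopifnot(inherits(polar, "polar_image"))
  polarity <- match.arg(polarity)
  if (!is.finite(smoothness) || smoothness < 0)
    .pex_error("smoothness must be >= 0", "pex_config_error")
  P <- polar$pixels
  R <- nrow(P); C <- ncol(P)
  r_lo <- rep_len(as.numeric(r_lo), C)
  r_hi <- rep_len(as.numeric(r_hi), C)
  if (any(!is.finite(r_lo)) || any(!is.finite(r_hi)) || any(r_lo >= r_hi))
    .pex_error("need r_lo < r_hi in every column", "pex_config_error")
  lo <- max(1L, floor(min(r_lo)))
  hi <- min(R - 2L, ceiling(max(r_hi)))
  if (hi - lo < 1L)
    .pex_error("empty search band", "pex_contour_error")
  rg <- lo:hi                               # radius values on the DP grid
  ri <- rg + 1L                             # matrix rows (radius r -> row r+1)

  # edge energy: negative signed gradient, normalized by a robust scale
  smP <- (P[pmax(ri - 1L, 1L), , drop = FALSE] + 2 * P[ri, , drop = FALSE] +
            P[pmin(ri + 1L, R), , drop = FALSE]) / 4
  grad <- (P[pmin(ri + 1L, R), , drop = FALSE] -
             P[pmax(ri - 1L, 1L), , drop = FALSE]) / 2
  gsm <- (smP[pmin(seq_along(rg) + 1L, length(rg)), , drop = FALSE] -
            smP[pmax(seq_along(rg) - 1L, 1L), , drop = FALSE]) / 2
  g <- (grad + gsm) / 2
  E <- if (polarity == "dark_to_light") -g else g
  RGm <- matrix(rg, length(rg), C)
  LOm <- matrix(r_lo, length(rg), C, byrow = TRUE)
  HIm <- matrix(r_hi, length(rg), C, byrow = TRUE)
  inband <- RGm >= LOm & RGm <= HIm
  if (!any(inband)) .pex_error("empty search band", "pex_contour_error")
  scale <- stats::quantile(abs(E[inband]), 0.95, names = FALSE)
  if (!is.finite(scale) || scale < 1e-9) scale <- 1
  E <- E / scale + radial_bias * RGm
  BIG <- 1e8
  E[!inband] <- BIG

  nR <- length(rg)
  dp <- .snake_dp(E, smoothness)
  if (dp$cost >= BIG)
    .pex_error("no feasible snake path in the search band", "pex_contour_error")
  path <- dp$path
  radius <- rg[path]
  best_cost <- dp$cost
  if (subpixel) {
    off <- numeric(C)
    can <- path > 1L & path < nR
    i <- which(can)
    if (length(i)) {
      em <- E[cbind(path[i] - 1L, i)]
      e0 <- E[cbind(path[i], i)]
      ep <- E[cbind(path[i] + 1L, i)]
      den <- em - 2 * e0 + ep
      okq <- is.finite(em) & is.finite(ep) & em < BIG / 2 & ep < BIG / 2 & den > 1e-12
      o <- ifelse(okq, 0.5 * (em - ep) / pmax(den, 1e-12), 0)
      off[i] <- pmin(pmax(o, -0.5), 0.5)
    }
    radius <- radius + off
  }
  out <- radial_contour(pmax(radius, 1e-6), label, angles = polar$angles)
  attr(out, "path_cost") <- best_cost
  attr(out, "path_int") <- rg[path]
  # raw polarity-signed gradient at the chosen path: per-angle evidence that
  # an edge of the expected polarity actually exists where the contour sits
  gsign <- if (polarity == "dark_to_light") g else -g
  attr(out, "edge_strength") <- pmax(gsign[cbind(path, seq_len(C))], 0)
  out
}

# TRUE when the contour rests on visible edge evidence everywhere: no
# wrap-around arc of `arc` consecutive angles whose mean edge strength falls
# below `frac` times the overall median strength
.rim_visible <- function(contour, frac = 0.2, arc = 15L) {
  s <- attr(contour, "edge_strength")
  if (is.null(s)) return(TRUE)
  med <- stats::median(s)
  if (!is.finite(med) || med <= 0) return(FALSE)
  k <- max(1L, as.integer(arc))
  sw <- c(s, s[seq_len(k)])                # circular rolling mean
  roll <- stats::filter(sw, rep(1 / k, k), sides = 1)
  roll <- roll[k:(length(s) + k - 1L)]
  min(roll, na.rm = TRUE) >= frac * med
}

#' Extract the PEX and iris contours given the pupil contour
#'
#' Runs the radial snake twice: first for the outer rim of the PEX deposit
#' (`K_P`, a light-to-dark transition searched between the pupil contour plus
#' a safety margin and 95% of the polar range), then for the iris/sclera
#' border (`K_I`, a dark-to-light transition searched outward of `K_P`). The
#' band construction enforces the ordering `K_z <= K_P <= K_I` at every
#' angle. Angles whose contour sample falls outside the original image frame
#' are marked invalid.
#'
#' @param polar A [to_polar()] result.
#' @param K_z Pupil contour from [pupil_contour()].
#' @param pex_margin Safety margin (pixels) above the pupil contour for the
#'   PEX search band (default 3).
#' @param smooth_pex,smooth_iris Snake smoothness weights (defaults 2 and 5:
#'   the PEX rim is irregular, the iris border nearly circular).
#' @return List with elements `pex` and `iris` (`radial_contour`s).
#' @export
extract_contours <- function(polar, K_z, pex_margin = 3,
                             smooth_pex = 2, smooth_iris = 5) {
  stopifnot(inherits(polar, "polar_image"), inherits(K_z, "radial_contour"))
  R <- nrow(polar$pixels)
  rmax <- R - 1L
  r_lo_P <- pmax(K_z$radius + pex_margin, 2)
  r_hi_P <- rep(0.95 * rmax, ncol(polar$pixels))
  if (any(r_lo_P >= r_hi_P - 2))
    .pex_error("pupil fills the polar range; no room for PEX/iris search",
               "pex_contour_error")
  K_P <- radial_active_contour(polar, r_lo_P, r_hi_P, smooth_pex,
                               "light_to_dark", label = "pex")
  r_lo_I <- pmax(K_P$radius + 2, r_lo_P)
  r_hi_I <- rep(rmax - 1L, ncol(polar$pixels))
  K_I <- radial_active_contour(polar, r_lo_I, r_hi_I, smooth_iris,
                               "dark_to_light", label = "iris")
  # validity: the contour sample must come from inside the image frame
  jj <- seq_len(ncol(polar$pixels))
  K_P$valid <- polar$valid[cbind(pmin(round(K_P$radius) + 1L, R), jj)]
  K_I$valid <- polar$valid[cbind(pmin(round(K_I$radius) + 1L, R), jj)]
  list(pex = K_P, iris = K_I)
}
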