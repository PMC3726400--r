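#' Compute the PEX severity statistic W_PEX
#'
#' `W_PEX` measures the relative radial extent of the PEX deposit between the
#' iris border and the PEX rim: the per-angle ratio `(K_I - K_P) / K_I`,
#' averaged over all angles valid in both contours and expressed in percent.
#' (Averaging, rather than a bare sum over angles, keeps the statistic in
#' `[0, 100]` and independent of the angular sampling density.)
#'
#' The statistic is exactly invariant under a common rescaling of all radii,
#' so it does not depend on magnification.
#'
#' @param K_P PEX rim contour (`radial_contour`).
#' @param K_I Iris border contour (`radial_contour`) on the same angular grid.
#' @return Percentage in `[0, 100]`, with attribute `n_valid_angles`. If the
#'   ordering `K_P <= K_I` is violated anywhere, a warning is issued and the
#'   result is clipped into `[0, 100]`.
#' @export
compute_wpex <- function(K_P, K_I) {
  stopifnot(inherits(K_P, "radial_contour"), inherits(K_I, "radial_contour"))
  if (length(K_P$radius) != length(K_I$radius))
    .pex_error("contours must share the angular grid", "pex_input_error")
  ok <- K_P$valid & K_I$valid & K_I$radius > 0
  if (!any(ok))
    .pex_error("no angle is valid in both contours", "pex_metric_error")
  ratio <- (K_I$radius[ok] - K_P$radius[ok]) / K_I$radius[ok]
  if (any(ratio < 0))
    warning("contour ordering violated (K_P > K_I at some angles); clipping W_PEX")
  w <- mean(ratio) * 100
  w <- min(max(w, 0), 100)
  attr(w, "n_valid_angles") <- sum(ok)
  w
}

#' Reliability condition for a W_PEX measurement
#'
#' A measurement is reliable only when the PEX rim is fully visible, i.e. the
#' PEX contour stays strictly above the pupil contour everywhere. When the
#' two contours touch or cross (minimum separation `<= margin` at any valid
#' angle), the PEX rim was not resolved and the measurement is flagged
#' unreliable.
#'
#' @param K_z Pupil contour.
#' @param K_P PEX rim contour on the same angular grid.
#' @param margin Minimum required separation in pixels (default 0).
#' @return `TRUE` (reliable) or `FALSE` (PEX rim coincides with the pupil).
#' @export
reliability_flag <- function(K_z, K_P, margin = 0) {
  stopifnot(inherits(K_z, "radial_contour"), inherits(K_P, "radial_contour"))
  if (length(K_z$radius) != length(K_P$radius))
    .pex_error("contours must share the angular grid", "pex_input_error")
  ok <- K_z$valid & K_P$valid
  if (!any(ok))
    .pex_error("no angle is valid in both contours", "pex_metric_error")
  min(K_P$radius[ok] - K_z$radius[ok]) > margin
}

#' Relative error between a measured and a reference W_PEX
#'
#' Absolute relative deviation `|w_measured - w_reference| / w_reference`
#' in percent, used to compare the automatic measurement against a
#' reference (e.g. a physician's value or a phantom's ground truth).
#'
#' @param w_measured,w_reference Percentages; `w_reference` must be > 0.
#' @return Percentage (>= 0).
#' @export
delta_error <- function(w_measured, w_reference) {
  if (any(!is.finite(w_reference)) || any(w_reference <= 0))
    .pex_error("w_reference must be positive", "pex_metric_error")
  abs(w_measured - w_reference) / w_reference * 100
}
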