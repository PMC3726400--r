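#' Measure a phantom and compare against its ground truth
#'
#' Convenience wrapper: renders the phantom (if given as a spec), measures
#' it with the full pipeline, and reports the error against the analytic
#' ground-truth severity.
#'
#' @param phantom An `eye_phantom` or `eye_phantom_spec`.
#' @param config A [pex_config()]; the default resolution-scaled settings
#'   work for phantom frames.
#' @return List with `result` (`pex_result`), `truth`, `w_pex_true`, and
#'   `delta` (percent relative error of `w_pex` vs the ground truth).
#' @export
measure_phantom <- function(phantom, config = pex_config()) {
  if (inherits(phantom, "eye_phantom_spec")) phantom <- render_phantom(phantom)
  stopifnot(inherits(phantom, "eye_phantom"))
  res <- measure_pex(phantom$image, config)
  list(result = res, truth = phantom$truth,
       w_pex_true = phantom$truth$w_pex_true,
       delta = delta_error(res$w_pex, phantom$truth$w_pex_true))
}

#' Gaussian-noise robustness sweep
#'
#' Re-renders each phantom at every noise variance on the grid, runs the
#' full measurement pipeline, and records the measured severity and its
#' error against the phantom's ground truth. Pipeline failures are recorded
#' per cell (status column) and do not abort the sweep. The sweep is a pure
#' function of its arguments: the per-cell seed is derived from `base_seed`.
#'
#' @param specs List of `eye_phantom_spec` objects (noise settings inside
#'   them are overridden by the grid).
#' @param sigma_grid Noise variances to test (default 0 to 0.05 by 0.005).
#' @param replicates Independent noise draws per (phantom, variance) cell
#'   (default 5).
#' @param base_seed Integer master seed.
#' @param config A [pex_config()].
#' @return data.frame of class `pex_noise_sweep`: one row per cell with
#'   `sigma2`, `phantom`, `replicate`, `seed`, `w_true`, `w_pex`, `delta`,
#'   `reliable`, `status`.
#' @export
noise_sweep <- function(specs, sigma_grid = seq(0, 0.05, by = 0.005),
                        replicates = 5L, base_seed = 1L,
                        config = pex_config()) {
  if (inherits(specs, "eye_phantom_spec")) specs <- list(specs)
  if (replicates < 1L) .pex_error("replicates must be >= 1", "pex_config_error")
  rows <- list()
  n <- 0L
  for (si in seq_along(sigma_grid)) for (pi in seq_along(specs)) {
    for (rep_i in seq_len(replicates)) {
      # paired design (common random numbers): the seed depends on the
      # phantom and replicate but not on the noise level, so each replicate
      # sees the same noise field at growing amplitude — the same protocol
      # as adding increasing noise to one fixed photograph
      seed <- (base_seed + 1009L * pi + 104729L * rep_i) %% 2147483647L
      sp <- specs[[pi]]
      sp$noise_var <- sigma_grid[si]
      sp$seed <- seed
      ph <- render_phantom(sp)
      m <- tryCatch(measure_phantom(ph, config), error = function(e) e)
      n <- n + 1L
      rows[[n]] <- if (inherits(m, "error")) {
        data.frame(sigma2 = sigma_grid[si], phantom = pi, replicate = rep_i,
                   seed = seed, w_true = ph$truth$w_pex_true,
                   w_pex = NA_real_, delta = NA_real_, reliable = NA,
                   status = .error_category(m), stringsAsFactors = FALSE)
      } else {
        data.frame(sigma2 = sigma_grid[si], phantom = pi, replicate = rep_i,
                   seed = seed, w_true = ph$truth$w_pex_true,
                   w_pex = m$result$w_pex, delta = m$delta,
                   reliable = m$result$reliable, status = "ok",
                   stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pex_noise_sweep", class(out))
  out
}

#' Summarize a noise sweep per variance level
#'
#' @param sweep A [noise_sweep()] result.
#' @return data.frame with per-`sigma2` mean measured severity, mean error
#'   versus ground truth (over successful cells), and failure counts.
#' @export
summarize_noise_sweep <- function(sweep) {
  stopifnot(inherits(sweep, "pex_noise_sweep"))
  sp <- split(sweep, sweep$sigma2)
  out <- do.call(rbind, lapply(sp, function(d) {
    ok <- d$status == "ok"
    data.frame(sigma2 = d$sigma2[1], n = nrow(d), n_ok = sum(ok),
               mean_w_pex = if (any(ok)) mean(d$w_pex[ok]) else NA_real_,
               mean_delta = if (any(ok)) mean(d$delta[ok]) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Plot mean severity and error against noise variance
#'
#' @param sweep A [noise_sweep()] result.
#' @param file Optional PNG path; plots to the active device when `NULL`.
#' @return The summary data.frame, invisibly.
#' @export
plot_noise_sweep <- function(sweep, file = NULL) {
  s <- summarize_noise_sweep(sweep)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 450)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(s$sigma2, s$mean_w_pex, type = "b", pch = 19,
                 xlab = expression(sigma^2), ylab = "mean W_PEX [%]",
                 main = "Measured severity vs noise")
  graphics::plot(s$sigma2, s$mean_delta, type = "b", pch = 19,
                 xlab = expression(sigma^2), ylab = "mean delta [%]",
                 main = "Error vs ground truth")
  invisible(s)
}

#' Mean measurement error per magnification surrogate
#'
#' Groups phantom measurements by a magnification surrogate (e.g. the pupil
#' size regime) and reports the mean relative error per group, in the layout
#' of a per-magnification error table.
#'
#' @param results List of [measure_phantom()] results (each carries its own
#'   ground truth).
#' @param groups Vector of group labels, one per result.
#' @return data.frame with `magnification`, `n`, `mean_delta`.
#' @export
magnification_summary <- function(results, groups) {
  if (length(results) != length(groups))
    .pex_error("results and groups must have equal length", "pex_input_error")
  delta <- vapply(results, function(r) r$delta, numeric(1L))
  keep <- is.finite(delta)
  if (!all(keep)) warning(sprintf("%d results without a finite error omitted",
                                  sum(!keep)))
  sp <- split(delta[keep], groups[keep])
  if (length(sp) == 0L) .pex_error("no finite results to summarize",
                                   "pex_input_error")
  out <- data.frame(magnification = names(sp),
                    n = vapply(sp, length, integer(1L)),
                    mean_delta = vapply(sp, mean, numeric(1L)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
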