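#' Pipeline configuration
#'
#' Builds a validated configuration for [measure_pex()]. The only
#' instrument-specific parameter is `mask_size`, the oriented-mask size,
#' chosen once per slit-lamp type (45 for a full-resolution 1280 x 960
#' frame). All remaining parameters have resolution-aware defaults: when
#' `mask_size` or `vote_quantile` is `NULL` it is derived from the image
#' size at measurement time (the mask scales linearly with the frame, and
#' the voting quantile tracks the fraction of edge pixels, which grows as
#' frames shrink).
#'
#' @param mask_size Odd oriented-mask size in pixels, or `NULL` to scale
#'   `45 * min(M, N) / 960` (rounded to odd, minimum 7).
#' @param theta_step Direction-field angular increment in degrees (divisor
#'   of 180; default 5).
#' @param vote_quantile Voting threshold quantile in (0, 1), or `NULL` for
#'   the resolution-scaled default.
#' @param r_min_frac,r_max_frac Vote distance range as fractions of
#'   `min(M, N)` (defaults 0.02 and 0.5).
#' @param angular_step Polar angular step in degrees (default 1).
#' @param pupil_harmonics Harmonic pairs in the pupil-contour fit (default 4).
#' @param smooth_pex,smooth_iris Snake smoothness weights (defaults 2, 5).
#' @param pex_margin Search margin above the pupil contour in pixels
#'   (default 3).
#' @param reliability_slack Extra separation (pixels) beyond `pex_margin`
#'   below which a measurement is flagged unreliable (default 1.5; a snake
#'   pinned to its band floor within rasterization slack means the PEX rim
#'   was not resolved).
#' @param rim_strength_frac,rim_arc Rim-visibility requirement: the
#'   measurement is unreliable when any `rim_arc`-degree arc of the PEX rim
#'   rests on mean edge evidence below `rim_strength_frac` times the median
#'   rim strength (defaults 0.2 and 15). This catches rims that vanish at
#'   the pupil margin even when the snake bridges across the gap.
#' @param median_size Median pre-filter mask size (odd, default 3).
#' @param subpixel Sub-pixel contour refinement (default `TRUE`).
#' @return Object of class `pex_config` (a validated named list).
#' @export
pex_config <- function(mask_size = NULL, theta_step = 5, vote_quantile = NULL,
                       r_min_frac = 0.02, r_max_frac = 0.5, angular_step = 1,
                       pupil_harmonics = 4L, smooth_pex = 2, smooth_iris = 5,
                       pex_margin = 3, reliability_slack = 1.5,
                       rim_strength_frac = 0.2, rim_arc = 15L,
                       median_size = 3L, subpixel = TRUE) {
  cfg <- list(mask_size = mask_size, theta_step = theta_step,
              vote_quantile = vote_quantile, r_min_frac = r_min_frac,
              r_max_frac = r_max_frac, angular_step = angular_step,
              pupil_harmonics = pupil_harmonics, smooth_pex = smooth_pex,
              smooth_iris = smooth_iris, pex_margin = pex_margin,
              reliability_slack = reliability_slack,
              rim_strength_frac = rim_strength_frac, rim_arc = rim_arc,
              median_size = median_size, subpixel = subpixel)
  if (!is.null(cfg$mask_size)) .stopifnot_odd(cfg$mask_size, "mask_size")
  if (!is.null(cfg$vote_quantile) &&
      (cfg$vote_quantile <= 0 || cfg$vote_quantile >= 1))
    .pex_error("vote_quantile must be in (0, 1)", "pex_config_error")
  if (180 %% cfg$theta_step != 0 || cfg$theta_step <= 0)
    .pex_error("theta_step must divide 180", "pex_config_error")
  if (360 %% cfg$angular_step != 0 || cfg$angular_step <= 0)
    .pex_error("angular_step must divide 360", "pex_config_error")
  if (!(cfg$r_min_frac >= 0 && cfg$r_min_frac < cfg$r_max_frac &&
        cfg$r_max_frac <= 0.75))
    .pex_error("need 0 <= r_min_frac < r_max_frac <= 0.75", "pex_config_error")
  if (cfg$pupil_harmonics < 0) .pex_error("pupil_harmonics must be >= 0",
                                          "pex_config_error")
  if (cfg$smooth_pex < 0 || cfg$smooth_iris < 0)
    .pex_error("smoothness weights must be >= 0", "pex_config_error")
  if (cfg$pex_margin < 0 || cfg$reliability_slack < 0)
    .pex_error("margins must be >= 0", "pex_config_error")
  if (cfg$rim_strength_frac < 0 || cfg$rim_strength_frac >= 1 || cfg$rim_arc < 1)
    .pex_error("need 0 <= rim_strength_frac < 1 and rim_arc >= 1",
               "pex_config_error")
  .stopifnot_odd(cfg$median_size, "median_size")
  structure(cfg, class = "pex_config")
}

#' Re-create a configuration from a plain list
#'
#' Inverse of `as.list()` on a `pex_config`; unknown keys are rejected, so
#' serialize -> parse -> serialize is the identity.
#'
#' @param x Named list of configuration values.
#' @return A validated `pex_config`.
#' @export
as_pex_config <- function(x) {
  x <- x[!vapply(x, is.null, logical(1L))]
  known <- names(formals(pex_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    .pex_error(paste("unknown config keys:", paste(unknown, collapse = ", ")),
               "pex_config_error")
  do.call(pex_config, x)
}

# resolution-scaled defaults for the two size-dependent parameters
.resolve_config <- function(cfg, dm) {
  s <- min(dm[1:2])
  if (is.null(cfg$mask_size)) {
    ms <- round(45 * s / 960)
    ms <- max(7L, as.integer(ms + (ms %% 2 == 0)))
    cfg$mask_size <- ms
  }
  if (is.null(cfg$vote_quantile))
    cfg$vote_quantile <- 1 - min(0.25, 0.02 * 960 / s)
  cfg
}

#' Measure PEX severity in a single image
#'
#' Runs the full automatic pipeline: pre-processing (median filter,
#' channel normalization, gray conversion), direction-field pupil-centre
#' localization, polar resampling, contour extraction (pupil by Otsu
#' binarization + hole filling + periodic polynomial fit; PEX rim and iris
#' border by the dynamic-programming radial snake), and computation of the
#' `W_PEX` severity statistic with its reliability flag.
#'
#' @param image A file path (JPEG/PNG), an `M x N x 3` array in `[0, 1]`, a
#'   grayscale matrix (replicated to three channels), or an `eye_phantom`.
#' @param config A [pex_config()].
#' @param debug_dir Optional directory for diagnostic PNGs (direction-field
#'   response, vote accumulator, contour overlay).
#' @return Object of class `pex_result`: list with `w_pex` (percent),
#'   `reliable`, `center`, `pupil_radius`, `contours` (pupil/pex/iris
#'   `radial_contour`s), `n_valid_angles`, `low_confidence`,
#'   `otsu_threshold`, `config`, and provenance hashes.
#' @export
measure_pex <- function(image, config = pex_config(), debug_dir = NULL) {
  stopifnot(inherits(config, "pex_config"))
  if (inherits(image, "eye_phantom")) image <- image$image
  if (is.character(image)) image <- read_eye_image(image)
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  .validate_color(image)
  if (min(image) < 0 || max(image) > 1)
    .pex_error("image values must lie in [0, 1]", "pex_input_error")
  dm <- dim(image)
  cfg <- .resolve_config(config, dm)
  input_hash <- .fnv1a(image)

  gray <- preprocess(image, cfg$median_size)
  field <- direction_field(gray, cfg$mask_size, cfg$theta_step)
  acc <- vote_center(field, cfg$vote_quantile,
                     r_min = max(2, round(cfg$r_min_frac * min(dm[1:2]))),
                     r_max = round(cfg$r_max_frac * min(dm[1:2])))
  r_max_polar <- floor(0.5 * min(dm[1:2]))
  polar <- to_polar(gray, acc$center, r_max_polar, cfg$angular_step)
  K_z <- pupil_contour(polar, cfg$pupil_harmonics)
  ct <- extract_contours(polar, K_z, cfg$pex_margin,
                         cfg$smooth_pex, cfg$smooth_iris)
  w <- compute_wpex(ct$pex, ct$iris)
  reliable <- reliability_flag(K_z, ct$pex,
                               margin = cfg$pex_margin + cfg$reliability_slack) &&
    .rim_visible(ct$pex, cfg$rim_strength_frac, cfg$rim_arc) &&
    !acc$low_confidence
  res <- structure(list(
    w_pex = as.numeric(w),
    reliable = reliable,
    center = acc$center,
    pupil_radius = acc$pupil_radius,
    contours = list(pupil = K_z, pex = ct$pex, iris = ct$iris),
    n_valid_angles = attr(w, "n_valid_angles"),
    low_confidence = acc$low_confidence,
    otsu_threshold = attr(K_z, "otsu_threshold"),
    config = cfg,
    config_hash = .fnv1a(unclass(cfg)),
    input_hash = input_hash,
    schema_version = "1.0"), class = "pex_result")
  if (!is.null(debug_dir)) .write_debug(debug_dir, image, gray, field, acc, res)
  res
}

#' @export
print.pex_result <- function(x, ...) {
  cat(sprintf("PEX measurement: W_PEX = %.2f%% (%s)\n", x$w_pex,
              if (x$reliable) "reliable" else "UNRELIABLE"))
  cat(sprintf("  pupil centre (row, col) = (%.0f, %.0f), r_z = %.1f px\n",
              x$center[1], x$center[2], x$pupil_radius))
  cat(sprintf("  valid angles: %d / %d\n", x$n_valid_angles,
              length(x$contours$pupil$radius)))
  invisible(x)
}

#' Serialize a measurement result as JSON
#'
#' @param result A `pex_result`.
#' @param path Optional file to write to.
#' @return JSON string (invisibly when writing to file).
#' @export
pex_result_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "pex_result"))
  payload <- list(
    schema_version = result$schema_version,
    w_pex = round(result$w_pex, 6),
    reliable = result$reliable,
    center = round(as.numeric(result$center), 3),
    pupil_radius = round(result$pupil_radius, 3),
    n_valid_angles = result$n_valid_angles,
    low_confidence = result$low_confidence,
    otsu_threshold = round(result$otsu_threshold, 6),
    config = unclass(result$config),
    config_hash = result$config_hash,
    input_hash = result$input_hash,
    contours = list(
      angles = result$contours$pupil$angles,
      pupil = round(result$contours$pupil$radius, 4),
      pex = round(result$contours$pex$radius, 4),
      iris = round(result$contours$iris$radius, 4),
      valid = result$contours$pex$valid & result$contours$iris$valid))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# error category for a failed measurement, used by batch rows and the CLI
.error_category <- function(e) {
  cls <- class(e)
  if ("pex_read_error" %in% cls) "read_error"
  else if ("pex_no_pupil" %in% cls) "no_pupil"
  else if ("pex_contour_error" %in% cls) "contour_failure"
  else if ("pex_input_error" %in% cls) "invalid_input"
  else if ("pex_config_error" %in% cls) "config_error"
  else "internal_error"
}

#' Measure a batch of images
#'
#' Applies [measure_pex()] to each input; failures are recorded as rows with
#' an error status rather than aborting the batch.
#'
#' @param images Character vector of file paths, or a list whose elements
#'   are anything [measure_pex()] accepts.
#' @param config A [pex_config()] applied to every image.
#' @param csv Optional path; when given, the summary is also written as CSV.
#' @return data.frame with one row per image: `file`, `w_pex`, `reliable`,
#'   `center_row`, `center_col`, `r_z`, `n_valid_angles`, `status`,
#'   `config_hash`.
#' @export
batch_measure <- function(images, config = pex_config(), csv = NULL) {
  if (length(images) == 0L) .pex_error("empty input set", "pex_input_error")
  ids <- if (is.character(images)) images else
    sprintf("image_%03d", seq_along(images))
  rows <- lapply(seq_along(images), function(i) {
    img <- if (is.character(images)) images[[i]] else images[[i]]
    r <- tryCatch(measure_pex(img, config), error = function(e) e)
    if (inherits(r, "error")) {
      data.frame(file = ids[i], w_pex = NA_real_, reliable = NA,
                 center_row = NA_real_, center_col = NA_real_, r_z = NA_real_,
                 n_valid_angles = NA_integer_, status = .error_category(r),
                 config_hash = NA_character_, stringsAsFactors = FALSE)
    } else {
      data.frame(file = ids[i], w_pex = r$w_pex, reliable = r$reliable,
                 center_row = r$center[1], center_col = r$center[2],
                 r_z = r$pupil_radius, n_valid_angles = r$n_valid_angles,
                 status = "ok", config_hash = r$config_hash,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}

#' Draw the extracted contours over an image
#'
#' Renders the pupil / PEX / iris contours in green / blue / red over the
#' (grayscale or colour) image, mirroring the pipeline's diagnostic figures.
#'
#' @param image `M x N x 3` array or matrix in `[0, 1]`.
#' @param result A `pex_result`.
#' @return `M x N x 3` array with the contours painted in.
#' @export
overlay_contours <- function(image, result) {
  stopifnot(inherits(result, "pex_result"))
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  M <- dim(image)[1]; N <- dim(image)[2]
  cols <- list(pupil = c(0, 1, 0), pex = c(0, 0, 1), iris = c(1, 0, 0))
  ctr <- result$center
  for (nm in names(cols)) {
    K <- result$contours[[nm]]
    arad <- K$angles * pi / 180
    rr <- round(ctr[1] - K$radius * sin(arad))
    cc <- round(ctr[2] + K$radius * cos(arad))
    ok <- K$valid & rr >= 1 & rr <= M & cc >= 1 & cc <= N
    for (k in 1:3) {
      ch <- image[, , k]
      ch[(cc[ok] - 1) * M + rr[ok]] <- cols[[nm]][k]
      image[, , k] <- ch
    }
  }
  image
}

.write_png <- function(arr, path) {
  if (length(dim(arr)) == 2L) {
    EBImage::writeImage(EBImage::Image(t(arr)), path)
  } else {
    EBImage::writeImage(EBImage::Image(aperm(arr, c(2, 1, 3)),
                                       colormode = "Color"), path)
  }
}

.write_debug <- function(dir, image, gray, field, acc, res) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  norm01 <- function(m) {
    rg <- range(m)
    if (rg[2] - rg[1] <= 0) matrix(0, nrow(m), ncol(m))
    else (m - rg[1]) / (rg[2] - rg[1])
  }
  .write_png(norm01(field$response), file.path(dir, "L_m.png"))
  .write_png(norm01(field$theta), file.path(dir, "L_theta.png"))
  .write_png(norm01(acc$votes), file.path(dir, "L_T.png"))
  .write_png(overlay_contours(image, res), file.path(dir, "overlay.png"))
  invisible(NULL)
}
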