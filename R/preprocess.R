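#' Read an anterior-segment photograph
#'
#' Reads an 8-bit JPEG or PNG image into a numeric `M x N x 3` array with
#' values in `[0, 1]`, indexed `[row, column, channel]` with channels R, G, B.
#' Grayscale files are replicated to three channels so that the colour
#' pipeline applies unchanged.
#'
#' @param path Path to a JPEG or PNG file.
#' @return Numeric array of dimension `c(M, N, 3)` with values in `[0, 1]`.
#' @export
read_eye_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    .pex_error(sprintf("cannot read image file '%s'", path), "pex_read_error")
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) .pex_error(
                    sprintf("failed to decode '%s': %s", path, conditionMessage(e)),
                    "pex_read_error"))
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2L) {
    dat <- array(rep(dat, 3L), c(dim(dat), 3L))
  } else if (dim(dat)[3] > 3L) {
    dat <- dat[, , 1:3, drop = FALSE]    # drop alpha
  } else if (dim(dat)[3] == 2L) {        # gray + alpha
    dat <- array(rep(dat[, , 1L], 3L), c(dim(dat)[1:2], 3L))
  }
  # EBImage stores (x, y, c); transpose to (row, col, channel)
  out <- aperm(dat, c(2L, 1L, 3L))
  out[out < 0] <- 0; out[out > 1] <- 1
  .validate_color(out)
  out
}

.validate_color <- function(img, min_dim = 64L) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    .pex_error("expected an M x N x 3 colour array", "pex_input_error")
  if (d[1] < min_dim || d[2] < min_dim)
    .pex_error(sprintf("image too small (%d x %d); need at least %d x %d",
                       d[1], d[2], min_dim, min_dim), "pex_input_error")
  if (!all(is.finite(img)))
    .pex_error("image contains non-finite values", "pex_input_error")
  invisible(img)
}

#' Median-filter a colour image
#'
#' Applies an exact per-channel median filter with an odd rectangular mask
#' (default 3 x 3). Borders are handled by edge replication so the output has
#' the same size as the input. The implementation is an exact vectorized
#' sorting network, so each output pixel is precisely the sample median of
#' its neighbourhood.
#'
#' @param img Numeric `M x N x 3` array (or a matrix, filtered as one channel).
#' @param mask_rows,mask_cols Odd mask dimensions.
#' @return Filtered image of the same dimension.
#' @export
median_filter <- function(img, mask_rows = 3L, mask_cols = 3L) {
  .stopifnot_odd(mask_rows, "mask_rows")
  .stopifnot_odd(mask_cols, "mask_cols")
  if (is.matrix(img)) return(.median_one(img, mask_rows, mask_cols))
  if (length(dim(img)) != 3L)
    .pex_error("img must be a matrix or an M x N x C array", "pex_input_error")
  out <- img
  for (k in seq_len(dim(img)[3]))
    out[, , k] <- .median_one(img[, , k], mask_rows, mask_cols)
  out
}

.median_one <- function(mat, kr, kc) {
  M <- nrow(mat); N <- ncol(mat)
  hr <- (kr - 1L) %/% 2L; hc <- (kc - 1L) %/% 2L
  k <- kr * kc
  S <- matrix(0, M * N, k)
  idx <- 1L
  rows <- seq_len(M); cols <- seq_len(N)
  for (dc in -hc:hc) for (dr in -hr:hr) {
    rr <- pmin(pmax(rows + dr, 1L), M)
    cc <- pmin(pmax(cols + dc, 1L), N)
    S[, idx] <- mat[rr, cc]
    idx <- idx + 1L
  }
  # full compare-exchange (bubble) network with pmin/pmax: exact, vectorized
  for (i in seq_len(k - 1L)) for (j in seq_len(k - i)) {
    a <- S[, j]; b <- S[, j + 1L]
    S[, j] <- pmin(a, b)
    S[, j + 1L] <- pmax(a, b)
  }
  matrix(S[, (k + 1L) %/% 2L], M, N)
}

#' Normalize each colour channel to the range \[0, 1\]
#'
#' Per channel affine rescaling so that the channel minimum maps to 0 and the
#' maximum to 1. A constant channel carries no contrast information and is
#' mapped to all zeros (with a warning).
#'
#' @param img Numeric `M x N x 3` array.
#' @return Array of the same dimension with each channel spanning `[0, 1]`.
#' @export
normalize_channels <- function(img) {
  if (length(dim(img)) != 3L)
    .pex_error("img must be an M x N x C array", "pex_input_error")
  out <- img
  for (k in seq_len(dim(img)[3])) {
    ch <- img[, , k]
    rng <- range(ch)
    if (rng[2] - rng[1] <= 0) {
      warning(sprintf("channel %d is constant; normalized to 0", k))
      out[, , k] <- 0
    } else {
      out[, , k] <- (ch - rng[1]) / (rng[2] - rng[1])
    }
  }
  out
}

#' Convert a normalized colour image to gray levels
#'
#' Weighted sum of the R, G, B channels with the standard luma coefficients
#' 0.2989, 0.5870 and 0.1140. No re-normalization is applied, so a pure white
#' pixel maps to 0.9999 (the sum of the coefficients).
#'
#' @param img Numeric `M x N x 3` array with values in `[0, 1]`.
#' @return `M x N` matrix of gray levels.
#' @export
rgb_to_gray <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    .pex_error("img must be an M x N x 3 array", "pex_input_error")
  0.2989 * img[, , 1L] + 0.5870 * img[, , 2L] + 0.1140 * img[, , 3L]
}

#' Pre-process a colour eye image into the grayscale working image
#'
#' The three pre-processing steps applied before any analysis: median
#' filtering (noise removal), per-channel normalization to `[0, 1]`, and
#' conversion to gray levels.
#'
#' @param img `M x N x 3` array in `[0, 1]` (see [read_eye_image()]).
#' @param median_size Odd size of the square median mask (default 3).
#' @return `M x N` matrix of gray levels.
#' @export
preprocess <- function(img, median_size = 3L) {
  .validate_color(img)
  img <- median_filter(img, median_size, median_size)
  img <- normalize_channels(img)
  rgb_to_gray(img)
}
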