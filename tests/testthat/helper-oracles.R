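# Independent oracles used to cross-check the implementation.
# These deliberately use naive/brute-force formulations.

# exhaustive per-pixel sorted-neighborhood median with edge replication
brute_median <- function(mat, kr, kc) {
  M <- nrow(mat); N <- ncol(mat)
  hr <- (kr - 1) / 2; hc <- (kc - 1) / 2
  out <- mat
  for (i in seq_len(M)) for (j in seq_len(N)) {
    rr <- pmin(pmax((i - hr):(i + hr), 1), M)
    cc <- pmin(pmax((j - hc):(j + hc), 1), N)
    v <- sort(as.vector(mat[rr, cc]))
    out[i, j] <- v[(length(v) + 1) / 2]
  }
  out
}

# Kasa algebraic least-squares circle fit to (row, col) points
circle_fit_lsq <- function(r, c) {
  A <- cbind(2 * r, 2 * c, 1)
  b <- r^2 + c^2
  sol <- qr.solve(A, b)
  list(center = c(sol[1], sol[2]),
       radius = sqrt(sol[3] + sol[1]^2 + sol[2]^2))
}

# brute-force Hough circle transform: every pixel is a candidate centre;
# edge pixels vote into 1-px radius bins; score = best single-radius count
hough_circle_center <- function(gray, edge_quantile = 0.98,
                                r_min = 3, r_max = NULL) {
  M <- nrow(gray); N <- ncol(gray)
  if (is.null(r_max)) r_max <- floor(min(M, N) / 2)
  gr <- gray * 0
  gr[2:(M - 1), ] <- abs(gray[3:M, ] - gray[1:(M - 2), ]) / 2
  gc <- gray * 0
  gc[, 2:(N - 1)] <- abs(gray[, 3:N] - gray[, 1:(N - 2)]) / 2
  g <- sqrt(gr^2 + gc^2)
  ed <- which(g > quantile(g, edge_quantile))
  er <- (ed - 1) %% M + 1
  ec <- (ed - 1) %/% M + 1
  best <- c(-1, 0, 0)
  for (i in seq_len(M)) for (j in seq_len(N)) {
    d <- round(sqrt((er - i)^2 + (ec - j)^2))
    d <- d[d >= r_min & d <= r_max]
    if (!length(d)) next
    cnt <- tabulate(d, nbins = r_max)
    sc <- max(cnt)
    if (sc > best[1]) best <- c(sc, i, j)
  }
  c(best[2], best[3])
}

# exhaustive enumeration of all circular snake paths through an energy matrix
enum_snake_min <- function(E, lam) {
  nR <- nrow(E); C <- ncol(E)
  paths <- as.matrix(expand.grid(rep(list(seq_len(nR)), C)))
  cost <- numeric(nrow(paths))
  for (j in seq_len(C)) cost <- cost + E[cbind(paths[, j], j)]
  for (j in seq_len(C)) {
    jn <- if (j == C) 1L else j + 1L
    cost <- cost + lam * abs(paths[, jn] - paths[, j])
  }
  min(cost)
}

# per-angle accumulation of the severity statistic, written as a plain loop
wpex_loop <- function(kp, ki, valid = rep(TRUE, length(kp))) {
  s <- 0; n <- 0
  for (i in seq_along(kp)) {
    if (!valid[i]) next
    s <- s + (ki[i] - kp[i]) / ki[i]
    n <- n + 1
  }
  s / n * 100
}

# soft-edged dark disc on a bright background
disc_image <- function(M, N, center, rho, dark = 0.1, bright = 0.9, w = 1.2) {
  dr <- matrix(seq_len(M) - center[1], M, N)
  dc <- matrix(seq_len(N) - center[2], M, N, byrow = TRUE)
  d <- sqrt(dr^2 + dc^2)
  s <- pmin(pmax((rho - d) / w + 0.5, 0), 1)
  bright + (dark - bright) * s
}

# ideal straight soft step edge through the image centre at a given
# orientation (degrees from the row axis, counter-clockwise)
edge_image <- function(M, N, theta_deg, lo = 0.2, hi = 0.8, w = 1.5) {
  th <- theta_deg * pi / 180
  dr <- matrix(seq_len(M) - (M + 1) / 2, M, N)
  dc <- matrix(seq_len(N) - (N + 1) / 2, M, N, byrow = TRUE)
  # signed distance from the edge line along its normal
  d <- dr * (-cos(th)) + dc * (-sin(th))
  lo + (hi - lo) * pmin(pmax(d / w + 0.5, 0), 1)
}

# small standard phantom spec used across tests
test_phantom_spec <- function(seed = 11, noise_var = 0.005, w_target = 25,
                              size = 192) {
  r_z <- 0.35 * size / 2
  r_i <- 0.45 * size
  prof <- random_pex_profile(seed, r_z, r_i, n_harmonics = 3, amplitude = 0.35,
                             mean_radius = r_i * (1 - w_target / 100))
  eye_phantom_spec(size = c(size, size), pupil_radius = r_z, iris_radius = r_i,
                   pex_profile = prof, noise_var = noise_var, seed = seed)
}
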