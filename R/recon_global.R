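# Global (untruncated) reconstruction of f(x,y,q) from g(s,phi,r).
#
# Two algorithms:
#   * fbp_per_q(): treats every radial bin as a single momentum transfer (the
#     t = 0 mapping) and runs standard 2D parallel-beam filtered
#     backprojection per q-slice; exact only in the large detector-distance
#     limit.
#   * fdk_reconstruct(): the modified FDK for the parallel-fan geometry:
#     cosine-weights the data along the fan direction, ramp-filters along the
#     parallel coordinate s, and backprojects each radial bin along its
#     oblique fan ray in (x, y, q) space, so the q(r, t) depth dependence is
#     honored exactly.
#
# Both divide the data by the annulus solid-angle weight at t = 0 to convert
# annulus intensities to line-integral units, so reconstructed values are in
# the object's form-factor units.

#' Discrete ramp (Ram-Lak) convolution kernel
#'
#' Band-limited spatial-domain ramp filter kernel: `h(0) = 1/(4 ds^2)`,
#' `h(k) = -1/(pi^2 k^2 ds^2)` for odd k, zero for even k.
#'
#' @param n number of lags (kernel covers -n+1 .. n-1).
#' @param ds sample spacing.
#' @return numeric vector `h(0..n-1)` (the kernel is symmetric).
#' @export
ramp_kernel <- function(n, ds = 1) {
  k <- 0:(n - 1)
  h <- numeric(n)
  h[1] <- 1 / (4 * ds^2)
  odd <- k %% 2 == 1
  h[odd] <- -1 / (pi^2 * k[odd]^2 * ds^2)
  h
}

# frequency response of the (optionally apodized) ramp on m FFT bins,
# with the DC bin forced to zero so constant rows filter to exactly zero
ramp_response <- function(m, ds, window) {
  h <- ramp_kernel(m / 2, ds)
  hc <- numeric(m)
  hc[1:(m / 2)] <- h
  hc[m:(m / 2 + 2)] <- h[2:(m / 2)]
  H <- Re(stats::fft(hc))
  wn <- pmin(0:(m - 1), m - (0:(m - 1))) / (m / 2)   # normalized |freq|
  win <- switch(window,
                ramlak = rep(1, m),
                shepp = ifelse(wn > 0, sin(pi * wn / 2) / (pi * wn / 2), 1),
                hann = 0.5 * (1 + cos(pi * wn)),
                stop("unknown filter window: ", window))
  H <- H * win
  H[1] <- 0
  H
}

#' Ramp-filter sinogram rows along the translation axis
#'
#' Convolution with the discrete Ram-Lak kernel via FFT with zero-padding to
#' at least twice the row length, optionally apodized; the result is scaled
#' by the sample spacing so that backprojection integrates line-filtered
#' projections. The pad extends the rows with their edge values (identical
#' to zero-padding for projections with compact support, which vanish at the
#' window ends); together with the zeroed DC bin of the filter response this
#' makes a constant row filter to exactly zero.
#'
#' @param rows numeric matrix, each COLUMN a projection sampled along s (a
#'   vector is treated as one row).
#' @param ds uniform s spacing.
#' @param window `"ramlak"`, `"shepp"` or `"hann"`.
#' @return filtered rows, same shape as the input.
#' @export
ramp_filter <- function(rows, ds = 1, window = c("ramlak", "shepp", "hann")) {
  window <- match.arg(window)
  vec <- is.null(dim(rows))
  if (vec) rows <- matrix(rows, ncol = 1)
  n <- nrow(rows)
  m <- 2^ceiling(log2(max(2 * n, 8)))
  H <- ramp_response(m, ds, window)
  npad <- m - n
  n_hi <- ceiling(npad / 2)
  pad <- rbind(rows,
               matrix(rep(rows[n, ], each = n_hi), n_hi),
               matrix(rep(rows[1, ], each = npad - n_hi), npad - n_hi))
  ft <- stats::mvfft(pad) * H
  out <- Re(stats::mvfft(ft, inverse = TRUE)) / m
  out <- out[seq_len(n), , drop = FALSE] * ds
  if (vec) out[, 1] else out
}

# trapezoid angle weights in radians; halves the endpoints when the angle
# grid includes both 0 and 180 (the same parallel ray direction twice)
angle_weights <- function(angles_deg) {
  n <- length(angles_deg)
  if (n == 1) return(pi)
  d <- diff(angles_deg)[1] * pi / 180
  w <- rep(d, n)
  if (abs((angles_deg[n] - angles_deg[1]) - 180) < 1e-9)
    w[c(1, n)] <- d / 2
  w
}

# bilinear sample of matrix M on grid (xg, yg) at points (x, y); 0 outside
interp2_lin <- function(M, xg, yg, x, y) {
  nx <- length(xg); ny <- length(yg)
  fx <- (x - xg[1]) / (xg[2] - xg[1]) + 1
  fy <- (y - yg[1]) / (yg[2] - yg[1]) + 1
  i0 <- floor(fx); j0 <- floor(fy)
  wx <- fx - i0; wy <- fy - j0
  out <- numeric(length(x))
  for (k in 1:4) {
    ii <- i0 + (k == 2 | k == 4)
    jj <- j0 + (k == 3 | k == 4)
    w <- (if (k %% 2 == 1) 1 - wx else wx) * (if (k <= 2) 1 - wy else wy)
    ok <- ii >= 1 & ii <= nx & jj >= 1 & jj <= ny & w > 0
    if (any(ok)) out[ok] <- out[ok] + w[ok] * M[cbind(ii[ok], jj[ok])]
  }
  out
}

# 1D linear interpolation with zero outside, vectorized over x
interp1_lin <- function(v, g0, dg, x) {
  f <- (x - g0) / dg + 1
  i0 <- floor(f); w <- f - i0
  n <- length(v)
  out <- numeric(length(x))
  ok <- i0 >= 1 & i0 <= n
  out[ok] <- out[ok] + (1 - w[ok]) * v[i0[ok]]
  ok2 <- i0 + 1 >= 1 & i0 + 1 <= n
  out[ok2] <- out[ok2] + w[ok2] * v[i0[ok2] + 1]
  out
}

recon_grid <- function(grid) {
  stopifnot(all(c("n", "pitch_mm", "q_grid") %in% names(grid)))
  grid$x <- axis_centers(grid$n, grid$pitch_mm)
  grid
}

# pre-divide sinogram by the t=0 annulus weight; masked bins dropped
line_integral_units <- function(sino, geom, dr) {
  w0 <- annulus_weight(sino$r_mm, 0, dr, geom)
  keep_r <- !apply(sino$mask, 3, all) & w0 > 0
  g <- sweep(sino$values, 3, pmax(w0, .Machine$double.xmin), "/")
  list(g = g, keep_r = keep_r, w0 = w0)
}

#' Per-q parallel-beam filtered backprojection
#'
#' Reconstructs each radial bin as an independent 2D parallel-beam FBP slice
#' at the fixed momentum transfer `q(r, t = 0)`, then resamples the slices
#' onto the requested q grid. Valid when the detector distance is large
#' compared to the object; at table-top distances the depth dependence of
#' q(r, t) biases the result (which is what the modified FDK corrects).
#'
#' @param sino an [xdt_sinogram()] covering the full object.
#' @param geom an [xdt_geometry()].
#' @param grid list with `n`, `pitch_mm`, `q_grid`.
#' @param window ramp apodization, see [ramp_filter()].
#' @param clip clip negative values to zero.
#' @return an [xdt_volume()].
#' @export
fbp_per_q <- function(sino, geom, grid, window = "hann", clip = FALSE) {
  grid <- recon_grid(grid)
  warn_if_truncated(sino)
  li <- line_integral_units(sino, geom, dr = diff(sino$r_mm[1:2]))
  ds <- diff(sino$s_mm[1:2])
  wphi <- angle_weights(sino$angles_deg)
  a <- sino$angles_deg * pi / 180
  n <- grid$n
  X <- matrix(grid$x, n, n); Y <- matrix(grid$x, n, n, byrow = TRUE)
  rs <- which(li$keep_r)
  q_r <- momentum_transfer_at(sino$r_mm, 0, geom)
  slices <- array(0, c(n, n, length(rs)))
  for (k in seq_along(rs)) {
    gf <- ramp_filter(li$g[, , rs[k]], ds, window)    # S x Phi
    acc <- matrix(0, n, n)
    for (ia in seq_along(a)) {
      sv <- X * cos(a[ia]) + Y * sin(a[ia])
      acc <- acc + wphi[ia] *
        matrix(interp1_lin(gf[, ia], sino$s_mm[1], ds, as.vector(sv)), n, n)
    }
    slices[, , k] <- acc
  }
  vol <- array(0, c(n, n, length(grid$q_grid)))
  qr <- q_r[rs]
  for (j in seq_along(grid$q_grid)) {
    qj <- grid$q_grid[j]
    i <- findInterval(qj, qr)
    if (i < 1 || i >= length(qr)) {
      if (i == length(qr) && abs(qj - qr[i]) < 1e-12) vol[, , j] <- slices[, , i]
      next
    }
    w <- (qj - qr[i]) / (qr[i + 1] - qr[i])
    vol[, , j] <- (1 - w) * slices[, , i] + w * slices[, , i + 1]
  }
  vol <- vol / sino$scale
  if (clip) vol[vol < 0] <- 0
  xdt_volume(vol, grid$pitch_mm, grid$q_grid)
}

warn_if_truncated <- function(sino) {
  if (!is.null(sino$roi))
    warning("sinogram is truncated to an ROI: global filtered ",
            "backprojection will show interior artifacts")
  invisible(NULL)
}

#' Modified FDK reconstruction for the parallel-fan XDT geometry
#'
#' Normalizes the data to line-integral units along the fan direction — the
#' division by the annulus solid angle `w(r, 0)` contains the Feldkamp
#' cosine (fan-obliquity) weight `D / sqrt(D^2 + r^2)` — then ramp-filters
#' along the parallel coordinate s and backprojects every voxel (x, y, q)
#' along its oblique fan ray: at each angle the voxel's depth t and offset s
#' are computed and the filtered data sampled at
#' `(s, r = detector_radius(q, t))` with bilinear interpolation. Because the
#' in-rotation-plane geometry is parallel, no fan magnification weighting is
#' needed; the fan lives in the (depth, momentum transfer) plane.
#'
#' @inheritParams fbp_per_q
#' @param clip clip negative values to zero (default on).
#' @return an [xdt_volume()].
#' @export
fdk_reconstruct <- function(sino, geom, grid, window = "hann", clip = TRUE) {
  grid <- recon_grid(grid)
  warn_if_truncated(sino)
  D <- geom$detector_distance_mm
  dr <- diff(sino$r_mm[1:2])
  # the annulus solid-angle normalization already contains the Feldkamp
  # cosine (fan-obliquity) weight: w(r,0) = [2 pi r dr/(D^2+r^2)] * cos(kappa)
  li <- line_integral_units(sino, geom, dr)
  g <- li$g
  g[, , !li$keep_r] <- 0
  ds <- diff(sino$s_mm[1:2])
  S <- length(sino$s_mm); Phi <- length(sino$angles_deg)
  R <- length(sino$r_mm)
  gf <- array(0, c(S, Phi, R))
  for (r in which(li$keep_r)) gf[, , r] <- ramp_filter(g[, , r], ds, window)
  wphi <- angle_weights(sino$angles_deg)
  a <- sino$angles_deg * pi / 180
  n <- grid$n; Q <- length(grid$q_grid)
  X <- matrix(grid$x, n, n); Y <- matrix(grid$x, n, n, byrow = TRUE)
  tanth <- tan(scattering_angle_from_q(grid$q_grid,
                                       geom$wavelength_angstrom))
  vol <- array(0, c(n, n, Q))
  for (ia in seq_len(Phi)) {
    sv <- as.vector(X * cos(a[ia]) + Y * sin(a[ia]))
    tv <- as.vector(-X * sin(a[ia]) + Y * cos(a[ia]))
    gfa <- gf[, ia, ]                                  # S x R
    for (j in seq_len(Q)) {
      rv <- (D - tv) * tanth[j]
      vol[, , j] <- vol[, , j] + wphi[ia] *
        matrix(interp2_lin(gfa, sino$s_mm, sino$r_mm, sv, rv), n, n)
    }
  }
  vol <- vol / sino$scale
  if (clip) vol[vol < 0] <- 0
  xdt_volume(vol, grid$pitch_mm, grid$q_grid)
}
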