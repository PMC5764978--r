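# Forward model: project an object volume f(x,y,q) to the 3D sinogram
# g(s, phi, r) and back (exact adjoint).
#
# The projector is the composition of two sparse linear maps shared by all
# beams:
#   W : object pixels -> samples along every beam path (bilinear in space,
#       one row per (phi, s, t) sample), and
#   B : (depth t, q-grid) -> detector radial bins, combining the q(r, t)
#       fan-ray mapping (linear interpolation in q) with the annulus
#       solid-angle weight and the depth step dt.
# apply = reshape(B %*% reshape(W %*% f)); the adjoint uses the transposes of
# the same matrices, so <Hf, g> = <f, H^T g> holds to machine precision.

#' Scan plan: translation offsets, rotation angles, exposure
#'
#' @param s_offsets_mm beam translation offsets (mm), uniformly spaced on the
#'   geometry's translation grid.
#' @param angles_deg rotation angles (degrees).
#' @param exposure_s exposure per scan position (seconds).
#' @param keep optional logical matrix (offsets x angles); `FALSE` marks
#'   (s, phi) positions excluded from the plan (interior scans). Default all
#'   `TRUE`.
#' @return object of class `xdt_plan`.
#' @export
scan_plan <- function(s_offsets_mm, angles_deg, exposure_s = 45,
                      keep = NULL) {
  if (length(s_offsets_mm) > 1) {
    d <- diff(s_offsets_mm)
    stopifnot(max(abs(d - d[1])) < 1e-9)
  }
  if (is.null(keep))
    keep <- matrix(TRUE, length(s_offsets_mm), length(angles_deg))
  stopifnot(nrow(keep) == length(s_offsets_mm),
            ncol(keep) == length(angles_deg))
  structure(list(s_offsets_mm = as.numeric(s_offsets_mm),
                 angles_deg = as.numeric(angles_deg),
                 exposure_s = exposure_s, keep = keep),
            class = "xdt_plan")
}

#' Global scan plan covering a phantom's full support
#'
#' Offsets span the circumscribed radius of the non-air support at the
#' geometry's translation step, inclusive endpoints (a 32 mm disk at 1 mm
#' steps gives 33 offsets).
#'
#' @param phantom an [xdt_phantom()].
#' @param geom an [xdt_geometry()].
#' @param exposure_s exposure per position (seconds).
#' @return an [scan_plan()].
#' @export
plan_global <- function(phantom, geom, exposure_s = 45) {
  r <- support_radius(phantom)
  smax <- floor(r / geom$step_mm) * geom$step_mm
  scan_plan(seq(-smax, smax, by = geom$step_mm), geom$angles_deg, exposure_s)
}

#' Interior scan plan restricted to beams crossing the ROI
#'
#' Keeps, at every angle, only the offsets whose beam line passes within the
#' ROI radius of the ROI center (`|s - s_roi(phi)| <= radius` with
#' `s_roi(phi)` the center's signed offset at that angle).
#'
#' @inheritParams plan_global
#' @param roi list with `center` (mm) and `diameter` (mm); defaults to the
#'   phantom's ROI.
#' @return an [scan_plan()] with the same offset grid as the global plan and
#'   a `keep` mask selecting the interior beams.
#' @export
plan_interior <- function(phantom, geom, roi = phantom$roi, exposure_s = 45) {
  if (is.null(roi)) stop("phantom has no ROI and none was given")
  p <- plan_global(phantom, geom, exposure_s)
  a <- p$angles_deg * pi / 180
  s_roi <- roi$center[1] * cos(a) + roi$center[2] * sin(a)
  keep <- abs(outer(p$s_offsets_mm, s_roi, "-")) <= roi$diameter / 2 + 1e-9
  if (!any(keep)) stop("ROI outside scan range")
  scan_plan(p$s_offsets_mm, p$angles_deg, exposure_s, keep = keep)
}

support_radius <- function(phantom) {
  n <- nrow(phantom$label_grid)
  xc <- axis_centers(n, phantom$pixel_pitch_mm)
  X <- matrix(xc, n, n); Y <- matrix(xc, n, n, byrow = TRUE)
  sel <- phantom$label_grid != 1L
  if (!any(sel)) return(0)
  max(sqrt(X[sel]^2 + Y[sel]^2)) + phantom$pixel_pitch_mm / 2
}

#' 3D diffraction sinogram g(s, phi, r)
#'
#' @param values array offsets x angles x radial bins, non-negative.
#' @param s_mm translation offsets (mm).
#' @param angles_deg rotation angles (degrees).
#' @param r_mm detector radial bin centers (mm).
#' @param mask logical array of the same shape; `TRUE` marks entries that
#'   carry no information (beam stop, truncation) and are excluded from all
#'   fits.
#' @param roi optional ROI descriptor recorded by [truncate_to_roi()].
#' @param scale optional counts-per-form-factor-unit factor recorded by
#'   [simulate_scan()] so reconstructions can be returned in object units.
#' @return object of class `xdt_sinogram`.
#' @export
xdt_sinogram <- function(values, s_mm, angles_deg, r_mm, mask = NULL,
                         roi = NULL, scale = 1) {
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3,
            dim(values)[1] == length(s_mm),
            dim(values)[2] == length(angles_deg),
            dim(values)[3] == length(r_mm))
  if (is.null(mask)) mask <- array(FALSE, dim(values))
  stopifnot(all(dim(mask) == dim(values)))
  structure(list(values = values, s_mm = as.numeric(s_mm),
                 angles_deg = as.numeric(angles_deg),
                 r_mm = as.numeric(r_mm), mask = mask, roi = roi,
                 scale = scale),
            class = "xdt_sinogram")
}

#' @export
print.xdt_sinogram <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("XDT sinogram: %d offsets x %d angles x %d radial bins (%.0f%% masked)\n",
              d[1], d[2], d[3], 100 * mean(x$mask)))
  if (!is.null(x$roi))
    cat(sprintf("  truncated to ROI: %g mm at (%g, %g)\n", x$roi$diameter,
                x$roi$center[1], x$roi$center[2]))
  invisible(x)
}

#' Default radial bins for a reconstruction sinogram
#'
#' Covers the detector radii reachable by the object's q-grid over the full
#' depth range of the scanned support.
#'
#' @param geom an [xdt_geometry()].
#' @param q_grid momentum-transfer grid of the object.
#' @param t_max maximum |scatter depth| of the support (mm).
#' @param dr radial bin width (mm), default 1 mm.
#' @return numeric vector of radial bin centers (mm).
#' @export
default_r_bins <- function(geom, q_grid, t_max, dr = 1) {
  r_lo <- detector_radius(min(q_grid), t_max, geom)
  r_hi <- detector_radius(max(q_grid), -t_max, geom)
  seq(floor(r_lo / dr) * dr - dr, ceiling(r_hi / dr) * dr + dr, by = dr)
}

#' Build the forward operator H
#'
#' Constructs the matched (apply, adjoint) pair realizing the linear map from
#' an object volume on the FULL object grid to the sinogram entries of a scan
#' plan. The grid must cover the whole object even for interior plans:
#' diffracted photons originate from interior and exterior alike, so interior
#' reconstruction still discretizes the full object.
#'
#' @param geom an [xdt_geometry()].
#' @param grid list with `n` (pixels per side), `pitch_mm`, `q_grid`;
#'   alternatively an [xdt_volume()] whose grid is used.
#' @param plan an [scan_plan()].
#' @param r_bins radial bin centers (mm); default [default_r_bins()].
#' @param dr radial bin width (mm).
#' @param support_radius_mm radius that the grid must cover (mm); when the
#'   grid's half-extent is smaller the construction aborts, because a grid
#'   covering only the ROI violates the full-object requirement.
#' @param beam_width_mm pencil-beam footprint: 0 (default) models the beam
#'   as a zero-width line; a positive value models a top-hat of that full
#'   width by averaging `n_subbeams` parallel sub-beams (e.g. the 2.4 mm
#'   collimation envelope of the instrument).
#' @param n_subbeams number of sub-beams for the top-hat beam model.
#' @return object of class `xdt_operator` with elements `apply(f)` and
#'   `adjoint(g)` (arrays in/out), the axes, and the sinogram `mask`.
#' @export
build_forward_operator <- function(geom, grid, plan, r_bins = NULL, dr = 1,
                                   support_radius_mm = NULL,
                                   beam_width_mm = 0, n_subbeams = 5) {
  if (inherits(grid, "xdt_volume"))
    grid <- list(n = dim(grid$values)[1], pitch_mm = grid$pixel_pitch_mm,
                 q_grid = grid$q_grid)
  n <- grid$n; pitch <- grid$pitch_mm; q_grid <- grid$q_grid
  half <- n * pitch / 2
  if (!is.null(support_radius_mm) &&
      half + pitch / 2 < support_radius_mm - 1e-9)
    stop("reconstruction grid covers only part of the object: the full ",
         "object must be discretized, not just the interior region")
  t_max <- half * sqrt(2)
  if (is.null(r_bins)) r_bins <- default_r_bins(geom, q_grid, t_max, dr)
  D <- geom$detector_distance_mm
  stopifnot(t_max < D)

  t_grid <- seq(-t_max, t_max, by = pitch)
  Tn <- length(t_grid); S <- length(plan$s_offsets_mm)
  Phi <- length(plan$angles_deg); R <- length(r_bins)
  Q <- length(q_grid)

  ## ---- spatial sampling matrix W: (Phi*S*Tn) x (n*n), t fastest ----
  sub_offsets <- if (beam_width_mm > 0)
    seq(-beam_width_mm / 2, beam_width_mm / 2, length.out = n_subbeams)
  else 0
  a <- rep(plan$angles_deg * pi / 180, each = S * Tn)
  s0 <- rep(rep(plan$s_offsets_mm, each = Tn), times = Phi)
  tt <- rep(t_grid, times = S * Phi)
  rows <- seq_along(a)
  trip_r <- integer(0); trip_c <- integer(0); trip_v <- numeric(0)
  for (ds_sub in sub_offsets) {
    s <- s0 + ds_sub
    x <- s * cos(a) - tt * sin(a)
    y <- s * sin(a) + tt * cos(a)
    # fractional grid indices (pixel centers at axis_centers(n, pitch))
    fx <- (x + half) / pitch + 0.5
    fy <- (y + half) / pitch + 0.5
    i0 <- floor(fx); j0 <- floor(fy)
    wx <- fx - i0; wy <- fy - j0
    for (k in 1:4) {
      ii <- i0 + (k == 2 | k == 4)
      jj <- j0 + (k == 3 | k == 4)
      w <- (if (k %% 2 == 1) 1 - wx else wx) *
           (if (k <= 2) 1 - wy else wy) / length(sub_offsets)
      ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= n & w > 0
      trip_r <- c(trip_r, rows[ok])
      trip_c <- c(trip_c, ii[ok] + (jj[ok] - 1) * n)
      trip_v <- c(trip_v, w[ok])
    }
  }
  W <- Matrix::sparseMatrix(i = trip_r, j = trip_c, x = trip_v,
                            dims = c(Phi * S * Tn, n * n))

  ## ---- depth/q -> radial-bin matrix B: R x (Tn*Q), t fastest ----
  frm <- fan_ray_map(geom, r_bins, t_grid, dr = dr)
  qm <- frm$q                      # R x Tn
  wm <- frm$weight * pitch         # includes the depth step dt = pitch
  ridx <- rep(seq_len(R), times = Tn)
  tidx <- rep(seq_len(Tn), each = R)
  qv <- as.vector(qm); wv <- as.vector(wm)
  j <- findInterval(qv, q_grid)
  ok <- j >= 1 & j < Q
  frac <- (qv[ok] - q_grid[j[ok]]) / (q_grid[j[ok] + 1] - q_grid[j[ok]])
  col1 <- tidx[ok] + (j[ok] - 1) * Tn
  col2 <- tidx[ok] + j[ok] * Tn
  B <- Matrix::sparseMatrix(
    i = c(ridx[ok], ridx[ok]), j = c(col1, col2),
    x = c(wv[ok] * (1 - frac), wv[ok] * frac),
    dims = c(R, Tn * Q))

  ## ---- sinogram mask: beam stop bins and excluded (s, phi) positions ----
  mask <- array(FALSE, c(S, Phi, R))
  mask[, , frm$masked] <- TRUE
  if (!all(plan$keep)) {
    drop <- !plan$keep                       # S x Phi
    mask <- mask | array(rep(drop, times = R), c(S, Phi, R))
  }

  apply_fun <- function(f_arr) {
    f_mat <- matrix(f_arr, n * n, Q)
    Fm <- as.matrix(W %*% f_mat)                       # (Phi*S*Tn) x Q
    A <- array(Fm, c(Tn, S, Phi, Q))
    M <- matrix(aperm(A, c(1, 4, 2, 3)), Tn * Q)       # (Tn*Q) x (S*Phi)
    G <- as.matrix(B %*% M)                            # R x (S*Phi)
    g <- aperm(array(G, c(R, S, Phi)), c(2, 3, 1))
    g[mask] <- 0
    g
  }
  adjoint_fun <- function(g_arr) {
    g_arr[mask] <- 0
    G <- matrix(aperm(g_arr, c(3, 1, 2)), R)           # R x (S*Phi)
    M <- as.matrix(Matrix::crossprod(B, G))            # (Tn*Q) x (S*Phi)
    A <- aperm(array(M, c(Tn, Q, S, Phi)), c(1, 3, 4, 2))
    Fm <- matrix(A, Tn * S * Phi, Q)
    f_mat <- as.matrix(Matrix::crossprod(W, Fm))
    array(f_mat, c(n, n, Q))
  }

  structure(list(apply = apply_fun, adjoint = adjoint_fun,
                 geom = geom, plan = plan,
                 n = n, pitch_mm = pitch, q_grid = q_grid,
                 r_bins = r_bins, dr = dr, t_grid = t_grid,
                 mask = mask, fan_map = frm),
            class = "xdt_operator")
}

#' @export
print.xdt_operator <- function(x, ...) {
  cat(sprintf("XDT forward operator: %d x %d x %d object -> %d x %d x %d sinogram (%d unmasked entries)\n",
              x$n, x$n, length(x$q_grid),
              dim(x$mask)[1], dim(x$mask)[2], dim(x$mask)[3],
              sum(!x$mask)))
  invisible(x)
}

#' Project an object volume to a sinogram
#'
#' Evaluates the forward model `g(s, phi, r) = sum_t dt * w(r, t) *
#' f(x(s,phi,t), y(s,phi,t), q(r, t))` with bilinear interpolation in space
#' and linear interpolation in q.
#'
#' @param object an [xdt_volume()].
#' @param geom an [xdt_geometry()].
#' @param plan an [scan_plan()].
#' @param operator optional prebuilt [build_forward_operator()] matching the
#'   object grid and plan (reused for speed).
#' @param ... passed to [build_forward_operator()].
#' @return an [xdt_sinogram()].
#' @export
project <- function(object, geom, plan, operator = NULL, ...) {
  H <- operator %||% build_forward_operator(geom, object, plan, ...)
  g <- H$apply(object$values)
  xdt_sinogram(g, plan$s_offsets_mm, plan$angles_deg, H$r_bins,
               mask = H$mask)
}

#' Apply the exact adjoint of the projector
#'
#' @param sino an [xdt_sinogram()].
#' @param geom an [xdt_geometry()].
#' @param plan an [scan_plan()].
#' @param grid object grid (list with `n`, `pitch_mm`, `q_grid`).
#' @param operator optional prebuilt operator.
#' @return an [xdt_volume()] (the backprojection; masked entries contribute
#'   zero).
#' @export
apply_adjoint <- function(sino, geom, plan, grid, operator = NULL) {
  H <- operator %||% build_forward_operator(geom, grid, plan,
                                            r_bins = sino$r_mm)
  if (!isTRUE(all.equal(H$r_bins, sino$r_mm)) ||
      dim(sino$values)[1] != length(plan$s_offsets_mm) ||
      dim(sino$values)[2] != length(plan$angles_deg))
    stop("sinogram axes do not match the operator/plan")
  f <- H$adjoint(sino$values)
  xdt_volume(f, H$pitch_mm, H$q_grid)
}

#' Simulate a Poisson-noise diffraction scan directly in sinogram space
#'
#' Projects the object, scales the noiseless sinogram so that the mean
#' positive unmasked entry equals `target_counts`, and draws Poisson counts.
#' One RNG substream per (s, phi) position is derived from the master seed,
#' so scans are reproducible and independent of acquisition order. The
#' applied scale is stored in the sinogram so reconstructions can be mapped
#' back to form-factor units.
#'
#' @param object an [xdt_volume()].
#' @param geom an [xdt_geometry()].
#' @param plan an [scan_plan()].
#' @param target_counts expected counts per (positive, unmasked) sinogram
#'   entry; ~1e4 reproduces the phantom study's counting statistics.
#' @param seed master seed (integer).
#' @param operator optional prebuilt forward operator.
#' @param noiseless if `TRUE`, skip the Poisson draw (scaled expectation).
#' @return an [xdt_sinogram()] of counts with `scale` set.
#' @export
simulate_scan <- function(object, geom, plan, target_counts = 1e4,
                          seed = 1, operator = NULL, noiseless = FALSE) {
  H <- operator %||% build_forward_operator(geom, object, plan)
  g0 <- H$apply(object$values)
  pos <- g0[!H$mask & g0 > 0]
  scale <- if (length(pos)) target_counts / mean(pos) else 1
  lam <- g0 * scale
  if (noiseless) {
    vals <- lam
  } else {
    vals <- array(0, dim(lam))
    S <- dim(lam)[1]; Phi <- dim(lam)[2]
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    for (ia in seq_len(Phi)) {
      for (is in seq_len(S)) {
        if (!plan$keep[is, ia]) next
        set.seed(frame_seed(seed, is, ia))
        vals[is, ia, ] <- stats::rpois(dim(lam)[3], lam[is, ia, ])
      }
    }
  }
  vals[H$mask] <- 0
  xdt_sinogram(vals, plan$s_offsets_mm, plan$angles_deg, H$r_bins,
               mask = H$mask, scale = scale)
}

# deterministic per-frame seed below 2^31, mixing master seed and indices
frame_seed <- function(master, is, ia) {
  x <- (as.double(master) * 2654435.0 + ia * 97911.0 + is * 7919.0) %% 2147483629
  as.integer(x) + 1L
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Truncate a sinogram to the beams crossing a region of interest
#'
#' Masks, at every angle, the offsets whose beam line does not intersect the
#' ROI disk; the retained window shifts sinusoidally with angle for an
#' off-center ROI. The ROI is recorded on the returned sinogram.
#'
#' @param sino an [xdt_sinogram()].
#' @param roi list with `center` (mm, length 2) and `diameter` (mm).
#' @return an [xdt_sinogram()] with the truncation folded into its mask.
#' @export
truncate_to_roi <- function(sino, roi) {
  a <- sino$angles_deg * pi / 180
  s_roi <- roi$center[1] * cos(a) + roi$center[2] * sin(a)
  keep <- abs(outer(sino$s_mm, s_roi, "-")) <= roi$diameter / 2 + 1e-9
  if (!any(keep)) stop("ROI outside scan range")
  mask <- sino$mask |
    array(rep(!keep, times = length(sino$r_mm)), dim(sino$values))
  vals <- sino$values
  vals[mask] <- 0
  xdt_sinogram(vals, sino$s_mm, sino$angles_deg, sino$r_mm, mask = mask,
               roi = roi, scale = sino$scale)
}

#' Assemble a sinogram from per-position radial profiles
#'
#' Stacks azimuthally averaged profiles, keyed by their (s, phi) coordinates,
#' into the 3D sinogram; input order is irrelevant.
#'
#' @param profiles list of lists with elements `s_mm`, `angle_deg`, `r_mm`,
#'   `values`, `mask` (as returned by [azimuthal_average()] plus the scan
#'   coordinates).
#' @param plan an [scan_plan()].
#' @param geom an [xdt_geometry()].
#' @return an [xdt_sinogram()]; (s, phi) positions of the plan not covered by
#'   any profile are masked.
#' @export
assemble_sinogram <- function(profiles, plan, geom) {
  stopifnot(length(profiles) >= 1)
  r_mm <- profiles[[1]]$r_mm
  S <- length(plan$s_offsets_mm); Phi <- length(plan$angles_deg)
  vals <- array(0, c(S, Phi, length(r_mm)))
  mask <- array(TRUE, dim(vals))
  for (p in profiles) {
    stopifnot(isTRUE(all.equal(p$r_mm, r_mm)))
    is <- which(abs(plan$s_offsets_mm - p$s_mm) < 1e-9)
    ia <- which(abs(plan$angles_deg - p$angle_deg) < 1e-9)
    if (length(is) != 1 || length(ia) != 1)
      stop("profile coordinates not on the scan plan grid")
    vals[is, ia, ] <- p$values
    mask[is, ia, ] <- p$mask
  }
  xdt_sinogram(vals, plan$s_offsets_mm, plan$angles_deg, r_mm, mask = mask)
}
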