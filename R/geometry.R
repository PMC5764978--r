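# Scattering geometry of the pencil-beam XDT system.
#
# Conventions used throughout the package:
#   * q = sin(theta/2) / lambda  [1/Angstrom], theta the full scattering angle.
#   * Scatter depth t is measured along the beam from the isocenter, positive
#     toward the detector; |t| < D always.
#   * s is the signed beam offset perpendicular to the beam in the rotation
#     plane; phi rotates the object counter-clockwise.
#   * All grids are pixel-center coordinates; lengths in mm, energies in keV.

HC_KEV_ANGSTROM <- 12.3984

#' Scan geometry of the pencil-beam XDT instrument
#'
#' Collects every beam/detector/scan constant of the tomographic setup: photon
#' energy, isocenter-to-detector distance, detector pixel grid, central beam
#' stop, and the translation/rotation grids of the scan. Defaults describe a
#' table-top system with a quasi-monochromatic 8 keV pencil beam, a flat panel
#' 120 mm behind the rotation axis (588 x 736 pixels of 0.2 mm), a 10 x 10 mm
#' lead beam stop, 1 mm translation steps and 46 rotation angles at 4 degrees
#' covering 180 degrees.
#'
#' @param energy_keV photon energy in keV (monochromatic beam assumed).
#' @param detector_distance_mm distance from the center of rotation to the
#'   detector plane (mm).
#' @param pixel_mm effective detector pixel size (mm).
#' @param frame_shape integer vector of length 2, detector pixels (rows, cols).
#' @param beam_stop_mm half-width of the square central beam stop (mm).
#' @param step_mm translation step of the linear stage (mm).
#' @param angles_deg rotation angles in degrees, uniformly covering 180
#'   degrees.
#' @param beam_diameter_mm nominal beam envelope diameter at the rotation
#'   plane (mm); informational (the default forward model uses a line beam).
#' @return an object of class `xdt_geometry`.
#' @seealso [wavelength_from_energy()], [fan_ray_map()], [collimation_spec()]
#' @export
xdt_geometry <- function(energy_keV = 8.0,
                         detector_distance_mm = 120,
                         pixel_mm = 0.2,
                         frame_shape = c(588L, 736L),
                         beam_stop_mm = 5,
                         step_mm = 1,
                         angles_deg = seq(0, 180, by = 4),
                         beam_diameter_mm = 2.4) {
  stopifnot(energy_keV > 0, detector_distance_mm > 0, pixel_mm > 0,
            length(frame_shape) == 2, all(frame_shape >= 1),
            beam_stop_mm >= 0, step_mm > 0, length(angles_deg) >= 1)
  if (length(angles_deg) > 1) {
    d <- diff(angles_deg)
    if (max(abs(d - d[1])) > 1e-9)
      stop("rotation angles must be uniformly spaced")
    if (min(angles_deg) < 0 || max(angles_deg) > 180)
      stop("rotation angles must lie in [0, 180] degrees")
  }
  g <- list(
    energy_keV = energy_keV,
    wavelength_angstrom = wavelength_from_energy(energy_keV),
    detector_distance_mm = detector_distance_mm,
    pixel_mm = pixel_mm,
    frame_shape = as.integer(frame_shape),
    beam_stop_mm = beam_stop_mm,
    step_mm = step_mm,
    angles_deg = as.numeric(angles_deg),
    beam_diameter_mm = beam_diameter_mm
  )
  class(g) <- "xdt_geometry"
  g
}

#' @export
print.xdt_geometry <- function(x, ...) {
  cat("XDT scan geometry\n")
  cat(sprintf("  energy      : %.4g keV  (lambda = %.4f A)\n",
              x$energy_keV, x$wavelength_angstrom))
  cat(sprintf("  detector    : D = %g mm, %d x %d px of %g mm\n",
              x$detector_distance_mm, x$frame_shape[1], x$frame_shape[2],
              x$pixel_mm))
  cat(sprintf("  beam stop   : %g x %g mm (half-width %g mm)\n",
              2 * x$beam_stop_mm, 2 * x$beam_stop_mm, x$beam_stop_mm))
  cat(sprintf("  scan        : ds = %g mm, %d angles (%g..%g deg)\n",
              x$step_mm, length(x$angles_deg), min(x$angles_deg),
              max(x$angles_deg)))
  invisible(x)
}

#' Pencil-beam collimation geometry
#'
#' Source focal spot plus the pair of pinholes that collimate the tube output
#' into a pencil beam. Defaults are a 0.4 mm source spot and two 2 mm pinholes
#' 100 mm apart, the first 260 mm from the source, with the rotation plane
#' 60 mm past the second pinhole.
#'
#' @param source_spot_mm source focal-spot diameter (mm).
#' @param pinhole_diameters_mm diameters of the two pinholes (mm), length 2.
#' @param pinhole_separation_mm distance between the pinholes (mm).
#' @param source_to_first_pinhole_mm distance source -> first pinhole (mm).
#' @param second_pinhole_to_isocenter_mm distance second pinhole -> rotation
#'   plane (mm).
#' @return an object of class `xdt_collimation`.
#' @export
collimation_spec <- function(source_spot_mm = 0.4,
                             pinhole_diameters_mm = c(2, 2),
                             pinhole_separation_mm = 100,
                             source_to_first_pinhole_mm = 260,
                             second_pinhole_to_isocenter_mm = 60) {
  stopifnot(source_spot_mm >= 0, length(pinhole_diameters_mm) == 2,
            all(pinhole_diameters_mm > 0), pinhole_separation_mm > 0,
            source_to_first_pinhole_mm > 0,
            second_pinhole_to_isocenter_mm >= 0)
  c_ <- list(source_spot_mm = source_spot_mm,
             pinhole_diameters_mm = as.numeric(pinhole_diameters_mm),
             pinhole_separation_mm = pinhole_separation_mm,
             source_to_first_pinhole_mm = source_to_first_pinhole_mm,
             second_pinhole_to_isocenter_mm = second_pinhole_to_isocenter_mm)
  class(c_) <- "xdt_collimation"
  c_
}

#' X-ray wavelength from photon energy
#'
#' `lambda = hc / E` with `hc = 12.3984 keV*Angstrom`.
#'
#' @param energy_keV photon energy in keV, positive.
#' @return wavelength in Angstrom.
#' @export
wavelength_from_energy <- function(energy_keV) {
  if (any(!is.finite(energy_keV)) || any(energy_keV <= 0))
    stop("photon energy must be positive and finite")
  HC_KEV_ANGSTROM / energy_keV
}

#' Scattering angle from momentum transfer
#'
#' Inverts `q = sin(theta/2) / lambda`: `theta = 2 asin(q lambda)`.
#'
#' @param q momentum transfer in 1/Angstrom, `0 <= q*lambda < 1`.
#' @param lambda_angstrom wavelength in Angstrom.
#' @return scattering angle theta in radians.
#' @export
scattering_angle_from_q <- function(q, lambda_angstrom) {
  stopifnot(lambda_angstrom > 0)
  if (any(q < 0)) stop("momentum transfer must be non-negative")
  x <- q * lambda_angstrom
  if (any(x >= 1))
    stop("unphysical scattering angle: q * lambda must be < 1")
  2 * asin(x)
}

#' Detector radius of the diffraction ring
#'
#' A photon scattered at depth `t` along the beam (positive toward the
#' detector) with momentum transfer `q` lands on the detector annulus of
#' radius `r = (D - t) tan(theta(q))`.
#'
#' @param q momentum transfer (1/Angstrom).
#' @param t scatter depth along the beam (mm), `|t| < D`.
#' @param geom an [xdt_geometry()].
#' @return detector radius r in mm.
#' @export
detector_radius <- function(q, t, geom) {
  D <- geom$detector_distance_mm
  if (any(t >= D)) stop("scatter depth must be smaller than D")
  theta <- scattering_angle_from_q(q, geom$wavelength_angstrom)
  (D - t) * tan(theta)
}

#' Momentum transfer of a detector radius at a given scatter depth
#'
#' Exact inverse of [detector_radius()]: `theta = atan(r / (D - t))`,
#' `q = sin(theta/2) / lambda`.
#'
#' @param r detector radius (mm), non-negative.
#' @param t scatter depth (mm), `|t| < D`.
#' @param geom an [xdt_geometry()].
#' @return momentum transfer q in 1/Angstrom.
#' @export
momentum_transfer_at <- function(r, t, geom) {
  D <- geom$detector_distance_mm
  if (any(t >= D)) stop("scatter depth must be smaller than D")
  if (any(r < 0)) stop("detector radius must be non-negative")
  theta <- atan2(r, D - t)
  sin(theta / 2) / geom$wavelength_angstrom
}

#' Solid angle subtended by a detector annulus from a scatter point
#'
#' Small-width approximation of the solid angle of the annulus `[r, r + dr]`
#' in the detector plane, seen from a point on the beam axis at depth `t`:
#' `w = 2 pi r dr (D - t) / ((D - t)^2 + r^2)^(3/2)` steradian.
#'
#' @param r annulus radius (mm).
#' @param t scatter depth (mm), `|t| < D`.
#' @param dr annulus radial width (mm).
#' @param geom an [xdt_geometry()].
#' @return solid angle in steradian.
#' @export
annulus_weight <- function(r, t, dr, geom) {
  D <- geom$detector_distance_mm
  if (any(t >= D)) stop("scatter depth must be smaller than D")
  if (any(r < 0)) stop("detector radius must be non-negative")
  stopifnot(dr > 0)
  2 * pi * r * dr * (D - t) / ((D - t)^2 + r^2)^1.5
}

#' Full width of the collimated beam envelope
#'
#' Penumbra-to-penumbra diameter of the set of points reachable, in a plane a
#' given distance past the second pinhole, by a straight ray that starts
#' anywhere on the source spot and clears both pinhole apertures. Solved as a
#' small linear program in the ray's lateral positions at the two pinhole
#' planes (vertex enumeration; the constraint set is a convex polygon).
#'
#' @param collim a [collimation_spec()].
#' @param plane_offset_mm distance of the evaluation plane past the second
#'   pinhole (mm), non-negative; defaults to the spec's isocenter distance.
#' @return envelope diameter in mm.
#' @export
beam_envelope_diameter <- function(collim,
                                   plane_offset_mm =
                                     collim$second_pinhole_to_isocenter_mm) {
  stopifnot(inherits(collim, "xdt_collimation"), plane_offset_mm >= 0)
  a0 <- collim$source_spot_mm / 2
  a1 <- collim$pinhole_diameters_mm[1] / 2
  a2 <- collim$pinhole_diameters_mm[2] / 2
  L1 <- collim$source_to_first_pinhole_mm
  Lsep <- collim$pinhole_separation_mm
  z <- plane_offset_mm
  # Variables (x1, x2): lateral ray position at the two pinhole planes.
  # Source position back-extrapolated: x0 = x1 - (x2 - x1) * L1 / Lsep.
  # Plane position forward-extrapolated: xp = x2 + (x2 - x1) * z / Lsep.
  # Maximize xp subject to |x1| <= a1, |x2| <= a2, |x0| <= a0.
  cc <- c(-z / Lsep, 1 + z / Lsep)
  k1 <- 1 + L1 / Lsep
  k2 <- -L1 / Lsep
  # Half-plane constraints A %*% x <= b
  A <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
             c(k1, k2), c(-k1, -k2))
  b <- c(a1, a1, a2, a2, a0, a0)
  best <- -Inf
  n <- nrow(A)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      M <- A[c(i, j), , drop = FALSE]
      if (abs(det(M)) < 1e-12) next
      v <- solve(M, b[c(i, j)])
      if (all(A %*% v <= b + 1e-9)) best <- max(best, sum(cc * v))
    }
  }
  if (!is.finite(best)) stop("infeasible collimation geometry")
  2 * best
}

#' Fan-ray coordinate map of the XDT geometry
#'
#' For each detector radial bin, tabulates the (scatter depth t, momentum
#' transfer q) curve along which scatter contributes to that bin, together
#' with the annulus solid-angle weight at every depth. These curves are the
#' fan rays that make the 2D diffraction scan equivalent to a 3D circular
#' parallel-fan-beam CT: in (t, 1/q) coordinates the rays are straight with a
#' virtual vertex at the detector plane (t = D).
#'
#' @param geom an [xdt_geometry()].
#' @param r_bins centers of the detector radial bins (mm).
#' @param t_grid scatter depths (mm) at which to tabulate the curves.
#' @param dr radial bin width (mm); defaults to the detector pixel size.
#' @param small_angle if `TRUE` use the small-angle closed form
#'   `q = r / (2 lambda (D - t))` instead of exact trigonometry.
#' @return an object of class `xdt_fan_ray_map`: list with `r_bins`, `t_grid`,
#'   matrices `q` and `weight` (rows = r bins, cols = depths), and logical
#'   `masked` flagging bins inside the beam stop.
#' @export
fan_ray_map <- function(geom, r_bins, t_grid, dr = geom$pixel_mm,
                        small_angle = FALSE) {
  stopifnot(all(r_bins >= 0), all(abs(t_grid) < geom$detector_distance_mm))
  D <- geom$detector_distance_mm
  lam <- geom$wavelength_angstrom
  Dt <- outer(rep(1, length(r_bins)), D - t_grid)
  R <- outer(r_bins, rep(1, length(t_grid)))
  q <- if (small_angle) R / (2 * lam * Dt) else {
    theta <- atan2(R, Dt)
    sin(theta / 2) / lam
  }
  w <- 2 * pi * R * dr * Dt / (Dt^2 + R^2)^1.5
  out <- list(r_bins = r_bins, t_grid = t_grid, q = q, weight = w,
              masked = r_bins < geom$beam_stop_mm, dr = dr)
  class(out) <- "xdt_fan_ray_map"
  out
}

#' Write / read a scan geometry as YAML
#'
#' @param geom an [xdt_geometry()].
#' @param path file path.
#' @return `write_geometry` returns `path` invisibly; `read_geometry` returns
#'   an `xdt_geometry`.
#' @export
write_geometry <- function(geom, path) {
  yaml::write_yaml(list(
    energy_keV = geom$energy_keV,
    detector_distance_mm = geom$detector_distance_mm,
    pixel_mm = geom$pixel_mm,
    frame_shape = geom$frame_shape,
    beam_stop_mm = geom$beam_stop_mm,
    step_mm = geom$step_mm,
    angles_deg = geom$angles_deg,
    beam_diameter_mm = geom$beam_diameter_mm
  ), path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("energy_keV", "detector_distance_mm", "pixel_mm", "frame_shape",
            "beam_stop_mm", "step_mm", "angles_deg")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("malformed geometry file, missing: ", paste(miss, collapse = ", "))
  xdt_geometry(energy_keV = y$energy_keV,
               detector_distance_mm = y$detector_distance_mm,
               pixel_mm = y$pixel_mm,
               frame_shape = unlist(y$frame_shape),
               beam_stop_mm = y$beam_stop_mm,
               step_mm = y$step_mm,
               angles_deg = unlist(y$angles_deg),
               beam_diameter_mm = y$beam_diameter_mm %||% 2.4)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
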