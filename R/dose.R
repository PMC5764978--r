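# Absorbed-dose comparison between global and interior scan plans.
#
# Deterministic pencil-beam primary-absorption transport: each beam is
# marched through the labeled phantom with exact Siddon ray/pixel
# intersection lengths; the energy absorbed in a pixel is
# I_entering * (1 - exp(-mu * l)) (Beer-Lambert at the beam energy, 8 keV by
# default, where photoelectric absorption dominates), and dose is absorbed
# energy per unit mass. No scattered-photon transport and no source
# spectrum: the global-vs-interior comparison is a ratio and is largely
# insensitive to those details.

#' Absorbed-dose map on a phantom grid
#'
#' @param dose non-negative matrix (same shape as the phantom label grid);
#'   arbitrary consistent energy/mass units.
#' @param pixel_pitch_mm grid pitch (mm).
#' @param phantom the source [xdt_phantom()].
#' @return object of class `xdt_dose_map`.
#' @export
xdt_dose_map <- function(dose, pixel_pitch_mm, phantom = NULL) {
  stopifnot(all(dose >= 0), all(is.finite(dose)))
  structure(list(dose = dose, pixel_pitch_mm = pixel_pitch_mm,
                 phantom = phantom),
            class = "xdt_dose_map")
}

#' @export
print.xdt_dose_map <- function(x, ...) {
  cat(sprintf("XDT dose map: %d x %d at %g mm, total %.4g (arb. energy/mass)\n",
              nrow(x$dose), ncol(x$dose), x$pixel_pitch_mm, sum(x$dose)))
  invisible(x)
}

# Siddon ray tracing: pixel indices and intersection lengths of the line
# p(t) = origin + t * dir (unit dir) through an n x n grid of given pitch
# centered on the origin
siddon_trace <- function(n, pitch, s_mm, angle_rad) {
  half <- n * pitch / 2
  u <- c(cos(angle_rad), sin(angle_rad))
  v <- c(-sin(angle_rad), cos(angle_rad))
  p0 <- s_mm * u          # point on the beam at t = 0
  # parametric range of t inside the bounding box
  tmin <- -Inf; tmax <- Inf
  for (d in 1:2) {
    if (abs(v[d]) < 1e-12) {
      if (abs(p0[d]) >= half) return(NULL)
    } else {
      t1 <- (-half - p0[d]) / v[d]; t2 <- (half - p0[d]) / v[d]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmin >= tmax) return(NULL)
  # crossing parameters with all grid lines
  ts <- c(tmin, tmax)
  for (d in 1:2) {
    if (abs(v[d]) > 1e-12) {
      edges <- seq(-half, half, by = pitch)
      tc <- (edges - p0[d]) / v[d]
      ts <- c(ts, tc[tc > tmin & tc < tmax])
    }
  }
  ts <- sort(unique(ts))
  if (length(ts) < 2) return(NULL)
  mid <- (ts[-1] + ts[-length(ts)]) / 2
  len <- diff(ts)
  px <- p0[1] + mid * v[1]; py <- p0[2] + mid * v[2]
  i <- floor((px + half) / pitch) + 1
  j <- floor((py + half) / pitch) + 1
  ok <- i >= 1 & i <= n & j >= 1 & j <= n & len > 1e-12
  if (!any(ok)) return(NULL)
  list(i = i[ok], j = j[ok], len_mm = len[ok])
}

# per-pixel linear attenuation (1/mm) and density maps of a phantom
phantom_mu_maps <- function(phantom) {
  mu_cm <- vapply(phantom$materials, linear_attenuation, numeric(1))
  rho <- vapply(phantom$materials, function(m) m$density_gcm3, numeric(1))
  list(mu_mm = matrix(mu_cm[phantom$label_grid] / 10,
                      nrow(phantom$label_grid)),
       rho = matrix(rho[phantom$label_grid], nrow(phantom$label_grid)))
}

#' Dose deposited by a single pencil beam
#'
#' Marches the beam through the phantom: with entering intensity `I`, pixel
#' k with linear attenuation `mu_k` and chord `l_k` absorbs
#' `I * (1 - exp(-mu_k l_k))`; the remainder propagates. Dose is absorbed
#' energy divided by pixel mass (density x pixel volume); air pixels
#' (zero density) absorb nothing.
#'
#' @param phantom an [xdt_phantom()].
#' @param s_mm beam offset (mm).
#' @param angle_deg beam angle (degrees).
#' @param photons_in incident photon count (energy units), positive.
#' @return list with `dose` (matrix increment), `absorbed`, `transmitted`.
#' @export
beam_dose <- function(phantom, s_mm, angle_deg, photons_in = 1) {
  stopifnot(photons_in > 0)
  n <- nrow(phantom$label_grid)
  maps <- phantom_mu_maps(phantom)
  tr <- siddon_trace(n, phantom$pixel_pitch_mm, s_mm, angle_deg * pi / 180)
  dose <- matrix(0, n, n)
  if (is.null(tr))
    return(list(dose = dose, absorbed = 0, transmitted = photons_in))
  I <- photons_in
  pixvol <- phantom$pixel_pitch_mm^2  # per unit thickness; arbitrary units
  for (k in seq_along(tr$len_mm)) {
    i <- tr$i[k]; j <- tr$j[k]
    mu <- maps$mu_mm[i, j]
    absd <- I * (1 - exp(-mu * tr$len_mm[k]))
    if (maps$rho[i, j] > 0)
      dose[i, j] <- dose[i, j] + absd / (maps$rho[i, j] * pixvol)
    I <- I - absd
  }
  list(dose = dose, absorbed = photons_in - I, transmitted = I)
}

#' Absorbed dose of a full scan plan
#'
#' Sum of [beam_dose()] over every retained (s, phi) position at equal
#' exposure per position; deterministic.
#'
#' @param phantom an [xdt_phantom()].
#' @param plan an [scan_plan()] (its `keep` mask selects the beams).
#' @param photons_per_position incident photons per scan position.
#' @return an [xdt_dose_map()].
#' @export
scan_dose <- function(phantom, plan, photons_per_position = 1) {
  n <- nrow(phantom$label_grid)
  maps <- phantom_mu_maps(phantom)
  pitch <- phantom$pixel_pitch_mm
  pixvol <- pitch^2
  dose <- matrix(0, n, n)
  for (ia in seq_along(plan$angles_deg)) {
    ar <- plan$angles_deg[ia] * pi / 180
    for (is in seq_along(plan$s_offsets_mm)) {
      if (!plan$keep[is, ia]) next
      tr <- siddon_trace(n, pitch, plan$s_offsets_mm[is], ar)
      if (is.null(tr)) next
      I <- photons_per_position
      for (k in seq_along(tr$len_mm)) {
        i <- tr$i[k]; j <- tr$j[k]
        absd <- I * (1 - exp(-maps$mu_mm[i, j] * tr$len_mm[k]))
        if (maps$rho[i, j] > 0)
          dose[i, j] <- dose[i, j] + absd / (maps$rho[i, j] * pixvol)
        I <- I - absd
      }
    }
  }
  xdt_dose_map(dose, pitch, phantom)
}

# region selector on a dose map: "total", "roi", or "exterior"
dose_region_mask <- function(dmap, region, roi) {
  n <- nrow(dmap$dose)
  if (region == "total") return(matrix(TRUE, n, n))
  if (is.null(roi)) stop("region '", region, "' needs an ROI")
  xc <- axis_centers(n, dmap$pixel_pitch_mm)
  X <- matrix(xc, n, n); Y <- matrix(xc, n, n, byrow = TRUE)
  inroi <- (X - roi$center[1])^2 + (Y - roi$center[2])^2 <=
    (roi$diameter / 2)^2
  if (region == "roi") inroi else !inroi
}

#' Percentage dose reduction of the interior scan relative to the global scan
#'
#' `100 * (1 - sum_region(interior) / sum_region(global))`.
#'
#' @param dose_global,dose_interior [xdt_dose_map()] objects on the same
#'   grid.
#' @param region `"total"`, `"exterior"` or `"roi"`.
#' @param roi ROI descriptor (needed for `"roi"`/`"exterior"`); defaults to
#'   the phantom's.
#' @return percent reduction.
#' @export
dose_reduction <- function(dose_global, dose_interior,
                           region = c("total", "exterior", "roi"),
                           roi = NULL) {
  region <- match.arg(region)
  stopifnot(all(dim(dose_global$dose) == dim(dose_interior$dose)))
  roi <- roi %||% dose_global$phantom$roi
  m <- dose_region_mask(dose_global, region, roi)
  100 * (1 - sum(dose_interior$dose[m]) / sum(dose_global$dose[m]))
}

#' Ratio of ROI dose, interior over global
#'
#' @inheritParams dose_reduction
#' @return `sum_roi(interior) / sum_roi(global)`.
#' @export
roi_dose_ratio <- function(dose_global, dose_interior, roi = NULL) {
  roi <- roi %||% dose_global$phantom$roi
  m <- dose_region_mask(dose_global, "roi", roi)
  sum(dose_interior$dose[m]) / sum(dose_global$dose[m])
}
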