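# Detector-plane simulation and preprocessing: render 2D diffraction frames
# with Poisson noise, a central beam stop and a flat background; average
# frames azimuthally back into radial profiles; subtract background frames.
#
# Radial profiles are expressed as annulus totals: the azimuthal mean over
# the unmasked pixels of a bin, multiplied by the bin's total pixel count.
# Under this convention a noiseless render followed by azimuthal averaging
# returns exactly the projector's (s, phi) line, including bins partially
# covered by the beam stop.

#' Detector frame
#'
#' @param counts non-negative integer matrix (detector_shape).
#' @param exposure_s exposure time (seconds).
#' @param beam_center pixel coordinates (row, col) of the beam axis.
#' @param beamstop_mask logical matrix, `TRUE` where the beam stop blocks the
#'   detector (counts are zero there).
#' @return object of class `xdt_frame`.
#' @export
xdt_frame <- function(counts, exposure_s, beam_center, beamstop_mask) {
  stopifnot(all(counts >= 0), all(dim(counts) == dim(beamstop_mask)),
            all(counts[beamstop_mask] == 0))
  structure(list(counts = counts, exposure_s = exposure_s,
                 beam_center = beam_center, beamstop_mask = beamstop_mask),
            class = "xdt_frame")
}

# pixel-center coordinates (mm) and radii of a frame; beam center at the
# geometric frame center
frame_pixel_radii <- function(geom) {
  nr <- geom$frame_shape[1]; nc <- geom$frame_shape[2]
  px <- geom$pixel_mm
  xr <- axis_centers(nr, px); yc <- axis_centers(nc, px)
  X <- matrix(xr, nr, nc); Y <- matrix(yc, nr, nc, byrow = TRUE)
  list(r = sqrt(X^2 + Y^2),
       stop = abs(X) <= geom$beam_stop_mm & abs(Y) <= geom$beam_stop_mm)
}

# radial bin index (width = pixel size) of each pixel, plus per-bin totals
frame_binning <- function(geom) {
  pr <- frame_pixel_radii(geom)
  bin <- pmin(floor(pr$r / geom$pixel_mm) + 1L,
              .Machine$integer.max)
  nb <- max(bin)
  list(bin = bin, n_bins = nb,
       r_mm = (seq_len(nb) - 0.5) * geom$pixel_mm,
       n_total = tabulate(bin, nb),
       n_open = tabulate(bin[!pr$stop], nb),
       stop = pr$stop)
}

#' Render a detector frame for one scan position
#'
#' Expected counts per pixel are `exposure * (ring intensity / annulus pixel
#' count + background_rate)`, with the ring intensity taken from the forward
#' projector restricted to the single (s, phi) position; counts are Poisson
#' sampled and beam-stop pixels zeroed.
#'
#' @param object an [xdt_volume()].
#' @param s_mm beam offset (mm).
#' @param angle_deg rotation angle (degrees).
#' @param geom an [xdt_geometry()].
#' @param exposure_s exposure (seconds), positive.
#' @param background_rate flat background in counts/pixel/second.
#' @param seed RNG seed; `NULL` for a noiseless (expectation) frame.
#' @return an [xdt_frame()].
#' @export
render_frame <- function(object, s_mm, angle_deg, geom, exposure_s = 45,
                         background_rate = 0, seed = NULL) {
  stopifnot(exposure_s > 0)
  fb <- frame_binning(geom)
  plan1 <- scan_plan(s_mm, angle_deg, exposure_s)
  sino <- project(object, geom, plan1, r_bins = fb$r_mm, dr = geom$pixel_mm)
  ring <- sino$values[1, 1, ]                       # annulus totals per bin
  per_pixel <- ifelse(fb$n_total > 0, ring / fb$n_total, 0)
  lam <- exposure_s * (per_pixel[fb$bin] + background_rate)
  dim(lam) <- dim(fb$bin)
  if (is.null(seed)) {
    counts <- lam
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    counts <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
  }
  counts[fb$stop] <- 0
  xdt_frame(counts, exposure_s, beam_center = (dim(lam) + 1) / 2,
            beamstop_mask = fb$stop)
}

#' Azimuthal average of a detector frame
#'
#' Bins pixels by center radius into bins one pixel wide and returns, per
#' bin, the annulus-total intensity: the mean over unmasked pixels times the
#' bin's total pixel count, divided by the exposure. Bins with no unmasked
#' pixel (fully inside the beam stop, or beyond the frame) are masked.
#'
#' @param frame an [xdt_frame()].
#' @param geom an [xdt_geometry()].
#' @return list with `r_mm` (bin centers), `values` (annulus totals per
#'   second), `n_pixels` (total pixels per bin, for converting back to
#'   per-pixel means), and logical `mask`.
#' @export
azimuthal_average <- function(frame, geom) {
  fb <- frame_binning(geom)
  stopifnot(all(dim(frame$counts) == dim(fb$bin)))
  open <- !frame$beamstop_mask
  sums <- rowsum(as.numeric(frame$counts[open]), fb$bin[open])
  idx <- as.integer(rownames(sums))
  n_open <- tabulate(fb$bin[open], fb$n_bins)
  vals <- rep(NA_real_, fb$n_bins)
  vals[idx] <- sums[, 1]
  mean_open <- ifelse(n_open > 0, vals / n_open, NA_real_)
  out <- mean_open * fb$n_total / frame$exposure_s
  mask <- n_open == 0
  out[mask] <- 0
  list(r_mm = fb$r_mm, values = out, n_pixels = fb$n_total, mask = mask)
}

#' Subtract a background frame
#'
#' Pixel-wise difference clipped at zero; beam-stop masks are OR-ed.
#'
#' @param frame,background_frame [xdt_frame()] objects of the same shape.
#' @return an [xdt_frame()].
#' @export
subtract_background <- function(frame, background_frame) {
  stopifnot(all(dim(frame$counts) == dim(background_frame$counts)))
  d <- pmax(frame$counts - background_frame$counts, 0)
  m <- frame$beamstop_mask | background_frame$beamstop_mask
  d[m] <- 0
  xdt_frame(d, frame$exposure_s, frame$beam_center, m)
}

#' Write / read detector frames as 16-bit grayscale TIFF
#'
#' File names follow `frame_sXXX_aYYY.tif` (translation index, angle index);
#' background frames `background_aYYY.tif`.
#'
#' @param frame an [xdt_frame()].
#' @param path output file path.
#' @param max_count full-scale count value mapped to 65535.
#' @return `write_frame_tiff` returns `path`; `read_frame_tiff` returns the
#'   counts matrix.
#' @export
write_frame_tiff <- function(frame, path, max_count = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for detector frame files")
  m <- pmin(frame$counts / max_count, 1)
  tiff::writeTIFF(m, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_frame_tiff
#' @export
read_frame_tiff <- function(path, max_count = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for detector frame files")
  round(tiff::readTIFF(path) * max_count)
}
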