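# Plain-text data containers shared by all modules: a single JSON file per
# object holding named datasets (numeric arrays with their dimensions) and
# metadata, written at full double precision so round trips are lossless.
# Dataset names mirror the layout used across the toolkit: /g, /s_mm,
# /angles_deg, /r_mm, /mask for sinograms; /f, /x_mm, /y_mm,
# /q_inv_angstrom for volumes; /dose, /pixel_mm for dose maps.

write_container <- function(datasets, path, kind) {
  enc <- lapply(datasets, function(d) {
    if (is.array(d) || is.matrix(d))
      list(dim = dim(d), data = as.vector(d))
    else d
  })
  # digits = I(17): 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(c(list(container = kind), enc), path,
                       auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

read_container <- function(path, kind, need) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$container, kind))
    stop("not a ", kind, " container: ", path)
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("malformed ", kind, " container, missing dataset(s): ",
         paste(miss, collapse = ", "))
  for (nm in names(x)) {
    d <- x[[nm]]
    if (is.list(d) && !is.null(d$dim))
      x[[nm]] <- array(as.double(unlist(d$data)), unlist(d$dim))
  }
  x
}

#' Write / read a sinogram container
#'
#' Datasets: `g` (offsets x angles x radial bins), `s_mm`, `angles_deg`,
#' `r_mm`, `mask`, plus the ROI descriptor and count scale.
#'
#' @param sino an [xdt_sinogram()].
#' @param path file path.
#' @return `write_sinogram` returns `path`; `read_sinogram` an
#'   [xdt_sinogram()].
#' @export
write_sinogram <- function(sino, path) {
  write_container(list(g = sino$values, s_mm = sino$s_mm,
                       angles_deg = sino$angles_deg, r_mm = sino$r_mm,
                       mask = sino$mask * 1L, roi = sino$roi,
                       scale = sino$scale),
                  path, "sinogram")
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  x <- read_container(path, "sinogram",
                      c("g", "s_mm", "angles_deg", "r_mm", "mask"))
  roi <- x$roi
  if (!is.null(roi)) roi <- list(center = unlist(roi$center),
                                 diameter = roi$diameter)
  xdt_sinogram(x$g, x$s_mm, x$angles_deg, x$r_mm,
               mask = array(x$mask != 0, dim(x$g)), roi = roi,
               scale = x$scale %||% 1)
}

#' Write / read an object-volume container
#'
#' Datasets: `f` (x by y by q), `x_mm`, `y_mm`, `q_inv_angstrom`.
#'
#' @param vol an [xdt_volume()].
#' @param path file path.
#' @export
write_volume <- function(vol, path) {
  write_container(list(f = vol$values, x_mm = vol$x_mm, y_mm = vol$y_mm,
                       q_inv_angstrom = vol$q_grid,
                       pixel_mm = vol$pixel_pitch_mm),
                  path, "volume")
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  x <- read_container(path, "volume", c("f", "q_inv_angstrom", "pixel_mm"))
  xdt_volume(x$f, x$pixel_mm, x$q_inv_angstrom)
}

#' Write / read a dose-map container
#'
#' Datasets: `dose`, `pixel_mm`.
#'
#' @param dmap an [xdt_dose_map()].
#' @param path file path.
#' @export
write_dose_map <- function(dmap, path) {
  write_container(list(dose = dmap$dose, pixel_mm = dmap$pixel_pitch_mm),
                  path, "dose")
}

#' @rdname write_dose_map
#' @export
read_dose_map <- function(path) {
  x <- read_container(path, "dose", c("dose", "pixel_mm"))
  xdt_dose_map(x$dose, x$pixel_mm)
}
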