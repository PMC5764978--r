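# Reference form-factor library, attenuation properties, and the built-in
# phantoms used throughout the package.
#
# The form factors are synthetic fixtures: parametric Gaussian-mixture
# stand-ins for measured coherent-scatter profiles, constrained so that the
# lipid (oil/fat) peak sits near q = 0.08 1/A, the water peak near 0.16 1/A,
# ethanol in between, and the water/ethanol/oil triplet is mutually
# distinguishable at q = 0.10 and 0.12 1/A. Attenuation values for fat and
# muscle are the 8 keV ICRU-44 numbers; the remaining materials carry
# documented synthetic fixture values.

#' Molecular form factor sampled on a momentum-transfer grid
#'
#' @param q_grid strictly increasing momentum-transfer grid (1/Angstrom).
#' @param values non-negative scatter intensities per unit length.
#' @return object of class `xdt_form_factor`.
#' @export
form_factor <- function(q_grid, values) {
  q_grid <- as.numeric(q_grid); values <- as.numeric(values)
  stopifnot(length(q_grid) == length(values), all(diff(q_grid) > 0),
            all(is.finite(q_grid)), all(is.finite(values)), all(values >= 0))
  structure(list(q_grid = q_grid, values = values), class = "xdt_form_factor")
}

#' Gaussian-mixture synthetic form factor
#'
#' Sum of Gaussian peaks plus a constant baseline evaluated on `q_grid`; the
#' parametric stand-in this package uses for measured form factors.
#'
#' @param peaks list of numeric triplets `c(center, sigma, amplitude)` with
#'   center/sigma in 1/Angstrom, sigma > 0, amplitude >= 0.
#' @param baseline non-negative constant offset.
#' @param q_grid strictly increasing momentum-transfer grid (1/Angstrom).
#' @return an [form_factor()] object.
#' @export
gaussian_mixture_form_factor <- function(peaks, baseline, q_grid) {
  stopifnot(baseline >= 0)
  v <- rep(baseline, length(q_grid))
  for (p in peaks) {
    stopifnot(length(p) == 3, p[2] > 0, p[3] >= 0)
    v <- v + p[3] * exp(-0.5 * ((q_grid - p[1]) / p[2])^2)
  }
  form_factor(q_grid, v)
}

#' A material: form factor plus attenuation properties
#'
#' @param name material name.
#' @param form_factor an [form_factor()] object.
#' @param mass_attenuation_cm2g mass attenuation coefficient at the beam
#'   energy (cm^2/g), non-negative.
#' @param density_gcm3 mass density (g/cm^3), non-negative.
#' @return object of class `xdt_material`.
#' @export
xdt_material <- function(name, form_factor, mass_attenuation_cm2g,
                         density_gcm3) {
  stopifnot(inherits(form_factor, "xdt_form_factor"),
            mass_attenuation_cm2g >= 0, density_gcm3 >= 0)
  structure(list(name = name, form_factor = form_factor,
                 mass_attenuation_cm2g = mass_attenuation_cm2g,
                 density_gcm3 = density_gcm3),
            class = "xdt_material")
}

#' Linear attenuation coefficient of a material
#'
#' `mu = (mu/rho) * rho`, returned in 1/cm.
#'
#' @param material an [xdt_material()].
#' @return linear attenuation coefficient in 1/cm.
#' @export
linear_attenuation <- function(material) {
  stopifnot(inherits(material, "xdt_material"))
  material$mass_attenuation_cm2g * material$density_gcm3
}

#' Default momentum-transfer grid of the built-in fixtures
#'
#' 24 bins over 0.05..0.25 1/Angstrom, bracketing every built-in peak.
#'
#' @param n number of bins.
#' @return numeric vector of q values (1/Angstrom).
#' @export
default_q_grid <- function(n = 24) seq(0.05, 0.25, length.out = n)

#' Built-in material libraries
#'
#' `"phantom4"` returns the five classes of the liquid phantom (air, water,
#' ethanol, soybean oil, Teflon); `"tissue"` returns air, fat and muscle. The
#' lipid materials (oil, fat) peak near q = 0.08 1/A, water near 0.16 1/A,
#' ethanol in between; muscle closely resembles water. Fat/muscle attenuation
#' uses the printed 8 keV values (6.3 and 10.4 cm^2/g at 0.95 and
#' 1.05 g/cm^3); the other attenuation entries are synthetic fixture values.
#'
#' @param name `"phantom4"` or `"tissue"`.
#' @param q_grid momentum-transfer grid on which to evaluate the library.
#' @return named list of [xdt_material()] objects; the first entry is always
#'   the air/background class (zero form factor).
#' @export
builtin_library <- function(name = c("phantom4", "tissue"),
                            q_grid = default_q_grid()) {
  name <- match.arg(name)
  gm <- function(peaks, baseline) {
    gaussian_mixture_form_factor(peaks, baseline, q_grid)
  }
  air <- xdt_material("air", form_factor(q_grid, rep(0, length(q_grid))), 0, 0)
  if (name == "phantom4") {
    list(
      air = air,
      water = xdt_material("water", gm(list(c(0.160, 0.025, 1.00)), 0.05),
                           10.37, 1.00),
      ethanol = xdt_material("ethanol", gm(list(c(0.125, 0.018, 0.85)), 0.05),
                             7.04, 0.789),
      oil = xdt_material("oil", gm(list(c(0.080, 0.015, 1.00)), 0.05),
                         6.3, 0.92),
      # sharpest profile of the set (semi-crystalline), but kept resolvable
      # on the default 24-bin q grid (sigma >= 2 * dq)
      teflon = xdt_material("teflon", gm(list(c(0.200, 0.020, 1.40)), 0.03),
                            13.1, 2.20)
    )
  } else {
    list(
      air = air,
      fat = xdt_material("fat", gm(list(c(0.080, 0.015, 1.00)), 0.05),
                         6.3, 0.95),
      muscle = xdt_material("muscle", gm(list(c(0.155, 0.027, 0.90)), 0.06),
                            10.4, 1.05)
    )
  }
}

#' Labeled 2D phantom
#'
#' @param label_grid integer matrix of material indices into `materials`
#'   (1 = first entry, conventionally air).
#' @param pixel_pitch_mm spatial sampling of the label grid (mm).
#' @param materials named list of [xdt_material()] objects.
#' @param roi list with `center` (mm, length 2) and `diameter` (mm), or NULL.
#' @return object of class `xdt_phantom`.
#' @export
xdt_phantom <- function(label_grid, pixel_pitch_mm, materials, roi = NULL) {
  label_grid <- as.matrix(label_grid)
  stopifnot(nrow(label_grid) == ncol(label_grid),
            all(label_grid >= 1), all(label_grid <= length(materials)))
  if (!is.null(roi)) {
    half <- nrow(label_grid) * pixel_pitch_mm / 2
    if (any(abs(roi$center) + roi$diameter / 2 > half))
      stop("roi must lie inside the phantom grid")
  }
  structure(list(label_grid = label_grid, pixel_pitch_mm = pixel_pitch_mm,
                 materials = materials, roi = roi),
            class = "xdt_phantom")
}

#' @export
print.xdt_phantom <- function(x, ...) {
  n <- nrow(x$label_grid)
  cat(sprintf("XDT phantom: %d x %d labels at %g mm (%g mm extent)\n",
              n, n, x$pixel_pitch_mm, n * x$pixel_pitch_mm))
  tab <- table(factor(x$label_grid, levels = seq_along(x$materials),
                      labels = names(x$materials)))
  cat("  composition:", paste(sprintf("%s=%d", names(tab), tab),
                              collapse = ", "), "\n")
  if (!is.null(x$roi))
    cat(sprintf("  ROI: %g mm disk at (%g, %g) mm\n", x$roi$diameter,
                x$roi$center[1], x$roi$center[2]))
  invisible(x)
}

# pixel-center coordinates of an n-cell axis of given pitch, centered on 0
axis_centers <- function(n, pitch) (seq_len(n) - (n + 1) / 2) * pitch

#' Build a phantom
#'
#' `"phantom4"`: a 32 mm Teflon disk holding three 9 mm liquid inserts (water,
#' ethanol, soybean oil) at 120-degree spacing, with a centered 14 mm ROI.
#' `"tissue"`: a 23 mm x 23 mm muscle block with a fat lobe in the upper-right
#' quadrant and a circular ROI (default 6 mm) over the fat/muscle boundary.
#' A custom phantom is a list of placed disks/rectangles.
#'
#' @param spec `"phantom4"`, `"tissue"`, or a list with elements `extent_mm`,
#'   `shape` ("disk"/"square" container), `container` (material name or
#'   "air"), `inserts` (list of lists with `type` ("disk" or "rect"),
#'   `material`, `center`, and `diameter` or `size`), and optional `roi`.
#' @param library named material list; defaults to the library matching the
#'   builtin spec.
#' @param pitch_mm label-grid pitch (mm); default 0.5 (half the 1 mm
#'   translation step, so the forward model supersamples the beam).
#' @param roi_diameter_mm ROI diameter for `"tissue"` (mm); the printed value is
#'   ambiguous (5 vs 6 mm) so it is a parameter, default 6.
#' @return an [xdt_phantom()].
#' @export
build_phantom <- function(spec = c("phantom4", "tissue"), library = NULL,
                          pitch_mm = 0.5, roi_diameter_mm = 6) {
  if (is.character(spec)) {
    spec <- match.arg(spec)
    if (spec == "phantom4") {
      library <- library %||% builtin_library("phantom4")
      ang <- c(90, 210, 330) * pi / 180
      ins <- lapply(seq_along(ang), function(i) {
        list(type = "disk",
             material = c("water", "ethanol", "oil")[i],
             center = 7.5 * c(cos(ang[i]), sin(ang[i])), diameter = 9)
      })
      spec <- list(extent_mm = 32, shape = "disk", container = "teflon",
                   inserts = ins,
                   roi = list(center = c(0, 0), diameter = 14))
    } else {
      library <- library %||% builtin_library("tissue")
      spec <- list(extent_mm = 23, shape = "square", container = "muscle",
                   inserts = list(list(type = "disk", material = "fat",
                                       center = c(5.5, 5.5), diameter = 9)),
                   roi = list(center = c(5.75, 5.75),
                              diameter = roi_diameter_mm))
    }
  } else {
    library <- library %||% builtin_library("phantom4")
  }
  ext <- spec$extent_mm
  n <- round(ext / pitch_mm)
  xc <- axis_centers(n, pitch_mm)
  X <- matrix(xc, n, n)            # x varies along rows
  Y <- matrix(xc, n, n, byrow = TRUE)
  idx_of <- function(nm) {
    i <- match(nm, names(library))
    if (is.na(i)) stop("unknown material: ", nm)
    i
  }
  lab <- matrix(1L, n, n)   # first library entry is the air/background class
  cont <- spec$container %||% "air"
  inside <- if (identical(spec$shape, "disk")) {
    X^2 + Y^2 <= (ext / 2)^2
  } else matrix(TRUE, n, n)
  if (!identical(cont, "air")) lab[inside] <- idx_of(cont)
  half <- ext / 2
  assigned <- matrix(FALSE, n, n)
  for (ins in spec$inserts %||% list()) {
    m <- idx_of(ins$material)
    if (identical(ins$type, "rect")) {
      sz <- ins$size
      if (any(abs(ins$center) + sz / 2 > half + 1e-9))
        stop("insert outside container")
      sel <- abs(X - ins$center[1]) <= sz[1] / 2 &
             abs(Y - ins$center[2]) <= sz[2] / 2
    } else {
      rad <- ins$diameter / 2
      fits <- if (identical(spec$shape, "disk"))
        sqrt(sum(ins$center^2)) + rad <= half + 1e-9
      else all(abs(ins$center) + rad <= half + 1e-9)
      if (!fits) stop("insert outside container")
      sel <- (X - ins$center[1])^2 + (Y - ins$center[2])^2 <= rad^2
    }
    sel <- sel & inside
    if (any(assigned[sel]))
      warning("overlapping inserts: last placed wins")
    lab[sel] <- m
    assigned <- assigned | sel
  }
  xdt_phantom(lab, pitch_mm, library, roi = spec$roi)
}

#' Discretized object volume f(x, y, q)
#'
#' @param values non-negative array X x Y x Q.
#' @param pixel_pitch_mm spatial pitch (mm).
#' @param q_grid momentum-transfer grid (1/Angstrom).
#' @return object of class `xdt_volume`.
#' @export
xdt_volume <- function(values, pixel_pitch_mm, q_grid) {
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3, dim(values)[3] == length(q_grid),
            all(is.finite(values)))
  structure(list(values = values, pixel_pitch_mm = pixel_pitch_mm,
                 q_grid = as.numeric(q_grid),
                 x_mm = axis_centers(dim(values)[1], pixel_pitch_mm),
                 y_mm = axis_centers(dim(values)[2], pixel_pitch_mm)),
            class = "xdt_volume")
}

#' @export
print.xdt_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("XDT object volume: %d x %d spatial (%g mm pitch) x %d q-bins (%.3f..%.3f 1/A)\n",
              d[1], d[2], x$pixel_pitch_mm, d[3], min(x$q_grid), max(x$q_grid)))
  invisible(x)
}

#' Expand a labeled phantom into an object volume
#'
#' Every pixel's spectrum is the form factor of its material, resampled onto
#' `q_grid` by linear interpolation (zero outside the library grid); air is
#' all zeros.
#'
#' @param phantom an [xdt_phantom()].
#' @param library optional material list overriding the phantom's.
#' @param q_grid momentum-transfer grid for the volume.
#' @return an [xdt_volume()].
#' @export
phantom_to_object <- function(phantom, library = phantom$materials,
                              q_grid = default_q_grid()) {
  n <- nrow(phantom$label_grid)
  spectra <- vapply(library, function(m) {
    ff <- m$form_factor
    stats::approx(ff$q_grid, ff$values, xout = q_grid, rule = 1,
                  yleft = 0, yright = 0)$y -> v
    v[is.na(v)] <- 0
    v
  }, numeric(length(q_grid)))            # Q x nmat
  vol <- array(0, c(n, n, length(q_grid)))
  for (m in seq_along(library)) {
    sel <- phantom$label_grid == m
    if (!any(sel)) next
    for (k in seq_along(q_grid)) {
      slice <- vol[, , k]
      slice[sel] <- spectra[k, m]
      vol[, , k] <- slice
    }
  }
  xdt_volume(vol, phantom$pixel_pitch_mm, q_grid)
}

#' Read / write form factors as two-column CSV
#'
#' Columns `q_angstrom_inv`, `value`.
#'
#' @param ff an [form_factor()].
#' @param path file path.
#' @export
write_form_factor <- function(ff, path) {
  utils::write.csv(data.frame(q_angstrom_inv = ff$q_grid, value = ff$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_form_factor
#' @export
read_form_factor <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("q_angstrom_inv", "value") %in% names(d)))
    stop("malformed form-factor CSV: need columns q_angstrom_inv, value")
  form_factor(d$q_angstrom_inv, d$value)
}
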