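# Shared fixtures and oracles for the test suite. Heavy end-to-end objects
# (the full phantom-study reconstructions) are computed once per session and
# memoized in `fixture_cache`.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_cache))
    assign(name, force(expr), envir = fixture_cache)
  get(name, envir = fixture_cache)
}

# a small operator backed by an explicit dense matrix, for toy MLEM/oracle
# tests: dims_in / dims_out give the array shapes
matrix_operator <- function(A, dims_in, dims_out, mask = NULL) {
  if (is.null(mask)) mask <- array(FALSE, dims_out)
  list(
    apply = function(f) array(as.vector(A %*% as.vector(f)), dims_out),
    adjoint = function(g) { g[mask] <- 0
      array(as.vector(crossprod(A, as.vector(g))), dims_in) },
    mask = mask, n = dims_in[1], pitch_mm = 1,
    q_grid = seq_len(if (length(dims_in) >= 3) dims_in[3] else 1)
  )
}

# small scan geometry for fast unit tests
small_geometry <- function(angles = seq(0, 180, by = 30))
  xdt_geometry(angles_deg = angles)

small_q_grid <- function(n = 8) seq(0.05, 0.25, length.out = n)

# a 16 x 16 version of the liquid phantom (2 mm pitch)
small_phantom4 <- function(n_q = 8) {
  lib <- builtin_library("phantom4", q_grid = small_q_grid(n_q))
  ph <- build_phantom("phantom4", library = lib, pitch_mm = 2)
  list(lib = lib, phantom = ph,
       object = phantom_to_object(ph, lib, small_q_grid(n_q)))
}

# full-scale phantom study at the nominal scan conditions (32 mm phantom at
# 0.5 mm pitch, 24 q bins, 33 offsets x 46 angles, ~1e4 counts/entry);
# computed once and shared by the acceptance tests
phantom_study <- function() {
  cached("phantom_study", {
    geom <- xdt_geometry()
    lib <- builtin_library("phantom4")
    ph <- build_phantom("phantom4")
    obj <- phantom_to_object(ph)
    plan_g <- plan_global(ph, geom)
    plan_i <- plan_interior(ph, geom)
    H <- build_forward_operator(geom, obj, plan_g)
    sino_g <- simulate_scan(obj, geom, plan_g, seed = 41, operator = H)
    sino_i <- truncate_to_roi(
      simulate_scan(obj, geom, plan_i, seed = 42, operator = H), ph$roi)
    grid <- list(n = 64, pitch_mm = 0.5, q_grid = obj$q_grid)
    vol_global <- fdk_reconstruct(sino_g, geom, grid)
    rec <- ml_tv_reconstruct(sino_i, H, recon_params())
    sino_clean <- simulate_scan(obj, geom, plan_g, operator = H,
                                noiseless = TRUE)
    vol_clean <- fdk_reconstruct(sino_clean, geom, grid)
    list(geom = geom, lib = lib, phantom = ph, object = obj,
         plan_global = plan_g, plan_interior = plan_i, H = H,
         sino_global = sino_g, sino_interior = sino_i,
         vol_global = vol_global, vol_interior = rec$volume, recon = rec,
         vol_clean = vol_clean, grid = grid)
  })
}

# erode a logical mask by one pixel (4-neighborhood)
erode_mask <- function(m) {
  e <- m
  e[-1, ] <- e[-1, ] & m[-nrow(m), ]
  e[-nrow(m), ] <- e[-nrow(m), ] & m[-1, ]
  e[, -1] <- e[, -1] & m[, -ncol(m)]
  e[, -ncol(m)] <- e[, -ncol(m)] & m[, -1]
  e
}

# resample a material's form factor onto a q grid
library_spectrum <- function(lib, name, q_grid) {
  ff <- lib[[name]]$form_factor
  stats::approx(ff$q_grid, ff$values, xout = q_grid, rule = 2)$y
}
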