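test_that("ramp filter kills DC and reproduces its kernel on an impulse", {
  row <- rep(3.7, 33)
  out <- ramp_filter(row, ds = 1, window = "ramlak")
  expect_lt(max(abs(out)), 1e-8 * 3.7)
  imp <- c(rep(0, 16), 1, rep(0, 16))
  resp <- ramp_filter(imp, ds = 1, window = "ramlak")
  h <- ramp_kernel(17, ds = 1)
  # central lags match the analytic band-limited kernel (the DC correction
  # is spread over the padded length and is negligible per sample)
  expect_lt(max(abs(resp[17:25] - h[1:9])), 5e-5)
  expect_lt(max(abs(resp[16:9] - h[2:9])), 5e-5)
  # linearity
  set.seed(2)
  a <- runif(33); b <- runif(33)
  expect_equal(ramp_filter(2 * a + b, 1, "hann"),
               2 * ramp_filter(a, 1, "hann") + ramp_filter(b, 1, "hann"),
               tolerance = 1e-12)
})

test_that("classic FBP recovers a disk from its analytic sinogram", {
  # independent oracle: line integrals of a centered disk of radius R and
  # unit density are 2*sqrt(R^2 - s^2), sampled finely
  n <- 64; pitch <- 0.5
  R <- 9
  s_mm <- seq(-16, 16, by = 0.25)
  angles <- seq(0, 178, by = 2)
  chord <- function(s) ifelse(abs(s) < R, 2 * sqrt(pmax(R^2 - s^2, 0)), 0)
  sino_vals <- array(rep(chord(s_mm), times = length(angles)),
                     c(length(s_mm), length(angles), 1))
  g <- xdt_geometry(detector_distance_mm = 1e5, angles_deg = angles)
  # encode as a single-q sinogram in line-integral units: undo the w(r, 0)
  # division that fbp_per_q applies
  qg <- c(0.1, 0.11)
  r0 <- detector_radius(0.1, 0, g)
  r_bins <- c(r0, detector_radius(0.11, 0, g))
  w0 <- annulus_weight(r_bins[1], 0, diff(r_bins), g)
  sino <- xdt_sinogram(array(c(sino_vals * w0, sino_vals * 0),
                             c(length(s_mm), length(angles), 2)),
                       s_mm, angles, r_bins)
  vol <- fbp_per_q(sino, g, list(n = n, pitch_mm = pitch, q_grid = qg),
                   window = "ramlak")
  xc <- (seq_len(n) - (n + 1) / 2) * pitch
  disk <- outer(xc, xc, function(x, y) (x^2 + y^2 < R^2) * 1)
  err <- sqrt(mean((vol$values[, , 1] - disk)^2)) / 1
  expect_lt(err, 0.05)
})

test_that("zero sinograms reconstruct to zero and the pipeline is linear", {
  fx <- small_phantom4()
  g <- small_geometry()
  plan <- plan_global(fx$phantom, g)
  H <- build_forward_operator(g, fx$object, plan)
  grid <- list(n = 16, pitch_mm = 2, q_grid = fx$object$q_grid)
  z <- simulate_scan(xdt_volume(array(0, dim(fx$object$values)), 2,
                                fx$object$q_grid), g, plan,
                     operator = H, noiseless = TRUE)
  expect_true(all(fdk_reconstruct(z, g, grid)$values == 0))
  expect_true(all(fbp_per_q(z, g, grid)$values == 0))
  s1 <- simulate_scan(fx$object, g, plan, operator = H, noiseless = TRUE)
  v1 <- fdk_reconstruct(s1, g, grid, clip = FALSE)
  s2 <- s1; s2$values <- 2 * s1$values
  v2 <- fdk_reconstruct(s2, g, grid, clip = FALSE)
  expect_lt(max(abs(v2$values - 2 * v1$values)) / max(abs(v1$values)), 1e-8)
})

test_that("global reconstruction recovers the material spectra", {
  fx <- phantom_study()
  v <- fx$vol_clean
  for (nm in c("water", "ethanol", "oil", "teflon")) {
    m <- fx$phantom$label_grid == match(nm, names(fx$lib))
    for (k in 1:3) m <- erode_mask(m)
    sp <- apply(v$values, 3, function(sl) mean(sl[m]))
    truth <- library_spectrum(fx$lib, nm, v$q_grid)
    expect_gt(cor(sp, truth), 0.95)
  }
})

test_that("FDK reduces to per-q parallel FBP at large detector distance", {
  qg <- small_q_grid(10)
  lib <- builtin_library("phantom4", q_grid = qg)
  ph <- build_phantom("phantom4", library = lib, pitch_mm = 1)      # 32 x 32
  obj <- phantom_to_object(ph, lib, qg)
  # D = 100 x object radius
  g_far <- xdt_geometry(detector_distance_mm = 100 * 16)
  plan <- plan_global(ph, g_far)
  H <- build_forward_operator(g_far, obj, plan, dr = 8)
  sino <- simulate_scan(obj, g_far, plan, operator = H, noiseless = TRUE)
  grid <- list(n = 32, pitch_mm = 1, q_grid = qg)
  vf <- fdk_reconstruct(sino, g_far, grid, window = "ramlak", clip = FALSE)
  vp <- fbp_per_q(sino, g_far, grid, window = "ramlak", clip = FALSE)
  whole <- list(center = c(0, 0), diameter = 30)
  expect_lt(nrmsd(vf, vp, whole), 1)
  # and the two genuinely differ at the table-top distance, where the
  # depth dependence of q(r, t) matters
  g_near <- xdt_geometry()
  Hn <- build_forward_operator(g_near, obj, plan)
  sn <- simulate_scan(obj, g_near, plan, operator = Hn, noiseless = TRUE)
  vfn <- fdk_reconstruct(sn, g_near, grid, window = "ramlak", clip = FALSE)
  vpn <- fbp_per_q(sn, g_near, grid, window = "ramlak", clip = FALSE)
  expect_gt(nrmsd(vfn, vpn, whole), 3)
})

test_that("reconstruction is covariant under rotation by one angular step", {
  # smooth Gaussian blob: both the original and the rotated object are
  # rasterized faithfully, so the comparison isolates the operator and the
  # reconstruction, not label aliasing
  qg <- small_q_grid(6)
  n <- 32; pitch <- 1
  xc <- (seq_len(n) - (n + 1) / 2) * pitch
  blob <- function(cx, cy) {
    sp <- exp(-0.5 * ((qg - 0.12) / 0.03)^2)
    base <- outer(xc, xc, function(x, y)
      exp(-((x - cx)^2 + (y - cy)^2) / (2 * 3^2)))
    array(outer(as.vector(base), sp), c(n, n, length(qg)))
  }
  step <- 12 * pi / 180
  obj <- xdt_volume(blob(6, 2), pitch, qg)
  obj_r <- xdt_volume(blob(cos(step) * 6 - sin(step) * 2,
                           sin(step) * 6 + cos(step) * 2), pitch, qg)
  angles <- seq(0, 180, by = 12)
  g <- xdt_geometry(angles_deg = angles)
  plan <- scan_plan(seq(-16, 16), angles)
  H <- build_forward_operator(g, obj, plan)
  s1 <- simulate_scan(obj, g, plan, operator = H, noiseless = TRUE)
  s2 <- simulate_scan(obj_r, g, plan, operator = H, noiseless = TRUE)
  na <- length(angles)
  # projection at angle a of the rotated object = projection of the
  # original at a - step
  rel <- sqrt(mean((s2$values[, 2:na, ] - s1$values[, 1:(na - 1), ])^2)) /
    max(s1$values)
  expect_lt(rel, 0.01)
  # reconstruct from the common angular range: the original's angles
  # 0..168 and the rotated object's angles 12..180 relabeled by one step
  grid <- list(n = n, pitch_mm = pitch, q_grid = qg)
  sub <- function(sino, idx) xdt_sinogram(sino$values[, idx, , drop = FALSE],
                                          sino$s_mm, angles[1:(na - 1)],
                                          sino$r_mm)
  v1 <- fdk_reconstruct(sub(s1, 1:(na - 1)), g, grid)
  v2b <- fdk_reconstruct(sub(s2, 2:na), g, grid)
  expect_lt(nrmsd(v2b, v1, list(center = c(0, 0), diameter = 28)), 2)
})

test_that("finer sampling monotonically improves the reconstruction", {
  qg <- small_q_grid(6)
  lib <- builtin_library("phantom4", q_grid = qg)
  ph <- build_phantom("phantom4", library = lib, pitch_mm = 1)
  obj <- phantom_to_object(ph, lib, qg)
  grid <- list(n = 32, pitch_mm = 1, q_grid = qg)
  whole <- list(center = c(0, 0), diameter = 30)
  err <- sapply(list(list(ds = 2, da = 8), list(ds = 1, da = 4)),
                function(p) {
    g <- xdt_geometry(step_mm = p$ds, angles_deg = seq(0, 180, by = p$da))
    plan <- plan_global(ph, g)
    H <- build_forward_operator(g, obj, plan)
    sino <- simulate_scan(obj, g, plan, operator = H, noiseless = TRUE)
    nrmsd(fdk_reconstruct(sino, g, grid), obj, whole)
  })
  expect_lt(err[2], err[1])
})

test_that("truncated input triggers an interior-artifact warning", {
  fx <- small_phantom4()
  g <- small_geometry()
  plan <- plan_global(fx$phantom, g)
  H <- build_forward_operator(g, fx$object, plan)
  sino <- simulate_scan(fx$object, g, plan, operator = H, noiseless = TRUE)
  tr <- truncate_to_roi(sino, fx$phantom$roi)
  grid <- list(n = 16, pitch_mm = 2, q_grid = fx$object$q_grid)
  expect_warning(fdk_reconstruct(tr, g, grid), "truncated")
})
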