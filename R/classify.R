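# Material identification from reconstructed form-factor spectra:
# one-vs-rest linear SVMs (e1071) over L2-normalized spectra, with
# Platt-style sigmoid calibration of the decision scores, per-pixel material
# maps and region statistics.

l2_normalize_rows <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  nz <- nrm > 0
  M[nz, ] <- M[nz, , drop = FALSE] / nrm[nz]
  M
}

#' Synthetic labeled training spectra from a material library
#'
#' Replicates each material's form factor with additive Gaussian noise
#' (standard deviation relative to the spectrum RMS) and a random amplitude
#' scaling of +/- 20%, clipped at zero. Deterministic per seed.
#'
#' @param library named list of [xdt_material()] (as from
#'   [builtin_library()]).
#' @param n_per_class replicates per material.
#' @param noise_sigma relative noise level (0 = exact copies).
#' @param seed RNG seed.
#' @param q_grid grid on which spectra are sampled; default the library's.
#' @return list with matrix `x` (rows = spectra), factor `labels`, and
#'   `q_grid`.
#' @export
make_training_set <- function(library, n_per_class = 200, noise_sigma = 0.05,
                              seed = 1, q_grid = NULL) {
  stopifnot(n_per_class >= 1, noise_sigma >= 0)
  q_grid <- q_grid %||% library[[1]]$form_factor$q_grid
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  xs <- list(); labs <- character(0)
  for (nm in names(library)) {
    ff <- library[[nm]]$form_factor
    v <- stats::approx(ff$q_grid, ff$values, xout = q_grid, rule = 2)$y
    rms <- sqrt(mean(v^2))
    amp <- 1 + stats::runif(n_per_class, -0.2, 0.2)
    noise <- matrix(stats::rnorm(n_per_class * length(q_grid),
                                 sd = noise_sigma * max(rms, 1e-12)),
                    n_per_class)
    X <- pmax(outer(amp, v) + noise, 0)
    xs[[nm]] <- X
    labs <- c(labs, rep(nm, n_per_class))
  }
  list(x = do.call(rbind, xs), labels = factor(labs, levels = names(library)),
       q_grid = q_grid)
}

#' Train calibrated one-vs-rest SVMs on labeled spectra
#'
#' Fits one binary maximum-margin classifier per class (class vs rest,
#' linear kernel by default) on L2-normalized spectra, then fits a Platt
#' sigmoid `p = 1 / (1 + exp(A s + B))` per class by logistic regression on
#' a deterministic held-out third of the data.
#'
#' @param training list from [make_training_set()] (or with the same
#'   elements).
#' @param kernel SVM kernel, default `"linear"`.
#' @param cost SVM cost parameter.
#' @return object of class `xdt_classifier`.
#' @export
train_svms <- function(training, kernel = "linear", cost = 10) {
  x <- l2_normalize_rows(as.matrix(training$x))
  y <- training$labels
  classes <- levels(droplevels(y))
  if (length(classes) < 2) stop("need at least two classes")
  if (min(table(y)) < 2) stop("need at least two samples per class")
  n <- nrow(x)
  cal_idx <- seq_len(n) %% 3 == 0        # deterministic held-out third
  models <- list()
  for (cl in classes) {
    yy <- factor(ifelse(y == cl, "in", "out"), levels = c("in", "out"))
    fit <- e1071::svm(x[!cal_idx, , drop = FALSE], yy[!cal_idx],
                      kernel = kernel, cost = cost, scale = FALSE)
    sc_cal <- score_svm(fit, x[cal_idx, , drop = FALSE])
    z <- as.integer(yy[cal_idx] == "in")
    ab <- platt_fit(sc_cal, z)
    models[[cl]] <- list(fit = fit, A = ab[1], B = ab[2])
  }
  structure(list(models = models, classes = classes,
                 q_grid = training$q_grid, kernel = kernel),
            class = "xdt_classifier")
}

# decision score oriented so that larger = more likely the positive class
score_svm <- function(fit, x) {
  dvm <- attr(stats::predict(fit, x, decision.values = TRUE),
              "decision.values")
  dv <- dvm[, 1]
  if (grepl("^out/", colnames(dvm)[1])) dv <- -dv
  unname(dv)
}

# Platt sigmoid fit p = 1/(1 + exp(A s + B)) by regularized logistic
# regression (target shrinkage as in Platt's original recipe)
platt_fit <- function(scores, z) {
  n1 <- sum(z == 1); n0 <- sum(z == 0)
  t1 <- (n1 + 1) / (n1 + 2); t0 <- 1 / (n0 + 2)
  tt <- ifelse(z == 1, t1, t0)
  fit <- suppressWarnings(
    stats::glm(tt ~ scores, family = stats::quasibinomial()))
  co <- stats::coef(fit)
  c(A = -unname(co[2]), B = -unname(co[1]))
}

#' Sigmoid-calibrated probability of an SVM score
#'
#' `p = 1 / (1 + exp(A * score + B))`; strictly increasing in the score when
#' `A < 0`.
#'
#' @param score decision score(s).
#' @param A,B calibration parameters.
#' @return probability in (0, 1).
#' @export
calibrated_probability <- function(score, A, B) {
  stopifnot(all(is.finite(score)))
  1 / (1 + exp(A * score + B))
}

#' @export
print.xdt_classifier <- function(x, ...) {
  cat(sprintf("XDT material classifier: %d one-vs-rest %s SVMs (%s)\n",
              length(x$classes), x$kernel,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Per-pixel material map
#'
#' @param labels character matrix of class labels (`NA` = unclassified).
#' @param probability matrix of winning-class probabilities.
#' @param roi_mask logical matrix of classified pixels.
#' @return object of class `xdt_material_map`.
#' @export
xdt_material_map <- function(labels, probability, roi_mask) {
  structure(list(labels = labels, probability = probability,
                 roi_mask = roi_mask),
            class = "xdt_material_map")
}

#' Classify every pixel of a reconstructed volume
#'
#' Resamples each pixel spectrum onto the classifier's q grid, L2-normalizes
#' it, evaluates all class scorers and assigns the class with the highest
#' decision score; the reported probability is the winning class's
#' calibrated probability. Ties break toward the earlier class.
#'
#' @param volume an [xdt_volume()].
#' @param model an [train_svms()] classifier.
#' @param roi optional ROI (list with `center`, `diameter`); pixels outside
#'   are left unclassified (`NA`).
#' @return an [xdt_material_map()].
#' @export
classify_volume <- function(volume, model, roi = NULL) {
  n <- dim(volume$values)[1]
  msk <- if (is.null(roi)) matrix(TRUE, n, dim(volume$values)[2])
         else roi_mask(volume, roi)
  idx <- which(msk)
  spec <- matrix(volume$values, length(msk), dim(volume$values)[3])[idx, ,
                                                                    drop = FALSE]
  if (!isTRUE(all.equal(volume$q_grid, model$q_grid))) {
    spec <- t(apply(spec, 1, function(v)
      stats::approx(volume$q_grid, v, xout = model$q_grid, rule = 2)$y))
  }
  spec <- l2_normalize_rows(spec)
  scores <- sapply(model$classes, function(cl)
    score_svm(model$models[[cl]]$fit, spec))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  win <- apply(scores, 1, which.max)
  prob <- vapply(seq_along(win), function(i) {
    m <- model$models[[model$classes[win[i]]]]
    calibrated_probability(scores[i, win[i]], m$A, m$B)
  }, numeric(1))
  labs <- matrix(NA_character_, nrow(msk), ncol(msk))
  pmat <- matrix(NA_real_, nrow(msk), ncol(msk))
  labs[idx] <- model$classes[win]
  pmat[idx] <- prob
  xdt_material_map(labs, pmat, msk)
}

#' Mean and standard deviation of winning-class probability in a region
#'
#' @param map an [xdt_material_map()].
#' @param region logical matrix selecting pixels (e.g. a 3 x 3 block).
#' @return list with `mean`, `sd`, `n`.
#' @export
region_stats <- function(map, region) {
  stopifnot(all(dim(region) == dim(map$probability)))
  p <- map$probability[region & map$roi_mask]
  p <- p[!is.na(p)]
  if (!length(p)) stop("region contains no classified pixels")
  list(mean = mean(p), sd = stats::sd(p), n = length(p))
}
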