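#' Build the stimulus duration profile
#'
#' Indicator matrix (volumes x duration bins) marking, for every S1 event,
#' the volume containing its offset in the column of its nominal duration.
#' Standards and comparisons are pooled: any S1 offset counts.
#'
#' @param events an `event_table`.
#' @param scan a `scan_grid`.
#' @param bins sorted durations (s) defining the columns; must cover every
#'   S1 duration label present.
#' @return list of class `stimulus_profile`: `matrix`, `duration_bins`,
#'   `tr`.
#' @export
build_duration_profile <- function(events, scan, bins = NULL) {
  s1 <- events[events$role == "S1", , drop = FALSE]
  if (is.null(bins)) bins <- enumerate_s1_durations(events)
  bins <- sort(bins)
  m <- matrix(0, scan$n_volumes, length(bins))
  colnames(m) <- format(bins, trim = TRUE)
  if (nrow(s1) == 0) {
    warning("event table has no S1 events; profile is all zero")
  } else {
    b <- vapply(s1$duration_label, function(d) {
      j <- which(abs(bins - d) < 1e-9)
      if (length(j) != 1)
        stop("S1 duration ", d, " s absent from profile bins")
      j
    }, integer(1))
    v <- volume_index(s1$onset + s1$duration, scan$tr, one_based = TRUE)
    if (any(v > scan$n_volumes)) stop("S1 offset beyond run end")
    for (i in seq_along(v)) m[v[i], b[i]] <- m[v[i], b[i]] + 1
  }
  structure(list(matrix = m, duration_bins = bins, tr = scan$tr),
            class = "stimulus_profile")
}

# Gaussian tuning weight of each duration bin for a (mu, sigma) model;
# unit peak at d = mu.
gaussian_weights <- function(bins, mu, sigma) {
  exp(-(bins - mu)^2 / (2 * sigma^2))
}

#' Predicted timecourse of a Gaussian duration tuning model
#'
#' The neural series is the stimulus profile weighted by a unit-peak
#' Gaussian over duration, `sum_b profile[t, b] * exp(-(d_b - mu)^2 /
#' (2 sigma^2))`, convolved with the HRF and truncated to the run length.
#' Response amplitude is absorbed by the regression at fit time.
#'
#' @param mu preferred duration (s).
#' @param sigma tuning spread (s, > 0).
#' @param profile a `stimulus_profile` or list of them (per run; each run
#'   convolved separately, results concatenated).
#' @param hrf an `hrf_kernel`.
#' @return numeric series (one value per volume).
#' @export
predict_timecourse <- function(mu, sigma, profile, hrf) {
  stopifnot(sigma > 0)
  if (inherits(profile, "stimulus_profile")) profile <- list(profile)
  unlist(lapply(profile, function(p) {
    w <- gaussian_weights(p$duration_bins, mu, sigma)
    convolve_hrf(drop(p$matrix %*% w), hrf)
  }), use.names = FALSE)
}

# Grid of predictions for all (mu, sigma) combinations, as a matrix
# (volumes x grid points), plus the parameter table.
prf_prediction_grid <- function(profile, hrf, mu_grid, sigma_grid) {
  pars <- expand.grid(mu = mu_grid, sigma = sigma_grid)
  preds <- vapply(seq_len(nrow(pars)),
                  function(i) predict_timecourse(pars$mu[i], pars$sigma[i],
                                                 profile, hrf),
                  predict_timecourse(pars$mu[1], pars$sigma[1], profile, hrf))
  list(pars = pars, preds = preds)
}

# R^2 of the positive-slope linear fit of prediction (+ intercept) to a
# series; a negative best-fitting slope is assigned R^2 = 0.
r2_nonneg <- function(series, pred) {
  sy <- stats::sd(series)
  sp <- stats::sd(pred)
  if (!is.finite(sy) || sy == 0 || sp == 0) return(NA_real_)
  r <- stats::cor(series, pred)
  max(r, 0)^2
}

#' Fit the 1-D duration pRF model to one voxel
#'
#' Coarse-to-fine: an exhaustive (mu, sigma) grid search maximizing the
#' R-squared of the linear fit (prediction plus intercept) to the series,
#' followed by Nelder-Mead refinement from the grid optimum with sigma
#' clamped to the grid range and mu to the presented-duration range. The
#' refinement never degrades the grid optimum. The response amplitude is
#' constrained non-negative: parameter sets whose best-fitting slope is
#' negative score R-squared 0.
#'
#' @param series voxel timecourse (length = total profile rows).
#' @param profile a `stimulus_profile` or per-run list.
#' @param hrf an `hrf_kernel`.
#' @param mu_grid coarse grid of preferred durations (default: the profile
#'   bins).
#' @param sigma_grid coarse grid of spreads (default 0.05-1 s in 0.05-s
#'   steps, matching the observation that credible spreads stay below 1 s).
#' @param r2_threshold inclusion gate (default 0.1).
#' @param refine run the simplex refinement (default TRUE).
#' @param tol relative convergence tolerance of the refinement.
#' @param grid optional precomputed [prf_prediction_grid()] (shared across
#'   voxels by [prf_map()]).
#' @return list of class `prf_fit`: `mu`, `sigma`, `r2`, `beta`,
#'   `included` (`r2 > r2_threshold`), `degenerate` (constant series).
#' @export
fit_prf <- function(series, profile, hrf, mu_grid = NULL, sigma_grid = NULL,
                    r2_threshold = 0.1, refine = TRUE, tol = 1e-6,
                    grid = NULL) {
  if (inherits(profile, "stimulus_profile")) profile <- list(profile)
  bins <- profile[[1]]$duration_bins
  if (is.null(mu_grid)) mu_grid <- bins
  if (is.null(sigma_grid)) sigma_grid <- seq(0.05, 1, by = 0.05)
  stopifnot(length(mu_grid) > 0, length(sigma_grid) > 0)
  n <- sum(vapply(profile, function(p) nrow(p$matrix), integer(1)))
  if (length(series) != n)
    stop("series length does not match profile rows")
  if (stats::sd(series) == 0) {
    return(structure(list(mu = NA_real_, sigma = NA_real_, r2 = NA_real_,
                          beta = 0, included = FALSE, degenerate = TRUE),
                     class = "prf_fit"))
  }
  if (is.null(grid)) grid <- prf_prediction_grid(profile, hrf, mu_grid,
                                                 sigma_grid)
  r2g <- apply(grid$preds, 2, r2_nonneg, series = series)
  r2g[is.na(r2g)] <- -Inf
  best <- which.max(r2g)
  mu0 <- grid$pars$mu[best]; sg0 <- grid$pars$sigma[best]
  r2_best <- r2g[best]
  mu_lim <- range(mu_grid); sg_lim <- range(sigma_grid)
  obj <- function(par) {
    mu <- min(max(par[1], mu_lim[1]), mu_lim[2])
    sg <- min(max(par[2], sg_lim[1]), sg_lim[2])
    r2 <- r2_nonneg(series, predict_timecourse(mu, sg, profile, hrf))
    if (is.na(r2)) r2 <- 0
    -r2
  }
  mu_hat <- mu0; sg_hat <- sg0
  if (refine) {
    # restart the simplex from the best grid point of each of the top
    # distinct mu candidates: a preferred duration between two bins can
    # strand a single start on a boundary local optimum
    ord <- order(r2g, decreasing = TRUE)
    starts <- ord[!duplicated(grid$pars$mu[ord])][1:min(3, length(mu_grid))]
    for (s in starts) {
      opt <- stats::optim(c(grid$pars$mu[s], grid$pars$sigma[s]), obj,
                          method = "Nelder-Mead",
                          control = list(reltol = tol))
      if (-opt$value > r2_best) {
        mu_hat <- min(max(opt$par[1], mu_lim[1]), mu_lim[2])
        sg_hat <- min(max(opt$par[2], sg_lim[1]), sg_lim[2])
        r2_best <- -opt$value
      }
    }
  }
  pred <- predict_timecourse(mu_hat, sg_hat, profile, hrf)
  b <- if (stats::sd(pred) > 0)
    stats::cov(series, pred) / stats::var(pred) else 0
  if (b < 0) { b <- 0; r2_best <- 0 }
  structure(list(mu = mu_hat, sigma = sg_hat, r2 = r2_best, beta = b,
                 included = is.finite(r2_best) && r2_best > r2_threshold,
                 degenerate = FALSE),
            class = "prf_fit")
}

#' Fit the duration pRF model over a masked volume
#'
#' Runs [fit_prf()] per in-mask voxel (sharing one prediction grid) and
#' assembles mu, sigma and R-squared maps plus a winner-style label map in
#' which each included voxel's label is its fitted mu snapped to the
#' nearest presented duration.
#'
#' @param bold 4-D array, time x voxels matrix, or per-run list.
#' @param mask logical array / index vector of voxels to fit (default all).
#' @param events,scan per-run event tables and scan grids (or single).
#' @param mu_grid,sigma_grid,r2_threshold,refine,tol passed to [fit_prf()].
#' @param hrf optional `hrf_kernel` (default: canonical at the scan TR).
#' @return list of class `prf_map`: `labels` (a `label_map` with
#'   `source = "prf"`, stat = R-squared), `mu`, `sigma`, `r2` maps, and
#'   `fits` (per-voxel table).
#' @export
prf_map <- function(bold, mask = NULL, events, scan, mu_grid = NULL,
                    sigma_grid = NULL, hrf = NULL, r2_threshold = 0.1,
                    refine = TRUE, tol = 1e-6) {
  if (is.data.frame(events)) events <- list(events)
  if (inherits(scan, "scan_grid")) scan <- list(scan)
  Y <- as_bold_matrix(bold)
  dims <- attr(Y, "spatial_dim")
  nvox <- ncol(Y)
  if (is.null(mask)) mask_idx <- seq_len(nvox)
  else if (is.logical(mask)) mask_idx <- which(mask)
  else mask_idx <- as.integer(mask)
  if (length(mask_idx) == 0) stop("empty mask")
  if (is.null(hrf)) hrf <- canonical_hrf(scan[[1]]$tr)
  bins <- enumerate_s1_durations(events)
  profiles <- lapply(seq_along(events), function(r)
    build_duration_profile(events[[r]], scan[[r]], bins))
  if (is.null(mu_grid)) mu_grid <- bins
  if (is.null(sigma_grid)) sigma_grid <- seq(0.05, 1, by = 0.05)
  grid <- prf_prediction_grid(profiles, hrf, mu_grid, sigma_grid)
  fits <- lapply(mask_idx, function(v)
    fit_prf(Y[, v], profiles, hrf, mu_grid, sigma_grid, r2_threshold,
            refine, tol, grid = grid))
  take <- function(f, what) vapply(f, function(x) as.numeric(x[[what]]),
                                   numeric(1))
  mu <- sigma <- r2 <- lab <- stat <- rep(NA_real_, nvox)
  mu[mask_idx] <- take(fits, "mu")
  sigma[mask_idx] <- take(fits, "sigma")
  r2[mask_idx] <- take(fits, "r2")
  inc <- rep(FALSE, nvox)
  inc[mask_idx] <- vapply(fits, function(x) isTRUE(x$included), logical(1))
  snap <- function(m) bins[which.min(abs(bins - m))]
  lab[inc] <- vapply(mu[inc], snap, numeric(1))
  stat[inc] <- r2[inc]
  if (!is.null(dims)) {
    dim(mu) <- dim(sigma) <- dim(r2) <- dim(lab) <- dim(stat) <- dims
  }
  labels <- structure(list(label = lab, stat = stat, source = "prf",
                           durations = bins, spatial_dim = dims),
                      class = "label_map")
  ftab <- data.frame(voxel = mask_idx, mu = mu[mask_idx],
                     sigma = sigma[mask_idx], r2 = r2[mask_idx],
                     beta = take(fits, "beta"), included = inc[mask_idx])
  structure(list(labels = labels, mu = mu, sigma = sigma, r2 = r2,
                 fits = ftab),
            class = "prf_map")
}
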