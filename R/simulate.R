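#' Plant a ground-truth chronotopic voxel lattice
#'
#' Builds per-voxel Gaussian duration-tuning parameters on a lattice with
#' a preferred-duration gradient along one axis. `anterior_short` places
#' the shortest preferred duration at the low-coordinate (anterior) border
#' and the longest at the high-coordinate (posterior) border;
#' `anterior_long` is the reverse; `shuffled` permutes the preferred
#' durations across voxels, destroying the topography while preserving
#' their distribution.
#'
#' @param shape lattice dimensions in voxels (length 2 or 3).
#' @param duration_range `(min, max)` preferred duration in seconds.
#' @param sigma_star tuning spread in seconds (scalar or per-voxel array).
#' @param gradient `"anterior_short"`, `"anterior_long"` or `"shuffled"`.
#' @param seed integer seed (jitter and shuffling).
#' @param gradient_axis axis index along which the gradient runs
#'   (default 1).
#' @param jitter_sd s.d. of Gaussian jitter added to the linear gradient
#'   (seconds, default 0); jittered values are clipped to the range.
#' @param amplitude response gain (default 1).
#' @param baseline mean signal level (default 100).
#' @param voxel_size mm per axis (default 2).
#' @return list of class `truth_map`: arrays `mu_star`, `sigma_star`,
#'   `amplitude`, `baseline`; `shape`, `voxel_size`, `gradient_axis`,
#'   `gradient`, and border coordinates `border_low`/`border_high`
#'   (lattice indices along the gradient axis).
#' @export
make_truth_chronomap <- function(shape, duration_range = c(0.2, 1.0),
                                 sigma_star = 0.3,
                                 gradient = c("anterior_short",
                                              "anterior_long", "shuffled"),
                                 seed = 1L, gradient_axis = 1L,
                                 jitter_sd = 0, amplitude = 1,
                                 baseline = 100, voxel_size = 2) {
  gradient <- match.arg(gradient)
  stopifnot(all(shape >= 1), length(shape) %in% c(2, 3),
            duration_range[1] <= duration_range[2])
  if (length(shape) == 2) shape <- c(shape, 1L)
  shape <- as.integer(shape)
  if (duration_range[1] == duration_range[2])
    warning("degenerate duration range: all preferred durations equal")
  rng <- local_rng(seed)
  n_axis <- shape[gradient_axis]
  frac <- if (n_axis == 1) 0.5 else (seq_len(n_axis) - 1) / (n_axis - 1)
  mu_axis <- duration_range[1] + frac * diff(duration_range)
  if (gradient == "anterior_long") mu_axis <- rev(mu_axis)
  co <- arrayInd(seq_len(prod(shape)), shape)
  mu <- mu_axis[co[, gradient_axis]]
  if (jitter_sd > 0) {
    mu <- mu + rng$rnorm(length(mu), 0, jitter_sd)
    mu <- pmin(pmax(mu, duration_range[1]), duration_range[2])
  }
  if (gradient == "shuffled") mu <- mu[rng$sample(length(mu))]
  dim(mu) <- shape
  as_field <- function(x) {
    if (length(x) == 1) x <- rep(x, prod(shape))
    dim(x) <- shape
    x
  }
  structure(list(mu_star = mu, sigma_star = as_field(sigma_star),
                 amplitude = as_field(amplitude),
                 baseline = as_field(baseline),
                 shape = shape, voxel_size = rep(voxel_size, 3)[1:3],
                 gradient_axis = as.integer(gradient_axis),
                 gradient = gradient,
                 border_low = 1L, border_high = n_axis),
            class = "truth_map")
}

#' Noise specification for the BOLD simulator
#'
#' @param white_sd s.d. of white Gaussian noise (signal units).
#' @param drift_amplitude amplitude of a sinusoidal scanner drift.
#' @param drift_period drift period in seconds (>= 120 s keeps it inside
#'   the high-pass band).
#' @param seed integer seed.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(white_sd = 0, drift_amplitude = 0,
                       drift_period = 240, seed = 1L) {
  stopifnot(white_sd >= 0, drift_period > 0)
  structure(list(white_sd = white_sd, drift_amplitude = drift_amplitude,
                 drift_period = drift_period, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Simulate a 4-D BOLD volume from a truth chronomap
#'
#' Per voxel, a neural impulse of height `amplitude * exp(-(d - mu*)^2 /
#' (2 sigma*^2))` is placed at the offset of every S1 event of presented
#' duration `d` (and, scaled by `s2_gain`, at every S2 offset), convolved
#' with the canonical HRF and sampled at the TR; baseline, a sinusoidal
#' drift and white noise are added. Deterministic under the noise seed.
#'
#' @param truth a `truth_map`.
#' @param events an `event_table`.
#' @param scan a `scan_grid`.
#' @param noise a `noise_spec` (default: noise-free).
#' @param s2_gain amplitude of S2-evoked tuned responses relative to S1
#'   (default 0.5; 0 disables S2 responses).
#' @param hrf optional `hrf_kernel` (default canonical at the TR).
#' @return 4-D array `shape x n_volumes`.
#' @export
simulate_bold <- function(truth, events, scan, noise = noise_spec(),
                          s2_gain = 0.5, hrf = NULL) {
  if (max(events$onset + events$duration) > run_length(scan) + 1e-9)
    stop("scan shorter than last event")
  if (is.null(hrf)) hrf <- canonical_hrf(scan$tr)
  n <- scan$n_volumes
  nvox <- prod(truth$shape)
  resp <- matrix(0, n, nvox)
  for (spec in list(list(role = "S1", gain = 1),
                    list(role = "S2", gain = s2_gain))) {
    if (spec$gain == 0) next
    sel <- events$role == spec$role
    if (!any(sel)) next
    d <- events$duration_label[sel]
    bins <- sort(unique(d))
    sticks <- matrix(0, n, length(bins))
    v <- volume_index(events$onset[sel] + events$duration[sel], scan$tr,
                      one_based = TRUE)
    b <- match(round(d, 9), round(bins, 9))
    for (i in seq_along(v)) sticks[v[i], b[i]] <- sticks[v[i], b[i]] + 1
    conv <- convolve_hrf_cols(sticks, hrf)
    # Gaussian tuning weight of every voxel for every presented duration
    w <- outer(bins, as.vector(truth$mu_star),
               function(d0, m) exp(-(d0 - m)^2)) ^
      rep(1 / (2 * as.vector(truth$sigma_star)^2), each = length(bins))
    resp <- resp + spec$gain * (conv %*% w)
  }
  sig <- sweep(resp, 2, as.vector(truth$amplitude), `*`)
  sig <- sweep(sig, 2, as.vector(truth$baseline), `+`)
  if (noise$drift_amplitude != 0) {
    tt <- (seq_len(n) - 1) * scan$tr
    sig <- sig + noise$drift_amplitude *
      sin(2 * pi * tt / noise$drift_period)
  }
  if (noise$white_sd > 0) {
    rng <- local_rng(noise$seed)
    sig <- sig + matrix(rng$rnorm(n * nvox, 0, noise$white_sd), n, nvox)
  }
  array(t(sig), dim = c(truth$shape, n))
}

#' Snap ground-truth preferred durations to a duration set
#'
#' The label each voxel would receive under perfect recovery: its planted
#' preferred duration mapped to the nearest presented duration (ties break
#' toward the shorter duration).
#'
#' @param truth a `truth_map`.
#' @param durations presented duration set (s).
#' @return a `label_map` with `source = "truth"`.
#' @export
truth_labels <- function(truth, durations) {
  durations <- sort(durations)
  lab <- vapply(as.vector(truth$mu_star), function(m)
    durations[which.min(abs(durations - m))], numeric(1))
  dim(lab) <- truth$shape
  structure(list(label = lab, stat = array(Inf, truth$shape),
                 source = "truth", durations = durations,
                 spatial_dim = truth$shape),
            class = "label_map")
}

#' Simulate duration-discrimination behavior
#'
#' A scalar-timing comparison rule: perceived durations of S1 and S2 are
#' Gaussian around their true values with s.d. proportional to duration
#' (Weber fraction `1 / sensitivity`); a trial is correct when the
#' perceived ordering matches the true ordering. Returns accuracy per
#' standard-duration condition and the coefficient of variation of the
#' perceived standard (CV = s.d. / duration).
#'
#' @param design an `event_table` with paired S1/S2 trials (or list,
#'   pooled).
#' @param sensitivity inverse Weber fraction (>= 0; 0 = guessing,
#'   `Inf` = noiseless).
#' @param seed integer seed.
#' @param n_reps simulated repetitions of the design (default 1).
#' @return list of class `behavior_summary`: `accuracy` and `cv`, named by
#'   condition duration, plus `overall_accuracy` and `mean_cv`.
#' @export
simulate_behavior <- function(design, sensitivity, seed = 1L, n_reps = 1L) {
  if (is.data.frame(design)) design <- list(design)
  trials <- do.call(rbind, lapply(design, function(ev) {
    s1 <- ev[ev$role == "S1", ]
    s2 <- ev[ev$role == "S2", ]
    if (nrow(s1) == 0 || nrow(s1) != nrow(s2))
      stop("design has no paired S1/S2 trials")
    data.frame(d1 = s1$duration_label, d2 = s2$duration_label)
  }))
  trials <- trials[rep(seq_len(nrow(trials)), n_reps), ]
  # condition = the shorter (standard-side) duration of the pair
  cond <- pmin(trials$d1, trials$d2)
  rng <- local_rng(seed)
  w <- if (is.infinite(sensitivity)) 0 else if (sensitivity <= 0) Inf
  else 1 / sensitivity
  n <- nrow(trials)
  if (is.infinite(w)) {
    correct <- rng$sample_from(c(TRUE, FALSE), n, replace = TRUE)
    p1 <- trials$d1 * (1 + rng$rnorm(n) * 10)  # unusable percepts
  } else {
    p1 <- trials$d1 + rng$rnorm(n) * w * trials$d1
    p2 <- trials$d2 + rng$rnorm(n) * w * trials$d2
    correct <- (p1 > p2) == (trials$d1 > trials$d2)
  }
  acc <- tapply(correct, cond, mean)
  cv <- if (is.infinite(w)) {
    stats::setNames(rep(Inf, length(unique(cond))),
                    names(acc))
  } else {
    tapply(seq_len(n), cond, function(i)
      stats::sd(p1[i] / trials$d1[i]))
  }
  cv[is.na(cv)] <- if (is.infinite(w)) Inf else w
  structure(list(accuracy = acc, cv = cv,
                 overall_accuracy = mean(correct),
                 mean_cv = mean(cv)),
            class = "behavior_summary")
}
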