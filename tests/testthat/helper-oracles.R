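# Independent brute-force oracles and shared fixtures. The oracles are
# deliberately naive (loops, explicit enumeration) and never call the
# package code paths they check.

# wRD by direct looping over voxels: for each voxel of the label, count
# face-adjacent same-label voxels by scanning all other voxels, then apply
# the formula sum(w * D1/TD) / Nvd.
oracle_wrd <- function(lab, axis, d1_border_mm, d2_border_mm, voxel_size,
                       label) {
  dims <- dim(lab)
  idx <- which(!is.na(lab) & abs(lab - label) < 1e-9)
  co <- arrayInd(idx, dims)
  nvd <- length(idx)
  td <- abs(d2_border_mm - d1_border_mm)
  total <- 0
  for (i in seq_len(nvd)) {
    nn <- 0
    for (j in seq_len(nvd)) {
      if (i == j) next
      if (sum(abs(co[i, ] - co[j, ])) == 1) nn <- nn + 1
    }
    w <- nn / nvd
    d1 <- abs((co[i, axis] - 1) * voxel_size - d1_border_mm)
    total <- total + w * d1 / td
  }
  total / nvd
}

# t-statistics through explicit normal equations: beta = (X'X)^-1 X'y,
# t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c).
oracle_t_stats <- function(X, Y, contrasts) {
  XtXi <- solve(t(X) %*% X)
  out <- matrix(NA_real_, ncol(Y), length(contrasts))
  for (v in seq_len(ncol(Y))) {
    y <- Y[, v]
    beta <- XtXi %*% t(X) %*% y
    r <- y - X %*% beta
    s2 <- sum(r^2) / (nrow(X) - ncol(X))
    for (k in seq_along(contrasts)) {
      cv <- contrasts[[k]]
      out[v, k] <- sum(cv * beta) / sqrt(s2 * drop(t(cv) %*% XtXi %*% cv))
    }
  }
  out
}

# Exact one-sided signed-rank p by enumerating all 2^n sign patterns.
oracle_signrank_less <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  rk <- rank(abs(x))
  w_obs <- sum(rk[x > 0])
  count <- 0
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[1:n]
    if (sum(rk[signs == 1]) <= w_obs) count <- count + 1
  }
  count / 2^n
}

# Kendall tau-b by O(n^2) pair counting with tie corrections.
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Weighted centroid by explicit position repetition: each voxel's position
# is stacked as many times as its neighbor count, then plainly averaged.
oracle_centroid <- function(lab, label) {
  dims <- dim(lab)
  idx <- which(!is.na(lab) & abs(lab - label) < 1e-9)
  co <- arrayInd(idx, dims)
  reps <- integer(length(idx))
  for (i in seq_along(idx)) {
    for (j in seq_along(idx)) {
      if (i != j && sum(abs(co[i, ] - co[j, ])) == 1)
        reps[i] <- reps[i] + 1
    }
  }
  if (all(reps == 0)) reps <- rep(1L, length(idx))
  stacked <- co[rep(seq_along(idx), reps), , drop = FALSE]
  colMeans(stacked)
}

# Random label map on a 2-D sheet (stored as x-by-y-by-1 lattice).
random_label_map <- function(nx = 12, ny = 12, durations = c(0.2, 0.4, 0.6, 1),
                             p_unlabeled = 0.3) {
  lab <- array(NA_real_, c(nx, ny, 1))
  n <- nx * ny
  filled <- sample(c(TRUE, FALSE), n, replace = TRUE,
                   prob = c(1 - p_unlabeled, p_unlabeled))
  lab[filled] <- sample(durations, sum(filled), replace = TRUE)
  structure(list(label = lab, stat = lab, source = "glm",
                 durations = durations, spatial_dim = dim(lab)),
            class = "label_map")
}

# Label map of one synthetic subject: planted gradient plus preferred-
# duration jitter, snapped to the experiment's duration set. Stands in for
# the GLM label map of a subject at moderate noise.
subject_label_map <- function(seed, gradient = "anterior_short",
                              shape = c(12, 12, 1),
                              duration_range = c(0.2, 1.0),
                              durations = exp1_durations(),
                              jitter_sd = 0.2) {
  truth <- make_truth_chronomap(shape, duration_range, sigma_star = 0.3,
                                gradient = gradient, seed = seed,
                                jitter_sd = jitter_sd)
  list(labels = truth_labels(truth, durations),
       geom = truth_geometry(truth), truth = truth)
}

# Flatten per-run 4-D bold lists to a concatenated time x voxels matrix
# without going through the package's internal coercion.
as_bold_matrix_for_tests <- function(bold) {
  if (!is.list(bold)) bold <- list(bold)
  do.call(rbind, lapply(bold, function(b)
    t(matrix(b, prod(dim(b)[1:3]), dim(b)[4]))))
}

# Small noise-free Exp 1 simulation shared by labeling and tuning tests.
exp1_sim_fixture <- function(n_runs = 3, shape = c(10, 10, 1),
                             sigma_star = 0.15, white_sd = 0,
                             s2_gain = 0.5, seed = 11) {
  runs <- build_exp1_design(n_runs, seed = seed)
  truth <- make_truth_chronomap(shape, c(0.2, 1.0),
                                sigma_star = sigma_star, seed = seed + 1)
  bold <- lapply(seq_along(runs), function(r)
    simulate_bold(truth, runs[[r]]$events, runs[[r]]$scan,
                  noise_spec(white_sd = white_sd, seed = seed + 1 + r),
                  s2_gain = s2_gain))
  list(runs = runs, truth = truth, bold = bold,
       events = lapply(runs, `[[`, "events"),
       scans = lapply(runs, `[[`, "scan"))
}
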