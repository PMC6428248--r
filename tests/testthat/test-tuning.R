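test_that("normalization yields unit-variance traces and rejects degenerate input", {
  set.seed(41)
  runs <- lapply(1:3, function(i) matrix(100 + rnorm(60 * 4), 60, 4))
  tr <- normalize_bold(runs)
  expect_equal(sd(tr$values), 1, tolerance = 1e-10)
  expect_identical(tr$n_runs, 3L)
  expect_identical(tr$n_voxels, 4L)
  # scale invariance: multiplying all runs by a positive constant
  tr2 <- normalize_bold(lapply(runs, function(x) 3.7 * x))
  expect_equal(tr2$values, tr$values, tolerance = 1e-12)
  # constant signal: zero numerator, zero variance
  const <- lapply(1:2, function(i) matrix(5, 20, 2))
  expect_error(normalize_bold(const), "zero-variance")
})

test_that("normalization matches a hand-computed two-run one-voxel trace", {
  r1 <- matrix(c(10, 12, 14, 8), 4, 1)
  r2 <- matrix(c(11, 9, 13, 15), 4, 1)
  mb <- mean(c(r1, r2))                    # 11.5
  t1 <- (r1 - mb) / mb
  t2 <- (r2 - mb) / mb
  avg <- (t1 + t2) / 2
  expected <- as.vector(avg / sd(avg))
  got <- normalize_bold(list(r1, r2))
  expect_equal(got$values, expected, tolerance = 1e-12)
})

test_that("responses are sampled a fixed lag after each S1 offset", {
  scan <- scan_grid(tr = 2, n_volumes = 12)
  ev <- event_table(onset = c(9.5, 16), duration = c(0.5, 1),
                    duration_label = c(0.5, 1), role = c("S1", "S1"),
                    trial_index = 0:1)
  trace <- seq(0.1, 1.2, by = 0.1)
  # offset 10.0 s -> 0-based volume 5, +2 -> volume 7 -> trace[8]
  r <- extract_response(trace, ev, scan, lag_volumes = 2)
  expect_equal(unname(r["0.5"]), trace[8])
  expect_equal(unname(r["1"]), trace[floor(17 / 2) + 1 + 2])
  # a lagged sample beyond the run is dropped with a warning
  ev2 <- event_table(onset = c(9.5, 21), duration = c(0.5, 1),
                     duration_label = c(0.5, 1), role = c("S1", "S1"),
                     trial_index = 0:1)
  expect_warning(r2 <- extract_response(trace, ev2, scan, 2), "dropped")
  expect_true(is.na(r2["1"]))
  expect_equal(unname(r2["0.5"]), trace[8])
})

test_that("the 17 durations group onto the 10 trial types", {
  g <- exp2_grouping()
  expect_setequal(unique(g$duration), exp2_durations())
  # 0.6 s occurs in pairs 2 (as comparison) and 3 (as standard)
  expect_identical(sort(g$pair_id[abs(g$duration - 0.6) < 1e-9]), c(2L, 3L))
  expect_equal(g$weight[abs(g$duration - 0.6) < 1e-9], c(0.5, 0.5))
  shared <- c(0.6, 1.2, 1.8)
  for (d in exp2_durations()) {
    w <- g$weight[abs(g$duration - d) < 1e-9]
    expect_equal(sum(w), 1)
    expect_length(w, if (d %in% shared) 2L else 1L)
  }
})

test_that("tuning profiles normalize to the preferred duration", {
  conds <- exp1_durations()
  resp <- rbind(c(2.0, 1.2, 0.6, 0.2),
                c(0.5, 1.0, 0.7, 0.3),
                c(0.2, 0.5, 0.9, 1.8))
  colnames(resp) <- conds
  tp <- tuning_profile(resp, pd = c(0.2, 0.4, 1.0))
  expect_equal(tp$matrix[cbind(1:3, tp$pd_index)], rep(1, 3))
  expect_equal(tp$matrix[1, ], c(1, 0.6, 0.3, 0.1), ignore_attr = TRUE)
  expect_true(all(apply(tp$matrix, 1, which.max) == tp$pd_index))
  # zero PD response cannot be normalized
  bad <- resp; bad[1, 1] <- 0
  expect_error(tuning_profile(bad, pd = c(0.2, 0.4, 1.0)), "zero")
  # grouping collapses 17 columns to the 10 pairs
  resp17 <- matrix(runif(2 * 17, 0.5, 1), 2, 17,
                   dimnames = list(NULL, exp2_durations()))
  tp17 <- tuning_profile(resp17, pd = c(0.3, 2.4),
                         grouping = exp2_grouping(), normalize = "none")
  expect_identical(ncol(tp17$matrix), 10L)
  expect_identical(tp17$pd_index, c(1L, 8L))   # 0.3 -> pair 1, 2.4 -> pair 8
})

test_that("peaked profiles separate preferred from distant durations", {
  set.seed(61)
  conds <- exp1_durations()
  peaked <- t(vapply(rep(conds, length.out = 10), function(pd) {
    exp(-(conds - pd)^2 / (2 * 0.3^2)) + rnorm(4, sd = 0.02)
  }, numeric(4)))
  colnames(peaked) <- conds
  tp <- tuning_profile(peaked, pd = rep(conds, length.out = 10),
                       normalize = "none")
  res <- compare_pd_groups(tp)
  expect_true(all(res$p < 0.05))
  res_u <- compare_pd_groups(tp, scheme = "union")
  expect_lt(res_u$p, 0.05)
  # flat profiles carry no preference signal
  flat <- matrix(1 + rnorm(40, sd = 0.05), 10, 4,
                 dimnames = list(NULL, conds))
  tpf <- tuning_profile(flat, pd = rep(conds, length.out = 10),
                        normalize = "none")
  resf <- compare_pd_groups(tpf)
  expect_true(all(resf$p > 0.05))
  # a single observation has no test
  expect_error(compare_pd_groups(
    tuning_profile(peaked[1, , drop = FALSE], pd = 0.2,
                   normalize = "none")), "one observation")
})

test_that("cycle waveforms fold runs and align descending cycles", {
  x <- rep(1:22, 10) + rep(seq(0, 0.9, 0.1), each = 22)
  asc <- scan_grid(2, 220, direction = "ascending")
  wf <- cycle_timecourse(x, asc)
  expect_length(wf, 22L)
  expect_equal(wf, 1:22 + 0.45)
  des <- scan_grid(2, 220, direction = "descending")
  wfd <- cycle_timecourse(x, des)
  expect_equal(wfd, rev(wf))               # index j maps to 21 - j
  expect_error(cycle_timecourse(x[1:200], asc), "divisible")
})

test_that("short-preferring clusters peak earlier in the cycle", {
  asc <- build_exp2_design("ascending", 10, seed = 15)
  tm <- make_truth_chronomap(c(2, 1, 1), c(0.2, 3), sigma_star = 0.3,
                             seed = 1)
  b <- simulate_bold(tm, asc$events, asc$scan, noise_spec(), s2_gain = 0)
  short_wf <- cycle_timecourse(b[1, 1, 1, ] - 100, asc$scan)
  long_wf <- cycle_timecourse(b[2, 1, 1, ] - 100, asc$scan)
  expect_lt(which.max(short_wf), which.max(long_wf))
})

test_that("noise-free cluster responses are duration tuned end to end", {
  fx <- exp1_sim_fixture(n_runs = 3, shape = c(8, 8, 1), sigma_star = 0.3,
                         s2_gain = 0)
  labels <- truth_labels(fx$truth, exp1_durations())
  conds <- exp1_durations()
  resp <- t(vapply(conds, function(d) {
    vox <- which(abs(labels$label - d) < 1e-9)
    cr <- chronomapr:::cluster_runs(fx$bold, vox)
    mb <- colMeans(do.call(rbind, cr))
    rowMeans(vapply(seq_along(cr), function(r) {
      trace <- rowMeans(sweep(sweep(cr[[r]], 2, mb), 2, mb, `/`))
      extract_response(trace, fx$events[[r]], fx$scans[[r]], 2)
    }, numeric(4)))
  }, numeric(4)))
  colnames(resp) <- conds
  tp <- tuning_profile(resp, pd = conds)
  # exactly 1 at the preferred duration after normalization
  expect_equal(tp$matrix[cbind(1:4, tp$pd_index)], rep(1, 4))
  # strictly decreasing away from the preferred duration on the rank rings
  for (cl in 1:4) {
    i <- tp$pd_index[cl]
    ring1 <- mean(tp$matrix[cl, intersect(c(i - 1, i + 1), 1:4)])
    ring2 <- mean(tp$matrix[cl, intersect(c(i - 2, i + 2), 1:4)])
    expect_gt(tp$matrix[cl, i], ring1)
    expect_gt(ring1, ring2)
  }
})
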