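make_label_array <- function(nx, ny, fill = NA_real_) {
  array(fill, c(nx, ny, 1))
}
as_label_map <- function(lab, durations = sort(unique(lab[!is.na(lab)]))) {
  structure(list(label = lab, stat = lab, source = "glm",
                 durations = durations, spatial_dim = dim(lab)),
            class = "label_map")
}

test_that("clustering weights count face-adjacent same-label voxels", {
  lab <- make_label_array(5, 5)
  lab[1, 1, 1] <- 0.2                       # isolated voxel
  lab[3, 3, 1] <- 0.4; lab[3, 4, 1] <- 0.4  # adjacent pair
  lm <- as_label_map(lab)
  expect_equal(unname(vertex_weights(lm, 0.2)), 0)
  expect_equal(unname(vertex_weights(lm, 0.4)), c(0.5, 0.5))
  # solid 3x3 sheet: center voxel has 4 of the 9 as neighbors
  lab2 <- make_label_array(3, 3, fill = 0.6)
  w <- vertex_weights(as_label_map(lab2), 0.6)
  expect_equal(unname(w[names(w) == "5"]), 4 / 9)
  expect_error(vertex_weights(lm, 1.0), "absent")
})

test_that("wRD follows the weighted relative distance formula", {
  geom <- border_geometry(axis = 1, d1_border = 0, d2_border = 8,
                          voxel_size = 2)
  # all voxels of the label on the reference border
  lab <- make_label_array(5, 4)
  lab[1, 1:3, 1] <- 0.2
  expect_equal(weighted_relative_distance(as_label_map(lab), geom, 0.2)$wrd,
               0)
  # adjacent pair at half depth: wRD = (1/2*1/2 + 1/2*1/2)/2 = 1/4
  lab2 <- make_label_array(5, 4)
  lab2[3, 2:3, 1] <- 0.4
  expect_equal(weighted_relative_distance(as_label_map(lab2), geom,
                                          0.4)$wrd, 0.25)
  # voxels outside the borders are reported
  geom_narrow <- border_geometry(1, 0, 2, voxel_size = 2)
  expect_error(weighted_relative_distance(as_label_map(lab2), geom_narrow,
                                          0.4), "outside")
})

test_that("package wRD agrees with the brute-force oracle on random maps", {
  set.seed(77)
  geom <- border_geometry(axis = 1, d1_border = 0, d2_border = 22,
                          voxel_size = 2)
  for (i in 1:10) {
    lm <- random_label_map(12, 12)
    for (d in unique(lm$label[!is.na(lm$label)])) {
      got <- weighted_relative_distance(lm, geom, d)$wrd
      ref <- oracle_wrd(lm$label, 1, 0, 22, 2, d)
      expect_lt(abs(got - ref), 1e-12)
    }
  }
})

test_that("wRD slopes are least squares on duration rank", {
  tab <- data.frame(duration = c(0.2, 0.4, 0.6, 1.0),
                    wrd = c(0.9, 0.6, 0.3, 0.0))
  s <- fit_wrd_slope(tab)
  expect_equal(s$slope, -0.3)
  expect_equal(fit_wrd_slope(data.frame(duration = 1:4 / 4,
                                        wrd = rep(0.5, 4)))$slope, 0)
  inc <- data.frame(duration = c(0.2, 0.4, 0.6), wrd = c(0.1, 0.4, 0.9))
  expect_gt(fit_wrd_slope(inc)$slope, 0)
  # split slopes and the undefined-segment flag
  tab2 <- data.frame(duration = c(0.2, 0.6, 1.0, 1.4, 2.0),
                     wrd = c(0.8, 0.5, 0.2, 0.3, 0.4))
  s2 <- fit_wrd_slope(tab2, split_at = 1.0)
  expect_equal(s2$sub$slope, -0.3)
  expect_equal(s2$supra$slope, 0.1)
  s3 <- fit_wrd_slope(tab2[1:3, ], split_at = 1.0)
  expect_true(s3$supra$flagged)
})

test_that("the slope test matches exact signed-rank enumeration", {
  all_neg <- -c(1:10) / 20
  res <- test_slopes(all_neg)
  expect_equal(res$p, 2^-10)
  # symmetric slopes sit near the null center
  sym <- c(-4, 4, -3, 3, -2, 2, -1, 1) / 10
  expect_gt(test_slopes(sym)$p, 0.3)
  expect_lt(test_slopes(sym)$p, 0.8)
  # random instances against full 2^n enumeration
  set.seed(5)
  for (i in 1:5) {
    x <- round(rnorm(8), 3)
    expect_equal(test_slopes(x)$p, oracle_signrank_less(x))
  }
  # zeros dropped and counted; too-few slopes rejected
  withz <- c(-1, -2, -3, -4, -5, 0)
  expect_identical(test_slopes(withz)$n_zero, 1L)
  expect_identical(test_slopes(withz)$n_used, 5L)
  expect_error(test_slopes(c(-1, -2, -3, 0, 0)), "at least 5")
})

test_that("preferred-duration profiles bin, vote and reduce as specified", {
  # single subject, 1-voxel-thick column map: unanimous and majority bins
  lab <- make_label_array(6, 3)
  lab[1, 1:3, 1] <- 0.6                      # unanimous 0.6
  lab[2, 1:3, 1] <- c(0.2, 0.2, 1.0)         # majority 0.2
  lab[3, 1:2, 1] <- c(0.2, 1.0)              # tie -> shorter
  lm <- as_label_map(lab)
  geom <- border_geometry(1, 0, 10, voxel_size = 2)
  pdp <- preferred_duration_profile(list(lm), list(geom), bin_width = 2,
                                    reduce_every = 1)
  expect_equal(pdp$pooled$pd[1:3], c(0.6, 0.2, 0.2))
  # pooled sequence of length 10 reduces to 2 points
  lab10 <- make_label_array(10, 1)
  lab10[, 1, 1] <- seq(0.2, 1, length.out = 10)
  pd10 <- preferred_duration_profile(list(as_label_map(lab10)),
                                     list(border_geometry(1, 0, 18,
                                                          voxel_size = 2)),
                                     bin_width = 2, reduce_every = 5)
  expect_identical(nrow(pd10$pooled), 10L)
  expect_identical(nrow(pd10$profile), 2L)
  # a perfect gradient yields a non-decreasing profile
  expect_true(all(diff(pd10$profile$pd) >= 0))
  expect_true(all(pd10$profile$rd >= 0 & pd10$profile$rd <= 1))
})

test_that("weighted centroids repeat positions by neighbor count", {
  lab <- make_label_array(8, 8)
  lab[4, 4, 1] <- 0.2                        # single voxel -> fallback
  cen <- weighted_centroids(as_label_map(lab), voxel_size = 1)
  expect_equal(c(cen$x, cen$y, cen$z), c(4, 4, 1))
  expect_true(cen$fallback)
  # column of 4 (weights 1,2,2,1) vs pair (weights 1,1): x = (0*2+4*6)/8
  lab2 <- make_label_array(8, 8)
  lab2[1, 1:2, 1] <- 0.4
  lab2[5, 1:4, 1] <- 0.4
  cen2 <- weighted_centroids(as_label_map(lab2), voxel_size = 1)
  expect_equal(cen2$x_mm, 3)
  expect_false(cen2$fallback)
  # uniform weights equal the arithmetic mean (2x2 block, all weight 2)
  lab3 <- make_label_array(6, 6)
  lab3[2:3, 4:5, 1] <- 1.0
  cen3 <- weighted_centroids(as_label_map(lab3), voxel_size = 2)
  expect_equal(c(cen3$x, cen3$y), c(2.5, 4.5))
  # random maps against the position-repetition oracle
  set.seed(31)
  for (i in 1:5) {
    lm <- random_label_map(8, 8)
    for (d in unique(lm$label[!is.na(lm$label)])) {
      got <- weighted_centroids(lm, d, voxel_size = 1)
      ref <- oracle_centroid(lm$label, d)
      expect_equal(c(got$x, got$y, got$z), unname(ref), tolerance = 1e-12)
    }
  }
})

test_that("map comparison reports overlap, shifts, extents and proportions", {
  lab <- make_label_array(10, 4)
  lab[2, 1:2, 1] <- 0.2
  lab[5, 1:2, 1] <- 0.6
  lab[8, 1:2, 1] <- 1.0
  lm <- as_label_map(lab)
  geom <- border_geometry(1, d1_border = 18, d2_border = 0, voxel_size = 2)
  same <- compare_maps(lm, lm, geom, geom)
  expect_true(all(same$labels$overlap == 1))
  expect_true(all(same$labels$centroid_shift == 0))
  expect_equal(same$extent_a, 12)             # voxels 2..8 -> (8-2)*2 mm
  expect_equal(same$proportions$a$proportion, rep(1 / 3, 3))
  # translation by +2 voxels shifts centroids by 2 * voxel_size
  lab_t <- make_label_array(10, 4)
  lab_t[4, 1:2, 1] <- 0.2
  lab_t[7, 1:2, 1] <- 0.6
  lab_t[10, 1:2, 1] <- 1.0
  shifted <- compare_maps(lm, as_label_map(lab_t), geom, geom)
  expect_equal(shifted$labels$centroid_shift, rep(-4, 3))
  expect_true(all(shifted$labels$overlap == 0))
  # disjoint label sets flag the overlap as undefined
  lab_b <- make_label_array(10, 4)
  lab_b[3, 1:2, 1] <- 0.4
  disjoint <- compare_maps(lm, as_label_map(lab_b), geom, geom)
  expect_false(disjoint$overlap_defined)
})

test_that("slope-behavior correlations match pair-counting Kendall tau", {
  slopes <- c(-0.5, -0.4, -0.3, -0.2, -0.1, 0.1)
  acc <- c(0.95, 0.92, 0.9, 0.85, 0.8, 0.7)       # steeper -> better
  res <- correlate_slope_behavior(slopes, accuracy = acc)
  expect_equal(res$tau[res$index == "accuracy"], -1)
  res2 <- correlate_slope_behavior(slopes, cv = rev(acc))
  expect_equal(res2$tau[res2$index == "cv"], 1)
  # random instance against the O(n^2) oracle
  set.seed(13)
  x <- rnorm(6); y <- rnorm(6)
  res3 <- correlate_slope_behavior(x, accuracy = y)
  expect_equal(res3$tau, oracle_kendall(x, y))
  # constant behavior flagged
  resc <- correlate_slope_behavior(slopes, accuracy = rep(0.9, 6))
  expect_true(resc$flagged)
})

test_that("planted gradients produce detectable negative wRD slopes", {
  # one cohort of 10 jittered subjects: all slopes negative, p < 0.05
  slopes <- vapply(1:10, function(s) {
    sub <- subject_label_map(seed = 100 + s)
    fit_wrd_slope(wrd_by_label(sub$labels, sub$geom))$slope
  }, numeric(1))
  expect_true(median(slopes) < 0)
  expect_lt(test_slopes(slopes)$p, 0.05)
  # noise-free gradient: wRD strictly decreasing in duration
  sub0 <- subject_label_map(seed = 1, jitter_sd = 0)
  wrd0 <- wrd_by_label(sub0$labels, sub0$geom)
  expect_true(all(diff(wrd0$wrd) < 0))
})
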