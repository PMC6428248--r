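#' Border geometry of a chronotopic map
#'
#' Defines the axis of spatial progression and the two map borders between
#' which relative distances are measured. Positions are voxel centers at
#' `(index - 1) * voxel_size` mm, so the first lattice plane sits at 0 mm.
#'
#' @param axis lattice axis (1-3) of the progression.
#' @param d1_border mm coordinate of the reference (posterior/lateral)
#'   border.
#' @param d2_border mm coordinate of the opposite border.
#' @param voxel_size mm per voxel along the axis.
#' @return list of class `border_geometry` with total depth `td`.
#' @export
border_geometry <- function(axis, d1_border, d2_border, voxel_size = 2) {
  if (d1_border == d2_border) stop("borders must differ")
  structure(list(axis = as.integer(axis), d1_border = d1_border,
                 d2_border = d2_border, voxel_size = voxel_size,
                 td = abs(d2_border - d1_border)),
            class = "border_geometry")
}

#' Border geometry implied by a truth chronomap
#'
#' The reference border is the end of the gradient axis carrying the
#' longest preferred duration (the "posterior" border of an
#' anterior-short map), so that a recovered map yields a wRD that
#' decreases with duration.
#'
#' @param truth a `truth_map`.
#' @return a `border_geometry`.
#' @export
truth_geometry <- function(truth) {
  vs <- truth$voxel_size[truth$gradient_axis]
  lo <- (truth$border_low - 1) * vs
  hi <- (truth$border_high - 1) * vs
  if (identical(truth$gradient, "anterior_long"))
    border_geometry(truth$gradient_axis, lo, hi, vs)
  else
    border_geometry(truth$gradient_axis, hi, lo, vs)
}

# Indices, coordinates and same-label neighbor counts for one label.
label_voxels <- function(labelmap, label, tol = 1e-9) {
  lab <- labelmap$label
  if (is.null(dim(lab))) stop("label map has no spatial dims")
  dims <- dim(lab)
  idx <- which(!is.na(lab) & abs(lab - label) < tol)
  if (length(idx) == 0) stop("label ", label, " absent from map")
  co <- arrayInd(idx, dims)
  nnbrs <- vapply(seq_along(idx), function(i) {
    nb <- face_neighbors(co[i, ], dims)
    sum(!is.na(lab[nb]) & abs(lab[nb] - label) < tol)
  }, numeric(1))
  list(idx = idx, coords = co, nnbrs = nnbrs, nvd = length(idx))
}

#' Per-voxel clustering weights of a duration label
#'
#' `w_i = Nnbrs_i / Nvd`: the number of face-adjacent voxels sharing the
#' voxel's label (self excluded by default), divided by the total count of
#' voxels carrying that label. Isolated voxels get weight 0.
#'
#' @param labelmap a `label_map` with spatial dims.
#' @param label duration (s) present in the map.
#' @param include_self count the voxel itself among its neighbors
#'   (default FALSE).
#' @return numeric weights, one per voxel of the label (with the voxel
#'   linear indices as names).
#' @export
vertex_weights <- function(labelmap, label, include_self = FALSE) {
  lv <- label_voxels(labelmap, label)
  n <- lv$nnbrs + if (include_self) 1 else 0
  stats::setNames(n / lv$nvd, lv$idx)
}

#' Weighted relative distance of a duration label
#'
#' `wRD = sum_i w_i * RD_i / Nvd`, with `RD_i = D1_i / TD`, `D1_i` the
#' distance (mm) of voxel i from the reference border along the map axis
#' and `TD` the border-to-border depth. Lies in [0, 1]; 0 means the label
#' hugs the reference border.
#'
#' @param labelmap a `label_map`.
#' @param geom a `border_geometry`.
#' @param label duration (s).
#' @param include_self passed to [vertex_weights()].
#' @return list of class `wrd`: `wrd`, `nvd`, `mean_weight`, `label`.
#' @export
weighted_relative_distance <- function(labelmap, geom, label,
                                       include_self = FALSE) {
  lv <- label_voxels(labelmap, label)
  pos <- (lv$coords[, geom$axis] - 1) * geom$voxel_size
  lo <- min(geom$d1_border, geom$d2_border)
  hi <- max(geom$d1_border, geom$d2_border)
  out <- pos < lo - 1e-9 | pos > hi + 1e-9
  if (any(out))
    stop("labeled voxel(s) outside the map borders at ",
         paste(utils::head(pos[out]), collapse = ", "), " mm")
  w <- (lv$nnbrs + if (include_self) 1 else 0) / lv$nvd
  rd <- abs(pos - geom$d1_border) / geom$td
  structure(list(wrd = sum(w * rd) / lv$nvd, nvd = lv$nvd,
                 mean_weight = mean(w), label = label),
            class = "wrd")
}

#' wRD of every label of a map
#'
#' @param labelmap a `label_map`.
#' @param geom a `border_geometry`.
#' @param durations labels to evaluate (default: those present).
#' @param include_self passed down.
#' @return data frame with columns `duration`, `wrd`, `nvd`,
#'   `mean_weight` (labels absent from the map are skipped).
#' @export
wrd_by_label <- function(labelmap, geom, durations = NULL,
                         include_self = FALSE) {
  if (is.null(durations))
    durations <- sort(unique(labelmap$label[!is.na(labelmap$label)]))
  rows <- lapply(durations, function(d) {
    if (!any(abs(labelmap$label - d) < 1e-9, na.rm = TRUE)) return(NULL)
    r <- weighted_relative_distance(labelmap, geom, d, include_self)
    data.frame(duration = d, wrd = r$wrd, nvd = r$nvd,
               mean_weight = r$mean_weight)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Slope of wRD against duration rank
#'
#' Least-squares slope of wRD on the rank (1..k) of the duration; with
#' `split_at`, separate slopes for durations at or below versus above the
#' split (sub- and suprasecond segments when `split_at = 1`). A slope per
#' second of duration is reported alongside.
#'
#' @param wrd_tab data frame with columns `duration` and `wrd` (e.g. from
#'   [wrd_by_label()]).
#' @param split_at seconds, or `NULL` for one overall slope.
#' @return list of class `wrd_slopes`: `slope`, `slope_per_s`, and when
#'   split, `sub`/`supra` entries (NA with `flagged = TRUE` for segments
#'   with fewer than two labels).
#' @export
fit_wrd_slope <- function(wrd_tab, split_at = NULL) {
  wrd_tab <- wrd_tab[order(wrd_tab$duration), , drop = FALSE]
  one <- function(tab, rank_offset = 0) {
    if (nrow(tab) < 2)
      return(list(slope = NA_real_, slope_per_s = NA_real_,
                  flagged = TRUE))
    rk <- seq_len(nrow(tab)) + rank_offset
    list(slope = unname(stats::coef(stats::lm(tab$wrd ~ rk))[2]),
         slope_per_s = unname(stats::coef(
           stats::lm(tab$wrd ~ tab$duration))[2]),
         flagged = FALSE)
  }
  res <- one(wrd_tab)
  res$n <- nrow(wrd_tab)
  if (!is.null(split_at)) {
    sub <- wrd_tab[wrd_tab$duration <= split_at + 1e-9, , drop = FALSE]
    supra <- wrd_tab[wrd_tab$duration > split_at + 1e-9, , drop = FALSE]
    res$sub <- one(sub)
    res$supra <- one(supra, rank_offset = nrow(sub))
    res$split_at <- split_at
  }
  structure(res, class = "wrd_slopes")
}

#' Test wRD slopes against zero across subjects
#'
#' Exact one-sample Wilcoxon signed-rank test of the per-subject slopes
#' against zero (alternative: negative slope). Zero slopes are dropped, as
#' is conventional for the signed-rank statistic, and their count
#' reported.
#'
#' @param slopes numeric, one slope per subject (n >= 5 after dropping
#'   zeros).
#' @param alternative `"less"` (default), `"greater"` or `"two.sided"`.
#' @return list: `p`, `statistic`, `n_used`, `n_zero`, `exact`.
#' @export
test_slopes <- function(slopes, alternative = "less") {
  nz <- slopes[slopes != 0]
  n_zero <- length(slopes) - length(nz)
  if (length(nz) < 5)
    stop("need at least 5 nonzero slopes, got ", length(nz))
  exact <- length(nz) <= 15 && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(
    stats::wilcox.test(nz, mu = 0, alternative = alternative,
                       exact = exact, correct = !exact))
  list(p = wt$p.value, statistic = unname(wt$statistic),
       n_used = length(nz), n_zero = n_zero, exact = exact)
}

#' Pooled preferred-duration profile along the map axis
#'
#' Per subject, labeled voxels are binned into parallel planes of
#' `bin_width` mm along the map axis; each bin's preferred duration is the
#' majority label (ties toward the shorter duration) and its position the
#' bin-center distance from the reference border divided by the total
#' depth. All subjects' (relative distance, preferred duration) pairs are
#' pooled, sorted by relative distance, and reduced by averaging every
#' `reduce_every` consecutive values.
#'
#' @param labelmaps list of `label_map`s (one per subject).
#' @param geoms list of `border_geometry`s matching `labelmaps`.
#' @param bin_width plane width in mm (default 1.5).
#' @param reduce_every values averaged per reduced point (default 5).
#' @return list of class `pd_profile`: `profile` (data frame `rd`, `pd`),
#'   `pooled` (unreduced pairs), `n_subjects`.
#' @export
preferred_duration_profile <- function(labelmaps, geoms, bin_width = 1.5,
                                       reduce_every = 5L) {
  stopifnot(length(labelmaps) >= 1, length(labelmaps) == length(geoms))
  pooled <- list()
  for (s in seq_along(labelmaps)) {
    lm <- labelmaps[[s]]; geom <- geoms[[s]]
    lab <- lm$label
    idx <- which(!is.na(lab))
    if (length(idx) == 0) next
    co <- arrayInd(idx, dim(lab))
    d1 <- abs((co[, geom$axis] - 1) * geom$voxel_size - geom$d1_border)
    bin <- floor(d1 / bin_width + 1e-9)
    for (b in sort(unique(bin))) {
      labs <- lab[idx[bin == b]]
      tab <- table(labs)
      best <- as.numeric(names(tab)[tab == max(tab)])
      pd <- min(best)                       # tie -> shorter duration
      rd <- min(1, ((b + 0.5) * bin_width) / geom$td)
      pooled[[length(pooled) + 1L]] <- data.frame(rd = rd, pd = pd,
                                                  subject = s)
    }
  }
  if (length(pooled) == 0) stop("all bins empty across subjects")
  pooled <- do.call(rbind, pooled)
  pooled <- pooled[order(pooled$rd), , drop = FALSE]
  grp <- ceiling(seq_len(nrow(pooled)) / reduce_every)
  prof <- data.frame(rd = tapply(pooled$rd, grp, mean),
                     pd = tapply(pooled$pd, grp, mean))
  rownames(prof) <- NULL
  structure(list(profile = prof, pooled = pooled,
                 n_subjects = length(labelmaps)),
            class = "pd_profile")
}

#' Weighted centroids of duration-selective clusters
#'
#' Centroid of each label's voxels with every voxel counted as many times
#' as its same-label face-neighbor count; if every voxel of a label is
#' isolated (all weights zero), the unweighted mean is used and flagged.
#'
#' @param labelmap a `label_map`.
#' @param durations labels to evaluate (default: those present).
#' @param voxel_size mm per axis (scalar or length 3) for the mm
#'   coordinates; positions are `(index - 1) * voxel_size`.
#' @return data frame: `duration`, voxel-coordinate centroid (`x`, `y`,
#'   `z`), mm centroid (`x_mm`, `y_mm`, `z_mm`), `nvd`, `fallback`.
#' @export
weighted_centroids <- function(labelmap, durations = NULL, voxel_size = 2) {
  if (is.null(durations))
    durations <- sort(unique(labelmap$label[!is.na(labelmap$label)]))
  vs <- rep(voxel_size, 3)[1:3]
  rows <- lapply(durations, function(d) {
    lv <- label_voxels(labelmap, d)
    w <- lv$nnbrs
    fallback <- all(w == 0)
    if (fallback) w <- rep(1, length(w))
    cen <- colSums(lv$coords * w) / sum(w)
    cen <- c(cen, rep(NA, 3 - length(cen)))[1:3]
    data.frame(duration = d, x = cen[1], y = cen[2], z = cen[3],
               x_mm = (cen[1] - 1) * vs[1], y_mm = (cen[2] - 1) * vs[2],
               z_mm = (cen[3] - 1) * vs[3], nvd = lv$nvd,
               fallback = fallback)
  })
  do.call(rbind, rows)
}

#' Compare two chronotopic label maps
#'
#' For each label shared by the two maps: weighted-centroid distance from
#' each map's reference border along its axis, and label overlap (voxels
#' identically labeled in both maps over voxels carrying the label in
#' either). Also reports each map's extent along its axis (distance
#' between its extreme labeled voxels) and per-label cluster-size
#' proportions.
#'
#' @param map_a,map_b `label_map`s.
#' @param geom_a,geom_b their `border_geometry`s.
#' @return list of class `map_comparison`: `labels` (per-shared-label data
#'   frame with centroid-to-border distances `dist_a`/`dist_b` in mm,
#'   `centroid_shift`, `overlap`), `extent_a`, `extent_b` (mm),
#'   `proportions` (per-label cluster-size proportions per map),
#'   `overlap_defined`.
#' @export
compare_maps <- function(map_a, map_b, geom_a, geom_b) {
  labs_a <- sort(unique(map_a$label[!is.na(map_a$label)]))
  labs_b <- sort(unique(map_b$label[!is.na(map_b$label)]))
  shared <- intersect(round(labs_a, 9), round(labs_b, 9))
  extent <- function(m, g) {
    idx <- which(!is.na(m$label))
    co <- arrayInd(idx, dim(m$label))
    pos <- (co[, g$axis] - 1) * g$voxel_size
    diff(range(pos))
  }
  props <- function(m, labs) {
    n <- vapply(labs, function(d)
      sum(abs(m$label - d) < 1e-9, na.rm = TRUE), numeric(1))
    data.frame(duration = labs, proportion = n / sum(n))
  }
  cen_dist <- function(m, g, d) {
    cen <- weighted_centroids(m, d, g$voxel_size)
    abs(cen[[c("x_mm", "y_mm", "z_mm")[g$axis]]] - g$d1_border)
  }
  rows <- lapply(shared, function(d) {
    ina <- !is.na(map_a$label) & abs(map_a$label - d) < 1e-9
    inb <- !is.na(map_b$label) & abs(map_b$label - d) < 1e-9
    da <- cen_dist(map_a, geom_a, d)
    db <- cen_dist(map_b, geom_b, d)
    data.frame(duration = d, dist_a = da, dist_b = db,
               centroid_shift = db - da,
               overlap = sum(ina & inb) / sum(ina | inb))
  })
  structure(list(
    labels = if (length(rows)) do.call(rbind, rows) else NULL,
    extent_a = extent(map_a, geom_a), extent_b = extent(map_b, geom_b),
    proportions = list(a = props(map_a, labs_a), b = props(map_b, labs_b)),
    overlap_defined = length(shared) > 0),
    class = "map_comparison")
}

#' Correlate wRD slopes with behavioral indices
#'
#' Kendall tau-b between per-subject map slopes and per-subject accuracy,
#' and between slopes and the coefficient of variation.
#'
#' @param slopes numeric, one per subject (n >= 5).
#' @param accuracy,cv numeric vectors matching `slopes` (either may be
#'   omitted).
#' @return data frame with one row per index: `index`, `tau`, `p`,
#'   `flagged` (constant input).
#' @export
correlate_slope_behavior <- function(slopes, accuracy = NULL, cv = NULL) {
  stopifnot(length(slopes) >= 5)
  one <- function(y, name) {
    if (is.null(y)) return(NULL)
    stopifnot(length(y) == length(slopes))
    if (stats::sd(y) == 0 || stats::sd(slopes) == 0)
      return(data.frame(index = name, tau = NA_real_, p = NA_real_,
                        flagged = TRUE))
    ct <- suppressWarnings(stats::cor.test(slopes, y, method = "kendall"))
    data.frame(index = name, tau = unname(ct$estimate),
               p = ct$p.value, flagged = FALSE)
  }
  do.call(rbind, c(list(one(accuracy, "accuracy")), list(one(cv, "cv"))))
}
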