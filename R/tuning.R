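#' Normalize the BOLD signal of a voxel cluster
#'
#' Per voxel and run, percent signal change `(x(t) - MB) / MB` is computed
#' against the voxel's baseline MB (its mean signal across all runs by
#' default, or the per-timepoint mean across runs); the changes are
#' averaged over the voxels of the cluster, then over runs, and the
#' resulting trace is divided by its own standard deviation, so the output
#' has unit standard deviation by construction.
#'
#' @param runs list of matrices (volumes x voxels), one per run, equal
#'   sizes; a single matrix is treated as one run.
#' @param baseline `"grand"` (default) or `"timepoint"`.
#' @return list of class `normalized_trace`: `values` (per volume),
#'   `n_runs`, `n_voxels`, `baseline_def`.
#' @export
normalize_bold <- function(runs, baseline = c("grand", "timepoint")) {
  baseline <- match.arg(baseline)
  if (!is.list(runs)) runs <- list(runs)
  runs <- lapply(runs, as.matrix)
  stopifnot(length(runs) >= 1, ncol(runs[[1]]) >= 1)
  nv <- ncol(runs[[1]]); nt <- nrow(runs[[1]])
  stopifnot(all(vapply(runs, ncol, integer(1)) == nv),
            all(vapply(runs, nrow, integer(1)) == nt))
  stacked <- do.call(rbind, runs)
  mb <- if (baseline == "grand") {
    matrix(colMeans(stacked), nt, nv, byrow = TRUE)
  } else {
    Reduce(`+`, runs) / length(runs)      # per-timepoint mean across runs
  }
  if (any(abs(mb) < .Machine$double.eps))
    stop("baseline MB is zero for at least one voxel")
  per_run <- lapply(runs, function(x) rowMeans((x - mb) / mb))
  trace <- Reduce(`+`, per_run) / length(per_run)
  s <- stats::sd(trace)
  if (!is.finite(s) || s == 0)
    stop("zero-variance trace: normalization undefined")
  structure(list(values = trace / s, n_runs = length(runs),
                 n_voxels = nv,
                 baseline_def = paste0(baseline, " mean across runs")),
            class = "normalized_trace")
}

# Extract a cluster's per-run matrices from a list of 4-D arrays.
cluster_runs <- function(bold_runs, voxel_idx) {
  if (!is.list(bold_runs)) bold_runs <- list(bold_runs)
  lapply(bold_runs, function(b) {
    m <- as_bold_matrix(b)
    m[, voxel_idx, drop = FALSE]
  })
}

#' Offset-aligned response per S1 duration condition
#'
#' Samples the normalized trace a fixed number of volumes after each S1
#' offset (default: the second volume after offset) and averages within
#' duration condition. Events whose lagged sample falls beyond the run end
#' are dropped with a warning; conditions with no usable events are
#' reported as `NA`.
#'
#' @param trace a `normalized_trace` (or plain numeric series).
#' @param events an `event_table`.
#' @param scan a `scan_grid`.
#' @param lag_volumes volumes after the offset volume (default 2).
#' @return named numeric vector, one mean response per S1 duration.
#' @export
extract_response <- function(trace, events, scan, lag_volumes = 2L) {
  x <- if (inherits(trace, "normalized_trace")) trace$values else trace
  s1 <- events[events$role == "S1", , drop = FALSE]
  if (nrow(s1) == 0) stop("no S1 events")
  v <- volume_index(s1$onset + s1$duration, scan$tr, one_based = TRUE) +
    as.integer(lag_volumes)
  keep <- v <= length(x)
  if (any(!keep))
    warning(sum(!keep), " event(s) dropped: lagged sample beyond run end")
  conds <- sort(unique(round(s1$duration_label, 9)))
  out <- vapply(conds, function(d) {
    sel <- keep & abs(s1$duration_label - d) < 1e-9
    if (!any(sel)) return(NA_real_)
    mean(x[v[sel]])
  }, numeric(1))
  stats::setNames(out, as.character(conds))
}

#' Map of the 17 presented durations onto the 10 trial types
#'
#' Each duration is assigned to the duration pair(s) in which it occurs as
#' standard or comparison; durations occurring in two pairs (0.6, 1.2 and
#' 1.8 s) contribute to both, weighted by occurrence.
#'
#' @return data frame: `duration`, `pair_id`, `weight` (1 for durations in
#'   a single pair, 0.5 for shared ones).
#' @export
exp2_grouping <- function() {
  p <- exp2_pairs()
  occ <- rbind(data.frame(duration = p$standard, pair_id = p$pair_id),
               data.frame(duration = p$comparison, pair_id = p$pair_id))
  occ$duration <- round(occ$duration, 9)
  cnt <- table(occ$duration)
  occ$weight <- 1 / as.numeric(cnt[as.character(occ$duration)])
  occ[order(occ$duration, occ$pair_id), ]
}

#' Duration-tuning profiles of labeled clusters
#'
#' Arranges per-cluster condition responses into a profile matrix,
#' optionally collapsing the 17 presented durations onto the 10 trial
#' types (weighted by occurrence), and normalizing each cluster's profile
#' to its preferred-duration response so the profile equals 1 at the PD.
#'
#' @param responses matrix clusters x conditions (column names = duration
#'   in seconds), e.g. rows of [extract_response()] outputs.
#' @param pd numeric, preferred duration of each cluster (must be among
#'   the conditions, or among the pair standards when grouped).
#' @param grouping optional grouping table from [exp2_grouping()].
#' @param normalize `"pd"` (default: divide by the PD response) or
#'   `"none"`.
#' @return list of class `tuning_profile`: `matrix` (clusters x
#'   conditions), `conditions`, `pd_index` per cluster, `normalized`.
#' @export
tuning_profile <- function(responses, pd, grouping = NULL,
                           normalize = c("pd", "none")) {
  normalize <- match.arg(normalize)
  responses <- as.matrix(responses)
  conds <- as.numeric(colnames(responses))
  stopifnot(!anyNA(conds), length(pd) == nrow(responses))
  if (!is.null(grouping)) {
    pair_ids <- sort(unique(grouping$pair_id))
    grouped <- vapply(pair_ids, function(p) {
      g <- grouping[grouping$pair_id == p, ]
      j <- match(round(g$duration, 9), round(conds, 9))
      ok <- !is.na(j)
      as.vector(responses[, j[ok], drop = FALSE] %*% g$weight[ok] /
                  sum(g$weight[ok]))
    }, numeric(nrow(responses)))
    if (is.null(dim(grouped))) grouped <- matrix(grouped, 1)
    responses <- grouped
    # grouped condition axis: the pair's standard duration; a cluster's PD
    # maps to the (lowest) pair in which that duration occurs
    conds <- exp2_pairs()$standard[pair_ids]
    colnames(responses) <- format(conds, trim = TRUE)
    pd_index <- vapply(pd, function(d) {
      g <- grouping[abs(grouping$duration - d) < 1e-9, ]
      if (nrow(g) == 0) which.min(abs(conds - d))
      else match(min(g$pair_id), pair_ids)
    }, integer(1))
  } else {
    pd_index <- vapply(pd, function(d) which.min(abs(conds - d)),
                       integer(1))
  }
  if (normalize == "pd") {
    pd_resp <- responses[cbind(seq_len(nrow(responses)), pd_index)]
    if (any(!is.finite(pd_resp)) || any(pd_resp == 0))
      stop("preferred-duration response is zero or missing; cannot normalize")
    responses <- responses / pd_resp
  }
  structure(list(matrix = responses, conditions = conds,
                 pd_index = pd_index, normalized = normalize),
            class = "tuning_profile")
}

#' Test preferred against neighboring and distant durations
#'
#' Collapses each cluster's profile to its response at the preferred
#' duration (PD), at the adjacent conditions on the duration rank scale
#' (PD +/- 1) and at the next ring (PD +/- 2), truncated at the ends, and
#' compares them with paired Wilcoxon signed-rank tests: either `PD vs
#' PD+/-1` and `PD vs PD+/-2` (`pairwise_pd`) or `(PD and PD+/-1) vs
#' PD+/-2` (`union`).
#'
#' @param profile a `tuning_profile` (rows = observations:
#'   cluster/subject).
#' @param scheme `"pairwise_pd"` (default) or `"union"`.
#' @return data frame of comparisons with `p`, `n`, `flagged` (fewer than
#'   5 usable observations yields no p-value).
#' @export
compare_pd_groups <- function(profile, scheme = c("pairwise_pd", "union")) {
  scheme <- match.arg(scheme)
  m <- profile$matrix
  k <- ncol(m)
  if (nrow(m) < 2) stop("need more than one observation")
  ring <- function(i, offs) {
    j <- unique(pmin(pmax(i + offs, 1), k))
    j[j != i | 0 %in% offs]
  }
  ring_mean <- function(offs) vapply(seq_len(nrow(m)), function(r) {
    i <- profile$pd_index[r]
    j <- setdiff(unique(i + offs[i + offs >= 1 & i + offs <= k]), integer(0))
    if (length(j) == 0) return(NA_real_)
    mean(m[r, j])
  }, numeric(1))
  pd <- ring_mean(0)
  pd1 <- ring_mean(c(-1, 1))
  pd2 <- ring_mean(c(-2, 2))
  test <- function(a, b, name) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 5)
      return(data.frame(comparison = name, p = NA_real_, n = sum(ok),
                        flagged = TRUE))
    wt <- suppressWarnings(stats::wilcox.test(a[ok], b[ok], paired = TRUE,
                                              alternative = "greater"))
    data.frame(comparison = name, p = wt$p.value, n = sum(ok),
               flagged = FALSE)
  }
  if (scheme == "pairwise_pd") {
    rbind(test(pd, pd1, "PD vs PD+/-1"), test(pd, pd2, "PD vs PD+/-2"))
  } else {
    near <- rowMeans(cbind(pd, pd1), na.rm = TRUE)
    test(near, pd2, "PD u PD+/-1 vs PD+/-2")
  }
}

#' Mean waveform over stimulation cycles
#'
#' Reshapes a trace into cycles of fixed length, time-reverses the cycles
#' of descending runs so they align with ascending ones, and averages.
#'
#' @param trace a `normalized_trace` or numeric series.
#' @param scan a `scan_grid` (its `direction` decides the reversal).
#' @param cycle_len_volumes volumes per cycle (default 22).
#' @return numeric waveform of `cycle_len_volumes` points.
#' @export
cycle_timecourse <- function(trace, scan, cycle_len_volumes = 22L) {
  x <- if (inherits(trace, "normalized_trace")) trace$values else trace
  if (length(x) %% cycle_len_volumes != 0)
    stop("run length (", length(x), ") not divisible by cycle length (",
         cycle_len_volumes, ")")
  m <- matrix(x, cycle_len_volumes)
  if (identical(scan$direction, "descending")) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  rowMeans(m)
}
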