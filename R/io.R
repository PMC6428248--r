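#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers around RNifti preserving data and voxel size.
#'
#' @param vol 3-D or 4-D numeric array.
#' @param path file path (`.nii` / `.nii.gz`).
#' @param voxel_size mm per spatial axis (length 3).
#' @param tr seconds per volume for 4-D data (stored in the time pixdim).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns
#'   the array with attributes `voxel_size` and (4-D) `tr`.
#' @export
write_volume <- function(vol, path, voxel_size = c(2, 2, 2), tr = NULL) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(voxel_size,
                           if (length(dim(vol)) == 4) (tr %||% 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  pd <- RNifti::pixdim(img)
  attr(arr, "voxel_size") <- pd[1:3]
  if (length(dim(arr)) == 4) attr(arr, "tr") <- pd[4]
  arr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a truth chronomap
#'
#' Three 3-D NIfTI volumes (preferred duration, spread, amplitude) next to
#' a JSON sidecar holding baseline, borders, gradient axis and voxel size.
#'
#' @param truth a `truth_map`.
#' @param prefix path prefix; files become `<prefix>_mu.nii.gz` etc. and
#'   `<prefix>.json`.
#' @return `write_truth_map` returns `prefix` invisibly; `read_truth_map`
#'   a `truth_map`.
#' @export
write_truth_map <- function(truth, prefix) {
  vs <- truth$voxel_size
  write_volume(truth$mu_star, paste0(prefix, "_mu.nii.gz"), vs)
  write_volume(truth$sigma_star, paste0(prefix, "_sigma.nii.gz"), vs)
  write_volume(truth$amplitude, paste0(prefix, "_amplitude.nii.gz"), vs)
  side <- list(shape = truth$shape, voxel_size = vs,
               gradient_axis = truth$gradient_axis,
               gradient = truth$gradient,
               border_low = truth$border_low,
               border_high = truth$border_high,
               baseline = truth$baseline[1])
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_truth_map
#' @export
read_truth_map <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  strip <- function(a) { attributes(a)[c("voxel_size", "tr")] <- NULL; a }
  structure(list(
    mu_star = strip(read_volume(paste0(prefix, "_mu.nii.gz"))),
    sigma_star = strip(read_volume(paste0(prefix, "_sigma.nii.gz"))),
    amplitude = strip(read_volume(paste0(prefix, "_amplitude.nii.gz"))),
    baseline = array(side$baseline, side$shape),
    shape = as.integer(side$shape), voxel_size = side$voxel_size,
    gradient_axis = as.integer(side$gradient_axis),
    gradient = side$gradient,
    border_low = as.integer(side$border_low),
    border_high = as.integer(side$border_high)),
    class = "truth_map")
}

#' Write / read a duration label map
#'
#' Labels are stored as integer milliseconds (0 = unlabeled) in a NIfTI
#' volume, the winning statistic in a second volume, and a JSON sidecar
#' maps the millisecond codes back to seconds.
#'
#' @param labelmap a `label_map` with spatial dims.
#' @param prefix path prefix; files become `<prefix>_label.nii.gz`,
#'   `<prefix>_stat.nii.gz`, `<prefix>.json`.
#' @param voxel_size mm per axis.
#' @return `write_label_map` returns `prefix` invisibly; `read_label_map`
#'   a `label_map`.
#' @export
write_label_map <- function(labelmap, prefix, voxel_size = c(2, 2, 2)) {
  lab <- labelmap$label
  ms <- ifelse(is.na(lab), 0L, as.integer(round(lab * 1000)))
  dim(ms) <- dim(lab)
  write_volume(ms, paste0(prefix, "_label.nii.gz"), voxel_size)
  st <- labelmap$stat
  st[is.na(st)] <- 0
  write_volume(st, paste0(prefix, "_stat.nii.gz"), voxel_size)
  codes <- as.integer(round(labelmap$durations * 1000))
  jsonlite::write_json(
    list(source = labelmap$source,
         codes = stats::setNames(as.list(labelmap$durations),
                                 as.character(codes)),
         unlabeled = 0),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  ms <- read_volume(paste0(prefix, "_label.nii.gz"))
  st <- read_volume(paste0(prefix, "_stat.nii.gz"))
  dims <- dim(ms)
  lab <- ifelse(ms == 0, NA_real_, ms / 1000)
  stat <- ifelse(ms == 0, NA_real_, st)
  dim(lab) <- dim(stat) <- dims
  structure(list(label = lab, stat = stat, source = side$source,
                 durations = sort(as.numeric(unlist(side$codes))),
                 spatial_dim = dims),
            class = "label_map")
}

#' Default pipeline configuration
#'
#' The bundled defaults reproduce the analysis parameters of the two
#' paradigms: labeling threshold t > 3.13, pRF inclusion R^2 > 0.1,
#' 1.5-mm profile bins and a 1-s sub/suprasecond split.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function(experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  cfg <- list(
    experiment = experiment,
    design = if (experiment == "exp1") list(n_runs = 6L)
             else list(n_cycles = 10L, directions = c("ascending",
                                                      "descending")),
    truth = list(shape = c(20L, 20L, 4L),
                 duration_range = if (experiment == "exp1") c(0.2, 1.0)
                                  else c(0.2, 3.0),
                 sigma_star = 0.3, gradient = "anterior_short",
                 jitter_sd = 0, voxel_size = 2),
    noise = list(white_sd = 0.5, drift_amplitude = 1, drift_period = 240),
    glm = list(t_threshold = 3.13, hp_cutoff_hz = 0.0083,
               min_cluster = 0L),
    prf = list(r2_threshold = 0.1, sigma_grid = seq(0.05, 1, by = 0.05),
               tol = 1e-6),
    topography = list(bin_width = 1.5, split_at = 1.0),
    tuning = list(lag_volumes = 2L),
    qc = list(z_thresh = 8, intensity_quantile = 0.05,
              sigma_thresh = 1.0),
    seed = 1L)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the bundled defaults; dotted-path
#' overrides (e.g. `"noise.white_sd=1"`) may be supplied on top.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides character vector of `key.path=value` strings.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path = NULL, overrides = character(0)) {
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  cfg <- default_config(user$experiment %||% "exp1")
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        merge_into(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  cfg <- merge_into(cfg, user)
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad override: ", ov)
    keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    val <- utils::type.convert(kv[2], as.is = TRUE)
    cfg[[keys]] <- val
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full chronomap pipeline on synthetic data
#'
#' Simulates a subject from the configured truth map and paradigm, labels
#' voxels (GLM winner-take-all for the jittered paradigm, duration pRF for
#' the cyclic one), quantifies the map's spatial progression, runs the
#' tuning analysis and QC, and (optionally) writes all artifacts plus a
#' JSON topography report under `out_dir`.
#'
#' @param config a `pipeline_config` (default: bundled exp1 defaults).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return list of class `pipeline_result`: `truth`, `labels`, `wrd`,
#'   `slopes`, `pd_profile`, `centroids`, `tuning`, `qc`, `report`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  cfg <- config
  seed <- cfg$seed
  truth <- make_truth_chronomap(
    shape = cfg$truth$shape, duration_range = cfg$truth$duration_range,
    sigma_star = cfg$truth$sigma_star, gradient = cfg$truth$gradient,
    seed = seed, jitter_sd = cfg$truth$jitter_sd,
    voxel_size = cfg$truth$voxel_size)
  noise <- noise_spec(cfg$noise$white_sd, cfg$noise$drift_amplitude,
                      cfg$noise$drift_period, seed = seed + 1L)
  if (cfg$experiment == "exp1") {
    runs <- build_exp1_design(cfg$design$n_runs, seed = seed + 2L)
    events <- lapply(runs, `[[`, "events")
    scans <- lapply(runs, `[[`, "scan")
  } else {
    runs <- lapply(seq_along(cfg$design$directions), function(i)
      build_exp2_design(cfg$design$directions[i],
                        n_cycles = cfg$design$n_cycles,
                        seed = seed + 1L + i))
    events <- lapply(runs, `[[`, "events")
    scans <- lapply(runs, `[[`, "scan")
  }
  bold <- lapply(seq_along(events), function(r) {
    nr <- noise; nr$seed <- noise$seed + r
    simulate_bold(truth, events[[r]], scans[[r]], nr)
  })
  durations <- enumerate_s1_durations(events)
  if (cfg$experiment == "exp1") {
    design <- build_design_matrix(events, scans,
                                  hp_cutoff_hz = cfg$glm$hp_cutoff_hz)
    fit <- fit_glm(bold, design)
    labels <- winner_take_all(fit$tmap, threshold = cfg$glm$t_threshold,
                              min_cluster = cfg$glm$min_cluster)
    qc <- venous_check_glm(
      apply(fit$tmap$t, 1, max),
      colMeans(as_bold_matrix(bold)),
      cfg$qc$z_thresh, cfg$qc$intensity_quantile)
  } else {
    pm <- prf_map(bold, events = events, scan = scans,
                  sigma_grid = cfg$prf$sigma_grid,
                  r2_threshold = cfg$prf$r2_threshold, tol = cfg$prf$tol)
    labels <- pm$labels
    qc <- venous_check_prf(pm$fits, cfg$qc$sigma_thresh)
  }
  geom <- truth_geometry(truth)
  wrd <- wrd_by_label(labels, geom)
  slopes <- fit_wrd_slope(wrd, split_at = cfg$topography$split_at)
  pdp <- preferred_duration_profile(list(labels), list(geom),
                                    bin_width = cfg$topography$bin_width)
  cents <- weighted_centroids(labels, voxel_size = cfg$truth$voxel_size)
  # tuning on the cluster of each labeled duration: per-run percent-change
  # traces against the grand baseline, responses extracted per run against
  # that run's events and averaged across runs (the later PD normalization
  # makes the overall trace scaling immaterial)
  present <- sort(unique(labels$label[!is.na(labels$label)]))
  resp <- t(vapply(present, function(d) {
    vox <- which(!is.na(labels$label) & abs(labels$label - d) < 1e-9)
    cr <- cluster_runs(bold, vox)
    mb <- colMeans(do.call(rbind, cr))
    per_run <- vapply(seq_along(cr), function(r) {
      trace <- rowMeans(sweep(sweep(cr[[r]], 2, mb), 2, mb, `/`))
      extract_response(trace, events[[r]], scans[[r]],
                       cfg$tuning$lag_volumes)
    }, numeric(length(durations)))
    rowMeans(per_run, na.rm = TRUE)
  }, stats::setNames(numeric(length(durations)),
                     as.character(durations))))
  tp <- tuning_profile(resp, pd = present)
  report <- list(
    experiment = cfg$experiment, seed = seed,
    config_hash = config_hash(cfg),
    n_labeled = sum(!is.na(labels$label)),
    wrd = wrd, slope = slopes$slope, slope_per_s = slopes$slope_per_s,
    sub_slope = if (!is.null(slopes$sub)) slopes$sub$slope else NULL,
    supra_slope = if (!is.null(slopes$supra)) slopes$supra$slope else NULL,
    pd_profile = pdp$profile, centroids = cents,
    qc_n_flagged = qc$n_flagged)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_truth_map(truth, file.path(out_dir, "truth"))
    for (r in seq_along(bold)) {
      write_volume(bold[[r]],
                   file.path(out_dir, sprintf("bold_run%02d.nii.gz", r)),
                   truth$voxel_size, tr = scans[[r]]$tr)
      write_events_tsv(events[[r]],
                       file.path(out_dir, sprintf("events_run%02d.tsv", r)))
    }
    write_label_map(labels, file.path(out_dir, "labels"),
                    truth$voxel_size)
    jsonlite::write_json(report, file.path(out_dir, "topography_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
  }
  structure(list(truth = truth, labels = labels, wrd = wrd,
                 slopes = slopes, pd_profile = pdp, centroids = cents,
                 tuning = tp, qc = qc, report = report),
            class = "pipeline_result")
}

# Stable hash of the configuration for run logging: serialize to
# canonical JSON and fold into a hex digest.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}
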