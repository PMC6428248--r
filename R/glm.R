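#' Discrete-cosine drift basis
#'
#' Non-constant DCT-II columns implementing a high-pass cutoff: the number
#' of columns is `floor(2 * run_seconds * cutoff_hz)` so that drifts slower
#' than the cutoff fall inside the span of the basis.
#'
#' @param n_volumes volumes in the run.
#' @param tr seconds per volume.
#' @param cutoff_hz high-pass cutoff frequency (default 0.0083 Hz, i.e. a
#'   ~120-s period).
#' @return matrix `n_volumes x K` (K may be 0 for short runs).
#' @export
dct_drift_basis <- function(n_volumes, tr, cutoff_hz = 0.0083) {
  K <- floor(2 * n_volumes * tr * cutoff_hz)
  t0 <- seq_len(n_volumes) - 1
  if (K < 1) return(matrix(numeric(0), n_volumes, 0))
  m <- vapply(seq_len(K),
              function(k) cos(pi * (2 * t0 + 1) * k / (2 * n_volumes)),
              numeric(n_volumes))
  colnames(m) <- paste0("dct", seq_len(K))
  m
}

#' Build a first-level GLM design matrix
#'
#' One delta-at-offset regressor per S1 duration condition, one regressor
#' for S2 onsets and one for response-cue onsets, each convolved with the
#' canonical HRF; per-run intercepts and discrete-cosine drift columns
#' implement the high-pass filter. Runs are concatenated: condition
#' regressors share a column across runs (so their estimates average over
#' runs), drift/intercept blocks are run-wise.
#'
#' @param events an `event_table` or list of them (one per run).
#' @param scan a `scan_grid` or list matching `events`.
#' @param hrf an `hrf_kernel` from [canonical_hrf()]; defaults to one
#'   sampled at the scan TR.
#' @param hp_cutoff_hz high-pass cutoff (default 0.0083).
#' @param nuisance optional matrix (or per-run list) of extra columns,
#'   e.g. motion parameters.
#' @return list of class `design_matrix`: `matrix`, `regressor_names`,
#'   `contrasts` (one unit vector per S1 duration), `durations`,
#'   `hp_cutoff_hz`, `run_index`.
#' @export
build_design_matrix <- function(events, scan, hrf = NULL,
                                hp_cutoff_hz = 0.0083, nuisance = NULL) {
  if (is.data.frame(events)) events <- list(events)
  if (inherits(scan, "scan_grid")) scan <- list(scan)
  stopifnot(length(events) == length(scan))
  if (is.null(hrf)) hrf <- canonical_hrf(scan[[1]]$tr)
  durations <- enumerate_s1_durations(events)
  n_runs <- length(events)
  cond_blocks <- vector("list", n_runs)
  drift_blocks <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    ev <- events[[r]]; sc <- scan[[r]]
    if (max(ev$onset + ev$duration) > run_length(sc) + 1e-9)
      stop("events extend past run end in run ", r)
    n <- sc$n_volumes
    sticks <- matrix(0, n, length(durations) + 2)
    for (j in seq_along(durations)) {
      sel <- ev$role == "S1" & abs(ev$duration_label - durations[j]) < 1e-9
      if (!any(sel))
        stop("condition ", durations[j],
             " s has no events in run ", r, " (all-zero column)")
      v <- volume_index(ev$onset[sel] + ev$duration[sel], sc$tr,
                        one_based = TRUE)
      for (vi in v) sticks[vi, j] <- sticks[vi, j] + 1
    }
    for (role in c("S2", "response_cue")) {
      j <- length(durations) + match(role, c("S2", "response_cue"))
      sel <- ev$role == role
      v <- volume_index(ev$onset[sel], sc$tr, one_based = TRUE)
      for (vi in v) sticks[vi, j] <- sticks[vi, j] + 1
    }
    cond_blocks[[r]] <- convolve_hrf_cols(sticks, hrf)
    db <- cbind(intercept = rep(1, n),
                dct_drift_basis(n, sc$tr, hp_cutoff_hz))
    colnames(db) <- paste0("run", r, "_", colnames(db))
    drift_blocks[[r]] <- db
  }
  cond <- do.call(rbind, cond_blocks)
  cond_names <- c(paste0("S1_", format(durations, trim = TRUE)),
                  "S2", "response")
  # drop the response column when the paradigm has no response cue
  keep <- colSums(abs(cond)) > 0
  cond <- cond[, keep, drop = FALSE]
  cond_names <- cond_names[keep]
  n_per_run <- vapply(scan, function(s) s$n_volumes, integer(1))
  drift <- matrix(0, sum(n_per_run),
                  sum(vapply(drift_blocks, ncol, integer(1))))
  ro <- c(0L, cumsum(n_per_run)); co <- 0L
  drift_names <- character(0)
  for (r in seq_len(n_runs)) {
    db <- drift_blocks[[r]]
    drift[(ro[r] + 1):ro[r + 1], co + seq_len(ncol(db))] <- db
    drift_names <- c(drift_names, colnames(db))
    co <- co + ncol(db)
  }
  X <- cbind(cond, drift)
  if (!is.null(nuisance)) {
    if (is.list(nuisance)) nuisance <- do.call(rbind, nuisance)
    colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  colnames(X) <- c(cond_names, drift_names,
                   if (!is.null(nuisance)) colnames(nuisance))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  contrasts <- lapply(seq_along(durations), function(j) {
    cvec <- numeric(ncol(X))
    cvec[j] <- 1
    cvec
  })
  names(contrasts) <- cond_names[seq_along(durations)]
  structure(list(matrix = X, regressor_names = colnames(X),
                 contrasts = contrasts, durations = durations,
                 hp_cutoff_hz = hp_cutoff_hz,
                 run_index = rep(seq_len(n_runs), n_per_run)),
            class = "design_matrix")
}

# Coerce BOLD input (matrix time x voxels, 4-D array, or per-run list of
# either, concatenated over time) to a time x voxels matrix, remembering
# spatial dims when the input is volumetric.
as_bold_matrix <- function(bold) {
  dims <- NULL
  flatten <- function(b) {
    if (is.array(b) && length(dim(b)) == 4) {
      dims <<- dim(b)[1:3]
      t(matrix(b, prod(dim(b)[1:3]), dim(b)[4]))   # time x voxels
    } else as.matrix(b)
  }
  m <- if (is.list(bold)) do.call(rbind, lapply(bold, flatten))
  else flatten(bold)
  attr(m, "spatial_dim") <- dims
  m
}

#' Fit the GLM and compute t-contrast maps
#'
#' Ordinary least squares per voxel with t-statistics
#' `t = c'b / sqrt(s2 * c'(X'X)^-1 c)` for each S1-duration contrast.
#'
#' @param bold BOLD data: a matrix (time x voxels), a 4-D array, or a list
#'   of per-run matrices/arrays concatenated over time.
#' @param design a `design_matrix`.
#' @return list of class `glm_fit`: `betas` (regressors x voxels), `tmap`
#'   of class `t_map` (`t`: voxels x contrasts, `df`, `durations`,
#'   `spatial_dim`), `sigma2`, `df`.
#' @export
fit_glm <- function(bold, design) {
  Y <- as_bold_matrix(bold)
  X <- design$matrix
  if (nrow(Y) != nrow(X))
    stop("BOLD time length (", nrow(Y), ") does not match design rows (",
         nrow(X), ")")
  if (!all(is.finite(Y))) stop("BOLD data contain non-finite values")
  qrX <- qr(X)
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - qrX$rank
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot)]
  tmat <- vapply(design$contrasts, function(cvec) {
    cb <- drop(crossprod(cvec, beta))
    se <- sqrt(sigma2 * drop(crossprod(cvec, XtXinv %*% cvec)))
    cb / se
  }, numeric(ncol(Y)))
  if (is.null(dim(tmat))) tmat <- matrix(tmat, 1)
  colnames(tmat) <- names(design$contrasts)
  rownames(beta) <- design$regressor_names
  tmap <- structure(list(t = tmat, df = df, durations = design$durations,
                         spatial_dim = attr(Y, "spatial_dim")),
                    class = "t_map")
  structure(list(betas = beta, tmap = tmap, sigma2 = sigma2, df = df),
            class = "glm_fit")
}

#' Winner-take-all duration labeling
#'
#' Each voxel is labeled with the duration whose contrast has the largest
#' t-value, provided that value exceeds the threshold; ties break toward
#' the shorter duration. Optionally, labeled voxels in face-connected
#' clusters smaller than `min_cluster` are unlabeled.
#'
#' @param tmap a `t_map` from [fit_glm()].
#' @param durations duration (s) of each contrast column (defaults to the
#'   durations recorded in `tmap`).
#' @param threshold labeling threshold on the winning t (default 3.13).
#' @param min_cluster minimum face-connected cluster size (default 0 = no
#'   filtering); requires spatial dims.
#' @return list of class `label_map`: `label` (seconds, `NA` = unlabeled),
#'   `stat` (winning t), `source = "glm"`, `durations`, `spatial_dim`.
#'   `label`/`stat` carry spatial `dim` when known.
#' @export
winner_take_all <- function(tmap, durations = NULL, threshold = 3.13,
                            min_cluster = 0L) {
  if (is.null(durations)) durations <- tmap$durations
  if (length(durations) != ncol(tmap$t))
    stop("durations (", length(durations),
         ") do not match contrast count (", ncol(tmap$t), ")")
  ord <- order(durations)           # scan in duration order: ties -> shorter
  tt <- tmap$t[, ord, drop = FALSE]
  dd <- durations[ord]
  win <- apply(tt, 1, which.max)    # first (shortest) index on exact ties
  stat <- tt[cbind(seq_len(nrow(tt)), win)]
  label <- ifelse(stat > threshold, dd[win], NA_real_)
  stat[is.na(label)] <- NA_real_
  if (!is.null(tmap$spatial_dim)) {
    dim(label) <- tmap$spatial_dim
    dim(stat) <- tmap$spatial_dim
  }
  lm <- structure(list(label = label, stat = stat, source = "glm",
                       durations = dd, spatial_dim = tmap$spatial_dim),
                  class = "label_map")
  if (min_cluster > 0) lm <- filter_small_clusters(lm, min_cluster)
  lm
}

# Linear index of lattice coordinates (rows of a matrix), column-major.
lattice_index <- function(co, dims) {
  strides <- cumprod(c(1, dims[-length(dims)]))
  as.integer(drop((co - 1) %*% strides) + 1)
}

# Face-adjacent neighbor linear indices of one voxel (vector coords).
face_neighbors <- function(co, dims) {
  out <- integer(0)
  for (ax in seq_along(dims)) {
    for (dshift in c(-1L, 1L)) {
      nb <- co
      nb[ax] <- nb[ax] + dshift
      if (nb[ax] >= 1 && nb[ax] <= dims[ax])
        out <- c(out, lattice_index(matrix(nb, 1), dims))
    }
  }
  out
}

# Remove labeled voxels belonging to face-connected same-label components
# smaller than min_cluster (plain cluster-extent filter).
filter_small_clusters <- function(labelmap, min_cluster) {
  lab <- labelmap$label
  if (is.null(dim(lab))) stop("cluster filtering needs spatial dims")
  dims <- dim(lab)
  idx <- which(!is.na(lab))
  comp <- rep(NA_integer_, length(lab))
  nxt <- 0L
  for (i in idx) {
    if (!is.na(comp[i])) next
    nxt <- nxt + 1L
    queue <- i
    comp[i] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      co <- drop(arrayInd(cur, dims))
      for (j in face_neighbors(co, dims)) {
        if (!is.na(lab[j]) && is.na(comp[j]) &&
            abs(lab[j] - lab[cur]) < 1e-9) {
          comp[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  sizes <- table(comp[idx])
  small <- as.integer(names(sizes)[sizes < min_cluster])
  drop_idx <- idx[comp[idx] %in% small]
  labelmap$label[drop_idx] <- NA_real_
  labelmap$stat[drop_idx] <- NA_real_
  labelmap
}
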