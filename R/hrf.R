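#' Canonical double-gamma hemodynamic response function
#'
#' The standard canonical HRF: a positive gamma density peaking at 6 s
#' minus an undershoot gamma peaking at 16 s with a 6:1 peak-to-undershoot
#' ratio, sampled over a 32-s support and normalized to unit peak. The
#' mode of the finely sampled kernel sits near 5 s.
#'
#' @param tr sampling interval in seconds (> 0).
#' @param duration kernel support in seconds (default 32; values below 16 s
#'   would truncate the undershoot and are rejected).
#' @param peak_delay,undershoot_delay gamma shape parameters (rate 1), in
#'   seconds.
#' @param undershoot_ratio peak:undershoot amplitude ratio.
#' @return list of class `hrf_kernel` with `sample_times`, `values` and
#'   `params`.
#' @export
canonical_hrf <- function(tr, duration = 32, peak_delay = 6,
                          undershoot_delay = 16, undershoot_ratio = 6) {
  stopifnot(tr > 0)
  if (duration < 16)
    stop("HRF support shorter than 16 s truncates the kernel")
  tt <- seq(0, duration, by = tr)
  v <- stats::dgamma(tt, shape = peak_delay, rate = 1) -
    stats::dgamma(tt, shape = undershoot_delay, rate = 1) / undershoot_ratio
  # peak-normalize against the continuous-time maximum so kernels sampled
  # at different TRs agree on a common grid
  tfine <- seq(0, duration, by = 0.001)
  vmax <- max(stats::dgamma(tfine, shape = peak_delay, rate = 1) -
                stats::dgamma(tfine, shape = undershoot_delay, rate = 1) /
                undershoot_ratio)
  structure(list(sample_times = tt, values = v / vmax,
                 params = list(peak_delay = peak_delay,
                               undershoot_delay = undershoot_delay,
                               undershoot_ratio = undershoot_ratio,
                               tr = tr, duration = duration)),
            class = "hrf_kernel")
}

# Causal convolution of a per-volume neural series with an HRF kernel,
# truncated to the input length.
convolve_hrf <- function(x, hrf) {
  n <- length(x)
  h <- hrf$values
  y <- stats::convolve(c(x, numeric(length(h))), rev(h), type = "open")
  y[seq_len(n)]
}

# Column-wise HRF convolution of a matrix (volumes x series).
convolve_hrf_cols <- function(m, hrf) {
  apply(m, 2, convolve_hrf, hrf = hrf)
}
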