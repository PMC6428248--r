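#' Venous-artifact check on GLM statistics
#'
#' Venous voxels are expected to combine a very high statistic with very
#' low mean signal intensity. Flags voxels whose z (or t) exceeds
#' `z_thresh` while their mean intensity falls strictly below the given
#' quantile of the in-mask intensities. Defaults are deliberately
#' conservative screening values; the diagnostic is primarily the
#' scatterplot of the two quantities.
#'
#' @param zmap numeric statistic per voxel.
#' @param mean_intensity mean signal per voxel (same length).
#' @param z_thresh flagging threshold on the statistic (default 8).
#' @param intensity_quantile lower intensity quantile (default 0.05).
#' @return list of class `qc_report`: `table` (per-voxel `z`, `intensity`,
#'   `flag`), `n_flagged`, `thresholds`.
#' @export
venous_check_glm <- function(zmap, mean_intensity, z_thresh = 8,
                             intensity_quantile = 0.05) {
  z <- as.vector(zmap); mi <- as.vector(mean_intensity)
  if (length(z) == 0) stop("empty voxel set")
  stopifnot(length(z) == length(mi))
  cut <- stats::quantile(mi, intensity_quantile, names = FALSE)
  flag <- z > z_thresh & mi < cut
  structure(list(table = data.frame(z = z, intensity = mi, flag = flag),
                 n_flagged = sum(flag),
                 thresholds = list(z_thresh = z_thresh,
                                   intensity_quantile = intensity_quantile,
                                   intensity_cut = cut)),
            class = "qc_report")
}

#' Venous-artifact check on pRF fits
#'
#' A venous voxel should show no credible duration tuning: its fitted
#' spread is abnormally wide. Flags included voxels with sigma at or above
#' `sigma_thresh` and reports the Kendall correlation between sigma and mu
#' across included voxels (a check for a systematic spread-preference
#' relationship).
#'
#' @param fits data frame with columns `mu`, `sigma`, `included` (e.g.
#'   `prf_map()$fits`).
#' @param sigma_thresh spread threshold in seconds (default 1).
#' @return list of class `qc_report`: `table`, `n_flagged`,
#'   `sigma_mu_tau`, `sigma_mu_p` (`NA` and `tau_defined = FALSE` for
#'   constant input), `thresholds`.
#' @export
venous_check_prf <- function(fits, sigma_thresh = 1.0) {
  inc <- fits[fits$included, , drop = FALSE]
  if (nrow(inc) < 2) stop("need at least 2 included voxels")
  flag <- inc$sigma >= sigma_thresh
  tau <- p <- NA_real_
  defined <- stats::sd(inc$sigma) > 0 && stats::sd(inc$mu) > 0
  if (defined) {
    ct <- suppressWarnings(stats::cor.test(inc$sigma, inc$mu,
                                           method = "kendall"))
    tau <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(table = data.frame(voxel = inc$voxel, mu = inc$mu,
                                    sigma = inc$sigma, flag = flag),
                 n_flagged = sum(flag), sigma_mu_tau = tau,
                 sigma_mu_p = p, tau_defined = defined,
                 thresholds = list(sigma_thresh = sigma_thresh)),
            class = "qc_report")
}
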