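# Synthetic inputs: noisy observed-like concentration profiles, probe
# clearance-change points for the UGT1A4 fit, and the packaged
# predicted/observed validation pairs.

#' Generate a synthetic observed concentration profile
#'
#' Emulates a digitized literature study: the true (simulated) profile is
#' sampled at the given times and multiplicative log-normal observation
#' noise with coefficient of variation `cv` is drawn per subject and
#' time point; the per-time mean and SD across subjects are returned.
#'
#' @param truth a `pbpk_sim` providing the true profile.
#' @param sample_times sampling times (h) within the simulated grid.
#' @param cv observation CV (fraction, >= 0).
#' @param n_subjects number of virtual subjects.
#' @param seed integer seed.
#' @param study_id label for the synthetic study.
#' @return an `observed_profile` data frame with columns `time_h`,
#'   `mean_conc`, `sd_conc`; `n_subjects`, `dose_mg` and `study_id` are
#'   attached as attributes.
#' @export
generate_observed_profile <- function(truth, sample_times, cv, n_subjects,
                                      seed, study_id = "synthetic") {
  stopifnot(inherits(truth, "pbpk_sim"), cv >= 0, n_subjects >= 1)
  if (any(sample_times < min(truth$time) - 1e-9) ||
      any(sample_times > max(truth$time) + 1e-9)) {
    stop("sample_times outside the simulated grid", call. = FALSE)
  }
  set.seed(seed)
  true_conc <- stats::approx(truth$time, truth$plasma_concentration,
                             xout = sample_times)$y
  sdlog <- .cv_to_sdlog(cv)
  draws <- matrix(stats::rlnorm(length(sample_times) * n_subjects,
                                -sdlog^2 / 2, sdlog),
                  nrow = n_subjects)
  obs <- sweep(draws, 2, true_conc, `*`)
  out <- data.frame(time_h = sample_times,
                    mean_conc = colMeans(obs),
                    sd_conc = apply(obs, 2, stats::sd))
  attr(out, "study_id") <- study_id
  attr(out, "n_subjects") <- n_subjects
  attr(out, "dose_mg") <- truth$dose_events$amount_umol[1] * truth$model$cp$MW / 1000
  class(out) <- c("observed_profile", "data.frame")
  out
}

#' Generate probe clearance-change points for the UGT1A4 fit
#'
#' Emulates the structure of the lamotrigine apparent-clearance data: each
#' contributing study (default sample sizes 7, 11 and 53) contributes
#' percent-change observations at the given fertilization weeks, with
#' Gaussian noise scaled by `1/sqrt(weight)` so larger studies are more
#' precise. With `noise_sd = 0` the points lie exactly on the cubic.
#'
#' @param coeffs cubic coefficients `c(a1, a2, a3)` of
#'   `a1 FW + a2 FW^2 + a3 FW^3` (default: the fitted UGT1A4 trajectory).
#' @param study_sizes study sample sizes used as regression weights.
#' @param fw_values fertilization weeks sampled by every study.
#' @param noise_sd noise scale in percent-change units (before the
#'   `1/sqrt(weight)` scaling).
#' @param seed integer seed.
#' @return data frame with `FW`, `percent_change`, `weight`.
#' @export
generate_lamotrigine_points <- function(coeffs = c(8.669, -0.339, 0.00462),
                                        study_sizes = c(7, 11, 53),
                                        fw_values = c(8, 20, 32),
                                        noise_sd = 0, seed = 1) {
  stopifnot(length(coeffs) == 3, all(study_sizes > 0), noise_sd >= 0)
  set.seed(seed)
  grid <- expand.grid(FW = fw_values, weight = study_sizes)
  truth <- coeffs[1] * grid$FW + coeffs[2] * grid$FW^2 + coeffs[3] * grid$FW^3
  grid$percent_change <- truth +
    stats::rnorm(nrow(grid), 0, noise_sd / sqrt(grid$weight))
  grid[, c("FW", "percent_change", "weight")]
}

#' Packaged predicted/observed validation pairs
#'
#' The ten validation simulations' predicted and observed Cmax, AUC and
#' tmax, as a [fold_error_table()] with recomputed fold errors.
#'
#' @param path optional override CSV (same layout as the shipped fixture).
#' @return a `fold_error_table`.
#' @export
#' @examples
#' vt <- validation_pk_pairs()
#' vt$gmfe[["Cmax"]]  # ~1.14
validation_pk_pairs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "validation_pk_pairs.csv", package = "olapbpk")
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  fold_error_table(tab)
}
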