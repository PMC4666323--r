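#' Canonical double-gamma haemodynamic response function
#'
#' The impulse response linking neural events to BOLD: a gamma density
#' peaking near `peak_delay` seconds minus a scaled gamma density modelling
#' the post-stimulus undershoot. The response is exactly 0 at `t = 0` and
#' integrates to `1 - 1/ratio`.
#'
#' @param peak_delay Time-to-peak of the positive lobe (s).
#' @param undershoot_delay Time-to-peak of the undershoot (s).
#' @param peak_disp,undershoot_disp Dispersions (gamma scale parameters, s).
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @param duration Length of the sampled impulse response (s).
#'
#' @return An object of class `hrf_model`.
#' @export
hrf_model <- function(peak_delay = 6, undershoot_delay = 16,
                      peak_disp = 1, undershoot_disp = 1,
                      ratio = 6, duration = 32) {
  stopifnot(peak_delay > 0, undershoot_delay > 0,
            peak_disp > 0, undershoot_disp > 0, ratio > 0, duration > 0)
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_disp = peak_disp, undershoot_disp = undershoot_disp,
                 ratio = ratio, duration = duration),
            class = "hrf_model")
}

#' Evaluate an HRF at given times
#'
#' @param hrf An [hrf_model()].
#' @param t Times in seconds (values outside `[0, duration]` give 0).
#' @return Numeric vector of responses.
#' @examples
#' hrf_values(hrf_model(), 0:30)
#' @export
hrf_values <- function(hrf, t) {
  out <- dgamma(t, shape = hrf$peak_delay / hrf$peak_disp,
                scale = hrf$peak_disp) -
    dgamma(t, shape = hrf$undershoot_delay / hrf$undershoot_disp,
           scale = hrf$undershoot_disp) / hrf$ratio
  out[t < 0 | t > hrf$duration] <- 0
  out
}

#' Convolve trial events with the HRF and sample at volume times
#'
#' Builds a neural boxcar (amplitude 1 over each trial's duration) on a fine
#' time grid, convolves it with the HRF, and samples the result at the volume
#' acquisition times `0, tr, 2 tr, ...`.
#'
#' @param onsets Trial onsets in seconds from run start.
#' @param durations Trial durations in seconds (recycled).
#' @param n_volumes Number of volumes in the run.
#' @param tr Repetition time (s).
#' @param hrf An [hrf_model()].
#' @param dt Fine-grid resolution in seconds.
#' @return Numeric vector of length `n_volumes`: the condition regressor.
#' @export
convolve_events <- function(onsets, durations, n_volumes, tr,
                            hrf = hrf_model(), dt = 0.1) {
  durations <- rep_len(durations, length(onsets))
  total <- n_volumes * tr
  n_fine <- ceiling(total / dt) + 1L
  neural <- numeric(n_fine)
  grid <- (seq_len(n_fine) - 1) * dt
  for (i in seq_along(onsets)) {
    on <- which(grid >= onsets[i] & grid < onsets[i] + durations[i])
    neural[on] <- neural[on] + 1
  }
  h <- hrf_values(hrf, seq(0, hrf$duration, by = dt))
  conv <- convolve(neural, rev(h), type = "open")[seq_len(n_fine)] * dt
  vol_idx <- round((seq_len(n_volumes) - 1) * tr / dt) + 1L
  conv[vol_idx]
}
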