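#' Simulate one ROI's BOLD time series for one subject
#'
#' For each run, each condition's trials are convolved with the HRF to give
#' a condition regressor `s_c(t)`; voxel `v` then receives
#' `baseline_v + sum_c s_c(t) * (univariate_c + W[v, c])`
#' plus AR(1) noise and sinusoidal drift, sampled at the TR. Runs are
#' independent noise realizations. The generating [pattern_model()] is kept
#' in the result (`$truth`) for recovery tests.
#'
#' @param events Event table from [generate_design()].
#' @param spec The [design_spec()] the events were generated under.
#' @param pattern A [pattern_model()] for this ROI.
#' @param hrf An [hrf_model()].
#' @param noise A [noise_model()].
#' @param roi,subject,hemisphere Labels attached to the result.
#' @param seed Optional integer seed; per-run child seeds are derived with
#'   [derive_seed()], so runs are independent streams.
#' @return An [roi_ts()] of `spec$n_runs * spec$volumes_per_run` rows.
#' @export
simulate_roi_timeseries <- function(events, spec, pattern,
                                    hrf = hrf_model(), noise = noise_model(),
                                    roi = "roi", subject = "sub-01",
                                    hemisphere = "none", seed = NULL) {
  regs <- condition_regressors(events, spec, hrf)
  simulate_from_regressors(regs, spec, pattern, noise, roi = roi,
                           subject = subject, hemisphere = hemisphere,
                           seed = seed)
}

# Condition regressors per run: list over runs of n_volumes x n_conditions
# matrices. Computed once per subject and shared across ROIs.
condition_regressors <- function(events, spec, hrf = hrf_model(), dt = 0.1) {
  runs <- sort(unique(events$run))
  run_limit <- spec$volumes_per_run * spec$tr
  lapply(runs, function(r) {
    ev <- events[events$run == r, ]
    if (nrow(ev) && max(ev$onset + ev$duration) > run_limit) {
      abort(sprintf("Events of run %d extend past the %g s acquisition.",
                    r, run_limit))
    }
    S <- matrix(0, spec$volumes_per_run, length(spec$conditions),
                dimnames = list(NULL, spec$conditions))
    for (cond in spec$conditions) {
      sel <- ev$condition == cond
      if (!any(sel)) next
      S[, cond] <- convolve_events(ev$onset[sel], ev$duration[sel],
                                   spec$volumes_per_run, spec$tr, hrf, dt)
    }
    S
  })
}

# Assemble signal + noise from precomputed regressors.
simulate_from_regressors <- function(regs, spec, pattern,
                                     noise = noise_model(),
                                     roi = "roi", subject = "sub-01",
                                     hemisphere = "none", seed = NULL) {
  nv <- pattern$n_voxels
  n_runs <- length(regs)
  out <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    S <- regs[[r]][, pattern$conditions, drop = FALSE]
    n_t <- nrow(S)
    # amplitude per voxel and condition: univariate + multivariate weights
    A <- sweep(pattern$weights, 2, pattern$univariate, "+")
    Y <- S %*% t(A)
    Y <- sweep(Y, 2, pattern$baseline, "+")
    run_seed <- derive_seed(seed, r)
    Y <- Y + with_seed_if(run_seed, {
      E <- matrix(0, n_t, nv)
      if (noise$white_sd > 0) {
        innov <- matrix(rnorm(n_t * nv, sd = noise$white_sd), n_t, nv)
        if (noise$ar1 > 0) {
          E <- apply(innov, 2, function(x) {
            as.numeric(stats::filter(x, noise$ar1, method = "recursive"))
          })
        } else E <- innov
      }
      if (noise$drift_amplitude != 0) {
        tt <- (seq_len(n_t) - 1) * spec$tr
        phase <- runif(nv, 0, noise$drift_period)
        D <- noise$drift_amplitude *
          sin(outer(tt, phase, "+") * (2 * pi / noise$drift_period))
        E <- E + D
      }
      E
    })
    out[[r]] <- Y
  }
  roi_ts(do.call(rbind, out),
         run = rep(seq_len(n_runs), each = nrow(regs[[1]])),
         tr = spec$tr, roi = roi, subject = subject,
         hemisphere = hemisphere, truth = pattern)
}

#' Simulate all ROIs of one subject
#'
#' @param events Event table for this subject.
#' @param spec The [design_spec()].
#' @param patterns Named list of [pattern_model()] objects, one per ROI.
#' @param hrf,noise Shared [hrf_model()] / [noise_model()].
#' @param subject Subject label.
#' @param hemispheres Optional named character vector of hemisphere labels
#'   matching `patterns`.
#' @param seed Optional integer seed; each ROI gets an independent child
#'   stream.
#' @return Named list of [roi_ts()] objects.
#' @export
simulate_subject <- function(events, spec, patterns,
                             hrf = hrf_model(), noise = noise_model(),
                             subject = "sub-01", hemispheres = NULL,
                             seed = NULL) {
  stopifnot(is.list(patterns), !is.null(names(patterns)))
  regs <- condition_regressors(events, spec, hrf)
  out <- vector("list", length(patterns))
  names(out) <- names(patterns)
  for (i in seq_along(patterns)) {
    nm <- names(patterns)[i]
    hemi <- if (!is.null(hemispheres)) hemispheres[[nm]] else "none"
    out[[i]] <- simulate_from_regressors(
      regs, spec, patterns[[i]], noise, roi = nm, subject = subject,
      hemisphere = hemi, seed = derive_seed(seed, 100 + i))
  }
  out
}
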