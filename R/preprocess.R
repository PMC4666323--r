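#' Runwise voxel time-series preprocessing
#'
#' The chain applied to each ROI before decoding, each step operating on one
#' run at a time (runs are never mixed): standardize each voxel to zero mean
#' and unit standard deviation, remove linear trends, and project out slow
#' drifts below 0.01 Hz with a discrete-cosine basis.
#'
#' @param ts An [roi_ts()].
#' @return The transformed [roi_ts()].
#' @name preprocess
NULL

#' @describeIn preprocess Per voxel and run, subtract the mean and divide by
#'   the standard deviation (denominator `N - 1`). Constant voxels map to
#'   all zeros with a warning rather than `NaN`.
#' @export
standardize_runwise <- function(ts) {
  n_constant <- 0L
  out <- map_runs(ts, function(Y, r) {
    if (nrow(Y) < 2) {
      abort(sprintf("Run %s has fewer than 2 volumes; cannot standardize.", r))
    }
    mu <- colMeans(Y)
    sdv <- apply(Y, 2, sd)
    zero <- sdv == 0
    n_constant <<- n_constant + sum(zero)
    sdv[zero] <- 1
    Z <- sweep(sweep(Y, 2, mu), 2, sdv, "/")
    Z[, zero] <- 0
    Z
  })
  if (n_constant > 0) {
    warn(sprintf("%d constant voxel-run series set to zero during standardization.",
                 n_constant))
  }
  out
}

#' @describeIn preprocess Per voxel and run, keep the residual of an
#'   ordinary least-squares fit on intercept + linear time.
#' @export
detrend_runwise <- function(ts) {
  map_runs(ts, function(Y, r) {
    n <- nrow(Y)
    if (n < 3) abort(sprintf("Run %s has fewer than 3 volumes; cannot detrend.", r))
    X <- cbind(1, seq_len(n))
    Y - X %*% lm.fit(X, Y)$coefficients
  })
}

# DCT-II style cosine basis: columns k = 1..K with frequencies
# f_k = k / (2 N tr); K chosen so every column is below `cutoff_hz`.
dct_highpass_basis <- function(n, tr, cutoff_hz) {
  K <- floor(2 * n * tr * cutoff_hz)
  if (K < 1) return(matrix(numeric(0), n, 0))
  t0 <- seq_len(n) - 1
  sapply(seq_len(K), function(k) cos(pi * k * (2 * t0 + 1) / (2 * n)))
}

#' @describeIn preprocess Per run, project out the discrete-cosine
#'   components below `cutoff_hz` (default 0.01 Hz, i.e. a 100 s period),
#'   plus the constant. Zero phase distortion; modeled drifts are nulled
#'   exactly.
#' @param cutoff_hz High-pass cutoff in Hz; must be below the Nyquist
#'   frequency `1 / (2 tr)`.
#' @export
highpass_runwise <- function(ts, cutoff_hz = 0.01) {
  if (cutoff_hz >= 1 / (2 * ts$tr)) {
    abort(sprintf("`cutoff_hz` (%g) must be below the Nyquist frequency %g Hz.",
                  cutoff_hz, 1 / (2 * ts$tr)))
  }
  map_runs(ts, function(Y, r) {
    n <- nrow(Y)
    X <- cbind(1, dct_highpass_basis(n, ts$tr, cutoff_hz))
    Y - X %*% lm.fit(X, Y)$coefficients
  })
}

#' @describeIn preprocess Standardize, then detrend, then high-pass, in that
#'   order, all per run.
#' @export
preprocess_chain <- function(ts, cutoff_hz = 0.01) {
  ts |>
    standardize_runwise() |>
    detrend_runwise() |>
    highpass_runwise(cutoff_hz = cutoff_hz)
}
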