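#' Noise model for simulated BOLD time series
#'
#' Additive noise is white Gaussian innovations of standard deviation
#' `white_sd` passed through an AR(1) recursion with coefficient `ar1`, plus
#' a slow sinusoidal drift of the given amplitude and period (random phase
#' per voxel and run). The default 128 s drift period sits below the 0.01 Hz
#' high-pass cutoff, so the preprocessing chain has something real to remove.
#'
#' @param white_sd Innovation standard deviation (BOLD units, >= 0).
#' @param ar1 AR(1) coefficient in `[0, 1)`.
#' @param drift_amplitude Drift amplitude (BOLD units).
#' @param drift_period Drift period in seconds.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(white_sd = 1, ar1 = 0.3,
                        drift_amplitude = 1, drift_period = 128) {
  if (white_sd < 0) abort("`white_sd` must be >= 0.")
  if (ar1 < 0 || ar1 >= 1) abort("`ar1` must lie in [0, 1) for stationarity.")
  if (drift_period <= 0) abort("`drift_period` must be > 0.")
  structure(list(white_sd = white_sd, ar1 = ar1,
                 drift_amplitude = drift_amplitude,
                 drift_period = drift_period),
            class = "noise_model")
}

# Level sets of the stimulus features a condition pattern can encode. Each
# named effect contributes a voxel pattern shared by the conditions at the
# same level; conditions not carrying the feature (e.g. reaching-only trials
# for grasp type) contribute nothing.
condition_feature_levels <- function() {
  list(
    object_size = list(S = c("PGS", "WHGS", "RS"), L = c("PGL", "WHGL", "RL")),
    grasp_type  = list(PG = c("PGS", "PGL"), WHG = c("WHGS", "WHGL")),
    action_type = list(grasp = c("PGS", "PGL", "WHGS", "WHGL"),
                       reach = c("RS", "RL")),
    congruence  = list(congruent = c("PGS", "WHGL"),
                       incongruent = c("PGL", "WHGS")),
    condition   = list(PGS = "PGS", PGL = "PGL", WHGS = "WHGS",
                       WHGL = "WHGL", RS = "RS", RL = "RL")
  )
}

# Zero-mean, unit-sd voxel vector.
centered_unit_pattern <- function(n_voxels) {
  w <- rnorm(n_voxels)
  w <- w - mean(w)
  s <- sd(w)
  if (s > 0) w / s else w
}

#' Draw condition-specific multivoxel pattern weights
#'
#' Builds an `n_voxels x n_conditions` weight matrix as a sum of feature
#' patterns: each named effect (e.g. `grasp_type`) draws one zero-mean,
#' unit-sd voxel vector per feature level, scaled by the effect amplitude,
#' and assigns it to the conditions at that level. An amplitude of 0 for
#' every effect yields the all-zero matrix (no multivariate signal).
#'
#' @param n_voxels Number of voxels.
#' @param effects Named numeric vector of pattern amplitudes (BOLD units);
#'   names among `object_size`, `grasp_type`, `action_type`, `congruence`,
#'   `condition`.
#' @param conditions Condition labels.
#' @param seed Optional integer seed.
#' @return Matrix with zero-mean columns, `colnames = conditions`.
#' @export
draw_pattern_weights <- function(n_voxels, effects = c(condition = 1),
                                 conditions = grasp_conditions(),
                                 seed = NULL) {
  feats <- condition_feature_levels()
  bad <- setdiff(names(effects), names(feats))
  if (length(bad)) {
    abort(paste0("Unknown pattern effect(s): ", paste(bad, collapse = ", ")))
  }
  with_seed_if(seed, {
    W <- matrix(0, n_voxels, length(conditions),
                dimnames = list(NULL, conditions))
    for (f in names(effects)) {
      if (effects[[f]] == 0) next
      for (lvl in names(feats[[f]])) {
        w <- centered_unit_pattern(n_voxels) * effects[[f]]
        members <- intersect(feats[[f]][[lvl]], conditions)
        for (cond in members) W[, cond] <- W[, cond] + w
      }
    }
    W
  })
}

#' Multivoxel pattern model for one ROI
#'
#' Describes the condition-locked signal carried by an ROI's voxels: a
#' per-voxel baseline, a per-condition univariate amplitude applied equally
#' to every voxel, and a per-condition multivoxel weight matrix (zero mean
#' across voxels) carrying the pattern information the classifiers are meant
#' to recover. With `weights = NULL` (or all zero) and equal univariate
#' amplitudes, the class-conditional signal distributions are identical and
#' decoding can only perform at chance.
#'
#' @param n_voxels Number of voxels in the ROI.
#' @param conditions Condition labels.
#' @param baseline Baseline per voxel (scalar recycled).
#' @param univariate Per-condition scalar amplitude (scalar recycled or named
#'   vector over `conditions`).
#' @param weights `n_voxels x n_conditions` matrix from
#'   [draw_pattern_weights()], or `NULL` for no multivariate signal.
#' @return An object of class `pattern_model`.
#' @export
pattern_model <- function(n_voxels, conditions = grasp_conditions(),
                          baseline = 100, univariate = 1, weights = NULL) {
  stopifnot(is_count(n_voxels))
  baseline <- rep_len(baseline, n_voxels)
  if (is.null(names(univariate))) {
    univariate <- stats::setNames(rep_len(univariate, length(conditions)),
                                  conditions)
  } else {
    if (!all(conditions %in% names(univariate))) {
      abort("`univariate` must name every condition.")
    }
    univariate <- univariate[conditions]
  }
  if (is.null(weights)) {
    weights <- matrix(0, n_voxels, length(conditions),
                      dimnames = list(NULL, conditions))
  }
  if (!is.matrix(weights) || nrow(weights) != n_voxels ||
      ncol(weights) != length(conditions)) {
    abort("`weights` must be an n_voxels x n_conditions matrix.")
  }
  colnames(weights) <- conditions
  structure(list(n_voxels = as.integer(n_voxels), conditions = conditions,
                 baseline = baseline, univariate = univariate,
                 weights = weights,
                 informative = any(weights != 0)),
            class = "pattern_model")
}

#' Perturb a group-template pattern model into a subject-specific one
#'
#' Adds zero-mean Gaussian jitter of standard deviation `sd` to the weight
#' matrix (columns re-centred), modelling between-subject variability in the
#' multivoxel code around a shared group template. This is what gives the
#' group-level t-test on accuracies a realistic between-subject variance.
#'
#' @param pm A [pattern_model()] (the template).
#' @param sd Jitter standard deviation (BOLD units).
#' @param seed Optional integer seed.
#' @return A new `pattern_model`.
#' @export
perturb_pattern_model <- function(pm, sd = 0.3, seed = NULL) {
  if (sd < 0) abort("`sd` must be >= 0.")
  if (sd == 0 || !pm$informative) return(pm)
  with_seed_if(seed, {
    E <- matrix(rnorm(length(pm$weights), sd = sd), nrow(pm$weights))
    W <- pm$weights + E
    W <- sweep(W, 2, colMeans(W))
    pattern_model(pm$n_voxels, pm$conditions, pm$baseline, pm$univariate, W)
  })
}
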