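# Shared fixtures, built in code at test time.

# A small but complete design: 2 runs, 3 mini-blocks per condition, 80
# volumes per run. Keeps simulation-heavy tests fast while preserving the
# run-parity structure (each condition lives in a single run).
small_spec <- function(...) {
  design_spec(n_runs = 2, volumes_per_run = 80, trials_per_condition = 15,
              miniblock_size = 5, ...)
}

# Simulate one subject's single ROI through the full chain and return the
# mini-block samples (preprocessed unless raw = TRUE).
simulate_samples <- function(spec = small_spec(), effects = NULL,
                             n_voxels = 20, univariate = 1, seed = 1,
                             noise = noise_model(), raw = FALSE,
                             subject_sd = 0, hemisphere = "none") {
  ev <- generate_design(spec, seed = derive_seed(seed, 1))
  W <- if (!is.null(effects)) {
    draw_pattern_weights(n_voxels, effects, spec$conditions,
                         seed = derive_seed(seed, 2))
  }
  pm <- pattern_model(n_voxels, spec$conditions, univariate = univariate,
                      weights = W)
  if (subject_sd > 0) {
    pm <- perturb_pattern_model(pm, subject_sd, seed = derive_seed(seed, 3))
  }
  ts <- simulate_roi_timeseries(ev, spec, pm, noise = noise,
                                hemisphere = hemisphere,
                                seed = derive_seed(seed, 4))
  if (!raw) ts <- preprocess_chain(ts)
  mapping <- assign_volumes_to_miniblocks(ev, spec$tr, spec$volumes_per_run)
  build_samples(ts, mapping)
}

# Build a sample_set directly from a matrix and labels (bypassing the
# simulator) for classifier-level tests. Chronological order follows the
# row order given.
make_sample_set <- function(X, labels, classification = "test") {
  X <- as.matrix(X)
  meta <- tibble::tibble(subject = "sub-01", roi = "roi",
                         hemisphere = "none",
                         run = 1L, miniblock_id = seq_len(nrow(X)),
                         condition = ifelse(labels > 0, "A", "B"),
                         n_volumes_used = 1L)
  structure(list(X = X, labels = labels, meta = meta,
                 classification = classification,
                 n_pos = sum(labels == 1), n_neg = sum(labels == -1)),
            class = "sample_set")
}

# Independent 1-D leave-pair-out oracle for strictly separable training
# sets where the hard-margin solution is admissible for C = 1 (class gap of
# the two innermost points >= sqrt(2)): the decision boundary is the
# midpoint of the innermost cross-class pair, and a fold's prediction is
# the side of that midpoint. Enumerates folds by hand.
lopo_oracle_1d <- function(x, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == -1)
  stopifnot(length(pos) == length(neg))
  correct <- 0
  for (k in seq_along(pos)) {
    test <- c(pos[k], neg[k])
    xtr <- x[-test]; ltr <- labels[-test]
    inner_pos <- if (mean(xtr[ltr == 1]) > mean(xtr[ltr == -1])) {
      min(xtr[ltr == 1])
    } else max(xtr[ltr == 1])
    inner_neg <- if (mean(xtr[ltr == 1]) > mean(xtr[ltr == -1])) {
      max(xtr[ltr == -1])
    } else min(xtr[ltr == -1])
    stopifnot(abs(inner_pos - inner_neg) >= sqrt(2))  # soft margin inactive
    boundary <- (inner_pos + inner_neg) / 2
    sign_pos <- sign(inner_pos - boundary)
    pred <- ifelse(sign(x[test] - boundary) == sign_pos, 1, -1)
    pred[x[test] == boundary] <- 1
    correct <- correct + sum(pred == labels[test])
  }
  correct / (2 * length(pos))
}
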