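#' Specify the event-related experimental design
#'
#' Encodes the scanning and trial-schedule parameters of the reach-to-grasp
#' experiment: four runs of 117 volumes at TR = 3 s, six conditions with 45
#' trials each grouped into mini-blocks of five same-condition trials, and
#' stimulus-onset asynchronies drawn from a truncated exponential on 3--8 s.
#' Object size is blocked by run parity: odd runs present the small object
#' (PGS, WHGS, RS), even runs the large one (PGL, WHGL, RL).
#'
#' @param n_runs Number of scanning runs (even when `run_parity_rule` holds).
#' @param tr Repetition time in seconds.
#' @param volumes_per_run Volumes acquired per run.
#' @param conditions Condition labels; see [grasp_conditions()].
#' @param trials_per_condition Trials per condition across the session; must
#'   be divisible by `miniblock_size`.
#' @param miniblock_size Consecutive same-condition trials forming one
#'   mini-block (the unit later averaged into one classifier sample).
#' @param isi_range Length-2 numeric, min/max onset-to-onset interval in
#'   seconds.
#' @param isi_mean_target Desired mean onset-to-onset interval in seconds;
#'   the exponential rate is solved numerically so the truncated mean matches.
#' @param run_parity_rule If `TRUE`, small-object conditions appear only in
#'   odd runs and large-object conditions only in even runs.
#' @param trial_duration Movement/stimulus duration in seconds (used for the
#'   neural boxcar and the schedule-fit check).
#' @param max_schedule_attempts Maximum onset-sequence redraws per run before
#'   [generate_design()] gives up with a schedule-overflow error.
#'
#' @return An object of class `design_spec`.
#' @examples
#' spec <- design_spec()
#' spec$volumes_per_run * spec$tr  # 351 s per run
#' @export
design_spec <- function(n_runs = 4,
                        tr = 3,
                        volumes_per_run = 117,
                        conditions = grasp_conditions(),
                        trials_per_condition = 45,
                        miniblock_size = 5,
                        isi_range = c(3, 8),
                        isi_mean_target = 4.9,
                        run_parity_rule = TRUE,
                        trial_duration = 2,
                        max_schedule_attempts = 100) {
  stopifnot(is_count(n_runs), is_count(volumes_per_run),
            is_count(trials_per_condition), is_count(miniblock_size))
  if (!is.numeric(tr) || tr <= 0) {
    abort("`tr` must be a positive number of seconds.")
  }
  if (trials_per_condition %% miniblock_size != 0) {
    abort(sprintf(
      "`trials_per_condition` (%d) must be divisible by `miniblock_size` (%d).",
      trials_per_condition, miniblock_size))
  }
  if (length(isi_range) != 2 || isi_range[1] < 0 || isi_range[1] > isi_range[2]) {
    abort("`isi_range` must be c(min, max) with 0 <= min <= max.")
  }
  if (isi_mean_target < isi_range[1] || isi_mean_target > isi_range[2]) {
    abort("`isi_mean_target` must lie inside `isi_range`.")
  }
  if (run_parity_rule) {
    if (n_runs %% 2 != 0) {
      abort("`run_parity_rule` requires an even number of runs.")
    }
    if (!all(grasp_conditions() %in% conditions)) {
      abort("`run_parity_rule` assumes the six standard conditions.")
    }
  }
  structure(
    list(n_runs = as.integer(n_runs), tr = tr,
         volumes_per_run = as.integer(volumes_per_run),
         conditions = conditions,
         trials_per_condition = as.integer(trials_per_condition),
         miniblock_size = as.integer(miniblock_size),
         isi_range = as.numeric(isi_range),
         isi_mean_target = isi_mean_target,
         run_parity_rule = isTRUE(run_parity_rule),
         trial_duration = trial_duration,
         max_schedule_attempts = as.integer(max_schedule_attempts)),
    class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec>\n")
  cat(sprintf("  %d runs x %d volumes, TR %g s (%g s/run)\n",
              x$n_runs, x$volumes_per_run, x$tr, x$volumes_per_run * x$tr))
  cat(sprintf("  %d conditions x %d trials in mini-blocks of %d\n",
              length(x$conditions), x$trials_per_condition, x$miniblock_size))
  cat(sprintf("  SOA ~ truncated exponential on [%g, %g] s, mean %g s\n",
              x$isi_range[1], x$isi_range[2], x$isi_mean_target))
  invisible(x)
}

# Mean of an exponential truncated to [a, b] as a function of rate lambda.
truncated_exp_mean <- function(lambda, a, b) {
  if (a == b) return(a)
  w <- b - a
  # lambda -> 0 limit: uniform mean (a + b) / 2
  if (lambda < 1e-10) return((a + b) / 2)
  a + 1 / lambda - w / expm1(lambda * w)
}

# Solve the rate so that the truncated mean equals `target`.
truncated_exp_rate <- function(isi_range, target) {
  a <- isi_range[1]; b <- isi_range[2]
  if (a == b) return(Inf)
  lo <- (a + b) / 2
  if (target >= lo) {
    if (abs(target - lo) < 1e-12) return(0)
    abort(sprintf(
      "`isi_mean_target` (%g) is not achievable on [%g, %g]: the truncated exponential mean lies in (%g, %g).",
      target, a, b, a, lo))
  }
  if (target <= a) {
    abort(sprintf(
      "`isi_mean_target` (%g) is not achievable on [%g, %g]: the truncated exponential mean lies in (%g, %g).",
      target, a, b, a, lo))
  }
  uniroot(function(l) truncated_exp_mean(l, a, b) - target,
          lower = 1e-8, upper = 1e3, tol = 1e-12)$root
}

#' Draw stimulus-onset asynchronies
#'
#' Onset-to-onset intervals follow a "long exponential": an exponential
#' distribution truncated to `spec$isi_range`, with rate solved numerically so
#' the mean equals `spec$isi_mean_target`. Sampling is by inverse CDF.
#'
#' @param n Number of draws.
#' @param spec A [design_spec()].
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` intervals in seconds, all inside
#'   `spec$isi_range`.
#' @examples
#' mean(sample_isi(1e4, design_spec(), seed = 1))
#' @export
sample_isi <- function(n, spec = design_spec(), seed = NULL) {
  a <- spec$isi_range[1]; b <- spec$isi_range[2]
  if (a == b) return(rep(a, n))
  lambda <- truncated_exp_rate(spec$isi_range, spec$isi_mean_target)
  with_seed_if(seed, {
    u <- runif(n)
    if (lambda == 0) {
      a + u * (b - a)
    } else {
      # inverse CDF of the exponential truncated to [a, b]
      a - log1p(u * expm1(-lambda * (b - a))) / lambda
    }
  })
}

#' Whole volumes acquired in a given duration
#'
#' @param duration Seconds.
#' @param tr Repetition time in seconds (> 0).
#' @return Integer count, `floor(duration / tr)`.
#' @examples
#' volumes_for_duration(351, 3)  # 117
#' @export
volumes_for_duration <- function(duration, tr) {
  if (!is.numeric(tr) || any(tr <= 0)) abort("`tr` must be > 0.")
  as.integer(floor(duration / tr))
}

# Conditions allowed in a given run under the parity rule.
conditions_for_run <- function(spec, run) {
  if (!spec$run_parity_rule) return(spec$conditions)
  small <- c("PGS", "WHGS", "RS")
  large <- c("PGL", "WHGL", "RL")
  if (run %% 2 == 1) intersect(spec$conditions, small)
  else intersect(spec$conditions, large)
}

# Number of mini-blocks of each condition in each run. Per condition the
# mini-blocks are split as evenly as possible across that condition's runs,
# rotating the remainder across conditions so run totals stay balanced
# (e.g. 13/14 mini-blocks per run under the default design).
miniblock_allocation <- function(spec) {
  blocks_per_cond <- spec$trials_per_condition %/% spec$miniblock_size
  runs <- seq_len(spec$n_runs)
  alloc <- list()
  for (run in runs) alloc[[run]] <- integer(0)
  for (run in runs) {
    conds <- conditions_for_run(spec, run)
    alloc[[run]] <- stats::setNames(integer(length(conds)), conds)
  }
  totals <- integer(spec$n_runs)
  for (ci in seq_along(spec$conditions)) {
    cond <- spec$conditions[ci]
    cond_runs <- runs[vapply(runs, function(r) cond %in% conditions_for_run(spec, r), logical(1))]
    k <- length(cond_runs)
    base <- blocks_per_cond %/% k
    rem <- blocks_per_cond %% k
    counts <- rep(base, k)
    if (rem > 0) {
      # hand extras to the currently least-loaded runs so totals stay balanced
      ord <- order(totals[cond_runs], cond_runs)
      counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
    }
    for (j in seq_len(k)) alloc[[cond_runs[j]]][cond] <- counts[j]
    totals[cond_runs] <- totals[cond_runs] + counts
  }
  alloc
}

#' Generate a randomized trial schedule
#'
#' Lays out mini-blocks of same-condition trials within each run (order
#' randomized, run parity respected), with onset-to-onset intervals drawn via
#' [sample_isi()]. The first trial of each run starts at 0 s. If a drawn
#' onset sequence overruns the run (last trial must finish by
#' `volumes_per_run * tr`), the intervals for that run are redrawn, up to
#' `spec$max_schedule_attempts` times, after which an error names the run.
#'
#' @param spec A [design_spec()].
#' @param seed Optional integer seed; equal `(spec, seed)` give identical
#'   schedules.
#' @return A tibble (the event table) with columns `run`, `miniblock_id`
#'   (unique across the session, chronological), `trial_index` (within run),
#'   `onset` (seconds from run start), `duration`, and `condition`.
#' @examples
#' ev <- generate_design(design_spec(), seed = 1)
#' nrow(ev)                       # 270 trials
#' dplyr::n_distinct(ev$miniblock_id)  # 54 mini-blocks
#' @export
generate_design <- function(spec = design_spec(), seed = NULL) {
  alloc <- miniblock_allocation(spec)
  run_limit <- spec$volumes_per_run * spec$tr
  with_seed_if(seed, {
    out <- vector("list", spec$n_runs)
    block_counter <- 0L
    for (run in seq_len(spec$n_runs)) {
      counts <- alloc[[run]]
      block_conds <- rep(names(counts), counts)
      block_conds <- sample(block_conds)
      n_trials <- length(block_conds) * spec$miniblock_size
      onsets <- NULL
      for (attempt in seq_len(spec$max_schedule_attempts)) {
        gaps <- sample_isi(n_trials - 1, spec)
        cand <- c(0, cumsum(gaps))
        if (cand[n_trials] + spec$trial_duration <= run_limit) {
          onsets <- cand
          break
        }
      }
      if (is.null(onsets)) {
        abort(sprintf(
          "Schedule overflow in run %d: %d trials do not fit into %g s after %d attempts.",
          run, n_trials, run_limit, spec$max_schedule_attempts))
      }
      out[[run]] <- tibble(
        run = run,
        miniblock_id = block_counter +
          rep(seq_along(block_conds), each = spec$miniblock_size),
        trial_index = seq_len(n_trials),
        onset = onsets,
        duration = spec$trial_duration,
        condition = rep(block_conds, each = spec$miniblock_size))
      block_counter <- block_counter + length(block_conds)
    }
    dplyr::bind_rows(out)
  })
}

#' Write / read an event table as a BIDS-style events TSV
#'
#' Columns written: `onset`, `duration`, `trial_type`, `run`, `miniblock_id`.
#'
#' @param events Event table from [generate_design()].
#' @param path File path.
#' @return `write_events_tsv()` returns `path` invisibly; `read_events_tsv()`
#'   returns the event table tibble.
#' @export
write_events_tsv <- function(events, path) {
  out <- tibble(onset = events$onset,
                duration = events$duration,
                trial_type = events$condition,
                run = events$run,
                miniblock_id = events$miniblock_id)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tb <- tibble(run = as.integer(raw$run),
               miniblock_id = as.integer(raw$miniblock_id),
               onset = as.numeric(raw$onset),
               duration = as.numeric(raw$duration),
               condition = as.character(raw$trial_type))
  tb |>
    dplyr::group_by(run) |>
    dplyr::mutate(trial_index = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("run", "miniblock_id", "trial_index", "onset",
                  "duration", "condition")
}
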