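#' Default ROI set for simulated experiments
#'
#' Seven bilateral frontoparietal ROIs (SPOC, SPLap, hAIP, BA 1/2/3ab,
#' BA 4p, BA 6, BA 44/45) plus one out-of-brain control ROI, as a tibble of
#' simulation settings. Two presets are shipped:
#'
#' * `"null"` — no condition-specific signal anywhere (the control ROI
#'   additionally has no task response at all). Decoding can only perform
#'   at chance; this is the global-null calibration scenario.
#' * `"planted"` — a synthetic scenario qualitatively mirroring the kind of
#'   findings such experiments report: an action-type (grasp vs reach)
#'   pattern in every brain ROI, a grasp-type pattern everywhere except
#'   SPOC and right hAIP, no object-size or congruence information, and
#'   slightly stronger patterns on the left. Entirely synthetic; amplitudes
#'   are package defaults, not estimates from data.
#'
#' @param n_voxels Voxels per ROI.
#' @param preset `"planted"` or `"null"`.
#' @param beta_action,beta_grasp Left-hemisphere pattern amplitudes (BOLD
#'   units) for the planted preset; right-hemisphere ROIs get 80% of each.
#' @param univariate Task-response amplitude of brain ROIs (the control ROI
#'   always gets 0).
#' @return Tibble: `roi`, `hemisphere`, `n_voxels`, `univariate`, `effects`
#'   (list-column of named amplitude vectors for [draw_pattern_weights()]).
#' @export
default_roi_set <- function(n_voxels = 100, preset = c("planted", "null"),
                            beta_action = 0.8, beta_grasp = 0.6,
                            univariate = 1) {
  preset <- match.arg(preset)
  rois <- c("SPOC", "SPLap", "hAIP", "BA 1/2/3ab", "BA 4p", "BA 6",
            "BA 44/45")
  grid <- tidyr::expand_grid(roi = rois, hemisphere = c("L", "R"))
  grid$n_voxels <- n_voxels
  grid$univariate <- univariate
  grid$effects <- purrr::pmap(grid, function(roi, hemisphere, ...) {
    if (preset == "null") return(c(action_type = 0))
    side <- if (hemisphere == "L") 1 else 0.8
    eff <- c(action_type = beta_action * side)
    no_grasp_signal <- roi == "SPOC" ||
      (roi == "hAIP" && hemisphere == "R")
    if (!no_grasp_signal) eff <- c(eff, grasp_type = beta_grasp * side)
    eff
  })
  control <- tibble(roi = "Control", hemisphere = "none",
                    n_voxels = n_voxels, univariate = 0,
                    effects = list(c(action_type = 0)))
  dplyr::bind_rows(grid, control)
}

#' Assemble an experiment configuration
#'
#' Bundles every knob of the simulated experiment: design, ROI set, HRF,
#' noise, subject count, classifications and inference settings.
#'
#' @param design A [design_spec()].
#' @param rois ROI table as from [default_roi_set()].
#' @param hrf,noise [hrf_model()] / [noise_model()].
#' @param n_subjects Number of simulated subjects (>= 2).
#' @param classifications Character vector of classification ids (see
#'   [classification_specs()]).
#' @param subject_pattern_sd Between-subject jitter of the pattern weights
#'   around the group template (see [perturb_pattern_model()]).
#' @param baseline Baseline BOLD level per voxel.
#' @param q FDR level.
#' @param include_control_in_family Whether control-ROI tests enter the FDR
#'   family.
#' @param control_roi Control ROI label.
#' @param discard_volumes,lag_volumes Sampling settings (see
#'   [build_samples()] and [assign_volumes_to_miniblocks()]).
#' @param C SVM soft-margin cost.
#' @param cutoff_hz High-pass cutoff.
#' @param seed Master seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(design = design_spec(),
                              rois = default_roi_set(),
                              hrf = hrf_model(),
                              noise = noise_model(),
                              n_subjects = 16,
                              classifications = classification_specs()$classification,
                              subject_pattern_sd = 0.3,
                              baseline = 100,
                              q = 0.05,
                              include_control_in_family = TRUE,
                              control_roi = "Control",
                              discard_volumes = 4,
                              lag_volumes = 0,
                              C = 1,
                              cutoff_hz = 0.01,
                              seed = 1) {
  if (n_subjects < 2) abort("`n_subjects` must be >= 2.")
  if (!length(classifications)) abort("`classifications` must be non-empty.")
  stopifnot(inherits(design, "design_spec"), is.data.frame(rois))
  structure(list(design = design, rois = rois, hrf = hrf, noise = noise,
                 n_subjects = as.integer(n_subjects),
                 classifications = classifications,
                 subject_pattern_sd = subject_pattern_sd,
                 baseline = baseline, q = q,
                 include_control_in_family = include_control_in_family,
                 control_roi = control_roi,
                 discard_volumes = discard_volumes,
                 lag_volumes = lag_volumes, C = C, cutoff_hz = cutoff_hz,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# unique key per ROI row used for naming
roi_key <- function(rois) paste(rois$roi, rois$hemisphere, sep = "|")

# group-level pattern templates, one per ROI row
build_templates <- function(config) {
  purrr::map(seq_len(nrow(config$rois)), function(i) {
    row <- config$rois[i, ]
    W <- draw_pattern_weights(row$n_voxels, row$effects[[1]],
                              config$design$conditions,
                              seed = derive_seed(config$seed, 7000 + i))
    pattern_model(row$n_voxels, config$design$conditions,
                  baseline = config$baseline,
                  univariate = row$univariate, weights = W)
  })
}

#' Simulate, decode and analyze a full experiment
#'
#' Runs the complete chain for every simulated subject: schedule generation,
#' per-ROI BOLD simulation (subject-specific patterns drawn around the group
#' templates), runwise preprocessing, mini-block sampling, leave-pair-out
#' SVM decoding for every configured classification, then group t-tests with
#' FDR, the ROI x hemisphere repeated-measures ANOVA per classification, and
#' (when the three action-related classifications are present) the
#' per-ROI linear-contrast comparison across classifications. Deterministic
#' given `(config, seed)`.
#'
#' @param config An [experiment_config()].
#' @param seed Master seed (defaults to `config$seed`).
#' @return An object of class `experiment_report`.
#' @export
run_experiment <- function(config, seed = NULL) {
  seed <- seed %||% config$seed
  spec <- config$design
  templates <- build_templates(config)
  keys <- roi_key(config$rois)
  hemis <- stats::setNames(config$rois$hemisphere, keys)
  cells <- list()
  for (s in seq_len(config$n_subjects)) {
    sub_seed <- derive_seed(seed, s)
    subject <- sprintf("sub-%02d", s)
    events <- generate_design(spec, seed = derive_seed(sub_seed, 1))
    patterns <- stats::setNames(purrr::map(seq_along(templates), function(i) {
      perturb_pattern_model(templates[[i]], sd = config$subject_pattern_sd,
                            seed = derive_seed(sub_seed, 10 + i))
    }), keys)
    ts_list <- simulate_subject(events, spec, patterns, config$hrf,
                                config$noise, subject = subject,
                                hemispheres = hemis, seed = sub_seed)
    mapping <- assign_volumes_to_miniblocks(events, spec$tr,
                                            spec$volumes_per_run,
                                            config$lag_volumes)
    for (i in seq_along(ts_list)) {
      ts <- ts_list[[i]]
      ts$roi <- config$rois$roi[i]  # display name without hemisphere suffix
      pp <- preprocess_chain(ts, cutoff_hz = config$cutoff_hz)
      samples <- build_samples(pp, mapping,
                               discard_volumes = config$discard_volumes)
      for (cl in config$classifications) {
        cells[[length(cells) + 1]] <- tibble(
          samples = list(select_classification(samples, cl)))
      }
    }
  }
  sample_sets <- dplyr::bind_rows(cells)
  decoding <- decode_all(sample_sets, C = config$C)
  group <- group_ttests(decoding, q = config$q,
                        include_control = config$include_control_in_family,
                        control_roi = config$control_roi)
  anovas <- roi_hemisphere_anovas(decoding, config)
  contrasts <- classification_contrasts(decoding, config)
  structure(list(decoding = decoding, group = group, anovas = anovas,
                 contrasts = contrasts, config = config, seed = seed,
                 gaps = attr(decoding, "gaps"),
                 provenance = list(config_hash = rlang::hash(config),
                                   seed = seed,
                                   package_version =
                                     as.character(utils::packageVersion("graspdecode")))),
            class = "experiment_report")
}

# ROI x hemisphere RM-ANOVA per classification (brain ROIs only)
roi_hemisphere_anovas <- function(decoding, config) {
  brain <- decoding |>
    dplyr::filter(roi != config$control_roi, hemisphere %in% c("L", "R"))
  out <- list()
  for (cl in unique(brain$classification)) {
    d <- brain[brain$classification == cl, ]
    if (length(unique(d$roi)) < 2 || length(unique(d$hemisphere)) < 2) next
    res <- tryCatch(
      rm_anova_roi_hemisphere(d[, c("subject", "roi", "hemisphere",
                                    "accuracy")], q = config$q),
      error = function(e) {
        inform(sprintf("Skipping ROI x hemisphere ANOVA for '%s': %s",
                       cl, conditionMessage(e)))
        NULL
      })
    if (!is.null(res)) out[[cl]] <- res
  }
  out
}

# per-ROI linear contrast across grasp_type -> pg_vs_reach -> whg_vs_reach
classification_contrasts <- function(decoding, config) {
  wanted <- c("grasp_type", "pg_vs_reach", "whg_vs_reach")
  if (!all(wanted %in% unique(decoding$classification))) return(list())
  brain <- decoding |>
    dplyr::filter(roi != config$control_roi,
                  classification %in% wanted) |>
    dplyr::group_by(subject, roi, classification) |>
    dplyr::summarise(accuracy = mean(accuracy), .groups = "drop")
  out <- list()
  for (r in unique(brain$roi)) {
    d <- brain[brain$roi == r, c("subject", "classification", "accuracy")]
    out[[r]] <- rm_anova_classification_contrast(d, level_order = wanted)
  }
  out
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d subjects, %d ROI cells, %d classification(s), seed %d\n",
              x$config$n_subjects,
              dplyr::n_distinct(paste(x$decoding$roi, x$decoding$hemisphere)),
              length(unique(x$decoding$classification)), x$seed))
  cat(sprintf("  %d decoding cells; %d FDR-significant group tests at q = %g\n",
              nrow(x$decoding), sum(x$group$fdr_rejected), x$config$q))
  invisible(x)
}

format_p <- function(p) {
  ifelse(is.na(p), "NA", sprintf("%.4f", p))
}

format_cell <- function(mean_accuracy, sem, statistic, df, p_one_tailed,
                        degenerate) {
  if (degenerate) {
    sprintf("%.3f ± %.3f, t(%d) degenerate (sd 0)",
            mean_accuracy, sem, df)
  } else {
    sprintf("%.3f ± %.3f, t(%d) = %.3f, p = %s",
            mean_accuracy, sem, df, statistic, format_p(p_one_tailed))
  }
}

#' Render per-classification accuracy tables
#'
#' Formats the group results as one table per classification with rows
#' `ROI | Left hemisphere | Right hemisphere` and cells
#' `mean (+/-) SEM, t(df), p` (the layout of the experiment's report
#' tables). ROIs without a hemisphere (the control) appear in a single
#' spanning cell.
#'
#' @param report An [run_experiment()] report.
#' @return Named list of tibbles, one per classification.
#' @export
render_tables <- function(report) {
  out <- list()
  for (cl in unique(report$group$classification)) {
    g <- report$group[report$group$classification == cl, ]
    g$cell <- purrr::pmap_chr(
      g[, c("mean_accuracy", "sem", "statistic", "df", "p_one_tailed",
            "degenerate")], format_cell)
    rois <- unique(g$roi)
    rows <- purrr::map(rois, function(r) {
      gr <- g[g$roi == r, ]
      left <- gr$cell[gr$hemisphere == "L"]
      right <- gr$cell[gr$hemisphere == "R"]
      none <- gr$cell[gr$hemisphere == "none"]
      tibble(ROI = r,
             `Left hemisphere` = if (length(left)) left else
               if (length(none)) none else "",
             `Right hemisphere` = if (length(right)) right else "")
    })
    out[[cl]] <- dplyr::bind_rows(rows)
  }
  out
}

#' Write an experiment report to disk
#'
#' Writes `decoding.tsv` (one row per subject x ROI x hemisphere x
#' classification), `group.tsv`, `anova.tsv`, `contrast.tsv`,
#' `posthoc.tsv`, one rendered `table_<classification>.tsv` each, and
#' `provenance.yaml` (config hash, seed, package version). Outputs are
#' byte-identical across runs with the same config and seed.
#'
#' @param report An [run_experiment()] report.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$decoding, file.path(dir, "decoding.tsv"))
  readr::write_tsv(report$group, file.path(dir, "group.tsv"))
  if (length(report$anovas)) {
    anova_tbl <- dplyr::bind_rows(
      purrr::imap(report$anovas,
                  function(a, cl) dplyr::mutate(a$effects, classification = cl,
                                                .before = 1)))
    readr::write_tsv(anova_tbl, file.path(dir, "anova.tsv"))
    posthoc_tbl <- dplyr::bind_rows(
      purrr::imap(report$anovas, function(a, cl) {
        if (is.null(a$posthoc)) return(NULL)
        dplyr::mutate(a$posthoc, classification = cl, .before = 1)
      }))
    readr::write_tsv(posthoc_tbl, file.path(dir, "posthoc.tsv"))
  }
  if (length(report$contrasts)) {
    contrast_tbl <- dplyr::bind_rows(
      purrr::imap(report$contrasts,
                  function(a, r) dplyr::mutate(a$effects, roi = r, .before = 1)))
    readr::write_tsv(contrast_tbl, file.path(dir, "contrast.tsv"))
  }
  for (tb in names(tabs <- render_tables(report))) {
    readr::write_tsv(tabs[[tb]],
                     file.path(dir, paste0("table_", gsub("[^A-Za-z0-9_]", "_", tb), ".tsv")))
  }
  if (!is.null(report$gaps) && nrow(report$gaps)) {
    readr::write_tsv(report$gaps, file.path(dir, "gaps.tsv"))
  }
  yaml::write_yaml(report$provenance, file.path(dir, "provenance.yaml"))
  invisible(dir)
}
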