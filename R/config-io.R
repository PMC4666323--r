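#' Read an experiment configuration from YAML
#'
#' Every generator and pipeline parameter can be set from a YAML file.
#' Recognized top-level keys: `design`, `hrf`, `noise` (argument lists for
#' [design_spec()], [hrf_model()], [noise_model()]), `rois` (either
#' `preset: planted|null` with options for [default_roi_set()], or an
#' explicit list of entries with `roi`, `hemisphere`, `n_voxels`,
#' `univariate` and named `effects`), `classifications`, `stats`
#' (`q`, `include_control_in_family`, `control_roi`), plus scalar arguments
#' of [experiment_config()] (`n_subjects`, `seed`,
#' `subject_pattern_sd`, ...).
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  as_experiment_config(yaml::read_yaml(path))
}

#' @rdname read_experiment_config
#' @param x A named list (parsed YAML).
#' @export
as_experiment_config <- function(x) {
  stopifnot(is.list(x))
  design <- do.call(design_spec, as_args(x$design))
  hrf <- do.call(hrf_model, as_args(x$hrf))
  noise <- do.call(noise_model, as_args(x$noise))
  rois <- parse_roi_table(x$rois)
  args <- list(design = design, hrf = hrf, noise = noise, rois = rois)
  stats_block <- as_args(x$stats)
  if (!is.null(stats_block$q)) args$q <- stats_block$q
  if (!is.null(stats_block$include_control_in_family)) {
    args$include_control_in_family <- stats_block$include_control_in_family
  }
  if (!is.null(stats_block$control_roi)) {
    args$control_roi <- stats_block$control_roi
  }
  for (key in c("n_subjects", "classifications", "subject_pattern_sd",
                "baseline", "discard_volumes", "lag_volumes", "C",
                "cutoff_hz", "seed")) {
    if (!is.null(x[[key]])) args[[key]] <- x[[key]]
  }
  do.call(experiment_config, args)
}

as_args <- function(x) if (is.null(x)) list() else x

parse_roi_table <- function(x) {
  if (is.null(x)) return(default_roi_set())
  if (!is.null(x$preset)) {
    return(do.call(default_roi_set, x))
  }
  rows <- purrr::map(x, function(r) {
    tibble(roi = r$roi,
           hemisphere = r$hemisphere %||% "none",
           n_voxels = r$n_voxels %||% 100,
           univariate = r$univariate %||% 1,
           effects = list(unlist(r$effects %||% list(action_type = 0))))
  })
  dplyr::bind_rows(rows)
}

#' Serialize a sample set as a matrix TSV plus metadata TSV
#'
#' `<stem>_X.tsv` holds the sample x voxel matrix (columns `v1`, `v2`,
#' ...); `<stem>_meta.tsv` holds labels and per-sample metadata.
#'
#' @param samples A [select_classification()] sample set.
#' @param stem Output path stem.
#' @return The stem, invisibly.
#' @export
write_sample_set <- function(samples, stem) {
  X <- as.data.frame(samples$X)
  names(X) <- paste0("v", seq_len(ncol(X)))
  readr::write_tsv(as_tibble(X), paste0(stem, "_X.tsv"))
  meta <- dplyr::mutate(samples$meta, label = samples$labels,
                        classification = samples$classification)
  readr::write_tsv(meta, paste0(stem, "_meta.tsv"))
  invisible(stem)
}

#' @rdname write_sample_set
#' @export
read_sample_set <- function(stem) {
  X <- as.matrix(readr::read_tsv(paste0(stem, "_X.tsv"),
                                 show_col_types = FALSE, progress = FALSE))
  dimnames(X) <- NULL
  meta <- readr::read_tsv(paste0(stem, "_meta.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  labels <- meta$label
  classification <- meta$classification[1]
  meta <- dplyr::select(meta, -"label", -"classification")
  structure(list(X = X, labels = labels, meta = meta,
                 classification = classification,
                 n_pos = sum(labels == 1), n_neg = sum(labels == -1)),
            class = "sample_set")
}

#' Write an ROI time series as a tabular matrix file
#'
#' One row per volume: `run`, `volume`, then voxel columns `v1 ...`.
#' Written gzip-compressed when the path ends in `.gz`.
#'
#' @param ts An [roi_ts()].
#' @param path Output path (`.tsv` or `.tsv.gz`).
#' @return `path`, invisibly.
#' @export
write_roi_ts <- function(ts, path) {
  readr::write_tsv(as_tibble(ts), path)
  invisible(path)
}

#' @rdname write_roi_ts
#' @export
read_roi_ts <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  vox <- grep("^v[0-9]+$", names(tb), value = TRUE)
  roi_ts(as.matrix(tb[, vox]), run = tb$run,
         tr = if (nrow(tb) > 1) tb$time[2] - tb$time[1] else 1,
         roi = tb$roi[1], subject = tb$subject[1],
         hemisphere = tb$hemisphere[1])
}
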