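#' The six binary classifications of the experiment
#'
#' Each classification labels the samples of its positive condition set +1
#' and its negative set -1: object size within reach-to-grasp, object size
#' within reaching-only, grasp type, grasp/size congruence, and each grasp
#' type against reaching-only.
#'
#' @return A tibble with columns `classification`, `label` (display name),
#'   `positive` and `negative` (list-columns of condition labels).
#' @examples
#' classification_specs()
#' @export
classification_specs <- function() {
  tibble(
    classification = c("size_grasp", "size_reach", "grasp_type",
                       "congruence", "pg_vs_reach", "whg_vs_reach"),
    label = c("Object size in Reach-to-grasp", "Object size in Reaching-only",
              "Grasp type", "Congruence", "PG vs Reaching-only",
              "WHG vs Reaching-only"),
    positive = list(c("PGS", "WHGS"), "RS", c("PGS", "PGL"),
                    c("PGS", "WHGL"), c("PGS", "PGL"), c("WHGS", "WHGL")),
    negative = list(c("PGL", "WHGL"), "RL", c("WHGS", "WHGL"),
                    c("PGL", "WHGS"), c("RS", "RL"), c("RS", "RL"))
  )
}

#' Define a binary classification by its condition sets
#'
#' @param name Identifier.
#' @param positive,negative Disjoint, non-empty condition label sets; samples
#'   from `positive` are labeled +1, from `negative` -1.
#' @param label Display name (defaults to `name`).
#' @return An object of class `classification_spec`.
#' @export
classification_spec <- function(name, positive, negative, label = name) {
  if (!length(positive) || !length(negative)) {
    abort("Both condition sets must be non-empty.")
  }
  if (length(intersect(positive, negative))) {
    abort("`positive` and `negative` condition sets must be disjoint.")
  }
  structure(list(name = name, label = label,
                 positive = positive, negative = negative),
            class = "classification_spec")
}

# look up one of the built-in six by id
get_classification_spec <- function(name) {
  tbl <- classification_specs()
  i <- match(name, tbl$classification)
  if (is.na(i)) abort(sprintf("Unknown classification '%s'.", name))
  classification_spec(name, tbl$positive[[i]], tbl$negative[[i]], tbl$label[i])
}

#' Assign acquisition volumes to mini-blocks
#'
#' A volume belongs to mini-block `b` when its acquisition time (volume `v`,
#' 1-based, is acquired at `(v - 1) * tr`) falls in
#' `[onset of b's first trial, onset of the next mini-block's first trial)`
#' within the run; the last mini-block of a run extends to the end of the
#' run. `lag_volumes` shifts the whole partition forward by that many
#' volumes (clipped at the run end).
#'
#' @param events Event table from [generate_design()].
#' @param tr Repetition time (s).
#' @param n_volumes Volumes per run (scalar, or named by run).
#' @param lag_volumes Integer shift of the partition.
#' @return A tibble with columns `run`, `miniblock_id`, `condition`,
#'   `volume` (1-based within run) and `row` (1-based into the run-major
#'   time series).
#' @export
assign_volumes_to_miniblocks <- function(events, tr, n_volumes,
                                         lag_volumes = 0) {
  runs <- sort(unique(events$run))
  if (length(n_volumes) == 1) {
    n_volumes <- stats::setNames(rep(n_volumes, length(runs)), runs)
  }
  out <- vector("list", length(runs))
  offset <- 0L
  for (ri in seq_along(runs)) {
    r <- runs[ri]
    nv <- n_volumes[[as.character(r)]]
    ev <- events[events$run == r, ]
    firsts <- ev |>
      dplyr::group_by(miniblock_id) |>
      dplyr::summarise(start = min(onset), condition = condition[1],
                       .groups = "drop") |>
      dplyr::arrange(start)
    bounds <- c(firsts$start, nv * tr)
    times <- (seq_len(nv) - 1) * tr
    block_of <- findInterval(times, bounds)  # 0 = before first block
    keep <- block_of >= 1 & block_of <= nrow(firsts)
    tb <- tibble(run = r,
                 miniblock_id = firsts$miniblock_id[block_of[keep]],
                 condition = firsts$condition[block_of[keep]],
                 volume = which(keep) + as.integer(lag_volumes))
    tb <- tb[tb$volume >= 1 & tb$volume <= nv, ]
    tb$row <- tb$volume + offset
    out[[ri]] <- tb
    offset <- offset + as.integer(nv)
  }
  dplyr::bind_rows(out)
}

#' Average mini-block volumes into classifier samples
#'
#' Within each mini-block the first `discard_volumes` volumes are dropped to
#' let the haemodynamic response stabilize (and to decouple the sample from
#' the preceding mini-block); the remaining volumes are averaged per voxel
#' into a single pattern.
#'
#' @param ts A (preprocessed) [roi_ts()].
#' @param mapping Output of [assign_volumes_to_miniblocks()].
#' @param discard_volumes Leading volumes dropped per mini-block (default 4,
#'   i.e. 12 s at TR = 3 s).
#' @return An object of class `miniblock_samples`: list with `X` (mini-block
#'   x voxel matrix) and `meta` (tibble: `subject`, `roi`, `hemisphere`,
#'   `run`, `miniblock_id`, `condition`, `n_volumes_used`).
#' @export
build_samples <- function(ts, mapping, discard_volumes = 4) {
  m <- mapping[order(mapping$run, mapping$volume), ]
  ids <- unique(m$miniblock_id)  # chronological
  rows_by_block <- split(m$row, factor(m$miniblock_id, levels = ids))
  n_b <- length(ids)
  X <- matrix(NA_real_, n_b, ncol(ts$data))
  run_b <- integer(n_b); cond_b <- character(n_b); used_b <- integer(n_b)
  first <- match(ids, m$miniblock_id)
  for (i in seq_len(n_b)) {
    rows <- rows_by_block[[i]]
    if (length(rows) <= discard_volumes) {
      abort(sprintf(
        "Mini-block %s (run %d) has %d volume(s), not more than the %d to discard.",
        ids[i], m$run[first[i]], length(rows), discard_volumes))
    }
    keep <- sort(rows)[-seq_len(discard_volumes)]
    X[i, ] <- colMeans(ts$data[keep, , drop = FALSE])
    run_b[i] <- m$run[first[i]]
    cond_b[i] <- m$condition[first[i]]
    used_b[i] <- length(keep)
  }
  meta <- tibble(subject = ts$subject, roi = ts$roi,
                 hemisphere = ts$hemisphere, run = run_b,
                 miniblock_id = ids, condition = cond_b,
                 n_volumes_used = used_b)
  structure(list(X = X, meta = meta), class = "miniblock_samples")
}

#' @export
print.miniblock_samples <- function(x, ...) {
  cat(sprintf("<miniblock_samples> %d samples x %d voxels (%s / %s)\n",
              nrow(x$X), ncol(x$X), x$meta$subject[1], x$meta$roi[1]))
  print(table(x$meta$condition))
  invisible(x)
}

#' Select and label samples for one classification
#'
#' Keeps only mini-blocks whose condition belongs to either condition set of
#' the classification and labels them +1 / -1.
#'
#' @param samples A [build_samples()] result.
#' @param spec A [classification_spec()], or the id of one of the built-in
#'   six (see [classification_specs()]).
#' @return An object of class `sample_set`: `X`, `labels` (+1/-1), `meta`,
#'   `classification`, `n_pos`, `n_neg`.
#' @export
select_classification <- function(samples, spec) {
  if (is.character(spec)) spec <- get_classification_spec(spec)
  present <- unique(samples$meta$condition)
  missing <- setdiff(c(spec$positive, spec$negative), present)
  if (length(missing)) {
    abort(sprintf("Condition(s) %s absent from the samples.",
                  paste(missing, collapse = ", ")))
  }
  keep <- samples$meta$condition %in% c(spec$positive, spec$negative)
  meta <- samples$meta[keep, ]
  labels <- ifelse(meta$condition %in% spec$positive, 1, -1)
  if (!any(labels == 1) || !any(labels == -1)) {
    abort("A class is empty after selection.")
  }
  structure(list(X = samples$X[keep, , drop = FALSE],
                 labels = labels, meta = meta,
                 classification = spec$name,
                 n_pos = sum(labels == 1), n_neg = sum(labels == -1)),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> '%s': %d samples (%d +1 / %d -1) x %d voxels\n",
              x$classification, length(x$labels), x$n_pos, x$n_neg,
              ncol(x$X)))
  invisible(x)
}
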