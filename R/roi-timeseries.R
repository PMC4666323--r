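#' ROI time-series container
#'
#' A time x voxel matrix for one ROI of one subject, with per-volume run
#' labels. Rows are ordered run-major (all volumes of run 1, then run 2,
#' ...); columns follow a fixed, documented voxel order (ascending linear
#' voxel index when extracted from an image).
#'
#' @param data Numeric time x voxel matrix.
#' @param run Integer vector of run labels, one per row.
#' @param tr Repetition time (s).
#' @param roi ROI label.
#' @param subject Subject label.
#' @param hemisphere Hemisphere label (`"L"`, `"R"` or `"none"`).
#' @param truth Optional [pattern_model()] used to generate the data
#'   (ground-truth for recovery tests).
#' @return An object of class `roi_ts`.
#' @export
roi_ts <- function(data, run, tr, roi = "roi", subject = "sub-01",
                   hemisphere = "none", truth = NULL) {
  data <- as.matrix(data)
  if (length(run) != nrow(data)) {
    abort("`run` must have one label per row of `data`.")
  }
  if (anyNA(data)) abort("`data` must not contain missing values.")
  structure(list(data = data, run = as.integer(run), tr = tr,
                 roi = roi, subject = subject, hemisphere = hemisphere,
                 truth = truth),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> %s / %s (%s): %d volumes x %d voxels, %d run(s), TR %g s\n",
              x$subject, x$roi, x$hemisphere, nrow(x$data), ncol(x$data),
              length(unique(x$run)), x$tr))
  invisible(x)
}

#' @export
as_tibble.roi_ts <- function(x, ...) {
  tb <- tibble(subject = x$subject, roi = x$roi, hemisphere = x$hemisphere,
               run = x$run,
               volume = stats::ave(x$run, x$run, FUN = seq_along),
               time = NA_real_)
  tb$time <- (tb$volume - 1) * x$tr
  dat <- as_tibble(as.data.frame(x$data), .name_repair = "minimal")
  names(dat) <- paste0("v", seq_len(ncol(x$data)))
  dplyr::bind_cols(tb, dat)
}

# rows of `ts` belonging to run r, in order
run_rows <- function(ts, r) which(ts$run == r)

# apply f(run_matrix, run_index) runwise and reassemble; f returns a matrix
# of identical shape
map_runs <- function(ts, f) {
  out <- ts$data
  for (r in unique(ts$run)) {
    idx <- run_rows(ts, r)
    out[idx, ] <- f(ts$data[idx, , drop = FALSE], r)
  }
  ts$data <- out
  ts
}
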