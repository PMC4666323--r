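#' Train a linear soft-margin SVM
#'
#' Solves the standard C-SVM objective (libsvm via \pkg{e1071}) with a
#' linear kernel and no internal feature scaling, and returns the decision
#' function `f(x) = w . x + b` in explicit form. Prediction is `sign(f)`,
#' with `f = 0` assigned to the positive class (a measure-zero tie-break).
#'
#' @param X Training matrix (samples x features).
#' @param labels Numeric labels in `{+1, -1}`; both classes must be present.
#' @param C Soft-margin cost (the experiment fixes `C = 1`).
#' @return An object of class `linear_svm` with elements `w`, `b`.
#' @examples
#' fit <- train_linear_svm(matrix(c(1, 3, -1, -3)), c(1, 1, -1, -1))
#' fit$w; fit$b
#' @export
train_linear_svm <- function(X, labels, C = 1) {
  X <- as.matrix(X)
  if (!all(labels %in% c(-1, 1))) abort("`labels` must be +1 / -1.")
  if (length(unique(labels)) < 2) {
    abort("Both classes must be present in the training set.")
  }
  y <- factor(labels, levels = c(1, -1))
  fit <- e1071::svm(X, y, kernel = "linear", cost = C, scale = FALSE,
                    type = "C-classification")
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients decision values toward the class of the first training
  # sample; normalize so f > 0 always means the +1 class
  first_class <- fit$levels[fit$labels[1]]
  if (first_class == "-1") {
    w <- -w
    b <- -b
  }
  structure(list(w = w, b = b, C = C), class = "linear_svm")
}

#' Evaluate a linear SVM decision function
#'
#' @param object A `linear_svm` fit.
#' @param newdata Matrix of samples to classify.
#' @param type `"class"` for +1/-1 predictions, `"decision"` for raw
#'   `w . x + b` values.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.linear_svm <- function(object, newdata, type = c("class", "decision"),
                               ...) {
  type <- match.arg(type)
  f <- drop(as.matrix(newdata) %*% object$w + object$b)
  if (type == "decision") f else ifelse(f >= 0, 1, -1)
}

#' Leave-one-pair-out cross-validated decoding accuracy
#'
#' The modified leave-one-out scheme of the experiment: samples are split
#' into per-class sequences in chronological (run, mini-block) order; fold
#' `k` holds out the k-th positive and k-th negative sample, trains the
#' linear SVM on all remaining samples, and tests on the held-out pair.
#' Accuracy is the proportion of correct test predictions over the whole
#' loop (`2 x n_folds` predictions). Classes must be balanced.
#'
#' @param samples A [select_classification()] sample set.
#' @param C Soft-margin cost.
#' @param pairing `"chronological"` (default) pairs k-th with k-th in
#'   chronological order; `"random"` pairs positives with a seeded random
#'   permutation of negatives.
#' @param seed Seed for `pairing = "random"`.
#' @return One-row tibble: `subject`, `roi`, `hemisphere`, `classification`,
#'   `accuracy`, `n_folds`, `n_samples`.
#' @export
leave_pair_out_cv <- function(samples, C = 1,
                              pairing = c("chronological", "random"),
                              seed = NULL) {
  pairing <- match.arg(pairing)
  if (samples$n_pos != samples$n_neg) {
    abort(sprintf(
      "Leave-pair-out CV requires balanced classes (got %d vs %d).",
      samples$n_pos, samples$n_neg))
  }
  ord <- order(samples$meta$run, samples$meta$miniblock_id)
  X <- samples$X[ord, , drop = FALSE]
  labels <- samples$labels[ord]
  pos <- which(labels == 1)
  neg <- which(labels == -1)
  if (pairing == "random") {
    neg <- with_seed_if(seed, sample(neg))
  }
  n_folds <- length(pos)
  correct <- 0L
  for (k in seq_len(n_folds)) {
    test <- c(pos[k], neg[k])
    fit <- train_linear_svm(X[-test, , drop = FALSE], labels[-test], C = C)
    pred <- predict(fit, X[test, , drop = FALSE])
    correct <- correct + sum(pred == labels[test])
  }
  tibble(subject = samples$meta$subject[1],
         roi = samples$meta$roi[1],
         hemisphere = samples$meta$hemisphere[1],
         classification = samples$classification,
         accuracy = correct / (2 * n_folds),
         n_folds = n_folds,
         n_samples = length(labels))
}

#' Decode every (subject, ROI, hemisphere, classification) cell
#'
#' Maps [leave_pair_out_cv()] over a table of sample sets. Cells whose CV
#' fails (e.g. unbalanced classes) are logged, skipped, and listed in the
#' `gaps` attribute of the result.
#'
#' @param sample_sets A tibble with a list-column `samples` of
#'   [select_classification()] sample sets (one per cell).
#' @param C Soft-margin cost.
#' @return Tibble with one row per cell: `subject`, `roi`, `hemisphere`,
#'   `classification`, `accuracy`, `n_folds`, `n_samples`; attribute
#'   `gaps` lists skipped cells with the error message.
#' @export
decode_all <- function(sample_sets, C = 1) {
  stopifnot(is.data.frame(sample_sets), "samples" %in% names(sample_sets))
  rows <- vector("list", nrow(sample_sets))
  gaps <- list()
  for (i in seq_len(nrow(sample_sets))) {
    res <- tryCatch(leave_pair_out_cv(sample_sets$samples[[i]], C = C),
                    error = function(e) e)
    if (inherits(res, "error")) {
      ss <- sample_sets$samples[[i]]
      gap <- tibble(subject = ss$meta$subject[1], roi = ss$meta$roi[1],
                    hemisphere = ss$meta$hemisphere[1],
                    classification = ss$classification,
                    message = conditionMessage(res))
      gaps[[length(gaps) + 1]] <- gap
      inform(sprintf("Skipping cell %s/%s/%s/%s: %s",
                     gap$subject, gap$roi, gap$hemisphere,
                     gap$classification, gap$message))
    } else {
      rows[[i]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "gaps") <- dplyr::bind_rows(gaps)
  out
}
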