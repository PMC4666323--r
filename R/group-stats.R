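#' One-sample t-test of decoding accuracy against chance
#'
#' One-tailed test of `mean(accuracy) > chance` with
#' `t = (mean - chance) / (sd / sqrt(n))` and `df = n - 1`. A zero-variance
#' input yields an infinite (or undefined) statistic flagged as degenerate
#' rather than failing silently.
#'
#' @param accuracies Per-subject accuracy vector (length >= 2, finite).
#' @param chance Chance level (0.5 for balanced two-class decoding).
#' @return One-row tibble: `n`, `mean_accuracy`, `sem`, `statistic`, `df`,
#'   `p_one_tailed`, `degenerate`.
#' @examples
#' ttest_vs_chance(c(0.55, 0.6, 0.65, 0.5))
#' @export
ttest_vs_chance <- function(accuracies, chance = 0.5) {
  if (length(accuracies) < 2 || !all(is.finite(accuracies))) {
    abort("`accuracies` must be >= 2 finite values.")
  }
  n <- length(accuracies)
  m <- mean(accuracies)
  s <- sd(accuracies)
  sem <- s / sqrt(n)
  if (s == 0) {
    # zero spread: t is 0/0 at chance (reported as 0, p = 0.5) or +/-Inf
    stat <- if (m == chance) 0 else sign(m - chance) * Inf
    p <- if (m > chance) 0 else if (m < chance) 1 else 0.5
    return(tibble(n = n, mean_accuracy = m, sem = 0, statistic = stat,
                  df = n - 1, p_one_tailed = p, degenerate = m != chance))
  }
  stat <- (m - chance) / sem
  tibble(n = n, mean_accuracy = m, sem = sem, statistic = stat,
         df = n - 1, p_one_tailed = pt(stat, n - 1, lower.tail = FALSE),
         degenerate = FALSE)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure at level `q`. Alongside the rejection flags, the
#' realized "corrected alpha" is reported in the field's idiom: the largest
#' raw p-value that is still rejected (undefined when nothing is rejected).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return List with `rejected` (logical), `p_adjusted`,
#'   `corrected_alpha` (`NA` if no rejection) and `q`.
#' @examples
#' fdr_bh(c(0.001, 0.02, 0.04, 0.2))
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("`p` must be p-values in [0, 1].")
  }
  adj <- p.adjust(p, method = "BH")
  rejected <- adj <= q
  list(rejected = rejected, p_adjusted = adj,
       corrected_alpha = if (any(rejected)) max(p[rejected]) else NA_real_,
       q = q)
}

#' Group t-tests against chance for every ROI cell, FDR-corrected
#'
#' Runs [ttest_vs_chance()] across subjects for each (ROI, hemisphere) cell
#' of each classification, then applies [fdr_bh()] within each
#' classification's family of tests.
#'
#' @param decoding Tibble from [decode_all()].
#' @param chance Chance level.
#' @param q FDR level.
#' @param include_control Whether control-ROI tests belong to the FDR
#'   family (`TRUE`, the default) or are reported uncorrected.
#' @param control_roi Label of the control ROI.
#' @return Tibble with one row per cell: group test fields plus
#'   `fdr_rejected`, `corrected_alpha` and `q`.
#' @export
group_ttests <- function(decoding, chance = 0.5, q = 0.05,
                         include_control = TRUE, control_roi = "Control") {
  res <- decoding |>
    dplyr::group_by(classification, roi, hemisphere) |>
    dplyr::summarise(ttest_vs_chance(accuracy, chance = chance),
                     .groups = "drop")
  out <- vector("list", 0)
  for (cl in unique(res$classification)) {
    block <- res[res$classification == cl, ]
    in_family <- if (include_control) rep(TRUE, nrow(block))
                 else block$roi != control_roi
    block$fdr_rejected <- FALSE
    block$corrected_alpha <- NA_real_
    if (any(in_family)) {
      fam <- fdr_bh(block$p_one_tailed[in_family], q = q)
      block$fdr_rejected[in_family] <- fam$rejected
      block$corrected_alpha <- fam$corrected_alpha
    }
    block$q <- q
    out[[length(out) + 1]] <- block
  }
  dplyr::bind_rows(out)
}

# Extract effects from an aov() fit with Error() strata: F, dfs, SS and
# partial eta^2 (SS_effect / (SS_effect + SS_error of the same stratum)).
extract_rm_effects <- function(fit) {
  strata <- summary(fit)
  rows <- list()
  for (s in strata) {
    tab <- s[[1]]
    terms <- trimws(rownames(tab))
    resid_row <- which(terms == "Residuals")
    if (!length(resid_row)) next
    ss_err <- tab[resid_row, "Sum Sq"]
    df_err <- tab[resid_row, "Df"]
    for (i in setdiff(seq_len(nrow(tab)), resid_row)) {
      ss <- tab[i, "Sum Sq"]
      rows[[length(rows) + 1]] <- tibble(
        effect = gsub(":", " x ", terms[i]),
        df_num = tab[i, "Df"], df_den = df_err,
        sum_sq = ss, sum_sq_error = ss_err,
        statistic = tab[i, "F value"], p_value = tab[i, "Pr(>F)"],
        partial_eta_sq = if (ss + ss_err > 0) ss / (ss + ss_err) else 0)
    }
  }
  dplyr::bind_rows(rows)
}

#' Two-way repeated-measures ANOVA: ROI x hemisphere
#'
#' Within-subject ANOVA of decoding accuracy on ROI and hemisphere
#' (sphericity assumed, matching the uncorrected degrees of freedom
#' convention: `df = (levels - 1, (levels - 1)(n - 1))`), with partial eta
#' squared per effect and FDR-corrected paired post-hoc t-tests on the ROI
#' factor.
#'
#' @param data Tibble with columns `subject`, `roi`, `hemisphere`,
#'   `accuracy`; the design must be completely crossed within subjects.
#' @param posthoc_factor Factor for paired post-hocs (`"roi"` by default;
#'   `NULL` to skip).
#' @param q FDR level for the post-hocs.
#' @return An object of class `rm_anova_result` with `effects`, `posthoc`
#'   and `data` fields; see [tidy()][generics::tidy].
#' @export
rm_anova_roi_hemisphere <- function(data, posthoc_factor = "roi", q = 0.05) {
  check_complete_design(data, c("roi", "hemisphere"))
  df <- data
  df$subject <- factor(df$subject)
  df$roi <- factor(df$roi)
  df$hemisphere <- factor(df$hemisphere)
  fit <- aov(accuracy ~ roi * hemisphere +
               Error(subject / (roi * hemisphere)), data = df)
  effects <- extract_rm_effects(fit)
  posthoc <- if (!is.null(posthoc_factor)) {
    paired_ttests_fdr(df, factor = posthoc_factor, q = q)
  }
  structure(list(effects = effects, posthoc = posthoc, data = df,
                 formula = "accuracy ~ roi * hemisphere, within subjects"),
            class = "rm_anova_result")
}

check_complete_design <- function(data, factors) {
  need <- c("subject", factors, "accuracy")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(paste0("Missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (length(unique(data$subject)) < 2) abort("Need at least 2 subjects.")
  counts <- data |>
    dplyr::count(dplyr::across(dplyr::all_of(c("subject", factors))))
  n_cells <- prod(vapply(factors, function(f) length(unique(data[[f]])),
                         numeric(1)))
  if (any(counts$n != 1) ||
      nrow(counts) != length(unique(data$subject)) * n_cells) {
    abort("Design must be completely crossed with one observation per cell.")
  }
  invisible(TRUE)
}

#' Pairwise paired t-tests on one factor, FDR-corrected
#'
#' Accuracy is first averaged within subject over the other factors; every
#' pair of factor levels is then compared with a paired t-test and the
#' family is corrected with Benjamini-Hochberg FDR.
#'
#' @param data Tibble with `subject`, the factor column, `accuracy` (and
#'   possibly other factors, collapsed over).
#' @param factor Name of the factor column.
#' @param q FDR level.
#' @return Tibble: `level_1`, `level_2`, `mean_1`, `mean_2`, `statistic`,
#'   `df`, `p_value`, `fdr_rejected`, `corrected_alpha`.
#' @export
paired_ttests_fdr <- function(data, factor = "roi", q = 0.05) {
  collapsed <- data |>
    dplyr::group_by(subject, .level = .data[[factor]]) |>
    dplyr::summarise(accuracy = mean(accuracy), .groups = "drop")
  wide <- tidyr::pivot_wider(collapsed, names_from = ".level",
                             values_from = "accuracy")
  levels <- setdiff(names(wide), "subject")
  pairs <- utils::combn(levels, 2)
  rows <- vector("list", ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- wide[[pairs[1, i]]]; b <- wide[[pairs[2, i]]]
    d <- a - b
    n <- length(d)
    sdd <- sd(d)
    stat <- if (sdd == 0) {
      if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    } else mean(d) / (sdd / sqrt(n))
    p <- if (is.finite(stat)) 2 * pt(abs(stat), n - 1, lower.tail = FALSE)
         else if (is.nan(stat)) NA_real_ else 0
    rows[[i]] <- tibble(level_1 = pairs[1, i], level_2 = pairs[2, i],
                        mean_1 = mean(a), mean_2 = mean(b),
                        statistic = stat, df = n - 1, p_value = p)
  }
  out <- dplyr::bind_rows(rows)
  fam <- fdr_bh(out$p_value, q = q)
  out$fdr_rejected <- fam$rejected
  out$corrected_alpha <- fam$corrected_alpha
  out
}

#' One-way repeated-measures ANOVA across classifications, with linear
#' contrast
#'
#' Tests whether decoding accuracy differs across the (three) classification
#' levels within subjects, and whether it increases linearly across them:
#' the linear contrast applies weights `(-1, 0, +1)` (for three levels) to
#' each subject's level means and tests the resulting scores against zero
#' (`F = t^2`, `df = (1, n - 1)`).
#'
#' @param data Tibble with `subject`, `classification`, `accuracy`; one
#'   observation per subject x classification (average over ROIs first if
#'   needed).
#' @param level_order Order of classification levels for the contrast
#'   (defaults to order of appearance).
#' @param contrast_weights Contrast weights, one per level.
#' @return An `rm_anova_result` whose `effects` table carries the
#'   classification main effect and the linear contrast; `$scores` holds the
#'   per-subject contrast scores.
#' @export
rm_anova_classification_contrast <- function(data, level_order = NULL,
                                             contrast_weights = NULL) {
  check_complete_design(data, "classification")
  levels <- level_order %||% unique(data$classification)
  if (!setequal(levels, unique(data$classification))) {
    abort("`level_order` must list exactly the classification levels.")
  }
  if (is.null(contrast_weights)) {
    k <- length(levels)
    contrast_weights <- seq_len(k) - (k + 1) / 2   # -1, 0, +1 for k = 3
  }
  if (length(contrast_weights) != length(levels)) {
    abort("One contrast weight per level is required.")
  }
  df <- data
  df$subject <- factor(df$subject)
  df$classification <- factor(df$classification, levels = levels)
  fit <- aov(accuracy ~ classification + Error(subject / classification),
             data = df)
  effects <- extract_rm_effects(fit)
  wide <- tidyr::pivot_wider(df, id_cols = "subject",
                             names_from = "classification",
                             values_from = "accuracy")
  M <- as.matrix(wide[, levels])
  scores <- drop(M %*% contrast_weights)
  n <- length(scores)
  sem <- sd(scores) / sqrt(n)
  tstat <- if (sem == 0) {
    if (mean(scores) == 0) 0 else sign(mean(scores)) * Inf
  } else mean(scores) / sem
  Fstat <- tstat^2
  p <- if (is.finite(Fstat)) stats::pf(Fstat, 1, n - 1, lower.tail = FALSE)
       else 0
  contrast_row <- tibble(effect = "linear contrast",
                         df_num = 1, df_den = n - 1,
                         sum_sq = NA_real_, sum_sq_error = NA_real_,
                         statistic = Fstat, p_value = p,
                         partial_eta_sq = if (is.finite(Fstat))
                           Fstat / (Fstat + (n - 1)) else 1)
  structure(list(effects = dplyr::bind_rows(effects, contrast_row),
                 scores = tibble(subject = wide$subject, score = scores),
                 weights = stats::setNames(contrast_weights, levels),
                 data = df,
                 formula = "accuracy ~ classification, within subjects"),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat("<rm_anova_result>", x$formula, "\n")
  print(as.data.frame(x$effects), digits = 4)
  if (!is.null(x$posthoc)) {
    cat(sprintf("Post-hoc paired t-tests: %d pairs, %d FDR-significant\n",
                nrow(x$posthoc), sum(x$posthoc$fdr_rejected)))
  }
  invisible(x)
}
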