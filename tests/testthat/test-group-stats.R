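test_that("one-sample t against chance matches the closed form", {
  # all at chance: t = 0, one-tailed p = 0.5
  flat <- ttest_vs_chance(rep(0.5, 8))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_one_tailed, 0.5)
  expect_equal(flat$df, 7)

  # arbitrary vector vs the textbook formula, to 1e-10
  acc <- c(0.52, 0.61, 0.55, 0.47, 0.66, 0.58, 0.71, 0.49,
           0.53, 0.62, 0.57, 0.60, 0.51, 0.64, 0.56, 0.59)
  got <- ttest_vs_chance(acc)
  n <- length(acc)
  t_exp <- (mean(acc) - 0.5) / (sd(acc) / sqrt(n))
  expect_equal(got$statistic, t_exp, tolerance = 1e-10)
  expect_equal(got$p_one_tailed, pt(t_exp, n - 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(got$sem, sd(acc) / sqrt(n), tolerance = 1e-10)
  # agrees with stats::t.test
  ref <- t.test(acc, mu = 0.5, alternative = "greater")
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p_one_tailed, ref$p.value, tolerance = 1e-10)

  # zero variance is flagged, not silently propagated
  degen <- ttest_vs_chance(rep(0.6, 5))
  expect_true(degen$degenerate)
  expect_identical(degen$statistic, Inf)
})

test_that("BH-FDR matches a brute-force step-up enumeration", {
  bh_oracle <- function(p, q) {
    # largest k with p_(k) <= k q / m; reject all p <= that threshold
    m <- length(p)
    ps <- sort(p)
    ks <- which(ps <= seq_len(m) * q / m)
    if (!length(ks)) return(rep(FALSE, m))
    p <= ps[max(ks)]
  }
  cases <- list(c(0.001, 0.02, 0.04, 0.2), c(0.01), rep(1, 5),
                c(0.012, 0.013, 0.014, 0.8, 0.9),
                c(0.04, 0.045, 0.05, 0.051), runif(20))
  set.seed(20)
  for (p in cases) {
    got <- fdr_bh(p, q = 0.05)
    expect_identical(got$rejected, bh_oracle(p, 0.05))
    if (any(got$rejected)) {
      expect_equal(got$corrected_alpha, max(p[got$rejected]))
    } else {
      expect_true(is.na(got$corrected_alpha))
    }
  }
  expect_true(fdr_bh(0.01, q = 0.05)$rejected)
  expect_equal(fdr_bh(0.01)$corrected_alpha, 0.01)
})

test_that("BH-FDR is monotone and never beats uncorrected testing", {
  set.seed(21)
  for (i in 1:20) {
    p <- runif(15)^2
    r <- fdr_bh(p, q = 0.05)$rejected
    expect_true(all(p[r] <= 0.05))           # rejects only nominal-level ps
    r2 <- fdr_bh(p / 2, q = 0.05)$rejected   # lowering p cannot drop rejections
    expect_true(all(!r | r2))
    expect_true(sum(r2) >= sum(r))
  }
})

test_that("ROI x hemisphere RM-ANOVA reproduces a manual sums-of-squares oracle", {
  # 2 x 2 within-subject toy with 4 subjects, worked by hand from cell data
  set.seed(22)
  d <- tidyr::expand_grid(subject = paste0("s", 1:4),
                          roi = c("r1", "r2"), hemisphere = c("L", "R"))
  d$accuracy <- round(runif(nrow(d), 0.4, 0.9), 2)

  res <- rm_anova_roi_hemisphere(d, posthoc_factor = NULL)
  eff <- res$effects

  # independent oracle: classical within-subject SS decomposition
  Y <- array(d$accuracy[order(d$subject, d$roi, d$hemisphere)],
             dim = c(2, 2, 4))  # hemisphere x roi x subject (sorted order)
  grand <- mean(Y)
  m_r <- apply(Y, 2, mean); m_h <- apply(Y, 1, mean)
  m_s <- apply(Y, 3, mean)
  m_rs <- apply(Y, c(2, 3), mean); m_hs <- apply(Y, c(1, 3), mean)
  m_rh <- apply(Y, c(1, 2), mean)
  n_s <- 4
  ss_r <- n_s * 2 * sum((m_r - grand)^2)
  ss_h <- n_s * 2 * sum((m_h - grand)^2)
  ss_rs <- 2 * sum(sweep(sweep(m_rs, 1, m_r), 2, m_s - grand)^2)
  ss_hs <- 2 * sum(sweep(sweep(m_hs, 1, m_h), 2, m_s - grand)^2)
  ss_rh <- n_s * sum((m_rh - outer(m_h - grand, m_r - grand, "+") - grand)^2)
  ss_rhs <- 0
  for (s in 1:4) {
    for (h in 1:2) for (r in 1:2) {
      ss_rhs <- ss_rhs + (Y[h, r, s] - m_rh[h, r] - m_rs[r, s] - m_hs[h, s] +
                            m_r[r] + m_h[h] + m_s[s] - grand)^2
    }
  }
  F_r <- (ss_r / 1) / (ss_rs / 3)
  F_h <- (ss_h / 1) / (ss_hs / 3)
  F_rh <- (ss_rh / 1) / (ss_rhs / 3)

  expect_equal(eff$statistic[eff$effect == "roi"], F_r, tolerance = 1e-10)
  expect_equal(eff$statistic[eff$effect == "hemisphere"], F_h,
               tolerance = 1e-10)
  expect_equal(eff$statistic[eff$effect == "roi x hemisphere"], F_rh,
               tolerance = 1e-10)
  expect_equal(eff$partial_eta_sq[eff$effect == "roi"],
               ss_r / (ss_r + ss_rs), tolerance = 1e-10)
  expect_equal(eff$df_num, c(1, 1, 1))
  expect_equal(eff$df_den, c(3, 3, 3))
  expect_true(all(eff$partial_eta_sq >= 0 & eff$partial_eta_sq <= 1))
})

test_that("the 7 ROI x 2 hemisphere x 16 subject design has df (6, 90)", {
  set.seed(23)
  d <- tidyr::expand_grid(subject = sprintf("s%02d", 1:16),
                          roi = paste0("roi", 1:7),
                          hemisphere = c("L", "R"))
  d$accuracy <- runif(nrow(d), 0.45, 0.75)
  eff <- tidy(rm_anova_roi_hemisphere(d))
  roi_row <- eff[eff$effect == "roi", ]
  expect_equal(c(roi_row$df_num, roi_row$df_den), c(6, 90))
  hemi_row <- eff[eff$effect == "hemisphere", ]
  expect_equal(c(hemi_row$df_num, hemi_row$df_den), c(1, 15))
  inter <- eff[eff$effect == "roi x hemisphere", ]
  expect_equal(c(inter$df_num, inter$df_den), c(6, 90))

  # removing the ROI marginal means kills the ROI main effect
  d2 <- d |>
    dplyr::group_by(roi) |>
    dplyr::mutate(accuracy = accuracy - mean(accuracy) + 0.6) |>
    dplyr::ungroup()
  eff2 <- tidy(rm_anova_roi_hemisphere(d2))
  expect_lt(eff2$statistic[eff2$effect == "roi"], 1e-12)
  expect_lt(eff2$partial_eta_sq[eff2$effect == "roi"], 1e-12)
})

test_that("paired post-hocs cover all pairs and match one-sample t on differences", {
  set.seed(24)
  d <- tidyr::expand_grid(subject = paste0("s", 1:10),
                          roi = paste0("r", 1:7), hemisphere = c("L", "R"))
  d$accuracy <- runif(nrow(d), 0.4, 0.8)
  ph <- paired_ttests_fdr(d, factor = "roi", q = 0.05)
  expect_equal(nrow(ph), choose(7, 2))

  # pick one pair: paired t equals one-sample t on within-subject diffs
  collapsed <- d |>
    dplyr::group_by(subject, roi) |>
    dplyr::summarise(accuracy = mean(accuracy), .groups = "drop")
  a <- collapsed$accuracy[collapsed$roi == "r1"]
  b <- collapsed$accuracy[collapsed$roi == "r2"]
  ref <- t.test(a - b, mu = 0)
  row <- ph[ph$level_1 == "r1" & ph$level_2 == "r2", ]
  expect_equal(row$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(row$p_value, ref$p.value, tolerance = 1e-10)

  # duplicating a level gives t = 0 for that pair
  d3 <- dplyr::bind_rows(
    d, dplyr::mutate(d[d$roi == "r1", ], roi = "r8"))
  ph3 <- paired_ttests_fdr(d3, factor = "roi")
  expect_equal(ph3$statistic[ph3$level_1 == "r1" & ph3$level_2 == "r8"], 0)
})

test_that("classification RM-ANOVA detects a planted linear trend", {
  # equal level means: both the main effect and the contrast vanish
  set.seed(27)
  d0 <- tidyr::expand_grid(subject = paste0("s", 1:6),
                           classification = c("a", "b", "c"))
  eps <- matrix(rnorm(18, sd = 0.05), 6, 3)
  eps <- sweep(eps, 2, colMeans(eps))  # every level mean exactly 0.6
  d0$accuracy <- 0.6 + as.vector(t(eps))
  r0 <- rm_anova_classification_contrast(d0, level_order = c("a", "b", "c"))
  expect_lt(r0$effects$statistic[r0$effects$effect == "classification"],
            1e-12)
  expect_lt(abs(r0$effects$statistic[r0$effects$effect == "linear contrast"]),
            1e-12)

  # per-subject means (0.55, 0.65, 0.75) + small noise: strong increase
  set.seed(25)
  d1 <- tidyr::expand_grid(subject = sprintf("s%02d", 1:16),
                           classification = c("a", "b", "c"))
  d1$accuracy <- rep(c(0.55, 0.65, 0.75), times = 16) +
    rnorm(nrow(d1), sd = 0.03)
  r1 <- rm_anova_classification_contrast(d1, level_order = c("a", "b", "c"))
  contrast <- r1$effects[r1$effects$effect == "linear contrast", ]
  expect_lt(contrast$p_value, 0.01)
  expect_equal(c(contrast$df_num, contrast$df_den), c(1, 15))

  # the contrast score is exactly -m1 + m3 per subject
  wide <- tidyr::pivot_wider(d1, names_from = classification,
                             values_from = accuracy)
  expect_equal(r1$scores$score, wide$c - wide$a, tolerance = 1e-12)

  # and the contrast F equals the squared one-sample t on the scores
  tref <- t.test(r1$scores$score, mu = 0)
  expect_equal(contrast$statistic, unname(tref$statistic)^2,
               tolerance = 1e-10)
})

test_that("group_ttests applies the FDR family per classification", {
  set.seed(26)
  cells <- tidyr::expand_grid(subject = sprintf("s%02d", 1:16),
                              roi = c("A", "B", "Control"),
                              hemisphere = "L",
                              classification = c("c1", "c2"))
  cells$accuracy <- ifelse(cells$roi != "Control" &
                             cells$classification == "c1",
                           rnorm(nrow(cells), 0.7, 0.05),
                           rnorm(nrow(cells), 0.5, 0.05))
  g <- group_ttests(cells, q = 0.05)
  expect_equal(nrow(g), 6)
  sig <- g[g$classification == "c1" & g$roi != "Control", ]
  expect_true(all(sig$fdr_rejected))
  # family corrected alpha is the largest rejected raw p
  fam <- g[g$classification == "c1", ]
  expect_equal(unique(fam$corrected_alpha),
               max(fam$p_one_tailed[fam$fdr_rejected]))

  # control can be excluded from the family
  g2 <- group_ttests(cells, q = 0.05, include_control = FALSE)
  ctrl <- g2[g2$roi == "Control", ]
  expect_true(all(!ctrl$fdr_rejected))
})
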