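# Mixed-design ANOVA, simple main effects, pooled t-test, Bonferroni.

# Simulated participant x AOI metrics table.
sim_metrics <- function(n_expert = 7, n_novice = 17, seed = 1,
                        group_shift = 0, sd_p = 2, sd_e = 2) {
  set.seed(seed)
  n <- n_expert + n_novice
  grp <- rep(c("expert", "novice"), c(n_expert, n_novice))
  out <- tidyr::crossing(participant = seq_len(n), aoi = aoi_names())
  out$group <- grp[out$participant]
  intercept <- stats::rnorm(n, 0, sd_p)[out$participant]
  out$total_duration_pct <- 10 + intercept +
    stats::rnorm(nrow(out), 0, sd_e) +
    ifelse(out$group == "expert" & out$aoi == "head", group_shift, 0)
  out
}

test_that("the split-plot design yields the classical dfs", {
  fit <- mixed_anova(sim_metrics(7, 17))
  tab <- tidy(fit)
  expect_equal(tab$df1, c(1, 5, 5))
  expect_equal(tab$df2, c(22, 110, 110))
  expect_equal(tab$term, c("group", "aoi", "group:aoi"))
  g <- glance(fit)
  expect_equal(g$n_participants, 24)
})

test_that("identical group profiles give a between-group F of zero", {
  m <- sim_metrics(3, 3, seed = 2)
  # mirror expert participants' data onto the novices
  wide <- tidyr::pivot_wider(m, names_from = "aoi",
                             values_from = "total_duration_pct")
  for (a in aoi_names()) {
    vals <- wide[[a]][wide$group == "expert"]
    wide[[a]][wide$group == "novice"] <- vals
  }
  m2 <- tidyr::pivot_longer(wide, dplyr::all_of(aoi_names()),
                            names_to = "aoi",
                            values_to = "total_duration_pct")
  fit <- mixed_anova(m2)
  expect_equal(tidy(fit)$statistic[1], 0, tolerance = 1e-10)
})

test_that("F statistics equal a from-scratch sums-of-squares decomposition", {
  m <- sim_metrics(3, 3, seed = 7, group_shift = 4)
  fit <- mixed_anova(m)
  tab <- tidy(fit)

  # independent oracle: direct SS computation for the balanced split-plot
  y <- m$total_duration_pct
  n <- length(unique(m$participant))
  k <- 6
  grand <- mean(y)
  p_means <- tapply(y, m$participant, mean)
  g_of_p <- tapply(m$group, m$participant, function(g) g[1])
  g_means <- tapply(y, m$group, mean)
  a_means <- tapply(y, m$aoi, mean)
  ga_means <- tapply(y, list(m$group, m$aoi), mean)
  n_g <- table(g_of_p)

  ss_group <- sum(k * n_g * (g_means[names(n_g)] - grand)^2)
  ss_subj <- k * sum((p_means - g_means[as.character(g_of_p)])^2)
  ss_aoi <- n * sum((a_means - grand)^2)
  ss_ga <- sum(rep(n_g, times = k) *
                 (t(ga_means) - outer(a_means, rep(1, 2)) -
                    outer(rep(1, k), g_means) + grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_group - ss_subj - ss_aoi - ss_ga

  df_subj <- n - 2
  df_err <- (k - 1) * (n - 2)
  F_group <- (ss_group / 1) / (ss_subj / df_subj)
  F_aoi <- (ss_aoi / (k - 1)) / (ss_err / df_err)
  F_ga <- (ss_ga / (k - 1)) / (ss_err / df_err)

  expect_equal(tab$statistic, c(F_group, F_aoi, F_ga), tolerance = 1e-8)
  # the SS decomposition partitions the total exactly
  expect_equal(ss_group + ss_subj + ss_aoi + ss_ga + ss_err, ss_tot,
               tolerance = 1e-8)
  expect_equal(sum(tab$ss) + ss_subj + ss_err, ss_tot, tolerance = 1e-8)
})

test_that("simple main effects use the pooled error term", {
  m <- sim_metrics(4, 5, seed = 3, group_shift = 6)
  fit <- mixed_anova(m)
  se <- fit$simple_effects
  expect_equal(nrow(se), 6)
  # one shared pooled-error df across AOIs, Satterthwaite-bounded by the
  # stratum dfs
  expect_length(unique(se$df2), 1)
  expect_gte(unique(se$df2), min(9 - 2, 5 * (9 - 2)))
  expect_lte(unique(se$df2), (9 - 2) + 5 * (9 - 2))
  # the shifted AOI shows the largest effect
  expect_equal(se$aoi[which.max(se$statistic)], "head")
})

test_that("participants with missing cells are excluded listwise", {
  m <- sim_metrics(7, 17, seed = 4)
  m$total_duration_pct[m$participant == 3 & m$aoi == "foot"] <- NA
  fit <- mixed_anova(m)
  expect_equal(fit$excluded, "3")
  expect_equal(tidy(fit)$df2, c(21, 105, 105))
  expect_error(mixed_anova(sim_metrics(1, 5)), "at least 2",
               class = "standgaze_validation_error")
})

test_that("pairwise AOI comparisons are Bonferroni adjusted within group", {
  m <- sim_metrics(5, 6, seed = 8)
  fit <- mixed_anova(m)
  pw <- fit$pairwise
  expect_equal(nrow(pw), 2 * choose(6, 2))
  expect_equal(pw$p_adjusted, pmin(1, 15 * pw$p_value))
})

test_that("the pooled trial-level t-test reproduces the textbook formula", {
  idx <- tibble::tibble(
    group = rep(c("expert", "novice"), each = 3),
    deepest_trunk_deg = c(1, 2, 3, 2, 3, 4))
  out <- trial_t_test(idx)
  # oracle: closed-form pooled t for {1,2,3} vs {2,3,4}
  sp <- sqrt((2 * 1 + 2 * 1) / 4)
  t_ref <- (2 - 3) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(out$statistic, t_ref, tolerance = 1e-12)
  expect_equal(out$df, 4)
  expect_equal(out$cohens_d, -1)

  same <- tibble::tibble(group = rep(c("expert", "novice"), each = 4),
                         deepest_trunk_deg = rep(c(5, 6, 7, 8), 2))
  expect_equal(trial_t_test(same)$statistic, 0)
})

test_that("the default cohort design pools to df = 118", {
  set.seed(10)
  idx <- tibble::tibble(
    group = rep(c("expert", "novice"), c(35, 85)),
    com_velocity_ms = stats::rnorm(120, 0.45, 0.05))
  out <- trial_t_test(idx, "com_velocity_ms")
  expect_equal(out$df, 118)
  expect_equal(out$n_expert, 35)
  expect_equal(out$n_novice, 85)
})

test_that("bonferroni multiplies, clamps and preserves order", {
  expect_equal(bonferroni(0.01, m = 15), 0.15)
  expect_equal(bonferroni(0.2, m = 10), 1)
  set.seed(6)
  p <- stats::runif(50)
  adj <- bonferroni(p, m = 50)
  expect_equal(order(adj[order(p)]), seq_len(50))  # monotone in p
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_error(bonferroni(1.2, 5), "\\[0, 1\\]")
})

test_that("reports carry the expected table shapes", {
  m <- sim_metrics(4, 5, seed = 11)
  m$n_fixations <- 5
  m$mean_visit_ms <- 100
  m$latency_ms <- 900
  idx <- tibble::tibble(
    group = rep(c("expert", "novice"), c(10, 12)),
    deepest_trunk_deg = stats::rnorm(22, 40, 2),
    com_bos_m = stats::rnorm(22, -0.03, 0.01),
    com_velocity_ms = stats::rnorm(22, 0.45, 0.04))
  dir <- withr::local_tempdir()
  files <- render_report(m, idx, dir)
  gsum <- readr::read_csv(files$table_gaze, show_col_types = FALSE)
  expect_equal(nrow(gsum), 12)   # 6 AOIs x 2 groups
  ksum <- readr::read_csv(files$table_kinematics, show_col_types = FALSE)
  expect_equal(nrow(ksum), 6)    # 3 indices x 2 groups
  expect_true(all(c("min", "max", "mean", "sd", "median", "q1", "q3")
                  %in% names(ksum)))
  txt <- readLines(files$summary)
  expect_true(any(grepl("Median", txt)))
  expect_error(render_report(m[0, ], idx, dir), "empty",
               class = "standgaze_validation_error")
})

test_that("Greenhouse-Geisser correction is available behind a flag", {
  fit <- mixed_anova(sim_metrics(6, 8, seed = 12), gg_correction = TRUE)
  tab <- tidy(fit)
  expect_true(all(c("gg_epsilon", "p_gg") %in% names(tab)))
  eps <- tab$gg_epsilon[2]
  expect_gte(eps, 1 / 5)
  expect_lte(eps, 1)
})
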