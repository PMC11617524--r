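# Group statistics: two-factor mixed-design ANOVA (between = experience,
# within = AOI), simple main effects with a pooled error term, Bonferroni
# pairwise comparisons, and the pooled trial-level t-test.

#' Two-factor mixed-design ANOVA on a gaze metrics table
#'
#' Classical split-plot decomposition with experience group as the
#' between-participants factor and AOI as the within-participants factor:
#' for N participants and 6 AOIs the dfs are (1, N-2) for the group effect
#' and (5, 5(N-2)) for the AOI effect and the interaction. No sphericity
#' correction is applied by default (matching the uncorrected dfs commonly
#' reported); Greenhouse-Geisser epsilon is computed behind
#' `gg_correction`. Participants with any missing cell for the chosen
#' metric are excluded listwise (and reported).
#'
#' Simple main effects of experience at each AOI use the pooled error term
#' (participants-within-groups + within-cell error, consistent with the
#' omnibus decomposition); within-group AOI pairwise comparisons are paired
#' t-tests with Bonferroni adjustment over the 15 AOI pairs.
#'
#' @param metrics participant-level table: `participant`, `group`, `aoi`
#'   and metric columns (see [participant_gaze_metrics()]).
#' @param dependent name of the metric column to analyse.
#' @param gg_correction also report Greenhouse-Geisser corrected p-values.
#' @param pairwise compute the within-group AOI pairwise comparisons
#'   (set `FALSE` to skip them, e.g. in large simulation loops).
#' @return object of class `sg_mixed_anova` with `table` (omnibus tests),
#'   `simple_effects`, `pairwise`, `excluded` (participants dropped).
#' @export
mixed_anova <- function(metrics, dependent = "total_duration_pct",
                        gg_correction = FALSE, pairwise = TRUE) {
  abort_if(!dependent %in% names(metrics),
           sprintf("metrics has no column '%s'", dependent))
  d <- tibble::tibble(
    participant = factor(metrics$participant),
    group = factor(metrics$group),
    aoi = factor(metrics$aoi, levels = aoi_names()),
    y = metrics[[dependent]])
  bad <- unique(d$participant[is.na(d$y)])
  d <- d[!d$participant %in% bad, ]
  d$participant <- droplevels(d$participant)
  counts <- table(unique(d[c("participant", "group")])$group)
  abort_if(any(counts < 2),
           "need at least 2 participants per group",
           class = "standgaze_validation_error")

  fit <- stats::aov(y ~ group * aoi + Error(participant), data = d)
  s <- summary(fit)
  between <- as.data.frame(s[["Error: participant"]][[1]])
  within <- as.data.frame(s[["Error: Within"]][[1]])
  rn <- function(df) trimws(rownames(df))
  pick <- function(df, term) df[rn(df) == term, , drop = FALSE]
  row_of <- function(df, term, err) {
    r <- pick(df, term)
    tibble::tibble(term = term, df1 = r$Df, df2 = err$Df,
                   ss = r$`Sum Sq`, ms = r$`Mean Sq`,
                   statistic = r$`F value`, p_value = r$`Pr(>F)`)
  }
  err_b <- pick(between, "Residuals")
  err_w <- pick(within, "Residuals")
  table <- dplyr::bind_rows(
    row_of(between, "group", err_b),
    row_of(within, "aoi", err_w),
    row_of(within, "group:aoi", err_w))

  if (gg_correction) {
    eps <- .sg_gg_epsilon(d)
    table$gg_epsilon <- c(NA, eps, eps)
    table$p_gg <- ifelse(
      is.na(table$gg_epsilon), table$p_value,
      stats::pf(table$statistic, table$df1 * table$gg_epsilon,
                table$df2 * table$gg_epsilon, lower.tail = FALSE))
  }

  # pooled error for between-group contrasts at a fixed AOI. The pooled
  # mean square mixes the participants-within-groups and within-cell
  # strata, so its reference distribution gets a Welch-Satterthwaite
  # effective df (the naive sum of dfs makes the test slightly liberal).
  ss_pool <- err_b$`Sum Sq` + err_w$`Sum Sq`
  df_pool <- err_b$Df + err_w$Df
  ms_pool <- ss_pool / df_pool
  k <- length(levels(d$aoi))
  df_sat <- (err_b$`Sum Sq` / k + err_w$`Sum Sq` / k)^2 /
    ((err_b$`Sum Sq` / k)^2 / err_b$Df + (err_w$`Sum Sq` / k)^2 / err_w$Df)
  simple <- purrr::map_dfr(levels(d$aoi), function(a) {
    da <- d[d$aoi == a, ]
    m <- tapply(da$y, da$group, mean)
    n <- tapply(da$y, da$group, length)
    grand <- sum(m * n) / sum(n)
    ss_g <- sum(n * (m - grand)^2)
    f <- ss_g / 1 / ms_pool
    tibble::tibble(aoi = a, mean_expert = unname(m["expert"]),
                   mean_novice = unname(m["novice"]),
                   df1 = 1, df2 = df_sat, statistic = f,
                   p_value = stats::pf(f, 1, df_sat, lower.tail = FALSE))
  })

  pw <- NULL
  if (pairwise) {
  pairs <- utils::combn(levels(d$aoi), 2)
  pw <- purrr::map_dfr(levels(d$group), function(g) {
    wide <- tidyr::pivot_wider(d[d$group == g, c("participant", "aoi", "y")],
                               names_from = "aoi", values_from = "y")
    purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      tt <- stats::t.test(wide[[a]], wide[[b]], paired = TRUE)
      tibble::tibble(group = g, aoi_1 = a, aoi_2 = b,
                     mean_diff = unname(tt$estimate),
                     statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p_value = tt$p.value)
    })
  })
  pw <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(pw, .data$group),
    p_adjusted = bonferroni(.data$p_value, dplyr::n())))
  }

  structure(list(dependent = dependent, table = table,
                 simple_effects = simple, pairwise = pw,
                 excluded = as.character(bad),
                 n_participants = length(unique(d$participant))),
            class = "sg_mixed_anova")
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# AOI profiles.
.sg_gg_epsilon <- function(d) {
  wide <- tidyr::pivot_wider(d, names_from = "aoi", values_from = "y")
  mats <- lapply(split(wide, wide$group), function(w) {
    stats::cov(as.matrix(w[, aoi_names()]))
  })
  ns <- vapply(split(wide, wide$group), nrow, numeric(1))
  S <- Reduce(`+`, Map(`*`, mats, ns - 1)) / sum(ns - 1)
  k <- ncol(S)
  dbar <- mean(diag(S)); mbar <- mean(S)
  num <- (k * (dbar - mbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * mbar^2)
  max(1 / (k - 1), min(1, num / den))
}

#' @export
print.sg_mixed_anova <- function(x, ...) {
  cat(sprintf("<sg_mixed_anova> dependent: %s (%d participants)\n",
              x$dependent, x$n_participants))
  df <- x$table
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-10s F(%d, %d) = %.2f, p = %.4g\n", df$term[i],
                df$df1[i], df$df2[i], df$statistic[i], df$p_value[i]))
  }
  if (length(x$excluded)) {
    cat("  excluded participants:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pooled trial-level two-sample t-test on a kinematic index
#'
#' Pools the per-trial observations of both groups (ignoring the
#' within-participant correlation, as in the classical trial-level
#' analysis: 35 + 85 trials give df = 118) and runs a pooled-variance
#' two-sample t-test.
#'
#' @param indices tibble with `group` and the index column (one row per
#'   trial), e.g. [run_cohort()]`$kinematics`.
#' @param index name of the index column.
#' @return object of class `sg_group_comparison`.
#' @export
trial_t_test <- function(indices, index = "deepest_trunk_deg") {
  abort_if(!index %in% names(indices),
           sprintf("indices has no column '%s'", index))
  x <- indices[[index]][indices$group == "expert"]
  y <- indices[[index]][indices$group == "novice"]
  abort_if(length(x) < 2 || length(y) < 2,
           "need at least 2 trials per group",
           class = "standgaze_validation_error")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  sp <- sqrt(((length(x) - 1) * stats::var(x) +
                (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  structure(list(
    index = index,
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_expert = mean(x), sd_expert = stats::sd(x),
    mean_novice = mean(y), sd_novice = stats::sd(y),
    n_expert = length(x), n_novice = length(y),
    cohens_d = (mean(x) - mean(y)) / sp), class = "sg_group_comparison")
}

#' @export
print.sg_group_comparison <- function(x, ...) {
  cat(sprintf(
    "<sg_group_comparison> %s: t(%d) = %.2f, p = %.4g; expert %.3f (%.3f) vs novice %.3f (%.3f), d = %.2f\n",
    x$index, x$df, x$statistic, x$p_value, x$mean_expert, x$sd_expert,
    x$mean_novice, x$sd_novice, x$cohens_d))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` for an explicit family size `m` (e.g. the 15
#' AOI pairs).
#'
#' @param pvalues numeric vector of raw p-values.
#' @param m family size; defaults to `length(pvalues)`.
#' @return adjusted p-values, clamped at 1.
#' @export
#' @examples
#' bonferroni(0.01, m = 15)
bonferroni <- function(pvalues, m = length(pvalues)) {
  abort_if(any(pvalues < 0 | pvalues > 1, na.rm = TRUE),
           "p-values must lie in [0, 1]")
  abort_if(m < 1, "family size m must be >= 1")
  pmin(1, m * pvalues)
}

# ---- broom-style methods ----------------------------------------------

#' Tidy a mixed-design ANOVA
#'
#' @param x an `sg_mixed_anova`.
#' @param ... unused.
#' @return tibble of omnibus terms (term, df1, df2, statistic, p_value).
#' @export
tidy.sg_mixed_anova <- function(x, ...) x$table

#' @rdname tidy.sg_mixed_anova
#' @export
glance.sg_mixed_anova <- function(x, ...) {
  tibble::tibble(dependent = x$dependent,
                 n_participants = x$n_participants,
                 n_excluded = length(x$excluded),
                 p_group = x$table$p_value[x$table$term == "group"],
                 p_aoi = x$table$p_value[x$table$term == "aoi"],
                 p_interaction = x$table$p_value[x$table$term == "group:aoi"])
}

#' Tidy a trial-level group comparison
#'
#' @param x an `sg_group_comparison`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
tidy.sg_group_comparison <- function(x, ...) {
  tibble::tibble(index = x$index, statistic = x$statistic, df = x$df,
                 p_value = x$p_value, mean_expert = x$mean_expert,
                 sd_expert = x$sd_expert, mean_novice = x$mean_novice,
                 sd_novice = x$sd_novice, cohens_d = x$cohens_d)
}

#' @rdname tidy.sg_group_comparison
#' @export
glance.sg_group_comparison <- function(x, ...) tidy(x)
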