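# Cohort simulation: expert and novice groups with participant-level
# parameters drawn from group distributions (defaults reproduce the
# published group means/sds), held fixed across a participant's trials with
# a smaller within-participant component per trial.

#' Group-level simulation parameters
#'
#' @param trunk_angle_mean,trunk_angle_sd deepest trunk flexion (degrees).
#' @param com_bos_mean,com_bos_sd signed COM-BOS distance at seat-off (m);
#'   negative = COM behind the heel line.
#' @param com_velocity_mean,com_velocity_sd forward COM velocity (m/s).
#' @param gaze_profile tibble `aoi`, `dwell_mean`, `dwell_sd` (percent of
#'   the support period), `n_fix_mean`, `n_fix_sd` (fixation counts).
#' @return object of class `sg_group_params`.
#' @export
group_params <- function(trunk_angle_mean, trunk_angle_sd,
                         com_bos_mean, com_bos_sd,
                         com_velocity_mean, com_velocity_sd,
                         gaze_profile) {
  abort_if(any(c(trunk_angle_sd, com_bos_sd, com_velocity_sd,
                 gaze_profile$dwell_sd, gaze_profile$n_fix_sd) < 0),
           "all sds must be >= 0", class = "standgaze_validation_error")
  abort_if(any(gaze_profile$dwell_mean < 0) ||
             sum(gaze_profile$dwell_mean) > 100,
           "mean dwell fractions must be >= 0 and sum to at most 100%",
           class = "standgaze_validation_error")
  abort_if(!setequal(gaze_profile$aoi, aoi_names()),
           "gaze profile must cover exactly the six AOIs",
           class = "standgaze_validation_error")
  structure(list(
    trunk_angle_mean = trunk_angle_mean, trunk_angle_sd = trunk_angle_sd,
    com_bos_mean = com_bos_mean, com_bos_sd = com_bos_sd,
    com_velocity_mean = com_velocity_mean,
    com_velocity_sd = com_velocity_sd,
    gaze_profile = gaze_profile), class = "sg_group_params")
}

#' Published group parameter defaults
#'
#' Group means and standard deviations of the kinematic indices and of the
#' per-AOI gaze metrics for expert- and novice-assisted transfers, used as
#' the default simulation targets.
#'
#' @param group `"expert"` or `"novice"`.
#' @return an [group_params()] object.
#' @export
#' @examples
#' default_group_params("expert")$trunk_angle_mean
default_group_params <- function(group = c("expert", "novice")) {
  group <- match.arg(group)
  if (group == "expert") {
    gaze <- tibble::tibble(
      aoi = aoi_names(),
      dwell_mean = c(10.75, 6.72, 3.61, 1.03, 6.32, 0.82),
      dwell_sd = c(6.66, 5.77, 3.20, 1.27, 5.52, 1.00),
      n_fix_mean = c(25.71, 17.29, 7.43, 2.57, 14.57, 2.86),
      n_fix_sd = c(13.27, 13.20, 6.37, 3.02, 10.62, 3.36))
    group_params(41.0, 2.1, -0.023, 0.003, 0.436, 0.026, gaze)
  } else {
    gaze <- tibble::tibble(
      aoi = aoi_names(),
      dwell_mean = c(4.06, 4.65, 6.15, 3.63, 5.34, 0.93),
      dwell_sd = c(6.68, 4.50, 5.21, 4.05, 5.92, 1.58),
      n_fix_mean = c(8.65, 12.18, 12.18, 6.65, 9.12, 2.00),
      n_fix_sd = c(13.73, 14.74, 9.71, 17.73, 11.13, 2.99))
    group_params(37.8, 3.7, -0.047, 0.032, 0.492, 0.067, gaze)
  }
}

#' Cohort configuration
#'
#' @param n_expert,n_novice participants per group (defaults 7 and 17).
#' @param trials_per_participant trials per participant (default 5).
#' @param cycles_per_trial stand/sit cycles within each trial (default 5).
#' @param expert,novice [group_params()] for each group.
#' @param seed master seed; participant/trial/stream seeds are derived
#'   hierarchically so adding a participant does not perturb the others.
#' @param between_var_frac fraction of each group variance allocated between
#'   participants (the rest varies trial to trial; default 0.7).
#' @param marker_noise_sd,grf_noise_sd measurement noise levels.
#' @param mass_mean,mass_sd,stature_mean,stature_sd collaborator
#'   anthropometrics (not reported for the original cohort; configurable).
#' @return object of class `sg_cohort_config`.
#' @export
cohort_config <- function(n_expert = 7, n_novice = 17,
                          trials_per_participant = 5,
                          cycles_per_trial = 5,
                          expert = default_group_params("expert"),
                          novice = default_group_params("novice"),
                          seed = 1,
                          between_var_frac = 0.7,
                          marker_noise_sd = 5e-4, grf_noise_sd = 1,
                          mass_mean = 60, mass_sd = 8,
                          stature_mean = 1.65, stature_sd = 0.08) {
  counts <- c(n_expert, n_novice, trials_per_participant, cycles_per_trial)
  abort_if(any(counts < 1) || any(counts != round(counts)),
           "counts must be positive integers",
           class = "standgaze_validation_error")
  abort_if(between_var_frac < 0 || between_var_frac > 1,
           "between_var_frac must lie in [0, 1]",
           class = "standgaze_validation_error")
  structure(list(
    n_expert = as.integer(n_expert), n_novice = as.integer(n_novice),
    trials_per_participant = as.integer(trials_per_participant),
    cycles_per_trial = as.integer(cycles_per_trial),
    expert = expert, novice = novice, seed = as.integer(seed),
    between_var_frac = between_var_frac,
    marker_noise_sd = marker_noise_sd, grf_noise_sd = grf_noise_sd,
    mass_mean = mass_mean, mass_sd = mass_sd,
    stature_mean = stature_mean, stature_sd = stature_sd),
    class = "sg_cohort_config")
}

#' @export
print.sg_cohort_config <- function(x, ...) {
  cat(sprintf(
    "<sg_cohort_config> %d experts + %d novices x %d trials (%d cycles), seed %d\n",
    x$n_expert, x$n_novice, x$trials_per_participant, x$cycles_per_trial,
    x$seed))
  invisible(x)
}

# Participant-level parameter draw (between-participant component).
.sg_draw_participant <- function(config, group, p_index) {
  gp <- if (group == "expert") config$expert else config$novice
  fb <- sqrt(config$between_var_frac)
  with_sub_seed(sub_seed(config$seed, p_index, 101), {
    gaze <- gp$gaze_profile
    list(
      group = group,
      trunk = stats::rnorm(1, gp$trunk_angle_mean, fb * gp$trunk_angle_sd),
      bos = stats::rnorm(1, gp$com_bos_mean, fb * gp$com_bos_sd),
      vel = stats::rnorm(1, gp$com_velocity_mean,
                         fb * gp$com_velocity_sd),
      mass = max(40, stats::rnorm(1, config$mass_mean, config$mass_sd)),
      stature = max(1.4, stats::rnorm(1, config$stature_mean,
                                      config$stature_sd)),
      gaze = t(vapply(seq_len(nrow(gaze)), function(i) {
        rgamma_pair(gaze$dwell_mean[i], fb * gaze$dwell_sd[i],
                    gaze$n_fix_mean[i], fb * gaze$n_fix_sd[i])
      }, numeric(2))))
  })
}

# Trial-level draw around the participant parameters (within component).
.sg_draw_trial <- function(config, group, part, p_index, t_index) {
  gp <- if (group == "expert") config$expert else config$novice
  fw <- sqrt(1 - config$between_var_frac)
  with_sub_seed(sub_seed(config$seed, p_index, 211, t_index), {
    gaze <- gp$gaze_profile
    draws <- t(vapply(seq_len(nrow(gaze)), function(i) {
      rgamma_pair(part$gaze[i, 1], fw * gaze$dwell_sd[i],
                  part$gaze[i, 2], fw * gaze$n_fix_sd[i])
    }, numeric(2)))
    dwell <- draws[, 1]
    if (sum(dwell) > 90) dwell <- dwell * 90 / sum(dwell)
    list(
      trunk = min(max(stats::rnorm(1, part$trunk, fw * gp$trunk_angle_sd),
                      5), 70),
      bos = stats::rnorm(1, part$bos, fw * gp$com_bos_sd),
      vel = max(0.05, stats::rnorm(1, part$vel, fw * gp$com_velocity_sd)),
      dwell = dwell,
      n_fix = draws[, 2])
  })
}

#' Generate one synthetic trial
#'
#' Realises marker, force-plate and gaze streams for one participant-trial,
#' all aligned to a shared trial clock starting at 0 s.
#'
#' @param config an [cohort_config()].
#' @param group `"expert"` or `"novice"`.
#' @param p_index participant index within the cohort (1-based, experts
#'   first).
#' @param t_index trial index for that participant.
#' @param streams which streams to realise (all three by default); the
#'   seeded draws are identical regardless, so a gaze-only trial carries
#'   the same gaze stream it would in a full trial.
#' @return object of class `sg_trial`: list with `markers`, `grf`, `gaze`
#'   tibbles and a `meta` list.
#' @export
generate_trial <- function(config, group, p_index, t_index,
                           streams = c("markers", "grf", "gaze")) {
  part <- .sg_draw_participant(config, group, p_index)
  tr <- .sg_draw_trial(config, group, part, p_index, t_index)
  script <- motion_script(
    peak_flexion_deg = tr$trunk, com_velocity_ms = tr$vel,
    com_bos_m = tr$bos, cycles = config$cycles_per_trial)
  skeleton <- default_skeleton(part$mass, part$stature)
  markers <- generate_motion(
    script, skeleton, noise_sd = config$marker_noise_sd,
    seed = sub_seed(config$seed, p_index, 307, t_index))
  grf <- if ("grf" %in% streams) {
    generate_grf(
      script, body_mass_kg = part$mass, noise_sd = config$grf_noise_sd,
      seed = sub_seed(config$seed, p_index, 401, t_index))
  }
  gaze <- if ("gaze" %in% streams) {
    layout <- build_aoi_layout(markers)
    window <- c(script$lean_onset_s[1], script$release_s)
    gp <- if (group == "expert") config$expert else config$novice
    profile <- tibble::tibble(aoi = gp$gaze_profile$aoi,
                              dwell_pct = tr$dwell, n_fix = tr$n_fix)
    generate_gaze(
      profile, layout, window,
      seed = sub_seed(config$seed, p_index, 503, t_index))
  }
  window <- c(script$lean_onset_s[1], script$release_s)
  structure(list(
    markers = markers, grf = grf, gaze = gaze,
    meta = list(
      group = group, participant = p_index, trial = t_index,
      seed = config$seed, body_mass_kg = part$mass,
      stature_m = part$stature, release_s = script$release_s,
      support_window_s = window, rear_plates = c(5L, 6L),
      rates = list(markers = 100, grf = 1000, gaze = 50),
      units = list(markers = "m", grf = "N", gaze = "m"),
      script = list(
        peak_flexion_deg = script$peak_flexion_deg,
        com_velocity_ms = script$com_velocity_ms,
        com_bos_m = script$com_bos_m, cycles = script$cycles))),
    class = "sg_trial")
}

#' @export
print.sg_trial <- function(x, ...) {
  cat(sprintf(
    "<sg_trial> %s participant %d trial %d: %d marker frames, %d force samples, %d gaze samples\n",
    x$meta$group, x$meta$participant, x$meta$trial,
    nrow(x$markers), nrow(x$grf) / 6, nrow(x$gaze)))
  invisible(x)
}

# Cohort roster: participant index, group, trial index.
.sg_roster <- function(config) {
  participants <- tibble::tibble(
    p_index = seq_len(config$n_expert + config$n_novice),
    group = rep(c("expert", "novice"),
                c(config$n_expert, config$n_novice)))
  tidyr::crossing(participants,
                  t_index = seq_len(config$trials_per_participant))
}

#' Generate a full cohort of trials
#'
#' Materialises every trial of the configured cohort. For the default
#' 24-participant, 120-trial cohort this holds roughly a gigabyte of
#' streams; prefer [run_cohort()] (generate-analyse-discard) for cohort
#' level analyses.
#'
#' @param config an [cohort_config()].
#' @return tibble `participant`, `group`, `trial`, `data` (list column of
#'   [generate_trial()] objects).
#' @export
generate_cohort <- function(config = cohort_config()) {
  roster <- .sg_roster(config)
  tibble::tibble(
    participant = roster$p_index,
    group = roster$group,
    trial = roster$t_index,
    data = purrr::pmap(roster, function(p_index, group, t_index) {
      generate_trial(config, group, p_index, t_index)
    }))
}

#' Generate and analyse a cohort trial by trial
#'
#' Streams through the cohort: each trial is generated, pushed through the
#' kinematics and/or gaze pipelines, and discarded, keeping only the derived
#' indices. This is the memory-friendly path for full-size cohorts.
#'
#' @param config an [cohort_config()].
#' @param what `"kinematics"`, `"gaze"`, or `"both"`.
#' @param groups which groups to run (default both).
#' @param motion_bank for gaze-only runs: reuse a bank of this many
#'   pre-generated motions (markers, AOI layout, support window) across
#'   trials instead of generating fresh motion for every trial. The gaze
#'   draws and streams stay trial-specific; only the body motion the AOI
#'   bands are anchored to is shared, which leaves the gaze-metric recovery
#'   untouched while cutting the cost of large replicated cohorts.
#' @return list with `kinematics` (one row per trial) and/or `gaze` (one
#'   row per trial x AOI), as requested.
#' @export
run_cohort <- function(config = cohort_config(),
                       what = c("both", "kinematics", "gaze"),
                       groups = c("expert", "novice"),
                       motion_bank = NULL) {
  what <- match.arg(what)
  roster <- .sg_roster(config)
  roster <- roster[roster$group %in% groups, ]
  kin <- list()
  gaze <- list()

  bank <- NULL
  if (!is.null(motion_bank) && what == "gaze") {
    bank <- if (is.list(motion_bank)) motion_bank else
      build_motion_bank(config, motion_bank)
  }

  for (i in seq_len(nrow(roster))) {
    id <- tibble::tibble(participant = roster$p_index[i],
                         group = roster$group[i],
                         trial = roster$t_index[i])
    if (!is.null(bank)) {
      b <- bank[[(i - 1L) %% length(bank) + 1L]]
      gp <- if (id$group == "expert") config$expert else config$novice
      part <- .sg_draw_participant(config, id$group, id$participant)
      trd <- .sg_draw_trial(config, id$group, part, id$participant,
                            id$trial)
      profile <- tibble::tibble(aoi = gp$gaze_profile$aoi,
                                dwell_pct = trd$dwell, n_fix = trd$n_fix)
      gz <- generate_gaze(
        profile, b$layout, b$raw_window,
        seed = sub_seed(config$seed, id$participant, 503, id$trial))
      fix <- detect_fixations(gz)
      gaze[[i]] <- dplyr::bind_cols(
        id[rep(1, 6), ], aoi_metrics(fix, b$layout, b$window))
      next
    }
    streams <- switch(what, both = c("markers", "grf", "gaze"),
                      kinematics = c("markers", "grf"),
                      gaze = c("markers", "gaze"))
    tr <- generate_trial(config, id$group, id$participant, id$trial,
                         streams = streams)
    if (what %in% c("both", "kinematics")) {
      kin[[i]] <- dplyr::bind_cols(id, trial_kinematics(tr)$summary)
    }
    if (what %in% c("both", "gaze")) {
      gaze[[i]] <- dplyr::bind_cols(
        id[rep(1, 6), ], trial_gaze_metrics(tr))
    }
  }
  out <- list()
  if (what %in% c("both", "kinematics")) out$kinematics <- dplyr::bind_rows(kin)
  if (what %in% c("both", "gaze")) out$gaze <- dplyr::bind_rows(gaze)
  out
}


#' Pre-build a bank of motions for gaze-only cohort runs
#'
#' Generates `k` default-script motions (markers low-passed at 6 Hz, AOI
#' layout, detected support window) that [run_cohort()] can cycle through
#' when only gaze metrics are needed, e.g. across many replicate cohorts.
#'
#' @param config an [cohort_config()] (cycle count and noise are honoured).
#' @param k number of motions in the bank.
#' @return list of `k` entries with `layout`, `window`, `raw_window`.
#' @export
build_motion_bank <- function(config = cohort_config(), k = 4) {
  purrr::map(seq_len(k), function(b) {
    script <- motion_script(cycles = config$cycles_per_trial)
    markers <- generate_motion(
      script, noise_sd = config$marker_noise_sd,
      seed = sub_seed(config$seed, 0, 601, b))
    markers <- lowpass_filter(
      markers[c("frame", "time_s", .sg_gaze_marker_cols())], 6,
      rate_hz = attr(markers, "rate"))
    list(layout = build_aoi_layout(markers),
         window = support_period(markers, script$release_s),
         raw_window = c(script$lean_onset_s[1], script$release_s))
  })
}
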