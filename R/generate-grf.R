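# Synthetic six-plate ground reaction forces. Plates are arranged 2 x 3
# (two columns of three); the chair stands on the two rear plates (5, 6) and
# each foot rests on one middle plate (3, 4). The front pair is unloaded.

#' Generate synthetic ground reaction forces for one trial
#'
#' Rear (chair) plates carry the seated fraction of body weight, unload
#' smoothly (minimum-jerk profile) to exactly 0 N at each scripted
#' seat-off, and reload at the end of each sit-down. The foot plates carry
#' the complementary load so that total vertical force always equals body
#' weight (quasi-static; the event of interest is the rear-plate
#' unloading). The smooth profile has no slope discontinuity, so zero-phase
#' filtering does not displace the threshold crossing the event detector
#' looks for.
#'
#' @param script a [motion_script()].
#' @param body_mass_kg collaborator body mass in kg.
#' @param rate sampling rate in Hz (default 1000).
#' @param noise_sd additive white sensor noise sd in newtons.
#' @param seated_frac fraction of body weight carried by the chair when
#'   seated; defaults to the script's value.
#' @param decay_s duration of the rear-plate unloading (s); defaults to the
#'   script's value.
#' @param seed optional integer seed for the noise stream.
#' @return long tibble with columns `time_s`, `plate` (1-6), `fx`, `fy`,
#'   `fz` (N); attributes `rate` and `rear_plates`.
#' @export
generate_grf <- function(script, body_mass_kg = 60, rate = 1000,
                         noise_sd = 1, seated_frac = NULL, decay_s = NULL,
                         seed = NULL) {
  validate_script(script)
  seated_frac <- seated_frac %||% script$grf_seated_frac
  decay_s <- decay_s %||% script$grf_decay_s
  abort_if(!is.numeric(body_mass_kg) || !is.finite(body_mass_kg) ||
             body_mass_kg <= 0,
           "body mass must be > 0 kg", class = "standgaze_validation_error")
  abort_if(rate <= 0, "rate must be > 0 Hz")
  abort_if(decay_s <= 0 || decay_s > script$lean_s + script$hold_s / 2,
           "unloading ramp must fit inside the lean/hold phases",
           class = "standgaze_validation_error")

  t <- seq(0, script$duration_s, by = 1 / rate)
  w <- body_mass_kg * 9.80665
  f_rear <- rep(seated_frac * w, length(t))

  for (k in seq_len(script$cycles)) {
    so <- script$seat_off_s[k]
    sit_end <- script$sit_end_s[k]
    ramp <- t >= so - decay_s & t < so
    f_rear[ramp] <- seated_frac * w *
      (1 - mjerk((t[ramp] - (so - decay_s)) / decay_s))
    up <- t >= so & t < sit_end - decay_s
    f_rear[up] <- 0
    reload <- t >= sit_end - decay_s & t < sit_end
    f_rear[reload] <- seated_frac * w *
      mjerk((t[reload] - (sit_end - decay_s)) / decay_s)
  }

  f_feet <- w - f_rear
  zeros <- numeric(length(t))
  plates <- list(`1` = zeros, `2` = zeros,
                 `3` = f_feet / 2, `4` = f_feet / 2,
                 `5` = f_rear / 2, `6` = f_rear / 2)

  grf <- tibble::tibble(
    time_s = rep(t, times = 6),
    plate = rep(1:6, each = length(t)),
    fx = 0,
    fy = 0,
    fz = unlist(plates, use.names = FALSE))

  if (noise_sd > 0) {
    grf$fz <- grf$fz + with_sub_seed(seed %||% sub_seed(2, 11, 1), {
      stats::rnorm(nrow(grf), 0, noise_sd)
    })
  }
  attr(grf, "rate") <- rate
  attr(grf, "rear_plates") <- c(5L, 6L)
  grf
}
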