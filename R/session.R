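#' Session timing parameters
#'
#' Trial-event durations for the oculomotor foraging task: a random
#' initial fixation of 500--1000 ms, a 6-s search limit, a 200-ms reward
#' delay, and an 800-ms intertrial interval. `mean_isi`/`sd_isi` set the
#' intersaccadic-interval distribution used to pace the agent's choices
#' (truncated normal, floor 80 ms).
#'
#' @param fixation_range `c(min, max)` fixation duration, ms.
#' @param search_limit search time limit, ms.
#' @param reward_delay delay between target fixation and reward, ms.
#' @param intertrial_interval ms.
#' @param mean_isi mean intersaccadic interval, ms.
#' @param sd_isi SD of the intersaccadic interval, ms.
#' @return An object of class `session_timing`.
#' @export
session_timing <- function(fixation_range = c(500, 1000),
                           search_limit = 6000, reward_delay = 200,
                           intertrial_interval = 800,
                           mean_isi = 220, sd_isi = 40) {
  stopifnot(length(fixation_range) == 2L, all(fixation_range > 0),
            fixation_range[1] <= fixation_range[2],
            search_limit > 0, reward_delay > 0, intertrial_interval > 0,
            mean_isi > 0, sd_isi >= 0)
  structure(list(fixation_range = as.numeric(fixation_range),
                 search_limit = as.numeric(search_limit),
                 reward_delay = as.numeric(reward_delay),
                 intertrial_interval = as.numeric(intertrial_interval),
                 mean_isi = as.numeric(mean_isi),
                 sd_isi = as.numeric(sd_isi)),
            class = "session_timing")
}

#' Phenomenological drug-effect profile
#'
#' Describes a time-varying modulation of the agent's parameters and of
#' saccade kinematics after an injection at session time zero: the
#' effect ramps linearly to its maximum within `onset_minutes` and then
#' decays exponentially with half-life `recovery_halflife_minutes`.
#' At effect level `e(t)` in `[0, 1]`, each model parameter is scaled by
#' `1 + (scale - 1) * e(t)` (so `effect_scale` gives the value of the
#' multiplier at peak effect). Kinematic effects scale peak saccade
#' velocity, inject postsaccadic drift (degrees per 100 ms at peak), and
#' inflate the intersaccadic interval.
#'
#' @param effect_scale named numeric: peak multiplicative factors for
#'   `capacity`, `decay`, `utility` (missing names default to 1).
#' @param onset_minutes time to peak effect, minutes.
#' @param recovery_halflife_minutes recovery half-life, minutes.
#' @param peak_velocity_scale multiplier on main-sequence velocity at
#'   peak effect.
#' @param drift_magnitude postsaccadic drift at peak effect, degrees
#'   over the 100 ms following saccade offset.
#' @param isi_inflation multiplier on the mean intersaccadic interval at
#'   peak effect.
#' @return An object of class `drug_profile`.
#' @examples
#' drug_profile(effect_scale = c(utility = 0.43, capacity = 0.85))
#' @export
drug_profile <- function(effect_scale = c(capacity = 1, decay = 1, utility = 1),
                         onset_minutes = 10, recovery_halflife_minutes = 20,
                         peak_velocity_scale = 1, drift_magnitude = 0,
                         isi_inflation = 1) {
  scales <- c(capacity = 1, decay = 1, utility = 1)
  if (is.null(names(effect_scale)) && length(effect_scale) == 3L)
    names(effect_scale) <- c("capacity", "decay", "utility")
  scales[names(effect_scale)] <- effect_scale
  stopifnot(all(scales > 0), onset_minutes > 0,
            recovery_halflife_minutes > 0, peak_velocity_scale > 0,
            drift_magnitude >= 0, isi_inflation > 0)
  if (scales[["utility"]] > 1)
    stop("utility factor must keep utility in [0, 1]", call. = FALSE)
  structure(list(effect_scale = scales, onset_minutes = onset_minutes,
                 recovery_halflife_minutes = recovery_halflife_minutes,
                 peak_velocity_scale = peak_velocity_scale,
                 drift_magnitude = drift_magnitude,
                 isi_inflation = isi_inflation),
            class = "drug_profile")
}

#' Drug effect level at a given time
#'
#' @param profile a [drug_profile()].
#' @param t_minutes time since injection (vectorized); negative times
#'   give 0.
#' @return Effect level in `[0, 1]`: linear ramp to 1 over the onset,
#'   then exponential decay at the recovery half-life.
#' @export
drug_effect_level <- function(profile, t_minutes) {
  stopifnot(inherits(profile, "drug_profile"))
  e <- ifelse(t_minutes < 0, 0,
              ifelse(t_minutes <= profile$onset_minutes,
                     t_minutes / profile$onset_minutes,
                     2^(-(t_minutes - profile$onset_minutes) /
                          profile$recovery_halflife_minutes)))
  pmin(pmax(e, 0), 1)
}

#' Model parameters under a drug effect
#'
#' @param params baseline [forage_params()].
#' @param profile a [drug_profile()] or `NULL`.
#' @param t_minutes time since injection, minutes.
#' @return A [forage_params()] with each parameter scaled by
#'   `1 + (scale - 1) * e(t)`; capacity is rounded and clamped to
#'   `[1, 15]`, decay to `[1, capacity]`, utility to `[0, 1]`.
#' @export
params_at_time <- function(params, profile, t_minutes) {
  params <- as_forage_params(params)
  if (is.null(profile)) return(params)
  e <- drug_effect_level(profile, t_minutes)
  f <- 1 + (profile$effect_scale - 1) * e
  cap <- max(1L, min(15L, as.integer(round(params$capacity * f[["capacity"]]))))
  dec <- max(1L, min(cap, as.integer(round(params$decay * f[["decay"]]))))
  util <- min(1, max(0, params$utility * f[["utility"]]))
  forage_params(cap, dec, util)
}

CONDITION_LEVELS <- c("none", "saline", "ketamine-0.7", "ketamine-1.0",
                      "ketamine-1.5", "medetomidine")

#' Generate a complete synthetic foraging session
#'
#' Drives the foraging agent through `n_trials` trials of the task:
#' each trial gets a fresh stimulus array, a choice sequence from the
#' agent (under parameters possibly modulated by a [drug_profile()]
#' evaluated at the trial's start time), per-saccade timestamps drawn
#' from the intersaccadic-interval distribution, and censoring when the
#' cumulative search time exceeds the 6-s limit (a hard 25-saccade cap
#' also applies, matching the 25-bin summary support). Wall-clock
#' timestamps accumulate fixation, search, reward delay, and intertrial
#' interval.
#'
#' @param params baseline [forage_params()] for the agent.
#' @param n_trials number of trials.
#' @param timing a [session_timing()].
#' @param drug optional [drug_profile()]; requires `injection_minutes`.
#' @param injection_minutes injection time in session minutes (`NA` for
#'   none; trials before it are unaffected by `drug`).
#' @param subject subject identifier.
#' @param condition one of `"none"`, `"saline"`, `"ketamine-0.7"`,
#'   `"ketamine-1.0"`, `"ketamine-1.5"`, `"medetomidine"`.
#' @param n_objects objects per trial.
#' @param max_saccades hard saccade cap per trial.
#' @return An object of class `forage_session`: subject, condition,
#'   injection time, timing, and a list of trial records (array, target,
#'   choices, found/censored flags, per-saccade timestamps).
#' @examples
#' set.seed(1)
#' s <- generate_session(forage_params(10, 2, 0.9), n_trials = 20)
#' session_trials(s)
#' @export
generate_session <- function(params, n_trials, timing = session_timing(),
                             drug = NULL, injection_minutes = NA_real_,
                             subject = "synthetic", condition = "none",
                             n_objects = 15L, max_saccades = 25L) {
  params <- as_forage_params(params)
  condition <- match.arg(condition, CONDITION_LEVELS)
  stopifnot(n_trials >= 1L)
  if (!is.null(drug) && is.na(injection_minutes))
    injection_minutes <- 0
  t_now <- 0  # session clock, ms
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    t_min <- t_now / 60000
    p_i <- if (is.null(drug)) params else
      params_at_time(params, drug, t_min - injection_minutes)
    e_i <- if (is.null(drug)) 0 else
      drug_effect_level(drug, t_min - injection_minutes)
    arr <- generate_stimulus_array(n_sites = n_objects)
    raw <- simulate_trials_cpp(p_i$capacity, p_i$decay, p_i$utility,
                               as.integer(n_objects),
                               as.integer(max_saccades), 1L)
    choices <- raw$choices[[1L]]
    found <- raw$found[1L]
    # time budget: each choice lands one intersaccadic interval after
    # the previous fixation; censor choices that no longer fit
    isi_scale <- if (is.null(drug)) 1 else 1 + (drug$isi_inflation - 1) * e_i
    isi <- pmax(80, stats::rnorm(length(choices),
                                 timing$mean_isi * isi_scale, timing$sd_isi))
    t_sacc <- cumsum(isi)
    n_fit <- sum(t_sacc <= timing$search_limit)
    if (n_fit < length(choices)) {
      choices <- choices[seq_len(n_fit)]
      t_sacc <- t_sacc[seq_len(n_fit)]
      found <- FALSE
    }
    fix_dur <- stats::runif(1, timing$fixation_range[1],
                            timing$fixation_range[2])
    search_end <- if (length(t_sacc)) t_sacc[length(t_sacc)] else 0
    trials[[i]] <- list(
      trial = i,
      array = arr,
      target = raw$target[1L],
      choices = choices,
      found = found,
      censored = !found,
      t_start_ms = t_now,
      fixation_ms = fix_dur,
      saccade_t_ms = t_now + fix_dur + t_sacc,
      excluded = FALSE,
      exclude_reason = NA_character_)
    t_now <- t_now + fix_dur +
      (if (!found) timing$search_limit else search_end + timing$reward_delay) +
      timing$intertrial_interval
  }
  structure(list(subject = subject, condition = condition,
                 injection_minutes = injection_minutes,
                 timing = timing, drug = drug, params = params,
                 n_objects = as.integer(n_objects),
                 max_saccades = as.integer(max_saccades),
                 trials = trials),
            class = "forage_session")
}

#' @export
print.forage_session <- function(x, ...) {
  cat(sprintf(
    "<forage_session> subject %s, condition %s, %d trials, %.1f min\n",
    x$subject, x$condition, length(x$trials),
    max(vapply(x$trials, `[[`, numeric(1), "t_start_ms")) / 60000))
  invisible(x)
}

#' Tabular view of a session's trials
#'
#' @param session a `forage_session`.
#' @return A tibble with one row per trial: trial id, start time
#'   (minutes), target, saccade count, found/censored flags, and the
#'   choice sequence as a list-column.
#' @export
session_trials <- function(session) {
  stopifnot(inherits(session, "forage_session"))
  tr <- session$trials
  tibble::tibble(
    trial = vapply(tr, `[[`, numeric(1), "trial"),
    t_start_min = vapply(tr, `[[`, numeric(1), "t_start_ms") / 60000,
    target = vapply(tr, `[[`, numeric(1), "target"),
    n_saccades = vapply(tr, function(t) length(t$choices), numeric(1)),
    found = vapply(tr, `[[`, logical(1), "found"),
    censored = vapply(tr, `[[`, logical(1), "censored"),
    choices = lapply(tr, `[[`, "choices"))
}

#' Convert session trials to a `forage_trials` collection
#'
#' Pools the choice sequences of one or several sessions into the
#' trial-collection format consumed by [summarize_trials()] and the
#' fitting functions.
#'
#' @param sessions a `forage_session` or list of them.
#' @param window optional `c(start, end)` in session minutes relative to
#'   the injection time (trials are selected by their start time);
#'   requires each session to have a non-`NA` injection time.
#' @return A `forage_trials` object.
#' @export
session_outcomes <- function(sessions, window = NULL) {
  if (inherits(sessions, "forage_session")) sessions <- list(sessions)
  pick <- function(sess) {
    tr <- sess$trials
    if (!is.null(window)) {
      t0 <- if (is.na(sess$injection_minutes)) 0 else sess$injection_minutes
      t_rel <- vapply(tr, `[[`, numeric(1), "t_start_ms") / 60000 - t0
      tr <- tr[t_rel >= window[1] & t_rel < window[2]]
    }
    tr
  }
  trs <- unlist(lapply(sessions, pick), recursive = FALSE)
  out <- list(choices = lapply(trs, `[[`, "choices"),
              target = vapply(trs, `[[`, numeric(1), "target"),
              found = vapply(trs, `[[`, logical(1), "found"),
              censored = vapply(trs, `[[`, logical(1), "censored"),
              n_saccades = vapply(trs, function(t) length(t$choices),
                                  numeric(1)),
              params = NULL,
              n_objects = sessions[[1L]]$n_objects,
              max_saccades = sessions[[1L]]$max_saccades)
  class(out) <- "forage_trials"
  out
}
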