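#' Generate a synthetic 1-kHz eye-position trace for a trial
#'
#' Renders a trial's choice sequence as a two-channel (x, y) gaze trace
#' sampled at 1 kHz. Each saccade follows a minimum-jerk position
#' profile whose peak velocity obeys the main-sequence relation
#' `v_peak = e_max * (1 - exp(tau * Amp))` (so duration is
#' `1.875 * Amp / v_peak`). Optional postsaccadic drift is an
#' exponential position creep after each saccade offset (time constant
#' 30 ms), parameterized by its total displacement over the 100 ms
#' measurement window. Optional white Gaussian position noise is added
#' per channel.
#'
#' @param trial a trial record from [generate_session()] (needs
#'   `array`, `choices`), or a list with those fields.
#' @param main_sequence numeric `c(e_max, tau)`: asymptotic peak
#'   velocity (deg/s, > 0) and exponential constant (1/deg, < 0).
#' @param drift_magnitude postsaccadic drift, degrees per 100 ms.
#' @param noise_sd per-sample Gaussian position noise SD, degrees.
#' @param mean_isi,sd_isi intersaccadic (fixation) interval
#'   distribution, ms.
#' @param fixation_ms initial fixation duration; defaults to the
#'   trial's own, else 600 ms.
#' @param tail_ms trace padding after the last saccade, ms.
#' @return An object of class `eye_trace`: `samples` (tibble
#'   `time_ms`, `x`, `y`), `events` (fixation onset, stimulus onset,
#'   trial end), `sampling_rate`, the stimulus `array`, and a `truth`
#'   tibble (per-saccade onset/offset ms, amplitude, peak velocity,
#'   choice index) used by the round-trip tests.
#' @examples
#' set.seed(1)
#' s <- generate_session(forage_params(10, 2, 0.9), 1)
#' tr <- generate_eye_trace(s$trials[[1]])
#' nrow(tr$samples)
#' @export
generate_eye_trace <- function(trial, main_sequence = c(500, -0.1),
                               drift_magnitude = 0, noise_sd = 0,
                               mean_isi = 220, sd_isi = 0,
                               fixation_ms = NULL, tail_ms = 300) {
  e_max <- main_sequence[[1]]
  tau <- main_sequence[[2]]
  stopifnot(e_max > 0, tau < 0)
  if (is.null(fixation_ms))
    fixation_ms <- if (!is.null(trial$fixation_ms)) trial$fixation_ms else 600
  fixation_ms <- max(50, round(fixation_ms))
  sites <- trial$array$sites
  choices <- trial$choices
  pos <- trial$array$fixation
  drift_tau <- 30
  drift_gain <- if (drift_magnitude > 0)
    drift_magnitude / (1 - exp(-100 / drift_tau)) else 0

  xs <- list(rep(pos[1], fixation_ms))
  ys <- list(rep(pos[2], fixation_ms))
  t_now <- fixation_ms  # samples so far; sample i covers time (i-1) ms
  truth <- vector("list", length(choices))

  hold <- function(p, dur, drift_vec) {
    tt <- seq_len(dur)
    if (is.null(drift_vec)) {
      list(x = rep(p[1], dur), y = rep(p[2], dur), end = p)
    } else {
      d <- drift_gain * (1 - exp(-tt / drift_tau))
      list(x = p[1] + drift_vec[1] * d, y = p[2] + drift_vec[2] * d,
           end = c(p[1] + drift_vec[1] * d[dur], p[2] + drift_vec[2] * d[dur]))
    }
  }

  for (i in seq_along(choices)) {
    if (i > 1L) {
      dur <- max(120, round(stats::rnorm(1, mean_isi, sd_isi)))
      drift_vec <- if (drift_gain > 0) {
        ang <- stats::runif(1, 0, 2 * pi)
        c(cos(ang), sin(ang))
      } else NULL
      h <- hold(pos, dur, drift_vec)
      xs <- c(xs, list(h$x)); ys <- c(ys, list(h$y))
      pos <- h$end
      t_now <- t_now + dur
    }
    tgt <- sites[choices[i], ]
    amp <- sqrt(sum((tgt - pos)^2))
    v_peak <- e_max * (1 - exp(tau * amp))
    dur <- max(12, round(1.875 * amp / v_peak * 1000))
    s <- seq_len(dur) / dur
    mj <- 10 * s^3 - 15 * s^4 + 6 * s^5
    xs <- c(xs, list(pos[1] + (tgt[1] - pos[1]) * mj))
    ys <- c(ys, list(pos[2] + (tgt[2] - pos[2]) * mj))
    truth[[i]] <- tibble::tibble(onset = t_now, offset = t_now + dur,
                                 amplitude = amp, peak_velocity = v_peak,
                                 duration = dur, choice = choices[i])
    pos <- c(tgt[1], tgt[2])
    t_now <- t_now + dur
  }
  # terminal dwell (with drift) so the last saccade has a full
  # postsaccadic measurement window
  drift_vec <- if (drift_gain > 0) {
    ang <- stats::runif(1, 0, 2 * pi)
    c(cos(ang), sin(ang))
  } else NULL
  h <- hold(pos, max(tail_ms, 150), drift_vec)
  xs <- c(xs, list(h$x)); ys <- c(ys, list(h$y))

  x <- unlist(xs, use.names = FALSE)
  y <- unlist(ys, use.names = FALSE)
  if (noise_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, noise_sd)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  samples <- tibble::tibble(time_ms = seq_along(x) - 1, x = x, y = y)
  structure(list(samples = samples,
                 events = list(fixation_onset = 0,
                               stimulus_onset = fixation_ms,
                               trial_end = nrow(samples) - 1),
                 sampling_rate = 1000,
                 array = trial$array,
                 truth = do.call(rbind, truth)),
            class = "eye_trace")
}

#' @export
print.eye_trace <- function(x, ...) {
  cat(sprintf("<eye_trace> %d ms at %g Hz, %d ground-truth saccades\n",
              nrow(x$samples), x$sampling_rate,
              if (is.null(x$truth)) 0L else nrow(x$truth)))
  invisible(x)
}
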