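#' Smoothed kinematics of an eye trace
#'
#' Positions are low-pass filtered with a Savitzky-Golay filter
#' (default 2nd order, 21-ms window) before differentiation; velocity
#' and acceleration are central differences of the smoothed channels,
#' scaled to deg/s and deg/s^2. Unsmoothed 1-kHz differentiation is
#' noise-dominated, so the filter parameters are exposed rather than
#' hard-coded.
#'
#' @param trace an `eye_trace`.
#' @param sg_order,sg_window Savitzky-Golay polynomial order and window
#'   length (samples, odd).
#' @return A tibble with `time_ms`, smoothed `x`, `y`, `speed` (deg/s),
#'   and `accel` (deg/s^2, magnitude of the acceleration vector).
#' @export
trace_kinematics <- function(trace, sg_order = 2L, sg_window = 21L) {
  stopifnot(inherits(trace, "eye_trace"))
  fs <- trace$sampling_rate
  n <- nrow(trace$samples)
  if (n < sg_window + 2L)
    stop("trace shorter than the smoothing filter support", call. = FALSE)
  xs <- signal::sgolayfilt(trace$samples$x, p = sg_order, n = sg_window)
  ys <- signal::sgolayfilt(trace$samples$y, p = sg_order, n = sg_window)
  cdiff <- function(v) {
    d <- c(v[2L] - v[1L], (v[-(1:2)] - v[seq_len(n - 2L)]) / 2,
           v[n] - v[n - 1L])
    d * fs
  }
  vx <- cdiff(xs)
  vy <- cdiff(ys)
  ax <- cdiff(vx)  # cdiff scales by fs once per derivative order
  ay <- cdiff(vy)
  tibble::tibble(time_ms = trace$samples$time_ms, x = xs, y = ys,
                 speed = sqrt(vx^2 + vy^2), accel = sqrt(ax^2 + ay^2))
}

#' Detect saccades on a 1-kHz eye trace
#'
#' Conjunctive velocity/acceleration/amplitude criteria: a candidate
#' event is an epoch where smoothed angular eye velocity exceeds
#' `v_thresh`; epochs closer than `min_gap_ms` are merged (corrective
#' movements within the gap count as one event); each epoch is extended
#' to the surrounding `onset_thresh` velocity crossings, and kept only
#' if its peak acceleration exceeds `a_thresh` and its net displacement
#' exceeds `min_amp`.
#'
#' @param trace an `eye_trace`.
#' @param v_thresh detection velocity threshold, deg/s.
#' @param a_thresh peak-acceleration criterion, deg/s^2.
#' @param min_amp minimum net displacement, degrees.
#' @param onset_thresh velocity level defining onset/offset, deg/s.
#' @param min_gap_ms merge gap between adjacent supra-threshold epochs.
#' @param sg_order,sg_window smoothing parameters for
#'   [trace_kinematics()].
#' @return A tibble of class `saccade_events`: `onset`, `offset` (ms),
#'   `amplitude` (deg), `peak_velocity` (deg/s), `peak_accel`
#'   (deg/s^2).
#' @examples
#' set.seed(1)
#' s <- generate_session(forage_params(10, 2, 0.9), 1)
#' tr <- generate_eye_trace(s$trials[[1]])
#' nrow(detect_saccades(tr)) == length(s$trials[[1]]$choices)
#' @export
detect_saccades <- function(trace, v_thresh = 70, a_thresh = 1000,
                            min_amp = 2, onset_thresh = 10,
                            min_gap_ms = 20, sg_order = 2L,
                            sg_window = 21L) {
  kin <- trace_kinematics(trace, sg_order, sg_window)
  n <- nrow(kin)
  above <- kin$speed > v_thresh
  if (!any(above)) {
    out <- tibble::tibble(onset = numeric(0), offset = numeric(0),
                          amplitude = numeric(0),
                          peak_velocity = numeric(0),
                          peak_accel = numeric(0))
    class(out) <- c("saccade_events", class(out))
    return(out)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  epochs <- cbind(starts[r$values], ends[r$values])
  # merge epochs separated by less than min_gap_ms
  if (nrow(epochs) > 1L) {
    keep <- list(epochs[1L, ])
    for (i in 2L:nrow(epochs)) {
      last <- keep[[length(keep)]]
      if (epochs[i, 1L] - last[2L] < min_gap_ms) {
        keep[[length(keep)]] <- c(last[1L], epochs[i, 2L])
      } else {
        keep[[length(keep) + 1L]] <- epochs[i, ]
      }
    }
    epochs <- do.call(rbind, keep)
  }
  rows <- lapply(seq_len(nrow(epochs)), function(i) {
    a <- epochs[i, 1L]
    b <- epochs[i, 2L]
    while (a > 1L && kin$speed[a - 1L] > onset_thresh) a <- a - 1L
    while (b < n && kin$speed[b + 1L] > onset_thresh) b <- b + 1L
    # then follow the monotone velocity slope to its foot, where the
    # smoothed profile actually leaves the fixation plateau
    while (a > 1L && kin$speed[a - 1L] < kin$speed[a]) a <- a - 1L
    while (b < n && kin$speed[b + 1L] < kin$speed[b]) b <- b + 1L
    disp <- sqrt((kin$x[b] - kin$x[a])^2 + (kin$y[b] - kin$y[a])^2)
    pk_acc <- max(kin$accel[a:b])
    if (disp <= min_amp || pk_acc <= a_thresh) return(NULL)
    tibble::tibble(onset = kin$time_ms[a], offset = kin$time_ms[b],
                   amplitude = disp,
                   peak_velocity = max(kin$speed[a:b]),
                   peak_accel = pk_acc)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(onset = numeric(0), offset = numeric(0),
                   amplitude = numeric(0), peak_velocity = numeric(0),
                   peak_accel = numeric(0))
  class(out) <- c("saccade_events", class(out))
  out
}

#' Register the inspected-object sequence from gaze position
#'
#' An object is registered when gaze stays within `radius` of it for
#' more than `dwell_ms`; consecutive dwells on the same object merge
#' into one registration, and brief in-transit passes are rejected by
#' the dwell criterion.
#'
#' @param trace an `eye_trace`.
#' @param array the trial's `stimulus_array` (defaults to the one
#'   carried by the trace).
#' @param radius capture radius around each object, degrees.
#' @param dwell_ms minimum dwell, ms.
#' @return Integer vector of object indices in dwell order.
#' @export
register_choices <- function(trace, array = trace$array, radius = 2,
                             dwell_ms = 100) {
  stopifnot(inherits(trace, "eye_trace"), !is.null(array))
  s <- trace$samples
  sites <- array$sites
  d2 <- outer(s$x, sites[, 1L], `-`)^2 + outer(s$y, sites[, 2L], `-`)^2
  nearest <- max.col(-d2, ties.method = "first")
  within <- d2[cbind(seq_len(nrow(s)), nearest)] <= radius^2
  assign <- ifelse(within, nearest, 0L)
  r <- rle(assign)
  seqv <- r$values[r$values > 0L & r$lengths > dwell_ms]
  if (length(seqv) > 1L)
    seqv <- seqv[c(TRUE, diff(seqv) != 0L)]
  as.integer(seqv)
}

#' Postsaccadic drift
#'
#' Straight-line eye displacement during the `window_ms` (default
#' 100 ms) following each saccade's termination. The estimate is
#' flagged missing (`NA`) when the window is truncated by the end of
#' the trace or crosses the next saccade's onset.
#'
#' @param trace an `eye_trace`.
#' @param saccades a `saccade_events` tibble from [detect_saccades()].
#' @param window_ms measurement window, ms.
#' @return Numeric vector of drift sizes in degrees, one per saccade.
#' @export
postsaccadic_drift <- function(trace, saccades, window_ms = 100) {
  stopifnot(inherits(trace, "eye_trace"))
  s <- trace$samples
  n <- nrow(s)
  ns <- nrow(saccades)
  out <- rep(NA_real_, ns)
  for (i in seq_len(ns)) {
    i0 <- saccades$offset[i] + 1  # time 0 is sample 1
    i1 <- i0 + window_ms
    if (i1 > n) next
    if (i < ns && saccades$onset[i + 1L] < saccades$offset[i] + window_ms)
      next
    out[i] <- sqrt((s$x[i1] - s$x[i0])^2 + (s$y[i1] - s$y[i0])^2)
  }
  out
}

#' Intersaccadic intervals
#'
#' Fixation intervals from each saccade's end to the following
#' saccade's onset.
#'
#' @param saccades a `saccade_events` tibble (at least 2 rows for a
#'   non-empty result).
#' @return Numeric vector of intervals in ms (length `n - 1`).
#' @export
intersaccadic_intervals <- function(saccades) {
  n <- nrow(saccades)
  if (n < 2L) return(numeric(0))
  saccades$onset[-1L] - saccades$offset[-n]
}

#' Fit the saccadic main sequence
#'
#' Least-squares fit of the saturating-exponential amplitude/velocity
#' relation `v = e_max * (1 - exp(tau * amp))`, with starting values
#' `e_max = max(v)`, `tau = -2 / median(amp)` and bounds `e_max > 0`,
#' `tau < 0`. The fitted curve is evaluated at 20 degrees (`v20`), the
#' reference amplitude at which drug effects on velocity are compared;
#' post/pre ratios of `v20` from separately fitted epochs give the
#' normalized velocity.
#'
#' @param saccades a `saccade_events` tibble, or a numeric vector of
#'   amplitudes (then `peak_velocity` must be given).
#' @param peak_velocity peak velocities, deg/s (when `saccades` is a
#'   bare amplitude vector).
#' @return An object of class `main_sequence_fit`: `e_max`, `tau`,
#'   `v20`, `n`, and the underlying `nls` fit.
#' @examples
#' amp <- seq(3, 25, length.out = 30)
#' v <- 500 * (1 - exp(-0.1 * amp))
#' fit_main_sequence(amp, v)$v20  # ~432.3
#' @export
fit_main_sequence <- function(saccades, peak_velocity = NULL) {
  if (is.data.frame(saccades)) {
    amp <- saccades$amplitude
    vel <- saccades$peak_velocity
  } else {
    amp <- as.numeric(saccades)
    vel <- as.numeric(peak_velocity)
  }
  ok <- is.finite(amp) & is.finite(vel)
  amp <- amp[ok]
  vel <- vel[ok]
  if (length(amp) < 5L)
    stop("need at least 5 saccades to fit the main sequence",
         call. = FALSE)
  if (diff(range(amp)) < 5)
    stop("degenerate amplitude range (< 5 deg) for main-sequence fit",
         call. = FALSE)
  dat <- data.frame(amp = amp, vel = vel)
  fit <- minpack.lm::nlsLM(
    vel ~ e_max * (1 - exp(tau * amp)), data = dat,
    start = list(e_max = max(vel), tau = -2 / stats::median(amp)),
    lower = c(e_max = 1e-6, tau = -Inf),
    upper = c(e_max = Inf, tau = -1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(e_max = unname(cf["e_max"]), tau = unname(cf["tau"]),
                 v20 = unname(cf["e_max"] * (1 - exp(20 * cf["tau"]))),
                 n = length(amp), fit = fit),
            class = "main_sequence_fit")
}

#' @export
print.main_sequence_fit <- function(x, ...) {
  cat(sprintf(
    "<main_sequence_fit> e_max = %.1f deg/s, tau = %.4f 1/deg, v20 = %.1f deg/s (n = %d)\n",
    x$e_max, x$tau, x$v20, x$n))
  invisible(x)
}

#' Predicted main-sequence peak velocity
#'
#' @param fit a `main_sequence_fit`.
#' @param amplitude saccade amplitude(s), degrees.
#' @return Peak velocity deg/s.
#' @export
main_sequence_velocity <- function(fit, amplitude) {
  stopifnot(inherits(fit, "main_sequence_fit"))
  fit$e_max * (1 - exp(fit$tau * amplitude))
}

#' Saccade gain along the target direction
#'
#' The saccade vector is projected onto the unit vector toward the
#' target, and the projected amplitude is divided by the target
#' distance: 1 means an accurate saccade, 0 an orthogonal one.
#'
#' @param saccade_vec saccade displacement `c(x, y)`, degrees.
#' @param target_vec vector from the starting fixation to the target,
#'   degrees; must be nonzero.
#' @return Dimensionless gain.
#' @examples
#' saccade_gain(c(10, 0), c(10, 0))  # 1
#' @export
saccade_gain <- function(saccade_vec, target_vec) {
  tl2 <- sum(target_vec^2)
  if (tl2 == 0) stop("zero target distance", call. = FALSE)
  sum(saccade_vec * target_vec) / tl2
}

#' Virtual-window trial exclusion
#'
#' A trial is excluded when any gaze sample during the search epoch
#' falls outside the virtual window covering the possible stimulus
#' locations plus a 4-degree margin (33 x 48 degrees by default),
#' indicating lapses of task engagement.
#'
#' @param trace an `eye_trace`.
#' @param half_width,half_height window half-extents, degrees
#'   (defaults give 48 wide x 33 tall).
#' @param center window center `c(x, y)`, degrees.
#' @param epoch `c(start, end)` in ms; defaults to stimulus onset
#'   through trial end.
#' @return `TRUE` if the trial should be excluded.
#' @export
exclude_trial <- function(trace, half_width = 24, half_height = 16.5,
                          center = c(0, 0), epoch = NULL) {
  stopifnot(inherits(trace, "eye_trace"))
  s <- trace$samples
  if (is.null(epoch))
    epoch <- c(trace$events$stimulus_onset, trace$events$trial_end)
  sel <- s$time_ms >= epoch[1] & s$time_ms <= epoch[2]
  any(abs(s$x[sel] - center[1]) > half_width |
        abs(s$y[sel] - center[2]) > half_height)
}
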