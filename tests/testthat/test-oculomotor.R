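make_trace <- function(seed = 1, n_trials = 1, params = forage_params(10, 2, 0.9),
                       ...) {
  set.seed(seed)
  s <- generate_session(params, n_trials)
  lapply(s$trials, generate_eye_trace, ...)
}

test_that("saccade detection inverts the trace generator", {
  traces <- make_trace(seed = 61, n_trials = 8)
  for (tr in traces) {
    ev <- detect_saccades(tr)
    expect_identical(nrow(ev), nrow(tr$truth))
    expect_true(all(abs(ev$onset - tr$truth$onset) <= 5))
    # offsets sit on the slow min-jerk tail, where the velocity
    # criterion triggers a few ms early
    expect_true(all(abs(ev$offset - tr$truth$offset) <= 10))
    expect_true(all(abs(ev$amplitude - tr$truth$amplitude) < 0.2))
    # peak velocity follows the generating main sequence
    expect_true(all(abs(ev$peak_velocity - tr$truth$peak_velocity) /
                      tr$truth$peak_velocity < 0.05))
  }
})

test_that("a constant-position trace contains no saccades", {
  tr <- structure(list(
    samples = tibble::tibble(time_ms = 0:999, x = 3, y = -2),
    events = list(fixation_onset = 0, stimulus_onset = 100,
                  trial_end = 999),
    sampling_rate = 1000, array = NULL, truth = NULL),
    class = "eye_trace")
  expect_identical(nrow(detect_saccades(tr)), 0L)
})

test_that("sub-amplitude movements are rejected by the displacement rule", {
  # a 1.5-degree movement with saccadic speed profile
  dur <- 20
  sgm <- seq_len(dur) / dur
  mj <- 10 * sgm^3 - 15 * sgm^4 + 6 * sgm^5
  x <- c(rep(0, 300), 1.5 * mj, rep(1.5, 300))
  tr <- structure(list(
    samples = tibble::tibble(time_ms = seq_along(x) - 1, x = x, y = 0),
    events = list(fixation_onset = 0, stimulus_onset = 100,
                  trial_end = length(x) - 1),
    sampling_rate = 1000, array = NULL, truth = NULL),
    class = "eye_trace")
  expect_identical(nrow(detect_saccades(tr)), 0L)
})

test_that("choice registration recovers the generating sequence", {
  set.seed(62)
  s <- generate_session(forage_params(10, 2, 0.9), 10)
  for (trial in s$trials) {
    tr <- generate_eye_trace(trial)
    expect_identical(register_choices(tr), as.integer(trial$choices))
  }
})

test_that("dwells shorter than the threshold are not registered", {
  set.seed(63)
  s <- generate_session(forage_params(10, 2, 0.9), 3)
  trial <- s$trials[[which.max(vapply(s$trials,
                                      function(t) length(t$choices),
                                      numeric(1)))]]
  tr <- generate_eye_trace(trial, mean_isi = 220, tail_ms = 150)
  # raising the dwell criterion above the fixation durations must drop
  # every registration that the default criterion accepts
  expect_identical(register_choices(tr), as.integer(trial$choices))
  expect_length(register_choices(tr, dwell_ms = 400), 0L)
})

test_that("postsaccadic drift estimates recover the implanted magnitude", {
  traces <- make_trace(seed = 64, n_trials = 6, drift_magnitude = 0.5)
  drifts <- unlist(lapply(traces, function(tr)
    postsaccadic_drift(tr, detect_saccades(tr))))
  drifts <- drifts[!is.na(drifts)]
  expect_gt(length(drifts), 10L)
  expect_lt(abs(mean(drifts) - 0.5), 0.1)
  # and a clean trace has drift at the noise floor
  clean <- make_trace(seed = 64, n_trials = 2, drift_magnitude = 0)
  d0 <- unlist(lapply(clean, function(tr)
    postsaccadic_drift(tr, detect_saccades(tr))))
  expect_lt(max(d0, na.rm = TRUE), 0.05)
})

test_that("truncated drift windows are flagged missing", {
  traces <- make_trace(seed = 65, n_trials = 1, tail_ms = 150)
  tr <- traces[[1]]
  ev <- detect_saccades(tr)
  # shrink the trace so the last window is truncated
  tr$samples <- tr$samples[seq_len(ev$offset[nrow(ev)] + 50), ]
  d <- postsaccadic_drift(tr, ev)
  expect_true(is.na(d[length(d)]))
})

test_that("intersaccadic intervals match the generator's dwell times", {
  expect_identical(
    intersaccadic_intervals(tibble::tibble(onset = c(900, 1250),
                                           offset = c(1000, 1300))),
    250)
  traces <- make_trace(seed = 66, n_trials = 10, mean_isi = 220)
  isis <- unlist(lapply(traces, function(tr)
    intersaccadic_intervals(detect_saccades(tr))))
  expect_gt(length(isis), 20L)
  expect_lt(abs(mean(isis) - 220) / 220, 0.05)
  expect_identical(intersaccadic_intervals(tibble::tibble(onset = 1,
                                                          offset = 2)),
                   numeric(0))
})

test_that("main-sequence fitting recovers noiseless parameters", {
  set.seed(67)
  amp <- runif(100, 3, 30)
  v <- 500 * (1 - exp(-0.1 * amp))
  fit <- fit_main_sequence(amp, v)
  expect_lt(abs(fit$e_max - 500) / 500, 0.02)
  expect_lt(abs(fit$tau + 0.1) / 0.1, 0.02)
  expect_equal(fit$v20, 500 * (1 - exp(-2)), tolerance = 0.02)
  expect_equal(main_sequence_velocity(fit, 20), fit$v20)
})

test_that("main-sequence fitting tolerates multiplicative noise", {
  set.seed(68)
  v20s <- replicate(20, {
    amp <- runif(300, 3, 30)
    v <- 500 * (1 - exp(-0.1 * amp)) * (1 + rnorm(300, 0, 0.1))
    fit_main_sequence(amp, v)$v20
  })
  expect_true(all(abs(v20s - 500 * (1 - exp(-2))) / (500 * (1 - exp(-2)))
                  < 0.05))
})

test_that("main-sequence fit is scale-consistent and plateaus", {
  set.seed(69)
  amp <- runif(150, 3, 30)
  v <- 480 * (1 - exp(-0.12 * amp))
  f1 <- fit_main_sequence(amp, v)
  f2 <- fit_main_sequence(amp, 2.5 * v)
  expect_equal(f2$e_max / f1$e_max, 2.5, tolerance = 1e-3)
  expect_equal(f2$tau, f1$tau, tolerance = 1e-3)
  # amplitudes far beyond 1/|tau| approach the asymptote
  expect_lt(abs(main_sequence_velocity(f1, 100) - f1$e_max), 1e-3 * f1$e_max)
  expect_error(fit_main_sequence(amp[1:3], v[1:3]), "at least 5")
  expect_error(fit_main_sequence(rep(10, 20) + runif(20, 0, 1),
                                 rep(300, 20)), "amplitude range")
})

test_that("saccade gain follows the projection identities", {
  expect_equal(saccade_gain(c(10, 0), c(10, 0)), 1)
  expect_equal(saccade_gain(c(0, 7), c(7, 0)), 0)
  g <- saccade_gain(10 * c(cos(pi / 4), sin(pi / 4)), c(10, 0))
  expect_equal(g, sqrt(2) / 2)
  expect_error(saccade_gain(c(1, 1), c(0, 0)), "zero target")
  # rotation invariance
  set.seed(70)
  for (i in 1:10) {
    s <- runif(2, -10, 10)
    t <- runif(2, -10, 10) + c(1, 0)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    expect_equal(saccade_gain(as.numeric(R %*% s), as.numeric(R %*% t)),
                 saccade_gain(s, t))
  }
})

test_that("virtual-window exclusion flags excursions at the expected rate", {
  set.seed(71)
  s <- generate_session(forage_params(10, 2, 0.9), 40)
  excursion <- rbinom(40, 1, 0.2) == 1
  flags <- vapply(seq_len(40), function(i) {
    tr <- generate_eye_trace(s$trials[[i]])
    if (excursion[i]) {
      j <- nrow(tr$samples) - 100
      tr$samples$x[j:(j + 50)] <- 30  # 6 degrees beyond the window edge
    }
    exclude_trial(tr)
  }, logical(1))
  expect_identical(flags, excursion)
})
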