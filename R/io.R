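SESSION_SCHEMA_VERSION <- 1L

num_chr <- function(x) sprintf("%.17g", x)  # exact double round trip

#' Write a session to a text file
#'
#' Sessions are stored as CSV with a one-line JSON header (prefixed
#' `#oculoforage-session `) carrying the schema version, subject,
#' condition, injection time, timing, and task dimensions. Per-trial
#' vector fields (choices, saccade timestamps, site coordinates) are
#' semicolon-joined within their CSV field, so files stay diff-able and
#' spreadsheet-openable. Numeric fields are written with full double
#' precision; the round trip through [read_session()] is lossless.
#'
#' @param session a `forage_session`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "forage_session"))
  header <- jsonlite::toJSON(list(
    schema_version = SESSION_SCHEMA_VERSION,
    subject = session$subject,
    condition = session$condition,
    injection_minutes = session$injection_minutes,
    timing = unclass(session$timing),
    n_objects = session$n_objects,
    max_saccades = session$max_saccades), auto_unbox = TRUE, digits = NA,
    na = "null")
  rows <- lapply(session$trials, function(tr) {
    data.frame(
      trial = tr$trial,
      target = tr$target,
      found = tr$found,
      censored = tr$censored,
      t_start_ms = num_chr(tr$t_start_ms),
      fixation_ms = num_chr(tr$fixation_ms),
      choices = paste(tr$choices, collapse = ";"),
      saccade_t_ms = paste(num_chr(tr$saccade_t_ms), collapse = ";"),
      sites = paste(apply(tr$array$sites, 1L,
                          function(p) paste(num_chr(p), collapse = " ")),
                    collapse = ";"),
      fixation_xy = paste(num_chr(tr$array$fixation), collapse = " "),
      excluded = tr$excluded,
      exclude_reason = ifelse(is.na(tr$exclude_reason), "",
                              tr$exclude_reason),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#oculoforage-session ", header), con)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

parse_num_field <- function(x) {
  if (!nzchar(x)) return(numeric(0))
  as.numeric(strsplit(x, ";", fixed = TRUE)[[1L]])
}

#' Read a session file
#'
#' Parses and validates the dialect written by [write_session()].
#' Malformed rows produce errors naming the offending trial row and
#' field; a schema-version mismatch is an error.
#'
#' @param path file path.
#' @return A `forage_session`.
#' @export
read_session <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#oculoforage-session "))
    stop("not a session file (missing header line): ", path, call. = FALSE)
  header <- jsonlite::fromJSON(sub("^#oculoforage-session ", "", first))
  if (!identical(as.integer(header$schema_version), SESSION_SCHEMA_VERSION))
    stop("unsupported session schema version: ", header$schema_version,
         call. = FALSE)
  df <- utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE,
                        colClasses = c(choices = "character",
                                       saccade_t_ms = "character",
                                       sites = "character",
                                       fixation_xy = "character",
                                       exclude_reason = "character"))
  n_objects <- as.integer(header$n_objects)
  trials <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    choices <- as.integer(parse_num_field(r$choices))
    if (any(choices < 1L | choices > n_objects))
      stop(sprintf("row %d: choice index outside 1..%d", i, n_objects),
           call. = FALSE)
    if (r$found && r$censored)
      stop(sprintf("row %d: found and censored are mutually exclusive", i),
           call. = FALSE)
    site_vals <- lapply(strsplit(r$sites, ";", fixed = TRUE)[[1L]],
                        function(p) as.numeric(strsplit(p, " ")[[1L]]))
    sites <- do.call(rbind, site_vals)
    if (ncol(sites) != 2L || nrow(sites) != n_objects)
      stop(sprintf("row %d: malformed sites field", i), call. = FALSE)
    colnames(sites) <- c("x", "y")
    list(trial = r$trial,
         array = structure(list(sites = sites,
                                target_index = r$target,
                                fixation = as.numeric(
                                  strsplit(r$fixation_xy, " ")[[1L]])),
                           class = "stimulus_array"),
         target = r$target,
         choices = choices,
         found = r$found,
         censored = r$censored,
         t_start_ms = as.numeric(r$t_start_ms),
         fixation_ms = as.numeric(r$fixation_ms),
         saccade_t_ms = parse_num_field(r$saccade_t_ms),
         excluded = r$excluded,
         exclude_reason = if (nzchar(r$exclude_reason)) r$exclude_reason
                          else NA_character_)
  })
  t_starts <- vapply(trials, `[[`, numeric(1), "t_start_ms")
  if (any(diff(t_starts) <= 0))
    stop("trial timestamps are not strictly increasing", call. = FALSE)
  timing <- header$timing
  structure(list(subject = header$subject, condition = header$condition,
                 injection_minutes =
                   if (is.null(header$injection_minutes)) NA_real_
                   else as.numeric(header$injection_minutes),
                 timing = structure(list(
                   fixation_range = as.numeric(timing$fixation_range),
                   search_limit = as.numeric(timing$search_limit),
                   reward_delay = as.numeric(timing$reward_delay),
                   intertrial_interval =
                     as.numeric(timing$intertrial_interval),
                   mean_isi = as.numeric(timing$mean_isi),
                   sd_isi = as.numeric(timing$sd_isi)),
                   class = "session_timing"),
                 drug = NULL, params = NULL,
                 n_objects = n_objects,
                 max_saccades = as.integer(header$max_saccades),
                 trials = trials),
            class = "forage_session")
}

#' Write / read a 1-kHz eye trace
#'
#' The trace goes to a two-column CSV (`time_ms`, `x`, `y`, degrees)
#' with a JSON sidecar (`<path>.json`) holding the sampling rate,
#' units, and event timestamps.
#'
#' @param trace an `eye_trace`.
#' @param path CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_eye_trace <- function(trace, path) {
  stopifnot(inherits(trace, "eye_trace"))
  utils::write.csv(
    data.frame(time_ms = trace$samples$time_ms,
               x = num_chr(trace$samples$x),
               y = num_chr(trace$samples$y)),
    path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(sampling_rate = trace$sampling_rate,
                            units = "degrees",
                            events = trace$events),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_eye_trace
#' @export
read_eye_trace <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  df <- utils::read.csv(path)
  structure(list(samples = tibble::tibble(time_ms = df$time_ms,
                                          x = df$x, y = df$y),
                 events = lapply(meta$events, as.numeric),
                 sampling_rate = as.numeric(meta$sampling_rate),
                 array = NULL, truth = NULL),
            class = "eye_trace")
}

#' Run the full analysis pipeline on synthetic sessions
#'
#' Executes generate, summarize, fit, and optionally bootstrap and
#' sliding-window stages as configured, and returns (optionally writes)
#' a JSON-serializable report carrying every seed and option, so any
#' number in the report can be reproduced from its provenance block.
#' All randomness derives from `config$seed` via fixed per-stage
#' offsets (generate: +1, grid: +2, bootstrap: +3), so stages can be
#' re-run in isolation.
#'
#' @param config a list (or path to a JSON file) with elements:
#'   `seed`; `params` (length-3 numeric: capacity, decay, utility);
#'   `n_trials`; `n_sessions` (default 1); optional `grid`
#'   (`n_sim_trials`, `cache_path`); optional `bootstrap` (`n_boot`);
#'   optional `timecourse` (`window_minutes`, `step_minutes`, `drug`
#'   profile fields, `injection_minutes`).
#' @param out optional path for the JSON report.
#' @return The report list, invisibly if `out` is given.
#' @export
run_pipeline <- function(config, out = NULL) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  if (is.null(config$seed) || is.null(config$params) ||
      is.null(config$n_trials))
    stop("config requires `seed`, `params`, `n_trials`", call. = FALSE)
  tc <- config$timecourse
  if (!is.null(tc) && !is.null(tc$step_minutes) &&
      !is.null(tc$window_minutes) && tc$step_minutes > tc$window_minutes)
    stop("config: timecourse step must not exceed window length",
         call. = FALSE)
  seed <- as.integer(config$seed)
  params <- as_forage_params(as.numeric(config$params))
  n_sessions <- if (is.null(config$n_sessions)) 1L
                else as.integer(config$n_sessions)
  grid_opts <- config$grid
  n_sim <- if (is.null(grid_opts$n_sim_trials)) 1000L
           else as.integer(grid_opts$n_sim_trials)

  drug <- NULL
  injection <- NA_real_
  if (!is.null(tc)) {
    drug <- drug_profile(
      effect_scale = unlist(tc$effect_scale),
      onset_minutes = tc$onset_minutes %||% 10,
      recovery_halflife_minutes = tc$recovery_halflife_minutes %||% 20)
    injection <- tc$injection_minutes %||% 0
  }

  set.seed(seed + 1L)
  sessions <- lapply(seq_len(n_sessions), function(i)
    generate_session(params, as.integer(config$n_trials), drug = drug,
                     injection_minutes = injection,
                     subject = sprintf("synthetic-%02d", i)))
  pooled <- session_outcomes(sessions)
  observed <- summarize_trials(pooled)

  cache <- build_grid_cache(n_sim_trials = n_sim, seed = seed + 2L,
                            path = grid_opts$cache_path)
  fit <- fit_forage_model(observed, cache)

  report <- list(
    provenance = list(seed = seed,
                      stage_seeds = list(generate = seed + 1L,
                                         grid = seed + 2L,
                                         bootstrap = seed + 3L),
                      params = as.numeric(params),
                      n_trials = as.integer(config$n_trials),
                      n_sessions = n_sessions,
                      n_sim_trials = n_sim),
    generate = list(n_pooled_trials = length(pooled$choices),
                    found_rate = mean(pooled$found),
                    mean_saccades = mean(pooled$n_saccades)),
    summary = list(position = observed$position,
                   distance = observed$distance,
                   count = observed$count,
                   zero_flags = as.list(observed$zero_flags)),
    fit = list(capacity = fit$best_params$capacity,
               decay = fit$best_params$decay,
               utility = fit$best_params$utility,
               cd = fit$best_cd, reliable = fit$reliable))

  if (!is.null(config$bootstrap)) {
    set.seed(seed + 3L)
    bs <- bootstrap_intervals(pooled, cache,
                              n_boot = as.integer(config$bootstrap$n_boot))
    report$bootstrap <- list(n_boot = bs$n_boot,
                             intervals = as.data.frame(bs$intervals))
  }
  if (!is.null(tc)) {
    tw <- sliding_window_fit(sessions, cache,
                             window_minutes = tc$window_minutes %||% 10,
                             step_minutes = tc$step_minutes %||% 5)
    report$timecourse <- as.data.frame(tw)
  }
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         na = "null")
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
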