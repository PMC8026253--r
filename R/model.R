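#' Update the agent's working-memory store after visiting an object
#'
#' The store is an ordered integer vector, oldest first. Registering a
#' new item when the store is at `capacity` first evicts one of the
#' `decay` oldest entries, chosen uniformly (`decay = 1`: strictly the
#' oldest; `decay = capacity`: any entry with equal probability), then
#' appends the new item as most recent. Re-registering an item already
#' in the store moves it to most recent without eviction
#' (`refresh = "refresh"`, the default) or leaves the store untouched
#' (`refresh = "ignore"`).
#'
#' @param memory integer vector of stored object indices, oldest first.
#' @param new_item object index to register.
#' @param params a [forage_params()] object.
#' @param refresh what to do when `new_item` is already stored.
#' @return The updated memory vector.
#' @examples
#' p <- forage_params(10, 1, 0.9)
#' update_memory(1:10, 11L, p)  # oldest (1) dropped
#' @export
update_memory <- function(memory, new_item, params,
                          refresh = c("refresh", "ignore")) {
  refresh <- match.arg(refresh)
  params <- as_forage_params(params)
  pos <- match(new_item, memory)
  if (!is.na(pos)) {
    if (refresh == "ignore") return(memory)
    return(c(memory[-pos], new_item))
  }
  if (length(memory) >= params$capacity) {
    memory <- memory[-runif_index(params$decay)]
  }
  c(memory, new_item)
}

#' Choose the next object to inspect
#'
#' With probability `utility` the agent exploits its memory: the choice
#' is uniform among objects neither stored in memory nor currently
#' fixated. With probability `1 - utility` (or when the exploit
#' candidate set is empty) it explores: uniform among all objects except
#' the currently fixated one. At the start of a trial gaze is on the
#' fixation point, not on an object (`current = NA`), so all `n_objects`
#' are candidates.
#'
#' @param current index of the currently fixated object, or `NA` at
#'   trial start.
#' @param memory integer vector of remembered object indices.
#' @param params a [forage_params()] object.
#' @param n_objects number of objects in the array.
#' @return A single object index in `1:n_objects`.
#' @export
choose_next <- function(current, memory, params, n_objects = 15L) {
  params <- as_forage_params(params)
  if (n_objects < 2L) stop("`n_objects` must be at least 2", call. = FALSE)
  if (is.null(current) || is.na(current))
    return(runif_index(n_objects))
  if (stats::runif(1L) < params$utility) {
    cand <- setdiff(seq_len(n_objects), c(current, memory))
    # note candidate order must stay ascending (compiled engine lockstep)
    if (length(cand) > 0L) return(cand[runif_index(length(cand))])
  }
  k <- runif_index(n_objects - 1L)
  if (k >= current) k + 1L else k
}

#' Simulate a single foraging trial
#'
#' A hidden target is drawn uniformly among the `n_objects` identical
#' objects. The agent inspects objects one saccade at a time via
#' [choose_next()], registering each visited non-target object with
#' [update_memory()]. The trial ends when the target is found
#' (`found = TRUE`) or after `max_saccades` choices
#' (`censored = TRUE`).
#'
#' @param params a [forage_params()] object.
#' @param n_objects number of objects in the array.
#' @param max_saccades saccade cap per trial.
#' @return A list with elements `choices` (integer vector),
#'   `target`, `found`, `censored`, `n_saccades`.
#' @export
simulate_trial <- function(params, n_objects = 15L, max_saccades = 25L) {
  params <- as_forage_params(params)
  if (max_saccades < 1L) stop("`max_saccades` must be >= 1", call. = FALSE)
  target <- runif_index(n_objects)
  memory <- integer(0)
  current <- NA_integer_
  choices <- integer(0)
  found <- FALSE
  for (s in seq_len(max_saccades)) {
    ch <- choose_next(current, memory, params, n_objects)
    choices <- c(choices, ch)
    if (ch == target) {
      found <- TRUE
      break
    }
    memory <- update_memory(memory, ch, params)
    current <- ch
  }
  list(choices = choices, target = target, found = found,
       censored = !found, n_saccades = length(choices))
}

#' Monte-Carlo simulation of the foraging agent
#'
#' Runs `n_trials` independent trials of [simulate_trial()]. The default
#' `engine = "compiled"` uses the C++ core; `engine = "reference"` runs
#' the interpreted R implementation. Both engines consume the R RNG
#' stream identically, so under a fixed seed they produce bit-identical
#' outcomes.
#'
#' @param params a [forage_params()] object.
#' @param n_trials number of trials to simulate.
#' @param n_objects number of objects in the array.
#' @param max_saccades saccade cap per trial.
#' @param engine `"compiled"` (default) or `"reference"`.
#' @return An object of class `forage_trials`: a list with parallel
#'   elements `choices` (list of integer vectors), `target`, `found`,
#'   `censored`, `n_saccades`, plus the generating `params`.
#' @examples
#' set.seed(1)
#' tr <- simulate_agent(forage_params(10, 2, 0.9), n_trials = 100)
#' mean(tr$n_saccades)
#' @export
simulate_agent <- function(params, n_trials = 5000L, n_objects = 15L,
                           max_saccades = 25L,
                           engine = c("compiled", "reference")) {
  params <- as_forage_params(params)
  engine <- match.arg(engine)
  if (n_trials < 1L) stop("`n_trials` must be >= 1", call. = FALSE)
  if (engine == "compiled") {
    raw <- simulate_trials_cpp(params$capacity, params$decay, params$utility,
                               as.integer(n_objects), as.integer(max_saccades),
                               as.integer(n_trials))
    out <- list(choices = raw$choices, target = raw$target, found = raw$found,
                censored = !raw$found, n_saccades = raw$n_saccades)
  } else {
    trials <- lapply(seq_len(n_trials), function(i)
      simulate_trial(params, n_objects, max_saccades))
    out <- list(choices = lapply(trials, `[[`, "choices"),
                target = vapply(trials, `[[`, integer(1), "target"),
                found = vapply(trials, `[[`, logical(1), "found"),
                censored = vapply(trials, `[[`, logical(1), "censored"),
                n_saccades = vapply(trials, `[[`, integer(1), "n_saccades"))
  }
  out$params <- params
  out$n_objects <- as.integer(n_objects)
  out$max_saccades <- as.integer(max_saccades)
  class(out) <- "forage_trials"
  out
}

#' @export
print.forage_trials <- function(x, ...) {
  cat(sprintf(
    "<forage_trials> %d trials, %d objects; found %.1f%%, mean saccades %.2f\n",
    length(x$choices), x$n_objects, 100 * mean(x$found), mean(x$n_saccades)))
  invisible(x)
}

#' Subset a collection of simulated or recorded trials
#'
#' @param trials a `forage_trials` object.
#' @param idx integer indices (duplicates allowed, e.g. for bootstrap
#'   resampling).
#' @return A `forage_trials` object with the selected trials.
#' @export
trials_subset <- function(trials, idx) {
  stopifnot(inherits(trials, "forage_trials"))
  out <- trials
  out$choices <- trials$choices[idx]
  out$target <- trials$target[idx]
  out$found <- trials$found[idx]
  out$censored <- trials$censored[idx]
  out$n_saccades <- trials$n_saccades[idx]
  out
}
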