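#' Foraging-model parameters
#'
#' Construct and validate the three-parameter description of the
#' memory-guided foraging agent:
#'
#' * `capacity` — maximal number of inspected objects held in working
#'   memory at once (integer, 1--15);
#' * `decay` — order-of-forgetting parameter: when the store is full,
#'   the evicted item is drawn uniformly among the `decay` oldest
#'   entries (1 = strictly oldest, `capacity` = uniformly random;
#'   integer, 1--`capacity`);
#' * `utility` — probability that a choice consults the memory store
#'   (exploit) rather than picking uniformly among all non-current
#'   objects (explore); in `[0, 1]`.
#'
#' @param capacity integer memory capacity.
#' @param decay integer order-of-forgetting parameter.
#' @param utility utility rate in `[0, 1]`.
#' @return An object of class `forage_params`: a named list with
#'   elements `capacity`, `decay`, `utility`.
#' @examples
#' forage_params(10, 2, 0.9)
#' @export
forage_params <- function(capacity, decay, utility) {
  if (length(capacity) != 1L || is.na(capacity) || capacity != round(capacity))
    stop("`capacity` must be a single integer", call. = FALSE)
  if (length(decay) != 1L || is.na(decay) || decay != round(decay))
    stop("`decay` must be a single integer", call. = FALSE)
  if (length(utility) != 1L || is.na(utility))
    stop("`utility` must be a single number", call. = FALSE)
  capacity <- as.integer(capacity)
  decay <- as.integer(decay)
  utility <- as.numeric(utility)
  if (capacity < 1L || capacity > 15L)
    stop("`capacity` must be between 1 and 15", call. = FALSE)
  if (decay < 1L || decay > capacity)
    stop("`decay` must be between 1 and `capacity`", call. = FALSE)
  if (utility < 0 || utility > 1)
    stop("`utility` must be in [0, 1]", call. = FALSE)
  structure(list(capacity = capacity, decay = decay, utility = utility),
            class = "forage_params")
}

#' @export
print.forage_params <- function(x, ...) {
  cat(sprintf("<forage_params> capacity = %d, decay = %d, utility = %.2f\n",
              x$capacity, x$decay, x$utility))
  invisible(x)
}

#' @export
as.numeric.forage_params <- function(x, ...) {
  c(capacity = x$capacity, decay = x$decay, utility = x$utility)
}

as_forage_params <- function(x) {
  if (inherits(x, "forage_params")) return(x)
  if (is.numeric(x) && length(x) == 3L)
    return(forage_params(x[[1L]], x[[2L]], x[[3L]]))
  if (is.list(x) && all(c("capacity", "decay", "utility") %in% names(x)))
    return(forage_params(x$capacity, x$decay, x$utility))
  stop("cannot interpret `x` as foraging-model parameters", call. = FALSE)
}

# Index draws use floor(u * n) on a single unif_rand() deviate so the
# interpreted engine consumes the exact same RNG stream as the compiled one.
runif_index <- function(n) {
  k <- floor(stats::runif(1L) * n) + 1L
  if (k > n) n else as.integer(k)
}
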