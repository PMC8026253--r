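#' Candidate stimulus grid
#'
#' The task places objects on a 7 x 11 rectangular grid with 4 degrees
#' of visual angle between adjacent sites (77 sites covering roughly a
#' 25 x 40 degree area, centered on the screen center).
#'
#' @param n_rows,n_cols grid dimensions (rows span the vertical axis).
#' @param spacing inter-site spacing in degrees.
#' @return A numeric matrix with columns `x`, `y` (degrees), one row
#'   per site, in deterministic row-major order.
#' @export
stimulus_grid <- function(n_rows = 7L, n_cols = 11L, spacing = 4) {
  x <- (seq_len(n_cols) - (n_cols + 1) / 2) * spacing
  y <- (seq_len(n_rows) - (n_rows + 1) / 2) * spacing
  g <- cbind(x = rep(x, times = n_rows), y = rep(y, each = n_cols))
  g
}

#' Generate one trial's stimulus array
#'
#' Samples 15 distinct sites uniformly without replacement from the
#' candidate grid minus the site nearest the fixation point (76
#' candidates for the default 77-site grid), and draws the rewarded
#' target uniformly among the 15. Grid spacing guarantees all pairwise
#' distances are at least 4 degrees.
#'
#' @param n_sites number of objects per trial.
#' @param fixation fixation-point position `c(x, y)` in degrees; the
#'   candidate site nearest to it is excluded.
#' @param grid candidate site matrix, as from [stimulus_grid()].
#' @return An object of class `stimulus_array`: a list with `sites`
#'   (`n_sites` x 2 matrix, degrees), `target_index`, `fixation`.
#' @examples
#' set.seed(1)
#' arr <- generate_stimulus_array()
#' min(dist(arr$sites))  # >= 4
#' @export
generate_stimulus_array <- function(n_sites = 15L, fixation = c(0, 0),
                                    grid = stimulus_grid()) {
  d2 <- (grid[, 1] - fixation[1])^2 + (grid[, 2] - fixation[2])^2
  candidates <- grid[-which.min(d2), , drop = FALSE]
  if (n_sites > nrow(candidates))
    stop("more sites requested than candidates available", call. = FALSE)
  picked <- sample.int(nrow(candidates), n_sites)
  structure(list(sites = candidates[picked, , drop = FALSE],
                 target_index = sample.int(n_sites, 1L),
                 fixation = as.numeric(fixation)),
            class = "stimulus_array")
}

#' Random-pair distance statistic
#'
#' For each session, repeatedly draws pairs of distinct object positions
#' from the session's realized trial arrays and averages their Euclidean
#' distances: the reference value against which initial saccade
#' amplitudes are compared (under random choice, consecutive inspections
#' would be separated by this distance on average). Each iteration
#' samples one trial uniformly and `pairs_per_iteration` object pairs
#' within it (`mode = "within"`, default); `mode = "across"` draws each
#' pair from an independently sampled trial.
#'
#' @param sessions a `forage_session` object or list of them.
#' @param pairs_per_iteration pairs drawn per iteration.
#' @param iterations number of iterations per session.
#' @param mode `"within"` or `"across"` (see Details).
#' @return Numeric vector of per-session mean pair distances (degrees).
#' @export
random_pair_distance_stat <- function(sessions, pairs_per_iteration = 5L,
                                      iterations = 100L,
                                      mode = c("within", "across")) {
  mode <- match.arg(mode)
  if (inherits(sessions, "forage_session")) sessions <- list(sessions)
  vapply(sessions, function(sess) {
    arrays <- lapply(sess$trials, function(tr) tr$array$sites)
    n_tr <- length(arrays)
    d <- numeric(iterations * pairs_per_iteration)
    k <- 0L
    for (it in seq_len(iterations)) {
      if (mode == "within") {
        s <- arrays[[sample.int(n_tr, 1L)]]
        for (p in seq_len(pairs_per_iteration)) {
          ij <- sample.int(nrow(s), 2L)
          k <- k + 1L
          d[k] <- sqrt(sum((s[ij[1L], ] - s[ij[2L], ])^2))
        }
      } else {
        for (p in seq_len(pairs_per_iteration)) {
          s <- arrays[[sample.int(n_tr, 1L)]]
          ij <- sample.int(nrow(s), 2L)
          k <- k + 1L
          d[k] <- sqrt(sum((s[ij[1L], ] - s[ij[2L], ])^2))
        }
      }
    }
    mean(d)
  }, numeric(1))
}
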