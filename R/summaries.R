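#' Revisit flags for a choice sequence
#'
#' Flag `k` is `TRUE` iff the object chosen at saccade `k` was already
#' inspected earlier in the same trial (a recursive choice).
#'
#' @param choices integer vector of visited object indices.
#' @return Logical vector, one flag per saccade.
#' @examples
#' revisit_flags(c(3, 7, 3))  # FALSE FALSE TRUE
#' @export
revisit_flags <- function(choices) {
  duplicated(choices)
}

#' Revisit distances (index lags)
#'
#' For each revisit, the number of saccades since the most recent
#' previous inspection of the same object, measured as the difference
#' of saccade indices: an A-B-A pattern has distance 2. Because the
#' currently fixated object is never a candidate, the minimum possible
#' distance is 2.
#'
#' @param choices integer vector of visited object indices.
#' @return Integer vector of lags, one per revisit (possibly empty),
#'   in order of occurrence.
#' @examples
#' revisit_distances(c(1, 2, 1, 2, 1))  # 2 2 2
#' @export
revisit_distances <- function(choices) {
  n <- length(choices)
  if (n < 2L) return(integer(0))
  idx <- seq_len(n)
  flags <- duplicated(choices)
  if (!any(flags)) return(integer(0))
  last_seen <- integer(max(choices))
  out <- integer(sum(flags))
  j <- 0L
  for (k in idx) {
    obj <- choices[k]
    if (last_seen[obj] > 0L) {
      j <- j + 1L
      out[j] <- k - last_seen[obj]
    }
    last_seen[obj] <- k
  }
  out
}

#' The three 25-bin behavioral summary distributions
#'
#' Computes the summary triplet that the model is fitted to, identically
#' for simulated and recorded trials:
#'
#' 1. **Revisit by position** — proportion of recursive choices at each
#'    saccade ordinal 1--`n_bins`, conditioned (by default) on trials
#'    surviving to that ordinal;
#' 2. **Revisit by distance** — histogram of revisit index-lags;
#' 3. **Saccade count** — histogram of per-trial saccade counts.
#'
#' Values beyond `n_bins` accumulate in the last bin. Each vector is
#' sum-normalized to 1; a component with no mass (e.g. no revisits under
#' a perfect-memory agent) is left all-zero and flagged rather than
#' raising an error.
#'
#' @param trials a `forage_trials` object (or a bare list of choice
#'   vectors).
#' @param n_bins number of bins per component.
#' @param denominator `"surviving"` (revisit proportion at ordinal `k`
#'   divided by the number of trials with at least `k` saccades, the
#'   default) or `"all"` (divided by the total trial count).
#' @return An object of class `summary_triplet`: normalized `position`,
#'   `distance`, `count` vectors, their unnormalized `raw_*`
#'   counterparts, `zero_flags`, and `n_trials`.
#' @examples
#' set.seed(1)
#' tr <- simulate_agent(forage_params(10, 2, 0.9), 1000)
#' s <- summarize_trials(tr)
#' sum(s$position)  # 1
#' @export
summarize_trials <- function(trials, n_bins = 25L,
                             denominator = c("surviving", "all")) {
  denominator <- match.arg(denominator)
  choices <- if (inherits(trials, "forage_trials")) trials$choices
             else trials
  n_trials <- length(choices)
  if (n_trials < 1L) stop("need at least one trial", call. = FALSE)
  ns <- lengths(choices)

  ord <- sequence(ns)
  fl <- unlist(lapply(choices, duplicated), use.names = FALSE)
  rev_count <- tabulate(pmin(ord[fl], n_bins), nbins = n_bins)

  # trials surviving to ordinal k (ordinals beyond n_bins clip into the
  # last bin, so its denominator is trials with >= n_bins saccades)
  cnt_hist <- tabulate(pmin(ns, n_bins), nbins = n_bins)
  surviving <- rev(cumsum(rev(cnt_hist)))
  denom <- if (denominator == "surviving") surviving
           else rep(n_trials, n_bins)
  pos_raw <- ifelse(denom > 0, rev_count / denom, 0)

  lags <- unlist(lapply(choices, revisit_distances), use.names = FALSE)
  dist_raw <- tabulate(pmin(lags, n_bins), nbins = n_bins)

  normalize <- function(v) {
    s <- sum(v)
    if (s > 0) v / s else as.numeric(v)
  }
  zero_flags <- c(position = sum(pos_raw) == 0,
                  distance = sum(dist_raw) == 0,
                  count = sum(cnt_hist) == 0)
  structure(list(position = normalize(pos_raw),
                 distance = normalize(dist_raw),
                 count = normalize(cnt_hist),
                 raw_position = as.numeric(pos_raw),
                 raw_distance = as.numeric(dist_raw),
                 raw_count = as.numeric(cnt_hist),
                 zero_flags = zero_flags,
                 n_trials = n_trials,
                 n_bins = as.integer(n_bins),
                 denominator = denominator),
            class = "summary_triplet")
}

#' @export
print.summary_triplet <- function(x, ...) {
  cat(sprintf(
    "<summary_triplet> %d trials, %d bins; zero-flagged: %s\n",
    x$n_trials, x$n_bins,
    if (any(x$zero_flags)) paste(names(which(x$zero_flags)), collapse = ", ")
    else "none"))
  invisible(x)
}

#' Concatenated fitting vector of a summary triplet
#'
#' The fixed concatenation order consumed by the fitting routines:
#' position, then distance, then count (75 bins by default). Zero-flagged
#' components contribute their zero bins, keeping the geometry fixed.
#'
#' @param x a `summary_triplet`.
#' @return Numeric vector of length `3 * n_bins`.
#' @export
as_fit_vector <- function(x) {
  stopifnot(inherits(x, "summary_triplet"))
  c(x$position, x$distance, x$count)
}
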