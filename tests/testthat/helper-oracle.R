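# Exact outcome-probability oracle for small agents, by exhaustive
# enumeration over all choice paths and memory-eviction branches.
# Independent of the simulation code: probabilities are propagated
# analytically from the model's choice and forgetting rules.
#
# Outcomes are keyed "c1.c2...|F" (found) or "c1.c2...|C" (censored).
enumerate_outcome_probs <- function(capacity, decay, utility, n_objects,
                                    max_saccades) {
  probs <- new.env(parent = emptyenv())
  add <- function(key, p) {
    cur <- if (is.null(probs[[key]])) 0 else probs[[key]]
    probs[[key]] <- cur + p
  }
  choice_probs <- function(current, memory) {
    if (is.na(current)) return(rep(1 / n_objects, n_objects))
    explore <- rep(1 / (n_objects - 1), n_objects)
    explore[current] <- 0
    cand <- setdiff(seq_len(n_objects), c(memory, current))
    if (length(cand) == 0L) return(explore)
    exploit <- numeric(n_objects)
    exploit[cand] <- 1 / length(cand)
    utility * exploit + (1 - utility) * explore
  }
  recurse <- function(seqv, current, memory, target, p) {
    if (length(seqv) == max_saccades) {
      add(paste0(paste(seqv, collapse = "."), "|C"), p)
      return(invisible(NULL))
    }
    pr <- choice_probs(current, memory)
    for (ch in which(pr > 0)) {
      pc <- p * pr[ch]
      if (ch == target) {
        add(paste0(paste(c(seqv, ch), collapse = "."), "|F"), pc)
      } else if (ch %in% memory) {
        recurse(c(seqv, ch), ch, c(memory[memory != ch], ch), target, pc)
      } else if (length(memory) >= capacity) {
        for (e in seq_len(decay))
          recurse(c(seqv, ch), ch, c(memory[-e], ch), target, pc / decay)
      } else {
        recurse(c(seqv, ch), ch, c(memory, ch), target, pc)
      }
    }
  }
  for (tg in seq_len(n_objects))
    recurse(integer(0), NA_integer_, integer(0), tg, 1 / n_objects)
  unlist(as.list(probs))
}

outcome_keys <- function(trials) {
  paste0(vapply(trials$choices, paste, character(1), collapse = "."),
         ifelse(trials$found, "|F", "|C"))
}

# One moderately sized grid cache shared across test files (built lazily,
# once per test run).
shared_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_grid_cache(n_sim_trials = 500L, seed = 20260901L)
    cache
  }
})
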