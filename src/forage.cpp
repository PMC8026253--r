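#include <Rcpp.h>
using namespace Rcpp;

// Core simulation of the memory-guided foraging agent.
//
// Object indices are 0-based internally and 1-based at the R boundary.
// All randomness goes through R's RNG (unif_rand), and every draw is a
// single unif_rand() call mapped by floor(u * n), so the interpreted
// reference implementation in R/model.R can reproduce the exact stream:
// set.seed(s) followed by either engine yields identical outcomes.

namespace {

inline int runif_int(int n) {
  // uniform on 0 .. n-1
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

struct Agent {
  int capacity;
  int decay;
  double utility;
  int n_objects;
  std::vector<int> memory;  // oldest first
  std::vector<int> cand;    // scratch

  Agent(int cap, int dec, double util, int n)
      : capacity(cap), decay(dec), utility(util), n_objects(n) {
    memory.reserve(cap);
    cand.reserve(n);
  }

  void reset() { memory.clear(); }

  bool in_memory(int item) const {
    for (size_t j = 0; j < memory.size(); ++j)
      if (memory[j] == item) return true;
    return false;
  }

  // current < 0 means the trial's first choice (gaze on the fixation
  // point, not on an object): uniform over all objects.
  int choose(int current) {
    if (current < 0) return runif_int(n_objects);
    if (unif_rand() < utility) {
      cand.clear();
      for (int o = 0; o < n_objects; ++o) {
        if (o == current) continue;
        if (!in_memory(o)) cand.push_back(o);
      }
      if (!cand.empty()) return cand[runif_int((int)cand.size())];
      // exploit set empty: fall through to the explore rule
    }
    int k = runif_int(n_objects - 1);
    return (k >= current) ? k + 1 : k;
  }

  void update(int item) {
    // re-registration refreshes recency, no eviction
    for (size_t j = 0; j < memory.size(); ++j) {
      if (memory[j] == item) {
        memory.erase(memory.begin() + j);
        memory.push_back(item);
        return;
      }
    }
    if ((int)memory.size() >= capacity) {
      // evict uniformly among the `decay` oldest entries
      memory.erase(memory.begin() + runif_int(decay));
    }
    memory.push_back(item);
  }
};

void sim_trial(Agent& ag, int max_saccades, std::vector<int>& choices,
               bool& found, int& target) {
  ag.reset();
  choices.clear();
  target = runif_int(ag.n_objects);
  found = false;
  int current = -1;
  for (int s = 0; s < max_saccades; ++s) {
    int c = ag.choose(current);
    choices.push_back(c);
    if (c == target) {
      found = true;
      break;
    }
    ag.update(c);
    current = c;
  }
}

}  // namespace

// [[Rcpp::export]]
List simulate_trials_cpp(int capacity, int decay, double utility,
                         int n_objects, int max_saccades, int n_trials) {
  Agent ag(capacity, decay, utility, n_objects);
  List choices(n_trials);
  LogicalVector found(n_trials);
  IntegerVector target(n_trials), n_sacc(n_trials);
  std::vector<int> ch;
  ch.reserve(max_saccades);
  bool f;
  int tg;
  for (int t = 0; t < n_trials; ++t) {
    sim_trial(ag, max_saccades, ch, f, tg);
    IntegerVector cv((int)ch.size());
    for (size_t j = 0; j < ch.size(); ++j) cv[j] = ch[j] + 1;
    choices[t] = cv;
    found[t] = f;
    target[t] = tg + 1;
    n_sacc[t] = (int)ch.size();
  }
  return List::create(_["choices"] = choices, _["found"] = found,
                      _["target"] = target, _["n_saccades"] = n_sacc);
}

// Simulate each parameter set and accumulate its normalized 3 x n_bins
// summary (revisit proportion by saccade ordinal conditioned on trials
// surviving to that ordinal, revisit-lag histogram, saccade-count
// histogram; overflow clipped into the last bin; each block
// sum-normalized unless all-zero).  One row per parameter set, columns
// [position | distance | count].  Must stay in lockstep with
// summarize_trials() in R/summaries.R.
// [[Rcpp::export]]
NumericMatrix grid_summaries_cpp(IntegerVector capacity, IntegerVector decay,
                                 NumericVector utility, int n_trials,
                                 int n_objects, int max_saccades, int n_bins,
                                 bool denom_all) {
  int n_grid = capacity.size();
  NumericMatrix out(n_grid, 3 * n_bins);
  std::vector<int> ch;
  ch.reserve(max_saccades);
  std::vector<int> last_pos(n_objects);
  std::vector<double> rev_cnt(n_bins), surv(n_bins), lag_cnt(n_bins),
      cnt_cnt(n_bins);
  bool f;
  int tg;

  for (int g = 0; g < n_grid; ++g) {
    Agent ag(capacity[g], decay[g], utility[g], n_objects);
    std::fill(rev_cnt.begin(), rev_cnt.end(), 0.0);
    std::fill(surv.begin(), surv.end(), 0.0);
    std::fill(lag_cnt.begin(), lag_cnt.end(), 0.0);
    std::fill(cnt_cnt.begin(), cnt_cnt.end(), 0.0);

    for (int t = 0; t < n_trials; ++t) {
      sim_trial(ag, max_saccades, ch, f, tg);
      int ns = (int)ch.size();
      std::fill(last_pos.begin(), last_pos.end(), 0);
      for (int k = 1; k <= ns; ++k) {
        int obj = ch[k - 1];
        int kk = (k < n_bins) ? k : n_bins;
        if (last_pos[obj] > 0) {
          rev_cnt[kk - 1] += 1.0;
          int lag = k - last_pos[obj];
          int lb = (lag < n_bins) ? lag : n_bins;
          lag_cnt[lb - 1] += 1.0;
        }
        last_pos[obj] = k;
      }
      int nb = (ns < n_bins) ? ns : n_bins;
      for (int k = 0; k < nb; ++k) surv[k] += 1.0;
      cnt_cnt[nb - 1] += 1.0;
    }

    double psum = 0.0, lsum = 0.0, csum = 0.0;
    for (int k = 0; k < n_bins; ++k) {
      double denom = denom_all ? (double)n_trials : surv[k];
      double p = (denom > 0.0) ? rev_cnt[k] / denom : 0.0;
      out(g, k) = p;
      psum += p;
      lsum += lag_cnt[k];
      csum += cnt_cnt[k];
    }
    for (int k = 0; k < n_bins; ++k) {
      if (psum > 0.0) out(g, k) /= psum;
      out(g, n_bins + k) = (lsum > 0.0) ? lag_cnt[k] / lsum : 0.0;
      out(g, 2 * n_bins + k) = (csum > 0.0) ? cnt_cnt[k] / csum : 0.0;
    }
    if (g % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
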