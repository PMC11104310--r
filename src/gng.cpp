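#include <Rcpp.h>
using namespace Rcpp;

// Natural-scale parameter slots, fixed order (filled by par_slots() on the
// R side, with neutral values for inactive components so no model flags are
// needed here):
//   0 alpha      learning rate, win-valence stimuli
//   1 beta       reward sensitivity (scales outcomes in the update)
//   2 b          go bias (0 when absent)
//   3 xi         lapse, win-valence stimuli (0 when absent)
//   4 pi_app     Pavlovian weight, win stimuli, administrations 1-2
//   5 pi_av      Pavlovian weight, loss stimuli, administrations 1-3
//   6 pi_app_post  win weight from administration 3 on (= pi_app if fixed)
//   7 pi_av_post   loss weight from administration 4 on (= pi_av if fixed)
//   8 alpha_loss learning rate, loss-valence stimuli (= alpha when shared)
//   9 xi_loss    lapse, loss-valence stimuli (= xi when shared)

static inline double p_go_of(const double wgo, const double wnogo,
                             const double xi) {
  double m = wgo > wnogo ? wgo : wnogo;
  double ego = std::exp(wgo - m), eng = std::exp(wnogo - m);
  double p = ego / (ego + eng);
  return p * (1.0 - xi) + xi / 2.0;
}

// Per-trial log-probability of the observed action. Trials must be ordered
// by administration then trial index; the learner state (Q, V) resets to
// zero whenever `administration` changes. `learn[t] == 0` skips the value
// update for that trial (used for the no-learning missed-response policy).
// [[Rcpp::export]]
NumericVector cpp_trial_loglik(IntegerVector condition, IntegerVector valence_win,
                               IntegerVector action_go, NumericVector outcome,
                               IntegerVector administration, IntegerVector learn,
                               NumericVector par) {
  const int n = condition.size();
  NumericVector ll(n);
  const double *p = REAL(par);
  double Q[2][4], V[4];
  int cur_admin = INT_MIN;
  for (int t = 0; t < n; ++t) {
    if (administration[t] != cur_admin) {
      cur_admin = administration[t];
      for (int s = 0; s < 4; ++s) { Q[0][s] = Q[1][s] = V[s] = 0.0; }
    }
    int s = condition[t] - 1;
    bool win = valence_win[t] == 1;
    double pi = win ? (cur_admin >= 3 ? p[6] : p[4])
                    : (cur_admin >= 4 ? p[7] : p[5]);
    double alpha = win ? p[0] : p[8];
    double xi = win ? p[3] : p[9];
    double wgo = Q[1][s] + p[2] + pi * V[s];
    double pg = p_go_of(wgo, Q[0][s], xi);
    double pa = action_go[t] == 1 ? pg : 1.0 - pg;
    ll[t] = std::log(pa);
    if (learn[t] == 1) {
      int a = action_go[t] == 1 ? 1 : 0;
      double r = outcome[t];
      Q[a][s] += alpha * (p[1] * r - Q[a][s]);
      V[s] += alpha * (p[1] * r - V[s]);
    }
  }
  return ll;
}

static inline int draw_outcome(const double *probs, double u) {
  // probs over outcomes {-1, 0, +1}
  if (u < probs[0]) return -1;
  if (u < probs[0] + probs[1]) return 0;
  return 1;
}

// Simulate one administration for a model-family agent. Outcome probability
// matrices are 4 (condition) x 3 (outcome -1/0/+1), one per action.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_simulate_admin(IntegerVector condition, IntegerVector valence_win,
                        NumericMatrix go_probs, NumericMatrix nogo_probs,
                        NumericVector par, int administration) {
  const int n = condition.size();
  IntegerVector action_go(n);
  NumericVector outcome(n);
  const double *p = REAL(par);
  double Q[2][4], V[4];
  for (int s = 0; s < 4; ++s) { Q[0][s] = Q[1][s] = V[s] = 0.0; }
  for (int t = 0; t < n; ++t) {
    int s = condition[t] - 1;
    bool win = valence_win[t] == 1;
    double pi = win ? (administration >= 3 ? p[6] : p[4])
                    : (administration >= 4 ? p[7] : p[5]);
    double alpha = win ? p[0] : p[8];
    double xi = win ? p[3] : p[9];
    double wgo = Q[1][s] + p[2] + pi * V[s];
    double pg = p_go_of(wgo, Q[0][s], xi);
    int a = R::runif(0.0, 1.0) < pg ? 1 : 0;
    double row[3];
    for (int k = 0; k < 3; ++k)
      row[k] = a == 1 ? go_probs(s, k) : nogo_probs(s, k);
    double r = (double) draw_outcome(row, R::runif(0.0, 1.0));
    action_go[t] = a;
    outcome[t] = r;
    Q[a][s] += alpha * (p[1] * r - Q[a][s]);
    V[s] += alpha * (p[1] * r - V[s]);
  }
  return List::create(_["action_go"] = action_go, _["outcome"] = outcome);
}
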