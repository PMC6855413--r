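#include <Rcpp.h>
using namespace Rcpp;

// Canonical natural-scale parameter layout used by the compiled core:
//   par[0] wMB    stage-1 weight on model-based values (>= 0)
//   par[1] wMF    stage-1 weight on model-free values (>= 0)
//   par[2] beta2  stage-2 softmax inverse temperature (>= 0)
//   par[3] alpha1 stage-1 learning rate in (0,1)
//   par[4] alpha2 stage-2 learning rate in (0,1)
//   par[5] lambda eligibility in (0,1)
//   par[6] p      perseveration (unbounded), multiplies a {0,1} repeat flag
//
// Model-based stage-1 values are computed from the instructed transition
// scheme (action k commonly leads to state k) and the current stage-2
// values; transition probabilities are fixed, not learned.

static inline void compute_qmb(const double q2[2][2], double pc, double out[2]) {
    double m0 = q2[0][0] > q2[0][1] ? q2[0][0] : q2[0][1];
    double m1 = q2[1][0] > q2[1][1] ? q2[1][0] : q2[1][1];
    out[0] = pc * m0 + (1.0 - pc) * m1;
    out[1] = pc * m1 + (1.0 - pc) * m0;
}

static inline double log_softmax_pick(double l0, double l1, int pick) {
    double mx = l0 > l1 ? l0 : l1;
    double lse = mx + std::log(std::exp(l0 - mx) + std::exp(l1 - mx));
    return (pick == 0 ? l0 : l1) - lse;
}

// [[Rcpp::export]]
double cpp_session_loglik(NumericVector par,
                          IntegerVector choice1, IntegerVector state2,
                          IntegerVector choice2, IntegerVector reward,
                          LogicalVector missed, double p_common) {
    const double wmb = par[0], wmf = par[1], b2 = par[2];
    const double a1 = par[3], a2 = par[4], lam = par[5], pp = par[6];
    double q1[2] = {0.0, 0.0};
    double q2[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
    int prev = -1;
    double ll = 0.0;
    const int n = choice1.size();
    for (int t = 0; t < n; ++t) {
        if (missed[t]) continue;
        const int c1 = choice1[t], s2 = state2[t], c2 = choice2[t];
        const double r = (double) reward[t];
        double qb[2];
        compute_qmb(q2, p_common, qb);
        double l0 = wmb * qb[0] + wmf * q1[0] + (prev == 0 ? pp : 0.0);
        double l1 = wmb * qb[1] + wmf * q1[1] + (prev == 1 ? pp : 0.0);
        ll += log_softmax_pick(l0, l1, c1);
        ll += log_softmax_pick(b2 * q2[s2][0], b2 * q2[s2][1], c2);
        // SARSA(lambda) updates; delta1 uses the pre-update stage-2 value
        double d1 = q2[s2][c2] - q1[c1];
        q1[c1] += a1 * d1;
        double d2 = r - q2[s2][c2];
        q2[s2][c2] += a2 * d2;
        q1[c1] += a1 * lam * d2;
        prev = c1;
    }
    return ll;
}

// Closed-loop simulation of one session. `walk` is n_trials x 4 with
// columns (state0/action0, state0/action1, state1/action0, state1/action1)
// giving the reward probability of each stage-2 option at each trial.
// Missed trials carry NA choices and produce no value update; the
// perseveration flag keeps referring to the last valid stage-1 choice.
// [[Rcpp::export]]
List cpp_simulate_session(NumericVector par, NumericMatrix walk,
                          double p_common, double miss_rate) {
    const double wmb = par[0], wmf = par[1], b2 = par[2];
    const double a1 = par[3], a2 = par[4], lam = par[5], pp = par[6];
    const int n = walk.nrow();
    IntegerVector choice1(n), state2(n), choice2(n), reward(n);
    LogicalVector missed(n);
    CharacterVector transition(n);
    double q1[2] = {0.0, 0.0};
    double q2[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
    int prev = -1;
    for (int t = 0; t < n; ++t) {
        if (miss_rate > 0.0 && R::runif(0.0, 1.0) < miss_rate) {
            missed[t] = true;
            choice1[t] = NA_INTEGER; state2[t] = NA_INTEGER;
            choice2[t] = NA_INTEGER; reward[t] = NA_INTEGER;
            transition[t] = NA_STRING;
            continue;
        }
        missed[t] = false;
        double qb[2];
        compute_qmb(q2, p_common, qb);
        double l0 = wmb * qb[0] + wmf * q1[0] + (prev == 0 ? pp : 0.0);
        double l1 = wmb * qb[1] + wmf * q1[1] + (prev == 1 ? pp : 0.0);
        double mx = l0 > l1 ? l0 : l1;
        double p0 = std::exp(l0 - mx) / (std::exp(l0 - mx) + std::exp(l1 - mx));
        int c1 = (R::runif(0.0, 1.0) < p0) ? 0 : 1;
        bool common = R::runif(0.0, 1.0) < p_common;
        int s2 = common ? c1 : 1 - c1;
        double m0 = b2 * q2[s2][0], m1 = b2 * q2[s2][1];
        double mx2 = m0 > m1 ? m0 : m1;
        double p20 = std::exp(m0 - mx2) / (std::exp(m0 - mx2) + std::exp(m1 - mx2));
        int c2 = (R::runif(0.0, 1.0) < p20) ? 0 : 1;
        double pr = walk(t, s2 * 2 + c2);
        int r = (R::runif(0.0, 1.0) < pr) ? 1 : 0;
        double d1 = q2[s2][c2] - q1[c1];
        q1[c1] += a1 * d1;
        double d2 = (double) r - q2[s2][c2];
        q2[s2][c2] += a2 * d2;
        q1[c1] += a1 * lam * d2;
        prev = c1;
        choice1[t] = c1; state2[t] = s2; choice2[t] = c2; reward[t] = r;
        transition[t] = common ? "common" : "uncommon";
    }
    return List::create(_["choice1"] = choice1, _["state2"] = state2,
                        _["choice2"] = choice2, _["transition"] = transition,
                        _["reward"] = reward, _["missed"] = missed);
}
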