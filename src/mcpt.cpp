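#include <Rcpp.h>
using namespace Rcpp;

// Metropolis Monte Carlo over ionizable-site charge configurations.
//
// State: occ[i] = 1 if site i is charged (q_i = sign_i), 0 if neutral.
// Energy: E = sum_i h[i] * occ[i] + sum_{i<j} J(i,j) * occ[i] * occ[j]
// where h[i] = -2.3 RT sign_i (pKa_i^intr - pH) and J already carries the
// sign product and dielectric screening (zero beyond the cutoff).
//
// Moves per attempted step:
//   - bulk exchange (prob 1 - p_pair): toggle one site charged <-> neutral
//   - pair proton transfer (prob p_pair): move a proton from a donor
//     (protonated site: neutral acid or charged base) to an acceptor
//     (deprotonated site: charged acid or neutral base); conserves the
//     total proton count. An invalid draw counts as a rejected attempt.
//
// One sweep = n attempted moves. Per-sweep charges and energies are
// accumulated over production sweeps. Uses R's RNG so set.seed() in R
// gives bit-reproducible chains.

static inline double local_field(const NumericMatrix &J,
                                 const IntegerVector &occ, int i) {
  double s = 0.0;
  int n = occ.size();
  for (int j = 0; j < n; ++j)
    if (j != i && occ[j]) s += J(i, j);
  return s;
}

// [[Rcpp::export]]
List mcpt_run_cpp(NumericVector h, NumericMatrix J, IntegerVector sgn,
                  double rt, int n_burn, int n_prod, double p_pair,
                  IntegerVector occ_init) {
  int n = h.size();
  IntegerVector occ = clone(occ_init);
  double e_h = 0.0, e_qq = 0.0;
  for (int i = 0; i < n; ++i) {
    if (occ[i]) {
      e_h += h[i];
      for (int j = i + 1; j < n; ++j)
        if (occ[j]) e_qq += J(i, j);
    }
  }
  NumericVector q_sum(n), q_sumsq(n);
  double e_sum = 0.0, qq_sum = 0.0;
  long long n_acc = 0, n_att = 0;

  int total_sweeps = n_burn + n_prod;
  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int k = 0; k < n; ++k) {
      ++n_att;
      double u = unif_rand();
      if (u < p_pair && n >= 2) {
        // pair proton transfer: donor d -> acceptor a
        int d = (int)(unif_rand() * n); if (d == n) d = n - 1;
        int a = (int)(unif_rand() * (n - 1)); if (a >= d) ++a;
        bool d_has_proton = (sgn[d] < 0) ? (occ[d] == 0) : (occ[d] == 1);
        bool a_lacks_proton = (sgn[a] < 0) ? (occ[a] == 1) : (occ[a] == 0);
        if (!d_has_proton || !a_lacks_proton) continue;
        // donor loses proton: acid 0->1 charged, base 1->0 neutral
        // acceptor gains proton: acid 1->0, base 0->1
        int new_d = (sgn[d] < 0) ? 1 : 0;
        int new_a = (sgn[a] < 0) ? 0 : 1;
        double dE = 0.0, dqq = 0.0, dh = 0.0;
        // toggle d first
        double fd = local_field(J, occ, d);
        if (new_d == 1) { dh += h[d]; dqq += fd; }
        else            { dh -= h[d]; dqq -= fd; }
        occ[d] = new_d;
        double fa = local_field(J, occ, a);
        if (new_a == 1) { dh += h[a]; dqq += fa; }
        else            { dh -= h[a]; dqq -= fa; }
        occ[d] = 1 - new_d; // revert until accepted
        dE = dh + dqq;
        if (dE <= 0.0 || unif_rand() < std::exp(-dE / rt)) {
          occ[d] = new_d; occ[a] = new_a;
          e_h += dh; e_qq += dqq; ++n_acc;
        }
      } else {
        int i = (int)(unif_rand() * n); if (i == n) i = n - 1;
        double f = local_field(J, occ, i);
        double dh, dqq;
        if (occ[i]) { dh = -h[i]; dqq = -f; }
        else        { dh =  h[i]; dqq =  f; }
        double dE = dh + dqq;
        if (dE <= 0.0 || unif_rand() < std::exp(-dE / rt)) {
          occ[i] = 1 - occ[i];
          e_h += dh; e_qq += dqq; ++n_acc;
        }
      }
    }
    if (sweep >= n_burn) {
      for (int i = 0; i < n; ++i) {
        double q = occ[i] ? (double)sgn[i] : 0.0;
        q_sum[i] += q;
        q_sumsq[i] += q * q;
      }
      e_sum += e_h + e_qq;
      qq_sum += e_qq;
    }
  }
  NumericVector mean_q(n), se_q(n);
  for (int i = 0; i < n; ++i) {
    mean_q[i] = q_sum[i] / n_prod;
    double var = q_sumsq[i] / n_prod - mean_q[i] * mean_q[i];
    if (var < 0) var = 0;
    se_q[i] = std::sqrt(var / n_prod);
  }
  return List::create(_["mean_charge"] = mean_q,
                      _["charge_se"] = se_q,
                      _["e_mean"] = e_sum / n_prod,
                      _["qq_mean"] = qq_sum / n_prod,
                      _["acceptance"] = (double)n_acc / (double)n_att,
                      _["final_occ"] = occ);
}
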