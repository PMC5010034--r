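#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for a Dirichlet-process mixture of
// Beta-Binomial components over per-read methylated-CpG counts.
// Each read contributes k successes out of n_trials (n_trials = 4 for
// 4-CpG segments). Base measure Beta(a0, b0), concentration alpha.
// Uses R's RNG so results are reproducible under set.seed().

static double bb_logpred(int k, int n, double a, double b) {
  // log predictive of k | component with posterior Beta(a, b)
  return Rf_lchoose(n, k) + Rf_lbeta(a + k, b + n - k) - Rf_lbeta(a, b);
}

// [[Rcpp::export(name = ".dpGibbsFit")]]
List dpGibbsFit(IntegerVector k, int n_trials, double alpha,
                double a0, double b0, int sweeps, int burnin,
                double hypo_max, double hyper_min, double w_min) {
  int n = k.size();
  std::vector<int> z(n, 0);         // component assignment
  std::vector<int> csize, csum;     // reads, methylated-call sums
  csize.push_back(n);
  int tot = 0;
  for (int i = 0; i < n; ++i) tot += k[i];
  csum.push_back(tot);

  int recorded = 0, bipolar_hits = 0;
  std::vector<double> probs;

  for (int s = 0; s < sweeps; ++s) {
    for (int i = 0; i < n; ++i) {
      int c = z[i];
      csize[c] -= 1; csum[c] -= k[i];
      if (csize[c] == 0) {  // drop empty component, relabel
        csize.erase(csize.begin() + c);
        csum.erase(csum.begin() + c);
        for (int j = 0; j < n; ++j) if (z[j] > c) z[j] -= 1;
      }
      int m = csize.size();
      probs.resize(m + 1);
      double mx = R_NegInf;
      for (int c2 = 0; c2 < m; ++c2) {
        double lp = std::log((double)csize[c2]) +
          bb_logpred(k[i], n_trials, a0 + csum[c2],
                     b0 + (double)csize[c2] * n_trials - csum[c2]);
        probs[c2] = lp; if (lp > mx) mx = lp;
      }
      double lpnew = std::log(alpha) + bb_logpred(k[i], n_trials, a0, b0);
      probs[m] = lpnew; if (lpnew > mx) mx = lpnew;
      double tot_p = 0.0;
      for (int c2 = 0; c2 <= m; ++c2) { probs[c2] = std::exp(probs[c2] - mx); tot_p += probs[c2]; }
      double u = unif_rand() * tot_p, acc = 0.0;
      int pick = m;
      for (int c2 = 0; c2 <= m; ++c2) { acc += probs[c2]; if (u <= acc) { pick = c2; break; } }
      if (pick == m) { csize.push_back(0); csum.push_back(0); }
      z[i] = pick;
      csize[pick] += 1; csum[pick] += k[i];
    }
    if (s >= burnin) {
      recorded += 1;
      bool has_hypo = false, has_hyper = false;
      for (size_t c = 0; c < csize.size(); ++c) {
        double mean = (a0 + csum[c]) / (a0 + b0 + (double)csize[c] * n_trials);
        double w = (double)csize[c] / n;
        if (w >= w_min && mean <= hypo_max) has_hypo = true;
        if (w >= w_min && mean >= hyper_min) has_hyper = true;
      }
      if (has_hypo && has_hyper) bipolar_hits += 1;
    }
  }

  int m = csize.size();
  NumericVector means(m), weights(m);
  for (int c = 0; c < m; ++c) {
    means[c] = (a0 + csum[c]) / (a0 + b0 + (double)csize[c] * n_trials);
    weights[c] = (double)csize[c] / n;
  }
  return List::create(
    _["bipolar_prob"] = recorded ? (double)bipolar_hits / recorded : 0.0,
    _["component_means"] = means,
    _["component_weights"] = weights);
}
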