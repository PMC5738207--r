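// Gibbs sampler over pedigree parent-pair assignments with
// Metropolis-Hastings updates of the unsampled population sizes.
//
// Each individual is an offspring slot with an enumerated candidate set per
// parental role (sampled candidates plus the UNSAMPLED category). The full
// conditional for an offspring's (dam, sire) pair is
//   w(d, s) ~ L(d, s) * pw_dam(d) * pw_sire(s)
// where L is the precomputed pair likelihood (scaled per offspring) and the
// prior weights follow the categorical scheme
//   pw(sampled candidate) = 1 / (n_cand + N_unsampled)
//   pw(UNSAMPLED)         = N_unsampled / (n_cand + N_unsampled).
// Assignments that would create a cycle (the offspring an ancestor of its
// own parent) are rejected and redrawn from the remaining support, which is
// exactly sampling from the legality-restricted conditional. Unsampled
// male/female sizes get lognormal priors and random-walk MH on the log
// scale, with the step tuned during burn-in towards a target acceptance
// window. Uses R's RNG throughout so set.seed() in R fixes the chain.

#include <Rcpp.h>
using namespace Rcpp;

// Is `anc` an ancestor of `node` under current parent links? (1-based ids
// converted to 0-based indices; -1 = no sampled parent.)
static bool is_ancestor(int anc, int node, const std::vector<int> &pd,
                        const std::vector<int> &ps,
                        std::vector<int> &stack, std::vector<char> &seen,
                        int stamp) {
  stack.clear();
  stack.push_back(node);
  while (!stack.empty()) {
    int cur = stack.back();
    stack.pop_back();
    if (cur == anc) return true;
    if (seen[cur] == stamp) continue;
    seen[cur] = stamp;
    int d = pd[cur], s = ps[cur];
    if (d >= 0 && seen[d] != stamp) stack.push_back(d);
    if (s >= 0 && seen[s] != stamp) stack.push_back(s);
  }
  return false;
}

// [[Rcpp::export]]
List gibbs_pedigree_chain(List pair_lik,      // per offspring: (nd+1)x(ns+1) likelihood matrix, UNSAMPLED last
                          List dam_idx,       // per offspring: 0-based indices of sampled dam candidates
                          List sire_idx,
                          IntegerVector sweep_order,  // 0-based offspring order
                          double mu_f, double sig_f,
                          double mu_m, double sig_m,
                          double nf_init, double nm_init,
                          bool update_sizes,
                          int iterations, int burn_in, int thin,
                          double acc_lo, double acc_hi) {
  int n = pair_lik.size();
  std::vector<NumericMatrix> L(n);
  std::vector<std::vector<int>> dcand(n), scand(n);
  for (int i = 0; i < n; ++i) {
    L[i] = as<NumericMatrix>(pair_lik[i]);
    IntegerVector di = dam_idx[i], si = sire_idx[i];
    dcand[i] = std::vector<int>(di.begin(), di.end());
    scand[i] = std::vector<int>(si.begin(), si.end());
  }

  // state: chosen column/row index per offspring (last index = UNSAMPLED)
  std::vector<int> dch(n), sch(n);
  std::vector<int> pd(n, -1), ps(n, -1);   // parent individual indices
  for (int i = 0; i < n; ++i) {
    dch[i] = (int)dcand[i].size();   // start fully UNSAMPLED: always legal
    sch[i] = (int)scand[i].size();
  }

  double lnf = std::log(nf_init), lnm = std::log(nm_init);
  double step_f = 0.5, step_m = 0.5;
  int acc_f = 0, try_f = 0, acc_m = 0, try_m = 0;

  std::vector<IntegerMatrix> counts(n);
  for (int i = 0; i < n; ++i) {
    counts[i] = IntegerMatrix(L[i].nrow(), L[i].ncol());
  }
  int n_keep = 0;
  for (int it = burn_in; it < iterations; ++it) {
    if ((it - burn_in) % thin == 0) ++n_keep;
  }
  NumericVector chain_nf(n_keep), chain_nm(n_keep), chain_ll(n_keep);

  std::vector<int> stack;
  std::vector<char> seen(n, 0);
  int stamp = 0;
  std::vector<double> wd, wrow;

  // Because the sire prior weights take only two values (sampled vs
  // UNSAMPLED), the dam marginal needs just the per-dam row sum over
  // sampled sires and the UNSAMPLED column. Precompute both per offspring;
  // they are invalidated only by the rare legality masking, which falls
  // back to the full loop.
  std::vector<std::vector<double>> row_sampled(n), col_uns(n);
  for (int i = 0; i < n; ++i) {
    int nd = (int)dcand[i].size(), ns = (int)scand[i].size();
    row_sampled[i].assign(nd + 1, 0.0);
    col_uns[i].assign(nd + 1, 0.0);
    for (int d = 0; d <= nd; ++d) {
      double acc = 0.0;
      for (int s = 0; s < ns; ++s) acc += L[i](d, s);
      row_sampled[i][d] = acc;
      col_uns[i][d] = L[i](d, ns);
    }
  }

  // log prior-weight sums given current assignments, for the N updates:
  // sum over offspring of log pw(assigned candidate)
  auto size_loglik = [&](double N, bool female) -> double {
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      int nc = female ? (int)dcand[i].size() : (int)scand[i].size();
      int ch = female ? dch[i] : sch[i];
      ll += (ch == nc ? std::log(N) : 0.0) - std::log(nc + N);
    }
    return ll;
  };

  int keep = 0;   // RNG state handled by the Rcpp attributes wrapper
  for (int it = 0; it < iterations; ++it) {
    double Nf = std::exp(lnf), Nm = std::exp(lnm);
    for (int oo = 0; oo < n; ++oo) {
      int i = sweep_order[oo];
      int nd = (int)dcand[i].size(), ns = (int)scand[i].size();
      // prior weights
      wd.assign(nd + 1, 1.0 / (nd + Nf));
      wd[nd] = Nf / (nd + Nf);
      std::vector<double> ws(ns + 1, 1.0 / (ns + Nm));
      ws[ns] = Nm / (ns + Nm);
      // Lazy legality: draw from the unrestricted conditional, test the
      // drawn candidates for cycles, and on failure zero the offending
      // candidate in its role weights and redraw the whole pair. This
      // samples exactly from the legality-restricted conditional; cycles
      // are rare so the redraw almost never triggers. Candidate legality
      // (offspring is an ancestor of the candidate) depends only on the
      // candidate, not on the partner, so role-level masking is valid.
      const NumericMatrix &Li = L[i];
      std::vector<double> md(nd + 1);
      int dpick = nd, spick = ns;
      bool redo = true;
      bool fast = true;   // row sums valid until a sire is masked
      double wsamp = ws[0], wuns = ws[ns];
      while (redo) {
        redo = false;
        double tot = 0.0;
        if (fast) {
          for (int d = 0; d <= nd; ++d) {
            md[d] = wd[d] * (wsamp * row_sampled[i][d] +
                             wuns * col_uns[i][d]);
            tot += md[d];
          }
        } else {
          for (int d = 0; d <= nd; ++d) {
            double acc = 0.0;
            for (int s = 0; s <= ns; ++s) acc += Li(d, s) * ws[s];
            md[d] = wd[d] * acc;
            tot += md[d];
          }
        }
        if (tot <= 0.0) { dpick = nd; spick = ns; break; }
        double u = unif_rand() * tot, cum = 0.0;
        dpick = nd;
        for (int d = 0; d <= nd; ++d) {
          cum += md[d];
          if (u <= cum) { dpick = d; break; }
        }
        if (dpick < nd) {
          ++stamp;
          if (is_ancestor(i, dcand[i][dpick], pd, ps, stack, seen, stamp)) {
            wd[dpick] = 0.0;
            redo = true;
            continue;
          }
        }
        double tots = 0.0;
        std::vector<double> wsd(ns + 1);
        for (int s = 0; s <= ns; ++s) {
          wsd[s] = Li(dpick, s) * ws[s];
          tots += wsd[s];
        }
        if (tots <= 0.0) { wd[dpick] = 0.0; redo = true; continue; }
        double us = unif_rand() * tots, cums = 0.0;
        spick = ns;
        for (int s = 0; s <= ns; ++s) {
          cums += wsd[s];
          if (us <= cums) { spick = s; break; }
        }
        if (spick < ns) {
          ++stamp;
          if (is_ancestor(i, scand[i][spick], pd, ps, stack, seen, stamp)) {
            ws[spick] = 0.0;
            fast = false;
            redo = true;
            continue;
          }
        }
      }
      dch[i] = dpick;
      sch[i] = spick;
      pd[i] = dpick < nd ? dcand[i][dpick] : -1;
      ps[i] = spick < ns ? scand[i][spick] : -1;
    }

    if (update_sizes) {
      // females
      double prop = lnf + step_f * norm_rand();
      double cur_lp = R::dnorm(lnf, mu_f, sig_f, 1) +
        size_loglik(std::exp(lnf), true);
      double new_lp = R::dnorm(prop, mu_f, sig_f, 1) +
        size_loglik(std::exp(prop), true);
      ++try_f;
      if (std::log(unif_rand()) < new_lp - cur_lp) { lnf = prop; ++acc_f; }
      // males
      prop = lnm + step_m * norm_rand();
      cur_lp = R::dnorm(lnm, mu_m, sig_m, 1) +
        size_loglik(std::exp(lnm), false);
      new_lp = R::dnorm(prop, mu_m, sig_m, 1) +
        size_loglik(std::exp(prop), false);
      ++try_m;
      if (std::log(unif_rand()) < new_lp - cur_lp) { lnm = prop; ++acc_m; }

      if (it < burn_in && try_f >= 50) {   // tune towards the window
        double rf = (double)acc_f / try_f, rm = (double)acc_m / try_m;
        if (rf > acc_hi) step_f *= 1.3; else if (rf < acc_lo) step_f /= 1.3;
        if (rm > acc_hi) step_m *= 1.3; else if (rm < acc_lo) step_m /= 1.3;
        acc_f = try_f = acc_m = try_m = 0;
      }
    }

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      double ll = 0.0;
      for (int i = 0; i < n; ++i) {
        counts[i](dch[i], sch[i]) += 1;
        ll += std::log(std::max(L[i](dch[i], sch[i]), 1e-300));
      }
      chain_nf[keep] = std::exp(lnf);
      chain_nm[keep] = std::exp(lnm);
      chain_ll[keep] = ll;
      ++keep;
    }
  }

  List cnt(n);
  for (int i = 0; i < n; ++i) cnt[i] = counts[i];
  return List::create(
    _["counts"] = cnt,
    _["N_female"] = chain_nf,
    _["N_male"] = chain_nm,
    _["loglik"] = chain_ll,
    _["accept_female"] = try_f > 0 ? (double)acc_f / try_f : NA_REAL,
    _["accept_male"] = try_m > 0 ? (double)acc_m / try_m : NA_REAL,
    _["step_female"] = step_f,
    _["step_male"] = step_m);
}
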