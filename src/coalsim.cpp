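#include <Rcpp.h>
using namespace Rcpp;

// Structured coalescent for two demes (0 = west, 1 = east) plus a single
// ancestral deme after the split.  Time runs backwards from the present in
// units where one pair of lineages within a deme coalesces at rate 1, so
// T_coal = T_gen / (4 N_e).  Each lineage migrates to the other deme at
// rate M_coal / 2 while migration is active:
//   isolation (0):          never
//   ongoing_migration (1):  t < T_coal
//   secondary_contact (2):  t < tau * T_coal
// At t = T_coal all remaining lineages merge into the ancestral deme.
//
// Mutations follow the infinite-sites model at rate theta_locus / 2 per
// lineage per time unit, theta_locus = theta * scalar * length.

enum ModelKind { ISOLATION = 0, ONGOING = 1, SECONDARY = 2 };

struct Genealogy {
  std::vector<int> parent;     // 2n-1 entries, root has parent -1
  std::vector<double> time;    // node times, leaves at 0
};

static Genealogy simulate_core(int nw, int ne, double T_coal, double M_coal,
                               double tau, int model) {
  const int n = nw + ne;
  Genealogy g;
  g.parent.assign(2 * n - 1, -1);
  g.time.assign(2 * n - 1, 0.0);

  std::vector<int> deme0, deme1;
  deme0.reserve(n);
  deme1.reserve(n);
  for (int i = 0; i < nw; ++i) deme0.push_back(i);
  for (int i = nw; i < n; ++i) deme1.push_back(i);

  double mig_end;
  switch (model) {
    case ISOLATION: mig_end = 0.0; break;
    case ONGOING:   mig_end = T_coal; break;
    default:        mig_end = tau * T_coal; break;
  }

  double t = 0.0;
  int next_node = n;
  bool merged = (T_coal <= 0.0);
  if (merged) {
    deme0.insert(deme0.end(), deme1.begin(), deme1.end());
    deme1.clear();
  }

  while ((int)(deme0.size() + deme1.size()) > 1) {
    const int k0 = deme0.size(), k1 = deme1.size();
    double rc0 = 0.5 * k0 * (k0 - 1);
    double rc1 = 0.5 * k1 * (k1 - 1);
    double rm = (!merged && t < mig_end) ? 0.5 * (k0 + k1) * M_coal : 0.0;
    double rate = rc0 + rc1 + rm;

    // next structural boundary, +Inf once demes are merged
    double tb = merged ? R_PosInf : (t < mig_end ? mig_end : T_coal);

    double t_next = (rate > 0.0) ? t + R::rexp(1.0 / rate) : R_PosInf;
    if (t_next >= tb) {
      t = tb;
      if (t >= T_coal && !merged) {
        deme0.insert(deme0.end(), deme1.begin(), deme1.end());
        deme1.clear();
        merged = true;
      }
      continue;
    }
    t = t_next;

    double u = unif_rand() * rate;
    if (u < rc0 || u < rc0 + rc1) {
      std::vector<int>& d = (u < rc0) ? deme0 : deme1;
      const int k = d.size();
      int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
      int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      int a = d[i], b = d[j];
      g.parent[a] = next_node;
      g.parent[b] = next_node;
      g.time[next_node] = t;
      // remove the larger index first so the smaller stays valid
      if (i < j) std::swap(i, j);
      d.erase(d.begin() + i);
      d.erase(d.begin() + j);
      d.push_back(next_node);
      ++next_node;
    } else {
      int pick = (int)(unif_rand() * (k0 + k1));
      if (pick >= k0 + k1) pick = k0 + k1 - 1;
      if (pick < k0) {
        deme1.push_back(deme0[pick]);
        deme0.erase(deme0.begin() + pick);
      } else {
        pick -= k0;
        deme0.push_back(deme1[pick]);
        deme1.erase(deme1.begin() + pick);
      }
    }
  }
  return g;
}

// Branch lengths by Wakeley-Hey class of the mutations they would carry.
// out[0..4]: private_west, private_east, shared, fixed, total span.
// A branch whose descendants are the entire sample contributes only to
// the total (a mutation there is monomorphic within the sample).
static void wh_lengths(const Genealogy& g, int nw, int ne, double* out) {
  const int n = nw + ne;
  std::vector<int> cw(2 * n - 1, 0), ce(2 * n - 1, 0);
  for (int i = 0; i < nw; ++i) cw[i] = 1;
  for (int i = nw; i < n; ++i) ce[i] = 1;
  out[0] = out[1] = out[2] = out[3] = out[4] = 0.0;
  for (int i = 0; i < 2 * n - 2; ++i) {
    int p = g.parent[i];
    cw[p] += cw[i];
    ce[p] += ce[i];
    double len = g.time[p] - g.time[i];
    out[4] += len;
    bool pw = cw[i] > 0 && cw[i] < nw;
    bool pe = ce[i] > 0 && ce[i] < ne;
    if (pw && pe)      out[2] += len;
    else if (pw)       out[0] += len;
    else if (pe)       out[1] += len;
    else if ((cw[i] == nw && ce[i] == 0) || (cw[i] == 0 && ce[i] == ne))
                       out[3] += len;
    // cw == nw && ce == ne: ancestral to the whole sample, monomorphic
  }
}

//' @noRd
// [[Rcpp::export]]
List sim_genealogy_cpp(int nw, int ne, double T_coal, double M_coal,
                       double tau, int model) {
  Genealogy g = simulate_core(nw, ne, T_coal, M_coal, tau, model);
  return List::create(_["parent"] = IntegerVector(g.parent.begin(), g.parent.end()),
                      _["time"] = NumericVector(g.time.begin(), g.time.end()));
}

//' @noRd
// [[Rcpp::export]]
NumericVector wh_branch_lengths_cpp(IntegerVector parent, NumericVector time,
                                    int nw, int ne) {
  Genealogy g;
  g.parent.assign(parent.begin(), parent.end());
  g.time.assign(time.begin(), time.end());
  double out[5];
  wh_lengths(g, nw, ne, out);
  return NumericVector::create(out[0], out[1], out[2], out[3], out[4]);
}

// Batch simulation of the four across-locus Wakeley-Hey sums.
// Per locus, mutation counts per class are Poisson with mean
// (theta_locus / 2) * class branch length; summed over loci per replicate.
//' @noRd
// [[Rcpp::export]]
IntegerMatrix sim_wh_batch_cpp(IntegerVector nw, IntegerVector ne,
                               NumericVector theta_locus,
                               double T_coal, double M_coal, double tau,
                               int model, int n_sims) {
  const int L = theta_locus.size();
  IntegerMatrix out(n_sims, 4);
  double len[5];
  for (int s = 0; s < n_sims; ++s) {
    int acc[4] = {0, 0, 0, 0};
    for (int l = 0; l < L; ++l) {
      Genealogy g = simulate_core(nw[l], ne[l], T_coal, M_coal, tau, model);
      wh_lengths(g, nw[l], ne[l], len);
      for (int c = 0; c < 4; ++c)
        acc[c] += (int)R::rpois(0.5 * theta_locus[l] * len[c]);
    }
    for (int c = 0; c < 4; ++c) out(s, c) = acc[c];
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
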