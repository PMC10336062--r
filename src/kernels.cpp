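#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Candidate SSB pairs closer than `d` in 3D. `pos` must be sorted by its
// first column; the sorted sweep prunes the quadratic scan to near pairs.
// [[Rcpp::export(name = ".close_pairs_cpp")]]
List close_pairs_cpp(NumericMatrix pos, double d) {
  const int n = pos.nrow();
  const double d2 = d * d;
  std::vector<int> ii, jj;
  std::vector<double> dd;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(j, 0) - pos(i, 0);
      if (dx > d) break;  // sorted by x
      double dy = pos(j, 1) - pos(i, 1);
      double dz = pos(j, 2) - pos(i, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 <= d2) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
        dd.push_back(std::sqrt(r2));
      }
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj),
                      _["dist"] = wrap(dd));
}

// Greedy distance-ordered opposite-strand matching, averaged over strand
// re-assignments. `pi`, `pj` are 1-based SSB indices of candidate pairs
// already sorted by increasing distance (ties broken by index upstream).
// Each resample draws fair Bernoulli strands for all SSBs, then accepts
// pairs in distance order when both SSBs are unused and on opposite strands.
// Returns per-resample DSB counts and the accepted pairs of the first
// resample (for downstream break positions).
// [[Rcpp::export(name = ".greedy_pair_counts_cpp")]]
List greedy_pair_counts_cpp(IntegerVector pi, IntegerVector pj, int n_ssb,
                            int n_resamples) {
  const int m = pi.size();
  IntegerVector counts(n_resamples);
  std::vector<int> first_i, first_j;
  std::vector<char> strand(n_ssb), used(n_ssb);
  for (int s = 0; s < n_resamples; ++s) {
    for (int k = 0; k < n_ssb; ++k) {
      strand[k] = (unif_rand() < 0.5) ? 0 : 1;
      used[k] = 0;
    }
    int c = 0;
    for (int p = 0; p < m; ++p) {
      int a = pi[p] - 1, b = pj[p] - 1;
      if (!used[a] && !used[b] && strand[a] != strand[b]) {
        used[a] = used[b] = 1;
        ++c;
        if (s == 0) {
          first_i.push_back(a + 1);
          first_j.push_back(b + 1);
        }
      }
    }
    counts[s] = c;
  }
  return List::create(_["counts"] = counts,
                      _["first_i"] = wrap(first_i),
                      _["first_j"] = wrap(first_j));
}

// Exact Gillespie kinetic Monte Carlo of DSB end joining.
//
// Every free end can join any other free end with rate
//   k_pair * exp(-r^2 / (2 sigma^2)),
// where r is the distance between the parent breaks' positions and k_pair
// the rate constant of the slower complexity class among the two parents
// (complexity: 0 = simple -> rate_fast, 1 = complex -> rate_slow). Breaks of
// the second fraction are injected at `inject_time` (ignored if the second
// position matrix has zero rows). Runs until no join can occur or `t_max`.
//
// Returns per-break status (0 correct, 1 misrepaired, 2 unrepaired at
// t_max), the fraction origin of each break, and each break's completion
// time (time its second end joined; NA if unrepaired).
// [[Rcpp::export(name = ".simulate_repair_cpp")]]
List simulate_repair_cpp(NumericMatrix pos1, IntegerVector complex1,
                         NumericMatrix pos2, IntegerVector complex2,
                         double inject_time, double sigma,
                         double rate_fast, double rate_slow, double t_max) {
  const int nb1 = pos1.nrow(), nb2 = pos2.nrow();
  const int nb = nb1 + nb2, ne = 2 * nb;
  if (nb == 0) stop("at least one break is required");

  std::vector<double> bx(nb), by(nb), bz(nb), brate(nb);
  for (int b = 0; b < nb1; ++b) {
    bx[b] = pos1(b, 0); by[b] = pos1(b, 1); bz[b] = pos1(b, 2);
    brate[b] = complex1[b] ? rate_slow : rate_fast;
  }
  for (int b = 0; b < nb2; ++b) {
    bx[nb1 + b] = pos2(b, 0); by[nb1 + b] = pos2(b, 1); bz[nb1 + b] = pos2(b, 2);
    brate[nb1 + b] = complex2[b] ? rate_slow : rate_fast;
  }

  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  // end e belongs to break e / 2
  std::vector<char> active(ne, 0);
  std::vector<int> partner(ne, -1);
  std::vector<double> jtime(ne, NA_REAL);

  // pair rate between ends a and b (parents pa, pb)
  auto pair_rate = [&](int a, int b) -> double {
    int pa = a / 2, pb = b / 2;
    double dx = bx[pa] - bx[pb], dy = by[pa] - by[pb], dz = bz[pa] - bz[pb];
    double k = std::min(brate[pa], brate[pb]);
    return k * std::exp(-(dx * dx + dy * dy + dz * dz) * inv2s2);
  };

  std::vector<double> rates((size_t)ne * ne, 0.0);
  std::vector<double> rowsum(ne, 0.0);

  auto activate_range = [&](int e_lo, int e_hi) {
    for (int e = e_lo; e < e_hi; ++e) active[e] = 1;
    // (re)build the full rate table over active ends
    std::fill(rowsum.begin(), rowsum.end(), 0.0);
    for (int a = 0; a < ne; ++a) {
      if (!active[a]) continue;
      for (int b = a + 1; b < ne; ++b) {
        if (!active[b]) continue;
        double r = pair_rate(a, b);
        rates[(size_t)a * ne + b] = r;
        rates[(size_t)b * ne + a] = r;
        rowsum[a] += r;
        rowsum[b] += r;
      }
    }
  };

  double t = 0.0;
  bool injected = (nb2 == 0);
  activate_range(0, 2 * nb1);

  RNGScope scope;
  while (true) {
    double total = 0.0;
    for (int a = 0; a < ne; ++a) if (active[a]) total += rowsum[a];
    total *= 0.5;
    double t_next = (total > 1e-300) ? t + exp_rand() / total : R_PosInf;
    if (!injected && t_next > inject_time) {
      t = inject_time;
      injected = true;
      activate_range(2 * nb1, ne);
      continue;
    }
    if (t_next > t_max) break;
    t = t_next;

    // sample end a proportional to rowsum, then b within its row
    double u = unif_rand() * 2.0 * total;
    int a = -1;
    double acc = 0.0;
    for (int e = 0; e < ne; ++e) {
      if (!active[e]) continue;
      acc += rowsum[e];
      if (u <= acc) { a = e; break; }
    }
    if (a < 0) break;  // numerical corner: treat as no event
    double v = unif_rand() * rowsum[a];
    int b = -1;
    acc = 0.0;
    for (int e = 0; e < ne; ++e) {
      if (!active[e] || e == a) continue;
      acc += rates[(size_t)a * ne + e];
      if (v <= acc) { b = e; break; }
    }
    if (b < 0) continue;

    // join a and b
    active[a] = active[b] = 0;
    partner[a] = b; partner[b] = a;
    jtime[a] = jtime[b] = t;
    for (int e = 0; e < ne; ++e) {
      if (!active[e]) continue;
      rowsum[e] -= rates[(size_t)e * ne + a] + rates[(size_t)e * ne + b];
      if (rowsum[e] < 0) rowsum[e] = 0;
    }
    // any joins left?
    bool any = false;
    for (int e = 0; e < ne && !any; ++e) if (active[e]) any = true;
    if (!any) {
      if (!injected) { t = inject_time; injected = true; activate_range(2 * nb1, ne); }
      else break;
    }
  }

  IntegerVector status(nb);
  NumericVector done_time(nb);
  IntegerVector fraction(nb);
  for (int bidx = 0; bidx < nb; ++bidx) {
    int e1 = 2 * bidx, e2 = 2 * bidx + 1;
    fraction[bidx] = (bidx < nb1) ? 1 : 2;
    if (partner[e1] < 0 || partner[e2] < 0) {
      status[bidx] = 2;
      done_time[bidx] = NA_REAL;
    } else {
      status[bidx] = (partner[e1] == e2) ? 0 : 1;
      done_time[bidx] = std::max(jtime[e1], jtime[e2]);
    }
  }
  return List::create(_["status"] = status, _["fraction"] = fraction,
                      _["completion_min"] = done_time);
}
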