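// Collapsed Gibbs sampler for the mixture-of-PWMs model: assignment
// sweeps, width moves, slope-based convergence, update cap, terminal
// hill climbing. Mirrors the R reference engine draw for draw (same
// candidate ordering, same single-uniform inverse-CDF draws via R's
// RNG), so a chain is reproducible across engines from one seed.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

namespace {

inline int comp(int b) { return b < 4 ? 3 - b : 4; }

struct Move { int dw, ds_f, de_f, ds_r, de_r; };
// none, grow-left, shrink-left, grow-right, shrink-right
static const Move MOVES[5] = {
  {0, 0, 0, 0, 0}, {1, -1, 0, 0, 1}, {-1, 1, 0, 0, -1},
  {1, 0, 1, -1, 0}, {-1, 0, -1, 1, 0}};

struct Sampler {
  int n, m, wmin, wmax;
  bool both;
  double ag, beta0;
  std::array<double, 4> beta;
  std::vector<std::vector<int>> X;       // 0..3, 4 = N
  std::vector<std::vector<double>> pref; // bg prefix sums, length L+1
  std::vector<int> z, md, rv;            // per-sequence assignment
  std::vector<int> widths, members;
  std::vector<std::vector<std::array<int, 4>>> cnt; // per mode, w rows

  int siteBase(int i, int p, int w, int r, int a) const {
    int b = r ? X[i][p + w - 1 - a] : X[i][p + a];
    return r ? comp(b) : b;
  }
  void bump(int i, int d) {
    int k = md[i], w = widths[k];
    for (int a = 0; a < w; a++) {
      int b = siteBase(i, z[i], w, rv[i], a);
      if (b < 4) cnt[k][a][b] += d;
    }
    members[k] += d;
  }
  double bgWin(int i, int s, int e) const { return pref[i][e] - pref[i][s]; }

  double logDM(const std::vector<std::array<int, 4>> &c) const {
    double s = 0, lgb = 0;
    for (int b = 0; b < 4; b++) lgb += std::lgamma(beta[b]);
    for (size_t a = 0; a < c.size(); a++) {
      int rs = c[a][0] + c[a][1] + c[a][2] + c[a][3];
      s += std::lgamma(beta0) - std::lgamma(rs + beta0) - lgb;
      for (int b = 0; b < 4; b++) s += std::lgamma(c[a][b] + beta[b]);
    }
    return s;
  }

  double logPost() const {
    double lp = 0;
    for (int k = 0; k < m; k++) lp += logDM(cnt[k]);
    lp += std::lgamma(m * ag) - std::lgamma(n + m * ag) - m * std::lgamma(ag);
    for (int k = 0; k < m; k++) lp += std::lgamma(members[k] + ag);
    for (int i = 0; i < n; i++) {
      int L = X[i].size();
      lp += pref[i][L] - bgWin(i, z[i], z[i] + widths[md[i]]);
    }
    return lp;
  }

  // score every (mode, position, strand) candidate for sequence i
  // (whose counts must already be removed); fills parallel arrays
  void scoreCandidates(int i, std::vector<double> &sc, std::vector<int> &ck,
                       std::vector<int> &cp, std::vector<int> &cr) const {
    sc.clear(); ck.clear(); cp.clear(); cr.clear();
    int L = X[i].size();
    std::vector<double> lpred;
    for (int k = 0; k < m; k++) {
      int w = widths[k];
      if (w > L) continue;
      lpred.assign(w * 4, 0.0);
      for (int a = 0; a < w; a++) {
        int rs = cnt[k][a][0] + cnt[k][a][1] + cnt[k][a][2] + cnt[k][a][3];
        for (int b = 0; b < 4; b++)
          lpred[a * 4 + b] = std::log((cnt[k][a][b] + beta[b]) / (rs + beta0));
      }
      double t1 = std::log(members[k] + ag) - std::log(n - 1 + m * ag);
      for (int p = 0; p + w <= L; p++) {
        double bgw = bgWin(i, p, p + w);
        for (int r = 0; r <= (both ? 1 : 0); r++) {
          double s = t1;
          for (int a = 0; a < w; a++) {
            int b = r ? comp(X[i][p + w - 1 - a]) : X[i][p + a];
            if (b < 4) s += lpred[a * 4 + b];
          }
          s -= bgw;
          sc.push_back(s); ck.push_back(k); cp.push_back(p); cr.push_back(r);
        }
      }
    }
  }

  static int drawIdx(const std::vector<double> &sc, double u) {
    double mx = sc[0];
    for (double v : sc) if (v > mx) mx = v;
    double tot = 0;
    std::vector<double> e(sc.size());
    for (size_t j = 0; j < sc.size(); j++) { e[j] = std::exp(sc[j] - mx); tot += e[j]; }
    double target = u * tot, cs = 0;
    for (size_t j = 0; j < sc.size(); j++) { cs += e[j]; if (cs >= target) return j; }
    return sc.size() - 1;
  }
  static int argmaxIdx(const std::vector<double> &sc) {
    int best = 0;
    for (size_t j = 1; j < sc.size(); j++) if (sc[j] > sc[best]) best = j;
    return best;
  }

  void setAssign(int i, int k, int p, int r) { md[i] = k; z[i] = p; rv[i] = r; }

  bool updateAssign(int i, bool sample) {
    double u = sample ? unif_rand() : 0.0;
    bump(i, -1);
    std::vector<double> sc; std::vector<int> ck, cp, cr;
    scoreCandidates(i, sc, ck, cp, cr);
    if (sc.empty()) stop("no valid candidate for sequence %d", i + 1);
    int j = sample ? drawIdx(sc, u) : argmaxIdx(sc);
    bool changed = ck[j] != md[i] || cp[j] != z[i] || cr[j] != rv[i];
    setAssign(i, ck[j], cp[j], cr[j]);
    bump(i, +1);
    return changed;
  }

  // feasible width candidates for mode k: returns candidate move ids,
  // scores, and (via apply) the realigned counts/starts
  struct WidthCand {
    int move, nw;
    std::vector<int> ns;
    std::vector<std::array<int, 4>> c;
    double score;
  };

  void widthCandidates(int k, std::vector<WidthCand> &out) const {
    out.clear();
    std::vector<int> idx;
    for (int i = 0; i < n; i++) if (md[i] == k) idx.push_back(i);
    int w = widths[k];
    for (int mv = 0; mv < 5; mv++) {
      int nw = w + MOVES[mv].dw;
      if (nw < 1 || (MOVES[mv].dw != 0 && (nw < wmin || nw > wmax))) continue;
      WidthCand wc; wc.move = mv; wc.nw = nw;
      bool ok = true;
      for (int i : idx) {
        int ds = rv[i] ? MOVES[mv].ds_r : MOVES[mv].ds_f;
        int de = rv[i] ? MOVES[mv].de_r : MOVES[mv].de_f;
        int ns = z[i] + ds, ne = z[i] + w + de;
        if (ns < 0 || ne > (int)X[i].size()) { ok = false; break; }
        wc.ns.push_back(ns);
      }
      if (!ok) continue;
      wc.c.assign(nw, {0, 0, 0, 0});
      double bgsum = 0;
      for (size_t t = 0; t < idx.size(); t++) {
        int i = idx[t];
        for (int a = 0; a < nw; a++) {
          int b = siteBase(i, wc.ns[t], nw, rv[i], a);
          if (b < 4) wc.c[a][b]++;
        }
        bgsum += bgWin(i, wc.ns[t], wc.ns[t] + nw);
      }
      wc.score = logDM(wc.c) - bgsum;
      out.push_back(std::move(wc));
    }
  }

  bool updateWidth(int k, bool sample) {
    if (members[k] == 0) return false;
    std::vector<WidthCand> cands;
    widthCandidates(k, cands);
    double u = sample ? unif_rand() : 0.0;
    std::vector<double> sc;
    for (auto &c : cands) sc.push_back(c.score);
    int j = sample ? drawIdx(sc, u) : argmaxIdx(sc);
    if (cands[j].move == 0) return false;
    std::vector<int> idx;
    for (int i = 0; i < n; i++) if (md[i] == k) idx.push_back(i);
    for (size_t t = 0; t < idx.size(); t++) z[idx[t]] = cands[j].ns[t];
    widths[k] = cands[j].nw;
    cnt[k] = cands[j].c;
    return true;
  }
};

double traceSlope(const std::vector<double> &tr, int window) {
  int len = tr.size();
  double xbar = (window - 1) / 2.0, ybar = 0;
  for (int j = 0; j < window; j++) ybar += tr[len - window + j];
  ybar /= window;
  double num = 0, den = 0;
  for (int j = 0; j < window; j++) {
    num += (j - xbar) * (tr[len - window + j] - ybar);
    den += (j - xbar) * (j - xbar);
  }
  return num / den;
}

} // namespace

// [[Rcpp::export]]
List cpp_run_chain(List seqs, List bgpref, NumericVector beta,
                   double alpha_gamma, int m, int w_init, int w_min,
                   int w_max, double slope_tol, int trace_window,
                   double max_updates, int hill_rounds, bool both_strands,
                   int log_every) {
  Sampler S;
  S.n = seqs.size(); S.m = m; S.wmin = w_min; S.wmax = w_max;
  S.both = both_strands; S.ag = alpha_gamma;
  for (int b = 0; b < 4; b++) S.beta[b] = beta[b];
  S.beta0 = S.beta[0] + S.beta[1] + S.beta[2] + S.beta[3];
  S.X.resize(S.n); S.pref.resize(S.n);
  for (int i = 0; i < S.n; i++) {
    IntegerVector v = seqs[i];
    S.X[i] = std::vector<int>(v.begin(), v.end());
    NumericVector p = bgpref[i];
    S.pref[i] = std::vector<double>(p.begin(), p.end());
    if ((int)S.X[i].size() < w_init)
      stop("sequence %d shorter than initial width", i + 1);
  }
  S.z.resize(S.n); S.md.resize(S.n); S.rv.resize(S.n);
  S.widths.assign(m, w_init);
  S.members.assign(m, 0);
  S.cnt.assign(m, std::vector<std::array<int, 4>>(w_init, {0, 0, 0, 0}));

  // random initialisation: per sequence a position, a mode, and (when
  // both strands are searched) a strand, each from one uniform
  for (int i = 0; i < S.n; i++) {
    int L = S.X[i].size();
    S.z[i] = (int)std::floor(unif_rand() * (L - w_init + 1));
    S.md[i] = (int)std::floor(unif_rand() * m);
    S.rv[i] = both_strands ? (unif_rand() >= 0.5 ? 1 : 0) : 0;
    S.bump(i, +1);
  }

  std::vector<double> trace;
  double updates = 0;
  bool converged = false;
  double best_lp = R_NegInf;
  std::vector<int> bz, bmd, brv, bw;
  for (;;) {
    for (int i = 0; i < S.n; i++) S.updateAssign(i, true);
    for (int k = 0; k < m; k++) S.updateWidth(k, true);
    double lp = S.logPost();
    trace.push_back(lp);
    updates += S.n;
    if (log_every > 0 && (int)trace.size() % log_every == 0) {
      Rprintf("sweep %d: log posterior %.3f, widths", (int)trace.size(), lp);
      for (int k = 0; k < m; k++) Rprintf(" %d", S.widths[k]);
      Rprintf("\n");
    }
    if (lp > best_lp) {
      best_lp = lp; bz = S.z; bmd = S.md; brv = S.rv; bw = S.widths;
    }
    if ((int)trace.size() >= trace_window &&
        std::fabs(traceSlope(trace, trace_window)) < slope_tol) {
      converged = true; break;
    }
    if (updates >= max_updates) break;
    Rcpp::checkUserInterrupt();
  }

  // restore the highest-posterior sample and hill climb from it
  S.z = bz; S.md = bmd; S.rv = brv; S.widths = bw;
  S.members.assign(m, 0);
  for (int k = 0; k < m; k++)
    S.cnt[k].assign(S.widths[k], {0, 0, 0, 0});
  for (int i = 0; i < S.n; i++) S.bump(i, +1);
  for (int round = 0; round < hill_rounds; round++) {
    bool changed = false;
    for (int i = 0; i < S.n; i++)
      if (S.updateAssign(i, false)) changed = true;
    for (int k = 0; k < m; k++)
      if (S.updateWidth(k, false)) changed = true;
    if (!changed) break;
  }

  IntegerVector mode1(S.n);
  for (int i = 0; i < S.n; i++) mode1[i] = S.md[i] + 1;
  return List::create(
      _["mode"] = mode1, _["pos"] = wrap(S.z), _["rev"] = wrap(S.rv),
      _["widths"] = wrap(S.widths), _["trace"] = wrap(trace),
      _["converged"] = converged, _["updates"] = updates);
}
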