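// Event-probability-tree engine.
//
// Every possible substitution event (site i -> target nucleotide j) at an
// unprotected site lives at exactly one tip of a hierarchical structure
// whose levels are, root to tip:
//   target nucleotide j -> transition/transversion class -> effective mu
//   category -> region (ORF-membership class) -> omega-combination class.
// All events in one tip share every rate factor, hence one rate
//   lambda = norm * mu_i * kappa^[transition] * pi_j * prod(omega),
// so a tip's weight is lambda * (#events) and sampling proportional to
// cached subtree weights followed by a uniform choice within the tip
// reproduces the flat distribution lambda_e / Lambda exactly.
//
// Updates after a substitution re-derive the events of the mutated site and
// of every site sharing a codon with it in any reading frame (conservative
// recomputation; an R-side property test asserts equality with a full
// rebuild).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdio>
#include <cmath>

using namespace Rcpp;

struct Tip {
  double lambda;
  int j, t, mu, reg;           // all 0-based
  long long code4;             // encoded (j, t, mu, reg)
  std::string wkey;            // canonical omega-combination key
  std::vector<int> ev;         // event ids = site * 4 + j
};

struct Engine {
  int L, nmu, nreg;
  double kappa, norm;
  double pi[4];
  std::vector<int> seq;                  // 0=A 1=C 2=G 3=T
  std::vector<char> prot;
  std::vector<int> region;               // 0-based per site
  std::vector<double> muval;             // effective mu per site
  std::vector<int> mucat;                // 0-based effective mu category
  // per-(site, ORF) membership rows, CSR by site
  std::vector<int> mptr;
  std::vector<int> morf, mocat, moff, mstrand;
  std::vector<double> moval;
  std::vector<int> mp1, mp2, mp3;        // codon genome positions, 0-based,
                                         // in reading order
  // codon neighbourhoods (sites whose events depend on a site's state)
  std::vector<int> nptr, nidx;
  std::vector<int> aacode;               // 64 entries, amino acid id per codon
  // tree state
  std::vector<Tip> tips;
  std::unordered_map<std::string, int> key2tip;
  std::unordered_map<long long, double> w3, w4;
  std::unordered_map<long long, std::vector<int>> tips4;
  double w1[4], w2[8], total;
  std::vector<int> tip_of, pos_of;       // per event id; tip_of = -1 if absent
  long long nsub;
};

static inline bool transition(int a, int b) { return (a ^ b) == 2; }

static inline void add_weight(Engine &E, int j, int t, int mu, int reg,
                              double d) {
  E.total += d;
  E.w1[j] += d;
  E.w2[j * 2 + t] += d;
  long long c3 = (long long)(j * 2 + t) * E.nmu + mu;
  E.w3[c3] += d;
  E.w4[c3 * E.nreg + reg] += d;
}

struct EvInfo {
  int t, mu, reg;
  double lambda;
  std::string wkey;
};

static EvInfo compute_event(const Engine &E, int i, int j) {
  EvInfo e;
  e.t = transition(E.seq[i], j) ? 1 : 0;
  e.mu = E.mucat[i];
  e.reg = E.region[i];
  double om = 1.0;
  char buf[64];
  e.wkey.clear();
  for (int r = E.mptr[i]; r < E.mptr[i + 1]; ++r) {
    int p[3] = {E.mp1[r], E.mp2[r], E.mp3[r]};
    int b[3], a[3];
    for (int k = 0; k < 3; ++k) b[k] = E.seq[p[k]];
    for (int k = 0; k < 3; ++k) a[k] = b[k];
    a[E.moff[r]] = j;
    if (E.mstrand[r] < 0) {
      for (int k = 0; k < 3; ++k) { b[k] = 3 - b[k]; a[k] = 3 - a[k]; }
    }
    int cb = b[0] * 16 + b[1] * 4 + b[2];
    int ca = a[0] * 16 + a[1] * 4 + a[2];
    if (E.aacode[cb] != E.aacode[ca]) {
      om *= E.moval[r];
      std::snprintf(buf, sizeof(buf), "%s%d:%d", e.wkey.empty() ? "" : ",",
                    E.morf[r], E.mocat[r]);
      e.wkey += buf;  // membership rows are ordered by ORF id within a site
    }
  }
  e.lambda = E.norm * E.muval[i] * (e.t ? E.kappa : 1.0) * E.pi[j] * om;
  return e;
}

static void insert_event(Engine &E, int i, int j) {
  EvInfo e = compute_event(E, i, j);
  char buf[96];
  std::snprintf(buf, sizeof(buf), "%d|%d|%d|%d|", j, e.t, e.mu, e.reg);
  std::string key = std::string(buf) + e.wkey;
  int tid;
  auto it = E.key2tip.find(key);
  if (it == E.key2tip.end()) {
    tid = (int)E.tips.size();
    Tip T;
    T.lambda = e.lambda;
    T.j = j; T.t = e.t; T.mu = e.mu; T.reg = e.reg;
    T.code4 = ((long long)(j * 2 + e.t) * E.nmu + e.mu) * E.nreg + e.reg;
    T.wkey = e.wkey;
    E.tips.push_back(T);
    E.key2tip[key] = tid;
    E.tips4[T.code4].push_back(tid);
  } else {
    tid = it->second;
    // all members of a tip must share one probability
    double ref = E.tips[tid].lambda;
    if (std::fabs(ref - e.lambda) > 1e-9 * (std::fabs(ref) + 1e-300))
      stop("event tree invariant violated: unequal rates within a tip subset");
  }
  int eid = i * 4 + j;
  E.pos_of[eid] = (int)E.tips[tid].ev.size();
  E.tips[tid].ev.push_back(eid);
  E.tip_of[eid] = tid;
  add_weight(E, j, e.t, e.mu, e.reg, E.tips[tid].lambda);
}

static void remove_event(Engine &E, int eid) {
  int tid = E.tip_of[eid];
  Tip &T = E.tips[tid];
  int p = E.pos_of[eid];
  int last = T.ev.back();
  T.ev[p] = last;
  E.pos_of[last] = p;
  T.ev.pop_back();
  E.tip_of[eid] = -1;
  add_weight(E, T.j, T.t, T.mu, T.reg, -T.lambda);
}

static void apply_event(Engine &E, int i, int j) {
  if (E.prot[i]) stop("internal error: substitution at a protected site");
  if (E.seq[i] == j) stop("internal error: substitution to the same base");
  for (int a = E.nptr[i]; a < E.nptr[i + 1]; ++a) {
    int s = E.nidx[a];
    if (E.prot[s]) continue;
    for (int jj = 0; jj < 4; ++jj) {
      int eid = s * 4 + jj;
      if (E.tip_of[eid] >= 0) remove_event(E, eid);
    }
  }
  E.seq[i] = j;
  for (int a = E.nptr[i]; a < E.nptr[i + 1]; ++a) {
    int s = E.nidx[a];
    if (E.prot[s]) continue;
    for (int jj = 0; jj < 4; ++jj)
      if (jj != E.seq[s]) insert_event(E, s, jj);
  }
  E.nsub++;
}

// Weight-proportional choice among the children of one internal node; u is
// uniform on (0, weight). Falls back to the last positive-weight child when
// floating-point round-off lets u overshoot.
static int sample_tip(Engine &E) {
  double u = unif_rand() * E.total;
  int j = 3;
  for (int k = 0; k < 4; ++k) {
    if (u < E.w1[k]) { j = k; break; }
    u -= E.w1[k];
  }
  double u2 = unif_rand() * E.w1[j];
  int t = E.w2[j * 2 + 1] > 0 ? 1 : 0;
  if (u2 < E.w2[j * 2]) t = 0;
  else if (E.w2[j * 2 + 1] > 0) t = 1;
  long long c2 = j * 2 + t;
  double u3 = unif_rand() * E.w2[c2];
  int mu = -1;
  for (int m = 0; m < E.nmu; ++m) {
    auto it = E.w3.find(c2 * E.nmu + m);
    if (it == E.w3.end()) continue;
    if (u3 < it->second) { mu = m; break; }
    u3 -= it->second;
    if (it->second > 0) mu = m;
  }
  long long c3 = c2 * E.nmu + mu;
  double u4 = unif_rand() * E.w3[c3];
  int reg = -1;
  for (int r = 0; r < E.nreg; ++r) {
    auto it = E.w4.find(c3 * E.nreg + r);
    if (it == E.w4.end()) continue;
    if (u4 < it->second) { reg = r; break; }
    u4 -= it->second;
    if (it->second > 0) reg = r;
  }
  long long c4 = c3 * E.nreg + reg;
  std::vector<int> &cand = E.tips4[c4];
  double u5 = unif_rand() * E.w4[c4];
  int chosen = -1;
  for (size_t k = 0; k < cand.size(); ++k) {
    Tip &T = E.tips[cand[k]];
    double w = T.lambda * (double)T.ev.size();
    if (w <= 0) continue;
    if (u5 < w) { chosen = cand[k]; break; }
    u5 -= w;
    chosen = cand[k];
  }
  if (chosen < 0) stop("internal error: event tree sampling failed");
  return chosen;
}

static int sample_event_id(Engine &E) {
  if (E.total <= 0) stop("event tree has zero total rate");
  int tid = sample_tip(E);
  Tip &T = E.tips[tid];
  int m = (int)(unif_rand() * T.ev.size());
  if (m >= (int)T.ev.size()) m = (int)T.ev.size() - 1;
  return T.ev[m];
}

// ---- R interface -----------------------------------------------------------

// [[Rcpp::export]]
SEXP engine_build(IntegerVector seq0, LogicalVector prot, IntegerVector region,
                  NumericVector muval, IntegerVector mucat,
                  IntegerVector msite, IntegerVector morf, IntegerVector mocat,
                  NumericVector moval, IntegerVector mp1, IntegerVector mp2,
                  IntegerVector mp3, IntegerVector moff, IntegerVector mstrand,
                  double kappa, NumericVector pi, double norm,
                  IntegerVector aacode) {
  Engine *E = new Engine();
  E->L = seq0.size();
  E->kappa = kappa;
  E->norm = norm;
  for (int k = 0; k < 4; ++k) E->pi[k] = pi[k];
  E->seq.assign(seq0.begin(), seq0.end());
  E->prot.resize(E->L);
  for (int i = 0; i < E->L; ++i) E->prot[i] = prot[i] ? 1 : 0;
  E->region.resize(E->L);
  for (int i = 0; i < E->L; ++i) E->region[i] = region[i] - 1;
  E->muval.assign(muval.begin(), muval.end());
  E->mucat.resize(E->L);
  for (int i = 0; i < E->L; ++i) E->mucat[i] = mucat[i] - 1;
  E->nmu = 0;
  for (int i = 0; i < E->L; ++i) if (E->mucat[i] + 1 > E->nmu) E->nmu = E->mucat[i] + 1;
  E->nreg = 0;
  for (int i = 0; i < E->L; ++i) if (E->region[i] + 1 > E->nreg) E->nreg = E->region[i] + 1;
  // membership CSR: rows must arrive sorted by (site, orf)
  int M = msite.size();
  E->mptr.assign(E->L + 1, 0);
  for (int r = 0; r < M; ++r) E->mptr[msite[r]]++;  // msite is 1-based
  for (int i = 0; i < E->L; ++i) E->mptr[i + 1] += E->mptr[i];
  E->morf.assign(morf.begin(), morf.end());
  E->mocat.assign(mocat.begin(), mocat.end());
  E->moval.assign(moval.begin(), moval.end());
  E->moff.assign(moff.begin(), moff.end());
  E->mstrand.assign(mstrand.begin(), mstrand.end());
  E->mp1.resize(M); E->mp2.resize(M); E->mp3.resize(M);
  for (int r = 0; r < M; ++r) {
    E->mp1[r] = mp1[r] - 1; E->mp2[r] = mp2[r] - 1; E->mp3[r] = mp3[r] - 1;
  }
  // codon neighbourhoods: self plus all codon positions of all memberships
  E->nptr.assign(E->L + 1, 0);
  {
    std::vector<std::vector<int>> nb(E->L);
    for (int i = 0; i < E->L; ++i) nb[i].push_back(i);
    for (int i = 0; i < E->L; ++i) {
      for (int r = E->mptr[i]; r < E->mptr[i + 1]; ++r) {
        int p[3] = {E->mp1[r], E->mp2[r], E->mp3[r]};
        for (int k = 0; k < 3; ++k) {
          bool seen = false;
          for (int q : nb[i]) if (q == p[k]) { seen = true; break; }
          if (!seen) nb[i].push_back(p[k]);
        }
      }
    }
    for (int i = 0; i < E->L; ++i) E->nptr[i + 1] = E->nptr[i] + (int)nb[i].size();
    E->nidx.resize(E->nptr[E->L]);
    for (int i = 0; i < E->L; ++i)
      for (size_t k = 0; k < nb[i].size(); ++k)
        E->nidx[E->nptr[i] + k] = nb[i][k];
  }
  E->aacode.assign(aacode.begin(), aacode.end());
  for (int k = 0; k < 4; ++k) E->w1[k] = 0;
  for (int k = 0; k < 8; ++k) E->w2[k] = 0;
  E->total = 0;
  E->nsub = 0;
  E->tip_of.assign((size_t)E->L * 4, -1);
  E->pos_of.assign((size_t)E->L * 4, 0);
  int nevents = 0;
  for (int i = 0; i < E->L; ++i) {
    if (E->prot[i]) continue;
    for (int j = 0; j < 4; ++j)
      if (j != E->seq[i]) { insert_event(*E, i, j); ++nevents; }
  }
  if (nevents == 0) {
    delete E;
    stop("no simulatable events: every site is protected");
  }
  XPtr<Engine> ptr(E, true);
  return ptr;
}

// [[Rcpp::export]]
SEXP engine_clone(SEXP eptr) {
  XPtr<Engine> E(eptr);
  Engine *C = new Engine(*E);
  XPtr<Engine> ptr(C, true);
  return ptr;
}

// [[Rcpp::export]]
double engine_total_rate(SEXP eptr) {
  XPtr<Engine> E(eptr);
  return E->total;
}

// [[Rcpp::export]]
IntegerVector engine_sequence(SEXP eptr) {
  XPtr<Engine> E(eptr);
  IntegerVector out(E->L);
  for (int i = 0; i < E->L; ++i) out[i] = E->seq[i] + 1;
  return out;
}

// [[Rcpp::export]]
List engine_sample(SEXP eptr) {
  XPtr<Engine> E(eptr);
  int eid = sample_event_id(*E);
  int i = eid / 4, j = eid % 4;
  return List::create(_["site"] = i + 1, _["from"] = E->seq[i] + 1,
                      _["to"] = j + 1,
                      _["lambda"] = E->tips[E->tip_of[eid]].lambda);
}

// [[Rcpp::export]]
IntegerVector engine_sample_counts(SEXP eptr, int n) {
  XPtr<Engine> E(eptr);
  IntegerVector out((size_t)E->L * 4);
  for (int k = 0; k < n; ++k) out[sample_event_id(*E)]++;
  return out;
}

// [[Rcpp::export]]
void engine_apply(SEXP eptr, int site, int to) {
  XPtr<Engine> E(eptr);
  apply_event(*E, site - 1, to - 1);
}

// [[Rcpp::export]]
List engine_simulate_branch(SEXP eptr, double duration) {
  XPtr<Engine> E(eptr);
  std::vector<int> vsite, vfrom, vto;
  std::vector<double> vtime;
  double elapsed = 0.0;
  for (;;) {
    if (E->total <= 0) break;
    elapsed += exp_rand() / E->total;
    if (elapsed > duration) break;
    int eid = sample_event_id(*E);
    int i = eid / 4, j = eid % 4;
    vsite.push_back(i + 1);
    vfrom.push_back(E->seq[i] + 1);
    vto.push_back(j + 1);
    vtime.push_back(elapsed);
    apply_event(*E, i, j);
  }
  return List::create(_["site"] = wrap(vsite), _["from"] = wrap(vfrom),
                      _["to"] = wrap(vto), _["time"] = wrap(vtime));
}

// [[Rcpp::export]]
DataFrame engine_events(SEXP eptr) {
  XPtr<Engine> E(eptr);
  std::vector<int> site, to;
  std::vector<double> lambda;
  std::vector<std::string> wkey;
  for (size_t t = 0; t < E->tips.size(); ++t) {
    const Tip &T = E->tips[t];
    for (int eid : T.ev) {
      site.push_back(eid / 4 + 1);
      to.push_back(eid % 4 + 1);
      lambda.push_back(T.lambda);
      wkey.push_back(T.wkey);
    }
  }
  return DataFrame::create(_["site"] = site, _["to"] = to,
                           _["lambda"] = lambda, _["omega_key"] = wkey,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
List engine_weights(SEXP eptr) {
  XPtr<Engine> E(eptr);
  NumericVector w1(4), w2(8);
  for (int k = 0; k < 4; ++k) w1[k] = E->w1[k];
  for (int k = 0; k < 8; ++k) w2[k] = E->w2[k];
  std::vector<int> j3, t3, m3;
  std::vector<double> v3;
  for (auto &kv : E->w3) {
    long long c = kv.first;
    m3.push_back((int)(c % E->nmu) + 1);
    int c2 = (int)(c / E->nmu);
    t3.push_back(c2 % 2);
    j3.push_back(c2 / 2 + 1);
    v3.push_back(kv.second);
  }
  std::vector<int> j4, t4, m4, r4, ntips4;
  std::vector<double> v4;
  for (auto &kv : E->w4) {
    long long c = kv.first;
    r4.push_back((int)(c % E->nreg) + 1);
    long long c3 = c / E->nreg;
    m4.push_back((int)(c3 % E->nmu) + 1);
    int c2 = (int)(c3 / E->nmu);
    t4.push_back(c2 % 2);
    j4.push_back(c2 / 2 + 1);
    v4.push_back(kv.second);
    auto it = E->tips4.find(c);
    int nt = 0;
    if (it != E->tips4.end())
      for (int tid : it->second) if (!E->tips[tid].ev.empty()) ++nt;
    ntips4.push_back(nt);
  }
  std::vector<int> tj, tt, tm, tr, tn;
  std::vector<double> tl;
  std::vector<std::string> tw;
  for (const Tip &T : E->tips) {
    tj.push_back(T.j + 1); tt.push_back(T.t); tm.push_back(T.mu + 1);
    tr.push_back(T.reg + 1); tn.push_back((int)T.ev.size());
    tl.push_back(T.lambda); tw.push_back(T.wkey);
  }
  return List::create(
    _["total"] = E->total,
    _["by_target"] = w1,
    _["by_target_transclass"] = w2,
    _["level_mu"] = DataFrame::create(_["target"] = j3, _["transition"] = t3,
                                      _["mu_cat"] = m3, _["weight"] = v3),
    _["level_region"] = DataFrame::create(_["target"] = j4, _["transition"] = t4,
                                          _["mu_cat"] = m4, _["region"] = r4,
                                          _["weight"] = v4,
                                          _["n_omega_classes"] = ntips4),
    _["tips"] = DataFrame::create(_["target"] = tj, _["transition"] = tt,
                                  _["mu_cat"] = tm, _["region"] = tr,
                                  _["omega_key"] = tw, _["lambda"] = tl,
                                  _["n_events"] = tn,
                                  _["stringsAsFactors"] = false),
    _["n_substitutions"] = (double)E->nsub);
}
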