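// Lattice engine for the hallmark-integrated tumor-immune agent model.
//
// Two agent layers share one 2D grid: melanocytes (at most one per site) and
// cytotoxic T lymphocytes (at most one per site; co-location across layers is
// allowed). Melanocyte genomes are immutable after birth, so each cell's
// action probabilities and antigenicity are cached at creation, and the
// immune stimulatory factor (ISF) field is maintained incrementally as
// melanoma cells appear and disappear.
//
// All randomness draws from R's RNG stream (unif_rand / R::rpois), so
// set.seed() on the R side gives bitwise-reproducible trajectories.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <string>
#include <cmath>
using namespace Rcpp;

static const int MOORE[8][2] = {
  {-1,-1},{-1,0},{-1,1},{0,-1},{0,1},{1,-1},{1,0},{1,1}};

static inline int rint_below(int n) {
  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

class Engine {
public:
  // --- configuration -------------------------------------------------------
  int nr, nc, ngenes;
  double p0, q0, r0, f, a0min, a0max, m0;
  bool immune_on;
  double s0, fT, nT, gammaT, pi0, k0, qi, isf_sat;
  int isf_radius;
  bool count_mtc_only;
  std::vector<int> didx;                    // driver loci (0-based)
  std::vector<std::array<int,5>> dtags;     // per driver: p,q,r,c,ct flags
  std::vector<int> excl;                    // exclusivity-group loci, ascending
  int motil_locus;                          // locus enabling motility (-1: none)

  // --- melanocytes ---------------------------------------------------------
  std::vector<uint8_t> gen;                 // ncell * ngenes
  std::vector<double>  a0v, av, pv, qv, rv;
  std::vector<int>     rw, cl, birth;
  std::vector<uint8_t> alive, mtc, motile;

  // --- CTLs ----------------------------------------------------------------
  std::vector<int> ctl_r, ctl_c;
  std::vector<uint8_t> ctl_alive;

  // --- grids ---------------------------------------------------------------
  std::vector<int> mgrid;                   // melanocyte index + 1, 0 = empty
  std::vector<int> cgrid;                   // CTL index + 1, 0 = empty
  std::vector<double> F;                    // ISF field
  std::vector<int> stamp;
  int stampgen;

  int t;
  long nmel, nmtc, nctl;
  // event ledger for the current step (invariant checks)
  long ev_birth, ev_death, ev_kill;

  Engine(List cfg) {
    nr = as<int>(cfg["nrow"]); nc = as<int>(cfg["ncol"]);
    ngenes = as<int>(cfg["n_genes"]);
    p0 = as<double>(cfg["p0"]); q0 = as<double>(cfg["q0"]);
    r0 = as<double>(cfg["r0"]); f = as<double>(cfg["f"]);
    a0min = as<double>(cfg["a0_min"]); a0max = as<double>(cfg["a0_max"]);
    m0 = as<double>(cfg["m0"]);
    immune_on = as<bool>(cfg["immune_enabled"]);
    s0 = as<double>(cfg["s0"]); fT = as<double>(cfg["f_T"]);
    nT = as<double>(cfg["n_T"]); gammaT = as<double>(cfg["gamma_T"]);
    pi0 = as<double>(cfg["p_i0"]); k0 = as<double>(cfg["k0"]);
    qi = as<double>(cfg["q_i"]); isf_sat = as<double>(cfg["isf_sat"]);
    isf_radius = as<int>(cfg["isf_radius"]);
    count_mtc_only = as<bool>(cfg["count_mtc_only"]);
    IntegerVector di = cfg["driver_idx"];      // 0-based
    IntegerMatrix tg = cfg["driver_tags"];     // ndriver x 5 (p,q,r,c,ct)
    for (int i = 0; i < di.size(); ++i) {
      didx.push_back(di[i]);
      std::array<int,5> a;
      for (int j = 0; j < 5; ++j) a[j] = tg(i, j);
      dtags.push_back(a);
    }
    IntegerVector ex = cfg["excl_idx"];        // 0-based
    for (int i = 0; i < ex.size(); ++i) excl.push_back(ex[i]);
    std::sort(excl.begin(), excl.end());
    motil_locus = as<int>(cfg["motility_locus"]); // 0-based or -1
    mgrid.assign((size_t)nr * nc, 0);
    cgrid.assign((size_t)nr * nc, 0);
    F.assign((size_t)nr * nc, 0.0);
    stamp.assign((size_t)nr * nc, 0);
    stampgen = 0; t = 0; nmel = nmtc = nctl = 0;
    ev_birth = ev_death = ev_kill = 0;
  }

  inline int gi(int r, int c) const { return r * nc + c; }
  inline bool inb(int r, int c) const {
    return r >= 0 && r < nr && c >= 0 && c < nc;
  }

  // per-hallmark driver counts for one genome: p,q,r,c,ct
  void hallmark_counts(const uint8_t *g, int out[5]) const {
    for (int j = 0; j < 5; ++j) out[j] = 0;
    for (size_t i = 0; i < didx.size(); ++i)
      if (g[didx[i]])
        for (int j = 0; j < 5; ++j) out[j] += dtags[i][j];
  }

  bool genome_is_mtc(const uint8_t *g) const {
    for (size_t i = 0; i < didx.size(); ++i)
      if (g[didx[i]]) return true;
    return false;
  }

  // ISF kernel: linear taper (R + 1 - d) / (R + 1) in Chebyshev distance d,
  // so the field increases toward each source and strictly-uphill
  // chemotaxis can home in on isolated antigenic cells
  void field_add(int r, int c, double val) {
    if (val == 0.0) return;
    int R = isf_radius;
    int r1 = std::max(0, r - R), r2 = std::min(nr - 1, r + R);
    int c1 = std::max(0, c - R), c2 = std::min(nc - 1, c + R);
    for (int i = r1; i <= r2; ++i)
      for (int j = c1; j <= c2; ++j) {
        int d = std::max(std::abs(i - r), std::abs(j - c));
        F[gi(i, j)] += val * (double)(R + 1 - d) / (double)(R + 1);
      }
  }

  // create a melanocyte; genome is copied. Returns cell index.
  int add_cell(const uint8_t *g, int r, int c, double a0, int b) {
    int idx = (int)rw.size();
    gen.insert(gen.end(), g, g + ngenes);
    int cnt[5]; hallmark_counts(g, cnt);
    bool is_m = genome_is_mtc(g);
    double p = std::min(1.0, p0 * std::pow(10.0, f * cnt[0]));
    double q = q0 * std::pow(10.0, -f * cnt[1]);
    double rr = std::min(1.0, r0 * std::pow(10.0, f * cnt[2]));
    double a = is_m ? a0 * std::pow(10.0, f * (cnt[4] - cnt[3])) : 0.0;
    a0v.push_back(a0); av.push_back(a);
    pv.push_back(p); qv.push_back(q); rv.push_back(rr);
    rw.push_back(r); cl.push_back(c); birth.push_back(b);
    alive.push_back(1); mtc.push_back(is_m ? 1 : 0);
    motile.push_back((motil_locus >= 0 && g[motil_locus]) ? 1 : 0);
    mgrid[gi(r, c)] = idx + 1;
    ++nmel; if (is_m) ++nmtc;
    field_add(r, c, a);
    return idx;
  }

  void remove_cell(int idx) {
    alive[idx] = 0;
    mgrid[gi(rw[idx], cl[idx])] = 0;
    --nmel; if (mtc[idx]) --nmtc;
    field_add(rw[idx], cl[idx], -av[idx]);
  }

  // daughter genome from parent: wild genes flip with probability r,
  // in ascending index order; exclusivity-group genes never flip while
  // another group member is mutated; no back-mutation.
  void mutate_into(const uint8_t *par, double r, uint8_t *out) const {
    std::copy(par, par + ngenes, out);
    for (int k = 0; k < ngenes; ++k) {
      if (out[k]) continue;
      bool in_excl = std::binary_search(excl.begin(), excl.end(), k);
      if (in_excl) {
        bool other = false;
        for (size_t e = 0; e < excl.size(); ++e)
          if (excl[e] != k && out[excl[e]]) { other = true; break; }
        if (other) continue;
      }
      if (unif_rand() < r) out[k] = 1;
    }
  }

  // move melanocyte idx to (r2,c2) (must be melanocyte-free)
  void relocate(int idx, int r2, int c2) {
    mgrid[gi(rw[idx], cl[idx])] = 0;
    field_add(rw[idx], cl[idx], -av[idx]);
    rw[idx] = r2; cl[idx] = c2;
    mgrid[gi(r2, c2)] = idx + 1;
    field_add(r2, c2, av[idx]);
  }

  // push move in Moore direction d: if target empty, simple move; else the
  // contiguous run of melanocytes along the ray shifts outward by one site
  // and the mover takes the vacated target. Aborts (returns false) when the
  // ray reaches the grid boundary before an empty site.
  bool push_move(int idx, int d) {
    int dr = MOORE[d][0], dc = MOORE[d][1];
    int tr = rw[idx] + dr, tc = cl[idx] + dc;
    if (!inb(tr, tc)) return false;
    if (!mgrid[gi(tr, tc)]) { relocate(idx, tr, tc); return true; }
    // scan ray for first empty site
    int er = tr, ec = tc;
    while (true) {
      er += dr; ec += dc;
      if (!inb(er, ec)) return false;      // boundary: abort
      if (!mgrid[gi(er, ec)]) break;
    }
    // shift run from far end back to target
    int cr = er - dr, cc = ec - dc;
    while (!(cr == rw[idx] && cc == cl[idx])) {
      int j = mgrid[gi(cr, cc)] - 1;
      relocate(j, cr + dr, cc + dc);
      cr -= dr; cc -= dc;
    }
    relocate(idx, tr, tc);
    return true;
  }

  // one melanocyte action: death -> division -> motility
  void melanocyte_update(int i) {
    if (!alive[i]) return;
    if (unif_rand() < qv[i]) { remove_cell(i); ++ev_death; return; }
    if (unif_rand() < pv[i]) {
      int er[8], ec[8], ne = 0;
      for (int d = 0; d < 8; ++d) {
        int r2 = rw[i] + MOORE[d][0], c2 = cl[i] + MOORE[d][1];
        if (inb(r2, c2) && !mgrid[gi(r2, c2)]) { er[ne] = r2; ec[ne] = c2; ++ne; }
      }
      if (ne > 0) {
        int k = rint_below(ne);
        std::vector<uint8_t> child(ngenes);
        mutate_into(&gen[(size_t)i * ngenes], rv[i], child.data());
        add_cell(child.data(), er[k], ec[k], a0v[i], t + 1);
        ++ev_birth;
      }
      return; // division attempt (even failed) ends the action set
    }
    if (motile[i] && m0 > 0 && unif_rand() < m0) {
      int ed[8], ne = 0;
      for (int d = 0; d < 8; ++d) {
        int r2 = rw[i] + MOORE[d][0], c2 = cl[i] + MOORE[d][1];
        if (inb(r2, c2) && !mgrid[gi(r2, c2)]) ed[ne++] = d;
      }
      if (ne > 0) push_move(i, ed[rint_below(ne)]);
      else push_move(i, rint_below(8));
    }
  }

  // total ISF of border melanoma cells (>=1 non-MTC Moore neighbor,
  // out-of-grid counting as non-MTC)
  double border_isf(std::vector<int> *border_out = nullptr) const {
    double Fb = 0.0;
    for (size_t i = 0; i < rw.size(); ++i) {
      if (!alive[i] || !mtc[i]) continue;
      bool border = false;
      for (int d = 0; d < 8 && !border; ++d) {
        int r2 = rw[i] + MOORE[d][0], c2 = cl[i] + MOORE[d][1];
        if (!inb(r2, c2)) { border = true; break; }
        int m = mgrid[gi(r2, c2)];
        if (!m || !mtc[m - 1]) border = true;
      }
      if (border) {
        Fb += av[i];
        if (border_out) border_out->push_back((int)i);
      }
    }
    return Fb;
  }

  double recruitment_rate(double Fb) const {
    if (Fb <= 0.0) return s0;
    double h = std::pow(Fb, nT);
    return s0 + fT * h / (gammaT + h);
  }

  void add_ctl(int r, int c) {
    int idx = (int)ctl_r.size();
    ctl_r.push_back(r); ctl_c.push_back(c); ctl_alive.push_back(1);
    cgrid[gi(r, c)] = idx + 1;
    ++nctl;
  }

  void remove_ctl(int j) {
    ctl_alive[j] = 0;
    cgrid[gi(ctl_r[j], ctl_c[j])] = 0;
    --nctl;
  }

  // Poisson recruitment onto empty sites within Chebyshev distance 2 of a
  // border melanoma cell
  void recruit(double sT) {
    int n = (int)R::rpois(sT);
    if (n <= 0) return;
    std::vector<int> border;
    border_isf(&border);
    ++stampgen;
    std::vector<int> band;
    for (size_t b = 0; b < border.size(); ++b) {
      int i = border[b];
      for (int dr2 = -2; dr2 <= 2; ++dr2)
        for (int dc2 = -2; dc2 <= 2; ++dc2) {
          int r2 = rw[i] + dr2, c2 = cl[i] + dc2;
          if (!inb(r2, c2)) continue;
          int s = gi(r2, c2);
          if (stamp[s] == stampgen) continue;
          stamp[s] = stampgen;
          if (!mgrid[s] && !cgrid[s]) band.push_back(s);
        }
    }
    int navail = (int)band.size();
    for (int k = 0; k < n && navail > 0; ++k) {
      int j = rint_below(navail);
      int s = band[j];
      band[j] = band[--navail];
      add_ctl(s / nc, s % nc);
    }
  }

  // one CTL action set: apoptosis -> ISF-dependent kill -> ISF-dependent
  // division -> strictly uphill chemotaxis
  void ctl_update(int j) {
    if (!ctl_alive[j]) return;
    if (unif_rand() < qi) { remove_ctl(j); return; }
    double Fh = F[gi(ctl_r[j], ctl_c[j])];
    // kill: highest-antigenicity adjacent melanoma cell, ties uniform
    int best[8], nbest = 0; double besta = -1.0;
    for (int d = 0; d < 8; ++d) {
      int r2 = ctl_r[j] + MOORE[d][0], c2 = ctl_c[j] + MOORE[d][1];
      if (!inb(r2, c2)) continue;
      int m = mgrid[gi(r2, c2)];
      if (m && mtc[m - 1]) {
        double a = av[m - 1];
        if (a > besta + 1e-12) { besta = a; nbest = 0; best[nbest++] = m - 1; }
        else if (std::fabs(a - besta) <= 1e-12) best[nbest++] = m - 1;
      }
    }
    double kp = std::min(1.0, k0 * Fh / (isf_sat + Fh));
    if (nbest > 0 && unif_rand() < kp) {
      remove_cell(best[rint_below(nbest)]);
      ++ev_kill;
      return;
    }
    double pp = std::min(1.0, pi0 * Fh / (isf_sat + Fh));
    if (unif_rand() < pp) {
      int er[8], ec[8], ne = 0;
      for (int d = 0; d < 8; ++d) {
        int r2 = ctl_r[j] + MOORE[d][0], c2 = ctl_c[j] + MOORE[d][1];
        if (inb(r2, c2) && !cgrid[gi(r2, c2)]) { er[ne] = r2; ec[ne] = c2; ++ne; }
      }
      if (ne > 0) { int k = rint_below(ne); add_ctl(er[k], ec[k]); }
      return;
    }
    // chemotaxis: Moore neighbor (CTL-free) with maximal F, strictly uphill
    int br[8], bc[8]; int nb = 0; double bF = Fh;
    for (int d = 0; d < 8; ++d) {
      int r2 = ctl_r[j] + MOORE[d][0], c2 = ctl_c[j] + MOORE[d][1];
      if (!inb(r2, c2) || cgrid[gi(r2, c2)]) continue;
      double Fn = F[gi(r2, c2)];
      if (Fn > bF + 1e-12) { bF = Fn; nb = 0; br[nb] = r2; bc[nb] = c2; ++nb; }
      else if (nb > 0 && std::fabs(Fn - bF) <= 1e-12) { br[nb] = r2; bc[nb] = c2; ++nb; }
    }
    if (nb > 0) {
      int k = rint_below(nb);
      cgrid[gi(ctl_r[j], ctl_c[j])] = 0;
      ctl_r[j] = br[k]; ctl_c[j] = bc[k];
      cgrid[gi(br[k], bc[k])] = j + 1;
    }
  }

  void immune_round() {
    double Fb = border_isf();
    recruit(recruitment_rate(Fb));
    std::vector<int> order;
    for (size_t j = 0; j < ctl_r.size(); ++j)
      if (ctl_alive[j]) order.push_back((int)j);
    for (int k = (int)order.size() - 1; k > 0; --k)
      std::swap(order[k], order[rint_below(k + 1)]);
    for (size_t k = 0; k < order.size(); ++k) ctl_update(order[k]);
  }

  // one synchronous round: melanocytes in shuffled order, then immune
  void step() {
    ev_birth = ev_death = ev_kill = 0;
    std::vector<int> order;
    order.reserve((size_t)nmel);
    for (size_t i = 0; i < rw.size(); ++i)
      if (alive[i]) order.push_back((int)i);
    for (int k = (int)order.size() - 1; k > 0; --k)
      std::swap(order[k], order[rint_below(k + 1)]);
    for (size_t k = 0; k < order.size(); ++k) melanocyte_update(order[k]);
    if (immune_on) immune_round();
    ++t;
  }

  long pop_count() const { return count_mtc_only ? nmtc : nmel; }

  DataFrame cells_df() const {
    std::vector<int> id, r_, c_, b_;
    std::vector<double> a0_;
    std::vector<std::string> type, g_;
    for (size_t i = 0; i < rw.size(); ++i) {
      if (!alive[i]) continue;
      id.push_back((int)i + 1);
      type.push_back(mtc[i] ? "MTC" : "NC");
      r_.push_back(rw[i] + 1); c_.push_back(cl[i] + 1);
      b_.push_back(birth[i]); a0_.push_back(a0v[i]);
      std::string s(ngenes, '0');
      const uint8_t *g = &gen[(size_t)i * ngenes];
      for (int k = 0; k < ngenes; ++k) if (g[k]) s[k] = '1';
      g_.push_back(s);
    }
    int nm = (int)id.size();
    for (size_t j = 0; j < ctl_r.size(); ++j) {
      if (!ctl_alive[j]) continue;
      id.push_back(nm + (int)j + 1);
      type.push_back("CTL");
      r_.push_back(ctl_r[j] + 1); c_.push_back(ctl_c[j] + 1);
      b_.push_back(NA_INTEGER); a0_.push_back(NA_REAL);
      g_.push_back("NA");
    }
    CharacterVector gv(g_.size());
    for (size_t i = 0; i < g_.size(); ++i)
      gv[i] = (g_[i] == "NA") ? NA_STRING : String(g_[i]);
    return DataFrame::create(
      _["cell_id"] = id, _["type"] = type, _["row"] = r_, _["col"] = c_,
      _["birth_step"] = b_, _["a0"] = a0_, _["genome"] = gv,
      _["stringsAsFactors"] = false);
  }
};

// [[Rcpp::export]]
SEXP eng_new(List cfg) {
  XPtr<Engine> p(new Engine(cfg), true);
  return p;
}

// standard initialization: 9 unmutated melanocytes and 1 founder melanoma
// cell (single mutated founder locus), contiguous at grid center
// [[Rcpp::export]]
void eng_init_standard(SEXP ptr, int founder_locus) {
  XPtr<Engine> e(ptr);
  if (e->nr < 5 || e->nc < 5) stop("grid too small for the initial cluster");
  int cr = e->nr / 2, cc = e->nc / 2;
  std::vector<uint8_t> wild(e->ngenes, 0);
  std::vector<uint8_t> founder(e->ngenes, 0);
  founder[founder_locus] = 1;
  // 3x3 block of normal cells, founder melanoma cell attached to its edge
  // so it starts with empty neighbors to divide into
  for (int dr = -1; dr <= 1; ++dr)
    for (int dc = -1; dc <= 1; ++dc) {
      double a0 = e->a0min + unif_rand() * (e->a0max - e->a0min);
      e->add_cell(wild.data(), cr + dr, cc + dc, a0, 0);
    }
  double a0f = e->a0min + unif_rand() * (e->a0max - e->a0min);
  e->add_cell(founder.data(), cr, cc + 2, a0f, 0);
}

// initialize from an explicit cell table (1-based coordinates)
// [[Rcpp::export]]
void eng_init_cells(SEXP ptr, IntegerVector row, IntegerVector col,
                    CharacterVector type, CharacterVector genome,
                    NumericVector a0, IntegerVector birth_step) {
  XPtr<Engine> e(ptr);
  std::vector<uint8_t> g(e->ngenes);
  for (int i = 0; i < row.size(); ++i) {
    int r = row[i] - 1, c = col[i] - 1;
    if (!e->inb(r, c)) stop("cell position outside grid");
    if (type[i] == "CTL") {
      if (e->cgrid[e->gi(r, c)]) stop("two CTLs on one site");
      e->add_ctl(r, c);
    } else {
      if (e->mgrid[e->gi(r, c)]) stop("two melanocytes on one site");
      std::string s = as<std::string>(genome[i]);
      if ((int)s.size() != e->ngenes) stop("genome string length mismatch");
      for (int k = 0; k < e->ngenes; ++k) g[k] = (s[k] == '1');
      double a = NumericVector::is_na(a0[i])
        ? e->a0min + unif_rand() * (e->a0max - e->a0min) : a0[i];
      int b = IntegerVector::is_na(birth_step[i]) ? 0 : birth_step[i];
      e->add_cell(g.data(), r, c, a, b);
    }
  }
}

// [[Rcpp::export]]
void eng_step(SEXP ptr, int nsteps) {
  XPtr<Engine> e(ptr);
  for (int i = 0; i < nsteps; ++i) e->step();
}

// [[Rcpp::export]]
List eng_run(SEXP ptr, int c_max, int t_max, int snapshot_every) {
  XPtr<Engine> e(ptr);
  List snaps;
  IntegerVector snap_t;
  std::vector<int> tr_t; std::vector<long> tr_mel, tr_mtc, tr_ctl;
  snaps.push_back(e->cells_df()); snap_t.push_back(e->t);
  tr_t.push_back(e->t); tr_mel.push_back(e->nmel);
  tr_mtc.push_back(e->nmtc); tr_ctl.push_back(e->nctl);
  std::string term;
  int last_snap = e->t;
  while (true) {
    if (e->pop_count() >= c_max) { term = "c_max"; break; }
    if (e->t >= t_max) { term = "t_max"; break; }
    if (e->nmel == 0) { term = "extinct"; break; }
    e->step();
    tr_t.push_back(e->t); tr_mel.push_back(e->nmel);
    tr_mtc.push_back(e->nmtc); tr_ctl.push_back(e->nctl);
    if (snapshot_every > 0 && e->t % snapshot_every == 0) {
      snaps.push_back(e->cells_df()); snap_t.push_back(e->t);
      last_snap = e->t;
    }
  }
  if (last_snap != e->t) { snaps.push_back(e->cells_df()); snap_t.push_back(e->t); }
  DataFrame trace = DataFrame::create(
    _["step"] = tr_t,
    _["n_melanocytes"] = NumericVector(tr_mel.begin(), tr_mel.end()),
    _["n_mtc"] = NumericVector(tr_mtc.begin(), tr_mtc.end()),
    _["n_ctl"] = NumericVector(tr_ctl.begin(), tr_ctl.end()));
  return List::create(_["snapshots"] = snaps, _["snapshot_step"] = snap_t,
                      _["trace"] = trace, _["termination"] = term,
                      _["steps"] = e->t);
}

// [[Rcpp::export]]
DataFrame eng_cells(SEXP ptr) { XPtr<Engine> e(ptr); return e->cells_df(); }

// [[Rcpp::export]]
NumericMatrix eng_field(SEXP ptr) {
  XPtr<Engine> e(ptr);
  NumericMatrix out(e->nr, e->nc);
  for (int r = 0; r < e->nr; ++r)
    for (int c = 0; c < e->nc; ++c)
      out(r + 0, c + 0) = e->F[e->gi(r, c)];
  return out;
}

// [[Rcpp::export]]
double eng_border_isf(SEXP ptr) { XPtr<Engine> e(ptr); return e->border_isf(); }

// [[Rcpp::export]]
List eng_counts(SEXP ptr) {
  XPtr<Engine> e(ptr);
  return List::create(_["step"] = e->t, _["n_melanocytes"] = (double)e->nmel,
                      _["n_mtc"] = (double)e->nmtc, _["n_ctl"] = (double)e->nctl,
                      _["births"] = (double)e->ev_birth,
                      _["deaths"] = (double)e->ev_death,
                      _["kills"] = (double)e->ev_kill);
}

// direct push-move test hook (1-based position, dir in 0..7 Moore order)
// [[Rcpp::export]]
bool eng_push(SEXP ptr, int row, int col, int dir) {
  XPtr<Engine> e(ptr);
  int m = e->mgrid[e->gi(row - 1, col - 1)];
  if (!m) stop("no melanocyte at the given site");
  return e->push_move(m - 1, dir);
}

// connected-component mask utilities ---------------------------------------

// largest 8-connected component of a logical mask
// [[Rcpp::export]]
LogicalMatrix mask_largest_component(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> lab((size_t)nr * nc, 0);
  int nlab = 0, bestlab = 0, bestn = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab[r * nc + c]) continue;
      ++nlab; int n = 0;
      stack.push_back(r * nc + c); lab[r * nc + c] = nlab;
      while (!stack.empty()) {
        int s = stack.back(); stack.pop_back(); ++n;
        int rr = s / nc, cc = s % nc;
        for (int d = 0; d < 8; ++d) {
          int r2 = rr + MOORE[d][0], c2 = cc + MOORE[d][1];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && !lab[r2 * nc + c2]) {
            lab[r2 * nc + c2] = nlab; stack.push_back(r2 * nc + c2);
          }
        }
      }
      if (n > bestn) { bestn = n; bestlab = nlab; }
    }
  LogicalMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      out(r, c) = (lab[r * nc + c] == bestlab);
  return out;
}

// fill interior holes: background is flood-filled (4-connectivity) from the
// matrix border; unreached background becomes foreground
// [[Rcpp::export]]
LogicalMatrix mask_fill_holes(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<uint8_t> outside((size_t)nr * nc, 0);
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    if (!mask(r, 0)) stack.push_back(r * nc);
    if (!mask(r, nc - 1)) stack.push_back(r * nc + nc - 1);
  }
  for (int c = 0; c < nc; ++c) {
    if (!mask(0, c)) stack.push_back(c);
    if (!mask(nr - 1, c)) stack.push_back((nr - 1) * nc + c);
  }
  const int d4[4][2] = {{-1,0},{1,0},{0,-1},{0,1}};
  while (!stack.empty()) {
    int s = stack.back(); stack.pop_back();
    if (outside[s]) continue;
    outside[s] = 1;
    int rr = s / nc, cc = s % nc;
    for (int d = 0; d < 4; ++d) {
      int r2 = rr + d4[d][0], c2 = cc + d4[d][1];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!mask(r2, c2) && !outside[r2 * nc + c2]) stack.push_back(r2 * nc + c2);
    }
  }
  LogicalMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      out(r, c) = mask(r, c) || !outside[r * nc + c];
  return out;
}
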