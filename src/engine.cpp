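// Compiled generational engine.
//
// Implements the identical algorithm and RNG draw order as the pure-R
// reference engine in R/engine-r.R (see the draw-order contract there).
// All random numbers come from the R RNG (unif_rand / norm_rand / R::rpois),
// so a run with a given set.seed() is bit-identical across the two engines.
// Accumulations that R performs with extended precision (sum, rowMeans) use
// long double here for the same reason.

#include <Rcpp.h>
#include <vector>
#include <deque>
#include <set>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

// unmarried-cohort ages are capped at MAXL marriage rounds
#define MAXL 8

struct Fam {
  int id;
  double t1, t2, p1, p2;
  bool repro;
  int men[MAXL], women[MAXL];  // counts by steps-since-maturity
};

struct Soc {
  int id;
  std::vector<Fam> fams;
};

struct Ev {
  int step, soc, g, b, c;
  double gv[4], bv[4], cv[4];
};

struct Engine {
  double d_c, d_m, b, mu, tau2;
  int N_f, N_s, n_steps, L, event_window;
  double thr;  // split threshold in families
  int next_fid, next_sid, step;
  std::vector<double> init_tp;  // optional n x 4 (t1,t2,p1,p2), row-major
  int init_n;
  std::vector<Soc> socs;
  std::deque<Ev> events;
  // split log: one row per split event
  std::vector<int> sp_step, sp_parent, sp_child, sp_removed;
  // per-step summaries
  std::vector<int> sm_step, sm_nfam, sm_alive, sm_pop;
  std::vector<double> sm_vt1, sm_vt2, sm_vp1, sm_vp2;
  std::string outcome;

  void init() {
    next_fid = 1;
    socs.assign(N_s, Soc());
    for (int s = 0; s < N_s; ++s) {
      socs[s].id = s + 1;
      socs[s].fams.reserve(4 * N_f);
      for (int k = 0; k < N_f; ++k) {
        Fam f;
        f.id = next_fid++;
        if (init_n > 0) {
          const int row = k % init_n;
          f.t1 = init_tp[row * 4 + 0];
          f.t2 = init_tp[row * 4 + 1];
          f.p1 = init_tp[row * 4 + 2];
          f.p2 = init_tp[row * 4 + 3];
        } else {
          f.t1 = f.t2 = f.p1 = f.p2 = 0.0;
        }
        f.repro = false;
        for (int a = 0; a < MAXL; ++a) f.men[a] = f.women[a] = 0;
        socs[s].fams.push_back(f);
      }
    }
    next_sid = N_s + 1;
    step = 0;
    outcome = "running";
  }

  void reproduce() {
    for (size_t s = 0; s < socs.size(); ++s) {
      std::vector<Fam>& fams = socs[s].fams;
      const int F = (int)fams.size();
      if (F == 0) continue;
      bool any = false;
      for (int i = 0; i < F; ++i) if (!fams[i].repro) { any = true; break; }
      if (!any) continue;
      for (int i = 0; i < F; ++i) {
        if (fams[i].repro) continue;
        long double accF = 0.0L, accR = 0.0L;
        const double t1i = fams[i].t1, t2i = fams[i].t2;
        const double p1i = fams[i].p1, p2i = fams[i].p2;
        for (int j = 0; j < F; ++j) {
          const double dt1 = t1i - fams[j].t1, dt2 = t2i - fams[j].t2;
          const double a1 = t1i - fams[j].p1, a2 = t2i - fams[j].p2;
          const double b1 = p1i - fams[j].t1, b2 = p2i - fams[j].t2;
          const double q1 = p1i - fams[j].p1, q2 = p2i - fams[j].p2;
          const double dtt = dt1 * dt1 + dt2 * dt2;
          const double dtp = a1 * a1 + a2 * a2;   // |t_i - p_j|^2
          const double dpt = b1 * b1 + b2 * b2;   // |p_i - t_j|^2
          const double dpp = q1 * q1 + q2 * q2;
          double dmin = dtt;
          if (dtp < dmin) dmin = dtp;
          if (dpt < dmin) dmin = dpt;
          accF += std::exp((-dmin) / tau2);
          accR += std::exp((-dpp) / tau2);
        }
        const double fr = (double)(accF / (long double)F);
        const double rv = (double)(accR / (long double)F);
        const double r = b * std::exp((-d_c) * (1.0 - fr) - d_m * rv);
        const int m = (int)R::rpois(r);
        const int w = (int)R::rpois(r);
        fams[i].men[0] += m;
        fams[i].women[0] += w;
        fams[i].repro = true;
      }
    }
  }

  void marry() {
    for (size_t s = 0; s < socs.size(); ++s) {
      std::vector<Fam>& fams = socs[s].fams;
      const int F0 = (int)fams.size();
      if (F0 == 0) continue;
      // enumerate man slots: family roster order, then age 0..L-1
      std::vector<int> slot_fam, slot_age;
      for (int fi = 0; fi < F0; ++fi)
        for (int a = 0; a < L; ++a)
          for (int k = 0; k < fams[fi].men[a]; ++k) {
            slot_fam.push_back(fi);
            slot_age.push_back(a);
          }
      const int nmen = (int)slot_fam.size();
      if (nmen == 0) continue;
      std::vector<double> u(nmen);
      for (int k = 0; k < nmen; ++k) u[k] = unif_rand();
      std::vector<int> ord(nmen);
      for (int k = 0; k < nmen; ++k) ord[k] = k;
      std::stable_sort(ord.begin(), ord.end(),
                       [&u](int a, int bb) { return u[a] < u[bb]; });
      // marriage offers are sampled over the whole phase-start roster
      // (eq-style normalization over Phi); an offer to a family without an
      // unmarried woman fails and the man stays unmarried this round
      std::vector<int> wtot(F0, 0);
      for (int fi = 0; fi < F0; ++fi) {
        int w = 0;
        for (int a = 0; a < L; ++a) w += fams[fi].women[a];
        wtot[fi] = w;
      }
      // lazy per-groom-family weight rows and their totals
      std::vector<std::vector<double> > wrow(F0);
      std::vector<double> wsum(F0, -1.0);
      for (int kk = 0; kk < nmen; ++kk) {
        const int k = ord[kk];
        const int g = slot_fam[k];
        if (wrow[g].empty()) {
          wrow[g].assign(F0, 0.0);
          const double tg1 = fams[g].t1, tg2 = fams[g].t2;
          long double ssl = 0.0L;
          for (int fi = 0; fi < F0; ++fi) {
            const double d1 = tg1 - fams[fi].p1, d2 = tg2 - fams[fi].p2;
            wrow[g][fi] = std::exp((-(d1 * d1 + d2 * d2)) / tau2);
            ssl += wrow[g][fi];
          }
          wsum[g] = (double)ssl;
        }
        double ssum = wsum[g];
        bool uniform = false;
        if (ssum <= 0.0) {
          ssum = (double)F0;
          uniform = true;
        }
        const double v = unif_rand() * ssum;
        double cum = 0.0;
        int bfi = F0 - 1;
        for (int fi = 0; fi < F0; ++fi) {
          cum += uniform ? 1.0 : wrow[g][fi];
          if (cum >= v) { bfi = fi; break; }
        }
        if (wtot[bfi] == 0) continue;  // failed offer
        // consume bride (oldest first) and groom
        for (int a = L - 1; a >= 0; --a)
          if (fams[bfi].women[a] > 0) { fams[bfi].women[a] -= 1; break; }
        wtot[bfi] -= 1;
        fams[g].men[slot_age[k]] -= 1;
        // child family: paternal (t1, p1) from groom, maternal (t2, p2)
        // from bride, plus transmission noise
        Fam ch;
        ch.id = next_fid++;
        ch.t1 = fams[g].t1 + mu * norm_rand();
        ch.t2 = fams[bfi].t2 + mu * norm_rand();
        ch.p1 = fams[g].p1 + mu * norm_rand();
        ch.p2 = fams[bfi].p2 + mu * norm_rand();
        ch.repro = false;
        for (int a = 0; a < MAXL; ++a) ch.men[a] = ch.women[a] = 0;
        Ev ev;
        ev.step = step;
        ev.soc = socs[s].id;
        ev.g = fams[g].id;
        ev.b = fams[bfi].id;
        ev.c = ch.id;
        ev.gv[0] = fams[g].t1; ev.gv[1] = fams[g].t2;
        ev.gv[2] = fams[g].p1; ev.gv[3] = fams[g].p2;
        ev.bv[0] = fams[bfi].t1; ev.bv[1] = fams[bfi].t2;
        ev.bv[2] = fams[bfi].p1; ev.bv[3] = fams[bfi].p2;
        ev.cv[0] = ch.t1; ev.cv[1] = ch.t2; ev.cv[2] = ch.p1; ev.cv[3] = ch.p2;
        events.push_back(ev);
        fams.push_back(ch);  // invalidates no indices used above (push_back
                             // may reallocate; fams[g] etc. re-read next loop)
      }
    }
  }

  void cull() {
    for (size_t s = 0; s < socs.size(); ++s) {
      std::vector<Fam>& fams = socs[s].fams;
      if (fams.empty()) continue;
      std::vector<Fam> kept;
      kept.reserve(fams.size());
      for (size_t fi = 0; fi < fams.size(); ++fi) {
        Fam& f = fams[fi];
        for (int a = L - 1; a > 0; --a) {
          f.men[a] = f.men[a - 1];
          f.women[a] = f.women[a - 1];
        }
        f.men[0] = 0;
        f.women[0] = 0;
        int tot = 0;
        for (int a = 0; a < L; ++a) tot += f.men[a] + f.women[a];
        if (tot > 0 || !f.repro) kept.push_back(f);
      }
      fams.swap(kept);
    }
  }

  int soc_pos(int sid) const {
    for (size_t s = 0; s < socs.size(); ++s)
      if (socs[s].id == sid) return (int)s;
    return -1;
  }

  void split() {
    std::vector<int> cand;
    for (size_t s = 0; s < socs.size(); ++s)
      if ((double)socs[s].fams.size() >= thr) cand.push_back((int)s);
    if (cand.empty()) return;
    const int nc = (int)cand.size();
    std::vector<double> u(nc);
    for (int k = 0; k < nc; ++k) u[k] = unif_rand();
    std::vector<int> ord(nc);
    for (int k = 0; k < nc; ++k) ord[k] = k;
    std::stable_sort(ord.begin(), ord.end(),
                     [&u](int a, int bb) { return u[a] < u[bb]; });
    std::deque<int> queue;
    for (int k = 0; k < nc; ++k) queue.push_back(socs[cand[ord[k]]].id);
    while (!queue.empty()) {
      const int sid = queue.front();
      queue.pop_front();
      const int pos = soc_pos(sid);
      if (pos < 0) continue;  // replaced by an earlier removal
      std::vector<Fam>& fams = socs[pos].fams;
      const int n = (int)fams.size();
      if ((double)n < thr) continue;
      std::vector<double> uf(n);
      for (int k = 0; k < n; ++k) uf[k] = unif_rand();
      std::vector<int> ordf(n);
      for (int k = 0; k < n; ++k) ordf[k] = k;
      std::stable_sort(ordf.begin(), ordf.end(),
                       [&uf](int a, int bb) { return uf[a] < uf[bb]; });
      const int nstay = (n + 1) / 2;  // ceiling(n / 2)
      std::vector<char> stays(n, 0);
      for (int k = 0; k < nstay; ++k) stays[ordf[k]] = 1;
      Soc ns;
      ns.id = next_sid++;
      std::vector<Fam> stay_f;
      stay_f.reserve(nstay);
      ns.fams.reserve(n - nstay);
      for (int k = 0; k < n; ++k) {
        if (stays[k]) stay_f.push_back(fams[k]);
        else ns.fams.push_back(fams[k]);
      }
      socs[pos].fams.swap(stay_f);
      // replace one other society, uniformly at random
      const int m = (int)socs.size() - 1;
      int ridx = (int)std::floor(unif_rand() * (double)m);
      if (ridx > m - 1) ridx = m - 1;
      int cnt = -1, target = -1;
      for (size_t s = 0; s < socs.size(); ++s) {
        if ((int)s == pos) continue;
        if (++cnt == ridx) { target = (int)s; break; }
      }
      sp_step.push_back(step);
      sp_parent.push_back(sid);
      sp_child.push_back(ns.id);
      sp_removed.push_back(socs[target].id);
      socs[target] = ns;
      if ((double)socs[pos].fams.size() >= thr) queue.push_back(sid);
      if ((double)socs[target].fams.size() >= thr) queue.push_back(ns.id);
    }
  }

  void summarise() {
    int nf = 0, pop = 0, alive = 0;
    for (size_t s = 0; s < socs.size(); ++s) {
      const int F = (int)socs[s].fams.size();
      nf += F;
      if (F > 0) ++alive;
      for (int fi = 0; fi < F; ++fi)
        for (int a = 0; a < L; ++a)
          pop += socs[s].fams[fi].men[a] + socs[s].fams[fi].women[a];
    }
    sm_step.push_back(step);
    sm_nfam.push_back(nf);
    sm_alive.push_back(alive);
    sm_pop.push_back(pop);
    double vt[4];
    for (int d = 0; d < 4; ++d) vt[d] = NA_REAL;
    if (nf >= 2) {
      long double mean[4] = {0.0L, 0.0L, 0.0L, 0.0L};
      long double ss[4] = {0.0L, 0.0L, 0.0L, 0.0L};
      for (size_t s = 0; s < socs.size(); ++s)
        for (size_t fi = 0; fi < socs[s].fams.size(); ++fi) {
          const Fam& f = socs[s].fams[fi];
          mean[0] += f.t1; mean[1] += f.t2; mean[2] += f.p1; mean[3] += f.p2;
        }
      for (int d = 0; d < 4; ++d) mean[d] /= nf;
      for (size_t s = 0; s < socs.size(); ++s)
        for (size_t fi = 0; fi < socs[s].fams.size(); ++fi) {
          const Fam& f = socs[s].fams[fi];
          const double x[4] = {f.t1, f.t2, f.p1, f.p2};
          for (int d = 0; d < 4; ++d) {
            const long double dd = (long double)x[d] - mean[d];
            ss[d] += dd * dd;
          }
        }
      for (int d = 0; d < 4; ++d) vt[d] = (double)(ss[d] / (nf - 1));
    }
    sm_vt1.push_back(vt[0]);
    sm_vt2.push_back(vt[1]);
    sm_vp1.push_back(vt[2]);
    sm_vp2.push_back(vt[3]);
  }

  bool all_extinct() const {
    for (size_t s = 0; s < socs.size(); ++s)
      if (!socs[s].fams.empty()) return false;
    return true;
  }

  void run() {
    if (L > MAXL) Rcpp::stop("unmarried_lifespan larger than supported (8).");
    init();
    for (int n = 1; n <= n_steps; ++n) {
      step = n;
      reproduce();
      marry();
      cull();
      split();
      while (!events.empty() && events.front().step <= n - event_window)
        events.pop_front();
      summarise();
      if (all_extinct()) {
        outcome = "extinct";
        break;
      }
    }
    if (outcome != "extinct") outcome = "completed";
  }
};

}  // namespace

// [[Rcpp::export(name = ".run_engine_cpp")]]
List run_engine_cpp(List params, Nullable<NumericMatrix> init = R_NilValue) {
  Engine eng;
  eng.init_n = 0;
  if (init.isNotNull()) {
    NumericMatrix im(init);
    if (im.ncol() != 4) stop("`init` must have 4 columns (t1, t2, p1, p2).");
    eng.init_n = im.nrow();
    eng.init_tp.resize((size_t)eng.init_n * 4);
    for (int i = 0; i < eng.init_n; ++i)
      for (int d = 0; d < 4; ++d) eng.init_tp[i * 4 + d] = im(i, d);
  }
  eng.d_c = as<double>(params["d_c"]);
  eng.d_m = as<double>(params["d_m"]);
  eng.b = as<double>(params["b"]);
  eng.mu = as<double>(params["mu"]);
  const double tau = as<double>(params["tau"]);
  eng.tau2 = tau * tau;
  eng.N_f = as<int>(params["N_f"]);
  eng.N_s = as<int>(params["N_s"]);
  eng.n_steps = as<int>(params["n_steps"]);
  eng.L = as<int>(params["unmarried_lifespan"]);
  eng.event_window = as<int>(params["event_window"]);
  eng.thr = as<double>(params["split_threshold_factor"]) * (double)eng.N_f;

  GetRNGstate();
  eng.run();
  PutRNGstate();

  // families table
  int nf = 0;
  for (size_t s = 0; s < eng.socs.size(); ++s) nf += (int)eng.socs[s].fams.size();
  IntegerVector f_soc(nf), f_id(nf), f_men(nf), f_wom(nf);
  NumericVector f_t1(nf), f_t2(nf), f_p1(nf), f_p2(nf);
  int k = 0;
  for (size_t s = 0; s < eng.socs.size(); ++s)
    for (size_t fi = 0; fi < eng.socs[s].fams.size(); ++fi, ++k) {
      const Fam& f = eng.socs[s].fams[fi];
      f_soc[k] = eng.socs[s].id;
      f_id[k] = f.id;
      f_t1[k] = f.t1; f_t2[k] = f.t2; f_p1[k] = f.p1; f_p2[k] = f.p2;
      int m = 0, w = 0;
      for (int a = 0; a < eng.L; ++a) { m += f.men[a]; w += f.women[a]; }
      f_men[k] = m;
      f_wom[k] = w;
    }
  DataFrame families = DataFrame::create(
      _["society_id"] = f_soc, _["family_id"] = f_id,
      _["t1"] = f_t1, _["t2"] = f_t2, _["p1"] = f_p1, _["p2"] = f_p2,
      _["n_men"] = f_men, _["n_women"] = f_wom);

  const int ne = (int)eng.events.size();
  IntegerVector e_step(ne), e_soc(ne), e_g(ne), e_b(ne), e_c(ne);
  NumericMatrix gcoord(ne, 4), bcoord(ne, 4), ccoord(ne, 4);
  for (int i = 0; i < ne; ++i) {
    const Ev& ev = eng.events[i];
    e_step[i] = ev.step; e_soc[i] = ev.soc;
    e_g[i] = ev.g; e_b[i] = ev.b; e_c[i] = ev.c;
    for (int d = 0; d < 4; ++d) {
      gcoord(i, d) = ev.gv[d];
      bcoord(i, d) = ev.bv[d];
      ccoord(i, d) = ev.cv[d];
    }
  }
  DataFrame events = DataFrame::create(
      _["step"] = e_step, _["society_id"] = e_soc,
      _["groom_family_id"] = e_g, _["bride_family_id"] = e_b,
      _["child_family_id"] = e_c,
      _["g_t1"] = gcoord(_, 0), _["g_t2"] = gcoord(_, 1),
      _["g_p1"] = gcoord(_, 2), _["g_p2"] = gcoord(_, 3),
      _["b_t1"] = bcoord(_, 0), _["b_t2"] = bcoord(_, 1),
      _["b_p1"] = bcoord(_, 2), _["b_p2"] = bcoord(_, 3),
      _["c_t1"] = ccoord(_, 0), _["c_t2"] = ccoord(_, 1),
      _["c_p1"] = ccoord(_, 2), _["c_p2"] = ccoord(_, 3));

  DataFrame summary = DataFrame::create(
      _["step"] = wrap(eng.sm_step), _["n_families"] = wrap(eng.sm_nfam),
      _["n_societies_alive"] = wrap(eng.sm_alive),
      _["population"] = wrap(eng.sm_pop),
      _["var_t1"] = wrap(eng.sm_vt1), _["var_t2"] = wrap(eng.sm_vt2),
      _["var_p1"] = wrap(eng.sm_vp1), _["var_p2"] = wrap(eng.sm_vp2));

  DataFrame splits = DataFrame::create(
      _["step"] = wrap(eng.sp_step), _["parent_id"] = wrap(eng.sp_parent),
      _["child_id"] = wrap(eng.sp_child),
      _["removed_id"] = wrap(eng.sp_removed));

  return List::create(_["families"] = families, _["events"] = events,
                      _["summary"] = summary, _["splits"] = splits,
                      _["outcome"] = eng.outcome,
                      _["final_step"] = eng.step);
}
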