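// Hot inner loops of the oncosimulator.
//
// A tumour state is a numeric matrix with one column per geometrical cell
// (GC) and one row per cell compartment:
//   rows 0..3   stem G1,S,G2,M
//   row  4      stem G0
//   rows 5+5g .. 5+5g+3   LIMP generation g (0..nl-1) G1,S,G2,M
//   row  5+5g+4           LIMP generation g G0
//   row  5+5nl  terminally differentiated
//   row  5+5nl+1 apoptotic (awaiting clearance)
//   row  5+5nl+2 necrotic  (awaiting clearance)
// All counts are expected values (non-negative doubles).
//
// These routines modify the state matrix IN PLACE; the R wrappers own the
// copy discipline.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct CytoPars {
  int nl;
  double p_ph[4];      // per-hour phase-exit probabilities G1,S,G2,M
  double ra, radiff, rndiff;
  double pg0g1, pg0death;
  double psleep, psym;
  double pa_clear, pn_clear;
  double crowd_thr;
};

static CytoPars parse_pars(const List& par) {
  CytoPars p;
  p.nl = as<int>(par["n_limp"]);
  double tc = as<double>(par["t_cycle"]);
  NumericVector pf = par["phase_frac"];
  for (int k = 0; k < 4; ++k) {
    double d = pf[k] * tc;
    p.p_ph[k] = (d <= 1.0) ? 1.0 : 1.0 / d;
  }
  p.ra = as<double>(par["r_a"]);
  p.radiff = as<double>(par["r_adiff"]);
  p.rndiff = as<double>(par["r_ndiff"]);
  p.pg0g1 = as<double>(par["p_g0g1"]);
  double tg0 = as<double>(par["t_g0"]);
  p.pg0death = (tg0 <= 1.0) ? 1.0 : 1.0 / tg0;
  p.psleep = as<double>(par["p_sleep"]);
  p.psym = as<double>(par["p_sym"]);
  double ta = as<double>(par["t_apoptosis"]);
  p.pa_clear = (ta <= 1.0) ? 1.0 : 1.0 / ta;
  double tn = as<double>(par["t_necrosis"]);
  p.pn_clear = (tn <= 1.0) ? 1.0 : 1.0 / tn;
  p.crowd_thr = as<double>(par["crowd_exit_threshold"]);
  return p;
}

// One expected-value cytokinetic hour for the given columns.
// crowding must be aligned with cols.  Returns per-column mitotic births
// and cleared (removed) dead cells, so callers can audit conservation:
// total_after = total_before + births - cleared.
// [[Rcpp::export]]
List cyto_step_cpp(NumericMatrix S, List par, IntegerVector cols,
                   NumericVector crowding) {
  CytoPars p = parse_pars(par);
  const int nl = p.nl;
  const int dcol = 5 + 5 * nl, acol = dcol + 1, ncol_ = dcol + 2;
  if (S.nrow() != ncol_ + 1)
    stop("state matrix has %d rows but parameters imply %d", S.nrow(), ncol_ + 1);
  const int n = cols.size();
  if (crowding.size() != n) stop("crowding not aligned with cols");
  NumericVector births(n), cleared(n);
  double* base = REAL(S);
  const int nr = S.nrow();

  std::vector<double> snap(5 * (nl + 1));

  for (int ii = 0; ii < n; ++ii) {
    double* v = base + (R_xlen_t)nr * (cols[ii] - 1);
    const double cr = crowding[ii];
    const double ps_eff = p.psleep * cr;
    const bool exit_ok = cr < p.crowd_thr;
    double born = 0.0, gone = 0.0;

    // 1. spontaneous apoptosis of stem and LIMP (all phases incl. G0)
    for (int c = 0; c < 5 + 5 * nl; ++c) {
      double loss = p.ra * v[c];
      v[c] -= loss;
      v[acol] += loss;
    }
    // 2. death of differentiated cells (apoptosis + necrosis)
    {
      double la = p.radiff * v[dcol];
      double ln = p.rndiff * v[dcol];
      double tot = la + ln;
      if (tot > v[dcol] && tot > 0) {  // guard pathological rates
        double s = v[dcol] / tot;
        la *= s; ln *= s;
      }
      v[dcol] -= la + ln;
      v[acol] += la;
      v[ncol_] += ln;
    }
    // 3. dormancy exit (gated by crowding)
    if (exit_ok) {
      for (int g = -1; g < nl; ++g) {
        int b = (g < 0) ? 0 : 5 + 5 * g;
        double e = p.pg0g1 * v[b + 4];
        v[b + 4] -= e;
        v[b] += e;
      }
    }
    // 4. phase advancement + mitosis, flows from a common snapshot
    for (int g = -1; g < nl; ++g) {
      int b = (g < 0) ? 0 : 5 + 5 * g;
      for (int k = 0; k < 4; ++k) snap[(g + 1) * 5 + k] = v[b + k];
    }
    // stem chain
    {
      double f1 = p.p_ph[0] * snap[0], f2 = p.p_ph[1] * snap[1];
      double f3 = p.p_ph[2] * snap[2], m = p.p_ph[3] * snap[3];
      v[0] += -f1;
      v[1] += f1 - f2;
      v[2] += f2 - f3;
      v[3] += f3 - m;
      born += m;  // each mitosis: 1 cell -> 2 daughters
      double stem_d = m * (1.0 + p.psym);       // symmetric: 2, asym: 1
      double limp_d = m * (1.0 - p.psym);       // asym: 1 LIMP gen 0
      v[4] += stem_d * ps_eff;
      v[0] += stem_d * (1.0 - ps_eff);
      if (nl > 0) {
        v[5 + 4] += limp_d * ps_eff;
        v[5] += limp_d * (1.0 - ps_eff);
      } else {
        v[dcol] += limp_d;  // no LIMP ladder: progeny differentiate at once
      }
    }
    // LIMP generations
    for (int g = 0; g < nl; ++g) {
      int b = 5 + 5 * g;
      const double* sg = &snap[(g + 1) * 5];
      double f1 = p.p_ph[0] * sg[0], f2 = p.p_ph[1] * sg[1];
      double f3 = p.p_ph[2] * sg[2], m = p.p_ph[3] * sg[3];
      v[b] += -f1;
      v[b + 1] += f1 - f2;
      v[b + 2] += f2 - f3;
      v[b + 3] += f3 - m;
      born += m;
      double daughters = 2.0 * m;
      if (g + 1 < nl) {
        v[b + 5 + 4] += daughters * ps_eff;
        v[b + 5] += daughters * (1.0 - ps_eff);
      } else {
        v[dcol] += daughters;  // generation nl daughters differentiate
      }
    }
    // 5. dormancy timeout: unrescued G0 cells die through necrosis
    for (int g = -1; g < nl; ++g) {
      int b = (g < 0) ? 0 : 5 + 5 * g;
      double dd = p.pg0death * v[b + 4];
      v[b + 4] -= dd;
      v[ncol_] += dd;
    }
    // 6. clearance of dead pools
    {
      double ca = p.pa_clear * v[acol];
      v[acol] -= ca;
      double cn = p.pn_clear * v[ncol_];
      v[ncol_] -= cn;
      gone = ca + cn;
    }
    births[ii] = born;
    cleared[ii] = gone;
  }
  return List::create(_["births"] = births, _["cleared"] = cleared);
}

// LQ kill applied to the given columns with per-column dose.
// gfac multiplies the quadratic term (1 for acute EBRT fractions, the
// per-pulse increment i*G_i-(i-1)*G_{i-1} for BT pulses).  Dormant (G0)
// compartments are treated as hypoxic: effective dose d/oer.  Stem
// compartments use alpha*stem_sens, beta*stem_sens.  Killed cells move to
// the necrotic pool.
// [[Rcpp::export]]
void irradiate_cpp(NumericMatrix S, IntegerVector cols, NumericVector dose,
                   int n_limp, double alpha, double beta, double gfac,
                   double oer, double stem_sens, bool kill_diff) {
  const int nl = n_limp;
  const int dcol = 5 + 5 * nl, ncol_ = dcol + 2;
  const int nr = S.nrow();
  if (nr != ncol_ + 1) stop("state/n_limp mismatch");
  if (dose.size() != cols.size()) stop("dose not aligned with cols");
  double* base = REAL(S);
  for (int ii = 0; ii < cols.size(); ++ii) {
    double* v = base + (R_xlen_t)nr * (cols[ii] - 1);
    const double d = dose[ii];
    if (d <= 0) continue;
    const double dh = d / oer;
    const double sf_n = std::exp(-(alpha * d + beta * gfac * d * d));
    const double sf_h = std::exp(-(alpha * dh + beta * gfac * dh * dh));
    const double sf_ns = std::exp(-stem_sens * (alpha * d + beta * gfac * d * d));
    const double sf_hs = std::exp(-stem_sens * (alpha * dh + beta * gfac * dh * dh));
    double killed = 0.0;
    for (int k = 0; k < 4; ++k) {  // stem cycling
      double kk = v[k] * (1.0 - sf_ns);
      v[k] -= kk; killed += kk;
    }
    {  // stem G0: hypoxic
      double kk = v[4] * (1.0 - sf_hs);
      v[4] -= kk; killed += kk;
    }
    for (int g = 0; g < nl; ++g) {
      int b = 5 + 5 * g;
      for (int k = 0; k < 4; ++k) {
        double kk = v[b + k] * (1.0 - sf_n);
        v[b + k] -= kk; killed += kk;
      }
      double kk = v[b + 4] * (1.0 - sf_h);
      v[b + 4] -= kk; killed += kk;
    }
    if (kill_diff) {
      double kk = v[dcol] * (1.0 - sf_n);
      v[dcol] -= kk; killed += kk;
    }
    v[ncol_] += killed;
  }
}

// Cisplatin administration: fraction ckr of LIMP and min(1, ckr*stem_sens)
// of stem cells (cycling and dormant) are lethally hit and move to the
// apoptotic pool.  Differentiated cells are unaffected.
// [[Rcpp::export]]
void cisplatin_cpp(NumericMatrix S, IntegerVector cols, int n_limp,
                   double ckr, double stem_sens) {
  const int nl = n_limp;
  const int acol = 5 + 5 * nl + 1;
  const int nr = S.nrow();
  double* base = REAL(S);
  double ckr_stem = std::min(1.0, ckr * stem_sens);
  for (int ii = 0; ii < cols.size(); ++ii) {
    double* v = base + (R_xlen_t)nr * (cols[ii] - 1);
    double hit = 0.0;
    for (int c = 0; c < 5; ++c) {
      double kk = v[c] * ckr_stem;
      v[c] -= kk; hit += kk;
    }
    for (int c = 5; c < 5 + 5 * nl; ++c) {
      double kk = v[c] * ckr;
      v[c] -= kk; hit += kk;
    }
    v[acol] += hit;
  }
}

// Move fraction `frac` of column `from` into column `to` (1-based).
// Conserves every compartment exactly: the amount subtracted is the amount
// added.
// [[Rcpp::export]]
void move_cells_cpp(NumericMatrix S, int from, int to, double frac) {
  const int nr = S.nrow();
  double* a = REAL(S) + (R_xlen_t)nr * (from - 1);
  double* b = REAL(S) + (R_xlen_t)nr * (to - 1);
  if (frac >= 1.0) {
    for (int k = 0; k < nr; ++k) { b[k] += a[k]; a[k] = 0.0; }
  } else {
    for (int k = 0; k < nr; ++k) {
      double amt = a[k] * frac;
      a[k] -= amt;
      b[k] += amt;
    }
  }
}

// Column totals (all compartments) for the given columns.
// [[Rcpp::export]]
NumericVector col_totals_cpp(NumericMatrix S, IntegerVector cols) {
  const int nr = S.nrow();
  double* base = REAL(S);
  NumericVector out(cols.size());
  for (int ii = 0; ii < cols.size(); ++ii) {
    double* v = base + (R_xlen_t)nr * (cols[ii] - 1);
    double s = 0.0;
    for (int k = 0; k < nr; ++k) s += v[k];
    out[ii] = s;
  }
  return out;
}
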