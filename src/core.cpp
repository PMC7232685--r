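#include <Rcpp.h>
using namespace Rcpp;

// All routines assume `time` sorted ascending and `status` in {0,1}.
// Ties between events and censorings at the same time are handled by the
// risk-set definition n_i = #{time >= t_i}: censored subjects remain at
// risk for an event occurring at their own censoring time.

// Kaplan-Meier median: smallest event time t with S(t) <= 0.5.
// Returns NA when the curve never reaches 0.5 (heavy censoring / cure).
// A 1e-9 slack absorbs floating rounding at exact-0.5 steps.
static double km_median_sorted(const double* t, const int* s, int n) {
  if (n == 0) return NA_REAL;
  double S = 1.0;
  int i = 0;
  while (i < n) {
    double ti = t[i];
    int d = 0, j = i;
    while (j < n && t[j] == ti) { d += s[j]; ++j; }
    if (d > 0) {
      S *= 1.0 - (double)d / (double)(n - i);
      if (S <= 0.5 + 1e-9) return ti;
    }
    i = j;
  }
  return NA_REAL;
}

// [[Rcpp::export(name = ".cppKmMedian")]]
double cpp_km_median(NumericVector time, IntegerVector status) {
  return km_median_sorted(time.begin(), status.begin(), time.size());
}

// [[Rcpp::export(name = ".cppKmCurve")]]
List cpp_km_curve(NumericVector time, IntegerVector status) {
  int n = time.size();
  std::vector<double> et, sv;
  std::vector<int> nr, dd;
  double S = 1.0;
  int i = 0;
  while (i < n) {
    double ti = time[i];
    int d = 0, j = i;
    while (j < n && time[j] == ti) { d += status[j]; ++j; }
    if (d > 0) {
      int atrisk = n - i;
      S *= 1.0 - (double)d / (double)atrisk;
      et.push_back(ti); nr.push_back(atrisk); dd.push_back(d); sv.push_back(S);
    }
    i = j;
  }
  return List::create(_["eventTimes"] = et, _["atRisk"] = nr,
                      _["events"] = dd, _["survival"] = sv);
}

// Two-sample log-rank accumulation. group is 0/1; group 1 is "group 1"
// of the statistic (observed d_1i). Event times with n_i == 1 contribute
// V_i = 0. Returns O-E sum, variance sum, and group presence flags.
struct LRAcc { double oe; double var; int n1; int n2; int events; };

static LRAcc logrank_sorted(const double* t, const int* s, const int* g, int n) {
  LRAcc a; a.oe = 0.0; a.var = 0.0; a.n1 = 0; a.n2 = 0; a.events = 0;
  int r1 = 0; // at-risk in group 1, filled below
  for (int i = 0; i < n; ++i) { if (g[i]) ++a.n1; else ++a.n2; }
  r1 = a.n1;
  int i = 0, atrisk = n;
  while (i < n) {
    double ti = t[i];
    int d = 0, d1 = 0, leave1 = 0, j = i;
    while (j < n && t[j] == ti) {
      d += s[j];
      if (g[j]) { d1 += s[j]; ++leave1; }
      ++j;
    }
    if (d > 0) {
      a.events += d;
      double ni = (double)atrisk, n1i = (double)r1;
      a.oe += (double)d1 - (double)d * n1i / ni;
      if (atrisk > 1) {
        double n2i = ni - n1i;
        a.var += (ni - d) * (double)d * n1i * n2i / ((ni - 1.0) * ni * ni);
      }
    }
    atrisk -= (j - i);
    r1 -= leave1;
    i = j;
  }
  return a;
}

// Fast path for the engine: squared log-rank score; 0 when degenerate
// (a group empty, no events, or zero variance).
// [[Rcpp::export(name = ".cppLogrankScore")]]
double cpp_logrank_score(NumericVector time, IntegerVector status,
                         IntegerVector group) {
  LRAcc a = logrank_sorted(time.begin(), status.begin(), group.begin(),
                           time.size());
  if (a.n1 == 0 || a.n2 == 0 || a.events == 0 || a.var <= 0.0) return 0.0;
  double z = a.oe / std::sqrt(a.var);
  return z * z;
}

// Full accumulation for the user-facing wrapper (R assembles per-time table).
// [[Rcpp::export(name = ".cppLogrank")]]
List cpp_logrank(NumericVector time, IntegerVector status, IntegerVector group) {
  LRAcc a = logrank_sorted(time.begin(), status.begin(), group.begin(),
                           time.size());
  return List::create(_["oe"] = a.oe, _["var"] = a.var,
                      _["n1"] = a.n1, _["n2"] = a.n2, _["events"] = a.events);
}

// KM-MDR cell classifier. cell in 0..ncells-1 per subject; tm = overall
// training median. Labels: 1 = HIGH, 0 = LOW. Provenance codes:
// 0 = cell median, 1 = complement rule, 2 = empty cell.
// HIGH iff cell median < tm; if the cell median is not estimable, the
// complement sample's median decides: complement median estimable and > tm
// => HIGH, otherwise LOW.
// [[Rcpp::export(name = ".cppClassifyKm")]]
List cpp_classify_km(NumericVector time, IntegerVector status,
                     IntegerVector cell, int ncells, double tm) {
  int n = time.size();
  IntegerVector labels(ncells, 0), prov(ncells, 2);
  std::vector<int> cnt(ncells, 0);
  for (int i = 0; i < n; ++i) ++cnt[cell[i]];
  std::vector<double> tbuf(n);
  std::vector<int> sbuf(n);
  for (int c = 0; c < ncells; ++c) {
    if (cnt[c] == 0) continue; // empty cell: LOW, provenance 2
    int m = 0;
    for (int i = 0; i < n; ++i)
      if (cell[i] == c) { tbuf[m] = time[i]; sbuf[m] = status[i]; ++m; }
    double med = km_median_sorted(tbuf.data(), sbuf.data(), m);
    if (!ISNAN(med)) {
      labels[c] = (med < tm) ? 1 : 0;
      prov[c] = 0;
    } else {
      // complement sample: everyone outside cell c
      int mc = 0;
      for (int i = 0; i < n; ++i)
        if (cell[i] != c) { tbuf[mc] = time[i]; sbuf[mc] = status[i]; ++mc; }
      double cmed = (mc > 0) ? km_median_sorted(tbuf.data(), sbuf.data(), mc)
                             : NA_REAL;
      labels[c] = (!ISNAN(cmed) && cmed > tm) ? 1 : 0;
      prov[c] = 1;
    }
  }
  return List::create(_["labels"] = labels, _["provenance"] = prov);
}

// Surv-MDR cell classifier: per cell, log-rank of cell membership vs rest;
// HIGH iff Z > 0. Degenerate statistics (empty side, no events, zero
// variance) default LOW. Provenance: 0 = log-rank sign, 2 = empty cell,
// 3 = degenerate statistic.
// [[Rcpp::export(name = ".cppClassifySurv")]]
List cpp_classify_surv(NumericVector time, IntegerVector status,
                       IntegerVector cell, int ncells) {
  int n = time.size();
  IntegerVector labels(ncells, 0), prov(ncells, 2);
  std::vector<int> cnt(ncells, 0);
  for (int i = 0; i < n; ++i) ++cnt[cell[i]];
  std::vector<int> g(n);
  for (int c = 0; c < ncells; ++c) {
    if (cnt[c] == 0 || cnt[c] == n) { if (cnt[c] > 0) prov[c] = 3; continue; }
    for (int i = 0; i < n; ++i) g[i] = (cell[i] == c) ? 1 : 0;
    LRAcc a = logrank_sorted(time.begin(), status.begin(), g.data(), n);
    if (a.events == 0 || a.var <= 0.0) { prov[c] = 3; continue; }
    labels[c] = (a.oe / std::sqrt(a.var) > 0.0) ? 1 : 0;
    prov[c] = 0;
  }
  return List::create(_["labels"] = labels, _["provenance"] = prov);
}
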