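// Hot loops of the group-equivariant layer stack. Feature maps are
// [M, G, C] arrays (voxel-within-batch, group slot, channel), matching the
// R array layout; they are viewed in place as arma::cube through aux
// memory (no copy at the R/C++ boundary — these tensors are tens of MB
// and are exchanged every layer). All index arguments arrive 1-based.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// in-place view of an R array as a cube (no copy, read-only by convention)
static arma::cube view3(const NumericVector& v) {
  IntegerVector d = v.attr("dim");
  if (d.size() == 2) {
    return arma::cube(const_cast<double*>(v.begin()), d[0], d[1], 1, false, true);
  }
  return arma::cube(const_cast<double*>(v.begin()), d[0], d[1], d[2], false, true);
}

// note: arma cube assignment copies, so output views are constructed in
// place at each use site (NumericVector first, then an aux-memory cube)
static NumericVector alloc_arr(arma::uword a, arma::uword b, arma::uword c) {
  NumericVector v(a * b * c);
  v.attr("dim") = IntegerVector::create(a, b, c);
  return v;
}

// out[m, g, co] = bias[co] + sum_{ci, j} x[m, idx[g, j], ci] * W[ci, co, j]
// [[Rcpp::export]]
NumericVector cpp_lift_fwd(const NumericVector& x_, const IntegerMatrix& idx,
                           const arma::cube& W, const arma::vec& bias) {
  const arma::cube x = view3(x_);
  const arma::uword M = x.n_rows, cin = x.n_slices, cout = W.n_cols;
  NumericVector res = alloc_arr(M, 60, cout);
  arma::cube out(res.begin(), M, 60, cout, false, true);
  arma::mat Z(M, 11 * cin);
  arma::mat Wm(11 * cin, cout); // row index j + 11*ci
  for (arma::uword ci = 0; ci < cin; ++ci)
    for (arma::uword co = 0; co < cout; ++co)
      for (arma::uword j = 0; j < 11; ++j)
        Wm(j + 11 * ci, co) = W.at(ci, co, j);
  for (arma::uword g = 0; g < 60; ++g) {
    for (arma::uword ci = 0; ci < cin; ++ci)
      for (arma::uword j = 0; j < 11; ++j)
        Z.col(j + 11 * ci) = x.slice(ci).col(idx(g, j) - 1);
    const arma::mat Y = Z * Wm;
    for (arma::uword co = 0; co < cout; ++co) {
      double* oc = out.slice(co).colptr(g);
      const double* yc = Y.colptr(co);
      const double b = bias.at(co);
      for (arma::uword r = 0; r < M; ++r) oc[r] = yc[r] + b;
    }
  }
  return res;
}

// [[Rcpp::export]]
List cpp_lift_bwd(const NumericVector& x_, const IntegerMatrix& idx,
                  const NumericVector& gout_) {
  const arma::cube x = view3(x_);
  const arma::cube gout = view3(gout_);
  const arma::uword M = x.n_rows, cin = x.n_slices, cout = gout.n_slices;
  arma::vec gb(cout, arma::fill::zeros);
  for (arma::uword co = 0; co < cout; ++co) gb(co) = arma::accu(gout.slice(co));
  arma::mat Z(M, 11 * cin);
  arma::mat Gg(M, cout);
  arma::mat gWm(11 * cin, cout, arma::fill::zeros);
  for (arma::uword g = 0; g < 60; ++g) {
    for (arma::uword ci = 0; ci < cin; ++ci)
      for (arma::uword j = 0; j < 11; ++j)
        Z.col(j + 11 * ci) = x.slice(ci).col(idx(g, j) - 1);
    for (arma::uword co = 0; co < cout; ++co) Gg.col(co) = gout.slice(co).col(g);
    gWm += Z.t() * Gg;
  }
  arma::cube gw(cin, cout, 11);
  for (arma::uword ci = 0; ci < cin; ++ci)
    for (arma::uword co = 0; co < cout; ++co)
      for (arma::uword j = 0; j < 11; ++j)
        gw.at(ci, co, j) = gWm(j + 11 * ci, co);
  return List::create(_["gw"] = gw, _["gb"] = gb);
}

// out[m, g, co] = bias[co] + sum_{ci, k} F[m, perm[g, k], ci] * W[ci, co, k]
// [[Rcpp::export]]
NumericVector cpp_gconv_fwd(const NumericVector& F_, const IntegerMatrix& perm,
                            const arma::cube& W, const arma::vec& bias) {
  const arma::cube F = view3(F_);
  const arma::uword M = F.n_rows, cin = F.n_slices, cout = W.n_cols;
  NumericVector res = alloc_arr(M, 60, cout);
  arma::cube out(res.begin(), M, 60, cout, false, true);
  arma::mat Z(M, 5 * cin);
  arma::mat Wm(5 * cin, cout); // row index k + 5*ci
  for (arma::uword ci = 0; ci < cin; ++ci)
    for (arma::uword co = 0; co < cout; ++co)
      for (arma::uword k = 0; k < 5; ++k)
        Wm(k + 5 * ci, co) = W.at(ci, co, k);
  for (arma::uword g = 0; g < 60; ++g) {
    for (arma::uword ci = 0; ci < cin; ++ci)
      for (arma::uword k = 0; k < 5; ++k)
        Z.col(k + 5 * ci) = F.slice(ci).col(perm(g, k) - 1);
    const arma::mat Y = Z * Wm;
    for (arma::uword co = 0; co < cout; ++co) {
      double* oc = out.slice(co).colptr(g);
      const double* yc = Y.colptr(co);
      const double b = bias.at(co);
      for (arma::uword r = 0; r < M; ++r) oc[r] = yc[r] + b;
    }
  }
  return res;
}

// [[Rcpp::export]]
List cpp_gconv_bwd(const NumericVector& F_, const IntegerMatrix& perm,
                   const arma::cube& W, const NumericVector& gout_,
                   const bool want_gx) {
  const arma::cube F = view3(F_);
  const arma::cube gout = view3(gout_);
  const arma::uword M = F.n_rows, cin = F.n_slices, cout = gout.n_slices;
  arma::vec gb(cout, arma::fill::zeros);
  for (arma::uword co = 0; co < cout; ++co) gb(co) = arma::accu(gout.slice(co));
  NumericVector gx_res;
  if (want_gx) gx_res = alloc_arr(M, 60, cin);
  arma::cube gx(want_gx ? gx_res.begin() : nullptr,
                want_gx ? M : 0, want_gx ? 60 : 0, want_gx ? cin : 0,
                false, true);
  arma::mat Wm(5 * cin, cout);
  for (arma::uword ci = 0; ci < cin; ++ci)
    for (arma::uword co = 0; co < cout; ++co)
      for (arma::uword k = 0; k < 5; ++k)
        Wm(k + 5 * ci, co) = W.at(ci, co, k);
  arma::mat Z(M, 5 * cin);
  arma::mat Gg(M, cout);
  arma::mat gWm(5 * cin, cout, arma::fill::zeros);
  for (arma::uword g = 0; g < 60; ++g) {
    for (arma::uword ci = 0; ci < cin; ++ci)
      for (arma::uword k = 0; k < 5; ++k)
        Z.col(k + 5 * ci) = F.slice(ci).col(perm(g, k) - 1);
    for (arma::uword co = 0; co < cout; ++co) Gg.col(co) = gout.slice(co).col(g);
    gWm += Z.t() * Gg;
    if (want_gx) {
      const arma::mat Gz = Gg * Wm.t(); // [M, 5*cin]
      for (arma::uword ci = 0; ci < cin; ++ci)
        for (arma::uword k = 0; k < 5; ++k)
          gx.slice(ci).col(perm(g, k) - 1) += Gz.col(k + 5 * ci);
    }
  }
  arma::cube gw(cin, cout, 5);
  for (arma::uword ci = 0; ci < cin; ++ci)
    for (arma::uword co = 0; co < cout; ++co)
      for (arma::uword k = 0; k < 5; ++k)
        gw.at(ci, co, k) = gWm(k + 5 * ci, co);
  if (want_gx) return List::create(_["gx"] = gx_res, _["gw"] = gw, _["gb"] = gb);
  return List::create(_["gw"] = gw, _["gb"] = gb);
}

// valid 3^3 correlation per group slot. rows: [m_out, 27] input-row index
// per output row and offset. Wm: [27*cin, cout, n_rot] im2col weights
// (row index t + 27*ci); rotidx: per-slot 1-based slice of Wm.
// [[Rcpp::export]]
NumericVector cpp_spatial_fwd(const NumericVector& F_, const IntegerMatrix& rows,
                              const arma::cube& Wm, const IntegerVector& rotidx,
                              const arma::vec& bias) {
  const arma::cube F = view3(F_);
  const arma::uword G = F.n_cols, cin = F.n_slices;
  const arma::uword m_out = rows.nrow(), cout = Wm.n_cols;
  NumericVector res = alloc_arr(m_out, G, cout);
  arma::cube out(res.begin(), m_out, G, cout, false, true);
  arma::mat Z(m_out, 27 * cin);
  for (arma::uword g = 0; g < G; ++g) {
    for (arma::uword ci = 0; ci < cin; ++ci) {
      const double* fc = F.slice(ci).colptr(g);
      for (arma::uword t = 0; t < 27; ++t) {
        double* zc = Z.colptr(t + 27 * ci);
        const int* rr = &rows(0, t);
        for (arma::uword r = 0; r < m_out; ++r) zc[r] = fc[rr[r] - 1];
      }
    }
    const arma::mat Y = Z * Wm.slice(rotidx[g] - 1);
    for (arma::uword co = 0; co < cout; ++co) {
      double* oc = out.slice(co).colptr(g);
      const double* yc = Y.colptr(co);
      const double b = bias.at(co);
      for (arma::uword r = 0; r < m_out; ++r) oc[r] = yc[r] + b;
    }
  }
  return res;
}

// [[Rcpp::export]]
List cpp_spatial_bwd(const NumericVector& F_, const IntegerMatrix& rows,
                     const arma::cube& Wm, const IntegerVector& rotidx,
                     const NumericVector& gout_, const bool want_gx) {
  const arma::cube F = view3(F_);
  const arma::cube gout = view3(gout_);
  const arma::uword G = F.n_cols, cin = F.n_slices;
  const arma::uword m_out = rows.nrow(), cout = gout.n_slices;
  const arma::uword n_rot = Wm.n_slices;
  arma::cube gWm(27 * cin, cout, n_rot, arma::fill::zeros);
  arma::vec gb(cout, arma::fill::zeros);
  for (arma::uword co = 0; co < cout; ++co) gb(co) = arma::accu(gout.slice(co));
  NumericVector gx_res;
  if (want_gx) gx_res = alloc_arr(F.n_rows, G, cin);
  arma::cube gx(want_gx ? gx_res.begin() : nullptr,
                want_gx ? F.n_rows : 0, want_gx ? G : 0, want_gx ? cin : 0,
                false, true);
  arma::mat Z(m_out, 27 * cin);
  arma::mat Gg(m_out, cout);
  for (arma::uword g = 0; g < G; ++g) {
    for (arma::uword ci = 0; ci < cin; ++ci) {
      const double* fc = F.slice(ci).colptr(g);
      for (arma::uword t = 0; t < 27; ++t) {
        double* zc = Z.colptr(t + 27 * ci);
        const int* rr = &rows(0, t);
        for (arma::uword r = 0; r < m_out; ++r) zc[r] = fc[rr[r] - 1];
      }
    }
    for (arma::uword co = 0; co < cout; ++co) Gg.col(co) = gout.slice(co).col(g);
    const arma::uword rs = rotidx[g] - 1;
    gWm.slice(rs) += Z.t() * Gg;
    if (want_gx) {
      const arma::mat Gz = Gg * Wm.slice(rs).t(); // [m_out, 27*cin]
      for (arma::uword ci = 0; ci < cin; ++ci) {
        double* gc = gx.slice(ci).colptr(g);
        for (arma::uword t = 0; t < 27; ++t) {
          const double* gzc = Gz.colptr(t + 27 * ci);
          const int* rr = &rows(0, t);
          for (arma::uword r = 0; r < m_out; ++r) gc[rr[r] - 1] += gzc[r];
        }
      }
    }
  }
  if (want_gx) return List::create(_["gx"] = gx_res, _["gWm"] = gWm, _["gb"] = gb);
  return List::create(_["gWm"] = gWm, _["gb"] = gb);
}

// elementwise ReLU; the output doubles as the backward mask (y > 0)
// [[Rcpp::export]]
NumericVector cpp_relu(const NumericVector& x) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const double* src = x.begin();
  double* dst = out.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) dst[i] = src[i] > 0 ? src[i] : 0.0;
  return out;
}

// masked gradient: g where y > 0, else 0
// [[Rcpp::export]]
NumericVector cpp_relu_bwd(const NumericVector& y, const NumericVector& g) {
  NumericVector out(g.size());
  out.attr("dim") = y.attr("dim");
  const double* yy = y.begin();
  const double* gg = g.begin();
  double* dst = out.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i) dst[i] = yy[i] > 0 ? gg[i] : 0.0;
  return out;
}
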