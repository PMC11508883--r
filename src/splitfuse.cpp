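// Matrix-free core of the split-variable CDP phase-retrieval solver.
//
// All operators act through the (unnormalized) DFT: for a mask diagonal
// w_j and real vector v, z_j = FFT(w_j . v).  The bilinear measurement
// operator anchored at `a` maps v to Re(Z_a . conj(Z_v)) entrywise, and
// its adjoint maps an N x K real matrix r to
//   Re( sum_j conj(w_j) . F^H (r_j . z_{a,j}) ).
// 2-D signals (w > 1) use the 2-D DFT.  FFTW plans are created once per
// solve and reused across all iterations; a CG iteration costs 2K FFTs.

#include <RcppArmadillo.h>
#include <fftw3.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Paired forward/backward DFT plans for one signal geometry.  Data are
// column-major; fftw_plan_dft_2d takes row-major dimensions, so the axes
// are swapped (the DFT of the transpose is the transpose of the DFT).
class Dft {
public:
  Dft(int h, int w) : N_(h * w) {
    buf_in_ = static_cast<fftw_complex*>(fftw_malloc(sizeof(fftw_complex) * N_));
    buf_out_ = static_cast<fftw_complex*>(fftw_malloc(sizeof(fftw_complex) * N_));
    unsigned flags = FFTW_ESTIMATE | FFTW_UNALIGNED;
    if (w > 1) {
      fwd_ = fftw_plan_dft_2d(w, h, buf_in_, buf_out_, FFTW_FORWARD, flags);
      bwd_ = fftw_plan_dft_2d(w, h, buf_in_, buf_out_, FFTW_BACKWARD, flags);
    } else {
      fwd_ = fftw_plan_dft_1d(N_, buf_in_, buf_out_, FFTW_FORWARD, flags);
      bwd_ = fftw_plan_dft_1d(N_, buf_in_, buf_out_, FFTW_BACKWARD, flags);
    }
  }
  ~Dft() {
    fftw_destroy_plan(fwd_);
    fftw_destroy_plan(bwd_);
    fftw_free(buf_in_);
    fftw_free(buf_out_);
  }
  // y = F x (unnormalized forward DFT)
  void forward(const cx_vec& x, cx_vec& y) const {
    fftw_execute_dft(fwd_, cast(x), cast(y));
  }
  // y = F^H x (unnormalized conjugate-transpose DFT)
  void backwardH(const cx_vec& x, cx_vec& y) const {
    fftw_execute_dft(bwd_, cast(x), cast(y));
  }
private:
  static fftw_complex* cast(const cx_vec& v) {
    return reinterpret_cast<fftw_complex*>(const_cast<cx_double*>(v.memptr()));
  }
  int N_;
  fftw_complex* buf_in_;
  fftw_complex* buf_out_;
  fftw_plan fwd_, bwd_;
};

static cx_mat masked_spectra(const Dft& dft, const vec& v, const cx_mat& masks) {
  const uword N = v.n_elem, K = masks.n_cols;
  cx_mat Z(N, K);
  cx_vec cv = conv_to<cx_vec>::from(v);
  cx_vec mv(N), z(N);
  for (uword j = 0; j < K; ++j) {
    mv = masks.col(j) % cv;
    dft.forward(mv, z);
    Z.col(j) = z;
  }
  return Z;
}

// (H_a v)(i, j) = Re(z_{a,ij} * conj(z_{v,ij}))
static mat apply_forward(const Dft& dft, const cx_mat& Za, const cx_mat& masks,
                         const vec& v) {
  cx_mat Zv = masked_spectra(dft, v, masks);
  return real(Za % conj(Zv));
}

// H_a^T r = Re( sum_j conj(w_j) . F^H (r_j . z_{a,j}) )
static vec apply_adjoint(const Dft& dft, const cx_mat& Za, const cx_mat& masks,
                         const mat& r) {
  const uword N = Za.n_rows, K = Za.n_cols;
  cx_vec acc(N, fill::zeros), u(N), t(N);
  for (uword j = 0; j < K; ++j) {
    u = conv_to<cx_vec>::from(r.col(j)) % Za.col(j);
    dft.backwardH(u, t);
    acc += conj(masks.col(j)) % t;
  }
  return real(acc);
}

static vec normal_op(const Dft& dft, const cx_mat& Za, const cx_mat& masks,
                     const vec& v) {
  return apply_adjoint(dft, Za, masks, apply_forward(dft, Za, masks, v));
}

// CG on the normal equations (H_a^T H_a) b = rhs, relative residual tol.
static vec cg_normal(const Dft& dft, const cx_mat& Za, const cx_mat& masks,
                     const vec& rhs, const vec& x0, double tol, int maxit) {
  const double rhs_norm = norm(rhs);
  if (rhs_norm == 0.0) return zeros<vec>(rhs.n_elem);
  vec x = x0;
  vec r = rhs - normal_op(dft, Za, masks, x);
  vec p = r;
  double rs = dot(r, r);
  for (int it = 0; it < maxit; ++it) {
    if (std::sqrt(rs) <= tol * rhs_norm) break;
    vec Ap = normal_op(dft, Za, masks, p);
    double pAp = dot(p, Ap);
    if (!std::isfinite(pAp)) Rcpp::stop("conjugate gradient breakdown: non-finite curvature");
    if (pAp <= 0.0) break;  // numerically singular direction
    double alpha = rs / pAp;
    x += alpha * p;
    r -= alpha * Ap;
    double rs_new = dot(r, r);
    if (!std::isfinite(rs_new)) Rcpp::stop("conjugate gradient breakdown: non-finite residual");
    p = r + (rs_new / rs) * p;
    rs = rs_new;
  }
  return x;
}

static double sign_invariant_err(const vec& a, const vec& xt, double xnorm) {
  return std::min(norm(a - xt), norm(a + xt)) / xnorm;
}

// [[Rcpp::export(name = ".cpp_half_step")]]
arma::vec cpp_half_step(const arma::mat& Y, const arma::cx_mat& masks,
                        const arma::vec& anchor, const arma::vec& warm,
                        double cg_tol, int cg_max, int h, int w) {
  if (norm(anchor) == 0.0)
    Rcpp::stop("degenerate operator: the anchor vector is identically zero");
  Dft dft(h, w);
  cx_mat Za = masked_spectra(dft, anchor, masks);
  vec rhs = apply_adjoint(dft, Za, masks, Y);
  return cg_normal(dft, Za, masks, rhs, warm, cg_tol, cg_max);
}

// [[Rcpp::export(name = ".cpp_split_solve")]]
Rcpp::List cpp_split_solve(const arma::mat& Y, const arma::cx_mat& masks,
                           const arma::vec& init, double tol, int max_outer,
                           double cg_tol, int cg_max, bool warm_start,
                           bool do_recombine,
                           Rcpp::Nullable<Rcpp::NumericVector> truth,
                           int h, int w) {
  Dft dft(h, w);
  vec a = init, b = init;
  bool have_truth = truth.isNotNull();
  vec xt;
  double xnorm = 0.0;
  if (have_truth) {
    xt = Rcpp::as<vec>(truth.get());
    xnorm = norm(xt);
  }
  std::vector<double> err_trace, delta_trace;
  bool converged = false;
  int n = 0;
  for (n = 1; n <= max_outer; ++n) {
    if (norm(a) == 0.0)
      Rcpp::stop("degenerate operator: the current estimate collapsed to zero");
    cx_mat Za = masked_spectra(dft, a, masks);
    vec rhs = apply_adjoint(dft, Za, masks, Y);
    b = cg_normal(dft, Za, masks, rhs, warm_start ? b : a, cg_tol, cg_max);
    vec a_new;
    if (do_recombine) {
      a_new = 0.5 * (a + b);
    } else {
      // pure alternation (no fusing): second half-step anchored at b
      if (norm(b) == 0.0)
        Rcpp::stop("degenerate operator: the current estimate collapsed to zero");
      cx_mat Zb = masked_spectra(dft, b, masks);
      vec rhs2 = apply_adjoint(dft, Zb, masks, Y);
      a_new = cg_normal(dft, Zb, masks, rhs2, warm_start ? a : b, cg_tol, cg_max);
    }
    double an = norm(a_new);
    double delta = (an > 0.0) ? norm(a_new - a) / an : norm(a_new - a);
    a = a_new;
    if (do_recombine) b = a;
    delta_trace.push_back(delta);
    if (have_truth) err_trace.push_back(sign_invariant_err(a, xt, xnorm));
    if (delta < tol) { converged = true; break; }
  }
  if (n > max_outer) n = max_outer;
  return Rcpp::List::create(
      Rcpp::Named("xhat") = a,
      Rcpp::Named("n_iters") = n,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("err_trace") = err_trace,
      Rcpp::Named("delta_trace") = delta_trace);
}
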