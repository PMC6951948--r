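#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Matrix exponential (scaling-and-squaring), used for transition
// probabilities A(delta) = expm(delta * Q).
// [[Rcpp::export]]
arma::mat expm_cpp(const arma::mat& X) {
  return expmat(X);
}

// Endpoint-conditioned expected sojourn times and transition counts for a
// CTMC observed only at the two ends of an interval of length delta.
//
// Uses the auxiliary block-matrix construction: for a one-hot matrix B,
//   expm(delta * [[Q, B], [0, Q]])
// has top-right block  int_0^delta expm(sQ) B expm((delta-s)Q) ds.
// With B = e_k e_k' the (i,j) entry of that block, divided by A(delta)(i,j),
// is E[time in k | S(0)=i, S(delta)=j]; with B = e_k e_l' and a factor
// Q(k,l) it is E[#jumps k->l | S(0)=i, S(delta)=j].
//
// `pairs` holds 0-based (k,l) index pairs for which transition counts are
// requested (normally the entries with Q(k,l) > 0).
// Returns A = expm(delta*Q), ER as an M x M x M cube (i, j, k), and EN as an
// M x M x P cube whose slice p corresponds to pairs(p, ).
// [[Rcpp::export]]
Rcpp::List cond_expect_cpp(const arma::mat& Q, double delta,
                           const arma::umat& pairs) {
  const uword M = Q.n_rows;
  const uword P = pairs.n_rows;
  mat A = expmat(delta * Q);

  cube ER(M, M, M, fill::zeros);
  cube EN(M, M, P, fill::zeros);

  mat G(2 * M, 2 * M, fill::zeros);
  G.submat(0, 0, M - 1, M - 1) = Q;
  G.submat(M, M, 2 * M - 1, 2 * M - 1) = Q;

  for (uword k = 0; k < M; ++k) {
    G.submat(0, M, M - 1, 2 * M - 1).zeros();
    G(k, M + k) = 1.0;
    mat E = expmat(delta * G);
    mat U = E.submat(0, M, M - 1, 2 * M - 1);
    for (uword j = 0; j < M; ++j)
      for (uword i = 0; i < M; ++i)
        ER(i, j, k) = (A(i, j) > 0.0) ? U(i, j) / A(i, j) : 0.0;
  }

  for (uword p = 0; p < P; ++p) {
    const uword k = pairs(p, 0);
    const uword l = pairs(p, 1);
    G.submat(0, M, M - 1, 2 * M - 1).zeros();
    G(k, M + l) = 1.0;
    mat E = expmat(delta * G);
    mat U = E.submat(0, M, M - 1, 2 * M - 1);
    for (uword j = 0; j < M; ++j)
      for (uword i = 0; i < M; ++i)
        EN(i, j, p) = (A(i, j) > 0.0) ? Q(k, l) * U(i, j) / A(i, j) : 0.0;
  }

  // the exponential can leave tiny negative round-off in entries that are
  // mathematically zero
  ER.clamp(0.0, datum::inf);
  EN.clamp(0.0, datum::inf);

  return Rcpp::List::create(Rcpp::Named("A") = A,
                            Rcpp::Named("ER") = ER,
                            Rcpp::Named("EN") = EN);
}

namespace {

// per-interval endpoint-conditioned expectations, cached by gap length
struct CondExpect {
  mat A;
  mat ER;   // (M*M) x M,        rows index endpoint pair (i,j) col-major
  mat EN;   // (M*M) x n_pairs
};

CondExpect make_cond_expect(const mat& Q, double delta, const umat& pairs) {
  const uword M = Q.n_rows;
  const uword P = pairs.n_rows;
  CondExpect ce;
  ce.A = expmat(delta * Q);
  ce.ER.set_size(M * M, M);
  ce.EN.set_size(M * M, P);
  mat G(2 * M, 2 * M, fill::zeros);
  G.submat(0, 0, M - 1, M - 1) = Q;
  G.submat(M, M, 2 * M - 1, 2 * M - 1) = Q;
  for (uword k = 0; k < M; ++k) {
    G.submat(0, M, M - 1, 2 * M - 1).zeros();
    G(k, M + k) = 1.0;
    mat E = expmat(delta * G);
    mat U = E.submat(0, M, M - 1, 2 * M - 1);
    for (uword j = 0; j < M; ++j)
      for (uword i = 0; i < M; ++i)
        ce.ER(j * M + i, k) =
          (ce.A(i, j) > 0.0) ? std::max(U(i, j) / ce.A(i, j), 0.0) : 0.0;
  }
  for (uword p = 0; p < P; ++p) {
    const uword k = pairs(p, 0);
    const uword l = pairs(p, 1);
    G.submat(0, M, M - 1, 2 * M - 1).zeros();
    G(k, M + l) = 1.0;
    mat E = expmat(delta * G);
    mat U = E.submat(0, M, M - 1, 2 * M - 1);
    for (uword j = 0; j < M; ++j)
      for (uword i = 0; i < M; ++i)
        ce.EN(j * M + i, p) =
          (ce.A(i, j) > 0.0)
            ? std::max(Q(k, l) * U(i, j) / ce.A(i, j), 0.0) : 0.0;
  }
  return ce;
}

} // namespace

// Full E-step over a cohort: scaled forward-backward per patient with
// interval-specific transition matrices, accumulation of expected
// transition counts / sojourn times through cached endpoint-conditioned
// expectations, posterior-weighted emission moments, first-visit
// posteriors and the total observed-data log-likelihood.
//
// The cohort arrives flattened: `times` and `obs` are the concatenated
// visit times / feature rows, `offsets` (0-based) and `lens` delimit each
// patient. Gaps are canonicalized to 1e-6 years for the expectation cache.
// [[Rcpp::export]]
Rcpp::List estep_cohort_cpp(const arma::mat& Q, const arma::vec& pi,
                            const arma::mat& means, const arma::mat& vars,
                            const arma::umat& pairs,
                            const arma::vec& times, const arma::mat& obs,
                            const arma::uvec& offsets,
                            const arma::uvec& lens) {
  const uword M = Q.n_rows;
  const uword K = means.n_cols;
  const uword N = offsets.n_elem;
  const uword P = pairs.n_rows;

  mat exp_N(M, M, fill::zeros);
  vec exp_R(M, fill::zeros);
  vec moment0(M, fill::zeros);
  mat moment1(M, K, fill::zeros);
  mat moment2(M, K, fill::zeros);
  mat first_gamma(N, M, fill::zeros);
  double loglik = 0.0;

  // emission constants: -0.5 * log(2*pi*sigma^2)
  mat lognorm = -0.5 * log(2.0 * datum::pi * vars);
  mat inv2v = 0.5 / vars;

  std::map<long long, CondExpect> ce_cache;
  std::map<long long, mat> a_cache;

  for (uword n = 0; n < N; ++n) {
    const uword o = offsets(n);
    const uword Tn = lens(n);

    // emission log-densities, Tn x M
    mat logb(Tn, M);
    for (uword m = 0; m < M; ++m) {
      for (uword t = 0; t < Tn; ++t) {
        double s = 0.0;
        for (uword k = 0; k < K; ++k) {
          const double d = obs(o + t, k) - means(m, k);
          s += lognorm(m, k) - d * d * inv2v(m, k);
        }
        logb(t, m) = s;
      }
    }
    vec bmax = max(logb, 1);
    mat b = exp(logb.each_col() - bmax);

    // interval transition matrices (cached by rounded gap)
    std::vector<const mat*> Amats(Tn > 0 ? Tn - 1 : 0);
    std::vector<long long> gap_keys(Tn > 0 ? Tn - 1 : 0);
    for (uword t = 0; t + 1 < Tn; ++t) {
      const double gap = times(o + t + 1) - times(o + t);
      const long long key = llround(gap * 1e6);
      gap_keys[t] = key;
      auto it = a_cache.find(key);
      if (it == a_cache.end()) {
        it = a_cache.emplace(key,
                             mat(expmat((key / 1e6) * Q))).first;
      }
      Amats[t] = &it->second;
    }

    // scaled forward pass
    mat alpha(Tn, M);
    vec cvec(Tn);
    rowvec a = pi.t() % b.row(0);
    cvec(0) = accu(a);
    if (!(cvec(0) > 0)) Rcpp::stop("zero likelihood at a first visit");
    alpha.row(0) = a / cvec(0);
    for (uword t = 1; t < Tn; ++t) {
      a = (alpha.row(t - 1) * (*Amats[t - 1])) % b.row(t);
      cvec(t) = accu(a);
      if (!(cvec(t) > 0)) Rcpp::stop("zero likelihood within a series");
      alpha.row(t) = a / cvec(t);
    }
    loglik += accu(log(cvec)) + accu(bmax);

    // scaled backward pass
    mat beta(Tn, M, fill::zeros);
    beta.row(Tn - 1).ones();
    for (uword t = Tn - 1; t-- > 0; ) {
      beta.row(t) = ((*Amats[t]) *
                     (b.row(t + 1) % beta.row(t + 1)).t()).t() / cvec(t + 1);
    }

    mat gamma = alpha % beta;
    gamma.each_col() /= sum(gamma, 1);
    first_gamma.row(n) = gamma.row(0);
    moment0 += sum(gamma, 0).t();
    moment1 += gamma.t() * obs.rows(o, o + Tn - 1);
    moment2 += gamma.t() * square(obs.rows(o, o + Tn - 1));

    if (Tn < 2 || P == 0) continue;

    for (uword t = 1; t < Tn; ++t) {
      mat xi = (alpha.row(t - 1).t() * (b.row(t) % beta.row(t))) %
               (*Amats[t - 1]);
      xi /= accu(xi);
      const long long key = gap_keys[t - 1];
      auto it = ce_cache.find(key);
      if (it == ce_cache.end()) {
        it = ce_cache.emplace(key,
                              make_cond_expect(Q, key / 1e6, pairs)).first;
      }
      const CondExpect& ce = it->second;
      const vec w = vectorise(xi);            // (i,j) column-major
      exp_R += ce.ER.t() * w;
      const vec en = ce.EN.t() * w;
      for (uword p = 0; p < P; ++p) {
        exp_N(pairs(p, 0), pairs(p, 1)) += en(p);
      }
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("exp_N") = exp_N,
    Rcpp::Named("exp_R") = exp_R,
    Rcpp::Named("first_visit_gamma") = first_gamma,
    Rcpp::Named("moment0") = moment0,
    Rcpp::Named("moment1") = moment1,
    Rcpp::Named("moment2") = moment2,
    Rcpp::Named("loglik") = loglik);
}
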