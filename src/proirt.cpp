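#define TMB_LIB_INIT R_init_proirt
#include <TMB.hpp>

// Graded response model category log-probability.
// lin:   discrimination-weighted latent value, sum_d a_d * psi_d
// B:     ordered intercepts, P(Y >= k) = invlogit(lin - B_{k-1}), k = 1..X
// Floor keeps log finite when a category probability underflows.
template <class Type>
Type grm_logprob(const Type &lin, const vector<Type> &B, int y) {
  int X = B.size();
  Type p;
  if (y == 0)
    p = Type(1) - invlogit(lin - B(0));
  else if (y == X)
    p = invlogit(lin - B(X - 1));
  else
    p = invlogit(lin - B(y - 1)) - invlogit(lin - B(y));
  return log(p + Type(1e-12));
}

// Assemble per-item ordered intercepts from (B1, positive log-increments).
template <class Type>
vector<vector<Type> > build_B(const vector<int> &ncat,
                              const vector<Type> &B1,
                              const vector<Type> &log_dB) {
  int J = ncat.size();
  vector<vector<Type> > B(J);
  int off = 0;
  for (int j = 0; j < J; j++) {
    int X = ncat[j] - 1;
    vector<Type> Bj(X);
    Bj(0) = B1(j);
    for (int k = 1; k < X; k++) {
      Bj(k) = Bj(k - 1) + exp(log_dB(off));
      off++;
    }
    B(j) = Bj;
  }
  return B;
}

template <class Type>
Type objective_function<Type>::operator()() {
  DATA_INTEGER(model); // 1 = pooled ICC stage, 2 = longitudinal stage
  DATA_INTEGER(m);     // number of latent dimensions

  // Item structure (shared by both models)
  DATA_IVECTOR(ncat);     // categories per item (X + 1)
  DATA_IVECTOR(load_n);   // loadings per item
  DATA_IVECTOR(load_dim); // concatenated 0-based dimension indices

  DATA_IVECTOR(obs_unit); // subject-visit (model 1) or subject (model 2)
  DATA_IVECTOR(obs_item);
  DATA_IVECTOR(obs_y);

  PARAMETER_VECTOR(log_a); // one per loading, item-major
  PARAMETER_VECTOR(B1);
  PARAMETER_VECTOR(log_dB);

  int J = ncat.size();
  vector<Type> a = exp(log_a);
  vector<vector<Type> > B = build_B(ncat, B1, log_dB);

  // item-major offsets into (log_a, load_dim)
  vector<int> aoff(J);
  {
    int s = 0;
    for (int j = 0; j < J; j++) { aoff[j] = s; s += load_n[j]; }
  }

  Type nll = 0;

  if (model == 1) {
    // Pooled ICC estimation: every subject-visit has an independent latent
    // vector; baseline fixed N(0, I), post-baseline N(mu, diag(sd^2)).
    // Marginal likelihood by Gauss-Hermite quadrature on the prior scale.
    DATA_MATRIX(zg);      // G x m standard-normal node coordinates
    DATA_VECTOR(logwg);   // G log quadrature weights (sum exp = 1)
    DATA_IVECTOR(sv_post); // n_sv, 0 = baseline visit, 1 = post-baseline
    PARAMETER_VECTOR(post_mu);     // m
    PARAMETER_VECTOR(log_post_sd); // m

    int G = zg.rows();
    int n_sv = sv_post.size();
    vector<Type> post_sd = exp(log_post_sd);

    // Per item, per visit type: G x ncat log-probability tables
    vector<matrix<Type> > lp0(J), lp1(J);
    for (int j = 0; j < J; j++) {
      matrix<Type> t0(G, ncat[j]), t1(G, ncat[j]);
      for (int g = 0; g < G; g++) {
        Type lin0 = 0, lin1 = 0;
        for (int l = 0; l < load_n[j]; l++) {
          int d = load_dim[aoff[j] + l];
          lin0 += a(aoff[j] + l) * zg(g, d);
          lin1 += a(aoff[j] + l) * (post_mu(d) + post_sd(d) * zg(g, d));
        }
        for (int y = 0; y < ncat[j]; y++) {
          t0(g, y) = grm_logprob(lin0, B[j], y);
          t1(g, y) = grm_logprob(lin1, B[j], y);
        }
      }
      lp0(j) = t0;
      lp1(j) = t1;
    }

    matrix<Type> M(n_sv, G);
    for (int s = 0; s < n_sv; s++)
      for (int g = 0; g < G; g++) M(s, g) = logwg(g);
    int n_obs = obs_unit.size();
    for (int i = 0; i < n_obs; i++) {
      int s = obs_unit[i], j = obs_item[i], y = obs_y[i];
      const matrix<Type> &lp = sv_post[s] ? lp1(j) : lp0(j);
      for (int g = 0; g < G; g++) M(s, g) += lp(g, y);
    }
    for (int s = 0; s < n_sv; s++) {
      Type mx = M(s, 0);
      for (int g = 1; g < G; g++) mx = CppAD::CondExpGt(M(s, g), mx, M(s, g), mx);
      Type acc = 0;
      for (int g = 0; g < G; g++) acc += exp(M(s, g) - mx);
      nll -= mx + log(acc);
    }

    vector<Type> post_var = post_sd * post_sd;
    ADREPORT(a);
    ADREPORT(post_mu);
    ADREPORT(post_var);
    // thresholds on the latent scale for single-loading items: b = B / a
    int nB = B1.size() + log_dB.size();
    vector<Type> bflat(nB);
    {
      int s = 0;
      for (int j = 0; j < J; j++)
        for (int k = 0; k < ncat[j] - 1; k++) {
          bflat(s) = (load_n[j] == 1) ? B[j](k) / a(aoff[j]) : B[j](k);
          s++;
        }
    }
    ADREPORT(bflat);
  } else {
    // Longitudinal stage: per-subject random effects on Baseline (one per
    // dimension), Pmax, Drift, log Tprog; Laplace integration via TMB.
    DATA_VECTOR(obs_time);
    DATA_IVECTOR(obs_post); // 1 if the observation is post-dose (time > 0)
    DATA_IVECTOR(trt);    // n_subj, 1 if dose > 0
    DATA_MATRIX(zcov);    // n_subj x n_cov, centered covariates
    DATA_IVECTOR(cov_target); // 0 baseline, 1 pmax, 2 drug
    DATA_IVECTOR(cov_form);   // 0 additive, 1 multiplicative
    DATA_IVECTOR(cov_dim);    // 0-based dimension the effect acts on
    DATA_INTEGER(no_re);      // 1 = pure fixed-effects likelihood
    DATA_IMATRIX(Lmask);      // n_re x n_re strict lower-tri free pattern

    PARAMETER_VECTOR(base);      // m
    PARAMETER_VECTOR(pmax);      // m
    PARAMETER_VECTOR(log_tprog); // m
    PARAMETER_VECTOR(drug);      // m
    PARAMETER(drift);
    PARAMETER(log_wei);
    PARAMETER_VECTOR(cov_coef);
    PARAMETER_VECTOR(log_sd); // n_re: base_1..m, pmax, drift, log tprog
    PARAMETER_VECTOR(ltheta); // free Cholesky entries per Lmask
    PARAMETER_MATRIX(eta);    // n_subj x n_re (random)

    int n_subj = trt.size();
    int n_re = m + 3;
    Type wei = exp(log_wei);
    Type ln2 = log(Type(2));

    // Correlation via row-normalized unit lower-triangular factor; zeros in
    // Lmask give exact zero correlations while keeping the matrix PSD.
    matrix<Type> L(n_re, n_re);
    L.setZero();
    {
      int s = 0;
      for (int i = 0; i < n_re; i++) {
        L(i, i) = 1;
        for (int jj = 0; jj < i; jj++)
          if (Lmask(i, jj)) { L(i, jj) = ltheta(s); s++; }
        Type nrm = 0;
        for (int jj = 0; jj <= i; jj++) nrm += L(i, jj) * L(i, jj);
        nrm = sqrt(nrm);
        for (int jj = 0; jj <= i; jj++) L(i, jj) /= nrm;
      }
    }
    matrix<Type> C = L * L.transpose();
    vector<Type> sd = exp(log_sd);
    matrix<Type> Sigma(n_re, n_re);
    for (int i = 0; i < n_re; i++)
      for (int jj = 0; jj < n_re; jj++) Sigma(i, jj) = C(i, jj) * sd(i) * sd(jj);

    if (!no_re) {
      density::MVNORM_t<Type> dmvn(Sigma);
      for (int i = 0; i < n_subj; i++) {
        vector<Type> ei = eta.row(i);
        nll += dmvn(ei);
      }
    }

    int n_obs = obs_unit.size();
    for (int o = 0; o < n_obs; o++) {
      int i = obs_unit[o], j = obs_item[o], y = obs_y[o];
      Type t = obs_time(o);
      Type lin = 0;
      for (int l = 0; l < load_n[j]; l++) {
        int d = load_dim[aoff[j] + l];
        Type e_base = no_re ? Type(0) : eta(i, d);
        Type e_pmax = no_re ? Type(0) : eta(i, m);
        Type e_drift = no_re ? Type(0) : eta(i, m + 1);
        Type e_tp = no_re ? Type(0) : eta(i, m + 2);
        Type base_i = base(d) + e_base;
        Type pmax_i = pmax(d);
        Type drug_i = drug(d);
        for (int c = 0; c < cov_coef.size(); c++) {
          if (cov_dim[c] != d) continue;
          Type z = zcov(i, c);
          if (cov_target[c] == 0)
            base_i += (cov_form[c] == 0) ? cov_coef(c) * z
                                         : base(d) * cov_coef(c) * z;
          else if (cov_target[c] == 1)
            pmax_i *= (cov_form[c] == 1) ? 1 + cov_coef(c) * z : Type(1);
          else
            drug_i *= (cov_form[c] == 1) ? 1 + cov_coef(c) * z : Type(1);
        }
        pmax_i += e_pmax;
        Type psi = base_i;
        if (obs_post[o]) {
          Type tprog_i = exp(log_tprog(d) + e_tp);
          Type pl = pmax_i * (1 - exp(-pow((ln2 / tprog_i) * t, wei))) +
                    (drift + e_drift) * t;
          psi += pl;
          if (trt[i]) psi += drug_i;
        }
        lin += a(aoff[j] + l) * psi;
      }
      nll -= grm_logprob(lin, B[j], y);
    }

    ADREPORT(sd);
    vector<Type> tprog = exp(log_tprog);
    ADREPORT(tprog);
    ADREPORT(wei);
    // report estimated correlations in Lmask order
    {
      int nfree = ltheta.size();
      vector<Type> rho(nfree);
      int s = 0;
      for (int i = 0; i < n_re; i++)
        for (int jj = 0; jj < i; jj++)
          if (Lmask(i, jj)) { rho(s) = C(i, jj); s++; }
      ADREPORT(rho);
    }
  }
  return nll;
}
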