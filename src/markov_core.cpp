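// Compiled numerical core: 13-state generator assembly, matrix-exponential
// occupancy propagation, and the single-compartment membrane integrator.
//
// State ordering (fixed package-wide): C1..C5 = 0..4, O = 5, OB = 6,
// I1..I6 = 7..12.  Convention: dp/dt = p %*% Q (row vector), so Q[i][j] is
// the rate i -> j and rows sum to zero.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Rate-parameter vector layout shared with R (see .rate_fields in R/rates.R):
// 0 alpha0, 1 beta0, 2 alpha_i0, 3 beta_i0, 4 gamma0, 5 delta0, 6 epsilon,
// 7 zeta0, 8 Con, 9 Coff, 10 Oon, 11 Ooff, 12 k_alpha, 13 k_beta, 14 k_zeta,
// 15 density_scale
static const int N_STATE = 13;

static void fill_generator(arma::mat &Q, double V, const double *r) {
  const double al  = r[0] * std::exp(V / r[12]);
  const double be  = r[1] * std::exp(-V / r[13]);
  const double ali = r[2] * std::exp(V / r[12]);
  const double bei = r[3] * std::exp(-V / r[13]);
  const double ga = r[4], de = r[5], ep = r[6];
  const double ze = r[7] * std::exp(-V / r[14]);
  const double Con = r[8], Coff = r[9], Oon = r[10], Ooff = r[11];
  // Allosteric scaling of the inactivated tier: forward/downward rates carry
  // alfac, backward/upward rates carry btfac; guarded so all-zero vertical
  // rate sets (used for closed-tier-only reductions) stay finite.
  const double alfac = (Con > 0.0 && Oon > 0.0) ? std::pow(Oon / Con, 0.25) : 1.0;
  const double btfac = (Coff > 0.0 && Ooff > 0.0) ? std::pow(Ooff / Coff, 0.25) : 1.0;

  Q.zeros(N_STATE, N_STATE);
  for (int n = 0; n < 4; ++n) {
    Q(n, n + 1) = (4 - n) * al;              // C(n+1) -> C(n+2): 4a,3a,2a,a
    Q(n + 1, n) = (n + 1) * be;              // backward: b,2b,3b,4b
    Q(7 + n, 8 + n) = (4 - n) * ali * alfac; // inactivated tier mirrors
    Q(8 + n, 7 + n) = (n + 1) * bei * btfac;
  }
  Q(4, 5) = ga;   // C5 -> O
  Q(5, 4) = de;   // O  -> C5
  Q(11, 12) = ga; // I5 -> I6 (mirrors C5 -> O)
  Q(12, 11) = de; // I6 -> I5
  Q(5, 6) = ep;   // O  -> OB (0 in all shipped conditions)
  Q(6, 5) = ze;   // OB -> O
  for (int n = 0; n < 5; ++n) {
    Q(n, 7 + n) = Con * std::pow(alfac, n);  // Cn -> In
    Q(7 + n, n) = Coff * std::pow(btfac, n); // In -> Cn
  }
  Q(5, 12) = Oon;  // O  -> I6
  Q(12, 5) = Ooff; // I6 -> O
  for (int i = 0; i < N_STATE; ++i) {
    double s = 0.0;
    for (int j = 0; j < N_STATE; ++j) if (j != i) s += Q(i, j);
    Q(i, i) = -s;
  }
}

// [[Rcpp::export(name = ".cpp_generator")]]
arma::mat cpp_generator(double V, NumericVector rates) {
  arma::mat Q(N_STATE, N_STATE);
  fill_generator(Q, V, rates.begin());
  return Q;
}

// One-step transition matrix P = expm(Q * dt) for a fixed voltage.
// [[Rcpp::export(name = ".cpp_expm_step")]]
arma::mat cpp_expm_step(const arma::mat &Q, double dt) {
  return arma::expmat(Q * dt);
}

// Propagate p0 through n_steps applications of P; returns the n_steps
// successive occupancies (one row per step, excluding p0).
// [[Rcpp::export(name = ".cpp_propagate")]]
arma::mat cpp_propagate(const arma::rowvec &p0, const arma::mat &P, int n_steps) {
  arma::mat out(n_steps, N_STATE);
  arma::rowvec p = p0;
  for (int k = 0; k < n_steps; ++k) {
    p = p * P;
    out.row(k) = p;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Single-compartment membrane model
//
// C dV/dt = -( sum_j gNa * frac_j * density_j * popen_j * (V - ENa)
//              + gK n^4 (V - EK) + gL (V - EL) + gH q (V - EH) ) + Istim
// Units: mV, ms, mS/cm^2, uF/cm^2, uA/cm^2.
//
// Numerics: backward Euler for each Markov occupancy vector (A-stable,
// conserves sum(p) exactly and preserves positivity for a generator matrix),
// Rush-Larsen for the HH gates, exponential Euler for V.
// ---------------------------------------------------------------------------

struct KGate {
  double vhalf, slope, tau_min, tau_amp, tau_vmid, tau_width;
  double inf(double V) const { return 1.0 / (1.0 + std::exp(-(V - vhalf) / slope)); }
  double tau(double V) const {
    double z = (V - tau_vmid) / tau_width;
    return tau_min + tau_amp * std::exp(-z * z);
  }
};

// [[Rcpp::export(name = ".cpp_sim_membrane")]]
List cpp_sim_membrane(const arma::mat &rate_mat,     // n_comp x 16
                      const arma::vec &fractions,    // n_comp
                      const arma::mat &p0,           // n_comp x 13
                      double gna, double gk, double gl, double gh,
                      double ena, double ek, double el, double eh,
                      double cm, double v0, double n0, double q0,
                      double dt, double t_total,
                      double stim_amp, double stim_start, double stim_end,
                      double record_dt, double spike_threshold,
                      double spike_lockout, NumericVector kgate_par) {
  const int n_comp = rate_mat.n_rows;
  KGate kg{kgate_par[0], kgate_par[1], kgate_par[2], kgate_par[3],
           kgate_par[4], kgate_par[5]};

  std::vector<arma::rowvec> p(n_comp), rpar(n_comp);
  std::vector<double> dens(n_comp);
  for (int j = 0; j < n_comp; ++j) {
    p[j] = p0.row(j);
    rpar[j] = rate_mat.row(j);
    dens[j] = rate_mat(j, 15);
  }

  const long n_steps = (long)std::llround(t_total / dt);
  const long rec_every = std::max(1L, (long)std::llround(record_dt / dt));
  const long n_rec = n_steps / rec_every + 1;

  NumericVector rec_t(n_rec), rec_v(n_rec);
  std::vector<double> spikes;
  arma::mat Q(N_STATE, N_STATE), A(N_STATE, N_STATE);
  const arma::mat I13 = arma::eye(N_STATE, N_STATE);

  double V = v0, n = n0, q = q0;
  double last_spike = -1e9;
  bool below = (V < spike_threshold);
  long ri = 0;
  rec_t[ri] = 0.0; rec_v[ri] = V; ++ri;

  for (long k = 0; k < n_steps; ++k) {
    const double t = k * dt;
    // Markov occupancies (implicit step at current V)
    double gna_open = 0.0;
    for (int j = 0; j < n_comp; ++j) {
      fill_generator(Q, V, rpar[j].memptr());
      A = I13 - dt * Q.t();
      arma::vec pv = arma::solve(A, p[j].t(), arma::solve_opts::fast);
      p[j] = pv.t();
      gna_open += gna * fractions[j] * dens[j] * p[j][5];
    }
    // HH gates, Rush-Larsen
    const double ninf = kg.inf(V), ntau = kg.tau(V);
    n += (ninf - n) * (1.0 - std::exp(-dt / ntau));
    if (gh > 0.0) {
      const double qinf = 1.0 / (1.0 + std::exp((V + 90.0) / 7.0));
      q += (qinf - q) * (1.0 - std::exp(-dt / 100.0));
    }
    // Membrane potential, exponential Euler
    const double n4 = n * n * n * n;
    const double istim =
        (t >= stim_start && t < stim_end) ? stim_amp : 0.0;
    const double gtot = gna_open + gk * n4 + gl + gh * q;
    const double gsum_e =
        gna_open * ena + gk * n4 * ek + gl * el + gh * q * eh + istim;
    const double vinf = gsum_e / gtot;
    V = vinf + (V - vinf) * std::exp(-dt * gtot / cm);

    // Spike detection: upward threshold crossing with lockout
    const double tnow = t + dt;
    if (below && V >= spike_threshold && (tnow - last_spike) > spike_lockout) {
      spikes.push_back(tnow);
      last_spike = tnow;
    }
    below = (V < spike_threshold);

    if ((k + 1) % rec_every == 0 && ri < n_rec) {
      rec_t[ri] = tnow; rec_v[ri] = V; ++ri;
    }
  }

  NumericMatrix pfin(n_comp, N_STATE);
  for (int j = 0; j < n_comp; ++j)
    for (int s = 0; s < N_STATE; ++s) pfin(j, s) = p[j][s];

  return List::create(_["time"] = rec_t[Range(0, ri - 1)],
                      _["v"] = rec_v[Range(0, ri - 1)],
                      _["spikes"] = wrap(spikes),
                      _["v_final"] = V, _["n_final"] = n,
                      _["p_final"] = pfin);
}
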