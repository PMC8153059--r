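// Fixed-step stochastic integrator for the coupled membrane / synapse /
// residual-calcium system.
//
// The between-event synapse dynamics are linear with distinct real
// eigenvalues, so each edge is stored in the eigenbasis of the generator and
// materialised lazily: an edge's state is reconstructed (exactly, via the
// closed-form exponential factors) only when a release event touches it.
// Quantities needed every step are maintained incrementally and exactly:
// the per-neuron conductances G = sum w*Y decay with the single uniform
// Y-rate, and the population state sum evolves by the same one-step affine
// map as every edge. This keeps the per-step cost proportional to the
// number of neurons plus the number of release events, not the number of
// edges, while remaining equivalent to advancing every synapse with the
// exact matrix-exponential propagator each step.
//
// All randomness comes from R's RNG, so runs reproduce from set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
arma::mat mat_exp_cpp(const arma::mat& M) {
  return arma::expmat(M);
}

static inline double ipow(double x, int k) {
  double r = 1.0;
  while (k-- > 0) r *= x;
  return r;
}

// Number of asynchronous events among k efferent edges, each firing
// independently with probability p this step (binomial inversion with a
// cheap k*p short-circuit for the overwhelmingly common zero-event case).
static inline int draw_event_count(int k, double p) {
  double u = unif_rand();
  if (u >= k * p) return 0;          // P(>=1) = 1-(1-p)^k <= k*p
  double q = std::pow(1.0 - p, k);
  if (u >= 1.0 - q) return 0;
  double pr = q, cum = 0.0;
  double odds = p / (1.0 - p);
  for (int j = 1; j <= k; ++j) {
    pr *= odds * (double)(k - j + 1) / (double)j;
    cum += pr;
    if (u < cum) return j;
  }
  return k;
}

// mode: 0 tuma (4-state), 1 tum, 2 clamp (3-state + affine inflow), 3 reduced.
// P, Pinv, lambda: eigen decomposition of the between-event generator
// (state order X, Y, Z[, A]); dY = exp(lambda_Y * dt) is the uniform decay
// factor of the active fraction. For the clamp mode, affine_a = A_fixed/tau_g
// is the constant inflow into Z and tau_r closes the secular X term.
// [[Rcpp::export]]
List run_engine_cpp(int n_neurons,
                    IntegerVector eff_ptr, IntegerVector edge_post,
                    NumericVector edge_w, LogicalVector neuron_inh,
                    List ml, List ca, List syn,
                    double duration, double dt, int trace_stride,
                    int mode, NumericMatrix P_in, NumericMatrix Pinv_in,
                    NumericVector lambda, double affine_a, double A_record,
                    double x_init, double R_init, bool record_traces) {
  const int n_edges = edge_post.size();
  const long n_steps = (long)std::llround(duration / dt);
  const int ns = (mode == 0) ? 4 : 3;

  // membrane parameters
  const double gCa = ml["g_Ca"], gK = ml["g_K"], gL = ml["g_L"];
  const double VCa = ml["V_Ca"], VK = ml["V_K"], VL = ml["V_L"];
  const double V1 = ml["V_1"], V2 = ml["V_2"], V3 = ml["V_3"], V4 = ml["V_4"];
  const double Cm = ml["C"], theta = ml["theta"], Vth = ml["V_th"];
  const double Vr = ml["V_r"], Vi = ml["V_i"];
  const double bg_mean = ml["I_bg_mean"], bg_sd = ml["I_bg_sd"];
  const double inv_V2_2 = 2.0 / V2, inv_2V4 = 0.5 / V4;
  const double thdt = theta * dt, dt_invC = dt / Cm;

  // calcium parameters (ms scale)
  const double beta = ca["beta"], kr = ca["kappa_r"], Ip = ca["I_p"];
  const double gam = ca["gamma"], R0 = ca["R_Ca0"];
  const double eta_max = ca["eta_max"], kap_a = ca["kappa_a"];
  const double ca_floor = ca["floor"];
  const int nH = ca["n"], mH = ca["m"];
  const double krn = ipow(kr, nH), kam = ipow(kap_a, mH);
  const double eta_dt = eta_max * dt;

  // synapse parameters
  const double u_rel = syn["u"], xi = syn["xi_bar"], b = syn["b"];
  const double tau_r = syn["tau_r"];
  const bool b_on = (b != 0.0);

  // eigen machinery (local copies; row-major p[i*ns+j])
  double p[16], pinv[16], d[4], jv[4];
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < ns; ++j) {
      p[i * ns + j] = P_in(i, j);
      pinv[i * ns + j] = Pinv_in(i, j);
    }
  for (int j = 0; j < ns; ++j) d[j] = std::exp(lambda[j] * dt);
  // release jump (-rel on X, +rel on Y) mapped into eigencoordinates
  for (int j = 0; j < ns; ++j) jv[j] = pinv[j * ns + 1] - pinv[j * ns + 0];
  const double dY = std::exp(lambda[1] * dt);   // Y is eigencoordinate 1
  const double dr = std::exp(-dt / tau_r);
  const bool affine = (mode == 2) && affine_a != 0.0;
  // per-step affine increment g(dt) of the clamped mode, in eigencoords
  double pg[4] = {0, 0, 0, 0};
  if (affine) {
    double gz = affine_a * tau_r * (1.0 - dr);
    double gx = affine_a * dt - gz;
    for (int j = 0; j < ns; ++j)
      pg[j] = pinv[j * ns + 0] * gx + pinv[j * ns + 2] * gz;
  }

  // per-edge eigencoordinates (AoS) + last materialisation step
  std::vector<double> C(std::max(1, n_edges) * ns);
  std::vector<long> last(std::max(1, n_edges), 0);
  double c0[4];
  for (int j = 0; j < ns; ++j) c0[j] = pinv[j * ns + 0] * x_init;
  for (int e = 0; e < n_edges; ++e)
    for (int j = 0; j < ns; ++j) C[e * ns + j] = c0[j];
  double Sc[4] = {0, 0, 0, 0};
  for (int j = 0; j < ns; ++j) Sc[j] = n_edges * c0[j];

  // neuron state
  std::vector<double> V(n_neurons, VL), W(n_neurons), Rca(n_neurons, R_init);
  std::vector<char> above(n_neurons, 0);
  {
    double q0 = std::exp((VL - V3) * inv_2V4), q4 = q0 * q0 * q0 * q0;
    for (int i = 0; i < n_neurons; ++i)
      W[i] = 0.5 + 0.5 * (q4 - 1.0) / (q4 + 1.0);
  }
  std::vector<double> Ge(n_neurons, 0.0), Gi(n_neurons, 0.0),
      Gb(n_neurons, 0.0), Gbi(n_neurons, 0.0);

  std::vector<int> spike_unit;
  std::vector<double> spike_time;
  spike_unit.reserve(1 << 16);
  spike_time.reserve(1 << 16);

  long now = 0;  // current step count, the lazy-update clock

  // reconstruct the true state s of edge e at step `now`
  auto materialize = [&](int e, double* s) {
    const double* c = &C[(size_t)e * ns];
    const long k = now - last[e];
    double cf[4];
    if (k == 0) {
      for (int j = 0; j < ns; ++j) cf[j] = c[j];
    } else if (k == 1) {
      for (int j = 0; j < ns; ++j) cf[j] = c[j] * d[j];
    } else {
      for (int j = 0; j < ns; ++j) cf[j] = c[j] * std::pow(d[j], (double)k);
    }
    for (int i = 0; i < ns; ++i) {
      double acc = 0;
      for (int j = 0; j < ns; ++j) acc += p[i * ns + j] * cf[j];
      s[i] = acc;
    }
    if (affine && k > 0) {
      const double fr = (k == 1) ? dr : std::pow(dr, (double)k);
      const double gz = affine_a * tau_r * (1.0 - fr);
      s[0] += affine_a * (k * dt) - gz;
      s[2] += gz;
    }
  };
  // store edge e's post-jump state and apply the jump to the running sums
  auto commit = [&](int e, const double* s, double rel) {
    double* c = &C[(size_t)e * ns];
    for (int j = 0; j < ns; ++j) {
      double acc = 0;
      for (int i = 0; i < ns; ++i) acc += pinv[j * ns + i] * s[i];
      c[j] = acc;
      Sc[j] += rel * jv[j];
    }
    last[e] = now;
  };
  // one release of fraction `frac` of the ready pool at edge e, whose
  // presynaptic neuron is inhibitory iff `inh`
  auto release = [&](int e, double frac, bool inh) {
    double s[4];
    materialize(e, s);
    const double rel = frac * s[0];
    const double y_old = s[1];
    s[0] -= rel;
    s[1] += rel;
    commit(e, s, rel);
    const int post = edge_post[e];
    const double w = edge_w[e];
    if (inh) {
      Gi[post] += w * rel;
      if (b_on) Gbi[post] += w * b * (2.0 * y_old * rel + rel * rel);
    } else {
      Ge[post] += w * rel;
      if (b_on) Gb[post] += w * b * (2.0 * y_old * rel + rel * rel);
    }
  };

  const long n_samples = record_traces ? n_steps / trace_stride + 1 : 0;
  NumericVector tr_t(n_samples), tr_X(n_samples), tr_Y(n_samples),
      tr_Z(n_samples), tr_A(n_samples);
  long sample = 0;
  auto record = [&](double t) {
    double s[4] = {0, 0, 0, 0};
    for (int i = 0; i < ns; ++i)
      for (int j = 0; j < ns; ++j) s[i] += p[i * ns + j] * Sc[j];
    const double inv_n = 1.0 / n_edges;
    tr_t[sample] = t;
    tr_X[sample] = s[0] * inv_n;
    tr_Y[sample] = s[1] * inv_n;
    tr_Z[sample] = s[2] * inv_n;
    tr_A[sample] = (ns == 4) ? s[3] * inv_n : A_record;
    ++sample;
  };
  if (record_traces && n_edges > 0) record(0.0);

  const double dY2 = dY * dY;
  for (long step = 0; step < n_steps; ++step) {
    // (1) between-event decay: advance the lazy clock, the running state
    // sums and the conductances (Y decays at the single uniform rate)
    now = step + 1;
    for (int j = 0; j < ns; ++j) Sc[j] = Sc[j] * d[j] + n_edges * pg[j];
    for (int i = 0; i < n_neurons; ++i) { Ge[i] *= dY; Gi[i] *= dY; }
    if (b_on)
      for (int i = 0; i < n_neurons; ++i) { Gb[i] *= dY2; Gbi[i] *= dY2; }

    // (2) asynchronous release events, per presynaptic neuron
    for (int i = 0; i < n_neurons; ++i) {
      const int k0 = eff_ptr[i], k = eff_ptr[i + 1] - k0;
      if (k == 0) continue;
      const double R = Rca[i];
      const double R2 = R * R;
      const double Rm = (mH == 4) ? R2 * R2 : ipow(R, mH);
      const double pr = eta_dt * Rm / (kam + Rm);
      const int nev = draw_event_count(k, pr);
      if (nev == 0) continue;
      const bool inh_i = neuron_inh[i];
      if (nev == 1) {
        release(k0 + (int)(unif_rand() * k), xi, inh_i);
      } else {
        int chosen[16];
        int nch = 0;
        while (nch < nev && nch < 16) {
          int e = k0 + (int)(unif_rand() * k);
          bool dup = false;
          for (int c2 = 0; c2 < nch; ++c2)
            if (chosen[c2] == e) { dup = true; break; }
          if (!dup) chosen[nch++] = e;
        }
        for (int c2 = 0; c2 < nch; ++c2) release(chosen[c2], xi, inh_i);
      }
    }

    // (3)+(4) currents and membrane update; (5) spike-triggered release
    const double t_now = now * dt;
    for (int i = 0; i < n_neurons; ++i) {
      const double Vold = V[i];
      const double em = std::exp((Vold - V1) * inv_V2_2);
      const double minf = 0.5 + 0.5 * (em - 1.0) / (em + 1.0);
      const double Iion = gCa * minf * (Vold - VCa) + gK * W[i] * (Vold - VK)
                        + gL * (Vold - VL);
      const double ge = b_on ? Ge[i] - Gb[i] : Ge[i];
      const double gi = b_on ? Gi[i] - Gbi[i] : Gi[i];
      const double Isyn = ge * (Vr - Vold) + gi * (Vi - Vold);
      double Ibg = bg_mean;
      if (bg_sd > 0) Ibg += bg_sd * norm_rand();
      const double Vnew = Vold + dt_invC * (Isyn + Ibg - Iion);
      const double q = std::exp((Vold - V3) * inv_2V4);
      const double q2 = q * q, q4 = q2 * q2;
      const double winf = 0.5 + 0.5 * (q4 - 1.0) / (q4 + 1.0);
      const double ch = 0.5 * (q + 1.0 / q);  // cosh = 1/tau_W
      W[i] = winf + (W[i] - winf) * std::exp(-thdt * ch);
      if (!std::isfinite(Vnew))
        stop("non-finite membrane potential at step %ld (t = %.3f ms); reduce dt",
             step, t_now);
      V[i] = Vnew;
      const bool spiked = !above[i] && Vnew >= Vth;
      above[i] = Vnew >= Vth;

      // residual calcium: pump/influx decay, then the spike impulse
      const double R = Rca[i];
      const double Rn = (nH == 2) ? R * R : ipow(R, nH);
      double Rnew = R + dt * (Ip - beta * Rn / (krn + Rn));
      if (spiked) {
        if (Rnew < ca_floor) Rnew = ca_floor;
        Rnew += gam * std::log(R0 / Rnew);
      }
      Rca[i] = (Rnew > ca_floor) ? Rnew : ca_floor;

      if (spiked) {
        spike_unit.push_back(i + 1);
        spike_time.push_back(t_now);
        const bool inh_i = neuron_inh[i];
        for (int e = eff_ptr[i]; e < eff_ptr[i + 1]; ++e)
          release(e, u_rel, inh_i);
      }
    }

    // (6) record
    if (record_traces && n_edges > 0 && now % trace_stride == 0)
      record(t_now);

    if ((step & 0xFFFFF) == 0) checkUserInterrupt();
  }

  return List::create(
      _["spike_unit"] = wrap(spike_unit),
      _["spike_time"] = wrap(spike_time),
      _["trace_time"] = tr_t, _["mean_X"] = tr_X, _["mean_Y"] = tr_Y,
      _["mean_Z"] = tr_Z, _["mean_A"] = tr_A,
      _["final_V"] = wrap(V), _["final_W"] = wrap(W),
      _["final_R_Ca"] = wrap(Rca));
}
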