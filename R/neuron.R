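#' Morris-Lecar gating functions
#'
#' Steady-state open fractions of the calcium and potassium gates and the
#' (unscaled) potassium gate time constant at a given membrane potential:
#' `m_inf = (1 + tanh((V - V_1)/V_2))/2`,
#' `W_inf = (1 + tanh((V - V_3)/V_4))/2`,
#' `tau_W = 1/cosh((V - V_3)/(2 V_4))`.
#'
#' @param V Membrane potential (mV); vectorised.
#' @param p An [ml_params()] object.
#' @return A list with components `m_inf`, `W_inf`, `tau_W`.
#' @export
gate_steady_states <- function(V, p) {
  stopifnot(inherits(p, "ml_params"))
  list(m_inf = 0.5 * (1 + tanh((V - p$V_1) / p$V_2)),
       W_inf = 0.5 * (1 + tanh((V - p$V_3) / p$V_4)),
       tau_W = 1 / cosh((V - p$V_3) / (2 * p$V_4)))
}

#' Total ionic membrane current
#'
#' Sum of the instantaneous calcium current (gate at steady state), the
#' potassium current through the open fraction `W`, and the leak.
#'
#' @param V Membrane potential (mV).
#' @param W Open potassium channel fraction in `[0, 1]`.
#' @param p An [ml_params()] object.
#' @return Current (uA), positive outward.
#' @export
ionic_current <- function(V, W, p) {
  g <- gate_steady_states(V, p)
  p$g_Ca * g$m_inf * (V - p$V_Ca) + p$g_K * W * (V - p$V_K) +
    p$g_L * (V - p$V_L)
}

#' Initial membrane state
#'
#' @param V Membrane potential (mV).
#' @param W Open potassium fraction; defaults to its steady state at `V`.
#' @param p An [ml_params()] object (used for the default `W`).
#' @return A list with `V`, `W` and the `above_threshold` flag.
#' @export
ml_state <- function(V = -65, W = NULL, p = ml_params()) {
  if (is.null(W)) W <- gate_steady_states(V, p)$W_inf
  stopifnot(W >= 0, W <= 1)
  list(V = V, W = W, above_threshold = V >= p$V_th)
}

#' Advance the membrane one step
#'
#' Forward-Euler update of the potential and exponential-Euler update of the
#' potassium gate (`dW/dt = theta (W_inf - W)/tau_W`). The background
#' current is drawn from a Gaussian with the configured mean and standard
#' deviation (constant when the sd is zero), unless supplied explicitly.
#' A spike is flagged exactly on an upward crossing of the threshold: the
#' state must have been below threshold before the step.
#'
#' @param s A membrane state as from [ml_state()].
#' @param I_syn Synaptic current (uA).
#' @param p An [ml_params()] object.
#' @param dt Step (ms).
#' @param I_bg Optional fixed background current overriding the stochastic
#'   draw.
#' @return A list with the advanced `state` and logical `spiked`.
#' @export
step_membrane <- function(s, I_syn, p, dt, I_bg = NULL) {
  stopifnot(dt > 0)
  if (is.null(I_bg)) {
    I_bg <- p$I_bg_mean
    if (p$I_bg_sd > 0) I_bg <- I_bg + p$I_bg_sd * stats::rnorm(1)
  }
  g <- gate_steady_states(s$V, p)
  I_ion <- p$g_Ca * g$m_inf * (s$V - p$V_Ca) + p$g_K * s$W * (s$V - p$V_K) +
    p$g_L * (s$V - p$V_L)
  V_new <- s$V + dt * (-I_ion + I_syn + I_bg) / p$C
  W_new <- g$W_inf + (s$W - g$W_inf) * exp(-p$theta * dt / g$tau_W)
  if (!is.finite(V_new) || !is.finite(W_new))
    stop(sprintf("membrane state non-finite after step (dt = %g ms)", dt),
         call. = FALSE)
  spiked <- !s$above_threshold && V_new >= p$V_th
  list(state = list(V = V_new, W = W_new,
                    above_threshold = V_new >= p$V_th),
       spiked = spiked)
}

#' No-spike fixed point of the residual-calcium pump equation
#'
#' Solves `beta R^n / (kappa_r^n + R^n) = I_p` for the resting
#' concentration, in closed form.
#'
#' @param p A [calcium_params()] object.
#' @return Resting residual calcium (uM).
#' @export
calcium_fixed_point <- function(p) {
  stopifnot(inherits(p, "calcium_params"))
  if (p$I_p >= p$beta)
    stop("no fixed point: passive influx exceeds maximal pump rate",
         call. = FALSE)
  p$kappa_r * (p$I_p / (p$beta - p$I_p))^(1 / p$n)
}

#' Advance the residual-calcium pool one step
#'
#' Euler update of the pump/influx balance
#' `dR/dt = -beta R^n/(kappa_r^n + R^n) + I_p`, plus, per spike in the
#' step, an impulse increment `gamma * log(R_Ca0 / R)`. The result is
#' clamped at the configured floor so the logarithm stays defined.
#'
#' @param R_Ca Residual calcium (uM).
#' @param spikes Number of spikes in this step.
#' @param p A [calcium_params()] object.
#' @param dt Step (ms).
#' @return Updated residual calcium (uM).
#' @export
step_residual_calcium <- function(R_Ca, spikes, p, dt) {
  stopifnot(dt > 0, spikes >= 0)
  if (R_Ca <= 0) {
    warning("residual calcium at or below zero; clamped to floor")
    R_Ca <- p$floor
  }
  Rn <- R_Ca^p$n
  R_new <- R_Ca + dt * (-p$beta * Rn / (p$kappa_r^p$n + Rn) + p$I_p)
  if (spikes > 0)
    R_new <- R_new + spikes * p$gamma * log(p$R_Ca0 / max(R_new, p$floor))
  max(R_new, p$floor)
}

#' Calcium-dependent asynchronous release rate
#'
#' Hill function `eta_max R^m / (kappa_a^m + R^m)`: zero at zero calcium,
#' half-maximal at `kappa_a`, saturating at `eta_max`.
#'
#' @param R_Ca Residual calcium (uM); vectorised.
#' @param p A [calcium_params()] object.
#' @return Release rate (ms^-1) in `[0, eta_max)`.
#' @export
async_release_rate <- function(R_Ca, p) {
  stopifnot(all(R_Ca >= 0))
  Rm <- R_Ca^p$m
  p$eta_max * Rm / (p$kappa_a^p$m + Rm)
}
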