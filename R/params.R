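#' Morris-Lecar membrane parameters
#'
#' Bundles the parameters of the two-variable Morris-Lecar membrane model:
#' calcium, potassium and leak conductances, their reversal potentials, the
#' half-activation/slope voltages of the gating functions, the gate rate scale
#' and the spike threshold used for edge-triggered spike registration.
#' Defaults are the simulation values used throughout the package.
#'
#' @param g_Ca,g_K,g_L Channel conductances (mS cm^-2).
#' @param V_Ca,V_K,V_L Reversal potentials (mV).
#' @param V_1,V_2 Half-activation and slope voltage of the calcium gate (mV).
#' @param V_3,V_4 Half-activation and slope voltage of the potassium gate (mV).
#' @param C Membrane capacitance (uF cm^-2).
#' @param theta Potassium gate rate scale (ms^-1), a temperature-like factor.
#' @param V_th Spike threshold (mV); a spike is registered on an upward
#'   crossing, and cannot re-register until the potential falls back below.
#' @param V_r Excitatory synaptic reversal potential (mV).
#' @param V_i Inhibitory synaptic reversal potential (mV).
#' @param I_bg_mean,I_bg_sd Mean and standard deviation of the background
#'   current (uA); `I_bg_sd = 0` gives a constant drive.
#' @return An object of class `ml_params`.
#' @export
ml_params <- function(g_Ca = 1.1, g_K = 2, g_L = 0.46,
                      V_Ca = 100, V_K = -70, V_L = -65,
                      V_1 = -1, V_2 = 15, V_3 = 0, V_4 = 30,
                      C = 1, theta = 0.2, V_th = 10,
                      V_r = 0, V_i = -90,
                      I_bg_mean = 27, I_bg_sd = 0) {
  p <- list(g_Ca = g_Ca, g_K = g_K, g_L = g_L,
            V_Ca = V_Ca, V_K = V_K, V_L = V_L,
            V_1 = V_1, V_2 = V_2, V_3 = V_3, V_4 = V_4,
            C = C, theta = theta, V_th = V_th,
            V_r = V_r, V_i = V_i,
            I_bg_mean = I_bg_mean, I_bg_sd = I_bg_sd)
  stopifnot(vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                   logical(1)))
  if (g_Ca < 0 || g_K < 0 || g_L < 0)
    stop("conductances must be non-negative", call. = FALSE)
  if (C <= 0) stop("capacitance C must be positive", call. = FALSE)
  if (V_2 == 0 || V_4 == 0)
    stop("gate slope voltages V_2 and V_4 must be non-zero", call. = FALSE)
  if (!(V_Ca > V_th && V_th > V_L && V_L > V_K))
    stop("expected potential ordering V_Ca > V_th > V_L > V_K", call. = FALSE)
  if (I_bg_sd < 0) stop("I_bg_sd must be non-negative", call. = FALSE)
  structure(p, class = "ml_params")
}

#' Residual-calcium and asynchronous-release parameters
#'
#' Parameters of the presynaptic residual-calcium pool and of the
#' calcium-dependent asynchronous release rate. Pump and influx rates are
#' supplied in the conventional per-second units (uM s^-1) and converted to
#' the per-millisecond scale used internally; the stored fields `beta`,
#' `I_p` and `gamma` are therefore in uM ms^-1 (for `gamma`, uM per spike,
#' since the spike influx enters as an impulse).
#'
#' @param beta Maximal pump extrusion rate (uM s^-1).
#' @param kappa_r Pump half-saturation concentration (uM).
#' @param n Pump Hill exponent (integer >= 1).
#' @param I_p Passive calcium influx (uM s^-1).
#' @param gamma Spike-influx scale (uM s^-1 as printed; one spike increments
#'   the pool by `gamma/1000 * log(R_Ca0 / R_Ca)` uM).
#' @param R_Ca0 Reference concentration in the logarithmic spike-influx term
#'   (uM). The default is the extracellular calcium concentration `Ca_o`, so
#'   the per-spike influx is proportional to the log of the transmembrane
#'   concentration ratio and shrinks as residual calcium accumulates.
#' @param eta_max Maximal asynchronous release rate (ms^-1).
#' @param kappa_a Release half-saturation concentration (uM).
#' @param m Release Hill exponent (integer >= 1).
#' @param Ca_o Extracellular calcium concentration (uM); used as the default
#'   for `R_Ca0`.
#' @param floor Lower clamp on residual calcium (uM) keeping the logarithm
#'   defined.
#' @return An object of class `calcium_params` with rate fields on the
#'   millisecond scale.
#' @export
calcium_params <- function(beta = 5, kappa_r = 0.4, n = 2,
                           I_p = 0.11, gamma = 50,
                           R_Ca0 = NULL,
                           eta_max = 0.32, kappa_a = 0.1, m = 4,
                           Ca_o = 2000, floor = 1e-6) {
  if (is.null(R_Ca0)) R_Ca0 <- Ca_o
  stopifnot(is.numeric(beta), is.numeric(kappa_r), is.numeric(I_p),
            is.numeric(gamma), is.numeric(eta_max), is.numeric(kappa_a),
            is.numeric(R_Ca0), is.numeric(Ca_o), is.numeric(floor))
  if (beta <= 0 || kappa_r <= 0 || gamma <= 0 || eta_max <= 0 || kappa_a <= 0)
    stop("beta, kappa_r, gamma, eta_max and kappa_a must be positive",
         call. = FALSE)
  if (n < 1 || m < 1 || n != round(n) || m != round(m))
    stop("Hill exponents n and m must be integers >= 1", call. = FALSE)
  if (I_p < 0) stop("I_p must be non-negative", call. = FALSE)
  if (R_Ca0 <= 0 || floor <= 0)
    stop("R_Ca0 and floor must be positive", call. = FALSE)
  structure(list(beta = beta / 1000, kappa_r = kappa_r, n = as.integer(n),
                 I_p = I_p / 1000, gamma = gamma / 1000,
                 R_Ca0 = R_Ca0, eta_max = eta_max, kappa_a = kappa_a,
                 m = as.integer(m), Ca_o = Ca_o, floor = floor),
            class = "calcium_params")
}

#' Glutamate-recycling synapse parameters
#'
#' Parameters of the three-state (neuronal-only uptake) and four-state
#' (astrocytic pool) synaptic resource models. All timescales are in
#' milliseconds.
#'
#' @param u Fraction of the ready pool released per presynaptic spike.
#' @param tau_r Recovery (repackaging) time from the recovered pool back to
#'   the ready pool (ms).
#' @param tau_d Active-state decay time of the three-state model (ms); by
#'   default equal to the neuronal uptake time.
#' @param tau_nu Neuronal uptake time of the four-state model (ms).
#' @param tau_au Astrocytic uptake time (ms).
#' @param tau_g Astrocytic inactivation time: the lumped
#'   glutamate-glutamine-cycle return time (ms).
#' @param xi_bar Fraction of the ready pool released per asynchronous event.
#' @param b Postsynaptic saturation factor in the conductance term
#'   `w * Y * (1 - b * Y)`.
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(u = 0.2, tau_r = 600, tau_d = tau_nu,
                           tau_nu = 50, tau_au = 250, tau_g = 30000,
                           xi_bar = 0.02, b = 0) {
  if (!(u > 0 && u <= 1)) stop("u must be in (0, 1]", call. = FALSE)
  if (!(xi_bar >= 0 && xi_bar <= 1)) stop("xi_bar must be in [0, 1]", call. = FALSE)
  if (any(c(tau_r, tau_d, tau_nu, tau_au, tau_g) <= 0))
    stop("all synaptic timescales must be positive", call. = FALSE)
  if (b < 0) stop("b must be non-negative", call. = FALSE)
  structure(list(u = u, tau_r = tau_r, tau_d = tau_d, tau_nu = tau_nu,
                 tau_au = tau_au, tau_g = tau_g, xi_bar = xi_bar, b = b),
            class = "synapse_params")
}

#' Synchronous-burst detection parameters
#'
#' Two-threshold burst detection on the array-wide firing-rate time
#' histogram: a bin at or above `epsilon * R_max` marks the network active, a
#' candidate is promoted to a burst only if some bin reaches
#' `delta * R_max`, and bursts separated by less than `tau_rest` of
#' quiescence are merged.
#'
#' @param epsilon Lower threshold as a fraction of the maximal bin count.
#' @param delta Upper threshold fraction; must exceed `epsilon`.
#' @param tau_rest Minimum quiescence separating bursts (ms).
#' @param bin_width Histogram bin width used for detection (ms).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(epsilon = 0.04, delta = 0.2,
                             tau_rest = 1000, bin_width = 10) {
  if (!(epsilon > 0 && epsilon < delta && delta <= 1))
    stop("need 0 < epsilon < delta <= 1", call. = FALSE)
  if (tau_rest <= 0 || bin_width <= 0)
    stop("tau_rest and bin_width must be positive", call. = FALSE)
  structure(list(epsilon = epsilon, delta = delta,
                 tau_rest = tau_rest, bin_width = bin_width),
            class = "detection_params")
}

#' Random network parameters
#'
#' @param n_neurons Number of neurons.
#' @param p_connect Independent connection probability for each ordered pair.
#' @param inh_ratio Inhibitory fraction; exactly `round(inh_ratio * n)`
#'   neurons are labelled inhibitory.
#' @param w_mean Mean synaptic weight.
#' @param w_width_frac Half-width of the truncated Gaussian weight
#'   distribution as a fraction of the mean.
#' @return An object of class `network_params`.
#' @export
network_params <- function(n_neurons = 100, p_connect = 0.1, inh_ratio = 0.2,
                           w_mean = 4, w_width_frac = 0.2) {
  if (n_neurons < 2) stop("need at least 2 neurons", call. = FALSE)
  if (!(p_connect > 0 && p_connect < 1)) stop("p_connect must be in (0, 1)", call. = FALSE)
  if (!(inh_ratio >= 0 && inh_ratio < 1)) stop("inh_ratio must be in [0, 1)", call. = FALSE)
  if (w_mean <= 0 || w_width_frac < 0 || w_width_frac >= 1)
    stop("w_mean must be positive and w_width_frac in [0, 1)", call. = FALSE)
  structure(list(n_neurons = as.integer(n_neurons), p_connect = p_connect,
                 inh_ratio = inh_ratio, w_mean = w_mean,
                 w_width_frac = w_width_frac),
            class = "network_params")
}

#' Full simulation configuration
#'
#' Assembles all parameter blocks with the run-control fields: duration,
#' integration step, trace recording and the synapse-model mode.
#'
#' Modes: `"tuma"` is the free four-state model; `"tum"` the baseline
#' three-state model (decay time `tau_d`); `"clamp"` holds the astrocytic
#' fraction at `A_fixed` while keeping every flux term (the sum X+Y+Z then
#' fluctuates around `1 - A_fixed`); `"reduced"` is the hard three-state
#' reduction with total `1 - A_fixed` and combined uptake time
#' `1/(1/tau_nu + 1/tau_au)`.
#'
#' @param duration Simulated time (ms).
#' @param dt Integration step (ms). The per-step asynchronous-release
#'   probability `eta_max * dt` must stay at or below 0.05.
#' @param seeds Named list with integer `topology` and `dynamics` seeds.
#' @param record_traces Record population-mean synapse states?
#' @param trace_stride Recording stride in steps (default 1 ms of simulated
#'   time at the default `dt`).
#' @param mode One of `"tuma"`, `"tum"`, `"clamp"`, `"reduced"`.
#' @param A_fixed Clamped astrocytic fraction, for the clamp/reduced modes.
#' @param neuron,calcium,synapse,network,detection Parameter blocks; see
#'   [ml_params()], [calcium_params()], [synapse_params()],
#'   [network_params()], [detection_params()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration = 300000, dt = 0.05,
                       seeds = list(topology = 1L, dynamics = 1L),
                       record_traces = TRUE, trace_stride = round(1 / dt),
                       mode = c("tuma", "tum", "clamp", "reduced"),
                       A_fixed = NA_real_,
                       neuron = ml_params(), calcium = calcium_params(),
                       synapse = synapse_params(), network = network_params(),
                       detection = detection_params()) {
  mode <- match.arg(mode)
  if (duration < 10 * dt) stop("duration must be at least 10 * dt", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (trace_stride < 1) stop("trace_stride must be >= 1", call. = FALSE)
  if (calcium$eta_max * dt > 0.05)
    stop("eta_max * dt exceeds 0.05; reduce dt for valid Bernoulli thinning",
         call. = FALSE)
  if (mode %in% c("clamp", "reduced")) {
    if (!is.finite(A_fixed) || A_fixed < 0 || A_fixed >= 1)
      stop("clamped modes need A_fixed in [0, 1)", call. = FALSE)
  }
  stopifnot(inherits(neuron, "ml_params"), inherits(calcium, "calcium_params"),
            inherits(synapse, "synapse_params"),
            inherits(network, "network_params"),
            inherits(detection, "detection_params"))
  seeds$topology <- as.integer(seeds$topology)
  seeds$dynamics <- as.integer(seeds$dynamics)
  structure(list(duration = duration, dt = dt, seeds = seeds,
                 record_traces = isTRUE(record_traces),
                 trace_stride = as.integer(trace_stride), mode = mode,
                 A_fixed = A_fixed, neuron = neuron, calcium = calcium,
                 synapse = synapse, network = network, detection = detection),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %s mode, %.0f ms at dt = %g ms, %d neurons\n",
              x$mode, x$duration, x$dt, x$network$n_neurons))
  cat(sprintf("  synapse: tau_nu=%g tau_au=%g tau_g=%g ms, u=%g, xi_bar=%g\n",
              x$synapse$tau_nu, x$synapse$tau_au, x$synapse$tau_g,
              x$synapse$u, x$synapse$xi_bar))
  cat(sprintf("  seeds: topology=%d dynamics=%d\n",
              x$seeds$topology, x$seeds$dynamics))
  invisible(x)
}

# Accepted config-file keys, section by section, with the constructor
# argument each maps to. Table-style aliases (k_a, k_r, I_bgm, xi_ave,
# u_low/u_up, ...) are accepted verbatim.
.config_key_maps <- list(
  neuron = c(g_Ca = "g_Ca", g_K = "g_K", g_L = "g_L",
             V_Ca = "V_Ca", V_K = "V_K", V_L = "V_L",
             V_1 = "V_1", V_2 = "V_2", V_3 = "V_3", V_4 = "V_4",
             C = "C", theta = "theta", upsilon = "theta",
             V_th = "V_th", V_r = "V_r", V_i = "V_i",
             I_bgm = "I_bg_mean", I_bgs = "I_bg_sd",
             I_bg_mean = "I_bg_mean", I_bg_sd = "I_bg_sd"),
  calcium = c(beta = "beta", k_r = "kappa_r", kappa_r = "kappa_r", n = "n",
              I_p = "I_p", gamma = "gamma", k_a = "kappa_a",
              kappa_a = "kappa_a", m = "m", eta_max = "eta_max",
              R_Ca0 = "R_Ca0", Ca_o = "Ca_o", floor = "floor"),
  synapse = c(u = "u", u_low = "u", u_up = "u", tau_r = "tau_r",
              tau_d = "tau_d", tau_nu = "tau_nu", tau_au = "tau_au",
              tau_g = "tau_g", xi_ave = "xi_bar", xi_bar = "xi_bar", b = "b"),
  network = c(n = "n_neurons", n_neurons = "n_neurons", p = "p_connect",
              p_connect = "p_connect", inh_ratio = "inh_ratio",
              w = "w_mean", w_ee = "w_mean", w_ei = "w_mean",
              w_mean = "w_mean", w_width = "w_width_frac",
              w_width_frac = "w_width_frac"),
  detection = c(epsilon = "epsilon", delta = "delta", tau_rest = "tau_rest",
                bin_width = "bin_width"),
  run = c(duration = "duration", dt = "dt", record_traces = "record_traces",
          trace_stride = "trace_stride", mode = "mode", A_fixed = "A_fixed",
          seed_topology = "seed_topology", seed_dynamics = "seed_dynamics")
)

#' Read a simulation configuration file
#'
#' Reads a flat YAML or JSON configuration with sections `neuron`,
#' `calcium`, `synapse`, `network`, `detection` and `run`. Keys follow the
#' conventional parameter names (`g_Ca`, `tau_au`, `k_a`, `I_bgm`,
#' `xi_ave`, ...); any unknown section or key is an error rather than being
#' silently ignored, which guards against typos reverting a parameter to
#' its default. `u_low`/`u_up` both map onto the constant release fraction
#' `u` and must agree if both are given.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [sim_config()] object.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) stop("config file must contain a mapping", call. = FALSE)
  bad_sec <- setdiff(names(raw), names(.config_key_maps))
  if (length(bad_sec))
    stop("unknown config section(s): ", paste(bad_sec, collapse = ", "),
         call. = FALSE)
  args <- lapply(names(.config_key_maps), function(sec) {
    keys <- .config_key_maps[[sec]]
    given <- raw[[sec]]
    if (is.null(given)) return(list())
    # YAML 1.1 parses a bare `n:` key as the boolean FALSE; map it back
    if (sec == "network") names(given)[names(given) == "FALSE"] <- "n"
    bad <- setdiff(names(given), names(keys))
    if (length(bad))
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
    out <- list()
    for (k in names(given)) {
      tgt <- keys[[k]]
      if (!is.null(out[[tgt]]) && !identical(out[[tgt]], given[[k]]))
        stop(sprintf("conflicting values for '%s' in section '%s'", tgt, sec),
             call. = FALSE)
      out[[tgt]] <- given[[k]]
    }
    out
  })
  names(args) <- names(.config_key_maps)
  run <- args$run
  seeds <- list(topology = run$seed_topology %||% 1L,
                dynamics = run$seed_dynamics %||% 1L)
  run$seed_topology <- NULL
  run$seed_dynamics <- NULL
  do.call(sim_config, c(run, list(
    seeds = seeds,
    neuron = do.call(ml_params, args$neuron),
    calcium = do.call(calcium_params, args$calcium),
    synapse = do.call(synapse_params, args$synapse),
    network = do.call(network_params, args$network),
    detection = do.call(detection_params, args$detection))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
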