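#' Run a network simulation
#'
#' Integrates the full stochastic network: per step, every synapse is
#' advanced through its exact linear decay, asynchronous release events are
#' drawn per efferent edge by Bernoulli thinning of the presynaptic
#' calcium-dependent rate, conductances and synaptic currents are computed,
#' membranes are stepped, and spiking neurons trigger synchronous release at
#' all their efferent synapses plus a residual-calcium influx. Runs are
#' bit-for-bit reproducible from the seeds in the configuration.
#'
#' @param config A [sim_config()] object.
#' @param topology Optional [build_random_network()] topology; built from
#'   `config$network` and the topology seed when omitted.
#' @return An object of class `tuma_sim`: a list with the spike `raster`
#'   ([spike_raster()]), the population-mean state `trace` (data.frame with
#'   `time`, `mean_X`, `mean_Y`, `mean_Z`, `mean_A`), the `topology`, the
#'   `config`, and the final per-neuron `V`, `W`, `R_Ca`.
#' @export
run_simulation <- function(config, topology = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(topology)) {
    np <- config$network
    topology <- build_random_network(np$n_neurons, np$p_connect,
                                     np$inh_ratio, np$w_mean,
                                     np$w_width_frac,
                                     seed = config$seeds$topology)
  }
  stopifnot(inherits(topology, "network_topology"))
  syn <- config$synapse
  dt <- config$dt
  if (nrow(topology$edges) == 0)
    stop("topology has no edges; nothing to simulate", call. = FALSE)
  mode_code <- match(config$mode, c("tuma", "tum", "clamp", "reduced")) - 1L
  eig <- synapse_eigen(syn, config$mode)
  A_fixed <- if (is.na(config$A_fixed)) 0 else config$A_fixed
  clamped <- config$mode %in% c("clamp", "reduced")
  x_init <- if (clamped) 1 - A_fixed else 1
  A_record <- if (clamped) A_fixed else 0
  affine_a <- if (config$mode == "clamp") A_fixed / syn$tau_g else 0

  # CSR layout of efferent edges, ordered by presynaptic neuron
  o <- order(topology$edges$pre, topology$edges$post)
  pre <- topology$edges$pre[o]
  post <- topology$edges$post[o]
  w <- topology$edges$weight[o]
  eff_ptr <- c(0L, cumsum(tabulate(pre, nbins = topology$n_neurons)))

  R_init <- calcium_fixed_point(config$calcium)
  set.seed(config$seeds$dynamics)
  res <- run_engine_cpp(topology$n_neurons,
                        as.integer(eff_ptr), as.integer(post - 1L), w,
                        topology$is_inhibitory,
                        unclass(config$neuron), unclass(config$calcium),
                        unclass(syn),
                        config$duration, dt, config$trace_stride,
                        mode_code, eig$P, eig$Pinv, eig$lambda,
                        affine_a, A_record, x_init, R_init,
                        config$record_traces)
  raster <- spike_raster(res$spike_unit, res$spike_time,
                         n_units = topology$n_neurons,
                         duration = config$duration)
  trace <- if (config$record_traces) {
    data.frame(time = res$trace_time, mean_X = res$mean_X,
               mean_Y = res$mean_Y, mean_Z = res$mean_Z,
               mean_A = res$mean_A)
  } else NULL
  structure(list(raster = raster, trace = trace, topology = topology,
                 config = config, final_V = res$final_V,
                 final_W = res$final_W, final_R_Ca = res$final_R_Ca),
            class = "tuma_sim")
}

#' @export
print.tuma_sim <- function(x, ...) {
  dur_s <- x$config$duration / 1000
  cat(sprintf("<tuma_sim> %s mode: %d spikes from %d neurons over %.0f s (%.2f spikes/s array-wide)\n",
              x$config$mode, nrow(x$raster), x$topology$n_neurons, dur_s,
              nrow(x$raster) / dur_s))
  invisible(x)
}

#' Time-averaged population-mean synapse states
#'
#' Averages the recorded population-mean state fractions over a time
#' window.
#'
#' @param trace A state trace data.frame (from [run_simulation()]) or a
#'   `tuma_sim` object.
#' @param window Two-element numeric `c(t0, t1)` in ms; the whole trace
#'   when omitted.
#' @return Named numeric vector `mean_X`, `mean_Y`, `mean_Z`, `mean_A`.
#' @export
population_mean_states <- function(trace, window = NULL) {
  if (inherits(trace, "tuma_sim")) trace <- trace$trace
  stopifnot(is.data.frame(trace), nrow(trace) > 0)
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] < window[2])
    keep <- trace$time >= window[1] & trace$time <= window[2]
    if (!any(keep)) stop("window contains no trace samples", call. = FALSE)
    trace <- trace[keep, ]
  }
  c(mean_X = mean(trace$mean_X), mean_Y = mean(trace$mean_Y),
    mean_Z = mean(trace$mean_Z), mean_A = mean(trace$mean_A))
}

#' Burst statistics of a simulation run
#'
#' Convenience pipeline: discards the settling transient, builds the
#' firing-rate time histogram, detects synchronous bursts with the
#' two-threshold rule and returns the burst statistics together with the
#' time-averaged astrocytic level over the analysed window.
#'
#' @param sim A `tuma_sim` object.
#' @param detection A [detection_params()] object; defaults to the one in
#'   the simulation config.
#' @param burn_in Transient to discard (ms).
#' @return A list: the [burst_stats()] fields plus `mean_A` and `n_bursts`.
#' @export
sim_burst_stats <- function(sim, detection = NULL, burn_in = 20000) {
  stopifnot(inherits(sim, "tuma_sim"))
  if (is.null(detection)) detection <- sim$config$detection
  raster <- trim_raster(sim$raster, burn_in)
  frth <- compute_frth(raster, detection$bin_width)
  bursts <- detect_sb(frth, detection)
  stats <- burst_stats(raster, bursts, attr(raster, "duration"))
  mean_A <- if (!is.null(sim$trace))
    unname(population_mean_states(sim$trace,
                                  c(burn_in, sim$config$duration))["mean_A"])
  else NA_real_
  c(stats, list(mean_A = mean_A))
}
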