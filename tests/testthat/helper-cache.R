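# Long network simulations are shared across test files through this cache
# (helpers persist for the whole test run). Seeds are fixed so every cached
# run is reproducible.
sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(tau_au = 250, seed = 1, mode = "tuma",
                       A_fixed = NA_real_, dt = 0.05, duration = 300000) {
  key <- paste(tau_au, seed, mode, signif(A_fixed, 8), dt, duration, sep = "|")
  if (is.null(sim_cache[[key]])) {
    cfg <- sim_config(duration = duration, dt = dt,
                      trace_stride = as.integer(round(1 / dt)),
                      mode = mode, A_fixed = A_fixed,
                      seeds = list(topology = 1000L + seed, dynamics = seed))
    cfg$synapse$tau_au <- tau_au
    sim_cache[[key]] <- run_simulation(cfg)
  }
  sim_cache[[key]]
}

cached_stats <- function(...) {
  sim_burst_stats(cached_sim(...))
}
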