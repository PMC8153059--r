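# Derive per-replicate seeds from the config's base seeds; kept additive and
# small so they stay well inside the 32-bit integer range.
replicate_seeds <- function(config, i) {
  list(topology = config$seeds$topology + 1000L * (i - 1L),
       dynamics = config$seeds$dynamics + (i - 1L))
}

with_sweep_cell <- function(config, tau_au, tau_g, seeds) {
  cfg <- config
  cfg$synapse$tau_au <- tau_au
  cfg$synapse$tau_g <- tau_g
  cfg$seeds <- seeds
  cfg
}

#' Sweep the astrocytic uptake and recycling timescales
#'
#' For every combination of `tau_au`, `tau_g` and replicate seed, runs the
#' network simulation, detects synchronous bursts and collects the burst
#' statistics together with the time-averaged astrocytic glutamate level.
#' Each replicate uses its own topology and dynamics seed derived from the
#' config's base seeds, so the table is deterministic. A cell that fails
#' numerically is kept in the table with its error message rather than
#' dropped.
#'
#' @param tau_au_values Astrocytic uptake times to sweep (ms).
#' @param tau_g_values Recycling (glutamate-glutamine) times to sweep (ms).
#' @param n_seeds Replicates per cell.
#' @param config Base [sim_config()].
#' @param burn_in Transient discarded before statistics (ms).
#' @return A long-format data.frame with columns `tau_au`, `tau_g`, `seed`,
#'   `firing_rate`, `sb_rate`, `sb_duration`, `sb_index`, `mean_A`,
#'   `n_bursts`, `error` (NA when the cell succeeded); exactly
#'   `length(tau_au_values) * length(tau_g_values) * n_seeds` rows.
#' @export
run_sweep <- function(tau_au_values, tau_g_values = 30000, n_seeds = 3,
                      config = sim_config(), burn_in = 20000) {
  stopifnot(length(tau_au_values) >= 1, length(tau_g_values) >= 1,
            n_seeds >= 1)
  grid <- expand.grid(seed = seq_len(n_seeds), tau_g = tau_g_values,
                      tau_au = tau_au_values)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    g <- grid[r, ]
    out <- data.frame(tau_au = g$tau_au, tau_g = g$tau_g, seed = g$seed,
                      firing_rate = NA_real_, sb_rate = NA_real_,
                      sb_duration = NA_real_, sb_index = NA_real_,
                      mean_A = NA_real_, n_bursts = NA_integer_,
                      error = NA_character_)
    res <- tryCatch({
      cfg <- with_sweep_cell(config, g$tau_au, g$tau_g,
                             replicate_seeds(config, g$seed))
      sim_burst_stats(run_simulation(cfg), burn_in = burn_in)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error <- conditionMessage(res)
    } else {
      out$firing_rate <- res$firing_rate
      out$sb_rate <- res$sb_rate
      out$sb_duration <- res$mean_sb_duration
      out$sb_index <- res$sb_index
      out$mean_A <- res$mean_A
      out$n_bursts <- res$n_bursts
    }
    out
  })
  do.call(rbind, rows)
}

#' Clamped-astrocyte control runs
#'
#' Runs the free four-state simulation, then the matching simulation with
#' the astrocytic fraction clamped, and reports both statistics rows plus
#' their relative differences. When `A_fixed` is omitted it is set to the
#' time-averaged astrocytic level of the free run, which is the control the
#' model predicts should leave the burst patterns unchanged.
#'
#' @param config Base [sim_config()] (free-run mode is forced to `"tuma"`).
#' @param A_fixed Clamped level; defaults to the free-run mean.
#' @param clamp_mode `"clamp"` (keep all fluxes) or `"reduced"` (hard
#'   three-state reduction).
#' @param burn_in Transient discarded before statistics (ms).
#' @return A list with `free` and `clamped` statistics, `A_fixed`, and
#'   `rel_diff`: named relative differences of SB rate, duration, firing
#'   rate and SB index (clamped vs free).
#' @export
run_fixed_a <- function(config = sim_config(), A_fixed = NULL,
                        clamp_mode = c("clamp", "reduced"),
                        burn_in = 20000) {
  clamp_mode <- match.arg(clamp_mode)
  cfg_free <- config
  cfg_free$mode <- "tuma"
  cfg_free$A_fixed <- NA_real_
  sim_free <- run_simulation(cfg_free)
  st_free <- sim_burst_stats(sim_free, burn_in = burn_in)
  if (is.null(A_fixed)) A_fixed <- st_free$mean_A
  cfg_cl <- config
  cfg_cl$mode <- clamp_mode
  cfg_cl$A_fixed <- A_fixed
  sim_cl <- run_simulation(cfg_cl, topology = sim_free$topology)
  st_cl <- sim_burst_stats(sim_cl, burn_in = burn_in)
  rel <- function(a, b) if (is.na(a) || is.na(b) || b == 0) NA_real_ else (a - b) / b
  list(free = st_free, clamped = st_cl, A_fixed = A_fixed,
       rel_diff = c(sb_rate = rel(st_cl$sb_rate, st_free$sb_rate),
                    sb_duration = rel(st_cl$mean_sb_duration,
                                      st_free$mean_sb_duration),
                    firing_rate = rel(st_cl$firing_rate, st_free$firing_rate),
                    sb_index = rel(st_cl$sb_index, st_free$sb_index)))
}

#' Run manifest
#'
#' Collects everything needed to reproduce a run bit-for-bit: the full
#' flattened configuration, the seeds and the package version.
#'
#' @param config A [sim_config()].
#' @return A list serialisable to JSON.
#' @export
run_manifest <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  list(package = "tumanet",
       version = as.character(utils::packageVersion("tumanet")),
       r_version = R.version.string,
       seeds = config$seeds,
       config = strip(config))
}
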