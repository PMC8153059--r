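#' Generate a synthetic MEA-like spike raster
#'
#' Emulates the structure of multielectrode-array recordings from cultured
#' networks: each unit fires homogeneous Poisson background spikes at a low
#' dormant-state rate, and network-wide burst epochs arrive as a Poisson
#' process; within each epoch every unit participates independently with
#' the given probability and fires Poisson at a high in-burst rate.
#' Overlapping epochs are merged (with a message). Ground-truth burst
#' windows are returned alongside the raster, so detection and statistics
#' can be checked against the generating parameters.
#'
#' @param n_units Number of units.
#' @param duration Recording length (ms).
#' @param background_rate Dormant-state rate per unit (Hz).
#' @param burst_rate Burst-epoch rate (min^-1).
#' @param burst_duration Epoch length (s).
#' @param in_burst_rate Per-unit firing rate inside an epoch (Hz). The
#'   default sits at the top of the observed 10-500 Hz multi-unit range so
#'   that the relative detection threshold `epsilon * R_max` stays well
#'   above typical background bin counts, which is the regime the
#'   two-threshold method is designed for.
#' @param participation Probability that a unit joins a given epoch.
#' @param seed Integer seed; the raster is fully determined by it.
#' @return A list with `raster` ([spike_raster()]) and `windows`
#'   (data.frame `t_s`, `t_e` in ms, merged ground-truth epochs).
#' @export
generate_fixture <- function(n_units = 14, duration = 600000,
                             background_rate = 1, burst_rate = 5,
                             burst_duration = 0.3, in_burst_rate = 500,
                             participation = 0.9, seed = 1L) {
  stopifnot(n_units >= 1, duration > 0, background_rate >= 0,
            burst_rate >= 0, burst_duration > 0, in_burst_rate >= 0,
            participation > 0, participation <= 1)
  withr::with_seed(seed, {
    dur_ms <- burst_duration * 1000
    n_epochs <- stats::rpois(1, burst_rate * duration / 60000)
    starts <- sort(stats::runif(n_epochs, 0, max(0, duration - dur_ms)))
    windows <- data.frame(t_s = starts, t_e = starts + dur_ms)
    if (nrow(windows) > 1) {
      overlap <- windows$t_s[-1] < windows$t_e[-nrow(windows)]
      if (any(overlap)) {
        message(sum(overlap), " overlapping burst epoch(s) merged")
        grp <- cumsum(c(TRUE, !overlap))
        windows <- data.frame(
          t_s = tapply(windows$t_s, grp, min),
          t_e = tapply(windows$t_e, grp, max))
        rownames(windows) <- NULL
      }
    }
    unit <- integer()
    time <- numeric()
    for (i in seq_len(n_units)) {
      n_bg <- stats::rpois(1, background_rate * duration / 1000)
      t_i <- stats::runif(n_bg, 0, duration)
      for (k in seq_len(nrow(windows))) {
        if (stats::runif(1) > participation) next
        len <- windows$t_e[k] - windows$t_s[k]
        n_in <- stats::rpois(1, in_burst_rate * len / 1000)
        t_i <- c(t_i, stats::runif(n_in, windows$t_s[k], windows$t_e[k]))
      }
      unit <- c(unit, rep.int(i, length(t_i)))
      time <- c(time, t_i)
    }
    list(raster = spike_raster(unit, time, n_units = n_units,
                               duration = duration),
         windows = windows)
  })
}
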