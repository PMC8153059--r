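#' Build a random excitatory/inhibitory network
#'
#' Each ordered pair of distinct neurons is connected independently with
#' probability `p_connect`. Exactly `round(inh_ratio * n)` neurons, chosen
#' uniformly, are labelled inhibitory. Weights are drawn from a Gaussian
#' with mean `w_mean` and standard deviation `w_mean * w_width_frac`,
#' truncated (by rejection) to
#' `[w_mean (1 - w_width_frac), w_mean (1 + w_width_frac)]`. The result is
#' fully determined by `seed`.
#'
#' @param n Number of neurons (>= 2).
#' @param p_connect Connection probability in (0, 1).
#' @param inh_ratio Inhibitory fraction in `[0, 1)`.
#' @param w_mean Mean synaptic weight.
#' @param w_width_frac Truncation half-width as a fraction of the mean.
#' @param seed Integer seed.
#' @return An object of class `network_topology`: a list with `n_neurons`,
#'   logical `is_inhibitory`, an `edges` data.frame (`pre`, `post`,
#'   `weight`) and the `seed`.
#' @export
build_random_network <- function(n = 100, p_connect = 0.1, inh_ratio = 0.2,
                                 w_mean = 4, w_width_frac = 0.2, seed = 1L) {
  if (n < 2) stop("need at least 2 neurons", call. = FALSE)
  stopifnot(p_connect > 0, p_connect < 1, inh_ratio >= 0, inh_ratio < 1)
  withr::with_seed(seed, {
    conn <- matrix(stats::runif(n * n) < p_connect, n, n)
    diag(conn) <- FALSE
    idx <- which(conn, arr.ind = TRUE)  # row = pre, col = post
    n_edges <- nrow(idx)
    lo <- w_mean * (1 - w_width_frac)
    hi <- w_mean * (1 + w_width_frac)
    w <- numeric(n_edges)
    need <- seq_len(n_edges)
    while (length(need)) {
      w[need] <- stats::rnorm(length(need), w_mean, w_mean * w_width_frac)
      need <- need[w[need] < lo | w[need] > hi]
    }
    n_inh <- round(inh_ratio * n)
    inh <- rep(FALSE, n)
    if (n_inh > 0) inh[sample.int(n, n_inh)] <- TRUE
    structure(list(n_neurons = as.integer(n), is_inhibitory = inh,
                   edges = data.frame(pre = idx[, 1], post = idx[, 2],
                                      weight = w),
                   seed = as.integer(seed)),
              class = "network_topology")
  })
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf("<network_topology> %d neurons (%d inhibitory), %d directed edges, seed %d\n",
              x$n_neurons, sum(x$is_inhibitory), nrow(x$edges), x$seed))
  invisible(x)
}

#' Postsynaptic conductances from per-edge active fractions
#'
#' For each postsynaptic neuron, the weighted sum `sum_j w_ji Y_ji (1 - b Y_ji)`
#' over its afferent edges, split into the excitatory and inhibitory
#' components (edges from inhibitory presynaptic neurons). Each component
#' drives a current `G * (V_rev - V)` with the matching reversal potential.
#'
#' @param Y Per-edge active fractions, aligned with `topo$edges`.
#' @param topo A [build_random_network()] topology.
#' @param b Postsynaptic saturation factor.
#' @return A list with numeric vectors `G_exc` and `G_inh` of length
#'   `topo$n_neurons`.
#' @export
synaptic_conductance <- function(Y, topo, b = 0) {
  stopifnot(inherits(topo, "network_topology"),
            length(Y) == nrow(topo$edges))
  contrib <- topo$edges$weight * Y * (1 - b * Y)
  inh_pre <- topo$is_inhibitory[topo$edges$pre]
  G_exc <- numeric(topo$n_neurons)
  G_inh <- numeric(topo$n_neurons)
  if (any(!inh_pre)) {
    sums <- rowsum(contrib[!inh_pre], topo$edges$post[!inh_pre])
    G_exc[as.integer(rownames(sums))] <- sums[, 1]
  }
  if (any(inh_pre)) {
    sums <- rowsum(contrib[inh_pre], topo$edges$post[inh_pre])
    G_inh[as.integer(rownames(sums))] <- sums[, 1]
  }
  list(G_exc = G_exc, G_inh = G_inh)
}

#' Spike raster objects
#'
#' A spike raster is a data.frame with columns `unit` (integer id) and
#' `time` (ms), carrying the number of units and the recording duration as
#' attributes. Spike times are sorted within each unit.
#'
#' @param unit Integer unit ids.
#' @param time Spike times (ms) in `[0, duration]`.
#' @param n_units Number of units in the recording (may exceed the number
#'   of units that fired).
#' @param duration Recording duration (ms).
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(unit, time, n_units, duration) {
  stopifnot(length(unit) == length(time), duration > 0)
  if (length(time) && (min(time) < 0 || max(time) > duration))
    stop("spike times must lie in [0, duration]", call. = FALSE)
  o <- order(unit, time)
  df <- data.frame(unit = as.integer(unit[o]), time = as.numeric(time[o]))
  structure(df, n_units = as.integer(n_units), duration = as.numeric(duration),
            class = c("spike_raster", "data.frame"))
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d spikes from %d units over %.1f s\n",
              nrow(x), attr(x, "n_units"), attr(x, "duration") / 1000))
  invisible(x)
}

#' Drop an initial transient from a raster
#'
#' Removes spikes before `t_start` and re-zeroes time, shortening the
#' recorded duration accordingly. Used to discard the settling transient
#' before computing burst statistics.
#'
#' @param raster A [spike_raster()].
#' @param t_start Cut point (ms).
#' @return A [spike_raster()] covering `[0, duration - t_start]`.
#' @export
trim_raster <- function(raster, t_start) {
  dur <- attr(raster, "duration")
  stopifnot(t_start >= 0, t_start < dur)
  keep <- raster$time >= t_start
  spike_raster(raster$unit[keep], raster$time[keep] - t_start,
               n_units = attr(raster, "n_units"), duration = dur - t_start)
}
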