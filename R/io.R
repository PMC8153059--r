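#' Spike raster CSV input/output
#'
#' Rasters are stored as two-column CSV (`unit`, `time_ms`), one row per
#' spike, with a header line. `read_raster()` also accepts the simple
#' multi-unit export dialect in which each column holds the spike times of
#' one unit (header per column, rows padded with empty cells).
#'
#' @param raster A [spike_raster()].
#' @param path File path.
#' @param n_units,duration Metadata for reading; inferred from the data
#'   when omitted (`n_units` from the largest id, `duration` from the last
#'   spike).
#' @return `read_raster()` returns a [spike_raster()]; `write_raster()`
#'   returns `path` invisibly.
#' @export
write_raster <- function(raster, path) {
  utils::write.csv(data.frame(unit = raster$unit, time_ms = raster$time),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path, n_units = NULL, duration = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (all(c("unit", "time_ms") %in% names(df))) {
    unit <- df$unit
    time <- df$time_ms
  } else {
    # one column of spike times per unit
    unit <- rep(seq_along(df), times = vapply(df, function(x) sum(!is.na(x)), 0L))
    time <- unlist(lapply(df, function(x) x[!is.na(x)]), use.names = FALSE)
  }
  if (is.null(n_units)) n_units <- max(unit, 1L)
  if (is.null(duration)) duration <- max(time, 1)
  spike_raster(unit, time, n_units = n_units, duration = duration)
}

#' Topology edge-list CSV input/output
#'
#' Edge-list CSV with columns `pre`, `post`, `weight`,
#' `is_inhibitory_pre`. The per-neuron inhibitory labels are reconstructed
#' from the edge flags on reading; neurons without efferent edges are
#' assumed excitatory.
#'
#' @param topo A [build_random_network()] topology.
#' @param path File path.
#' @param n_neurons Neuron count for reading; inferred from the largest id
#'   when omitted.
#' @return `read_topology()` returns a `network_topology`;
#'   `write_topology()` returns `path` invisibly.
#' @export
write_topology <- function(topo, path) {
  utils::write.csv(
    data.frame(pre = topo$edges$pre, post = topo$edges$post,
               weight = topo$edges$weight,
               is_inhibitory_pre = topo$is_inhibitory[topo$edges$pre]),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path, n_neurons = NULL) {
  df <- utils::read.csv(path)
  if (is.null(n_neurons)) n_neurons <- max(df$pre, df$post)
  inh <- rep(FALSE, n_neurons)
  inh[unique(df$pre[df$is_inhibitory_pre])] <- TRUE
  structure(list(n_neurons = as.integer(n_neurons), is_inhibitory = inh,
                 edges = data.frame(pre = df$pre, post = df$post,
                                    weight = df$weight),
                 seed = NA_integer_),
            class = "network_topology")
}

#' Write detected bursts and statistics
#'
#' @param bursts A [detect_sb()] result.
#' @param stats A [burst_stats()] result.
#' @param path File path (CSV for bursts; `.json` or `.csv` for stats).
#' @return `path`, invisibly.
#' @export
write_bursts <- function(bursts, path) {
  utils::write.csv(data.frame(t_s_ms = bursts$t_s, t_e_ms = bursts$t_e),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bursts
#' @export
write_stats <- function(stats, path) {
  out <- list(firing_rate = stats$firing_rate, sb_rate = stats$sb_rate,
              sb_duration = stats$mean_sb_duration,
              sb_index = stats$sb_index, n_bursts = stats$n_bursts)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(out), path, row.names = FALSE)
  }
  invisible(path)
}

#' Export a state trace to CSV
#'
#' @param trace A state trace data.frame from [run_simulation()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
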