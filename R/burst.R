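#' Firing-rate time histogram
#'
#' Counts spikes from all units in half-open bins
#' `[t0 + k*bin, t0 + (k+1)*bin)`: a spike exactly on a boundary counts in
#' the later bin.
#'
#' @param raster A [spike_raster()].
#' @param bin_width Bin width (ms).
#' @param t0 Histogram origin (ms).
#' @return An object of class `frth`: list with `bin_width`, integer
#'   `counts` and `t0`.
#' @export
compute_frth <- function(raster, bin_width = 10, t0 = 0) {
  stopifnot(bin_width > 0)
  duration <- attr(raster, "duration")
  n_bins <- max(1L, as.integer(ceiling((duration - t0) / bin_width)))
  if (nrow(raster) == 0) {
    warning("empty raster: all-zero histogram")
    return(structure(list(bin_width = bin_width,
                          counts = integer(n_bins), t0 = t0),
                     class = "frth"))
  }
  idx <- floor((raster$time - t0) / bin_width) + 1
  keep <- idx >= 1 & idx <= n_bins + 1
  idx <- pmin(idx[keep], n_bins)  # spike at t == duration joins the last bin
  structure(list(bin_width = bin_width,
                 counts = tabulate(idx, nbins = n_bins), t0 = t0),
            class = "frth")
}

#' @export
print.frth <- function(x, ...) {
  cat(sprintf("<frth> %d bins of %g ms, %d spikes, peak %d\n",
              length(x$counts), x$bin_width, sum(x$counts),
              if (length(x$counts)) max(x$counts) else 0L))
  invisible(x)
}

#' Interspike-interval return map
#'
#' Pairs of consecutive interspike intervals `(ISI_k, ISI_k+1)` of one
#' unit, used to separate in-burst firing (short intervals) from tonic
#' background firing (long intervals).
#'
#' @param times Spike times of a single unit (ms).
#' @return data.frame with columns `isi_k`, `isi_k1`; empty if fewer than
#'   3 spikes.
#' @export
isi_return_map <- function(times) {
  if (length(times) < 3)
    return(data.frame(isi_k = numeric(), isi_k1 = numeric()))
  d <- diff(sort(times))
  data.frame(isi_k = d[-length(d)], isi_k1 = d[-1])
}

#' Two-threshold synchronous-burst detection
#'
#' Detection operates on the firing-rate time histogram. With
#' `R_max` the maximal bin count of the recording: bins at or above
#' `epsilon * R_max` mark the network active; runs of active bins separated
#' by less than `tau_rest` of quiescence are merged into one candidate; a
#' candidate becomes a burst only if at least one of its bins reaches
#' `delta * R_max`. The burst spans from the start of its first active bin
#' to the end of its last.
#'
#' @param frth A [compute_frth()] histogram.
#' @param p A [detection_params()] object (its `bin_width` should match the
#'   histogram's).
#' @return An object of class `burst_events`: data.frame with columns
#'   `t_s`, `t_e` (ms), chronological and non-overlapping; empty for an
#'   all-zero histogram.
#' @export
detect_sb <- function(frth, p = detection_params()) {
  stopifnot(inherits(frth, "frth"), inherits(p, "detection_params"))
  counts <- frth$counts
  bin <- frth$bin_width
  out <- data.frame(t_s = numeric(), t_e = numeric())
  R_max <- if (length(counts)) max(counts) else 0L
  if (R_max == 0)
    return(structure(out, class = c("burst_events", "data.frame")))
  active <- counts >= p$epsilon * R_max
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(seg) > 1) {
    # merge segments separated by less than tau_rest of below-threshold bins
    gap_bins <- seg$start[-1] - seg$end[-nrow(seg)] - 1
    merge_up <- gap_bins * bin < p$tau_rest
    grp <- cumsum(c(TRUE, !merge_up))
    seg <- data.frame(start = tapply(seg$start, grp, min),
                      end = tapply(seg$end, grp, max))
  }
  if (nrow(seg)) {
    peak <- vapply(seq_len(nrow(seg)),
                   function(i) max(counts[seg$start[i]:seg$end[i]]), 0L)
    seg <- seg[peak >= p$delta * R_max, , drop = FALSE]
  }
  out <- data.frame(t_s = frth$t0 + (seg$start - 1) * bin,
                    t_e = frth$t0 + seg$end * bin)
  rownames(out) <- NULL
  structure(out, class = c("burst_events", "data.frame"))
}

#' Synchronous-burst index
#'
#' Fraction of all spikes that fall inside detected burst windows
#' (boundaries inclusive). An index of 0.5 means half of the array-wide
#' spiking occurred as synchronous bursts.
#'
#' @param raster A [spike_raster()].
#' @param bursts A [detect_sb()] result (non-overlapping windows).
#' @return A fraction in `[0, 1]`.
#' @export
sb_index <- function(raster, bursts) {
  n_total <- nrow(raster)
  if (n_total == 0)
    stop("SB index undefined: raster contains no spikes", call. = FALSE)
  if (nrow(bursts) == 0) return(0)
  inside <- rep(FALSE, n_total)
  for (i in seq_len(nrow(bursts)))
    inside <- inside | (raster$time >= bursts$t_s[i] &
                          raster$time <= bursts$t_e[i])
  sum(inside) / n_total
}

#' Burst statistics
#'
#' Array-wide firing rate, burst rate, mean burst duration and burst index
#' of a recording.
#'
#' @param raster A [spike_raster()].
#' @param bursts A [detect_sb()] result.
#' @param duration Recording duration (ms); defaults to the raster's.
#' @return A list of class `burst_stats`: `firing_rate` (spikes/s,
#'   array-wide), `sb_rate` (min^-1), `mean_sb_duration` (s; `NA` with no
#'   bursts), `sb_index`, `n_bursts`.
#' @export
burst_stats <- function(raster, bursts, duration = attr(raster, "duration")) {
  stopifnot(duration > 0)
  n_b <- nrow(bursts)
  structure(list(
    firing_rate = nrow(raster) / (duration / 1000),
    sb_rate = n_b / (duration / 60000),
    mean_sb_duration = if (n_b) mean(bursts$t_e - bursts$t_s) / 1000 else NA_real_,
    sb_index = if (nrow(raster)) sb_index(raster, bursts) else NA_real_,
    n_bursts = n_b), class = "burst_stats")
}

#' @export
print.burst_stats <- function(x, ...) {
  cat(sprintf("<burst_stats> firing rate %.2f spikes/s | SB rate %.2f min^-1 | SB duration %.3f s | SB index %.3f (%d bursts)\n",
              x$firing_rate, x$sb_rate, x$mean_sb_duration, x$sb_index,
              x$n_bursts))
  invisible(x)
}

#' Detrended relative fluorescence change
#'
#' Removes drift and photo-bleaching by fitting a polynomial (default
#' degree 3) to the intensity series and subtracting it, then scales by the
#' mean intensity: `dF/F = (F_t - trend) / mean(F)`. The output has mean
#' approximately zero.
#'
#' @param F_t Sampled fluorescence intensity (uniform sampling assumed).
#' @param times Optional sample times; defaults to the sample index.
#' @param degree Detrending polynomial degree.
#' @return Numeric dF/F series of the same length.
#' @export
delta_f_over_f <- function(F_t, times = seq_along(F_t), degree = 3) {
  stopifnot(length(F_t) >= 10, length(times) == length(F_t), degree >= 0)
  F_bar <- mean(F_t)
  if (isTRUE(all.equal(stats::sd(F_t), 0)) || F_bar == 0)
    return(rep(0, length(F_t)))
  fit <- stats::lm(F_t ~ stats::poly(times, degree, raw = TRUE))
  unname(stats::residuals(fit)) / F_bar
}

#' Transient decay time from half-life
#'
#' Locates the maximum of a dF/F transient, finds the first crossing of
#' half the peak value after it (linearly interpolated between samples),
#' and converts the half-decay time to an exponential time constant:
#' `tau_decay = tau_half / ln 2`.
#'
#' @param signal dF/F values around one transient.
#' @param times Sample times; units of the result (use seconds for a decay
#'   time in seconds).
#' @return Decay time in the units of `times`.
#' @export
tau_decay <- function(signal, times = seq_along(signal)) {
  stopifnot(length(signal) == length(times), length(signal) >= 3)
  ipk <- which.max(signal)
  half <- signal[ipk] / 2
  after <- seq(ipk, length(signal))
  below <- after[signal[after] <= half]
  if (!length(below))
    stop("signal never decays below half-peak; decay time undefined",
         call. = FALSE)
  j <- below[1]
  if (j == ipk) return(0)
  # linear interpolation between the last above-half and first below-half sample
  frac <- (signal[j - 1] - half) / (signal[j - 1] - signal[j])
  t_half <- (times[j - 1] + frac * (times[j] - times[j - 1])) - times[ipk]
  t_half / log(2)
}
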