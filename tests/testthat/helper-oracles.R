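# Independent reference implementations used as oracles.

# Brute-force two-threshold burst detector: explicit state-machine scan over
# the histogram, independent of the vectorised implementation in the package.
brute_detect <- function(counts, bin, epsilon = 0.04, delta = 0.2,
                         tau_rest = 1000, t0 = 0) {
  empty <- data.frame(t_s = numeric(), t_e = numeric())
  R_max <- if (length(counts)) max(counts) else 0
  if (R_max == 0) return(empty)
  thr_lo <- epsilon * R_max
  thr_hi <- delta * R_max
  segs <- list()
  cur <- NA
  for (i in seq_along(counts)) {
    if (counts[i] >= thr_lo) {
      if (is.na(cur)) cur <- i
    } else if (!is.na(cur)) {
      segs[[length(segs) + 1]] <- c(cur, i - 1)
      cur <- NA
    }
  }
  if (!is.na(cur)) segs[[length(segs) + 1]] <- c(cur, length(counts))
  merged <- list()
  for (s in segs) {
    if (length(merged)) {
      prev <- merged[[length(merged)]]
      if ((s[1] - prev[2] - 1) * bin < tau_rest) {
        merged[[length(merged)]][2] <- s[2]
        next
      }
    }
    merged[[length(merged) + 1]] <- s
  }
  keep <- Filter(function(s) max(counts[s[1]:s[2]]) >= thr_hi, merged)
  if (!length(keep)) return(empty)
  data.frame(t_s = t0 + (vapply(keep, `[`, 0, 1) - 1) * bin,
             t_e = t0 + vapply(keep, `[`, 0, 2) * bin)
}

# random burst-like histograms for the detector equivalence check
random_frth <- function(n_bins = 300, bin = 10) {
  counts <- rpois(n_bins, 0.5)
  for (k in seq_len(rpois(1, 4) + 1)) {
    at <- sample(n_bins, 1)
    len <- sample(1:20, 1)
    idx <- at:min(n_bins, at + len)
    counts[idx] <- counts[idx] + rpois(length(idx), sample(c(5, 20, 60), 1))
  }
  structure(list(bin_width = bin, counts = as.integer(counts), t0 = 0),
            class = "frth")
}

# deSolve reference for the single-neuron membrane equations
ml_ode_reference <- function(p, I_bg, times, V0 = p$V_L, W0 = NULL) {
  if (is.null(W0)) W0 <- gate_steady_states(V0, p)$W_inf
  rhs <- function(t, y, parms) {
    V <- y[1]; W <- y[2]
    g <- gate_steady_states(V, p)
    I_ion <- p$g_Ca * g$m_inf * (V - p$V_Ca) + p$g_K * W * (V - p$V_K) +
      p$g_L * (V - p$V_L)
    list(c((-I_ion + I_bg) / p$C,
           p$theta * (g$W_inf - W) / g$tau_W))
  }
  deSolve::ode(c(V = V0, W = W0), times, rhs, NULL,
               method = "lsoda", rtol = 1e-10, atol = 1e-10)
}
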