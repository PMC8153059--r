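mk_raster <- function(times, unit = 1, duration = max(times) + 1,
                      n_units = max(unit)) {
  spike_raster(rep_len(unit, length(times)), times, n_units, duration)
}

test_that("the firing-rate histogram uses half-open bins", {
  r <- mk_raster(c(1, 2, 3), duration = 10)
  expect_equal(compute_frth(r, 10)$counts, 3L)
  # a spike exactly on a boundary belongs to the later bin
  r <- mk_raster(c(5, 10), duration = 30)
  expect_equal(compute_frth(r, 10)$counts, c(1L, 1L, 0L))
  withr::with_seed(1, {
    r <- mk_raster(runif(1000, 0, 10000), duration = 10000)
  })
  expect_equal(sum(compute_frth(r, 10)$counts), 1000L)
  empty <- spike_raster(integer(), numeric(), 3, 1000)
  expect_warning(f0 <- compute_frth(empty, 10), "empty")
  expect_true(all(f0$counts == 0L))
})

test_that("ISI return maps pair consecutive intervals and separate regimes", {
  expect_equal(isi_return_map(c(0, 10, 20, 30)),
               data.frame(isi_k = c(10, 10), isi_k1 = c(10, 10)))
  expect_equal(isi_return_map(c(0, 5, 100)),
               data.frame(isi_k = 5, isi_k1 = 95))
  expect_identical(nrow(isi_return_map(c(1, 2))), 0L)
  # bursty unit plus tonic background: intervals split into a short-ISI
  # cluster (in-burst) and a long-ISI cluster (dormant), none in between
  withr::with_seed(5, {
    bursts <- lapply(seq(0, 540000, 12000),
                     function(t0) t0 + cumsum(rexp(20, 1 / 20)))
    times <- sort(unlist(bursts))
  })
  m <- isi_return_map(times)
  short <- m$isi_k < 250
  long <- m$isi_k > 1000
  expect_gt(sum(short), 100)
  expect_gt(sum(long), 10)
  expect_identical(sum(!short & !long), 0L)
})

test_that("two-threshold detection finds, rejects and merges candidates", {
  p <- detection_params()  # epsilon 0.04, delta 0.2, tau_rest 1 s, 10-ms bins
  mk_frth <- function(counts) structure(
    list(bin_width = 10, counts = as.integer(counts), t0 = 0), class = "frth")
  # isolated rectangular pulse at the maximum spans one event
  counts <- c(rep(0, 200), rep(100, 20), rep(0, 200))
  b <- detect_sb(mk_frth(counts), p)
  expect_equal(nrow(b), 1L)
  expect_equal(b$t_s, 2000)
  expect_equal(b$t_e, 2200)
  # a pulse below the upper threshold is rejected
  counts2 <- c(counts, rep(10, 5), rep(0, 200))
  b2 <- detect_sb(mk_frth(counts2), p)
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$t_e, 2200)
  # two pulses 400 ms apart merge into one event
  counts3 <- c(rep(0, 150), rep(100, 10), rep(0, 40), rep(100, 10), rep(0, 150))
  b3 <- detect_sb(mk_frth(counts3), p)
  expect_equal(nrow(b3), 1L)
  expect_equal(b3$t_s, 1500)
  expect_equal(b3$t_e, 2100)
  # all-zero histogram yields no events
  expect_identical(nrow(detect_sb(mk_frth(rep(0, 50)), p)), 0L)
})

test_that("detection agrees with the brute-force reference on random histograms", {
  p <- detection_params()
  withr::with_seed(101, {
    for (k in 1:200) {
      f <- random_frth()
      got <- detect_sb(f, p)
      ref <- brute_detect(f$counts, f$bin_width, p$epsilon, p$delta, p$tau_rest)
      expect_equal(unname(as.matrix(got)), unname(as.matrix(ref)))
    }
  })
})

test_that("the burst index counts the in-burst fraction of spikes", {
  b <- data.frame(t_s = c(100, 1000), t_e = c(300, 1400))
  r_in <- mk_raster(c(150, 200, 300, 1000, 1200), duration = 2000)
  expect_equal(sb_index(r_in, b), 1)  # boundaries inclusive
  expect_equal(sb_index(r_in, b[0, ]), 0)
  withr::with_seed(2, {
    t_in <- runif(80, 100, 300)
    t_out <- runif(20, 400, 900)
  })
  r <- mk_raster(c(t_in, t_out), duration = 2000)
  expect_equal(sb_index(r, b), 0.8)
  expect_error(sb_index(mk_raster(numeric(), duration = 10), b), "no spikes")
})

test_that("the burst index is invariant to relabeling and time shifts", {
  withr::with_seed(31, {
    fx <- generate_fixture(n_units = 6, duration = 60000, seed = 13)
    r <- fx$raster
    frth <- compute_frth(r, 10)
    b <- detect_sb(frth, detection_params())
    base <- sb_index(r, b)
    # unit relabeling
    perm <- sample(6)
    r2 <- spike_raster(perm[r$unit], r$time, 6, attr(r, "duration"))
    expect_equal(sb_index(r2, b), base)
    # time translation of raster and windows together
    r3 <- spike_raster(r$unit, r$time + 500, 6, attr(r, "duration") + 500)
    b3 <- b; b3$t_s <- b$t_s + 500; b3$t_e <- b$t_e + 500
    expect_equal(sb_index(r3, b3), base)
    # spikes added inside windows cannot decrease it; outside cannot increase
    extra_in <- runif(50, b$t_s[1], b$t_e[1])
    r_in <- spike_raster(c(r$unit, rep(1L, 50)), c(r$time, extra_in), 6,
                         attr(r, "duration"))
    expect_gte(sb_index(r_in, b), base)
    gap_t <- b$t_e[1] + 1 + runif(50) * 1  # strictly between windows
    r_out <- spike_raster(c(r$unit, rep(1L, 50)), c(r$time, gap_t), 6,
                          attr(r, "duration"))
    expect_lte(sb_index(r_out, b), base)
  })
})

test_that("burst statistics convert counts and durations to standard units", {
  withr::with_seed(3, r <- mk_raster(runif(600, 0, 60000), duration = 60000))
  b <- data.frame(t_s = seq(1000, 50000, length.out = 5),
                  t_e = seq(1000, 50000, length.out = 5) + 250)
  st <- burst_stats(r, b)
  expect_equal(st$firing_rate, 10)
  expect_equal(st$sb_rate, 5)
  expect_equal(st$mean_sb_duration, 0.25)
  expect_identical(st$n_bursts, 5L)
  st0 <- burst_stats(r, b[0, ])
  expect_equal(st0$sb_rate, 0)
  expect_true(is.na(st0$mean_sb_duration))
  expect_equal(st0$sb_index, 0)
})

test_that("dF/F detrending removes drift and preserves planted transients", {
  tt <- seq(0, 60, by = 0.04)
  ramp <- 1000 + 5 * tt
  out <- delta_f_over_f(ramp, tt)
  expect_lt(max(abs(out)), 1e-10)
  expect_equal(delta_f_over_f(rep(500, 100)), rep(0, 100))
  # transient of amplitude a * mean(F) on a bleaching trend
  a <- 0.15
  trend <- 1200 * exp(-tt / 300)
  transient <- a * mean(trend) * exp(-(tt - 30)^2 / 0.5)
  out <- delta_f_over_f(trend + transient, tt)
  expect_equal(max(out), a, tolerance = 0.05)
  expect_lt(abs(mean(out)), 1e-10)
})

test_that("decay time is the half-life over log 2", {
  # construct a transient whose half-crossing lands exactly at tau_half
  tt <- seq(0, 10, by = 0.001)
  sig <- ifelse(tt < 1, tt, exp(-(tt - 1) * log(2) / 0.6931))
  expect_equal(tau_decay(sig, tt), 1, tolerance = 1e-3)
  # pure exponential decay with time constant tau returns tau
  tau <- 0.26
  sig <- exp(-tt / tau)
  expect_equal(tau_decay(sig, tt), tau, tolerance = 0.01)
  sig <- ifelse(tt < 1, tt, exp(-(tt - 1) * log(2) / 0.18))
  expect_equal(tau_decay(sig, tt), 0.18 / log(2), tolerance = 1e-3)
  expect_equal(0.18 / log(2), 0.2597, tolerance = 1e-4)
  expect_error(tau_decay(c(0.1, 1, 0.9, 0.8), 1:4), "half-peak")
})
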