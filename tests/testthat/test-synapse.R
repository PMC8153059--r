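test_that("three-state decay follows the closed-form linear solution", {
  p <- synapse_params(tau_d = 3, tau_r = 600)
  s <- synapse_state(X = 1, Y = 0, Z = 0, A = NULL)
  expect_equal(tum_decay_step(s, p, 50), s)        # ready pool is absorbing
  s <- synapse_state(X = 0, Y = 1, Z = 0, A = NULL)
  expect_equal(unname(tum_decay_step(s, p, 1e9)), c(1, 0, 0), tolerance = 1e-9)
  out <- tum_decay_step(s, p, 3)                    # one decay time elapsed
  expect_equal(out[["Y"]], exp(-1), tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  # cross-check the matrix exponential against an adaptive ODE solve
  K <- tum_decay_matrix(p)
  ref <- deSolve::ode(c(X = 0, Y = 1, Z = 0), c(0, 3),
                      function(t, y, ...) list(drop(K %*% y)),
                      NULL, rtol = 1e-11, atol = 1e-12)
  expect_equal(unname(out), unname(ref[2, 2:4]), tolerance = 1e-8)
})

test_that("four-state decay conserves mass and splits uptake by timescale", {
  p <- synapse_params(tau_nu = 50, tau_au = 250, tau_g = 1e9)
  s0 <- synapse_state()
  expect_equal(tuma_decay_step(s0, p, 100), s0)
  s <- synapse_state(X = 0, Y = 1, Z = 0, A = 0)
  expect_equal(unname(tuma_decay_step(s, p, 1e12)), c(1, 0, 0, 0),
               tolerance = 1e-9)
  tau_e <- 1 / (1 / 50 + 1 / 250)                   # combined decay time
  out <- tuma_decay_step(s, p, tau_e)
  expect_equal(out[["Y"]], exp(-1), tolerance = 1e-12)
  # the astrocytic branch receives tau_nu/(tau_nu + tau_au) = 1/6 of the
  # decayed mass (tau_g here is effectively infinite)
  expect_equal(out[["A"]], (1 - exp(-1)) / 6, tolerance = 1e-6)
  expect_equal(sum(out), 1, tolerance = 1e-12)
})

test_that("release events transfer the released fraction exactly", {
  s <- synapse_state()
  out <- apply_synchronous_release(s, 0.2)
  expect_equal(unname(out), c(0.8, 0.2, 0, 0))
  out2 <- apply_synchronous_release(out, 0.2)
  expect_equal(out2[["X"]], 0.64)
  expect_equal(sum(out2), 1)
  empty <- synapse_state(X = 0, Y = 0.3, Z = 0.7, A = 0)
  expect_equal(apply_synchronous_release(empty, 0.2), empty)

  s <- synapse_state(X = 0.5, Y = 0, Z = 0.5, A = 0)
  out <- apply_asynchronous_release(s, 0.02)
  expect_equal(out[["Y"]], 0.01)
  expect_equal(apply_asynchronous_release(s, 0), s)
  out <- apply_asynchronous_release(s, 1)
  expect_equal(out[["X"]], 0)
  expect_equal(out[["Y"]], 0.5)
})

test_that("clamped astrocytic pool keeps fluxes and feeds the ready pool", {
  p <- synapse_params()
  s <- synapse_state(X = 0.3, Y = 0, Z = 0, A = 0.7)
  # with Y = Z = 0 the only flux is the clamped pool feeding Z then X
  out <- s
  for (k in 1:2000) out <- tuma_clamped_step(out, 0.7, p, 10)
  expect_gt(out[["X"]], s[["X"]])
  expect_equal(out[["A"]], 0.7)
  # with A clamped at 0 the astrocytic uptake flux leaves the presynaptic
  # system: after all active glutamate has cleared, the presynaptic total
  # has lost exactly the astrocytic share tau_nu/(tau_nu + tau_au) of Y
  p2 <- synapse_params(tau_g = 1e12)
  s4 <- synapse_state(X = 0.2, Y = 0.5, Z = 0.3, A = 0)
  for (k in 1:50) s4 <- tuma_clamped_step(s4, 0, p2, 100)
  expect_equal(sum(s4[1:3]), 1 - 0.5 / 6, tolerance = 1e-6)
  expect_lt(s4[["Y"]], 1e-12)
  # the hard "reduced" mode equals that three-state model by construction
  s4r <- synapse_state(X = 0.2, Y = 0.5, Z = 0.3, A = 0)
  for (k in 1:50) s4r <- tuma_clamped_step(s4r, 0, p, 7, mode = "reduced")
  s3r <- synapse_state(X = 0.2, Y = 0.5, Z = 0.3, A = NULL)
  p_red <- synapse_params(tau_d = 1 / (1 / p$tau_nu + 1 / p$tau_au))
  for (k in 1:50) s3r <- tum_decay_step(s3r, p_red, 7)
  expect_equal(unname(s4r[1:3]), unname(s3r), tolerance = 1e-12)
})

test_that("event-driven trajectories conserve total glutamate to 1e-9", {
  p <- synapse_params()
  withr::with_seed(42, {
    spikes <- cumsum(rexp(1500, 1 / 200))            # ~5 Hz for 300 s
    async <- cumsum(rexp(6000, 1 / 50))
  })
  tr <- simulate_synapse(spikes, p, duration = 300000, dt = 1,
                         async_times = async)
  total <- tr$X + tr$Y + tr$Z + tr$A
  expect_lt(max(abs(total - 1)), 1e-9)
  rng <- range(as.matrix(tr[, c("X", "Y", "Z", "A")]))
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 1)
})

test_that("with astrocytic uptake switched off the four-state model reduces to the three-state one", {
  p4 <- synapse_params(tau_au = 1e12)
  p3 <- synapse_params(tau_d = p4$tau_nu)
  spikes <- seq(200, 10000, by = 200)                # 5 Hz for 10 s
  tr4 <- simulate_synapse(spikes, p4, duration = 10000, dt = 0.05)
  tr3 <- simulate_synapse(spikes, p3, duration = 10000, dt = 0.05,
                          mode = "tum")
  err <- max(abs(as.matrix(tr4[, c("X", "Y", "Z")]) -
                   as.matrix(tr3[, c("X", "Y", "Z")])))
  expect_lt(err, 1e-6)
  expect_lt(max(tr4$A), 1e-6)
})

test_that("exact and Euler updates agree to first order in dt", {
  p <- synapse_params()
  s <- synapse_state(X = 0.4, Y = 0.3, Z = 0.2, A = 0.1)
  exact <- tuma_decay_step(s, p, 0.01)
  euler <- tuma_decay_step(s, p, 0.01, method = "euler")
  expect_equal(unname(exact), unname(euler), tolerance = 1e-6)
})

test_that("the analytic eigendecomposition reproduces the generator", {
  p <- synapse_params()
  for (mode in c("tuma", "tum", "reduced")) {
    eig <- tumanet:::synapse_eigen(p, mode)
    K <- eig$P %*% diag(eig$lambda) %*% eig$Pinv
    K_ref <- switch(mode,
      tuma = tuma_decay_matrix(p),
      tum = tum_decay_matrix(p),
      reduced = {
        pr <- synapse_params(tau_d = 1 / (1 / p$tau_nu + 1 / p$tau_au))
        tum_decay_matrix(pr)
      })
    expect_equal(unname(K), unname(K_ref), tolerance = 1e-12)
  }
  # clamp mode: homogeneous part only (constant inflow handled separately)
  eig <- tumanet:::synapse_eigen(p, "clamp")
  K <- eig$P %*% diag(eig$lambda) %*% eig$Pinv
  K3 <- matrix(c(0, 0, 1 / p$tau_r,
                 0, -(1 / p$tau_nu + 1 / p$tau_au), 0,
                 0, 1 / p$tau_nu, -1 / p$tau_r), 3, byrow = TRUE)
  expect_equal(unname(K), K3, tolerance = 1e-12)
  expect_error(tumanet:::synapse_eigen(synapse_params(tau_r = 250 * 50 / 300)),
               "degenerate|coincident")
})

test_that("stationary astrocytic storage falls with faster return and slower uptake", {
  # single synapse under fixed 5-Hz Poisson spiking; the astrocytic level
  # decreases as tau_au grows and increases as tau_g grows
  mean_A_at <- function(tau_au, tau_g) {
    p <- synapse_params(tau_au = tau_au, tau_g = tau_g)
    spikes <- withr::with_seed(7, cumsum(rexp(1000, 1 / 200)))
    tr <- simulate_synapse(spikes, p, duration = 180000, dt = 1)
    mean(tr$A[tr$time > 90000])
  }
  a <- vapply(c(200, 250, 300), mean_A_at, 0, tau_g = 30000)
  expect_true(all(diff(a) < 0))
  g <- vapply(c(10000, 30000, 60000), function(tg) mean_A_at(250, tg), 0)
  expect_true(all(diff(g) > 0))
})
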