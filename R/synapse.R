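#' Synapse state vectors
#'
#' A synapse state is a named numeric vector of glutamate fractions:
#' `X` (ready to release), `Y` (active in the cleft), `Z` (recovered,
#' presynaptic) and, in the four-state model, `A` (astrocytic pool).
#'
#' @param X,Y,Z,A Fractions in `[0, 1]`. Set `A = NULL` for a three-state
#'   state vector.
#' @return Named numeric vector of length 3 or 4.
#' @export
synapse_state <- function(X = 1, Y = 0, Z = 0, A = 0) {
  s <- if (is.null(A)) c(X = X, Y = Y, Z = Z) else c(X = X, Y = Y, Z = Z, A = A)
  if (any(s < -1e-12) || any(s > 1 + 1e-12))
    stop("state fractions must lie in [0, 1]", call. = FALSE)
  s
}

#' Generator matrix of the three-state decay dynamics
#'
#' Between release events the three-state model is linear:
#' `dX/dt = Z/tau_r`, `dY/dt = -Y/tau_d`, `dZ/dt = Y/tau_d - Z/tau_r`.
#' Columns sum to zero, so the total is conserved.
#'
#' @param p A [synapse_params()] object.
#' @return A 3x3 generator matrix (state order X, Y, Z).
#' @export
tum_decay_matrix <- function(p) {
  matrix(c(0, 0, 1 / p$tau_r,
           0, -1 / p$tau_d, 0,
           0, 1 / p$tau_d, -1 / p$tau_r),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
}

#' Generator matrix of the four-state decay dynamics
#'
#' Between events: `dX/dt = Z/tau_r`,
#' `dY/dt = -Y/tau_nu - Y/tau_au`,
#' `dZ/dt = Y/tau_nu + A/tau_g - Z/tau_r`,
#' `dA/dt = Y/tau_au - A/tau_g`. Columns sum to zero.
#'
#' @param p A [synapse_params()] object.
#' @return A 4x4 generator matrix (state order X, Y, Z, A).
#' @export
tuma_decay_matrix <- function(p) {
  nm <- c("X", "Y", "Z", "A")
  matrix(c(0, 0, 1 / p$tau_r, 0,
           0, -(1 / p$tau_nu + 1 / p$tau_au), 0, 0,
           0, 1 / p$tau_nu, -1 / p$tau_r, 1 / p$tau_g,
           0, 1 / p$tau_au, 0, -1 / p$tau_g),
         nrow = 4, byrow = TRUE, dimnames = list(nm, nm))
}

#' Matrix exponential
#'
#' Dense matrix exponential (scaling-and-squaring), used to turn the linear
#' between-event synapse dynamics into an exact one-step propagator.
#'
#' @param M A square numeric matrix.
#' @return `expm(M)`.
#' @export
mat_exp <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  out <- mat_exp_cpp(M)
  dimnames(out) <- dimnames(M)
  out
}

#' Advance a three-state synapse through one decay interval
#'
#' Exact (matrix-exponential) or forward-Euler update of the between-event
#' linear dynamics. The exact update conserves `X + Y + Z` to machine
#' precision.
#'
#' @param s A 3-component state from [synapse_state()] (an `A` component,
#'   if present, is ignored and returned unchanged).
#' @param p A [synapse_params()] object.
#' @param dt Interval length (ms).
#' @param method `"exact"` or `"euler"`.
#' @return Advanced state vector.
#' @export
tum_decay_step <- function(s, p, dt, method = c("exact", "euler")) {
  method <- match.arg(method)
  stopifnot(dt > 0)
  K <- tum_decay_matrix(p)
  v <- s[c("X", "Y", "Z")]
  out <- if (method == "exact") drop(mat_exp(K * dt) %*% v) else
    v + dt * drop(K %*% v)
  s[c("X", "Y", "Z")] <- out
  s
}

#' Advance a four-state synapse through one decay interval
#'
#' @inheritParams tum_decay_step
#' @param s A 4-component state from [synapse_state()].
#' @return Advanced state vector; the exact update conserves
#'   `X + Y + Z + A` to machine precision.
#' @export
tuma_decay_step <- function(s, p, dt, method = c("exact", "euler")) {
  method <- match.arg(method)
  stopifnot(dt > 0, length(s) == 4)
  K <- tuma_decay_matrix(p)
  if (method == "exact") drop(mat_exp(K * dt) %*% s) else
    s + dt * drop(K %*% s)
}

#' Spike-triggered synchronous release
#'
#' Moves the fraction `u` of the ready pool into the active state:
#' `X -> X - uX`, `Y -> Y + uX`. Total exactly conserved.
#'
#' @param s A synapse state vector.
#' @param u Release fraction in `(0, 1]`.
#' @return Updated state.
#' @export
apply_synchronous_release <- function(s, u) {
  stopifnot(u > 0, u <= 1)
  rel <- u * s[["X"]]
  s[["X"]] <- s[["X"]] - rel
  s[["Y"]] <- s[["Y"]] + rel
  s
}

#' Asynchronous (spontaneous) release
#'
#' One asynchronous event moves the fraction `xi_bar` of the ready pool
#' into the active state. Total exactly conserved.
#'
#' @param s A synapse state vector.
#' @param xi_bar Released fraction in `[0, 1]`.
#' @return Updated state.
#' @export
apply_asynchronous_release <- function(s, xi_bar) {
  stopifnot(xi_bar >= 0, xi_bar <= 1)
  rel <- xi_bar * s[["X"]]
  s[["X"]] <- s[["X"]] - rel
  s[["Y"]] <- s[["Y"]] + rel
  s
}

# Propagator (M, v) of the clamped-A affine system over one step:
# s3' = M s3 + v with s3 = (X, Y, Z), obtained from the exponential of the
# augmented generator [[K3, c], [0, 0]] with c = (0, 0, A_fixed/tau_g).
clamped_propagator <- function(p, A_fixed, dt) {
  K3 <- matrix(c(0, 0, 1 / p$tau_r,
                 0, -(1 / p$tau_nu + 1 / p$tau_au), 0,
                 0, 1 / p$tau_nu, -1 / p$tau_r),
               nrow = 3, byrow = TRUE)
  aug <- rbind(cbind(K3, c(0, 0, A_fixed / p$tau_g)), 0)
  E <- mat_exp(aug * dt)
  list(M = E[1:3, 1:3, drop = FALSE], v = E[1:3, 4])
}

#' Advance a synapse with the astrocytic pool clamped
#'
#' With `mode = "clamp"` the astrocytic fraction is held at `A_fixed` while
#' every flux term is retained: the active state still loses `Y/tau_au` to
#' the (clamped) pool and the recovered state still gains `A_fixed/tau_g`.
#' The presynaptic total `X + Y + Z` is then not instantaneously conserved
#' but fluctuates around `1 - A_fixed` in stationary runs. With
#' `mode = "reduced"` the system is instead reduced to a hard three-state
#' model with conserved total `1 - A_fixed` and combined active-state decay
#' time `1/(1/tau_nu + 1/tau_au)` (all uptake routed back to the recovered
#' pool).
#'
#' @param s A 4-component state; its `A` entry is overwritten by `A_fixed`.
#' @param A_fixed Clamped astrocytic fraction in `[0, 1)`.
#' @param p A [synapse_params()] object.
#' @param dt Interval (ms).
#' @param mode `"clamp"` or `"reduced"`.
#' @return Advanced 4-component state with `A = A_fixed`.
#' @export
tuma_clamped_step <- function(s, A_fixed, p, dt,
                              mode = c("clamp", "reduced")) {
  mode <- match.arg(mode)
  stopifnot(A_fixed >= 0, A_fixed < 1, dt > 0)
  v3 <- s[c("X", "Y", "Z")]
  if (mode == "clamp") {
    pr <- clamped_propagator(p, A_fixed, dt)
    out <- drop(pr$M %*% v3) + pr$v
  } else {
    tau_eff <- 1 / (1 / p$tau_nu + 1 / p$tau_au)
    p3 <- synapse_params(u = p$u, tau_r = p$tau_r, tau_d = tau_eff,
                         tau_nu = p$tau_nu, tau_au = p$tau_au,
                         tau_g = p$tau_g, xi_bar = p$xi_bar, b = p$b)
    out <- drop(mat_exp(tum_decay_matrix(p3) * dt) %*% v3)
  }
  s[c("X", "Y", "Z")] <- out
  s[["A"]] <- A_fixed
  s
}

#' Simulate a single synapse through a spike train
#'
#' Fixed-step integration of one synapse: exact linear decay within each
#' step, then instantaneous release events at step boundaries. Spike and
#' asynchronous event times are rounded up to the enclosing step.
#'
#' @param spike_times Presynaptic spike times (ms).
#' @param p A [synapse_params()] object.
#' @param duration Total simulated time (ms).
#' @param dt Step (ms).
#' @param mode `"tuma"`, `"tum"`, `"clamp"` or `"reduced"`.
#' @param A_fixed Clamped astrocytic fraction for the clamped modes.
#' @param async_times Optional asynchronous event times (ms).
#' @param init Initial state; defaults to all glutamate in the ready pool
#'   (minus `A_fixed` in the clamped modes).
#' @return A data.frame with one row per step boundary: `time`, `X`, `Y`,
#'   `Z` and (four-state and clamped modes) `A`.
#' @export
simulate_synapse <- function(spike_times, p, duration, dt = 0.05,
                             mode = c("tuma", "tum", "clamp", "reduced"),
                             A_fixed = NA_real_, async_times = numeric(),
                             init = NULL) {
  mode <- match.arg(mode)
  stopifnot(duration > 0, dt > 0)
  n_steps <- as.integer(round(duration / dt))
  four <- mode != "tum"
  if (is.null(init)) {
    init <- if (mode %in% c("clamp", "reduced"))
      synapse_state(X = 1 - A_fixed, Y = 0, Z = 0, A = A_fixed)
    else if (four) synapse_state() else synapse_state(A = NULL)
  }
  prop <- switch(mode,
    tuma = list(M = mat_exp(tuma_decay_matrix(p) * dt), v = NULL),
    tum = list(M = mat_exp(tum_decay_matrix(p) * dt), v = NULL),
    clamp = clamped_propagator(p, A_fixed, dt),
    reduced = {
      tau_eff <- 1 / (1 / p$tau_nu + 1 / p$tau_au)
      p3 <- p; p3$tau_d <- tau_eff
      list(M = mat_exp(tum_decay_matrix(p3) * dt), v = NULL)
    })
  spk_step <- if (length(spike_times)) pmax(1L, as.integer(ceiling(spike_times / dt))) else integer()
  asy_step <- if (length(async_times)) pmax(1L, as.integer(ceiling(async_times / dt))) else integer()
  spk_count <- tabulate(spk_step[spk_step <= n_steps], nbins = n_steps)
  asy_count <- tabulate(asy_step[asy_step <= n_steps], nbins = n_steps)

  d <- length(init)
  core_idx <- if (mode %in% c("clamp", "reduced")) 1:3 else seq_len(d)
  out <- matrix(NA_real_, nrow = n_steps + 1, ncol = d)
  out[1, ] <- init
  s <- unname(init)
  for (k in seq_len(n_steps)) {
    s[core_idx] <- prop$M %*% s[core_idx]
    if (!is.null(prop$v)) s[core_idx] <- s[core_idx] + prop$v
    if (spk_count[k] > 0) for (i in seq_len(spk_count[k])) {
      rel <- p$u * s[1]; s[1] <- s[1] - rel; s[2] <- s[2] + rel
    }
    if (asy_count[k] > 0) for (i in seq_len(asy_count[k])) {
      rel <- p$xi_bar * s[1]; s[1] <- s[1] - rel; s[2] <- s[2] + rel
    }
    out[k + 1, ] <- s
  }
  df <- data.frame(time = seq(0, by = dt, length.out = n_steps + 1))
  cols <- names(init)
  for (j in seq_len(d)) df[[cols[j]]] <- out[, j]
  df
}

# Analytic eigendecomposition of the between-event generator (state order
# X, Y, Z[, A]). The generator is lower-triangular in the order Y, A, Z, X,
# so the eigenvalues are the negative reciprocal timescales and the
# eigenvectors follow by back-substitution. Used by the simulation engine
# to advance synapses lazily by exact exponential factors.
synapse_eigen <- function(p, mode = c("tuma", "tum", "clamp", "reduced")) {
  mode <- match.arg(mode)
  tau_e <- 1 / (1 / p$tau_nu + 1 / p$tau_au)
  if (mode == "tuma") {
    lam <- c(0, -1 / tau_e, -1 / p$tau_r, -1 / p$tau_g)
    vY_A <- (1 / p$tau_au) / (lam[2] + 1 / p$tau_g)
    vY_Z <- (1 / p$tau_nu + vY_A / p$tau_g) / (lam[2] + 1 / p$tau_r)
    vY_X <- vY_Z / (p$tau_r * lam[2])
    vg_Z <- (1 / p$tau_g) / (lam[4] + 1 / p$tau_r)
    vg_X <- vg_Z / (p$tau_r * lam[4])
    P <- cbind(c(1, 0, 0, 0), c(vY_X, 1, vY_Z, vY_A),
               c(-1, 0, 1, 0), c(vg_X, 0, vg_Z, 1))
  } else {
    decay <- if (mode == "tum") 1 / p$tau_d else 1 / tau_e
    zflux <- if (mode == "clamp") 1 / p$tau_nu else decay
    lam <- c(0, -decay, -1 / p$tau_r)
    vY_Z <- zflux / (lam[2] + 1 / p$tau_r)
    vY_X <- vY_Z / (p$tau_r * lam[2])
    P <- cbind(c(1, 0, 0), c(vY_X, 1, vY_Z), c(-1, 0, 1))
  }
  if (any(!is.finite(P)) || min(abs(diff(sort(lam)))) == 0)
    stop("degenerate (coincident) synaptic timescales; perturb tau_r, tau_g ",
         "or the uptake times slightly", call. = FALSE)
  list(P = P, Pinv = solve(P), lambda = lam)
}
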