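#' Drift vector of the diffusion approximation
#'
#' Expected per-step change of the focal/other frequencies `(x, o)`, built
#' from the one-step transition probabilities: events move frequencies by
#' `1/N`, so `A_x = (t_xp + t_xp_om - t_xm_op - t_xm) / N` and
#' `A_o = (t_xm_op + t_op - t_xp_om - t_om) / N`.
#'
#' @inheritParams transition_probabilities
#' @return Numeric vector `c(A_x, A_o)`.
#' @export
drift_vector <- function(state, lh, pool, taxon = 1L) {
  ts <- transition_probabilities(state, lh, pool, taxon)
  c(A_x = unname((ts["t_xp"] + ts["t_xp_om"] - ts["t_xm_op"] - ts["t_xm"]) / lh$N),
    A_o = unname((ts["t_xm_op"] + ts["t_op"] - ts["t_xp_om"] - ts["t_om"]) / lh$N))
}

#' Covariance matrix of the per-step frequency change
#'
#' Exact one-step covariance `V = E[delta delta^T] - A A^T` of the jump
#' `delta = (delta_x, delta_o)`, with second moments
#' `E[delta_x^2] = (t_xm_op + t_xp_om + t_xp + t_xm) / N^2`,
#' `E[delta_o^2] = (t_xm_op + t_xp_om + t_op + t_om) / N^2` and
#' `E[delta_x delta_o] = -(t_xm_op + t_xp_om) / N^2` (replacement events move
#' `x` and `o` in opposite directions).
#'
#' @inheritParams transition_probabilities
#' @return A symmetric positive semi-definite 2x2 matrix.
#' @export
covariance_matrix <- function(state, lh, pool, taxon = 1L) {
  ts <- transition_probabilities(state, lh, pool, taxon)
  A <- drift_vector(state, lh, pool, taxon)
  N2 <- as.numeric(lh$N)^2
  Exx <- (ts[["t_xm_op"]] + ts[["t_xp_om"]] + ts[["t_xp"]] + ts[["t_xm"]]) / N2
  Eoo <- (ts[["t_xm_op"]] + ts[["t_xp_om"]] + ts[["t_op"]] + ts[["t_om"]]) / N2
  Exo <- -(ts[["t_xm_op"]] + ts[["t_xp_om"]]) / N2
  M <- matrix(c(Exx, Exo, Exo, Eoo), 2, 2,
              dimnames = list(c("x", "o"), c("x", "o")))
  M - tcrossprod(unname(A))
}

#' Noise factor of a covariance matrix
#'
#' Returns a symmetric matrix `B` with `t(B) %*% B = V`, via an
#' eigendecomposition with negative eigenvalues within `-1e-12` floored at 0
#' (numerical noise on a singular boundary). Asymmetric input or an
#' eigenvalue below `-1e-8` raises an error.
#'
#' @param V symmetric positive semi-definite matrix.
#' @return Symmetric matrix `B` of the same dimension.
#' @examples
#' noise_factor(diag(2) * 4)  # diag(2) * 2
#' @export
noise_factor <- function(V) {
  V <- as.matrix(V)
  if (max(abs(V - t(V))) > 1e-10)
    stop("'V' must be symmetric", call. = FALSE)
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop("'V' has a negative eigenvalue beyond tolerance", call. = FALSE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' One Euler-Maruyama update
#'
#' Applies `x <- x + A dt + B dW` with `dW ~ Normal(0, dt I)`, then the
#' boundary policy: negative components are clipped to 0 and, if the total
#' frequency exceeds 1, all components are rescaled by its inverse.
#'
#' @param state a [host_state()] with frequencies (any number of taxa).
#' @param lh a [life_history()].
#' @param pool a [colonizer_pool()].
#' @param dt timestep, in units of jump-process steps (`> 0`).
#' @return The new [host_state()].
#' @export
euler_maruyama_step <- function(state, lh, pool, dt = 1) {
  stopifnot(inherits(state, "host_state"), inherits(lh, "life_history"),
            inherits(pool, "colonizer_pool"))
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  x <- host_freqs(state)
  dd <- cpp_drift_cov(x, lh$N, lh$m, lh$tau, lh$alpha0, pool$p)
  B <- noise_factor(dd$V)
  xn <- x + dd$A * dt + as.numeric(B %*% stats::rnorm(length(x), 0, sqrt(dt)))
  xn[xn < 0] <- 0
  if (sum(xn) > 1) xn <- xn / sum(xn)
  host_state(freqs = xn, N = lh$N)
}

#' Sample a host lifespan
#'
#' Host lifetimes in the diffusion engine are exponential with density
#' `tau * exp(-tau * t)`, mean `1 / tau`. `tau = 0` represents an immortal
#' host (`Inf`; callers must bound the horizon by `t_max`).
#'
#' @param tau per-timestep host death probability.
#' @param n number of draws.
#' @return Lifespans in timesteps.
#' @export
sample_host_lifespan <- function(tau, n = 1L) {
  if (tau < 0 || tau > 1) stop("'tau' must be in [0, 1]", call. = FALSE)
  if (tau == 0) return(rep(Inf, n))
  rexp(n, rate = tau)
}

#' Simulate a single host with the Euler-Maruyama engine
#'
#' Integrates the diffusion approximation on a grid of width `dt` up to
#' `t_end`, recording roughly every `record_every` time units. One unit of
#' time corresponds to one step of the discrete jump process, so `dt = 1`
#' matches the jump process step-for-step in its first two moments.
#'
#' @param init a [host_state()] (counts are converted to frequencies).
#' @param lh a [life_history()].
#' @param pool a [colonizer_pool()].
#' @param t_end simulation horizon (`>= 0`).
#' @param dt integration step (`> 0`), default 1.
#' @param record_every recording stride in time units.
#' @return A `host_trajectory` with frequency rows and `engine = "sde"`.
#' @export
simulate_host_sde <- function(init, lh, pool, t_end, dt = 1,
                              record_every = dt) {
  stopifnot(inherits(init, "host_state"), inherits(lh, "life_history"),
            inherits(pool, "colonizer_pool"))
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (t_end < 0) stop("'t_end' must be >= 0", call. = FALSE)
  x0 <- host_freqs(init)
  if (length(x0) != pool$K)
    stop("state and pool disagree on the number of taxa", call. = FALSE)
  if (t_end == 0) {
    return(structure(list(times = 0, states = matrix(x0, nrow = 1),
                          death_step = NA_integer_, count_max = x0,
                          final = x0, N = lh$N, engine = "sde"),
                     class = "host_trajectory"))
  }
  res <- cpp_sim_host_sde(x0, lh$N, lh$m, lh$tau, lh$alpha0, pool$p, dt,
                          t_end, record_every)
  structure(list(times = res$times, states = res$freqs,
                 death_step = NA_integer_,
                 count_max = apply(res$freqs, 2, max), final = res$final,
                 N = lh$N, engine = "sde"),
            class = "host_trajectory")
}
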