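#' One-step transition probabilities of the within-host jump process
#'
#' For a focal taxon with frequency `x`, pooled other microbes `o` and free
#' space `x0 = 1 - x - o`, returns the seven per-step event probabilities of
#' the Moran-type death/immigration/birth process, plus the host-death
#' probability `tau`. Conditional on host survival (factor `1 - tau`), a
#' microbe or an empty slot is selected for turnover; replacement is an
#' immigrant with probability `m` or a replicative copy of a resident with
#' probability `1 - m`, weighted by `x_k / D` with
#' `D = alpha0 * x0 + x + o`; with weight `alpha0 * x0 / D` the dead microbe
#' is not replaced.
#'
#' Replication terms with a zero numerator evaluate to 0 even when `D = 0`
#' (empty host with `alpha0 = 0`), by continuity: there is no resident to
#' duplicate.
#'
#' @param state a [host_state()], or a numeric vector `c(x, o)` giving the
#'   focal/other projection directly.
#' @param lh a [life_history()].
#' @param pool a [colonizer_pool()], or a single number `p_i` when `state`
#'   is given as a projection.
#' @param taxon focal taxon index (used when `state`/`pool` are multi-taxon).
#' @return A named numeric vector of class `transition_set` with entries
#'   `t_xm_op` (focal dies, other replaces), `t_xp_om` (other dies, focal
#'   replaces), `t_op` (other fills empty space), `t_xp` (focal fills empty
#'   space), `t_xm` (focal dies unreplaced), `t_om` (other dies unreplaced),
#'   `t_stay`, and `t_hostdeath = tau`. The entries sum to 1.
#' @examples
#' lh <- life_history(m = 0.01, tau = 1e-4, alpha0 = 1, N = 100, H = 2)
#' ts <- transition_probabilities(c(x = 0.2, o = 0.3), lh, pool = 0.1)
#' sum(ts)  # exactly 1
#' @export
transition_probabilities <- function(state, lh, pool, taxon = 1L) {
  stopifnot(inherits(lh, "life_history"))
  if (inherits(state, "host_state")) {
    xo <- project_state(state, taxon)
  } else {
    xo <- as.numeric(state)
    if (length(xo) != 2L) stop("'state' must be a host_state or c(x, o)", call. = FALSE)
  }
  x <- xo[[1]]; o <- xo[[2]]
  if (x < 0 || o < 0 || x + o > 1 + 1e-12)
    stop("invalid state: frequencies outside the simplex", call. = FALSE)
  p_i <- if (inherits(pool, "colonizer_pool")) pool$p[taxon] else as.numeric(pool)
  if (is.na(p_i) || p_i < 0 || p_i > 1)
    stop("invalid pool frequency p_i", call. = FALSE)

  m <- lh$m; tau <- lh$tau; a0 <- lh$alpha0
  x0 <- max(0, 1 - x - o)
  D <- a0 * x0 + x + o
  s <- 1 - tau
  rep_frac <- function(num) if (num == 0) 0 else (1 - m) * num / D
  t_xm_op <- s * x * (m * (1 - p_i) + rep_frac(o))
  t_xp_om <- s * o * (m * p_i + rep_frac(x))
  t_op <- s * x0 * (m * (1 - p_i) + rep_frac(o))
  t_xp <- s * x0 * (m * p_i + rep_frac(x))
  t_xm <- s * x * rep_frac(a0 * x0)
  t_om <- s * o * rep_frac(a0 * x0)
  t_stay <- 1 - t_xm_op - t_xp_om - t_op - t_xp - t_xm - t_om - tau
  out <- c(t_xm_op = t_xm_op, t_xp_om = t_xp_om, t_op = t_op, t_xp = t_xp,
           t_xm = t_xm, t_om = t_om, t_stay = t_stay, t_hostdeath = tau)
  structure(out, class = c("transition_set", "numeric"))
}

#' Distribution over elementary events for a multi-taxon host
#'
#' Enumerates the one-step elementary events of the K-taxon jump process --
#' host death; (death of taxon j, replacement by taxon k != j); (fill of an
#' empty slot by taxon k); (unreplaced death of taxon j); stay -- with their
#' probabilities. Marginalizing onto any focal taxon (focal vs. all others
#' pooled) reproduces [transition_probabilities()] exactly.
#'
#' @param state a [host_state()].
#' @param lh a [life_history()].
#' @param pool a [colonizer_pool()] with one entry per taxon.
#' @return A data.frame with columns `type` (one of `host_death`, `replace`,
#'   `fill`, `unreplaced_death`, `stay`), `die`, `repl` (taxon indices or
#'   `NA`) and `prob`. Probabilities sum to 1.
#' @export
event_distribution <- function(state, lh, pool) {
  stopifnot(inherits(state, "host_state"), inherits(lh, "life_history"),
            inherits(pool, "colonizer_pool"))
  f <- host_freqs(state)
  K <- length(f)
  if (pool$K != K) stop("pool and state disagree on the number of taxa", call. = FALSE)
  m <- lh$m; tau <- lh$tau; a0 <- lh$alpha0
  L <- sum(f); x0 <- max(0, 1 - L); D <- a0 * x0 + L
  s <- 1 - tau
  repl_w <- function(k) { # replacement weight for taxon k given a turnover slot
    r <- if (D > 0) (1 - m) * f[k] / D else 0
    m * pool$p[k] + r
  }
  none_w <- if (D > 0) (1 - m) * a0 * x0 / D else (1 - m)

  rows <- list()
  rows[[1]] <- data.frame(type = "host_death", die = NA_integer_,
                          repl = NA_integer_, prob = tau)
  for (j in seq_len(K)) {
    for (k in seq_len(K)) {
      if (k == j) next
      rows[[length(rows) + 1L]] <- data.frame(
        type = "replace", die = j, repl = k, prob = s * f[j] * repl_w(k))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      type = "unreplaced_death", die = j, repl = NA_integer_,
      prob = s * f[j] * none_w)
  }
  for (k in seq_len(K)) {
    rows[[length(rows) + 1L]] <- data.frame(
      type = "fill", die = NA_integer_, repl = k, prob = s * x0 * repl_w(k))
  }
  ev <- do.call(rbind, rows)
  stay <- 1 - sum(ev$prob)
  if (stay < -1e-12) stop("internal error: negative stay probability", call. = FALSE)
  ev <- rbind(ev, data.frame(type = "stay", die = NA_integer_,
                             repl = NA_integer_, prob = max(0, stay)))
  ev
}

#' Marginalize an event distribution onto a focal taxon
#'
#' Pools the elementary events of [event_distribution()] into the
#' focal/others projection, yielding the same eight entries as
#' [transition_probabilities()].
#'
#' @param ev output of [event_distribution()].
#' @param taxon focal taxon index.
#' @return A named numeric vector matching [transition_probabilities()].
#' @export
marginalize_events <- function(ev, taxon) {
  stopifnot(is.data.frame(ev))
  p <- function(sel) sum(ev$prob[sel])
  is_rep <- ev$type == "replace"
  is_fill <- ev$type == "fill"
  is_un <- ev$type == "unreplaced_death"
  c(t_xm_op = p(is_rep & ev$die == taxon & ev$repl != taxon),
    t_xp_om = p(is_rep & ev$die != taxon & ev$repl == taxon),
    t_op = p(is_fill & ev$repl != taxon),
    t_xp = p(is_fill & ev$repl == taxon),
    t_xm = p(is_un & ev$die == taxon),
    t_om = p(is_un & ev$die != taxon),
    # other-to-other replacements leave the (x, o) projection unchanged
    t_stay = p(ev$type == "stay") +
      p(is_rep & ev$die != taxon & ev$repl != taxon),
    t_hostdeath = p(ev$type == "host_death"))
}

#' Advance a host by one step of the discrete jump process
#'
#' Applies exactly one sampled elementary event (or none), changing at most
#' two taxon counts by one microbe. With probability `tau` the host dies and
#' the state is returned unchanged with `died = TRUE`; handling of the
#' replacement birth belongs to the population layer.
#'
#' @param state a [host_state()] with counts.
#' @param lh a [life_history()].
#' @param pool a [colonizer_pool()].
#' @return A list with elements `state` (new [host_state()]) and `died`.
#' @export
step_discrete <- function(state, lh, pool) {
  stopifnot(inherits(state, "host_state"), state$type == "counts",
            inherits(lh, "life_history"), inherits(pool, "colonizer_pool"))
  res <- cpp_sim_host_discrete(state$counts, lh$N, lh$m, lh$tau, lh$alpha0,
                               pool$p, 1L, 1L)
  died <- !is.na(res$death_step)
  new_counts <- if (died) state$counts else res$final
  list(state = host_state(counts = new_counts, N = lh$N), died = died)
}

#' Simulate a single host with the discrete jump process
#'
#' Runs the exact jump process for up to `max_steps` timesteps, recording the
#' state every `record_every` steps. The trajectory terminates early if the
#' host dies (per-step probability `tau`).
#'
#' @param init a [host_state()] with counts.
#' @param lh a [life_history()].
#' @param pool a [colonizer_pool()].
#' @param max_steps number of timesteps, `>= 1`.
#' @param record_every recording stride in steps.
#' @return An object of class `host_trajectory`: list with `times`,
#'   `states` (matrix, one row per record, one column per taxon; counts),
#'   `death_step` (`NA` if the host survived), `count_max` (running maximum
#'   per taxon), `final`, `N`, and `engine = "discrete"`.
#' @examples
#' lh <- life_history(m = 1, tau = 0, alpha0 = 0, N = 100, H = 2)
#' pool <- colonizer_pool(c(0.3, 0.7))
#' tr <- simulate_host_discrete(host_state(counts = c(0, 0), N = 100),
#'                              lh, pool, max_steps = 500, record_every = 100)
#' @export
simulate_host_discrete <- function(init, lh, pool, max_steps,
                                   record_every = 1L) {
  stopifnot(inherits(init, "host_state"), init$type == "counts",
            inherits(lh, "life_history"), inherits(pool, "colonizer_pool"))
  if (length(init$counts) != pool$K)
    stop("state and pool disagree on the number of taxa", call. = FALSE)
  max_steps <- as.integer(max_steps)
  if (is.na(max_steps) || max_steps < 1L)
    stop("'max_steps' must be >= 1", call. = FALSE)
  record_every <- as.integer(record_every)
  if (is.na(record_every) || record_every < 1L)
    stop("'record_every' must be >= 1", call. = FALSE)
  res <- cpp_sim_host_discrete(init$counts, lh$N, lh$m, lh$tau, lh$alpha0,
                               pool$p, max_steps, record_every)
  structure(list(times = res$times, states = res$counts,
                 death_step = res$death_step, count_max = res$count_max,
                 final = res$final, N = lh$N, engine = "discrete"),
            class = "host_trajectory")
}

#' @export
print.host_trajectory <- function(x, ...) {
  cat("Host trajectory (", x$engine, "), ", length(x$times), " records, ",
      "final load ", signif(sum(x$final) / if (x$engine == "discrete") x$N else 1, 4),
      if (!is.na(x$death_step)) paste0(", host died at step ", x$death_step),
      "\n", sep = "")
  invisible(x)
}
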