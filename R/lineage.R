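#' Mean-increase condition for lineage taxa
#'
#' Lineage taxa (absent from the environmental pool, `p_i = 0`) increase in
#' expectation while the total microbial load satisfies
#' `x_i + o_i < 1 - m / (1 - alpha0)`. The derivation assumes
#' `0 <= alpha0 < 1`; for `alpha0 >= 1` the threshold expression changes
#' sign and the condition is undefined, which raises an error.
#'
#' @param state a [host_state()], or a bare total load in `[0, 1]`.
#' @param lh a [life_history()].
#' @return `TRUE` if the expected lineage frequency change is positive.
#' @examples
#' lh <- life_history(m = 1e-2, tau = 0, alpha0 = 0, N = 1000, H = 2)
#' increase_condition(0.5, lh)  # TRUE: 0.5 < 0.99
#' @export
increase_condition <- function(state, lh) {
  stopifnot(inherits(lh, "life_history"))
  load <- if (inherits(state, "host_state")) host_load(state) else as.numeric(state)
  if (is.na(load) || load < 0 || load > 1 + 1e-12)
    stop("total load must be in [0, 1]", call. = FALSE)
  load < max_lineage_frequency(lh)
}

#' Analytic maximum frequency of lineage taxa
#'
#' On average, the frequency of a lineage taxon peaks at
#' `1 - m / (1 - alpha0)` (clipped to `[0, 1]`): growth stops when the
#' microbial load reaches the point where immigration of environmental
#' microbes balances replication into free space. Requires `alpha0 < 1`.
#'
#' @param lh a [life_history()].
#' @return The peak frequency, in `[0, 1]`.
#' @examples
#' lh <- life_history(m = 1e-2, tau = 0, alpha0 = 0, N = 1000, H = 2)
#' max_lineage_frequency(lh)  # 0.99
#' @export
max_lineage_frequency <- function(lh) {
  stopifnot(inherits(lh, "life_history"))
  if (lh$alpha0 >= 1)
    stop("the increase condition is derived for alpha0 < 1; ",
         "the threshold expression is undefined for alpha0 >= 1", call. = FALSE)
  min(1, max(0, 1 - lh$m / (1 - lh$alpha0)))
}

#' Lineage persistence experiment
#'
#' Simulates a host population in which one taxon is initially present in
#' hosts but absent from the pool of colonizers (`p = 0`), tracking, per
#' host slot, the first time the lineage taxon is lost (extinction), the
#' peak lineage frequency, and the fraction of slots that still carry the
#' taxon at each recording time. Slots are followed through birth events:
#' the newborn inherits the slot's extinction clock, so losses at birth
#' (when the inherited lineage count rounds to zero) count as extinctions.
#'
#' @param lh a [life_history()].
#' @param pool a [colonizer_pool()] with `p = 0` for `lineage_taxon`.
#' @param init `H x K` matrix of initial counts (the lineage inoculum).
#' @param inheritance an [inheritance_spec()].
#' @param t_max horizon in timesteps; extinction times beyond it are
#'   censored (`NA`).
#' @param lineage_taxon index of the lineage taxon (default 1).
#' @param record_times snapshot times for the survival curve.
#' @return An object of class `lineage_run`: list with `extinction_times`
#'   (`NA` = censored at `t_max`), `peak_freqs`, `survival_curve`
#'   (data.frame `time`, `fraction`), `censored` (logical), `t_max`, and the
#'   final `run` object.
#' @export
run_lineage_experiment <- function(lh, pool, init, inheritance, t_max,
                                   lineage_taxon = 1L, record_times = NULL) {
  stopifnot(inherits(lh, "life_history"), inherits(pool, "colonizer_pool"))
  lineage_taxon <- as.integer(lineage_taxon)
  if (pool$p[lineage_taxon] > 0)
    stop("the lineage taxon must be absent from the pool (p = 0)", call. = FALSE)
  cfg <- population_config("discrete", t_max = t_max,
                           record_times = record_times,
                           inheritance = inheritance,
                           lineage_taxon = lineage_taxon)
  run <- run_population(lh, pool, cfg, init = init)
  ext <- run$lineage$ext_time
  censored <- is.na(ext)
  surv <- vapply(run$times, function(t) {
    mean(censored | ext > t)
  }, numeric(1))
  structure(list(extinction_times = ext,
                 peak_freqs = run$lineage$peak_count / lh$N,
                 survival_curve = data.frame(time = run$times,
                                             fraction = surv),
                 censored = censored, t_max = t_max, run = run),
            class = "lineage_run")
}

#' @export
print.lineage_run <- function(x, ...) {
  cat("Lineage run:", sum(!x$censored), "of", length(x$censored),
      "host slots lost the taxon by t =", x$t_max, "\n")
  invisible(x)
}

#' Host-death threshold for lineage persistence
#'
#' From the distribution of lineage extinction times, estimates `t_z`, the
#' time by which a fraction `z` of host slots has lost the taxon (empirical
#' z-quantile with linear interpolation), and returns the host-death
#' probability `tau_z = -log(1 - z) / t_z` at which host turnover outpaces
#' that loss. Censored observations enter as larger than any observed time;
#' the quantile must be identified by uncensored data, otherwise an error is
#' raised (no imputation).
#'
#' @param extinction_times numeric vector of extinction times; `NA` =
#'   censored (taxon still present at the end of the run).
#' @param z fraction of hosts losing the taxon, in `(0, 1)` (vectorized).
#' @return `tau_z`, the per-timestep host death probability.
#' @examples
#' persistence_threshold_tau(c(500, 1000, 2000, 4000), z = 0.5)
#' @export
persistence_threshold_tau <- function(extinction_times, z) {
  if (any(z <= 0 | z >= 1)) stop("'z' must be in (0, 1)", call. = FALSE)
  n <- length(extinction_times)
  if (n < 2L) stop("need at least two extinction times", call. = FALSE)
  cens <- is.na(extinction_times)
  if (all(cens)) stop("all extinction times are censored; t_z undefined",
                      call. = FALSE)
  full <- sort(ifelse(cens, Inf, extinction_times))
  vapply(z, function(zz) {
    # type-7 quantile, written out so an exactly-hit order statistic is
    # identified even when its right neighbour is censored (Inf)
    h <- (n - 1) * zz + 1
    j <- floor(h)
    g <- h - j
    t_z <- if (g == 0) full[j] else (1 - g) * full[j] + g * full[j + 1]
    if (!is.finite(t_z))
      stop("the z-quantile is not identified by uncensored extinction times",
           call. = FALSE)
    if (t_z <= 0)
      stop("non-positive t_z: extinction at or before time 0", call. = FALSE)
    -log(1 - zz) / t_z
  }, numeric(1))
}
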