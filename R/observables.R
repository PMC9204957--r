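#' Summary statistics of a population snapshot
#'
#' Exact empirical statistics over the `H` hosts of a snapshot: the fraction
#' of hosts carrying any microbes (`occurrence_any`, i.e. `P[x + o > 0]`),
#' per-taxon occurrence, mean microbial load `E[x + o]`, per-taxon mean
#' frequencies, the across-host spread (standard deviation of the load), and
#' a load histogram with a dedicated zero bin plus log-spaced bins from
#' `1/N` to 1 (the microbe-free state is shown separately, and one microbe
#' per host corresponds to a load of exactly `1/N`).
#'
#' A discrete host "contains microbes" when its count is positive; a
#' continuous (SDE) host when its total frequency is at least `1/(2N)` --
#' half the natural frequency quantum.
#'
#' @param snapshot a [population_snapshot()].
#' @param taxon optional focal taxon index for `occurrence_taxon` /
#'   `mean_freq` (default: all taxa).
#' @param bins number of logarithmic histogram bins between `1/N` and 1.
#' @return An object of class `summary_stats`: list with `occurrence_any`,
#'   `occurrence_taxon`, `mean_load`, `mean_freq`, `spread`,
#'   `load_histogram` (data.frame with `lower`, `upper`, `mass`), `H`,
#'   `time`.
#' @examples
#' snap <- population_snapshot(matrix(c(0, 25, 50, 100), 4, 1), 0, 100)
#' s <- summarize_snapshot(snap)
#' s$occurrence_any  # 0.75
#' s$mean_load       # 0.4375
#' @export
summarize_snapshot <- function(snapshot, taxon = NULL, bins = 20L) {
  stopifnot(inherits(snapshot, "population_snapshot"))
  st <- snapshot$states
  N <- snapshot$N
  H <- nrow(st)
  K <- ncol(st)
  freqs <- if (snapshot$type == "discrete") st / N else st
  loads <- rowSums(freqs)
  thresh <- if (snapshot$type == "discrete") 0.5 / N else 0.5 / N
  present <- function(v) v >= thresh

  taxa <- if (is.null(taxon)) seq_len(K) else as.integer(taxon)
  if (any(taxa < 1L | taxa > K)) stop("invalid taxon index", call. = FALSE)

  brk <- c(-Inf, exp(seq(log(1 / N), 0, length.out = bins + 1)))
  brk[2] <- brk[2] * (1 - 1e-9) # include loads of exactly 1/N in the first bin
  cuts <- cut(loads, breaks = brk, include.lowest = TRUE, right = TRUE)
  hist <- data.frame(lower = c(0, utils::head(brk[-1], -1)),
                     upper = c(0, brk[-(1:2)]),
                     mass = as.numeric(table(cuts)) / H)

  structure(list(
    occurrence_any = mean(present(loads)),
    occurrence_taxon = setNames(colMeans(present(freqs[, taxa, drop = FALSE])),
                                paste0("taxon_", taxa)),
    mean_load = mean(loads),
    mean_freq = setNames(colMeans(freqs[, taxa, drop = FALSE]),
                         paste0("taxon_", taxa)),
    spread = if (H > 1) sd(loads) else 0,
    load_histogram = hist,
    H = H, time = snapshot$time), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("Snapshot t =", x$time, ": occurrence =", signif(x$occurrence_any, 4),
      ", mean load =", signif(x$mean_load, 4), ", spread =",
      signif(x$spread, 4), "(", x$H, "hosts )\n")
  invisible(x)
}

#' Inheritance-induced change in microbial occurrence
#'
#' `delta_P = P[x + o > 0]_inh - P[x + o > 0]_no-inh`: positive values mean
#' inheritance increases the fraction of colonized hosts.
#'
#' @param with_inh,without_inh `summary_stats` from matched runs with and
#'   without inheritance (or bare occurrence numbers).
#' @return The change in occurrence, in `[-1, 1]`.
#' @export
delta_occurrence <- function(with_inh, without_inh) {
  g <- function(x) if (inherits(x, "summary_stats")) x$occurrence_any else as.numeric(x)
  g(with_inh) - g(without_inh)
}

#' Inheritance-induced change in mean microbial load
#'
#' `delta_E = E[x + o]_inh - E[x + o]_no-inh`.
#'
#' @param with_inh,without_inh `summary_stats` from matched runs (or bare
#'   mean loads).
#' @return The change in mean load, in `[-1, 1]`.
#' @export
delta_load <- function(with_inh, without_inh) {
  g <- function(x) if (inherits(x, "summary_stats")) x$mean_load else as.numeric(x)
  g(with_inh) - g(without_inh)
}

#' Replicated paired comparison: with vs. without inheritance
#'
#' Runs `n_pairs` matched population simulations with and without the given
#' inheritance kernel, summarizes the final snapshot of each arm, and
#' reports the mean and standard deviation of the occurrence change
#' `delta_P` and the mean-load change `delta_E` across pairs. With
#' `paired = TRUE` the two arms of each pair share the RNG state at launch
#' (common random numbers).
#'
#' @param lh a [life_history()].
#' @param pool a [colonizer_pool()].
#' @param cfg a [population_config()] whose `inheritance` is used for the
#'   "with" arm; the "without" arm runs with mode `"none"`.
#' @param n_pairs number of replicate pairs, `>= 2`.
#' @param paired share RNG state between the two arms of each pair.
#' @param init optional initial state matrix passed to both arms.
#' @return An object of class `paired_comparison`: list with `delta_P`,
#'   `delta_E`, `se` (standard errors of the means), `sd`, `n_pairs`, and
#'   the per-pair values.
#' @export
replicate_comparison <- function(lh, pool, cfg, n_pairs = 6L, paired = FALSE,
                                 init = NULL) {
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 2L) stop("'n_pairs' must be >= 2", call. = FALSE)
  cfg_no <- cfg
  cfg_no$inheritance <- inheritance_spec("none")
  dP <- dE <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    if (paired) {
      if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
      saved <- get(".Random.seed", envir = globalenv())
    }
    r1 <- run_population(lh, pool, cfg, init = init)
    s1 <- summarize_snapshot(r1$snapshots[[length(r1$snapshots)]])
    if (paired) assign(".Random.seed", saved, envir = globalenv())
    r0 <- run_population(lh, pool, cfg_no, init = init)
    s0 <- summarize_snapshot(r0$snapshots[[length(r0$snapshots)]])
    dP[i] <- delta_occurrence(s1, s0)
    dE[i] <- delta_load(s1, s0)
  }
  structure(list(delta_P = mean(dP), delta_E = mean(dE),
                 sd = c(delta_P = sd(dP), delta_E = sd(dE)),
                 se = c(delta_P = sd(dP) / sqrt(n_pairs),
                        delta_E = sd(dE) / sqrt(n_pairs)),
                 n_pairs = n_pairs, pairs = data.frame(delta_P = dP, delta_E = dE)),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat("Paired comparison over", x$n_pairs, "pairs:\n",
      " delta_P =", signif(x$delta_P, 4), "+-", signif(x$sd["delta_P"], 4), "\n",
      " delta_E =", signif(x$delta_E, 4), "+-", signif(x$sd["delta_E"], 4), "\n")
  invisible(x)
}
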