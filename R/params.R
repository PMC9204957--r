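#' Life-history parameters of the host-microbiome model
#'
#' Bundles the five scalar parameters governing all dynamics: the probability
#' `m` that a replacement event is an immigration from the environmental pool,
#' the per-timestep host death probability `tau`, the establishment parameter
#' `alpha0` weighting empty space in the replacement denominator, the
#' within-host carrying capacity `N` (number of microbe slots), and the
#' number of hosts `H`.
#'
#' `alpha0 = 0` means empty slots are filled as fast as occupied ones are
#' contested (fast establishment); `alpha0 > 1` means that, without
#' immigration, microbes cannot be maintained in a host.
#'
#' @param m immigration probability per replacement event, in `[0, 1]`.
#' @param tau per-timestep host death probability, in `[0, 1]`.
#' @param alpha0 establishment parameter, `>= 0`.
#' @param N carrying capacity (microbe slots per host), positive integer.
#' @param H number of hosts, integer `>= 2`.
#' @return An object of class `life_history`.
#' @examples
#' life_history(m = 1e-2, tau = 1e-4, alpha0 = 0, N = 1e3, H = 200)
#' @export
life_history <- function(m, tau, alpha0, N, H = 2L) {
  stopifnot(is.numeric(m), length(m) == 1L, is.numeric(tau), length(tau) == 1L,
            is.numeric(alpha0), length(alpha0) == 1L)
  if (m < 0 || m > 1) stop("'m' must be in [0, 1]", call. = FALSE)
  if (tau < 0 || tau > 1) stop("'tau' must be in [0, 1]", call. = FALSE)
  if (alpha0 < 0) stop("'alpha0' must be >= 0", call. = FALSE)
  N <- as.integer(N)
  H <- as.integer(H)
  if (is.na(N) || N < 1L) stop("'N' must be a positive integer", call. = FALSE)
  if (is.na(H) || H < 2L) stop("'H' must be an integer >= 2", call. = FALSE)
  structure(list(m = as.numeric(m), tau = as.numeric(tau),
                 alpha0 = as.numeric(alpha0), N = N, H = H),
            class = "life_history")
}

#' @export
print.life_history <- function(x, ...) {
  cat("Life history: m =", x$m, ", tau =", x$tau, ", alpha0 =", x$alpha0,
      ", N =", x$N, ", H =", x$H, "\n")
  invisible(x)
}

#' Environmental pool of colonizing microbes
#'
#' Constant per-taxon frequencies `p_i` in the environment. The pool has no
#' empty-space category, so the entries must sum to 1. Lineage taxa --
#' microbes present in hosts but absent from the environment -- are
#' represented by `p_i = 0`.
#'
#' @param p numeric vector of environmental frequencies, each in `[0, 1]`,
#'   summing to 1.
#' @return An object of class `colonizer_pool`.
#' @examples
#' colonizer_pool(c(0.5, 0.3, 0.2))
#' colonizer_pool(c(0, 1))  # taxon 1 is a lineage taxon
#' @export
colonizer_pool <- function(p) {
  p <- as.numeric(p)
  if (length(p) < 1L) stop("the pool needs at least one taxon", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("pool frequencies must be in [0, 1]", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8)
    stop("pool frequencies must sum to 1 (lineage taxa have p = 0)", call. = FALSE)
  structure(list(p = p, K = length(p)), class = "colonizer_pool")
}

#' @export
print.colonizer_pool <- function(x, ...) {
  cat("Colonizer pool with", x$K, "taxa: p =",
      paste(signif(x$p, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Single-host microbiome state
#'
#' One host's microbiome as integer taxon counts (discrete engine) or
#' per-taxon frequencies on the simplex (SDE engine). Derived quantities:
#' `x_i = counts_i / N`, `o_i = sum_{j != i} x_j`, and the free-space
#' frequency `x0 = 1 - sum_j x_j`.
#'
#' @param counts non-negative integer vector of per-taxon microbe counts
#'   (mutually exclusive with `freqs`).
#' @param freqs per-taxon frequencies in `[0, 1]` with sum `<= 1`.
#' @param N carrying capacity.
#' @return An object of class `host_state` with elements `counts` or
#'   `freqs`, `N`, and `type` (`"counts"` or `"freqs"`).
#' @examples
#' host_state(counts = c(200, 300), N = 1000)
#' host_state(freqs = c(0.2, 0.3), N = 1000)
#' @export
host_state <- function(counts = NULL, freqs = NULL, N) {
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("'N' must be a positive integer", call. = FALSE)
  if (!is.null(counts) && !is.null(freqs))
    stop("give either 'counts' or 'freqs', not both", call. = FALSE)
  if (!is.null(counts)) {
    counts <- as.integer(round(counts))
    if (any(is.na(counts)) || any(counts < 0))
      stop("counts must be non-negative integers", call. = FALSE)
    if (sum(counts) > N)
      stop("total count exceeds the carrying capacity N", call. = FALSE)
    return(structure(list(counts = counts, N = N, type = "counts"),
                     class = "host_state"))
  }
  if (is.null(freqs)) stop("give 'counts' or 'freqs'", call. = FALSE)
  freqs <- as.numeric(freqs)
  if (any(freqs < -1e-12) || sum(freqs) > 1 + 1e-9)
    stop("frequencies must be in [0, 1] with total <= 1", call. = FALSE)
  freqs[freqs < 0] <- 0
  structure(list(freqs = freqs, N = N, type = "freqs"), class = "host_state")
}

#' @export
print.host_state <- function(x, ...) {
  v <- if (x$type == "counts") x$counts else signif(x$freqs, 4)
  cat("Host state (", x$type, ", N = ", x$N, "): ", paste(v, collapse = ", "),
      "; load = ", signif(host_load(x), 4), "\n", sep = "")
  invisible(x)
}

#' Total microbial load of a host state
#'
#' The occupied fraction of the carrying capacity, `x_i + o_i`.
#'
#' @param state a [host_state()].
#' @return A number in `[0, 1]`.
#' @export
host_load <- function(state) {
  stopifnot(inherits(state, "host_state"))
  if (state$type == "counts") sum(state$counts) / state$N else sum(state$freqs)
}

#' Per-taxon frequencies of a host state
#'
#' @param state a [host_state()].
#' @return Numeric vector of frequencies `x_i`.
#' @export
host_freqs <- function(state) {
  stopifnot(inherits(state, "host_state"))
  if (state$type == "counts") state$counts / state$N else state$freqs
}

# internal: (x, o) projection of a state onto a focal taxon
project_state <- function(state, taxon) {
  f <- host_freqs(state)
  if (taxon < 1L || taxon > length(f)) stop("invalid taxon index", call. = FALSE)
  c(x = f[taxon], o = sum(f[-taxon]))
}
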