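#' Parental-transfer kernel specification
#'
#' Defines how a newborn's microbiome is seeded from its parent. In mode
#' `"beta"`, the fraction of the parent's taxon-i microbes transferred to the
#' offspring is drawn from a `Beta(a_i + 1, b_i + 1)` distribution,
#' independently per taxon; the parent keeps the exact complement, so the
#' number of microbes is conserved at every birth. Mode `"none"` produces
#' microbe-free newborns and leaves the parent untouched.
#'
#' @param mode `"none"` or `"beta"`.
#' @param a,b numeric vectors of per-taxon shape parameters, `>= 0`.
#'   Recycled to a common length. Ignored when `mode = "none"`.
#' @return An object of class `inheritance_spec`.
#' @examples
#' inheritance_spec("beta", a = 0, b = 9)   # 'low inheritance', mean 1/11
#' inheritance_spec("none")                 # microbe-free birth
#' @export
inheritance_spec <- function(mode = c("none", "beta"), a = 0, b = 0) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (any(a < 0) || any(b < 0))
    stop("shape parameters 'a' and 'b' must be >= 0", call. = FALSE)
  len <- max(length(a), length(b))
  structure(list(mode = mode, a = rep_len(a, len), b = rep_len(b, len)),
            class = "inheritance_spec")
}

#' @export
print.inheritance_spec <- function(x, ...) {
  if (x$mode == "none") {
    cat("Inheritance: none (microbe-free newborns)\n")
  } else {
    cat("Inheritance: beta kernel, a =", paste(x$a, collapse = ", "),
        "; b =", paste(x$b, collapse = ", "),
        "; mean fraction =",
        paste(signif(expected_inherited_fraction(x$a, x$b), 4), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Density of the transferred fraction
#'
#' Probability density of the fraction `f = delta_x / x_parent` of a parental
#' taxon transferred to the offspring: a `Beta(a + 1, b + 1)` density,
#' `f^a (1 - f)^b / B(a + 1, b + 1)`. With `a = b = 0` the parental microbes
#' are split uniformly at random between parent and offspring.
#'
#' @param f fraction(s) in `[0, 1]`.
#' @param a,b shape parameters, `>= 0`.
#' @return Density values at `f`.
#' @examples
#' transfer_density(0.5, 1, 1)  # 1.5
#' @export
transfer_density <- function(f, a, b) {
  if (any(a < 0) || any(b < 0))
    stop("shape parameters must be >= 0", call. = FALSE)
  if (any(f < 0 | f > 1))
    stop("'f' must be in [0, 1]", call. = FALSE)
  dbeta(f, a + 1, b + 1)
}

#' Draw transferred fractions from the inheritance kernel
#'
#' @param n number of draws.
#' @param a,b shape parameters, `>= 0`.
#' @return `n` fractions in `[0, 1]`, distributed `Beta(a + 1, b + 1)`.
#' @export
rtransfer <- function(n, a, b) {
  if (any(a < 0) || any(b < 0))
    stop("shape parameters must be >= 0", call. = FALSE)
  rbeta(n, a + 1, b + 1)
}

#' Expected fraction of a parental taxon transferred to the offspring
#'
#' Closed-form mean of the transfer kernel, `(a + 1) / (a + b + 2)`. For the
#' 'low inheritance' parameterizations `(a, b) = (0, 9)` and `(0, 99)` this
#' gives about 9\% and 1\% of the parental microbes, respectively.
#'
#' @param a,b shape parameters, `>= 0` (vectorized).
#' @return The expected transferred fraction.
#' @examples
#' expected_inherited_fraction(0, 9)   # 1/11
#' expected_inherited_fraction(0, 99)  # 1/101
#' @export
expected_inherited_fraction <- function(a, b) {
  if (any(a < 0) || any(b < 0))
    stop("shape parameters must be >= 0", call. = FALSE)
  (a + 1) / (a + b + 2)
}

#' Split a parent's microbiome between parent and offspring
#'
#' Draws, independently per taxon, a transferred fraction from the beta
#' kernel and applies it to the parental amount. On integer counts the
#' transferred number is `round(f * n_parent)` (ties to even), clamped to
#' `[0, n_parent]`; the parent keeps the exact complement, so per-taxon
#' conservation is exact on every draw. On frequencies the split is
#' continuous and likewise conserving.
#'
#' @param parent a [host_state()].
#' @param spec an [inheritance_spec()].
#' @return A list with `offspring` and `parent_after`, both [host_state()]s.
#' @examples
#' p <- host_state(counts = c(1000, 0), N = 2000)
#' sp <- inheritance_spec("beta", a = 0, b = 9)
#' sample_inheritance(p, sp)
#' @export
sample_inheritance <- function(parent, spec) {
  stopifnot(inherits(parent, "host_state"), inherits(spec, "inheritance_spec"))
  K <- length(host_freqs(parent))
  if (spec$mode == "none") {
    off <- if (parent$type == "counts")
      host_state(counts = integer(K), N = parent$N)
    else host_state(freqs = numeric(K), N = parent$N)
    return(list(offspring = off, parent_after = parent))
  }
  a <- rep_len(spec$a, K); b <- rep_len(spec$b, K)
  f <- rbeta(K, a + 1, b + 1)
  if (parent$type == "counts") {
    transf <- as.integer(pmin(pmax(round(f * parent$counts), 0), parent$counts))
    list(offspring = host_state(counts = transf, N = parent$N),
         parent_after = host_state(counts = parent$counts - transf,
                                   N = parent$N))
  } else {
    transf <- f * parent$freqs
    list(offspring = host_state(freqs = transf, N = parent$N),
         parent_after = host_state(freqs = parent$freqs - transf,
                                   N = parent$N))
  }
}

#' Canonical inheritance modes
#'
#' Convenience constructor for the three qualitative transfer-distribution
#' shapes: `"low"` (mode at 0; `a = 0, b = strength`, e.g. minimal transfer
#' during delivery), `"full"` (mode at the full parental amount;
#' `a = strength, b = 0`, e.g. reproduction by fragmentation) and
#' `"seed_like"` (symmetric, concentrated around one half;
#' `a = b = strength`, e.g. a consistent cargo in seeds).
#'
#' @param kind one of `"low"`, `"full"`, `"seed_like"`.
#' @param strength non-negative skew/concentration parameter.
#' @param taxa number of taxa (shapes are shared across taxa).
#' @return An [inheritance_spec()] in mode `"beta"`.
#' @examples
#' make_mode_spec("low", 9, 2)   # a = 0, b = 9: offspring get ~9% on average
#' @export
make_mode_spec <- function(kind = c("low", "full", "seed_like"), strength,
                           taxa = 1L) {
  kind <- match.arg(kind)
  if (strength < 0) stop("'strength' must be >= 0", call. = FALSE)
  taxa <- as.integer(taxa)
  ab <- switch(kind,
               low = c(0, strength),
               full = c(strength, 0),
               seed_like = c(strength, strength))
  inheritance_spec("beta", a = rep(ab[1], taxa), b = rep(ab[2], taxa))
}
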