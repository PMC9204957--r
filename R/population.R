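#' Population run configuration
#'
#' @param engine `"discrete"` (exact jump process) or `"sde"`
#'   (Euler-Maruyama).
#' @param t_max run horizon in timesteps.
#' @param record_times snapshot times within `[0, t_max]`; defaults to a
#'   geometric grid (plus 0 and `t_max`) so early colonization dynamics are
#'   resolved.
#' @param inheritance an [inheritance_spec()].
#' @param dt SDE integration step (ignored by the discrete engine).
#' @param log_births keep a per-birth audit log (discrete engine): parent
#'   state before the split, transferred counts, parent state after.
#' @param lineage_taxon 1-based taxon index whose slot-level extinction and
#'   peak frequency are tracked (discrete engine), or `NULL`.
#' @return An object of class `population_config`.
#' @export
population_config <- function(engine = c("discrete", "sde"), t_max,
                              record_times = NULL,
                              inheritance = inheritance_spec("none"),
                              dt = 1, log_births = FALSE,
                              lineage_taxon = NULL) {
  engine <- match.arg(engine)
  t_max <- as.numeric(t_max)
  if (is.na(t_max) || t_max < 1) stop("'t_max' must be >= 1", call. = FALSE)
  if (is.null(record_times)) {
    record_times <- unique(c(0, round(exp(seq(0, log(t_max), length.out = 20))),
                             t_max))
  }
  record_times <- sort(unique(as.numeric(record_times)))
  if (any(record_times < 0) || any(record_times > t_max))
    stop("'record_times' must lie within [0, t_max]", call. = FALSE)
  stopifnot(inherits(inheritance, "inheritance_spec"))
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (!is.null(lineage_taxon)) lineage_taxon <- as.integer(lineage_taxon)
  structure(list(engine = engine, t_max = t_max, record_times = record_times,
                 inheritance = inheritance, dt = dt,
                 log_births = isTRUE(log_births),
                 lineage_taxon = lineage_taxon),
            class = "population_config")
}

#' Run the host-population simulation
#'
#' Simulates `H` hosts. Within hosts, microbiomes evolve independently under
#' the chosen engine; a host death is immediately followed by the birth of a
#' new host, seeded from a parent chosen uniformly among the `H - 1`
#' survivors according to the inheritance kernel (the parent is debited by
#' exactly the transferred amount). The host count is constant throughout.
#' In the discrete engine host death is geometric with per-step probability
#' `tau` and same-step deaths are processed in ascending host index; the SDE
#' engine draws exponential lifespans with mean `1/tau`.
#'
#' @param lh a [life_history()].
#' @param pool a [colonizer_pool()].
#' @param cfg a [population_config()].
#' @param init optional `H x K` matrix of initial per-host taxon counts
#'   (discrete) or frequencies (sde); defaults to all-empty hosts.
#' @return An object of class `population_run`: list with `times`,
#'   `snapshots` (list of `population_snapshot` objects), `births` (audit
#'   data.frame or `NULL`), `lineage` (slot-level extinction times and peak
#'   counts, or `NULL`), plus the configuration and parameters.
#' @examples
#' lh <- life_history(m = 1e-2, tau = 1e-2, alpha0 = 0, N = 100, H = 10)
#' pool <- colonizer_pool(1)
#' cfg <- population_config("discrete", t_max = 200,
#'                          inheritance = make_mode_spec("low", 9, 1))
#' run <- run_population(lh, pool, cfg)
#' @export
run_population <- function(lh, pool, cfg, init = NULL) {
  stopifnot(inherits(lh, "life_history"), inherits(pool, "colonizer_pool"),
            inherits(cfg, "population_config"))
  H <- lh$H; K <- pool$K
  if (H < 2L && cfg$inheritance$mode != "none")
    stop("inheritance needs H >= 2 (no parent pool otherwise)", call. = FALSE)
  if (is.null(init)) init <- matrix(0, H, K)
  init <- as.matrix(init)
  if (nrow(init) != H || ncol(init) != K)
    stop("'init' must be an H x K matrix", call. = FALSE)
  inh <- cfg$inheritance
  inh_mode <- if (inh$mode == "beta") 1L else 0L
  a <- rep_len(inh$a, K); b <- rep_len(inh$b, K)

  if (cfg$engine == "discrete") {
    storage.mode(init) <- "integer"
    if (any(rowSums(init) > lh$N))
      stop("initial loads exceed the carrying capacity", call. = FALSE)
    res <- cpp_run_population_discrete(
      init, lh$N, lh$m, lh$tau, lh$alpha0, pool$p,
      as.integer(cfg$t_max), as.integer(cfg$record_times),
      inh_mode, a, b, cfg$log_births,
      if (is.null(cfg$lineage_taxon)) 0L else cfg$lineage_taxon)
    births <- NULL
    if (cfg$log_births && nrow(res$births) > 0) {
      bm <- res$births
      colnames(bm) <- c("step", "dead", "parent",
                        paste0("before_", seq_len(K)),
                        paste0("transferred_", seq_len(K)),
                        paste0("after_", seq_len(K)))
      births <- as.data.frame(bm)
    } else if (cfg$log_births) {
      births <- data.frame(matrix(numeric(0), 0, 3 + 3 * K))
    }
    lineage <- NULL
    if (!is.null(cfg$lineage_taxon)) {
      lineage <- list(ext_time = res$lineage_ext_time,
                      peak_count = res$lineage_peak)
    }
    snaps <- Map(function(s, t) population_snapshot(s, t, lh$N, "discrete"),
                 res$snapshots, res$times)
  } else {
    storage.mode(init) <- "double"
    if (max(init) > 1 || any(rowSums(init) > 1 + 1e-9))
      stop("SDE initial states must be frequencies on the simplex", call. = FALSE)
    res <- cpp_run_population_sde(
      init, lh$N, lh$m, lh$tau, lh$alpha0, pool$p, cfg$dt, cfg$t_max,
      cfg$record_times, inh_mode, a, b)
    births <- NULL
    lineage <- NULL
    snaps <- Map(function(s, t) population_snapshot(s, t, lh$N, "sde"),
                 res$snapshots, res$times)
  }
  structure(list(times = res$times, snapshots = snaps, births = births,
                 lineage = lineage, lh = lh, pool = pool, cfg = cfg),
            class = "population_run")
}

#' @export
print.population_run <- function(x, ...) {
  cat("Population run (", x$cfg$engine, "): H = ", x$lh$H, ", ",
      length(x$snapshots), " snapshots up to t = ", x$cfg$t_max, "\n", sep = "")
  invisible(x)
}

#' Population snapshot
#'
#' The states of all `H` hosts at one recording time.
#'
#' @param states `H x K` matrix of counts (discrete) or frequencies (sde).
#' @param time recording time in timesteps.
#' @param N carrying capacity.
#' @param type `"discrete"` or `"sde"`.
#' @return An object of class `population_snapshot`.
#' @export
population_snapshot <- function(states, time, N, type = "discrete") {
  states <- as.matrix(states)
  if (nrow(states) < 1L) stop("empty snapshot", call. = FALSE)
  structure(list(states = states, time = time, N = N, type = type),
            class = "population_snapshot")
}

#' Per-host microbial loads in a snapshot
#'
#' @param snapshot a [population_snapshot()].
#' @return Numeric vector of length `H` with values in `[0, 1]`.
#' @export
snapshot_loads <- function(snapshot) {
  stopifnot(inherits(snapshot, "population_snapshot"))
  l <- rowSums(snapshot$states)
  if (snapshot$type == "discrete") l / snapshot$N else l
}

#' Replace a dead host by a newborn seeded from a random parent
#'
#' In-place analogue of the birth step used inside [run_population()]: the
#' host at `dead_index` is replaced by a newborn drawn from a parent chosen
#' uniformly among the other hosts, and the parent is debited by the
#' transferred amount.
#'
#' @param snapshot a [population_snapshot()].
#' @param dead_index index of the dead host.
#' @param inheritance an [inheritance_spec()].
#' @return The updated [population_snapshot()], with attributes
#'   `parent_index` and `transferred`.
#' @export
replace_host <- function(snapshot, dead_index, inheritance) {
  stopifnot(inherits(snapshot, "population_snapshot"),
            inherits(inheritance, "inheritance_spec"))
  H <- nrow(snapshot$states)
  if (H < 2L) stop("need H >= 2 to pick a parent", call. = FALSE)
  dead_index <- as.integer(dead_index)
  if (is.na(dead_index) || dead_index < 1L || dead_index > H)
    stop("invalid 'dead_index'", call. = FALSE)
  candidates <- setdiff(seq_len(H), dead_index)
  parent <- candidates[sample.int(length(candidates), 1L)]
  ps <- if (snapshot$type == "discrete")
    host_state(counts = snapshot$states[parent, ], N = snapshot$N)
  else host_state(freqs = snapshot$states[parent, ], N = snapshot$N)
  sp <- sample_inheritance(ps, inheritance)
  snapshot$states[parent, ] <- if (snapshot$type == "discrete")
    sp$parent_after$counts else sp$parent_after$freqs
  snapshot$states[dead_index, ] <- if (snapshot$type == "discrete")
    sp$offspring$counts else sp$offspring$freqs
  attr(snapshot, "parent_index") <- parent
  attr(snapshot, "transferred") <- snapshot$states[dead_index, ]
  snapshot
}
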