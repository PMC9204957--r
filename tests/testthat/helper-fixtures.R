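# Shared builders and small statistical helpers for the test suite.
# All fixtures are generated in code; no data files.

lh_default <- function(m = 0.01, tau = 1e-4, alpha0 = 0, N = 100L, H = 2L) {
  life_history(m = m, tau = tau, alpha0 = alpha0, N = N, H = H)
}

pool2 <- function(p1 = 0.3) colonizer_pool(c(p1, 1 - p1))

# z-score for a difference of means of two samples
z_mean <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
}

# z-score for a difference of variances (4th-moment asymptotic SE)
z_var <- function(x, y) {
  se2 <- function(v) {
    n <- length(v)
    m4 <- mean((v - mean(v))^4)
    (m4 - var(v)^2 * (n - 3) / (n - 1)) / n
  }
  (var(x) - var(y)) / sqrt(se2(x) + se2(y))
}

# random valid host count vector with K taxa and capacity N
random_counts <- function(K, N) {
  load <- sample.int(N + 1L, 1L) - 1L
  if (load == 0L) return(integer(K))
  as.integer(stats::rmultinom(1, load, prob = rep(1, K)))
}

# final-snapshot summary of a quick discrete population run
final_summary <- function(lh, pool, t_max, inheritance, init = NULL, ...) {
  cfg <- population_config("discrete", t_max = t_max,
                           record_times = c(0, t_max),
                           inheritance = inheritance, ...)
  run <- run_population(lh, pool, cfg, init = init)
  summarize_snapshot(run$snapshots[[length(run$snapshots)]])
}
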