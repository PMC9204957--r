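# Exact one-step transition structure of the within-host jump process.

test_that("transition probabilities match hand-evaluated values", {
  # state (x, o) = (0.2, 0.3), m = 0.01, p_i = 0.1, alpha0 = 1, tau = 1e-4:
  # D = 1*0.5 + 0.5 = 1. Frozen values computed by direct hand evaluation
  # of the six replacement/fill/loss terms and the stay complement.
  lh <- lh_default(m = 0.01, tau = 1e-4, alpha0 = 1, N = 100L)
  ts <- transition_probabilities(c(0.2, 0.3), lh, pool = 0.1)
  expect_equal(unname(ts[["t_xm_op"]]), 0.06119388, tolerance = 1e-8)
  expect_equal(unname(ts[["t_xp_om"]]), 0.05969403, tolerance = 1e-8)
  expect_equal(unname(ts[["t_op"]]), 0.15298470, tolerance = 1e-8)
  expect_equal(unname(ts[["t_xp"]]), 0.09949005, tolerance = 1e-8)
  expect_equal(unname(ts[["t_xm"]]), 0.09899010, tolerance = 1e-8)
  expect_equal(unname(ts[["t_om"]]), 0.14848515, tolerance = 1e-8)
  expect_equal(unname(ts[["t_hostdeath"]]), 1e-4)
  expect_equal(sum(ts), 1)
})

test_that("degenerate states behave as the model prescribes", {
  # empty host without immigration is absorbing: all microbial events 0
  lh <- lh_default(m = 0, tau = 0.05, alpha0 = 2)
  ts <- transition_probabilities(c(0, 0), lh, pool = 0.4)
  expect_equal(unname(ts[1:6]), rep(0, 6))
  expect_equal(unname(ts[["t_stay"]]), 1 - 0.05)

  # full occupancy by the focal taxon: only focal-death replacement remains
  lh2 <- lh_default(m = 0.2, tau = 0.01, alpha0 = 3)
  ts2 <- transition_probabilities(c(1, 0), lh2, pool = 0.25)
  expect_equal(unname(ts2[["t_xm_op"]]), (1 - 0.01) * 0.2 * 0.75)
  expect_equal(unname(ts2[c("t_op", "t_xp", "t_xm", "t_om")]), rep(0, 4))

  expect_error(transition_probabilities(c(0.7, 0.5), lh, 0.1), "simplex")
  expect_error(transition_probabilities(c(0.2, 0.1), lh, 1.5), "p_i")
  expect_error(life_history(m = 2, tau = 0, alpha0 = 0, N = 10, H = 2), "'m'")
  expect_error(life_history(0.1, 0.1, -1, 10, 2), "alpha0")
  expect_error(colonizer_pool(c(0.5, 0.4)), "sum to 1")
})

test_that("transition sets are normalized and non-negative across random states", {
  set.seed(101)
  for (i in 1:200) {
    x <- runif(1); o <- runif(1, 0, 1 - x)
    lh <- life_history(m = runif(1), tau = runif(1), alpha0 = runif(1, 0, 3),
                       N = sample(10:1000, 1), H = 2L)
    ts <- transition_probabilities(c(x, o), lh, pool = runif(1))
    expect_true(all(ts >= -1e-15))
    expect_equal(sum(ts), 1, tolerance = 1e-12)
  }
})

test_that("multi-taxon event distribution marginalizes exactly to the projection", {
  set.seed(102)
  lh <- lh_default(m = 0.05, tau = 1e-3, alpha0 = 0.7, N = 200L)
  pool <- colonizer_pool(c(0.5, 0.3, 0.2))
  for (i in 1:25) {
    st <- host_state(counts = random_counts(3, 200L), N = 200L)
    ev <- event_distribution(st, lh, pool)
    expect_equal(sum(ev$prob), 1, tolerance = 1e-12)
    expect_true(all(ev$prob >= -1e-15))
    for (taxon in 1:3) {
      mg <- marginalize_events(ev, taxon)
      tp <- transition_probabilities(st, lh, pool, taxon)
      expect_equal(unname(mg), unname(unclass(tp)), tolerance = 1e-12)
    }
    # pooling taxa 2+3 into one reproduces the 2-taxon computation
    pooled <- host_state(counts = c(st$counts[1], sum(st$counts[2:3])),
                         N = 200L)
    tp2 <- transition_probabilities(pooled, lh,
                                    colonizer_pool(c(0.5, 0.5)), 1)
    tp3 <- transition_probabilities(st, lh, pool, 1)
    expect_equal(unname(unclass(tp2)), unname(unclass(tp3)), tolerance = 1e-12)
  }
})

test_that("sampled one-step event frequencies match the analytic probabilities", {
  set.seed(103)
  lh <- lh_default(m = 0.05, tau = 0.01, alpha0 = 0.7, N = 100L)
  pool <- pool2(0.2)
  init <- c(20L, 30L)
  nrep <- 1e5
  d <- mbinherit:::cpp_one_step_batch(init, 100L, lh$m, lh$tau, lh$alpha0,
                                      pool$p, nrep)
  ts <- transition_probabilities(host_state(counts = init, N = 100), lh,
                                 pool, 1)
  obs <- c(
    t_xm_op = mean(d[, 1] == -1 & d[, 2] == 1),
    t_xp_om = mean(d[, 1] == 1 & d[, 2] == -1),
    t_op = mean(d[, 1] == 0 & d[, 2] == 1),
    t_xp = mean(d[, 1] == 1 & d[, 2] == 0),
    t_xm = mean(d[, 1] == -1 & d[, 2] == 0),
    t_om = mean(d[, 1] == 0 & d[, 2] == -1),
    t_stay = mean(d[, 1] == 0 & d[, 2] == 0 & d[, 3] == 0),
    t_hostdeath = mean(d[, 3] == 1))
  for (nm in names(obs)) {
    p <- ts[[nm]]
    se <- sqrt(p * (1 - p) / nrep)
    expect_lt(abs(obs[[nm]] - p), 4 * se + 1e-12)
  }
})

test_that("one-step moves conserve counts and stay within [0, N]", {
  set.seed(104)
  for (i in 1:20) {
    n0 <- random_counts(3, 50L)
    d <- mbinherit:::cpp_one_step_batch(n0, 50L, runif(1), 0.02,
                                        runif(1, 0, 2), c(0.2, 0.3, 0.5), 500L)
    dl <- rowSums(d[, 1:3, drop = FALSE])
    expect_true(all(dl %in% c(-1L, 0L, 1L)))
    news <- sweep(d[, 1:3, drop = FALSE], 2, n0, "+")
    expect_true(all(news >= 0))
    expect_true(all(rowSums(news) <= 50L))
  }
})

test_that("death-immigration stationary mean recovers the pool frequency", {
  # tau = 0, alpha0 = 0, m = 1: every replacement is an immigrant, so the
  # long-run within-host frequency of taxon i is p_i.
  set.seed(105)
  N <- 200L
  lh <- life_history(m = 1, tau = 0, alpha0 = 0, N = N, H = 2L)
  pool <- pool2(0.3)
  nrep <- 200
  xf <- replicate(nrep, {
    tr <- simulate_host_discrete(host_state(counts = c(0L, 0L), N = N),
                                 lh, pool, max_steps = 5L * N,
                                 record_every = 5L * N)
    tr$final[1] / N
  })
  se <- sd(xf) / sqrt(nrep)
  expect_lt(abs(mean(xf) - 0.3), 4 * se)
  # with alpha0 = 0 the host also fills completely
  tr <- simulate_host_discrete(host_state(counts = c(0L, 0L), N = N),
                               lh, pool, max_steps = 20L * N,
                               record_every = 20L * N)
  expect_equal(sum(tr$final), N)
})

test_that("slow establishment without immigration drives microbiomes extinct", {
  # alpha0 > 1, m = 0: from interior states every trajectory absorbs at 0
  # (the exactly-full state is a second absorbing state; we start below it)
  set.seed(106)
  N <- 200L
  lh <- life_history(m = 0, tau = 0, alpha0 = 2, N = N, H = 2L)
  pool <- pool2(0.5)
  for (r in 1:20) {
    tr <- simulate_host_discrete(host_state(counts = c(60L, 60L), N = N),
                                 lh, pool, max_steps = 5e4, record_every = 5e4)
    expect_equal(sum(tr$final), 0)
  }
  # and the empty state is absorbing: nothing re-enters
  tr0 <- simulate_host_discrete(host_state(counts = c(0L, 0L), N = N),
                                lh, pool, max_steps = 1000, record_every = 1000)
  expect_equal(sum(tr0$final), 0)
})

test_that("host death timing follows the per-step probability", {
  lh <- life_history(0.5, 1, 0, 10, 2)
  res <- step_discrete(host_state(counts = c(1L, 1L), N = 10), lh, pool2())
  expect_true(res$died)
  set.seed(107)
  lh2 <- life_history(0, 0.2, 0, 10, 2)
  deaths <- replicate(2000, step_discrete(host_state(counts = c(1L, 1L), N = 10),
                                          lh2, pool2())$died)
  expect_lt(abs(mean(deaths) - 0.2), 4 * sqrt(0.2 * 0.8 / 2000))
  expect_error(simulate_host_discrete(host_state(counts = c(0L, 0L), N = 10),
                                      lh2, pool2(), max_steps = 0), "max_steps")
})
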