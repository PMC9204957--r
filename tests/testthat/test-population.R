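# Population orchestration: turnover, inheritance seeding, conservation.

test_that("host count stays constant and snapshots are valid", {
  set.seed(401)
  lh <- life_history(1e-2, 5e-3, 0, 200L, 25L)
  cfg <- population_config("discrete", t_max = 1000,
                           record_times = c(0, 250, 500, 1000),
                           inheritance = make_mode_spec("low", 9, 2))
  run <- run_population(lh, pool2(), cfg)
  expect_length(run$snapshots, 4L)
  for (s in run$snapshots) {
    expect_equal(nrow(s$states), 25L)
    expect_true(all(s$states >= 0))
    expect_true(all(rowSums(s$states) <= 200L))
  }
})

test_that("without inheritance every newborn starts microbe-free", {
  set.seed(402)
  lh <- life_history(0.5, 0.02, 0, 50L, 10L)
  cfg <- population_config("discrete", t_max = 500, record_times = 500,
                           inheritance = inheritance_spec("none"),
                           log_births = TRUE)
  run <- run_population(lh, pool2(), cfg)
  expect_gt(nrow(run$births), 20)
  expect_true(all(run$births$transferred_1 == 0))
  expect_true(all(run$births$transferred_2 == 0))
})

test_that("births split the parent exactly (conservation audit)", {
  set.seed(403)
  lh <- life_history(0.1, 0.01, 0, 100L, 15L)
  cfg <- population_config("discrete", t_max = 2000, record_times = 2000,
                           inheritance = make_mode_spec("low", 3, 2),
                           log_births = TRUE)
  run <- run_population(lh, pool2(), cfg)
  b <- run$births
  expect_gt(nrow(b), 50)
  for (k in 1:2) {
    expect_true(all(b[[paste0("before_", k)]] ==
                      b[[paste0("transferred_", k)]] + b[[paste0("after_", k)]]))
    expect_true(all(b[[paste0("transferred_", k)]] >= 0))
  }
})

test_that("parents are chosen uniformly among the other hosts", {
  set.seed(404)
  H <- 6L
  snap <- population_snapshot(matrix(5L, H, 2), 0, 100L)
  picks <- replicate(3000, {
    attr(replace_host(snap, 2L, inheritance_spec("none")), "parent_index")
  })
  expect_false(any(picks == 2L))
  tab <- table(factor(picks, levels = setdiff(1:H, 2L)))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
  # H = 2: the parent is always the surviving host
  snap2 <- population_snapshot(matrix(c(3L, 7L), 2, 1), 0, 10L)
  p2 <- replicate(20, attr(replace_host(snap2, 1L,
                                        inheritance_spec("none")),
                           "parent_index"))
  expect_true(all(p2 == 2L))
})

test_that("near-total inheritance nearly empties the parent", {
  set.seed(405)
  parent_full <- matrix(c(100L, 50L), 2, 2, byrow = TRUE)
  snap <- population_snapshot(rbind(c(100L, 50L), c(100L, 50L)), 0, 200L)
  spec <- make_mode_spec("full", 49, 2)
  fr <- replicate(200, {
    ns <- replace_host(snap, 1L, spec)
    sum(ns$states[1, ]) / 150
  })
  mu <- expected_inherited_fraction(49, 0) # 50/51
  expect_lt(abs(mean(fr) - mu), 4 * sd(fr) / sqrt(200))
})

test_that("population runs without inheritance equal independent hosts", {
  set.seed(406)
  N <- 200L; H <- 50L
  lh <- life_history(0.01, 0, 0, N, H)
  cfg <- population_config("discrete", t_max = 2000, record_times = 2000,
                           inheritance = inheritance_spec("none"))
  run <- run_population(lh, pool2(), cfg)
  pop_loads <- snapshot_loads(run$snapshots[[1]])
  ind_loads <- replicate(H, {
    tr <- simulate_host_discrete(host_state(counts = c(0L, 0L), N = N),
                                 lh, pool2(), 2000, 2000)
    sum(tr$final) / N
  })
  expect_lt(abs(z_mean(pop_loads, ind_loads)), 4)
})

test_that("inheritance needs a parent pool", {
  lh <- life_history(0.1, 0.1, 0, 50L, 2L)
  expect_error(population_config("discrete", t_max = 10,
                                 record_times = c(0, 20)), "record_times")
  expect_error(run_population(lh, pool2(),
                              population_config("discrete", t_max = 10),
                              init = matrix(0, 3, 2)), "H x K")
})

test_that("SDE population conserves at births and keeps H constant", {
  set.seed(407)
  lh <- life_history(1e-2, 5e-3, 0, 200L, 12L)
  cfg <- population_config("sde", t_max = 400, record_times = c(0, 200, 400),
                           inheritance = make_mode_spec("low", 9, 2))
  run <- run_population(lh, pool2(), cfg)
  for (s in run$snapshots) {
    expect_equal(nrow(s$states), 12L)
    expect_true(all(s$states >= -1e-12))
    expect_true(all(rowSums(s$states) <= 1 + 1e-9))
  }
})
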