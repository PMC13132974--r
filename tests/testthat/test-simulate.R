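test_that("expected-difficulty grids match hand arithmetic", {
  g <- ans_expected_grid(study1_values())
  expect_equal(g$difficulty[g$small == 40 & g$large == 45], log(9))
  expect_equal(g$difficulty[g$small == 5 & g$large == 45], log(45 / 40))
  flat <- ans_expected_grid(study1_values(), grid_params(a = 0, b = 2))
  expect_true(all(flat$difficulty == 2))
  d <- dss_expected_grid(1:9)
  expect_equal(d$difficulty[d$small == 1 & d$large == 2], 1.9)
  expect_equal(d$difficulty[d$small == 8 & d$large == 9],
               0.4 + 1 / 8 + 1 / 9)
  flat2 <- dss_expected_grid(1:9, grid_params(a1 = 0, a2 = 0, b = 1))
  expect_true(all(flat2$difficulty == 1))
  expect_error(dss_expected_grid(0:3), "zero value")
})

test_that("single-trial simulator validates input and maps sides", {
  expect_error(simulate_ddm_trial(c(10, 10), 1), "tie")
  expect_error(simulate_ddm_trial(c(5, 10), 1, phi = 1.2), "phi")
  set.seed(1)
  tr <- simulate_ddm_trial(c(45, 5), 1, ddm_params(k = 5, a0 = 0.15))
  expect_true(tr$correct)          # huge drift: error essentially impossible
  expect_identical(tr$response_side, "left")
  expect_identical(tr$choice, "larger")
})

test_that("zero drift yields chance accuracy", {
  set.seed(42)
  sim <- simulate_ddm_trials(0, 0.1, 0.2, n = 4000)
  expect_lt(abs(mean(sim$correct) - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("simulated first-passage moments track the closed forms", {
  v <- 0.2; a <- 0.1; s <- 0.1
  set.seed(7)
  sim <- simulate_ddm_trials(v, a, 0, n = 10000)
  pc_th <- 1 / (1 + exp(-v * a / s^2))
  mdt_th <- (a / (2 * v)) * tanh(v * a / (2 * s^2))
  expect_lt(abs(mean(sim$correct) - pc_th),
            3 * sqrt(pc_th * (1 - pc_th) / 10000))
  expect_lt(abs(mean(sim$rt) - mdt_th), 3 * sd(sim$rt) / sqrt(10000))
})

test_that("coarser Euler steps bias mean decision time more", {
  v <- 0.15; a <- 0.12
  mdt_th <- (a / (2 * v)) * tanh(v * a / (2 * 0.01))
  set.seed(5)
  coarse <- mean(simulate_ddm_trials(v, a, 0, n = 20000, dt = 0.02)$rt)
  set.seed(5)
  fine <- mean(simulate_ddm_trials(v, a, 0, n = 20000, dt = 0.001)$rt)
  expect_gt(abs(coarse - mdt_th), abs(fine - mdt_th))
})

test_that("cohorts are reproducible and carry the design structure", {
  s1 <- build_study1_design(repeats = 1L)
  ch <- cohort_spec(3, 0.1, 99)
  a <- simulate_ans_cohort(s1, ch)
  b <- simulate_ans_cohort(s1, ch)
  expect_identical(a, b)
  expect_equal(nrow(a), 3 * 30)
  expect_equal(sort(unique(a$block)), 1:4)
  expect_true(all(a$rt_ms == round(a$rt_ms) & a$rt_ms > 0))
  # block quarters are contiguous in presentation order
  one <- a[a$participant_id == "p001", ]
  expect_true(all(diff(one$block[order(one$trial_index)]) >= 0))
  d <- simulate_dss_cohort(s1, ch)
  expect_identical(d, simulate_dss_cohort(s1, ch))
  expect_true(all(validate_trials(d)$rt_ms > 0))
})

test_that("noiseless statistics-driven generator is deterministic in RT", {
  s1 <- build_study1_design(repeats = 1L)
  p <- dss_gen_params(rt_noise_sd = 0,
                      er_logit_intercept = -30)  # essentially error-free
  tr <- simulate_dss_cohort(s1, cohort_spec(1, 0, 5), p)
  key <- paste(pmin(tr$left_value, tr$right_value),
               pmax(tr$left_value, tr$right_value))
  spread <- tapply(tr$rt_ms, key, function(x) diff(range(x)))
  expect_true(all(spread == 0))
  expect_true(all(tr$correct))
})

test_that("threshold coupling speeds the frequent pairs of a session", {
  ev <- build_trial_templates(build_frequency_table("everyday"), 2L, seed = 3)
  tr0 <- simulate_ans_cohort(ev, cohort_spec(6, 0, 31), ddm_params(),
                             frequency_coupling())
  tr1 <- simulate_ans_cohort(ev, cohort_spec(6, 0, 31), ddm_params(),
                             frequency_coupling(threshold = 0.4))
  hi <- tr1$left_value + tr1$right_value == 15   # the (5,10) pair, phi = 1
  expect_lt(median(tr1$rt_ms[hi]), median(tr0$rt_ms[hi]))
  # and within the coupled session, frequent pairs beat rare ones by more
  # than the uncoupled difficulty gap
  lo <- tr1$left_value + tr1$right_value == 85   # the (40,45) pair
  gap1 <- median(tr1$rt_ms[lo]) - median(tr1$rt_ms[hi])
  lo0 <- tr0$left_value + tr0$right_value == 85
  hi0 <- tr0$left_value + tr0$right_value == 15
  gap0 <- median(tr0$rt_ms[lo0]) - median(tr0$rt_ms[hi0])
  expect_gt(gap1, gap0)
})

test_that("drift coupling makes frequent stimuli faster and more accurate", {
  # two pairs with the same 2:1 ratio (identical baseline drift) but extreme
  # frequency contrast: (5,10) carries phi = 1, (20,40) phi = 0.2
  tab <- structure(list(condition = "uniform",
                        values = c(5L, 10L, 20L, 40L),
                        freq = c(`5` = 5L, `10` = 5L, `20` = 2L, `40` = 2L)),
                   class = "frequency_table")
  d <- build_trial_templates(tab, repeats = 12L, seed = 6)
  keep <- paste(d$templates$left_value, d$templates$right_value) %in%
    c("5 10", "10 5", "20 40", "40 20")
  d$templates <- d$templates[keep, ]
  d$total_trials <- sum(d$templates$multiplicity)
  cpl <- frequency_coupling(drift = 1.0)
  tr <- simulate_ans_cohort(d, cohort_spec(4, 0, 41), ddm_params(k = 0.2),
                            cpl, center_phi = FALSE)
  freq <- pmax(tr$left_value, tr$right_value) == 10
  expect_lt(median(tr$rt_ms[freq]), median(tr$rt_ms[!freq]))
  expect_gt(mean(tr$correct[freq]), mean(tr$correct[!freq]))
})

test_that("block decay shrinks the frequency effect over the session", {
  ev <- build_trial_templates(build_frequency_table("everyday"), 2L, seed = 3)
  cpl <- frequency_coupling(threshold = 0.45, block_decay = 0.5)
  tr <- simulate_ans_cohort(ev, cohort_spec(8, 0, 51), ddm_params(), cpl)
  hi <- tr$left_value + tr$right_value == 15
  lo <- tr$left_value + tr$right_value >= 75
  gap <- sapply(1:4, function(b)
    median(tr$rt_ms[lo & tr$block == b]) - median(tr$rt_ms[hi & tr$block == b]))
  expect_gt(gap[1], gap[4])
})
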