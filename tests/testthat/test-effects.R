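test_that("regressors match their defining arithmetic", {
  v <- study1_values()
  rv <- make_regressor("value_distance", v)
  ra <- make_regressor("association_distance", v)
  rs <- make_regressor("size_sum", v)
  pick <- function(r, s, l) r$x[r$small == s & r$large == l]
  expect_equal(pick(rv, 5, 10), log(5))
  expect_equal(pick(ra, 5, 10), 0)            # adjacent ranks: ln 1
  expect_equal(pick(ra, 15, 35), 0)           # the omitted-range dissociation
  expect_equal(pick(rv, 15, 35), log(20))
  expect_equal(pick(rs, 5, 45), 10)
  # multiplying the values by 5 shifts the ln-distance predictor by ln 5
  rv5 <- make_regressor("value_distance", v * 5)
  expect_equal(rv5$x, rv$x + log(5))
  expect_error(make_regressor("value_distance", c(5, 5, 10)),
               "tie|duplicate")
})

test_that("distance and size regressors are orthogonal on the full design", {
  rv <- make_regressor("value_distance", study2_values())
  rs <- make_regressor("size_sum", study2_values())
  expect_lt(abs(cor(rv$x, rs$x)), 1e-10)
  # hence simple and multiple regression agree on the weights
  set.seed(3)
  y <- 2 * rv$x - 0.5 * rs$x + rnorm(36, 0, 0.3)
  simple_v <- coef(lm(y ~ rv$x))[2]
  simple_s <- coef(lm(y ~ rs$x))[2]
  multi <- coef(lm(y ~ rv$x + rs$x))
  expect_equal(unname(simple_v), unname(multi[2]))
  expect_equal(unname(simple_s), unname(multi[3]))
})

test_that("least-squares fits recover known structure", {
  reg <- make_regressor("value_distance", study1_values())
  base <- data.frame(participant_id = "p1", condition = "x",
                     small = reg$small, large = reg$large, n_trials = 10)
  lin <- base
  lin$median_rt_ms <- 700 - 90 * reg$x
  lin$mean_error_rate <- 0.2
  f <- fit_effect(lin, reg, "median_rt", "participant")
  expect_equal(f$slope, -90)
  expect_equal(f$intercept, 700)
  expect_equal(f$r_squared, 1)
  fc <- fit_effect(lin, reg, "error_rate", "participant")
  expect_equal(fc$slope, 0)
  expect_equal(fc$r_squared, 0)
  # frozen 3-point toy: slope 1.5, intercept 5/6, R^2 = 27/28
  toyreg <- structure(data.frame(small = c(1, 2, 3), large = c(9, 8, 7),
                                 x = c(0, 1, 2)), kind = "value_distance")
  attr(toyreg, "kind") <- "toy"
  toy <- data.frame(participant_id = "p1", condition = "x",
                    small = c(1, 2, 3), large = c(9, 8, 7), n_trials = 1,
                    median_rt_ms = c(1, 2, 4), mean_error_rate = 0)
  ft <- fit_effect(toy, toyreg, "median_rt", "participant")
  expect_equal(ft$slope, 1.5)
  expect_equal(ft$intercept, 5 / 6)
  expect_equal(ft$r_squared, 27 / 28)
})

test_that("group-level fit averages pairs across participants first", {
  reg <- make_regressor("value_distance", study1_values())
  mk <- function(id, noise) {
    d <- data.frame(participant_id = id, condition = "x", small = reg$small,
                    large = reg$large, n_trials = 10,
                    mean_error_rate = 0.1,
                    median_rt_ms = 700 - 90 * reg$x + noise)
    d
  }
  stats <- rbind(mk("p1", +25), mk("p2", -25))
  g <- fit_effect(stats, reg, "median_rt", "group")
  expect_identical(g$participant_id, "group")
  expect_equal(g$slope, -90)
  expect_equal(g$r_squared, 1)
  two <- stats[stats$small == 5 & stats$large %in% c(10, 15), ]
  expect_error(fit_effect(two, reg, "median_rt", "group"),
               "3 distinct pairs")
})

test_that("fits refuse a constant predictor", {
  reg <- make_regressor("value_distance", study1_values())
  reg$x[] <- 1
  stats <- data.frame(participant_id = "p1", condition = "x",
                      small = reg$small, large = reg$large, n_trials = 5,
                      mean_error_rate = 0.1, median_rt_ms = 500)
  expect_error(fit_effect(stats, reg, "median_rt", "participant"),
               "zero variance")
})

test_that("value-distance fits are invariant to the x5 numerosity scaling", {
  reg <- make_regressor("value_distance", 1:9)
  for (seed in 1:100) {
    set.seed(seed)
    stats <- data.frame(participant_id = "p1", condition = "x",
                        small = reg$small, large = reg$large, n_trials = 5,
                        mean_error_rate = runif(36),
                        median_rt_ms = 400 + 300 * runif(36))
    chk <- scale_invariance_check(stats, 1:9, "median_rt")
    expect_true(chk$invariant)
  }
})

test_that("grid difficulties are explained by their own account's regressor", {
  v <- study1_values()
  rv <- make_regressor("value_distance", v)
  ra <- make_regressor("association_distance", v)
  as_stats <- function(diff, small, large)
    data.frame(participant_id = "p1", condition = "x", small = small,
               large = large, n_trials = 1, mean_error_rate = 0,
               median_rt_ms = diff)
  g_ans <- ans_expected_grid(v)
  s_ans <- as_stats(g_ans$difficulty, g_ans$small, g_ans$large)
  r2 <- function(stats, reg)
    fit_effect(stats, reg, "median_rt", "participant")$r_squared
  expect_gt(r2(s_ans, rv), r2(s_ans, ra))
  # statistics-based difficulty laid out on the ranks: association wins
  om <- order_map(v)
  g_dss <- dss_expected_grid(seq_along(v))
  small <- v[g_dss$small]; large <- v[g_dss$large]
  s_dss <- as_stats(g_dss$difficulty, small, large)
  expect_gt(r2(s_dss, ra), r2(s_dss, rv))
})
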