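test_that("frequency tables reproduce the experimentally used counts", {
  ev <- build_frequency_table("everyday")
  expect_identical(unname(ev$freq),
                   c(10L, 5L, 4L, 3L, 2L, 2L, 2L, 2L, 1L))
  expect_equal(sum(ev$freq), 31)
  rv <- build_frequency_table("reversed_everyday")
  expect_identical(unname(rv$freq), rev(unname(ev$freq)))
  un <- build_frequency_table("uniform")
  expect_true(all(un$freq == 1L))
  expect_error(build_frequency_table("weekday"))
  expect_error(build_frequency_table("everyday", values = study1_values()),
               "9-value")
  expect_error(build_frequency_table("study1", values = study2_values()),
               "study1")
})

test_that("template expansion matches frequency-product combinatorics", {
  for (cnd in c("everyday", "uniform", "reversed_everyday")) {
    tab <- build_frequency_table(cnd)
    d <- build_trial_templates(tab, repeats = 1L)
    f <- tab$freq
    expect_equal(d$total_trials, sum(f)^2 - sum(f^2))
    # brute-force enumeration oracle: list every token-level ordered pair
    tokens <- rep(as.integer(names(f)), f)
    brute <- sum(outer(tokens, tokens, "!="))
    expect_equal(d$total_trials, brute)
    # left/right symmetry of summed multiplicity
    m <- d$templates
    key <- paste(pmin(m$left_value, m$right_value),
                 pmax(m$left_value, m$right_value))
    sym <- tapply(m$multiplicity, list(key, m$left_value < m$right_value), sum)
    expect_equal(unname(sym[, 1]), unname(sym[, 2]))
  }
})

test_that("session trial counts match the three conditions", {
  ev2 <- build_trial_templates(build_frequency_table("everyday"), 2L)
  expect_equal(ev2$total_trials, 1588)
  m <- ev2$templates
  expect_equal(m$multiplicity[m$left_value == 5 & m$right_value == 10], 100L)
  expect_equal(m$multiplicity[m$left_value == 40 & m$right_value == 45], 4L)
  un <- build_trial_templates(build_frequency_table("uniform"), 22L)
  expect_equal(un$total_trials, 1584)
  s1 <- build_study1_design(repeats = 20L)
  expect_equal(s1$total_trials, 600)
  expect_equal(nrow(s1$templates), 30)
  s1a <- build_study1_design(repeats = 1L)
  expect_equal(s1a$total_trials, 30)
  expect_true(all(s1$templates$left_value != s1$templates$right_value))
  expect_error(build_trial_templates(build_frequency_table("uniform"), 0L))
})

test_that("trial sequences shuffle reproducibly and cover the design", {
  s1 <- build_study1_design(repeats = 2L, seed = 7L)
  a <- trial_sequence(s1)
  b <- trial_sequence(s1)
  expect_identical(a, b)
  expect_false(identical(a, trial_sequence(s1, seed = 8L)))
  expect_equal(nrow(a), 60)
  expect_equal(as.vector(table(paste(a$left_value, a$right_value))),
               rep(2L, 30))
})

test_that("association statistics follow the design's co-occurrences", {
  s1 <- build_study1_design()
  tab <- association_statistics(s1)
  expect_equal(tab$p_smaller, c(1, 0.8, 0.6, 0.4, 0.2, 0))
  # uniform all-pairs: closed-form (m - rank)/(m - 1) for p_smaller
  u9 <- build_trial_templates(build_frequency_table("uniform", values = 1:9))
  t9 <- association_statistics(u9)
  expect_equal(t9$p_larger[t9$value == 8], 0.875)
  expect_equal(t9$p_smaller, (9 - seq_len(9)) / 8)
  # forced extremes in a two-value design
  t2 <- association_statistics(
    build_trial_templates(build_frequency_table("uniform", values = c(5L, 10L))))
  expect_equal(t2$p_smaller, c(1, 0))
  expect_equal(t2$p_larger, c(0, 1))
})

test_that("rank map sorts ascending with 1-based ranks", {
  om <- order_map(c(1, 2, 3, 7, 8, 9))
  expect_equal(unname(om["7"]), 4L)
  expect_equal(unname(order_map(study1_values())["35"]), 4L)
  expect_equal(unname(order_map(1:9)), 1:9)
  expect_error(order_map(c(5, 5, 10)), "duplicate")
})

test_that("dot arrays are non-overlapping, in-bounds, and reproducible", {
  d <- generate_dot_array(45, seed = 11)
  expect_equal(d$n_dots, 45L)
  expect_true(all(d$positions >= 0.1 & d$positions <= 1.9))
  dm <- as.matrix(stats::dist(d$positions))
  expect_true(min(dm[upper.tri(dm)]) >= 0.2)
  expect_equal(sort(table(d$colors), method = "radix"),
               sort(c(black = 23, white = 22), method = "radix"),
               ignore_attr = TRUE)
  expect_identical(generate_dot_array(45, seed = 11), d)
  expect_false(identical(generate_dot_array(45, seed = 12)$positions,
                         d$positions))
  expect_error(generate_dot_array(0), ">= 1")
  # crowding: 40 dots cannot fit a 0.5-degree field
  expect_error(generate_dot_array(40, seed = 1, field_size_deg = 0.5),
               "crowded")
})

test_that("numerosity correlates of the arrays (hull, density) differ", {
  hull_area <- function(p) {
    h <- chull(p)
    x <- p[h, 1]; y <- p[h, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  a5 <- generate_dot_array(5, seed = 2)
  a45 <- generate_dot_array(45, seed = 2)
  expect_lt(hull_area(a5$positions), hull_area(a45$positions))
  expect_lt(5 / hull_area(a5$positions), 45 / hull_area(a45$positions))
})

test_that("pair frequency is scale-invariant and sum-structured", {
  tab <- build_frequency_table("everyday")
  pf <- pair_frequency(tab)
  tab3 <- tab
  tab3$freq <- tab$freq * 3L
  expect_equal(pair_frequency(tab3)$phi, pf$phi)
  expect_equal(max(pf$phi), 1)
  expect_equal(pf$phi[pf$small == 5 & pf$large == 10], 1)  # 10 + 5 is the max
})

test_that("designs export to the trial CSV schema with empty responses", {
  s1 <- build_study1_design(repeats = 1L, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  export_trials_csv(s1, path)
  raw <- utils::read.csv(path, colClasses = "character")
  expect_identical(names(raw),
                   c("participant_id", "condition", "block", "trial_index",
                     "left_value", "right_value", "response_side", "correct",
                     "rt_ms"))
  expect_equal(nrow(raw), 30)
  expect_true(all(raw$response_side == "" & raw$rt_ms == ""))
  expect_equal(sort(as.integer(unique(raw$block))), 1:4)
})

test_that("design and dot-array specs serialize to JSON", {
  s1 <- build_study1_design(repeats = 1L)
  js <- spec_to_json(s1)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$total_trials, 30)
  expect_equal(back$base_frequency$`5`, 1)
  js2 <- spec_to_json(generate_dot_array(5, seed = 1))
  b2 <- jsonlite::fromJSON(js2)
  expect_equal(b2$n_dots, 5)
  expect_equal(length(b2$colors), 5)
})
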