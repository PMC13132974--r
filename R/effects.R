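#' Distance and size regressors
#'
#' Per-pair predictor values for the three effect regressors:
#' * `value_distance`: ln(large - small) on the raw values;
#' * `association_distance`: ln of the rank distance, with ranks from
#'   [order_map()] — the association-based prediction, under which a value's
#'   behavior follows its order in the session's set rather than its
#'   magnitude;
#' * `size_sum`: sum of the initial numbers, x1/5 + x2/5.
#'
#' Natural logarithms throughout. On a full all-pairs design the ln-distance
#' and sum-size regressors are uncorrelated, so simple regressions on either
#' equal their multiple-regression weights.
#'
#' @param kind Regressor kind.
#' @param values Value set.
#' @return data.frame with `small`, `large`, `x` (predictor value per
#'   unordered pair).
#' @export
make_regressor <- function(kind = c("value_distance", "association_distance",
                                    "size_sum"), values) {
  kind <- match.arg(kind)
  g <- pair_grid(values)
  if (any(g$large == g$small)) stop("tie pair")
  g$x <- switch(kind,
    value_distance = log(g$large - g$small),
    association_distance = {
      om <- order_map(values)
      log(om[as.character(g$large)] - om[as.character(g$small)])
    },
    size_sum = g$small / 5 + g$large / 5)
  g$x <- unname(g$x)
  attr(g, "kind") <- kind
  g
}

#' Fit an effect regressor to per-pair statistics
#'
#' Ordinary least-squares simple regression of a per-pair outcome (mean error
#' rate or median RT) on a regressor, per participant or on the group average
#' (each pair's statistic first averaged across participants, then fitted).
#' R-squared is the squared Pearson correlation of fitted and observed
#' values. Error rates are fitted as raw proportions.
#'
#' @param stats Per-pair statistics from [pair_stats()] (unordered pairs).
#' @param regressor A [make_regressor()] table.
#' @param outcome `"error_rate"` or `"median_rt"`.
#' @param level `"participant"` (one fit per participant) or `"group"`.
#' @return data.frame with `participant_id` (`"group"` at group level),
#'   `regressor`, `outcome`, `slope`, `intercept`, `r_squared`.
#' @export
fit_effect <- function(stats, regressor,
                       outcome = c("error_rate", "median_rt"),
                       level = c("participant", "group")) {
  outcome <- match.arg(outcome)
  level <- match.arg(level)
  ycol <- if (outcome == "error_rate") "mean_error_rate" else "median_rt_ms"
  key <- paste(regressor$small, regressor$large)
  one_fit <- function(df, id) {
    x <- regressor$x[match(paste(df$small, df$large), key)]
    if (anyNA(x)) stop("pair in data not covered by the regressor")
    y <- df[[ycol]]
    if (length(unique(paste(df$small, df$large))) < 3L)
      stop("need at least 3 distinct pairs to fit")
    if (stats::var(x) == 0) stop("zero variance in predictor")
    fit <- stats::lm(y ~ x)
    r2 <- if (stats::var(y) == 0) 0 else stats::cor(stats::fitted(fit), y)^2
    data.frame(participant_id = id, regressor = attr(regressor, "kind"),
               outcome = outcome, slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]), r_squared = r2)
  }
  if (level == "group") {
    key2 <- list(small = stats$small, large = stats$large)
    g <- aggregate(stats[[ycol]], key2, mean)
    names(g)[3] <- ycol
    one_fit(g, "group")
  } else {
    out <- lapply(split(stats, stats$participant_id),
                  function(df) one_fit(df, df$participant_id[1]))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  }
}

#' Check scale invariance of the value-distance fit
#'
#' Multiplying all values by 5 shifts the ln-distance predictor by exactly
#' ln 5, so slope and R-squared are unchanged and the intercept moves by
#' -slope * ln 5. Verifies this identity on the supplied statistics.
#'
#' @param stats Per-pair statistics whose `small`/`large` columns use
#'   `values`.
#' @param values The value set underlying `stats`.
#' @param outcome Outcome fitted.
#' @param tol Numerical tolerance.
#' @return list with both group fits and logical `invariant`.
#' @export
scale_invariance_check <- function(stats, values,
                                   outcome = c("error_rate", "median_rt"),
                                   tol = 1e-10) {
  outcome <- match.arg(outcome)
  reg1 <- make_regressor("value_distance", values)
  reg5 <- make_regressor("value_distance", values * 5)
  stats5 <- stats
  stats5$small <- stats$small * 5
  stats5$large <- stats$large * 5
  f1 <- fit_effect(stats, reg1, outcome, "group")
  f5 <- fit_effect(stats5, reg5, outcome, "group")
  ok <- abs(f1$slope - f5$slope) < tol &&
    abs(f1$r_squared - f5$r_squared) < tol &&
    abs((f1$intercept - f5$intercept) - f1$slope * log(5)) < tol
  list(fit = f1, fit_scaled = f5, invariant = ok)
}
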