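#' Compare value-based and association-based fits across participants
#'
#' Two-sided paired Wilcoxon signed-rank test on the per-participant
#' R-squared values of the two competing distance regressors, treated as
#' ordinal repeated measures. Zero differences are dropped; the exact null
#' distribution is used for up to 25 informative pairs, the normal
#' approximation with continuity correction above.
#'
#' @param fits_value,fits_assoc Per-participant [fit_effect()] tables for the
#'   value-based and association-based regressors (matched on
#'   `participant_id`).
#' @return list with `statistic` (T, the smaller signed-rank sum), `p_value`,
#'   `median_r2_value`, `median_r2_assoc`, `n_informative`, `direction`
#'   (`"value-dominant"`, `"association-dominant"`, or `"undecided"` when not
#'   significant at .05).
#' @export
study1_model_contrast <- function(fits_value, fits_assoc) {
  m <- merge(fits_value[c("participant_id", "r_squared")],
             fits_assoc[c("participant_id", "r_squared")],
             by = "participant_id", suffixes = c("_value", "_assoc"))
  d <- m$r_squared_value - m$r_squared_assoc
  n_inf <- sum(d != 0)
  if (n_inf < 5L)
    stop("fewer than 5 informative (nonzero-difference) pairs; test refused")
  wt <- stats::wilcox.test(m$r_squared_value, m$r_squared_assoc,
                           paired = TRUE, exact = n_inf <= 25,
                           correct = TRUE)
  # wilcox.test reports V = sum of positive ranks; T is the smaller sum
  v_pos <- unname(wt$statistic)
  t_stat <- min(v_pos, n_inf * (n_inf + 1) / 2 - v_pos)
  dir <- if (wt$p.value >= 0.05) "undecided"
    else if (stats::median(d) > 0) "value-dominant" else "association-dominant"
  list(test = "paired Wilcoxon signed-rank", statistic = t_stat,
       p_value = wt$p.value,
       median_r2_value = stats::median(m$r_squared_value),
       median_r2_assoc = stats::median(m$r_squared_assoc),
       n_informative = n_inf, direction = dir)
}

omega_squared <- function(fit_aov) {
  s <- summary(fit_aov)[[1]]
  ss_b <- s[["Sum Sq"]][1]; df_b <- s[["Df"]][1]
  ms_w <- s[["Mean Sq"]][2]; ss_t <- sum(s[["Sum Sq"]])
  (ss_b - df_b * ms_w) / (ss_t + ms_w)
}

#' Dunn's rank-based pairwise post hoc test
#'
#' Standard Dunn z statistics on the joint ranking with tie correction.
#' Unadjusted p values by default; Holm adjustment available.
#'
#' @param x Numeric response.
#' @param g Group labels.
#' @param adjust `"none"` or `"holm"`.
#' @return data.frame with `group1`, `group2`, `z`, `p_value`.
#' @export
dunn_test <- function(x, g, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  g <- factor(g)
  n <- length(x)
  r <- rank(x)
  tie <- table(r)
  tie_corr <- sum(tie^3 - tie) / (12 * (n - 1))
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  res <- apply(pairs, 2, function(p) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[[p[1]]] + 1 / ni[[p[2]]]))
    z <- (rbar[[p[1]]] - rbar[[p[2]]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  p <- res["p", ]
  if (adjust == "holm") p <- stats::p.adjust(p, "holm")
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = unname(res["z", ]), p_value = unname(p))
}

#' Compare effect slopes between frequency conditions
#'
#' Shapiro-Wilk normality per condition (alpha = .05) gates the omnibus:
#' when every group looks normal, a one-way fixed-effects ANOVA (F, omega
#' squared); otherwise a Kruskal-Wallis test with the rank epsilon-squared
#' effect size (reported as the rank analogue of omega squared) and Dunn
#' pairwise post hoc.
#'
#' @param slopes data.frame with `participant_id`, `condition`, `slope`.
#' @param outcome Label carried through to the result.
#' @param posthoc_adjust Passed to [dunn_test()].
#' @param force Optionally force `"anova"` or `"kruskal"` regardless of the
#'   normality gate.
#' @return list with `test`, `statistic`, `df`, `p_value`, `effect_size`,
#'   `effect_size_label`, `normality_p`, and `post_hoc` (Dunn table, present
#'   for the rank test with >= 3 groups).
#' @export
study2_slope_contrast <- function(slopes, outcome = "median_rt",
                                  posthoc_adjust = "none", force = NULL) {
  cnt <- table(slopes$condition)
  if (any(cnt < 2)) stop("every condition needs at least 2 participants")
  slopes$condition <- factor(slopes$condition)
  sw <- vapply(split(slopes$slope, slopes$condition),
               function(x) stats::shapiro.test(x)$p.value, 0)
  use_anova <- if (is.null(force)) all(sw > 0.05) else force == "anova"
  if (use_anova) {
    fit <- stats::aov(slope ~ condition, slopes)
    s <- summary(fit)[[1]]
    list(test = "one-way ANOVA", outcome = outcome,
         statistic = s[["F value"]][1],
         df = c(s[["Df"]][1], s[["Df"]][2]), p_value = s[["Pr(>F)"]][1],
         effect_size = omega_squared(fit), effect_size_label = "omega squared",
         normality_p = sw, post_hoc = NULL)
  } else {
    kw <- stats::kruskal.test(slope ~ condition, slopes)
    n <- nrow(slopes)
    eps2 <- unname(kw$statistic) * (n + 1) / (n^2 - 1)
    ph <- if (nlevels(slopes$condition) >= 3)
      dunn_test(slopes$slope, slopes$condition, posthoc_adjust) else NULL
    list(test = "Kruskal-Wallis", outcome = outcome,
         statistic = unname(kw$statistic), df = unname(kw$parameter),
         p_value = kw$p.value, effect_size = eps2,
         effect_size_label = "rank epsilon squared", normality_p = sw,
         post_hoc = ph)
  }
}

#' Per-participant effect slopes by condition
#'
#' Convenience wrapper: per-participant [pair_stats()] + [fit_effect()]
#' slopes with the participant's condition attached.
#'
#' @param trials Trial table (possibly several conditions).
#' @param regressor A [make_regressor()] table.
#' @param outcome Outcome fitted.
#' @return data.frame `participant_id`, `condition`, `slope`, `r_squared`.
#' @export
slopes_by_participant <- function(trials, regressor,
                                  outcome = c("error_rate", "median_rt")) {
  outcome <- match.arg(outcome)
  ps <- pair_stats(trials)
  fits <- fit_effect(ps, regressor, outcome, "participant")
  cond <- tapply(trials$condition, trials$participant_id, function(x) x[1])
  fits$condition <- unname(cond[fits$participant_id])
  fits[c("participant_id", "condition", "slope", "r_squared")]
}

#' Block-wise slope analysis (frequency-decay diagnostics)
#'
#' Computes the effect slope per participant per session block (blocks are
#' contiguous quarters of presentation order, carried in the trial table),
#' then runs a blocks (within) x conditions (between) mixed ANOVA with a
#' Tukey post hoc on blocks.
#'
#' @param trials Trial table with `block` column.
#' @param regressor A [make_regressor()] table.
#' @param outcome Outcome fitted.
#' @return list with `slopes` (participant x block table), `anova`
#'   (data.frame: effect, df1, df2, F, p), `tukey_blocks` (emmeans contrast
#'   summary).
#' @export
block_slope_analysis <- function(trials, regressor,
                                 outcome = c("error_rate", "median_rt")) {
  outcome <- match.arg(outcome)
  if (length(unique(trials$condition)) < 2L)
    stop("block x condition interaction needs >= 2 conditions")
  blocks <- sort(unique(trials$block))
  if (any(table(trials$block) == 0)) stop("empty block")
  sl <- do.call(rbind, lapply(blocks, function(b) {
    out <- slopes_by_participant(trials[trials$block == b, ], regressor,
                                 outcome)
    out$block <- b
    out
  }))
  sl$block <- factor(sl$block)
  sl$condition <- factor(sl$condition)
  sl$participant_id <- factor(sl$participant_id)
  # do.call embeds the data in the call so emmeans can re-fit the aovlist
  fit <- do.call(stats::aov,
                 list(slope ~ condition * block + Error(participant_id / block),
                      data = sl))
  s <- summary(fit)
  btw <- s[["Error: participant_id"]][[1]]
  wth <- s[["Error: participant_id:block"]][[1]]
  an <- data.frame(
    effect = c("condition", "block", "condition:block"),
    df1 = c(btw[["Df"]][1], wth[["Df"]][1:2]),
    df2 = c(btw[["Df"]][2], rep(wth[["Df"]][3], 2)),
    F = c(btw[["F value"]][1], wth[["F value"]][1:2]),
    p = c(btw[["Pr(>F)"]][1], wth[["Pr(>F)"]][1:2]))
  an$effect <- c("condition", "block", "condition:block")
  tk <- summary(emmeans::contrast(
    emmeans::emmeans(fit, "block", data = sl), method = "pairwise",
    adjust = "tukey"))
  list(slopes = sl, anova = an, tukey_blocks = tk)
}

#' Required sample size for a one-way fixed-effects ANOVA
#'
#' Smallest total N whose noncentral-F power reaches the target:
#' power(N) = P(F' > F_crit) with F' ~ noncentral F(k-1, N-k, ncp = f^2 N)
#' and F_crit the central-F (1 - alpha) quantile. By default N is stepped in
#' multiples of `k_groups` (equal per-group allocation, the G*Power
#' convention for this design); `equal_groups = FALSE` sweeps every integer
#' N.
#'
#' @param f Cohen's f effect size (> 0).
#' @param alpha Type-I error rate.
#' @param power Target power in (0, 1).
#' @param k_groups Number of groups (>= 2).
#' @param equal_groups Step N in multiples of `k_groups`.
#' @param n_max Search cap.
#' @return list with `n_total`, `power`, `ncp`, `df`.
#' @export
required_n_oneway_anova <- function(f, alpha = 0.05, power = 0.95,
                                    k_groups = 3L, equal_groups = TRUE,
                                    n_max = 100000L) {
  stopifnot(f > 0, alpha > 0, alpha < 1, power > 0, power < 1, k_groups >= 2)
  step <- if (equal_groups) k_groups else 1L
  n <- if (equal_groups) 2L * k_groups else k_groups + 1L
  repeat {
    pw <- anova_power(n, f, alpha, k_groups)
    if (pw >= power)
      return(list(n_total = n, power = pw, ncp = f^2 * n,
                  df = c(k_groups - 1L, n - k_groups)))
    n <- n + step
    if (n > n_max) stop("target power unattainable within n_max")
  }
}

#' @param n_total Total sample size.
#' @rdname required_n_oneway_anova
#' @export
anova_power <- function(n_total, f, alpha = 0.05, k_groups = 3L) {
  df1 <- k_groups - 1
  df2 <- n_total - k_groups
  if (df2 < 1) return(0)
  crit <- stats::qf(1 - alpha, df1, df2)
  1 - stats::pf(crit, df1, df2, ncp = f^2 * n_total)
}
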