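#' EZ-diffusion forward equations
#'
#' Closed-form proportion correct, correct-RT variance and mean RT of the
#' unbiased two-boundary Wiener process with drift `v`, boundary separation
#' `a`, nondecision time `ter` and noise scaling `s`:
#' pc = 1/(1 + exp(-a v / s^2)), mean decision time
#' (a / 2v) * (1 - e^(-av/s^2)) / (1 + e^(-av/s^2)), and the RT variance of
#' the EZ system. `ez_fit()` inverts them exactly.
#'
#' @param v Drift rate (non-zero).
#' @param a Boundary separation (> 0).
#' @param ter Nondecision time (s).
#' @param s Noise scaling constant.
#' @return list with `pc`, `vrt` (s^2), `mrt` (s).
#' @export
ez_forward <- function(v, a, ter, s = 0.1) {
  if (v == 0) stop("v = 0: proportion correct is degenerate at 0.5")
  stopifnot(a > 0, ter >= 0, s > 0)
  L <- a * v / s^2
  pc <- stats::plogis(L)
  vrt <- L * (L * pc^2 - L * pc + pc - 0.5) * s^4 / v^4
  mdt <- (a / (2 * v)) * (1 - exp(-L)) / (1 + exp(-L))
  list(pc = pc, vrt = vrt, mrt = mdt + ter)
}

#' EZ-diffusion parameter recovery
#'
#' Closed-form inversion of the EZ system: with L = logit(pc),
#' v = sign(pc - 1/2) s (L (L pc^2 - L pc + pc - 1/2) / vrt)^(1/4),
#' a = s^2 L / v, and ter = mrt minus the mean decision time implied by
#' (v, a). Perfect accuracy is edge-corrected to pc' = 1 - 1/(2n) (and 0 to
#' 1/(2n)), flagged in the result; pc = 0.5 exactly is refused (drift sign
#' undefined) — jitter the edge or collect more trials.
#'
#' @param pc Proportion correct.
#' @param vrt Variance of correct RTs (s^2, > 0).
#' @param mrt Mean correct RT (s).
#' @param n_trials Trial count behind `pc`, needed for the edge correction.
#' @param s Noise scaling constant.
#' @return list with `v`, `a`, `ter`, `s`, `edge_corrected` (logical).
#' @export
ez_fit <- function(pc, vrt, mrt, n_trials = NULL, s = 0.1) {
  stopifnot(vrt > 0, mrt > 0)
  edge <- FALSE
  if (pc <= 0 || pc >= 1) {
    if (is.null(n_trials))
      stop("pc at an edge needs n_trials for the 1/(2n) correction")
    pc <- if (pc >= 1) 1 - 1 / (2 * n_trials) else 1 / (2 * n_trials)
    edge <- TRUE
  }
  if (pc == 0.5)
    stop("pc = 0.5: drift sign undefined; jitter the edge or pool more trials")
  L <- stats::qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
  v <- sign(pc - 0.5) * s * x^0.25
  a <- s^2 * L / v
  mdt <- (a / (2 * v)) * (1 - exp(-L)) / (1 + exp(-L))
  list(v = v, a = a, ter = mrt - mdt, s = s, edge_corrected = edge)
}

#' Classify a frequency effect into diffusion-parameter signatures
#'
#' Qualitative attribution of a high-frequency-minus-low-frequency behavioral
#' contrast to diffusion parameters, from the canonical signature table:
#' an increased drift rate gives faster and more precise responses; an
#' increased threshold gives slower and (slightly) more precise responses; an
#' increased nondecision time gives slower responses with no precision
#' change. Faster responses without a precision gain (unchanged or
#' descriptively less precise) therefore indicate a threshold and/or
#' nondecision-time decrease, with drift excluded.
#'
#' @param delta_rt,delta_er Signed standardized differences (condition of
#'   interest minus reference) for RT and error rate.
#' @param sig_rt,sig_er Logical significance flags for the two effects.
#' @return list with `rt_effect` (`"faster"`/`"slower"`/`"none"`),
#'   `er_effect` (`"more_precise"`/`"less_precise"`/`"none"`), `attribution`
#'   (character subset of drift/threshold/nondecision with direction), and
#'   `rationale`.
#' @export
classify_signature <- function(delta_rt, delta_er, sig_rt, sig_er) {
  if (any(is.na(c(delta_rt, delta_er, sig_rt, sig_er))))
    stop("missing effect estimates")
  rt_eff <- if (!sig_rt) "none" else if (delta_rt < 0) "faster" else "slower"
  er_eff <- if (!sig_er) "none" else
    if (delta_er < 0) "more_precise" else "less_precise"
  res <- function(attr, why)
    list(rt_effect = rt_eff, er_effect = er_eff, attribution = attr,
         rationale = why)
  if (rt_eff == "faster" && er_eff == "more_precise")
    return(res("drift increase",
               "faster and more precise: the drift-rate signature"))
  if (rt_eff == "slower" && er_eff == "more_precise")
    return(res("threshold increase",
               "slower but more precise: the threshold signature"))
  if (rt_eff == "slower" && er_eff == "none")
    return(res("nondecision increase",
               "slower with unchanged precision: the nondecision signature"))
  if (rt_eff == "faster" && er_eff != "more_precise")
    return(res(c("threshold decrease", "nondecision decrease"),
               paste("faster without a precision gain excludes a drift",
                     "increase; a lowered threshold and/or nondecision time",
                     "fits")))
  if (rt_eff == "none" && er_eff == "none")
    return(res(character(0), "no reliable change in either measure"))
  if (rt_eff == "slower" && er_eff == "less_precise")
    return(res(c("drift decrease"),
               "slower and less precise: the reversed drift signature"))
  res(c("threshold change", "drift change"),
      "precision change without an RT change is ambiguous")
}

#' Per-frequency-stratum EZ estimates and signature verdict
#'
#' Bins each trial's unordered pair by the pair's normalized frequency phi
#' *within its own condition's* base-frequency table (terciles by default),
#' computes per-participant EZ estimates within the lowest and highest
#' strata, and classifies the high-minus-low behavioral contrast with
#' [classify_signature()].
#'
#' Within a single condition, phi is a fixed property of the pair, so a
#' frequency stratum is also a difficulty stratum (high-phi pairs of an
#' everyday-frequency session are the small, easy pairs): the raw
#' high-minus-low contrast would mimic a drift effect even with no frequency
#' sensitivity at all. The behavioral contrast is therefore a
#' between-condition one: for the two supplied conditions whose phi maps
#' differ most (everyday vs reversed-everyday in the canonical design), a
#' common pair-weight u(pair) = (phi_A - phi_B) * precision is built, each
#' participant is scored T = sum over pairs of u(pair) times their pair
#' mean, and the A and B groups are compared (two-sided Wilcoxon rank-sum;
#' the standardized delta is the two-sample Cohen's d). Because every
#' participant is scored with identical weights, pair difficulty cancels
#' exactly in the comparison and only frequency sensitivity remains. A
#' negative RT delta means frequent stimuli are answered faster. Cohorts
#' from a single condition are refused as confounded.
#' Frequency-manipulated strata necessarily have unequal trial counts, which
#' biases quantitative EZ estimates — a warning field flags this, and the
#' qualitative verdict, not the point estimates, is the supported inference.
#'
#' @param trials Trial table (one or more conditions).
#' @param freq_tables A [build_frequency_table()] result, or a named list of
#'   them keyed by condition label.
#' @param n_strata Number of phi bins per condition.
#' @param alpha Significance level for the effect flags.
#' @return list with `strata` (per-stratum, per-participant EZ estimates and
#'   raw behavioral means), `contrast` (the two conditions compared),
#'   `delta` (standardized frequency effect on RT and ER), `tests`
#'   (p values), `verdict` ([classify_signature()] result),
#'   `unequal_counts_warning`.
#' @export
frequency_diffusion_report <- function(trials, freq_tables, n_strata = 3L,
                                       alpha = 0.05) {
  if (inherits(freq_tables, "frequency_table"))
    freq_tables <- stats::setNames(list(freq_tables), freq_tables$condition)
  pair_key <- paste(pmin(trials$left_value, trials$right_value),
                    pmax(trials$left_value, trials$right_value))
  trials$stratum <- NA_integer_
  for (cnd in unique(trials$condition)) {
    ft <- freq_tables[[cnd]]
    if (is.null(ft)) stop("no frequency table supplied for condition ", cnd)
    phi_tab <- pair_frequency(ft)
    br <- stats::quantile(phi_tab$phi,
                          probs = seq(0, 1, length.out = n_strata + 1))
    phi_tab$stratum <- cut(phi_tab$phi, unique(br), labels = FALSE,
                           include.lowest = TRUE)
    # map bins onto the common 1..n_strata range; a condition with constant
    # phi (uniform) sits entirely in the middle stratum
    if (max(phi_tab$stratum) == 1L) {
      phi_tab$stratum[] <- as.integer(round((1 + n_strata) / 2))
    } else {
      phi_tab$stratum <- round(1 + (phi_tab$stratum - 1) *
                                 (n_strata - 1) / (max(phi_tab$stratum) - 1))
    }
    sel <- trials$condition == cnd
    trials$stratum[sel] <- phi_tab$stratum[match(
      pair_key[sel], paste(phi_tab$small, phi_tab$large))]
  }
  if (anyNA(trials$stratum)) stop("trial pair missing from frequency table")
  # a participant must sit in exactly one condition
  pc_map <- tapply(trials$condition, trials$participant_id,
                   function(x) length(unique(x)))
  if (any(pc_map > 1))
    stop("participant_id values are shared across conditions; ",
         "disambiguate the ids before pooling cohorts")
  ez_one <- function(df) {
    pc <- mean(df$correct)
    crt <- df$rt_ms[df$correct] / 1000
    if (length(crt) < 2) return(NULL)
    est <- ez_fit(pc, stats::var(crt), mean(crt), n_trials = nrow(df))
    data.frame(participant_id = df$participant_id[1],
               condition = df$condition[1], stratum = df$stratum[1],
               n_trials = nrow(df), pc = pc, mean_rt = mean(df$rt_ms),
               error_rate = 1 - pc, v = est$v, a = est$a,
               ter = est$ter, edge_corrected = est$edge_corrected)
  }
  strata <- do.call(rbind, lapply(
    split(trials, list(trials$participant_id, trials$stratum), drop = TRUE),
    ez_one))
  rownames(strata) <- NULL
  # frequency contrast: pick the two conditions whose phi maps differ most,
  # build the common pair-weight u = (phi_A - phi_B) * precision, and compare
  # the per-participant score T = sum_pairs u(pair) * pair mean between the
  # two groups. Identical weights for every participant make stimulus
  # difficulty cancel exactly in the A-vs-B comparison.
  conds <- names(freq_tables)[names(freq_tables) %in% trials$condition]
  phis <- lapply(freq_tables[conds], function(ft) {
    pt <- pair_frequency(ft)
    stats::setNames(pt$phi, paste(pt$small, pt$large))
  })
  if (length(conds) < 2L)
    stop("frequency effects are confounded with pair difficulty within a ",
         "single condition; supply cohorts from >= 2 conditions with ",
         "differing frequency tables (e.g. everyday plus reversed_everyday)")
  cp <- utils::combn(conds, 2)
  dis <- apply(cp, 2, function(p) {
    common <- intersect(names(phis[[p[1]]]), names(phis[[p[2]]]))
    sum(abs(phis[[p[1]]][common] - phis[[p[2]]][common]))
  })
  if (max(dis) == 0)
    stop("all supplied frequency tables are identical over the shared ",
         "pairs; the frequency effect is unidentifiable")
  ca <- cp[1, which.max(dis)]; cb <- cp[2, which.max(dis)]
  common <- intersect(names(phis[[ca]]), names(phis[[cb]]))
  cnt <- function(cnd) {
    tc <- tapply(trials$trial_index[trials$condition == cnd],
                 pair_key[trials$condition == cnd], length)
    n_part <- length(unique(trials$participant_id[trials$condition == cnd]))
    tc[common] / n_part
  }
  na <- cnt(ca); nb <- cnt(cb)
  h <- 1 / (1 / na + 1 / nb)                  # per-participant precision
  u <- (phis[[ca]][common] - phis[[cb]][common]) * h
  u <- u / sum(abs(u))
  score <- function(cnd) {
    sel <- trials$condition == cnd
    vapply(split(which(sel), trials$participant_id[sel]), function(i) {
      mrt <- tapply(trials$rt_ms[i], pair_key[i], mean)
      mer <- tapply(!trials$correct[i], pair_key[i], mean)
      pr <- intersect(names(mrt), common)
      c(sum(u[pr] * mrt[pr]), sum(u[pr] * mer[pr]))
    }, numeric(2))
  }
  ta <- score(ca); tb <- score(cb)
  if (ncol(ta) < 2 || ncol(tb) < 2)
    stop("need >= 2 participants per contrasted condition")
  cohen_d <- function(r) {
    sp <- sqrt((stats::var(ta[r, ]) + stats::var(tb[r, ])) / 2)
    if (sp == 0) 0 else (mean(ta[r, ]) - mean(tb[r, ])) / sp
  }
  pval <- function(r) {
    if (stats::sd(c(ta[r, ], tb[r, ])) == 0) return(1)
    stats::wilcox.test(ta[r, ], tb[r, ], exact = FALSE)$p.value
  }
  d_rt <- cohen_d(1); d_er <- cohen_d(2)
  p_rt <- pval(1); p_er <- pval(2)
  verdict <- classify_signature(d_rt, d_er, p_rt < alpha, p_er < alpha)
  counts <- tapply(trials$trial_index, trials$stratum, length)
  list(strata = strata,
       contrast = c(condition_high = ca, condition_low = cb),
       delta = c(rt = d_rt, er = d_er),
       tests = c(p_rt = p_rt, p_er = p_er),
       verdict = verdict,
       unequal_counts_warning = if (length(unique(counts)) > 1)
         paste("frequency strata have unequal trial counts",
               paste(counts, collapse = "/"),
               "- quantitative EZ estimates may be biased; rely on the",
               "qualitative verdict") else NULL)
}
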