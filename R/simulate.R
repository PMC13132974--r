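#' Expected-difficulty grids for the two accounts
#'
#' `ans_expected_grid()` maps each pair to the psychophysical (ratio-driven)
#' difficulty a * ln(large / (large - small)) + b: difficulty grows as the
#' ratio of the larger value to the numerical distance grows, the Weber-style
#' single gradient. `dss_expected_grid()` maps each pair to the
#' statistics-driven difficulty a1 * (large - small) + a2 * (1/x1 + 1/x2) + b,
#' where the linear distance term and the inverse-value (frequency-derived)
#' size term are independent contributions. Defaults a = a2 = 1, a1 = 0.4,
#' b = 0 put the two components on comparable arbitrary scales.
#'
#' @param values Value set (all pairs with large > small are tabulated).
#' @param params A [grid_params()] list.
#' @return data.frame with `small`, `large`, `difficulty`.
#' @export
ans_expected_grid <- function(values, params = grid_params()) {
  g <- pair_grid(values)
  if (any(g$large == g$small)) stop("tie pair has zero distance")
  within(g, difficulty <- params$a * log(large / (large - small)) + params$b)
}

#' @rdname ans_expected_grid
#' @export
dss_expected_grid <- function(values, params = grid_params()) {
  if (any(values == 0)) stop("zero value in size term")
  g <- pair_grid(values)
  within(g, difficulty <- params$a1 * (large - small) +
           params$a2 * (1 / small + 1 / large) + params$b)
}

pair_grid <- function(values) {
  pr <- t(utils::combn(sort(values), 2L))
  data.frame(small = pr[, 1], large = pr[, 2])
}

#' @param a,b ANS scale and offset.
#' @param a1,a2 DSS distance and size weights.
#' @rdname ans_expected_grid
#' @export
grid_params <- function(a = 1, b = 0, a1 = 0.4, a2 = 1) {
  stopifnot(is.finite(a), is.finite(b), is.finite(a1), is.finite(a2))
  list(a = a, b = b, a1 = a1, a2 = a2)
}

#' Diffusion-process parameters
#'
#' @param k Drift scale per unit log-ratio (evidence units/s): on a trial the
#'   drift is v = k * ln(large/small), so the ratio effect lives in the drift.
#' @param a0 Baseline boundary separation (evidence units).
#' @param ter0 Baseline nondecision time (s).
#' @param s Diffusion noise; fixed scaling constant, conventionally 0.1.
#' @return List of validated parameters.
#' @export
ddm_params <- function(k = 0.5, a0 = 0.10, ter0 = 0.30, s = 0.1) {
  stopifnot(k >= 0, a0 > 0, ter0 >= 0, s > 0)
  list(k = k, a0 = a0, ter0 = ter0, s = s)
}

#' Frequency coupling of diffusion parameters
#'
#' Stimulus frequency phi (normalized pair frequency, [pair_frequency()])
#' multiplicatively modulates diffusion parameters: boundary separation
#' becomes a0 * (1 - threshold * phi * block_decay^(block-1)) and nondecision
#' time analogously, while drift is multiplied by
#' (1 + drift * phi * block_decay^(block-1)). Gains of 0 switch a pathway
#' off. `block_decay` < 1 makes the coupling fade over the session's blocks.
#' Effective threshold is clamped at 0.2 * a0 and nondecision at 0.
#'
#' @param threshold,nondecision,drift Coupling gains in [0, 1).
#' @param block_decay Per-block decay delta in (0, 1].
#' @return List of validated gains.
#' @export
frequency_coupling <- function(threshold = 0, nondecision = 0, drift = 0,
                               block_decay = 1) {
  stopifnot(threshold >= 0, threshold < 1, nondecision >= 0, nondecision < 1,
            drift >= 0, block_decay > 0, block_decay <= 1)
  list(threshold = threshold, nondecision = nondecision, drift = drift,
       block_decay = block_decay)
}

coupled_params <- function(pair_small, pair_large, block, ddm, coupling, phi,
                           phi_ref = 0) {
  decay <- coupling$block_decay^(block - 1)
  m <- (phi - phi_ref) * decay
  a <- pmax(ddm$a0 * (1 - coupling$threshold * m), 0.2 * ddm$a0)
  ter <- pmax(ddm$ter0 * (1 - coupling$nondecision * m), 0)
  v <- ddm$k * log(pair_large / pair_small) * (1 + coupling$drift * m)
  list(v = v, a = a, ter = ter)
}

#' Simulate diffusion first-passage trials
#'
#' Vectorized Euler simulation (default step 1 ms, noise s = 0.1) of the
#' two-boundary Wiener process with unbiased start, with a within-step
#' Brownian-bridge crossing check so that accuracy and mean decision time
#' match the closed forms 1/(1 + exp(-v*a/s^2)) and
#' (a/(2v)) * tanh(v*a/(2 s^2)) at the default step size. Reproducible under
#' `set.seed()`.
#'
#' @param v,a,ter Drift, boundary separation, nondecision time (recycled to a
#'   common length).
#' @param n Number of trials when `v`, `a`, `ter` are scalars.
#' @param s Diffusion noise scaling.
#' @param dt Euler step (s).
#' @param tmax Censoring horizon (s).
#' @return data.frame with `correct` (0/1, upper = correct boundary) and
#'   `rt` (s, decision time + ter).
#' @export
simulate_ddm_trials <- function(v, a, ter, n = NULL, s = 0.1, dt = 0.001,
                                tmax = 10) {
  if (!is.null(n)) {
    v <- rep_len(v, n); a <- rep_len(a, n); ter <- rep_len(ter, n)
  } else {
    n <- max(length(v), length(a), length(ter))
    v <- rep_len(v, n); a <- rep_len(a, n); ter <- rep_len(ter, n)
  }
  ddm_fpt_cpp(as.numeric(v), as.numeric(a), as.numeric(ter), s, dt, tmax)
}

#' Simulate one frequency-coupled comparison trial
#'
#' @param pair Numeric length-2: (left_value, right_value), no ties.
#' @param block Block index (1-based) for the coupling decay.
#' @param ddm [ddm_params()].
#' @param coupling [frequency_coupling()].
#' @param phi Normalized pair frequency in [0, 1].
#' @param dt,s,tmax Passed to the simulator.
#' @return list with `choice` (`"larger"`/`"smaller"` side chosen, i.e.
#'   correct or not), `response_side` (`"left"`/`"right"`), `correct`
#'   (logical), `rt` (s).
#' @export
simulate_ddm_trial <- function(pair, block, ddm = ddm_params(),
                               coupling = frequency_coupling(), phi = 0,
                               dt = 0.001, s = ddm$s, tmax = 10) {
  if (pair[1] == pair[2]) stop("tie pair")
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
  p <- coupled_params(min(pair), max(pair), block, ddm, coupling, phi)
  out <- simulate_ddm_trials(p$v, p$a, p$ter, n = 1L, s = s, dt = dt,
                             tmax = tmax)
  correct <- out$correct[1] == 1L
  larger_side <- if (pair[1] > pair[2]) "left" else "right"
  side <- if (correct) larger_side else setdiff(c("left", "right"), larger_side)
  list(choice = if (correct) "larger" else "smaller",
       response_side = side, correct = correct, rt = out$rt[1])
}

#' Cohort specification for the generators
#'
#' @param n_participants Number of simulated participants (>= 1).
#' @param heterogeneity_cv Coefficient of variation of the per-participant
#'   log-normal multiplicative jitter on (k, a0, ter0).
#' @param seed Master seed; per-participant streams are derived from it.
#' @export
cohort_spec <- function(n_participants = 20L, heterogeneity_cv = 0.1,
                        seed = 1L) {
  stopifnot(n_participants >= 1, heterogeneity_cv >= 0)
  list(n_participants = as.integer(n_participants),
       heterogeneity_cv = heterogeneity_cv, seed = as.integer(seed))
}

lognormal_jitter <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a diffusion (ratio-driven) cohort over a design
#'
#' One simulated participant at a time: (k, a0, ter0) jittered by independent
#' log-normal multipliers, the design's trial list shuffled per participant,
#' blocks assigned as contiguous quarters of the presentation order, and
#' each trial run through the frequency-coupled diffusion process. RTs are
#' serialized in milliseconds (rounded half up).
#'
#' @param spec A `design_spec`.
#' @param cohort A [cohort_spec()].
#' @param ddm Baseline [ddm_params()].
#' @param coupling [frequency_coupling()]; phi is computed from the design's
#'   own base-frequency table.
#' @param n_blocks Number of contiguous session blocks.
#' @param dt Euler step (s).
#' @param center_phi If `TRUE` (default), the coupling acts on the deviation
#'   of phi from the session's mean pair frequency — an adaptation-to-session
#'   -statistics reading under which a uniform-frequency session produces no
#'   differential coupling at all (all pairs equally frequent). `FALSE`
#'   couples to raw phi.
#' @return Trial table (see [read_trials()] for the schema).
#' @export
simulate_ans_cohort <- function(spec, cohort = cohort_spec(),
                                ddm = ddm_params(),
                                coupling = frequency_coupling(),
                                n_blocks = 4L, dt = 0.001,
                                center_phi = TRUE) {
  stopifnot(inherits(spec, "design_spec"))
  phi_tab <- pair_frequency(spec$frequency_table)
  phi_key <- paste(phi_tab$small, phi_tab$large)
  phi_ref <- if (center_phi) mean(phi_tab$phi) else 0
  out <- withr_seed(cohort$seed, {
    lapply(seq_len(cohort$n_participants), function(pid) {
      jit <- lognormal_jitter(3, cohort$heterogeneity_cv)
      k <- ddm$k * jit[1]; a0 <- ddm$a0 * jit[2]; ter0 <- ddm$ter0 * jit[3]
      idx <- rep.int(seq_len(nrow(spec$templates)), spec$templates$multiplicity)
      idx <- idx[sample.int(length(idx))]
      left <- spec$templates$left_value[idx]
      right <- spec$templates$right_value[idx]
      n <- length(idx)
      block <- block_of(seq_len(n), n, n_blocks)
      phi <- phi_tab$phi[match(paste(pmin(left, right), pmax(left, right)),
                               phi_key)]
      p <- coupled_params(pmin(left, right), pmax(left, right), block,
                          ddm_params(k, a0, ter0, ddm$s), coupling, phi,
                          phi_ref)
      sim <- simulate_ddm_trials(p$v, p$a, p$ter, s = ddm$s, dt = dt)
      larger_left <- left > right
      side <- ifelse(sim$correct == 1L, ifelse(larger_left, "left", "right"),
                     ifelse(larger_left, "right", "left"))
      data.frame(participant_id = sprintf("p%03d", pid),
                 condition = spec$condition, block = block,
                 trial_index = seq_len(n), left_value = left,
                 right_value = right, response_side = side,
                 correct = sim$correct == 1L,
                 rt_ms = floor(sim$rt * 1000 + 0.5))
    })
  })
  do.call(rbind, out)
}

block_of <- function(trial_index, n_trials, n_blocks) {
  pmin(n_blocks, 1L + ((trial_index - 1L) * n_blocks) %/% n_trials)
}

#' Parameters of the association/frequency-driven generator
#'
#' Mean structure follows the statistics-based account: RT decreases with the
#' log distance on the chosen basis (raw value or rank) and increases with
#' the inverse-size term 1/u1 + 1/u2 computed on the initial numbers
#' (value / 5, or the rank when the basis is the order); errors follow a
#' logistic model with the same two terms.
#'
#' @param rt_base Baseline RT (s).
#' @param rt_distance_weight RT decrease per unit ln(distance) (s).
#' @param rt_size_weight RT increase per unit inverse-size term (s).
#' @param rt_noise_sd Gaussian RT noise (s); RTs truncated at > 0.
#' @param er_logit_intercept,er_distance_weight,er_size_weight Logistic
#'   error-probability coefficients.
#' @export
dss_gen_params <- function(rt_base = 0.62, rt_distance_weight = 0.06,
                           rt_size_weight = 0.03, rt_noise_sd = 0.10,
                           er_logit_intercept = -2.0,
                           er_distance_weight = 1.0, er_size_weight = 0.6) {
  stopifnot(rt_noise_sd >= 0)
  list(rt_base = rt_base, rt_distance_weight = rt_distance_weight,
       rt_size_weight = rt_size_weight, rt_noise_sd = rt_noise_sd,
       er_logit_intercept = er_logit_intercept,
       er_distance_weight = er_distance_weight,
       er_size_weight = er_size_weight)
}

#' Simulate a statistics-driven cohort over a design
#'
#' @param spec A `design_spec`.
#' @param cohort A [cohort_spec()] (heterogeneity jitters rt_base and the two
#'   RT weights).
#' @param params [dss_gen_params()].
#' @param basis `"value"`: distance computed on the initial numbers
#'   (value / 5); `"order"`: computed on the ranks of the design's value set.
#' @param n_blocks Contiguous session blocks.
#' @return Trial table (schema as [simulate_ans_cohort()]).
#' @export
simulate_dss_cohort <- function(spec, cohort = cohort_spec(),
                                params = dss_gen_params(),
                                basis = c("value", "order"), n_blocks = 4L) {
  stopifnot(inherits(spec, "design_spec"))
  basis <- match.arg(basis)
  om <- order_map(spec$values)
  to_basis <- function(v) {
    if (basis == "order") unname(om[as.character(v)]) else v / 5
  }
  out <- withr_seed(cohort$seed, {
    lapply(seq_len(cohort$n_participants), function(pid) {
      jit <- lognormal_jitter(3, cohort$heterogeneity_cv)
      idx <- rep.int(seq_len(nrow(spec$templates)), spec$templates$multiplicity)
      idx <- idx[sample.int(length(idx))]
      left <- spec$templates$left_value[idx]
      right <- spec$templates$right_value[idx]
      n <- length(idx)
      u1 <- to_basis(left); u2 <- to_basis(right)
      dist <- log(abs(u1 - u2))
      # size term always on the initial numbers: the frequency-derived size
      # effect depends on the values, only the distance basis switches
      size <- 5 / left + 5 / right
      if (any(!is.finite(dist)) || any(!is.finite(size)))
        stop("non-finite mean structure (tie pair or zero basis value?)")
      mu <- params$rt_base * jit[1] -
        params$rt_distance_weight * jit[2] * dist +
        params$rt_size_weight * jit[3] * size
      if (params$rt_noise_sd == 0) {
        rt <- pmax(mu, 1e-3)
      } else {
        rt <- stats::rnorm(n, mu, params$rt_noise_sd)
        while (any(rt <= 0)) {           # truncate at > 0
          bad <- rt <= 0
          rt[bad] <- stats::rnorm(sum(bad), mu[bad], params$rt_noise_sd)
        }
      }
      p_err <- stats::plogis(params$er_logit_intercept -
                               params$er_distance_weight * dist +
                               params$er_size_weight * size)
      correct <- stats::runif(n) >= p_err
      larger_left <- left > right
      side <- ifelse(correct, ifelse(larger_left, "left", "right"),
                     ifelse(larger_left, "right", "left"))
      data.frame(participant_id = sprintf("p%03d", pid),
                 condition = spec$condition,
                 block = block_of(seq_len(n), n, n_blocks),
                 trial_index = seq_len(n), left_value = left,
                 right_value = right, response_side = side, correct = correct,
                 rt_ms = floor(rt * 1000 + 0.5))
    })
  })
  do.call(rbind, out)
}
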