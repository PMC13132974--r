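trial_schema <- c("participant_id", "condition", "block", "trial_index",
                  "left_value", "right_value", "response_side", "correct",
                  "rt_ms")

#' Read and write trial tables
#'
#' Long-format behavioral trial tables, one row per trial, CSV with header
#' `participant_id,condition,block,trial_index,left_value,right_value,
#' response_side,correct,rt_ms`. Reading validates the schema and reports
#' violations with row numbers; writing round-trips losslessly.
#'
#' @param path CSV file path.
#' @return `read_trials()`: validated data.frame of trials.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trial_schema, names(df))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  df <- df[trial_schema]
  validate_trials(df)
}

#' @param trials Trial table to write.
#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a trial table against the schema invariants
#'
#' Checks numeric RT > 0, no tie pairs, and that `correct` agrees with the
#' side of the larger value; failures name the column and the offending row
#' numbers.
#'
#' @param trials Candidate trial table.
#' @return The table, with `correct` coerced to logical.
#' @export
validate_trials <- function(trials) {
  fail <- function(col, rows)
    stop("column '", col, "' invalid at row(s) ",
         paste(utils::head(rows, 5), collapse = ", "),
         if (length(rows) > 5) " ..." else "", call. = FALSE)
  rt <- suppressWarnings(as.numeric(trials$rt_ms))
  if (anyNA(rt)) fail("rt_ms", which(is.na(rt)))
  if (any(rt <= 0)) fail("rt_ms", which(rt <= 0))
  trials$rt_ms <- rt
  ties <- which(trials$left_value == trials$right_value)
  if (length(ties)) fail("left_value/right_value (tie pair)", ties)
  if (is.character(trials$correct))
    trials$correct <- trials$correct %in% c("TRUE", "True", "true", "1")
  trials$correct <- as.logical(trials$correct)
  if (anyNA(trials$correct)) fail("correct", which(is.na(trials$correct)))
  larger_side <- ifelse(trials$left_value > trials$right_value, "left", "right")
  bad <- which((trials$response_side == larger_side) != trials$correct)
  if (length(bad)) fail("correct/response_side (inconsistent)", bad)
  trials
}

#' Per-participant, per-pair descriptive statistics
#'
#' Mean error rate and median RT for each unordered value pair and each
#' participant, over all trials of the pair (correct and erroneous trials
#' included; slow responses are not trimmed — the median is robust to slow
#' outliers). Even-count medians are the mean of the two central values.
#'
#' @param trials Trial table.
#' @param ordered If `TRUE`, keep ordered (left, right) cells instead of
#'   collapsing to unordered pairs (for plotting full grids).
#' @return data.frame with `participant_id`, `condition`, `small`, `large`
#'   (or `left_value`/`right_value` when `ordered`), `n_trials`,
#'   `mean_error_rate`, `median_rt_ms`.
#' @export
pair_stats <- function(trials, ordered = FALSE) {
  if (nrow(trials) == 0L) stop("empty trial table")
  if (ordered) {
    key <- list(participant_id = trials$participant_id,
                left_value = trials$left_value,
                right_value = trials$right_value)
  } else {
    key <- list(participant_id = trials$participant_id,
                small = pmin(trials$left_value, trials$right_value),
                large = pmax(trials$left_value, trials$right_value))
  }
  cond <- tapply(trials$condition, key, function(x) x[1])
  agg <- function(x, f) as.vector(tapply(x, key, f))
  grid <- expand.grid(dimnames(cond), stringsAsFactors = FALSE)
  names(grid) <- names(key)
  out <- cbind(grid,
               condition = as.vector(cond),
               n_trials = agg(trials$rt_ms, length),
               mean_error_rate = agg(!trials$correct, mean),
               median_rt_ms = agg(trials$rt_ms, stats::median))
  out <- out[!is.na(out$n_trials), ]
  for (col in intersect(c("small", "large", "left_value", "right_value"),
                        names(out)))
    out[[col]] <- as.numeric(out[[col]])
  out <- out[order(out$participant_id, out[[2]], out[[3]]), ]
  rownames(out) <- NULL
  out
}

#' Participant exclusion report
#'
#' Flags (i) random or key-swapped responders (overall accuracy below
#' `accuracy_min`; below 0.50 additionally labeled "keys likely swapped"),
#' (ii) participants whose RT distance-effect fit R-squared falls below
#' `r2_min` (supply `rt_distance_r2`), and (iii) within-condition size-slope
#' outliers beyond `z_max` standard scores (supply `size_slopes`). The
#' accuracy rule is a configurable stand-in for "responded randomly", which
#' the modeled studies state as an outcome, not a cutoff.
#'
#' @param trials Trial table.
#' @param rt_distance_r2 Optional data.frame `participant_id`, `r_squared`.
#' @param size_slopes Optional data.frame `participant_id`, `condition`,
#'   `slope`.
#' @param accuracy_min,r2_min,z_max Rule thresholds.
#' @return data.frame `participant_id`, `excluded`, `reasons` (";"-joined
#'   labels with the triggering statistic; empty iff not excluded).
#' @export
apply_exclusions <- function(trials, rt_distance_r2 = NULL,
                             size_slopes = NULL, accuracy_min = 0.60,
                             r2_min = 0.20, z_max = 3.5) {
  ids <- sort(unique(trials$participant_id))
  reasons <- stats::setNames(vector("list", length(ids)), ids)
  acc <- tapply(trials$correct, trials$participant_id, mean)
  for (id in ids) {
    if (acc[[id]] < accuracy_min) {
      lab <- sprintf("random/swapped responder (accuracy %.3f)", acc[[id]])
      if (acc[[id]] < 0.50) lab <- paste0(lab, "; keys likely swapped")
      reasons[[id]] <- c(reasons[[id]], lab)
    }
  }
  if (!is.null(rt_distance_r2)) {
    for (i in seq_len(nrow(rt_distance_r2))) {
      id <- rt_distance_r2$participant_id[i]
      r2 <- rt_distance_r2$r_squared[i]
      if (id %in% ids && r2 < r2_min)
        reasons[[id]] <- c(reasons[[id]],
                           sprintf("RT distance fit R2 %.3f < %.2f", r2, r2_min))
    }
  }
  if (!is.null(size_slopes)) {
    for (cnd in unique(size_slopes$condition)) {
      sl <- size_slopes[size_slopes$condition == cnd, ]
      z <- (sl$slope - mean(sl$slope)) / stats::sd(sl$slope)
      for (i in which(abs(z) > z_max)) {
        id <- sl$participant_id[i]
        if (id %in% ids)
          reasons[[id]] <- c(reasons[[id]],
                             sprintf("size slope outlier (z = %.1f)", z[i]))
      }
    }
  }
  data.frame(participant_id = ids,
             excluded = lengths(reasons) > 0,
             reasons = vapply(reasons, function(r)
               paste(r, collapse = "; "), ""),
             row.names = NULL)
}
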