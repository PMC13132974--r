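#' Canonical value sets
#'
#' The omitted-range set used in the association study leaves out the middle
#' sub-range (20, 25, 30) of the multiples of 5 between 5 and 45, which
#' dissociates a value's numerical distance from its rank distance. The
#' frequency study uses the full set. Numerosities below 5 are excluded to
#' stay outside the subitizing range.
#'
#' @return Integer vector of numerosities (dot counts), strictly increasing.
#' @export
study1_values <- function() c(5L, 10L, 15L, 35L, 40L, 45L)

#' @rdname study1_values
#' @export
study2_values <- function() seq(5L, 45L, by = 5L)

# The canonical dot designs stay at >= 5 (subitizing excluded) via
# study1_values()/study2_values(); sets of initial numbers (1..9) are legal.
assert_value_set <- function(values) {
  if (length(values) < 2L) stop("value set needs at least 2 values")
  if (anyDuplicated(values)) stop("duplicate values in value set")
  if (is.unsorted(values, strictly = TRUE)) stop("values must be strictly increasing")
  if (any(values < 1)) stop("values must be positive")
  as.integer(values)
}

# Experimentally used token counts. The everyday table follows the inverse
# power-law frequency of numbers in natural language, 10/value on the initial
# (divided-by-five) numbers; the printed, irregularly rounded counts below are
# the ground truth, since these (not the formula) determined the sessions.
everyday_counts <- function() {
  c(`5` = 10L, `10` = 5L, `15` = 4L, `20` = 3L, `25` = 2L,
    `30` = 2L, `35` = 2L, `40` = 2L, `45` = 1L)
}

#' Build a base-frequency table for a condition
#'
#' Base frequencies are per-value token counts from which ordered pairs are
#' generated: a pair (i, j) appears f(i) * f(j) times per repeat. Conditions:
#' `everyday` presents small numerosities more often (power-law-like),
#' `reversed_everyday` mirrors those counts over the sorted values, `uniform`
#' and `study1` present every value equally often.
#'
#' @param condition One of `"everyday"`, `"uniform"`, `"reversed_everyday"`,
#'   `"study1"`.
#' @param values Value set the condition runs over; the everyday-based
#'   conditions require the full 9-value set.
#' @return A `frequency_table`: list with `condition`, `values`, and `freq`
#'   (named integer vector, value -> token count).
#' @export
build_frequency_table <- function(condition = c("everyday", "uniform",
                                                "reversed_everyday", "study1"),
                                  values = study2_values()) {
  condition <- match.arg(condition)
  values <- assert_value_set(values)
  if (condition %in% c("everyday", "reversed_everyday")) {
    ev <- everyday_counts()
    if (!identical(values, as.integer(names(ev))))
      stop(condition, " condition is defined over the 9-value set 5..45")
    freq <- if (condition == "everyday") ev else
      stats::setNames(rev(unname(ev)), names(ev))
  } else {
    if (condition == "study1" && !identical(values, study1_values()))
      stop("study1 condition is defined over {5,10,15,35,40,45}")
    freq <- stats::setNames(rep(1L, length(values)), values)
  }
  structure(list(condition = condition, values = values, freq = freq),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("Frequency table [", x$condition, "]\n", sep = "")
  print(x$freq)
  invisible(x)
}

#' Expand a frequency table into ordered-pair trial templates
#'
#' Every ordered pair (i, j), i != j, receives multiplicity
#' f(i) * f(j) * repeats. The template's order encodes presentation side
#' (left value, right value).
#'
#' @param table A [build_frequency_table()] result.
#' @param repeats Whole-design repetition count (>= 1).
#' @param seed Seed stored for downstream trial-order shuffling.
#' @return A `design_spec`: list with `condition`, `values`,
#'   `frequency_table`, `templates` (data.frame `left_value`, `right_value`,
#'   `multiplicity`), `total_trials`, `seed`.
#' @export
build_trial_templates <- function(table, repeats = 1L, seed = 1L) {
  stopifnot(inherits(table, "frequency_table"))
  if (repeats < 1L) stop("repeats must be >= 1")
  if (any(table$freq < 1L)) stop("all base frequencies must be >= 1")
  v <- table$values
  if (length(v) < 2L) stop("need at least 2 values")
  grid <- expand.grid(left_value = v, right_value = v)
  grid <- grid[grid$left_value != grid$right_value, , drop = FALSE]
  f <- table$freq
  mult <- f[as.character(grid$left_value)] * f[as.character(grid$right_value)] *
    as.integer(repeats)
  templates <- data.frame(left_value = grid$left_value,
                          right_value = grid$right_value,
                          multiplicity = as.integer(mult))
  templates <- templates[order(templates$left_value, templates$right_value), ]
  rownames(templates) <- NULL
  structure(list(condition = table$condition, values = v,
                 frequency_table = table, templates = templates,
                 total_trials = sum(templates$multiplicity),
                 seed = as.integer(seed)),
            class = "design_spec")
}

#' Omitted-range design: all ordered pairs of {5,10,15,35,40,45}
#'
#' @param repeats Presentations per ordered pair (20 gives the full 600-trial
#'   session).
#' @param seed Seed for the trial-order shuffle.
#' @return A `design_spec` (see [build_trial_templates()]).
#' @export
build_study1_design <- function(repeats = 20L, seed = 1L) {
  tab <- build_frequency_table("study1", study1_values())
  build_trial_templates(tab, repeats = repeats, seed = seed)
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Design [", x$condition, "]: ", length(x$values), " values, ",
      nrow(x$templates), " ordered-pair templates, ",
      x$total_trials, " trials\n", sep = "")
  invisible(x)
}

#' Expand a design into a shuffled trial sequence
#'
#' Unconstrained uniform shuffle of the expanded template list, seeded.
#'
#' @param spec A `design_spec`.
#' @param seed Overrides the seed stored in the spec if given.
#' @return data.frame with `trial_index`, `left_value`, `right_value`.
#' @export
trial_sequence <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "design_spec"))
  idx <- rep.int(seq_len(nrow(spec$templates)), spec$templates$multiplicity)
  ord <- withr_seed(seed, sample.int(length(idx)))
  idx <- idx[ord]
  data.frame(trial_index = seq_along(idx),
             left_value = spec$templates$left_value[idx],
             right_value = spec$templates$right_value[idx])
}

# run expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Association statistics of a design
#'
#' For each value, the multiplicity-weighted proportion of trials containing
#' it in which it is the larger (or smaller) member. For a uniform all-pairs
#' design this reduces to the rank-based fractions: p_larger(v) =
#' (rank(v) - 1) / (m - 1).
#'
#' @param spec A `design_spec`.
#' @return data.frame with `value`, `p_smaller`, `p_larger`.
#' @export
association_statistics <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  tm <- spec$templates
  if (length(spec$values) < 2L) stop("need at least 2 values")
  res <- lapply(spec$values, function(v) {
    has <- tm$left_value == v | tm$right_value == v
    if (!any(has)) stop("value ", v, " absent from all trials")
    n_all <- sum(tm$multiplicity[has])
    larger <- has & pmax(tm$left_value, tm$right_value) == v
    p_l <- sum(tm$multiplicity[larger]) / n_all
    data.frame(value = v, p_smaller = 1 - p_l, p_larger = p_l)
  })
  do.call(rbind, res)
}

#' Rank map of a value set
#'
#' 1-based rank of each value in ascending order; the basis of the
#' association-based (order) regressor.
#'
#' @param values Distinct numeric values.
#' @return Named integer vector, value -> rank.
#' @export
order_map <- function(values) {
  if (anyDuplicated(values)) stop("duplicate values")
  s <- sort(values)
  stats::setNames(seq_along(s), s)
}

#' Generate a non-overlapping random dot array
#'
#' Dots are placed by rejection sampling in a square field (degrees of visual
#' angle, origin at the field corner) so that every dot lies fully inside the
#' field and no two dots overlap. Half the dots are black and half white
#' (ceiling/floor split) so total luminance is uninformative about
#' numerosity; dot size is fixed, so density and convex hull remain
#' correlated with numerosity, as in the modeled displays.
#'
#' @param n Number of dots (>= 1).
#' @param seed Integer seed; same (n, seed) reproduces positions exactly.
#' @param field_size_deg Side of the square field (default 2 degrees).
#' @param dot_diameter_deg Dot diameter (default 0.2 degrees).
#' @param max_attempts Rejection-sampling cap per dot.
#' @return A `dot_array_spec`: list with `n_dots`, `positions` (n x 2 matrix
#'   of centers), `colors`, `field_size_deg`, `dot_diameter_deg`.
#' @export
generate_dot_array <- function(n, seed = 1L, field_size_deg = 2.0,
                               dot_diameter_deg = 0.2, max_attempts = 10000L) {
  if (n < 1L) stop("n must be >= 1")
  r <- dot_diameter_deg / 2
  lo <- r; hi <- field_size_deg - r
  if (hi <= lo) stop("field too small for a single dot")
  pos <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
  withr_seed(seed, {
    for (i in seq_len(n)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        p <- stats::runif(2, lo, hi)
        if (i == 1L || all((pos[seq_len(i - 1L), 1] - p[1])^2 +
                           (pos[seq_len(i - 1L), 2] - p[2])^2 >=
                           dot_diameter_deg^2)) {
          pos[i, ] <- p; ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place dot ", i, " after ", max_attempts,
                    " attempts: field too crowded")
    }
    colors <- sample(rep_len(c("black", "white"), n))
    structure(list(n_dots = as.integer(n), positions = pos, colors = colors,
                   field_size_deg = field_size_deg,
                   dot_diameter_deg = dot_diameter_deg),
              class = "dot_array_spec")
  })
}

#' Normalized pair frequency
#'
#' phi(i, j) = (f(i) + f(j)) / max over pairs of the same sum, computed from
#' the condition's base-frequency table. The sum-of-token-counts form mirrors
#' the sum structure of the size regressor; phi is invariant to rescaling all
#' base frequencies by a constant.
#'
#' @param table A `frequency_table`.
#' @return data.frame with `small`, `large`, `phi` for each unordered pair.
#' @export
pair_frequency <- function(table) {
  stopifnot(inherits(table, "frequency_table"))
  v <- table$values
  pr <- t(utils::combn(v, 2L))
  f <- table$freq
  s <- f[as.character(pr[, 1])] + f[as.character(pr[, 2])]
  data.frame(small = pr[, 1], large = pr[, 2], phi = unname(s / max(s)))
}

#' Export a design's shuffled trial list as an empty trial table
#'
#' Writes the trial-table CSV schema (see [read_trials()]) with the
#' response fields (`response_side`, `correct`, `rt_ms`) left empty, ready
#' to be filled by an experiment runner.
#'
#' @param spec A `design_spec`.
#' @param path Output CSV path.
#' @param participant_id Placeholder participant label.
#' @param n_blocks Session blocks assigned as contiguous quarters.
#' @return The path, invisibly.
#' @export
export_trials_csv <- function(spec, path, participant_id = "",
                              n_blocks = 4L) {
  seqn <- trial_sequence(spec)
  n <- nrow(seqn)
  out <- data.frame(participant_id = participant_id,
                    condition = spec$condition,
                    block = block_of(seq_len(n), n, n_blocks),
                    trial_index = seqn$trial_index,
                    left_value = seqn$left_value,
                    right_value = seqn$right_value,
                    response_side = "", correct = "", rt_ms = "")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize design and dot-array specs to JSON
#'
#' Stable key order; positions serialized as row-wise coordinate pairs.
#'
#' @param x A `design_spec` or `dot_array_spec`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
spec_to_json <- function(x, path = NULL) {
  obj <- if (inherits(x, "design_spec")) {
    list(condition = x$condition, values = x$values,
         base_frequency = as.list(x$frequency_table$freq),
         templates = x$templates, total_trials = x$total_trials,
         seed = x$seed)
  } else if (inherits(x, "dot_array_spec")) {
    list(n_dots = x$n_dots, field_size_deg = x$field_size_deg,
         dot_diameter_deg = x$dot_diameter_deg,
         positions = unname(apply(x$positions, 1, as.list)),
         colors = x$colors)
  } else stop("unsupported object")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
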