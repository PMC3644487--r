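#' Primer scoring configuration
#'
#' Seven weighted parameters, 100 raw points each at the optimal value, for
#' a theoretical maximum of `sum(weights) * 100 = 1000` points (= 100%).
#' Optima: Tm 66-74 C, GC 40-60%, 3'-GC 50%, 3' delta-G -5.62..-4.74
#' kcal/mol (unstable 3' end), 5' delta-G -13.50..-12.62 kcal/mol (stable
#' 5' end), no runs/repeats, and at least (but as few as possible)
#' 2 nucleotide changes.  Mismatches are scored in tiers (1-2 changes: no
#' deduction; 3-4: minus 50; 5-6: minus 80; 7 or more: zero) and weighted
#' three-fold; GC content is weighted two-fold.  Continuous parameters
#' outside their optimum lose `points` raw points per started `step` of
#' distance (floor 0).
#'
#' @param weights named integer vector of parameter weights (must sum
#'   to 10).
#' @param tm,gc,gc3,dg3,dg5 lists with `range` (closed optimal interval),
#'   `step` (distance unit) and `points` (deduction per started step).
#' @param repeats_penalty raw points deducted per run or repeat.
#' @return a `scoring_config` list.
#' @export
scoring_config <- function(weights = c(gc = 2, n_changes = 3, tm = 1,
                                       gc3 = 1, dg3 = 1, dg5 = 1,
                                       repeats = 1),
                           tm = list(range = c(66, 74), step = 1, points = 10),
                           gc = list(range = c(40, 60), step = 1, points = 5),
                           gc3 = list(range = c(50, 50), step = 25, points = 50),
                           dg3 = list(range = c(-5.62, -4.74), step = 0.5,
                                      points = 15),
                           dg5 = list(range = c(-13.50, -12.62), step = 0.5,
                                      points = 15),
                           repeats_penalty = 50) {
  stopifnot(sum(weights) == 10,
            setequal(names(weights),
                     c("gc", "n_changes", "tm", "gc3", "dg3", "dg5", "repeats")))
  structure(list(weights = weights, tm = tm, gc = gc, gc3 = gc3,
                 dg3 = dg3, dg5 = dg5, repeats_penalty = repeats_penalty),
            class = "scoring_config")
}

#' Raw score of the mismatch parameter
#'
#' Tiered: 1-2 changes cost nothing (100 points); 3-4 lose 50; 5-6 lose 80;
#' 7 or more score 0.  Zero changes also score 100, with a message -- an
#' SDM primer is expected to carry at least 2 changes.
#'
#' @param n_changes non-negative mismatch count.
#' @return raw score, 0-100.
#' @export
score_mismatch_param <- function(n_changes) {
  n_changes <- as.integer(n_changes)
  if (is.na(n_changes) || n_changes < 0L)
    stop("mismatch count must be a non-negative integer", call. = FALSE)
  if (n_changes == 0L)
    message("primer has no mismatches against the template; an SDM primer ",
            "is expected to carry at least 2 changes")
  if (n_changes <= 2L) 100 else if (n_changes <= 4L) 50
  else if (n_changes <= 6L) 20 else 0
}

#' Raw score of a continuous parameter
#'
#' 100 inside the closed optimal `range`; outside, `points` are deducted
#' per started `step` of distance from the nearer boundary, floored at 0.
#' Non-increasing with distance.
#'
#' @param value observed value.
#' @param range length-2 numeric, closed optimal interval.
#' @param step distance unit of the deduction schedule.
#' @param points raw points deducted per started step.
#' @return raw score, 0-100.
#' @export
score_range_param <- function(value, range, step, points) {
  dist <- max(0, range[[1]] - value, value - range[[2]])
  max(0, 100 - points * ceiling(dist / step - 1e-9))
}

#' Weighted seven-parameter primer score
#'
#' @param metrics a metric panel from [primer_metrics()].
#' @param config a [scoring_config()].
#' @return a `score_breakdown`: data frame `table` (parameter, value, raw,
#'   weight, weighted), `total_points` (0-1000) and `percent`
#'   (`total_points / 10`, rounded to integer for reporting).
#' @export
score_primer <- function(metrics, config = scoring_config()) {
  stopifnot(inherits(config, "scoring_config"))
  w <- config$weights
  raw <- c(
    gc = score_range_param(metrics$gc_pct, config$gc$range,
                           config$gc$step, config$gc$points),
    n_changes = score_mismatch_param(metrics$n_changes),
    tm = score_range_param(metrics$tm_c, config$tm$range,
                           config$tm$step, config$tm$points),
    gc3 = score_range_param(metrics$gc3_pct, config$gc3$range,
                            config$gc3$step, config$gc3$points),
    dg3 = score_range_param(metrics$dg3_kcal, config$dg3$range,
                            config$dg3$step, config$dg3$points),
    dg5 = score_range_param(metrics$dg5_kcal, config$dg5$range,
                            config$dg5$step, config$dg5$points),
    repeats = max(0, 100 - config$repeats_penalty *
                    (metrics$runs + metrics$repeats)))
  value <- c(gc = metrics$gc_pct, n_changes = metrics$n_changes,
             tm = metrics$tm_c, gc3 = metrics$gc3_pct,
             dg3 = metrics$dg3_kcal, dg5 = metrics$dg5_kcal,
             repeats = metrics$runs + metrics$repeats)
  tab <- data.frame(parameter = names(raw), value = unname(value[names(raw)]),
                    raw = unname(raw), weight = unname(w[names(raw)]),
                    weighted = unname(raw * w[names(raw)]),
                    stringsAsFactors = FALSE)
  total <- sum(tab$weighted)
  structure(list(table = tab, total_points = total,
                 percent = round(total / 10)),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("<primer score: %g / 1000 points (%d%%)>\n",
              x$total_points, x$percent))
  print.data.frame(transform(x$table, value = round(value, 2)),
                   row.names = FALSE)
  invisible(x)
}
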