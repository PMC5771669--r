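#' Circle-weighted DNA-circle propagation frequency
#'
#' For anaphase cells carrying 1, 2 or 4 non-centromeric DNA circles, the
#' propagation frequency is
#' \deqn{1 - \frac{n_1 p_1 + 2 n_2 p_2 + 4 n_4 p_4}{n_1 + 2 n_2 + 4 n_4}}
#' where \eqn{n_i} is the number of cells carrying \eqn{i} circles and
#' \eqn{p_i} the per-circle retention fraction within that class (circles
#' kept in the mother / total circles carried by class-\eqn{i} cells). The
#' statistic equals the circle-weighted fraction of circles ending in the
#' bud, and recovers the per-circle passage probability when passages are
#' independent and uniform.
#'
#' @param obs Data frame with columns `circle_count` (1, 2 or 4),
#'   `circles_in_mother` and optionally `experiment_id` (used for
#'   per-experiment frequencies and the SEM over experiments).
#' @return An object of class `propagation_estimate`: list with `frequency`
#'   (pooled), `per_experiment` (named numeric), `mean` and `sem` over
#'   experiments, and `n_cells`. A class absent from the data simply drops
#'   out of both sums.
#' @examples
#' obs <- data.frame(circle_count = c(rep(1, 10), rep(2, 5)),
#'                   circles_in_mother = c(rep(1, 9), 0, rep(2, 3), 1, 1))
#' propagation_frequency(obs)$frequency   # 1 - (9 + 8)/20 = 0.15
#' @export
propagation_frequency <- function(obs) {
  stopifnot(is.data.frame(obs),
            all(c("circle_count", "circles_in_mother") %in% names(obs)))
  if (nrow(obs) == 0L) stop("no observations")
  if (!all(obs$circle_count %in% c(1L, 2L, 4L)))
    stop("circle_count must be 1, 2 or 4")
  if (any(obs$circles_in_mother < 0 | obs$circles_in_mother > obs$circle_count))
    stop("circles_in_mother must lie in [0, circle_count]")

  pooled <- function(d) {
    # sum_i i*n_i*p_i = total circles retained; sum_i i*n_i = total circles
    1 - sum(d$circles_in_mother) / sum(d$circle_count)
  }

  per_exp <- if ("experiment_id" %in% names(obs)) {
    vapply(split(obs, obs$experiment_id), pooled, 0)
  } else {
    c(all = pooled(obs))
  }

  out <- list(frequency = pooled(obs),
              per_experiment = per_exp,
              mean = mean(per_exp),
              sem = if (length(per_exp) > 1L)
                stats::sd(per_exp) / sqrt(length(per_exp)) else 0,
              n_cells = nrow(obs))
  class(out) <- "propagation_estimate"
  out
}

#' @export
print.propagation_estimate <- function(x, ...) {
  cat(sprintf("Propagation frequency: %.3f (mean %.3f +/- %.3f SEM over %d experiment(s), n = %d cells)\n",
              x$frequency, x$mean, x$sem, length(x$per_experiment), x$n_cells))
  invisible(x)
}

# validate timelines, dropping non-monotone cells with a warning
check_timelines <- function(timelines) {
  stopifnot(all(c("t_entry_min", "t_dumbbell_min", "t_karyo_min") %in%
                  names(timelines)))
  ok <- timelines$t_entry_min == 0 &
    timelines$t_dumbbell_min > timelines$t_entry_min &
    timelines$t_karyo_min > timelines$t_dumbbell_min
  if (any(!ok))
    warning(sum(!ok), " cell(s) with non-monotone anaphase event times dropped")
  timelines[ok, , drop = FALSE]
}

#' Anaphase stage durations
#'
#' Early anaphase runs from nuclear entry into the bud (`t_entry`, 0 by
#' convention) to the dumbbell-shaped nucleus (`t_dumbbell`); late anaphase
#' from the dumbbell to karyokinesis (`t_karyo`). Cells with non-monotone
#' event times are dropped with a warning.
#'
#' @param timelines Data frame as produced by [gen_timelines()].
#' @return A data frame with one row per stage (`early`, `late`, `total`):
#'   `mean_min`, `sem_min`, `sd_min`, `n`.
#' @export
stage_durations <- function(timelines) {
  tl <- check_timelines(timelines)
  if (nrow(tl) == 0L) stop("no valid timelines")
  early <- tl$t_dumbbell_min - tl$t_entry_min
  late <- tl$t_karyo_min - tl$t_dumbbell_min
  total <- tl$t_karyo_min
  summ <- function(x) c(mean(x), stats::sd(x) / sqrt(length(x)),
                        stats::sd(x), length(x))
  m <- rbind(early = summ(early), late = summ(late), total = summ(total))
  data.frame(stage = rownames(m), mean_min = m[, 1], sem_min = m[, 2],
             sd_min = m[, 3], n = as.integer(m[, 4]), row.names = NULL)
}

#' Stage-resolved circle passage flux
#'
#' The propagation flux is the number of first-appearance passage events
#' per minute in each anaphase stage: events falling in the stage divided
#' by the summed stage durations over all cells (cell-minutes). With
#' `denominator = "per_cell"`, the per-cell mean stage duration is used
#' instead (events / (n_cells * mean duration)); the pooled cell-minutes
#' form is the default.
#'
#' @param timelines Data frame as produced by [gen_timelines()], with a
#'   `passage_times_min` column (semicolon separated).
#' @param denominator `"cell_minutes"` (default) or `"per_cell"`.
#' @return A data frame with one row per stage (`early`, `late`):
#'   `n_events`, `observed_min` (cell-minutes), `flux` (events per minute),
#'   `se_flux` (Poisson), `n_cells`. A stage with zero observed minutes
#'   gets `flux = NA` with a warning.
#' @examples
#' tl <- gen_timelines(timeline_sim_config(n_cells = 200, seed = 5))
#' propagation_flux(tl)
#' @export
propagation_flux <- function(timelines, denominator = c("cell_minutes", "per_cell")) {
  denominator <- match.arg(denominator)
  tl <- check_timelines(timelines)
  if (nrow(tl) == 0L) stop("no valid timelines")
  pass <- parse_passage_times(tl)

  early_min <- sum(tl$t_dumbbell_min - tl$t_entry_min)
  late_min <- sum(tl$t_karyo_min - tl$t_dumbbell_min)
  # a first appearance scored at the same frame as dumbbell formation counts
  # as early anaphase (the passage preceded or coincided with the boundary)
  n_early <- sum(vapply(seq_len(nrow(tl)), function(i)
    sum(pass[[i]] <= tl$t_dumbbell_min[i]), 0L))
  n_late <- sum(vapply(seq_len(nrow(tl)), function(i)
    sum(pass[[i]] > tl$t_dumbbell_min[i] & pass[[i]] <= tl$t_karyo_min[i]), 0L))

  if (denominator == "per_cell") {
    early_min <- nrow(tl) * mean(tl$t_dumbbell_min - tl$t_entry_min)
    late_min <- nrow(tl) * mean(tl$t_karyo_min - tl$t_dumbbell_min)
  }

  flux_of <- function(ev, minutes) {
    if (minutes <= 0) {
      warning("zero observed minutes; flux undefined")
      return(c(NA_real_, NA_real_))
    }
    c(ev / minutes, sqrt(ev) / minutes)
  }
  fe <- flux_of(n_early, early_min)
  fl <- flux_of(n_late, late_min)
  data.frame(stage = c("early", "late"),
             n_events = c(n_early, n_late),
             observed_min = c(early_min, late_min),
             flux = c(fe[1], fl[1]),
             se_flux = c(fe[2], fl[2]),
             n_cells = nrow(tl))
}

#' Compare propagation estimates across conditions
#'
#' Tabulates one estimate per condition and all pairwise ratios (fold
#' changes). Accepts plain numbers, [propagation_frequency()] results
#' (their pooled frequency) or single rows of [propagation_flux()] output
#' (their flux).
#'
#' @param estimates Named list or named numeric vector, one entry per
#'   condition.
#' @return A list with `conditions` (data frame: condition, estimate) and
#'   `ratios` (data frame: numerator, denominator, ratio; `NA` with a
#'   warning where the denominator is zero).
#' @examples
#' propagation_summary(c(`37C` = 0.06, `30C` = 0.03))$ratios
#' @export
propagation_summary <- function(estimates) {
  if (length(estimates) == 0L) stop("no conditions")
  vals <- vapply(seq_along(estimates), function(i) {
    e <- if (is.list(estimates)) estimates[[i]] else estimates[i]
    if (inherits(e, "propagation_estimate")) e$frequency
    else if (is.data.frame(e)) e$flux[1L]
    else as.numeric(e)
  }, 0)
  names(vals) <- names(estimates)
  if (is.null(names(vals)) || any(!nzchar(names(vals))))
    stop("conditions must be named")

  pairs <- expand.grid(numerator = names(vals), denominator = names(vals),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$numerator != pairs$denominator, , drop = FALSE]
  pairs$ratio <- vals[pairs$numerator] / vals[pairs$denominator]
  if (any(!is.finite(pairs$ratio)))
    warning("zero denominator: ratio reported as undefined (NA/Inf)")
  list(conditions = data.frame(condition = names(vals), estimate = unname(vals)),
       ratios = pairs)
}
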