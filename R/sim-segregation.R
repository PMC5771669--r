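#' Configuration for the DNA-circle segregation simulator
#'
#' Emulates the anaphase segregation assay: each cell carries 1, 2 or 4
#' non-centromeric DNA circles and each circle independently either stays in
#' the mother or ends up in the bud at division.
#'
#' @param n_cells Number of anaphase cells to simulate.
#' @param class_mix Proportions of cells carrying 1, 2 and 4 circles; must
#'   sum to 1.
#' @param p_pass Per-circle probability of ending in the bud, in \[0, 1\].
#' @param n_experiments Number of independent experiments the cells are
#'   split across (round-robin), mirroring replicate imaging sessions.
#' @param seed RNG seed.
#' @return An object of class `seg_sim_config`.
#' @seealso [gen_circle_observations()]
#' @export
segregation_sim_config <- function(n_cells = 100L,
                                   class_mix = c(0.6, 0.3, 0.1),
                                   p_pass = 0.04,
                                   n_experiments = 3L,
                                   seed = 1L) {
  stopifnot(n_cells >= 1, n_experiments >= 1)
  if (length(class_mix) != 3L || any(class_mix < 0))
    stop("class_mix must give three non-negative proportions (1, 2, 4 circles)")
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix must sum to 1")
  if (p_pass < 0 || p_pass > 1) stop("p_pass must lie in [0, 1]")
  structure(list(n_cells = as.integer(n_cells),
                 class_mix = as.numeric(class_mix),
                 p_pass = p_pass,
                 n_experiments = as.integer(n_experiments),
                 seed = as.integer(seed)),
            class = "seg_sim_config")
}

#' Simulate per-cell circle counts and retention outcomes
#'
#' Each cell draws its circle count (1, 2 or 4) from `class_mix`; each of its
#' circles independently lands in the bud with probability `p_pass`.
#'
#' @param config A [segregation_sim_config()] object.
#' @return A data frame with columns `cell_id`, `circle_count`,
#'   `circles_in_mother` and `experiment_id`.
#' @examples
#' obs <- gen_circle_observations(segregation_sim_config(n_cells = 50, seed = 2))
#' table(obs$circle_count)
#' @export
gen_circle_observations <- function(config) {
  stopifnot(inherits(config, "seg_sim_config"))
  set.seed(config$seed)
  counts <- sample(c(1L, 2L, 4L), config$n_cells, replace = TRUE,
                   prob = config$class_mix)
  in_bud <- stats::rbinom(config$n_cells, counts, config$p_pass)
  out <- data.frame(cell_id = sprintf("cell%05d", seq_len(config$n_cells)),
             circle_count = counts,
             circles_in_mother = counts - in_bud,
             experiment_id = sprintf(
               "exp%d", ((seq_len(config$n_cells) - 1L) %% config$n_experiments) + 1L),
             stringsAsFactors = FALSE)
  attr(out, "seed") <- config$seed
  out
}

#' Configuration for the anaphase-timeline simulator
#'
#' Emulates time-lapse movies scoring nuclear division at one frame per
#' minute: early anaphase runs from the entry of the nucleus into the bud to
#' the formation of a dumbbell-shaped nucleus, late anaphase from the
#' dumbbell to karyokinesis. Each DNA circle can pass to the bud at most
#' once, with a stage-specific constant hazard.
#'
#' @param n_cells Number of cells.
#' @param early_mean,early_sd Mean and SD of early-anaphase duration
#'   (minutes); drawn truncated-normal above zero.
#' @param late_mean,late_sd Mean and SD of late-anaphase duration (minutes).
#' @param hazard_early,hazard_late Passage hazard per circle per minute in
#'   each stage (>= 0).
#' @param circles_per_cell Number of circles carried by each cell.
#' @param frame_interval_min Frame spacing in minutes; all event times are
#'   snapped to this grid.
#' @param seed RNG seed.
#' @return An object of class `timeline_sim_config`.
#' @seealso [gen_timelines()]
#' @export
timeline_sim_config <- function(n_cells = 100L,
                                early_mean = 3.9, early_sd = 0.5,
                                late_mean = 14.5, late_sd = 2,
                                hazard_early = 0.03,
                                hazard_late = 0.004,
                                circles_per_cell = 1L,
                                frame_interval_min = 1,
                                seed = 1L) {
  stopifnot(n_cells >= 1, circles_per_cell >= 1)
  if (early_mean <= 0 || late_mean <= 0) stop("stage duration means must be positive")
  if (early_sd < 0 || late_sd < 0) stop("stage duration SDs must be non-negative")
  if (hazard_early < 0 || hazard_late < 0) stop("hazards must be non-negative")
  if (frame_interval_min <= 0) stop("frame_interval_min must be positive")
  cfg <- structure(list(n_cells = as.integer(n_cells),
                        early_mean = early_mean, early_sd = early_sd,
                        late_mean = late_mean, late_sd = late_sd,
                        hazard_early = hazard_early, hazard_late = hazard_late,
                        circles_per_cell = as.integer(circles_per_cell),
                        frame_interval_min = frame_interval_min,
                        seed = as.integer(seed)),
                   class = "timeline_sim_config")
  if (max(hazard_early, hazard_late) * circles_per_cell * frame_interval_min > 1)
    warning("expected passages per frame exceed 1; events will saturate the frame grid")
  cfg
}

# truncated-normal draw, > 0, by rejection
rtnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Simulate anaphase timelines with stage-specific circle passages
#'
#' Per cell, draws early and late anaphase durations (truncated normal,
#' positive), sets `t_entry = 0`, and exposes each circle to a constant
#' passage hazard in each stage; at most one passage per circle, scored as
#' its first appearance in the bud. All times are snapped to the frame grid.
#'
#' @param config A [timeline_sim_config()] object.
#' @return A data frame with one row per cell: `cell_id`, `t_entry_min` (0),
#'   `t_dumbbell_min`, `t_karyo_min` and `passage_times_min` (semicolon
#'   separated list, `""` when no circle passed).
#' @examples
#' tl <- gen_timelines(timeline_sim_config(n_cells = 20, seed = 3))
#' head(tl)
#' @export
gen_timelines <- function(config) {
  stopifnot(inherits(config, "timeline_sim_config"))
  set.seed(config$seed)
  n <- config$n_cells
  dt <- config$frame_interval_min
  snap <- function(t) round(t / dt) * dt

  early <- rtnorm_pos(n, config$early_mean, config$early_sd)
  late <- rtnorm_pos(n, config$late_mean, config$late_sd)
  # keep stage boundaries distinct after snapping
  t_dumbbell <- pmax(snap(early), dt)
  t_karyo <- pmax(snap(early + late), t_dumbbell + dt)

  passages <- character(n)
  for (i in seq_len(n)) {
    times <- numeric(0)
    for (k in seq_len(config$circles_per_cell)) {
      t_e <- if (config$hazard_early > 0)
        stats::rexp(1, config$hazard_early) else Inf
      if (t_e < t_dumbbell[i]) {
        times <- c(times, snap(t_e))
        next
      }
      t_l <- if (config$hazard_late > 0)
        stats::rexp(1, config$hazard_late) else Inf
      if (t_l < t_karyo[i] - t_dumbbell[i])
        times <- c(times, snap(t_dumbbell[i] + t_l))
    }
    passages[i] <- paste(times, collapse = ";")
  }

  out <- data.frame(cell_id = sprintf("cell%05d", seq_len(n)),
                    t_entry_min = 0,
                    t_dumbbell_min = t_dumbbell,
                    t_karyo_min = t_karyo,
                    passage_times_min = passages,
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- config$seed
  out
}
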