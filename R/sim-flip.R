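#' Configuration for the FLIP photobleaching simulator
#'
#' Describes a fluorescence-loss-in-photobleaching (FLIP) acquisition on
#' dividing cells: a bleach pulse is applied to the mother compartment at
#' every frame, nucleoporin-bound fluorescence exchanges between mother and
#' bud across the bud neck, and the whole field loses signal to acquisition
#' photobleaching. Neighbouring, unbleached whole cells serve as controls for
#' the acquisition decay.
#'
#' The per-frame update (latent, noise-free state) is
#' \deqn{M' = (1-a)\,[(1-b)M + x(B-M)], \quad
#'       B' = (1-a)\,[B - x(B-M)], \quad C' = (1-a)\,C,}
#' i.e. bleach pulse first, then exchange of a fraction `x` of the
#' mother/bud difference, then global acquisition decay `a`. The reported
#' intensity is latent state + `background` + Gaussian noise; the latent
#' dynamics stay deterministic so closed-form checks remain exact.
#'
#' @param n_cells Number of dividing (mother + bud) cells.
#' @param frame_interval Seconds between frames (and bleach pulses).
#' @param n_frames Number of frames acquired.
#' @param bleach_fraction Fraction `b` of mother signal removed per pulse,
#'   in (0, 1).
#' @param exchange_rate Fraction `x` of the mother/bud difference
#'   equilibrated per frame, in \[0, 0.5\]; values above 0.5 would overshoot
#'   equilibration in one step and are rejected.
#' @param acquisition_decay Global per-frame photobleaching fraction `a`
#'   applied to every cell, controls included.
#' @param noise_sd Standard deviation of additive measurement noise (a.u.),
#'   applied to reported values only.
#' @param background Constant camera/medium offset added to every reported
#'   intensity (a.u.).
#' @param n_controls Number of neighbouring control cells, between 3 and 5.
#' @param volume_ratio Bud-to-mother volume ratio. The default 1 makes the
#'   exchange symmetric; with ratio `v`, the bud gains `x (M - B)` while the
#'   mother loses `v x (M - B)` scaled so total signal is conserved.
#' @param seed RNG seed; the whole simulation is reproducible given the seed.
#'
#' @return An object of class `flip_sim_config`.
#' @seealso [gen_flip_traces()]
#' @export
flip_sim_config <- function(n_cells = 30L,
                            frame_interval = 4,
                            n_frames = 70L,
                            bleach_fraction = 0.05,
                            exchange_rate = 0.002,
                            acquisition_decay = 0.002,
                            noise_sd = 5,
                            background = 50,
                            n_controls = 4L,
                            volume_ratio = 1,
                            seed = 1L) {
  stopifnot(n_cells >= 1, n_frames >= 2, frame_interval > 0)
  if (bleach_fraction <= 0 || bleach_fraction >= 1)
    stop("bleach_fraction must lie in (0, 1)")
  if (exchange_rate < 0 || exchange_rate > 0.5)
    stop("exchange_rate must lie in [0, 0.5]: larger values overshoot equilibration")
  if (acquisition_decay < 0 || acquisition_decay > 1)
    stop("acquisition_decay must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (n_controls < 3 || n_controls > 5)
    stop("n_controls must be between 3 and 5")
  if (volume_ratio <= 0) stop("volume_ratio must be positive")
  structure(list(n_cells = as.integer(n_cells),
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 bleach_fraction = bleach_fraction,
                 exchange_rate = exchange_rate,
                 acquisition_decay = acquisition_decay,
                 noise_sd = noise_sd,
                 background = background,
                 n_controls = as.integer(n_controls),
                 volume_ratio = volume_ratio,
                 seed = as.integer(seed)),
            class = "flip_sim_config")
}

#' Simulate FLIP traces for a cohort of dividing cells and controls
#'
#' Iterates the two-compartment bleach/exchange/decay recurrence described in
#' [flip_sim_config()] from an initial latent intensity of 1000 a.u. in every
#' compartment. Mother and bud traces are emitted per dividing cell and one
#' whole-cell trace per control.
#'
#' @param config A [flip_sim_config()] object.
#' @return A data frame with columns `cell_id`, `role`
#'   (`"mother"`, `"bud"` or `"control"`), `frame` (0-based), `time_s` and
#'   `intensity` (a.u., including background and noise). The noise-free
#'   latent intensities are attached as attribute `"latent"` (same shape,
#'   column `latent` instead of `intensity`) for oracle checks.
#' @examples
#' tr <- gen_flip_traces(flip_sim_config(n_cells = 2, noise_sd = 0, seed = 7))
#' head(tr)
#' @export
gen_flip_traces <- function(config) {
  stopifnot(inherits(config, "flip_sim_config"))
  set.seed(config$seed)
  nf <- config$n_frames
  b <- config$bleach_fraction
  x <- config$exchange_rate
  a <- config$acquisition_decay
  v <- config$volume_ratio

  # latent recurrence, identical for every dividing cell (noise is
  # observation-only)
  M <- B <- numeric(nf)
  M[1] <- B[1] <- 1000
  for (t in seq_len(nf - 1L)) {
    flow <- x * (B[t] - M[t])             # signal moving bud -> mother if positive
    M[t + 1L] <- (1 - a) * ((1 - b) * M[t] + flow)
    B[t + 1L] <- (1 - a) * (B[t] - flow * v)
  }
  C <- 1000 * (1 - a)^(0:(nf - 1L))

  times <- (0:(nf - 1L)) * config$frame_interval
  one <- function(id, role, latent) {
    obs <- latent + config$background
    if (config$noise_sd > 0)
      obs <- obs + stats::rnorm(nf, 0, config$noise_sd)
    data.frame(cell_id = id, role = role, frame = 0:(nf - 1L),
               time_s = times, intensity = obs, latent = latent,
               stringsAsFactors = FALSE)
  }

  parts <- vector("list", 2L * config$n_cells + config$n_controls)
  k <- 0L
  for (i in seq_len(config$n_cells)) {
    parts[[k <- k + 1L]] <- one(sprintf("cell%03d", i), "mother", M)
    parts[[k <- k + 1L]] <- one(sprintf("cell%03d", i), "bud", B)
  }
  for (j in seq_len(config$n_controls))
    parts[[k <- k + 1L]] <- one(sprintf("ctrl%02d", j), "control", C)

  out <- do.call(rbind, parts)
  latent <- out[, c("cell_id", "role", "frame", "time_s", "latent")]
  out$latent <- NULL
  attr(out, "latent") <- latent
  attr(out, "seed") <- config$seed
  out
}
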