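#' Configuration for the nuclear-rim profile simulator
#'
#' Emulates per-cell intensity profiles measured along the closed nuclear
#' rim in two channels: GFP-tagged nucleoporin (NPC punctae on a baseline)
#' and an mCherry-labelled DNA circle (single peak). With probability
#' `p_attached` the circle sits exactly on an NPC punctum; otherwise it is
#' placed midway between two punctae.
#'
#' @param n_cells Number of cells.
#' @param n_positions Arc-length bins per rim trace (>= 21 so an alignment
#'   window exists).
#' @param n_punctae Number of evenly spaced NPC punctae per rim (random
#'   phase per cell).
#' @param npc_peak_amplitude Fold elevation of GFP at a punctum over the
#'   rim baseline; 1 means no punctae.
#' @param p_attached Probability the circle coincides with a GFP punctum.
#' @param gfp_peak_width,mcherry_peak_width Gaussian SD of the punctum /
#'   circle peak, in positions; must be < `n_positions`.
#' @param baseline Rim GFP baseline intensity (a.u.).
#' @param noise_sd Additive Gaussian noise SD (a.u.).
#' @param background Constant offset added to both channels (a.u.).
#' @param seed RNG seed.
#' @return An object of class `rim_sim_config`.
#' @seealso [gen_rim_profiles()]
#' @export
rim_sim_config <- function(n_cells = 50L,
                           n_positions = 60L,
                           n_punctae = 6L,
                           npc_peak_amplitude = 2,
                           p_attached = 1,
                           gfp_peak_width = 1.5,
                           mcherry_peak_width = 1.5,
                           baseline = 100,
                           noise_sd = 5,
                           background = 20,
                           seed = 1L) {
  stopifnot(n_cells >= 1, n_punctae >= 1)
  if (n_positions < 21) stop("n_positions must be >= 21 so an offset window exists")
  if (p_attached < 0 || p_attached > 1) stop("p_attached must lie in [0, 1]")
  if (gfp_peak_width >= n_positions || mcherry_peak_width >= n_positions)
    stop("peak widths must be smaller than n_positions")
  if (npc_peak_amplitude < 1) stop("npc_peak_amplitude is a fold elevation, >= 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(n_cells = as.integer(n_cells),
                 n_positions = as.integer(n_positions),
                 n_punctae = as.integer(n_punctae),
                 npc_peak_amplitude = npc_peak_amplitude,
                 p_attached = p_attached,
                 gfp_peak_width = gfp_peak_width,
                 mcherry_peak_width = mcherry_peak_width,
                 baseline = baseline,
                 noise_sd = noise_sd,
                 background = background,
                 seed = as.integer(seed)),
            class = "rim_sim_config")
}

# circular Gaussian bump centred at `centre` over positions 0..n-1
circ_bump <- function(n, centre, width) {
  pos <- 0:(n - 1L)
  d <- abs(pos - centre)
  d <- pmin(d, n - d)                    # wrap-around distance
  exp(-0.5 * (d / width)^2)
}

#' Simulate nuclear-rim GFP/mCherry intensity profiles
#'
#' Builds closed (circular) rim traces per [rim_sim_config()]: the GFP
#' channel is a baseline with punctae of amplitude
#' `(npc_peak_amplitude - 1) * baseline` at evenly spaced, randomly phased
#' positions; the mCherry channel carries a single circle peak, coincident
#' with a punctum for attached cells and midway between punctae otherwise.
#'
#' @param config A [rim_sim_config()] object.
#' @return A data frame with columns `cell_id`, `position_index` (0-based),
#'   `gfp`, `mcherry`. Attributes `"attached"` (logical per cell) and
#'   `"circle_position"` (integer per cell) record the ground truth.
#' @examples
#' rp <- gen_rim_profiles(rim_sim_config(n_cells = 3, noise_sd = 0, seed = 4))
#' head(rp)
#' @export
gen_rim_profiles <- function(config) {
  stopifnot(inherits(config, "rim_sim_config"))
  set.seed(config$seed)
  n <- config$n_positions
  spacing <- n / config$n_punctae
  amp <- (config$npc_peak_amplitude - 1) * config$baseline

  parts <- vector("list", config$n_cells)
  attached <- logical(config$n_cells)
  circle_pos <- integer(config$n_cells)
  for (i in seq_len(config$n_cells)) {
    phase <- sample.int(n, 1L) - 1L
    punctae <- (round(phase + spacing * (0:(config$n_punctae - 1L)))) %% n
    attached[i] <- stats::runif(1) < config$p_attached
    circle_pos[i] <- if (attached[i]) punctae[1L]
                     else (punctae[1L] + round(spacing / 2)) %% n

    # real NPC clusters vary in brightness; an attached circle sits on a
    # full-amplitude punctum, the remaining punctae are dimmed at random so
    # the profile has a unique brightest punctum
    rel_amp <- stats::runif(config$n_punctae, 0.6, 0.95)
    if (attached[i]) rel_amp[1L] <- 1
    gfp <- rep(config$baseline, n)
    if (amp > 0)
      for (k in seq_along(punctae))
        gfp <- gfp + amp * rel_amp[k] * circ_bump(n, punctae[k],
                                                  config$gfp_peak_width)
    mch <- 200 * circ_bump(n, circle_pos[i], config$mcherry_peak_width)

    gfp_obs <- gfp + config$background
    mch_obs <- mch + config$background
    if (config$noise_sd > 0) {
      gfp_obs <- gfp_obs + stats::rnorm(n, 0, config$noise_sd)
      mch_obs <- mch_obs + stats::rnorm(n, 0, config$noise_sd)
    }
    parts[[i]] <- data.frame(cell_id = sprintf("cell%04d", i),
                             position_index = 0:(n - 1L),
                             gfp = gfp_obs, mcherry = mch_obs,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, parts)
  attr(out, "attached") <- attached
  attr(out, "circle_position") <- circle_pos
  attr(out, "seed") <- config$seed
  out
}
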