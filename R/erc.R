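#' Configuration for the ERC accumulation simulator
#'
#' Parameters of the stochastic model of extrachromosomal rDNA circle (ERC)
#' dynamics in a dividing yeast mother cell. Each division: every circle
#' already present replicates (doubles) with probability `f` — rDNA-circle
#' origins fire in only about 60 percent of cell cycles, hence the default
#' `f = 0.6`; a Poisson(`e`) number of circles is excised de novo from the
#' chromosomal rDNA; and every resulting copy stays in the mother with
#' probability `r` (the diffusion-barrier-dependent retention), otherwise
#' it escapes to the daughter. The mother dies once its load reaches
#' `death_threshold` copies — old mothers accumulate ERCs up to the order
#' of a thousand copies, hence the default threshold of 1000. The de novo
#' rate and lethal load are not experimentally pinned down and remain free
#' parameters.
#'
#' @param r Per-copy retention probability at division, in \[0, 1\].
#' @param f Per-circle replication-firing probability per cycle.
#' @param e Expected de novo excision events per division (Poisson mean).
#' @param death_threshold ERC copies at which the mother dies (>= 1).
#' @param max_generations Censoring horizon; required to be finite.
#' @param n_lineages Number of independent mother lineages.
#' @param seed RNG seed.
#' @return An object of class `erc_config`.
#' @seealso [simulate_lineages()], [expected_load()]
#' @export
erc_config <- function(r = 0.96, f = 0.6, e = 0.1,
                       death_threshold = 1000L,
                       max_generations = 100L,
                       n_lineages = 1000L,
                       seed = 1L) {
  if (r < 0 || r > 1) stop("retention r must lie in [0, 1]")
  if (f < 0 || f > 1) stop("firing probability f must lie in [0, 1]")
  if (e < 0) stop("excision rate e must be non-negative")
  if (!is.finite(death_threshold) || death_threshold < 1)
    stop("death_threshold must be finite and >= 1 (an unbounded run never ends)")
  if (!is.finite(max_generations) || max_generations < 1)
    stop("max_generations must be finite and >= 1")
  stopifnot(n_lineages >= 1)
  structure(list(r = r, f = f, e = e,
                 death_threshold = as.integer(death_threshold),
                 max_generations = as.integer(max_generations),
                 n_lineages = as.integer(n_lineages),
                 seed = as.integer(seed)),
            class = "erc_config")
}

#' Simulate ERC lineages to death or censoring
#'
#' Each lineage starts with zero circles. Per division, existing circles
#' fire with probability `f` (adding one copy each), Poisson(`e`) new
#' circles are excised, and every copy is independently retained with
#' probability `r` or exported to the daughter. The lineage's lifespan is
#' the number of divisions completed before the mother's load first
#' reaches the death threshold. The expected load follows the recursion
#' \deqn{E[L_{g+1}] = (1+f)\,r\,E[L_g] + r\,e} (de novo circles do not fire
#' in the cycle they arise), see [expected_load()].
#'
#' @param config An [erc_config()] object.
#' @return An object of class `erc_lineages`: list with `loads`
#'   (`n_lineages x max_generations` integer matrix of mother loads after
#'   each division; `NA` after death), `exported` (same shape, copies given
#'   to the daughter that division), `created` (copies present after firing
#'   and excision, before partitioning), `lifespan` (generations completed
#'   before death; equals `max_generations` for censored lineages), `died`
#'   (logical) and `config`. Circle bookkeeping is exact:
#'   `created == loads + exported` at every division.
#' @examples
#' lin <- simulate_lineages(erc_config(n_lineages = 100, seed = 42))
#' table(lin$died)
#' @export
simulate_lineages <- function(config) {
  stopifnot(inherits(config, "erc_config"))
  set.seed(config$seed)
  n <- config$n_lineages
  G <- config$max_generations
  loads <- exported <- created <- matrix(NA_integer_, n, G)
  L <- integer(n)                 # current mother load
  alive <- rep(TRUE, n)
  lifespan <- rep(G, n)

  for (g in seq_len(G)) {
    idx <- which(alive)
    if (length(idx) == 0L) break
    fired <- stats::rbinom(length(idx), L[idx], config$f)
    new <- stats::rpois(length(idx), config$e)
    copies <- L[idx] + fired + new
    kept <- stats::rbinom(length(idx), copies, config$r)
    loads[idx, g] <- kept
    exported[idx, g] <- copies - kept
    created[idx, g] <- copies
    L[idx] <- kept

    dead <- idx[kept >= config$death_threshold]
    if (length(dead)) {
      # death at the end of the division that pushed the load over threshold:
      # that division still completes, so it counts toward the lifespan
      lifespan[dead] <- g
      alive[dead] <- FALSE
    }
  }

  structure(list(loads = loads, exported = exported, created = created,
                 lifespan = lifespan, died = !alive, config = config),
            class = "erc_lineages")
}

#' Closed-form expected ERC load per generation
#'
#' Iterates the expectation recursion
#' \eqn{E[L_{g+1}] = (1+f) r E[L_g] + r e} from \eqn{E[L_0] = 0}. Serves as
#' the analytic reference for the stochastic simulator (ignoring the death
#' threshold, so it matches simulations only while deaths are negligible).
#'
#' @param g Number of generations.
#' @param r,f,e Model parameters as in [erc_config()].
#' @return Numeric vector of length `g`: expected load after divisions
#'   1..g.
#' @export
expected_load <- function(g, r = 0.96, f = 0.6, e = 0.1) {
  out <- numeric(g)
  L <- 0
  for (i in seq_len(g)) {
    L <- (1 + f) * r * L + r * e
    out[i] <- L
  }
  out
}

#' Survival summary of simulated lineages
#'
#' Computes the fraction of lineages still alive after each generation and
#' the median replicative lifespan: the smallest generation at which
#' survival drops to one half, with midpoint interpolation when survival
#' sits exactly at 0.5 (so lifespans 1..100 give a median of 50.5).
#'
#' @param lineages An [simulate_lineages()] result.
#' @return A list with `generations`, `survival` (non-increasing fraction
#'   alive), `median` (NA with a warning when more than half the lineages
#'   are censored) and `n`.
#' @export
survival_summary <- function(lineages) {
  stopifnot(inherits(lineages, "erc_lineages"))
  G <- lineages$config$max_generations
  n <- length(lineages$lifespan)
  # lineage counted dead after generation g if it died and lifespan <= g
  death_gen <- ifelse(lineages$died, lineages$lifespan, Inf)
  surv <- vapply(seq_len(G), function(g) mean(death_gen > g), 0)

  med <- NA_real_
  at_half <- which(surv <= 0.5)
  if (length(at_half) == 0L) {
    warning("more than half the lineages are censored; median lifespan undefined")
  } else {
    g1 <- at_half[1L]
    if (surv[g1] == 0.5) {
      below <- which(surv < 0.5)
      med <- if (length(below)) (g1 + below[1L]) / 2 else NA_real_
    } else {
      med <- g1
    }
  }
  list(generations = seq_len(G), survival = surv, median = med, n = n)
}

#' Mean ERC load among survivors at a given generation
#'
#' @param lineages An [simulate_lineages()] result.
#' @param g Generation (>= 1).
#' @return A list with `mean`, `se` and `n_survivors` for the lineages
#'   still alive after division `g`.
#' @export
load_at_generation <- function(lineages, g) {
  stopifnot(inherits(lineages, "erc_lineages"), g >= 1)
  if (g > lineages$config$max_generations)
    stop("g exceeds max_generations")
  death_gen <- ifelse(lineages$died, lineages$lifespan, Inf)
  alive <- death_gen > g
  if (!any(alive)) {
    warning("no survivors at generation ", g)
    return(list(mean = NA_real_, se = NA_real_, n_survivors = 0L))
  }
  loads <- lineages$loads[alive, g]
  list(mean = mean(loads),
       se = stats::sd(loads) / sqrt(length(loads)),
       n_survivors = sum(alive))
}

#' Fold change between two Southern-blot lanes
#'
#' Band intensities (the four concatemer bands of circular rDNA species)
#' are summed per lane and the lane totals are compared as a ratio.
#'
#' @param lane_a,lane_b Numeric vectors of band intensities (a.u., >= 0).
#' @return The fold change `sum(lane_a) / sum(lane_b)`.
#' @examples
#' southern_fold_change(c(10, 5, 3, 2), c(3, 2, 0.5, 0.56))  # ~3.3
#' @export
southern_fold_change <- function(lane_a, lane_b) {
  if (any(lane_a < 0) || any(lane_b < 0)) stop("band intensities must be >= 0")
  tb <- sum(lane_b)
  if (tb <= 0) stop("zero total intensity in the denominator lane")
  sum(lane_a) / tb
}
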