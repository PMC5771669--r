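#' Normalize FLIP traces to control cells
#'
#' Applies the standard FLIP correction: background is subtracted from every
#' trace, the mother and bud traces are divided frame-wise by the mean of
#' the neighbouring control cells (correcting for fluorescence decay due to
#' exposure), and each corrected trace is rescaled so its first value is
#' 100 percent.
#'
#' @param mother,bud Data frames (or lists) with numeric columns/elements
#'   `time_s` and `intensity` on a common time grid.
#' @param controls List of control traces on the same grid (at least one).
#' @param background Scalar background (a.u.) subtracted from every trace.
#' @return A list with elements `mother` and `bud`, each a data frame with
#'   columns `time_s` and `percent` (`percent[1] == 100` exactly).
#' @examples
#' tr <- gen_flip_traces(flip_sim_config(n_cells = 1, noise_sd = 0, seed = 1))
#' sp <- split(tr, tr$role)
#' nd <- normalize_traces(sp$mother, sp$bud,
#'                        split(sp$control, sp$control$cell_id), background = 50)
#' head(nd$mother)
#' @export
normalize_traces <- function(mother, bud, controls, background = 0) {
  if (length(controls) == 0L) stop("at least one control trace is required")
  grids <- lapply(c(list(mother, bud), controls), function(tr) tr$time_s)
  for (g in grids[-1L])
    if (length(g) != length(grids[[1L]]) || any(abs(g - grids[[1L]]) > 1e-8))
      stop("all traces must share the same time grid")

  ctrl <- sapply(controls, function(tr) tr$intensity - background)
  ctrl_mean <- rowMeans(as.matrix(ctrl))
  if (any(ctrl_mean <= 0))
    stop("control mean is non-positive at frame(s) ",
         paste(which(ctrl_mean <= 0) - 1L, collapse = ", "),
         "; check the background estimate")

  scale100 <- function(tr) {
    corrected <- (tr$intensity - background) / ctrl_mean
    if (!is.finite(corrected[1L]) || corrected[1L] <= 0)
      stop("trace is non-positive at the first frame after correction")
    data.frame(time_s = tr$time_s, percent = 100 * corrected / corrected[1L])
  }
  list(mother = scale100(mother), bud = scale100(bud))
}

#' Pool normalized single-cell decay profiles
#'
#' Frame-wise mean of the normalized profiles, producing the single pooled
#' profile that is then fit to a one-phase decay.
#'
#' @param decays Non-empty list of data frames with columns `time_s`,
#'   `percent`, all on the same time grid.
#' @return A data frame `time_s`, `percent` with attribute `"n"` giving the
#'   number of pooled profiles.
#' @export
pool_profiles <- function(decays) {
  if (length(decays) == 0L) stop("no profiles to pool")
  t0 <- decays[[1L]]$time_s
  for (d in decays)
    if (length(d$time_s) != length(t0) || any(abs(d$time_s - t0) > 1e-8))
      stop("profiles must share the same time grid")
  m <- rowMeans(sapply(decays, function(d) d$percent))
  out <- data.frame(time_s = t0, percent = m)
  attr(out, "n") <- length(decays)
  out
}

#' Fit a one-phase decay with the initial value constrained to 100
#'
#' Least-squares fit of \deqn{Y(t) = P + (100 - P)\,e^{-K t}} with the
#' initial value Y0 fixed at 100 percent, the plateau `P` constrained below
#' 100 and the rate `K` constrained non-negative (bounded
#' Levenberg-Marquardt). Standard errors and the plateau-rate covariance
#' are taken from the fit for downstream error propagation.
#'
#' @param decay Data frame with columns `time_s` and `percent`
#'   (>= 10 points; the first value is expected to be 100).
#' @return An object of class `decay_fit`: list with `plateau`, `K`,
#'   `se_plateau`, `se_K`, `cov_PK`, `rss`, `n_points`, `converged`, and the
#'   data used. Non-convergence is flagged (`converged = FALSE`) with the
#'   fitter's message in `diagnostic`, never silently dropped.
#' @examples
#' t <- seq(0, 276, by = 4)
#' fit <- fit_one_phase_decay(data.frame(time_s = t,
#'                                       percent = 20 + 80 * exp(-0.05 * t)))
#' c(fit$plateau, fit$K)
#' @export
fit_one_phase_decay <- function(decay) {
  stopifnot(is.data.frame(decay), all(c("time_s", "percent") %in% names(decay)))
  if (nrow(decay) < 10L) stop("need at least 10 points to fit a decay")
  if (any(!is.finite(decay$percent))) stop("non-finite intensity values")

  # crude but serviceable starting values
  p0 <- min(decay$percent)
  tail_drop <- 100 - p0
  k0 <- if (tail_drop > 1e-6) {
    half_idx <- which(decay$percent <= p0 + tail_drop / 2)[1L]
    if (is.na(half_idx) || decay$time_s[half_idx] <= 0) 1e-3
    else log(2) / decay$time_s[half_idx]
  } else 1e-3

  try_fit <- function(P0, K0) tryCatch(
    minpack.lm::nlsLM(percent ~ P + (100 - P) * exp(-K * time_s),
                      data = decay,
                      start = list(P = P0, K = K0),
                      lower = c(P = -Inf, K = 0),
                      upper = c(P = 100 - 1e-9, K = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  fit <- try_fit(min(p0, 99), max(k0, 1e-8))
  if (inherits(fit, "error"))       # near-flat traces leave K unidentified;
    fit <- try_fit(mean(decay$percent) - 1, 1e-4)  # retry from a gentle slope

  if (inherits(fit, "error") && stats::sd(decay$percent) < 1) {
    # no resolvable decay: the flat fit K = 0 (Y identically 100); the
    # plateau sits at the Y0 boundary so threshold times censor downstream
    out <- list(plateau = 100 - 1e-9, K = 0, se_plateau = NA_real_,
                se_K = NA_real_, cov_PK = NA_real_,
                rss = sum((decay$percent - 100)^2),
                n_points = nrow(decay), converged = TRUE,
                diagnostic = "degenerate flat fit (K = 0)", data = decay)
    class(out) <- "decay_fit"
    return(out)
  }

  if (inherits(fit, "error")) {
    out <- list(plateau = NA_real_, K = NA_real_, se_plateau = NA_real_,
                se_K = NA_real_, cov_PK = NA_real_, rss = NA_real_,
                n_points = nrow(decay), converged = FALSE,
                diagnostic = conditionMessage(fit), data = decay)
    class(out) <- "decay_fit"
    return(out)
  }

  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  out <- list(plateau = unname(cf["P"]), K = unname(cf["K"]),
              se_plateau = sqrt(vc[1, 1]), se_K = sqrt(vc[2, 2]),
              cov_PK = vc[1, 2],
              rss = sum(stats::resid(fit)^2),
              n_points = nrow(decay), converged = TRUE,
              diagnostic = NA_character_, data = decay)
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("One-phase decay fit (Y0 = 100)\n")
  cat(sprintf("  plateau = %.4g +/- %.3g\n", x$plateau, x$se_plateau))
  cat(sprintf("  K       = %.4g +/- %.3g per s\n", x$K, x$se_K))
  cat(sprintf("  RSS %.4g over %d points%s\n", x$rss, x$n_points,
              if (isTRUE(x$converged)) "" else "  [DID NOT CONVERGE]"))
  invisible(x)
}

#' Time for a fitted decay to reach a fluorescence threshold
#'
#' Inverts the fitted one-phase decay at `threshold` percent of the initial
#' value: \deqn{t = \frac{1}{K}\,\ln\frac{100 - P}{\mathrm{threshold} - P}.}
#' When the plateau is at or above the threshold the curve never reaches it
#' and the time is censored. The standard error follows by the delta method
#' from the fit's standard errors and plateau-rate covariance, with
#' \eqn{\partial t/\partial K = -t/K} and
#' \eqn{\partial t/\partial P = (1/K)(100 - \mathrm{threshold}) /
#' ((100 - P)(\mathrm{threshold} - P))}.
#'
#' @param fit A [fit_one_phase_decay()] result.
#' @param threshold Percent of initial fluorescence; the default 75 gives
#'   the time to lose 25 percent of the signal.
#' @return A list with `t` (seconds), `se_t` and `censored`. Censored
#'   results carry `t = NA`.
#' @examples
#' # pure exponential to 0: t75 = ln(4/3)/K
#' t <- seq(0, 276, by = 4)
#' fit <- fit_one_phase_decay(data.frame(time_s = t, percent = 100 * exp(-0.05 * t)))
#' time_to_fraction(fit)$t
#' @export
time_to_fraction <- function(fit, threshold = 75) {
  stopifnot(inherits(fit, "decay_fit"))
  if (!isTRUE(fit$converged)) {
    warning("decay fit did not converge (", fit$diagnostic,
            "); time to threshold reported as censored")
    return(list(t = NA_real_, se_t = NA_real_, censored = TRUE))
  }
  P <- fit$plateau; K <- fit$K
  if (P >= threshold || K <= 0)
    return(list(t = NA_real_, se_t = NA_real_, censored = TRUE))

  t <- (1 / K) * log((100 - P) / (threshold - P))
  dt_dK <- -t / K
  dt_dP <- (1 / K) * (100 - threshold) / ((100 - P) * (threshold - P))
  cov_PK <- if (is.finite(fit$cov_PK)) fit$cov_PK else 0
  var_t <- dt_dK^2 * fit$se_K^2 + dt_dP^2 * fit$se_plateau^2 +
    2 * dt_dK * dt_dP * cov_PK
  list(t = t, se_t = sqrt(max(var_t, 0)), censored = FALSE)
}

#' Barrier Index from mother and bud decay fits
#'
#' The Barrier Index (BI) is the ratio of the time for the non-bleached
#' (bud) compartment to fall to 75 percent of its initial fluorescence to
#' the same time for the bleached (mother) compartment. A tight bud-neck
#' diffusion barrier slows fluorescence loss in the bud, giving a high BI.
#' The standard error combines the two t75 errors in relative terms:
#' \deqn{(se_{BI}/BI)^2 = (se_{t_b}/t_b)^2 + (se_{t_m}/t_m)^2.}
#'
#' @param fit_mother,fit_bud [fit_one_phase_decay()] results for the pooled
#'   mother and bud profiles.
#' @param threshold Percent threshold passed to [time_to_fraction()].
#' @return An object of class `barrier_index`: list with `value`, `se`,
#'   `censored`, `t75_mother`, `t75_bud` (and their SEs). When the bud
#'   never reaches the threshold the BI is censored (`value = NA`),
#'   mirroring conditions where bud fluorescence fails to decay; a censored
#'   mother is an error since the bleached compartment must decay.
#' @export
barrier_index <- function(fit_mother, fit_bud, threshold = 75) {
  tm <- time_to_fraction(fit_mother, threshold)
  tb <- time_to_fraction(fit_bud, threshold)
  if (tm$censored)
    stop("mother compartment never reaches the threshold; ",
         "the bleached compartment must decay")
  if (tb$censored) {
    out <- list(value = NA_real_, se = NA_real_, censored = TRUE,
                t75_mother = tm$t, se_t75_mother = tm$se_t,
                t75_bud = NA_real_, se_t75_bud = NA_real_,
                threshold = threshold)
    class(out) <- "barrier_index"
    return(out)
  }
  bi <- tb$t / tm$t
  se <- bi * sqrt((tb$se_t / tb$t)^2 + (tm$se_t / tm$t)^2)
  out <- list(value = bi, se = se, censored = FALSE,
              t75_mother = tm$t, se_t75_mother = tm$se_t,
              t75_bud = tb$t, se_t75_bud = tb$se_t,
              threshold = threshold)
  class(out) <- "barrier_index"
  out
}

#' @export
print.barrier_index <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("Barrier Index: n.d. (bud never reached %g%%); t%g mother = %.3g s\n",
                x$threshold, x$threshold, x$t75_mother))
  } else {
    cat(sprintf("Barrier Index = %.3g +/- %.3g (t%g bud %.3g s / mother %.3g s)\n",
                x$value, x$se, x$threshold, x$t75_bud, x$t75_mother))
  }
  invisible(x)
}

#' Normalize a Barrier Index across acquisition setups
#'
#' When a condition is measured on a different microscope, its BI is put on
#' the baseline scale via a reference strain measured in both runs:
#' `value = target * (reference_baseline / reference_same_run)`. The
#' standard error propagates over the triple ratio in relative terms.
#'
#' @param bi_target BI of the condition of interest (new setup).
#' @param bi_reference_same_run BI of the reference strain measured in the
#'   same run as the target.
#' @param bi_reference_baseline BI of the reference strain on the baseline
#'   setup.
#' @return A `barrier_index` object on the baseline scale.
#' @export
cross_run_normalize <- function(bi_target, bi_reference_same_run,
                                bi_reference_baseline) {
  for (b in list(bi_target, bi_reference_same_run, bi_reference_baseline)) {
    stopifnot(inherits(b, "barrier_index"))
    if (isTRUE(b$censored)) stop("cannot normalize with a censored Barrier Index")
  }
  if (bi_reference_same_run$value == 0) stop("zero reference Barrier Index")
  value <- bi_target$value *
    (bi_reference_baseline$value / bi_reference_same_run$value)
  rel2 <- (bi_target$se / bi_target$value)^2 +
    (bi_reference_baseline$se / bi_reference_baseline$value)^2 +
    (bi_reference_same_run$se / bi_reference_same_run$value)^2
  out <- list(value = value, se = value * sqrt(rel2), censored = FALSE,
              t75_mother = NA_real_, se_t75_mother = NA_real_,
              t75_bud = NA_real_, se_t75_bud = NA_real_,
              threshold = bi_target$threshold)
  class(out) <- "barrier_index"
  out
}

#' Full FLIP pipeline: traces to Barrier Index
#'
#' Convenience wrapper running normalize -> pool -> fit -> BI on a long
#' trace table (one pooled fit per compartment, the default analysis; set
#' `per_cell = TRUE` to fit each cell separately and average the resulting
#' BIs instead).
#'
#' @param traces Data frame as produced by [gen_flip_traces()] /
#'   [read_pipeline_csv()]: columns `cell_id`, `role`, `time_s`,
#'   `intensity`.
#' @param background Scalar background (a.u.).
#' @param threshold Percent threshold for [time_to_fraction()].
#' @param per_cell Fit per cell instead of pooling first (non-default).
#' @return A `barrier_index` object; the mother and bud `decay_fit`s are
#'   attached as attribute `"fits"`.
#' @export
flip_barrier_index <- function(traces, background = 0, threshold = 75,
                               per_cell = FALSE) {
  stopifnot(all(c("cell_id", "role", "time_s", "intensity") %in% names(traces)))
  controls <- split(traces[traces$role == "control", ],
                    traces$cell_id[traces$role == "control"])
  cells <- unique(traces$cell_id[traces$role == "mother"])
  if (length(cells) == 0L) stop("no mother traces found")

  norm <- lapply(cells, function(id) {
    normalize_traces(traces[traces$role == "mother" & traces$cell_id == id, ],
                     traces[traces$role == "bud" & traces$cell_id == id, ],
                     controls, background)
  })

  if (per_cell) {
    bis <- lapply(norm, function(nd) {
      barrier_index(fit_one_phase_decay(nd$mother),
                    fit_one_phase_decay(nd$bud), threshold)
    })
    vals <- vapply(bis, function(b) if (b$censored) NA_real_ else b$value, 0)
    out <- list(value = mean(vals, na.rm = TRUE),
                se = stats::sd(vals, na.rm = TRUE) / sqrt(sum(is.finite(vals))),
                censored = all(!is.finite(vals)),
                t75_mother = NA_real_, se_t75_mother = NA_real_,
                t75_bud = NA_real_, se_t75_bud = NA_real_,
                threshold = threshold)
    class(out) <- "barrier_index"
    return(out)
  }

  fit_m <- fit_one_phase_decay(pool_profiles(lapply(norm, `[[`, "mother")))
  fit_b <- fit_one_phase_decay(pool_profiles(lapply(norm, `[[`, "bud")))
  bi <- barrier_index(fit_m, fit_b, threshold)
  attr(bi, "fits") <- list(mother = fit_m, bud = fit_b)
  bi
}
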