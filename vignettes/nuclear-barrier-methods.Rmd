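---
title: "Models and methods: barrier strength, circle segregation and ERC-driven aging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: barrier strength, circle segregation and ERC-driven aging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucbarrier)
```

# The biological problem

Budding yeast mothers age while their daughters are born young. A major
aging factor is the extrachromosomal rDNA circle (ERC): a non-centromeric
DNA circle excised from the rDNA repeats that, lacking a centromere, is not
actively segregated and accumulates in the mother nucleus over successive
divisions. Retention of ERCs (and of model DNA circles used to study them)
in the mother depends on a lateral diffusion barrier in the outer nuclear
membrane at the bud neck: circles anchor to nuclear pore complexes (NPCs),
and the barrier confines NPC-bound material to the mother compartment
during anaphase. This package implements the quantitative procedures used
to study that system: a segregation statistic, a photobleaching-based
barrier assay, stage-resolved passage kinetics, an NPC-colocalization
readout, and a stochastic model linking circle retention to replicative
lifespan — together with synthetic-data generators so that the whole
pipeline is testable without microscopy data.

# Propagation frequency

Anaphase cells carry 1, 2 or 4 labelled circles. With $n_i$ the number of
cells in class $i$ and $p_i$ the per-circle retention fraction within the
class (circles kept in the mother divided by all circles carried by
class-$i$ cells), the propagation frequency is

$$1 - \frac{n_1 p_1 + 2 n_2 p_2 + 4 n_4 p_4}{n_1 + 2 n_2 + 4 n_4}.$$

Because the weights are the circle counts, the statistic reduces to the
circle-weighted fraction of circles that ended in the bud, and under
independent per-circle passage with uniform probability $p$ it is a
consistent estimator of $p$ (`propagation_frequency()` is tested for this
on 10,000-cell synthetic cohorts). The per-class retention $p_i$ is
interpreted as a per-circle fraction rather than a per-cell indicator; the
per-cell reading is ambiguous when a cell retains a strict subset of its
circles, while the per-circle reading makes the formula's weights exact
and the statistic equal to $1 - p$ under uniform retention. Retention
percentages quoted elsewhere are simply $100(1-\text{frequency})$.

# Anaphase stages and passage flux

Early anaphase runs from the entry of the nucleus into the bud to the
formation of a dumbbell-shaped nucleus; late anaphase runs from the
dumbbell to karyokinesis. `stage_durations()` summarizes both (mean, SEM,
SD) after dropping cells with non-monotone event times.

`propagation_flux()` estimates passages per minute per stage as
*events in the stage / summed stage durations over all cells*
(cell-minutes). The alternative denominator — cells times mean stage
duration — is available via `denominator = "per_cell"`; the two coincide
up to weighting and the pooled cell-minutes form is the default because it
is the maximum-likelihood rate estimator for a constant hazard. Events are
scored at the frame where the circle first appears in the daughter; an
event recorded on the same frame as dumbbell formation is counted as early
anaphase, since the underlying passage preceded or coincided with the
boundary. On a 1-minute frame grid this convention keeps the flux
estimator unbiased to within one frame per event (tested by jittering
events ±1 frame).

# FLIP and the Barrier Index

In a FLIP (fluorescence loss in photobleaching) experiment, a spot in the
mother part of the dividing nucleus is bleached at every frame while the
total fluorescence of a GFP-tagged nucleoporin is recorded in mother and
bud and in 3–5 neighbouring unbleached cells. The analysis chain is:

1. **Normalization** (`normalize_traces()`): subtract a scalar background,
   divide mother and bud frame-wise by the mean of the controls (removing
   acquisition photobleaching), and scale each trace so its first value is
   100%. The background is treated as one scalar per movie; nothing in the
   assay identifies a per-frame background, and the synthetic generator
   applies a constant offset.
2. **Pooling** (`pool_profiles()`): frame-wise mean across cells. The
   pooled profile is fit once per compartment; per-cell fitting with
   averaged indices is available (`per_cell = TRUE` in
   `flip_barrier_index()`) but is not the default, because pooling first
   matches how the assay is quantified and stabilizes the bud fit, whose
   per-cell decays are shallow and noisy.
3. **Constrained fit** (`fit_one_phase_decay()`): least squares for
   $Y(t) = P + (100 - P)e^{-Kt}$ with $Y_0$ fixed at 100, $K \ge 0$ and
   $P < 100$, via bounded Levenberg–Marquardt (`minpack.lm::nlsLM`).
   Unweighted least squares is used; the original quantification does not
   state a weighting scheme and the normalized profiles have roughly
   homogeneous noise. Near-flat traces make $K$ unidentifiable (at $K = 0$
   the model is constant and the Jacobian is singular); after two failed
   starts on a trace with negligible spread the fitter returns an explicit
   degenerate flat fit ($K = 0$, plateau at the $Y_0$ boundary, diagnostic
   recorded), which censors downstream threshold times instead of erroring.
4. **Threshold time** (`time_to_fraction()`): the time to reach 75% of the
   initial signal — i.e. to lose a quarter of it —
   $t_{75} = \frac{1}{K}\ln\frac{100-P}{75-P}$, with the delta-method
   standard error using $\partial t/\partial K = -t/K$,
   $\partial t/\partial P = \frac{1}{K}\frac{100-75}{(100-P)(75-P)}$ and
   the plateau–rate covariance when the fitter provides it (it is omitted,
   and the omission visible as `cov_PK = NA`, only if the covariance matrix
   is unavailable). A plateau at or above the threshold means the curve
   never gets there: the time is censored, reported as "n.d.", never as an
   infinity.
5. **Barrier Index** (`barrier_index()`):
   $\mathrm{BI} = t_{75}(\text{bud}) / t_{75}(\text{mother})$, with
   relative errors added in quadrature. A censored bud gives a censored BI
   (the barrier is too tight to measure on the acquisition window); a
   censored mother is an error, since the bleached compartment must decay.
6. **Cross-setup normalization** (`cross_run_normalize()`): conditions
   measured on a different microscope are rescaled through a reference
   strain measured on both, as a triple ratio with full error propagation.

The closed-form $t_{75}$ is verified against numeric root-finding on the
fitted curve to $10^{-9}$ relative tolerance.

# The FLIP generator

`gen_flip_traces()` iterates a discrete per-frame recurrence rather than a
continuous ODE: bleach pulse, exchange, acquisition decay, in that fixed
order, because the bleach really is pulsed once per frame and a discrete
recurrence admits an exact step-by-step oracle. With bleach fraction $b$,
exchange rate $x$ and acquisition decay $a$,

$$M' = (1-a)\big[(1-b)M + x(B-M)\big], \qquad
  B' = (1-a)\big[B - x(B-M)\big],$$

controls decaying as $(1-a)^t$. Exchange rates above $0.5$ would overshoot
equilibration in a single step and are rejected. Noise is applied to the
reported intensities only, so the latent dynamics stay deterministic and
exactly reproducible for oracle tests; with $a = b = 0$ the latent total
$M + B$ is conserved for any $x$. Mother and bud are given equal volumes by
default — the assay does not constrain the ratio — with `volume_ratio`
exposed for asymmetric exchange. Defaults (4-s frames, 70 frames, $b =
0.05$, $a = 0.002$, noise 5 a.u. on 1000 a.u. initial signal, 4 controls)
emulate a 4–5-minute acquisition; the default exchange rate $x = 0.002$
was chosen so that the simulated wild-type cohort lands in the
empirically observed BI regime of a few tens. The estimated BI decreases
monotonically in $x$, and $x = 0$ yields a censored (unmeasurably tight)
barrier — both tested.

# NPC–circle colocalization

`align_profiles()` takes per-cell rim intensity profiles (arc-length bins
along the nuclear rim, GFP = NPC reporter, mCherry = circle), subtracts
the background, centres every GFP trace on the cell's brightest mCherry
position (ties go to the first occurrence in scan order, with a message)
and averages per offset. Offsets are reported only where **more than 10**
cells contribute — the mask is a strict inequality, applied verbatim, so a
10-cell cohort reports nothing. Profiles are circular by default (the rim
is closed); `mode = "linear"` truncates instead of wrapping for traces
with the spindle-pole-body region excised. `circle_fold_change()` rescales
so the mean background-subtracted GFP over the whole rim is 1 and reads
the normalized intensity at offset 0: the fold induction of the NPC
reporter at the circle. The fold change is invariant to global GFP
rescaling and to per-cell rotation of the profiles, exact on constructed
noiseless cohorts, and increases monotonically with the generator's
attachment probability. The rim generator gives NPC punctae variable
brightness (uniform 0.6–0.95 of the nominal amplitude, with an attached
circle on a full-amplitude punctum) so each cell has a unique brightest
punctum, as real NPC clusters do; cells with the circle at the SPB are
assumed excluded upstream, as in the assay.

# ERC accumulation and lifespan

`simulate_lineages()` follows one mother per lineage, starting with zero
circles. Per division: every resident circle replicates with probability
$f$ (default 0.6 — rDNA-circle origins fire in only about 60% of cycles),
a Poisson($e$) number of new circles is excised, and every copy stays in
the mother with probability $r$ or is exported to the daughter. The mother
dies when her load reaches the threshold $T$. The expected load obeys

$$E[L_{g+1}] = (1+f)\,r\,E[L_g] + r\,e,$$

i.e. newly excised circles do not fire in the cycle they arise; the
simulator is ordered to match (fire residents, add arrivals, then
partition). `expected_load()` iterates this recursion and serves as the
analytic oracle: simulated mean loads match it within Monte-Carlo error at
every generation *when the death threshold is out of reach* (the oracle
ignores death; with deaths active, survivor truncation biases the mean
load down, so oracle-equivalence tests use $T = 10^9$). Bookkeeping is
exactly conservative: copies created = copies kept + copies exported at
each division.

A hard death threshold was chosen over a load-dependent hazard for
testability. $T = 1000$ (old mothers carry ERC loads of order a thousand)
and $e = 0.1$ per division are defaults, exposed in `erc_config()` because
neither is experimentally pinned down. At the measured retention levels,
$r = 0.96$ versus $r = 0.83$, the defaults give median lifespans of about
24 versus 35 generations and a roughly six-fold difference in the
16-generation ERC load — the right regime and direction (relaxed retention
extends life and lowers the aged-cell ERC load several-fold), but the
exact fold depends on $e$ and $T$ and is not treated as a calibrated
prediction. Daughters are not simulated as mothers; the lineage is one
mother, matching microdissection-style lifespan counting.

`survival_summary()` reports the fraction of lineages alive per generation
and the median lifespan: the smallest generation at which survival drops
to one half, with midpoint interpolation when survival sits exactly at 0.5
(so lifespans $1..100$ give 50.5). The median agrees with the
Kaplan–Meier median from the survival package on simulated cohorts.
`southern_fold_change()` sums the four concatemer-band intensities per
densitometry lane and compares lane totals as a ratio.

# What the generators do and do not emulate

The generators reproduce the *statistical structure* the analyses assume:
two-compartment exchange under pulsed bleaching with observation noise;
independent per-circle segregation in 1/2/4-circle classes;
truncated-normal stage durations with stage-specific, at-most-once passage
hazards snapped to a 1-minute grid; closed rim profiles with punctae and
attached/detached circles. They do not emulate image-level effects — focus
drift, segmentation error, SPB proximity, bleaching spot misplacement,
cell-to-cell kinetic heterogeneity, or circle return from bud to mother.
Passing tests therefore demonstrate that the estimators are correct and
consistent under the assumed data-generating process, not that the assay
is robust to those imaging artefacts.

# Problem sizes and numerical choices

Statistical recovery tests use 5,000–10,000 cells or 20,000 lineages with
fixed seeds and 3-standard-error bands; BI monotonicity uses 30 cells per
exchange-rate point over a 5-point grid. These sizes put Monte-Carlo error
well below the tested effects while keeping the whole suite to a few
seconds. Tolerances: closed-form vs root-finding at $10^{-9}$ relative;
exact arithmetic at $10^{-12}$; fits on noiseless curves at $10^{-6}$.
Ties: mCherry maxima to the first occurrence (logged); censoring at
plateau $\ge$ threshold exactly; flux events on the stage boundary to
early anaphase.
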