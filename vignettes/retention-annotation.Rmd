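---
title: "Retention-time modelling and annotation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retention-time modelling and annotation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lssrt)
```

This vignette documents the models implemented in `lssrt`, the assumptions
behind them, the numerical choices made where the mathematics alone does
not dictate one, and what the synthetic-data validation does and does not
demonstrate about real chromatographic data.

## The LSS retention model

Reversed-phase retention of an analyte in a binary mobile phase is
described by the linear solvent strength (LSS) law

$$ k(\varphi) = k_w e^{-S\varphi}, $$

where $\varphi$ is the volume fraction of strong (organic) solvent, $k_w$
the retention factor extrapolated to pure weak solvent and $S$ the
solvent-strength slope. Both parameters are intrinsic to a (compound,
stationary phase, solvent pair, temperature) combination and independent
of the gradient program — which is the entire point: one pair per compound
lets retention be predicted under *any* single-ramp gradient.

An analyte at position $z$ in a column of dead time $t_0$ migrates at
$u_0/(1+k)$, where the local composition follows the programmed ramp
delayed by the dwell time $t_D$ and by the transit of the mobile phase to
$z$. Integrating the migration equation yields the closed form

$$ t_R = t_0\left[1 + \frac{t_D}{t_0} + \frac{1}{b}\ln\!\left(1 +
   b\left(k_0 - \frac{t_D}{t_0}\right)\right)\right],
   \qquad b = \frac{\Delta\varphi\, S\, t_0}{t_G}, $$

with $k_0 = e^{\ln k_w - S\varphi_0}$ the retention factor at the starting
composition.

**The $k_0$ convention.** Some informal statements of the model drop
$k_w$ from $k_0$. We define $k_0 = \exp(\ln k_w - S\varphi_0)$,
consistently with the LSS law itself; only with $k_w$ included does $k_0$
reach the large values (typically $10^3$ and above) that justify the
approximations used for calibration below.

**Natural-log convention.** $\ln k_w$ and $S$ are stored in natural-log
units. Much of the chromatographic literature tabulates $\log_{10} k_w$
and a base-10 slope; both convert by multiplying by $\ln 10$. This is
stated prominently in the documentation because silently mixing the two
conventions produces retention errors far larger than any tolerance used
here.

**Elution regimes.** The closed form is valid only for analytes that are
still on the column when the delayed gradient front arrives and that elute
before the ramp ends at their position. `retention_time()` therefore
branches:

1. *Pre-gradient elution* ($t_0 k_0 \le t_D$): the analyte runs
   isocratically at $\varphi_0$ and $t_R = t_0(1+k_0)$. The two branches
   join continuously at $k_0 = t_D/t_0$.
2. *Ramp elution*: the closed form above. The $b \to 0$ limit
   ($t_R \to t_0(1+k_0)$) is substituted analytically below
   $b < 10^{-12}$ rather than risking 0/0.
3. *Plateau elution*: if the closed form would place elution after the
   ramp has fully passed the column ($t_R > t_0 + t_D + t_G$), the
   experimental method's final hold at $\varphi_0+\Delta\varphi$ matters
   and the closed form (which implicitly extrapolates the ramp
   indefinitely) is wrong. Here the migration integral is evaluated
   numerically with the plateau modelled explicitly.

**The migration oracle.** `migrate_oracle()` integrates
$\mathrm{d}z/\mathrm{d}t = u_0/(1+k(\varphi(t,z)))$ with a fixed-step
fourth-order Runge–Kutta scheme and locates the outlet crossing by linear
interpolation inside the final step. The default step of $10^{-3}$ min
puts the integration error near $10^{-8}$ min — four orders of magnitude
below the $10^{-3}$ min agreement demanded of it in the tests — while
keeping a 100-draw verification sweep under a second. The composition
field has kinks at the ramp boundaries, which degrades the formal RK4
order locally; at this step size the effect is irrelevant. The oracle is
deliberately independent of the closed form (no shared branching), so
their agreement over random parameter draws is a genuine two-route check.

## Two-gradient parameter estimation

Running the same compound under two gradients of intrinsic steepness
$b_1, b_2$ gives two equations $t_i = t_R(b_i; \ln k_w, S)$ in two
unknowns. `fit_lss()` eliminates $\ln k_w$ in closed form — for a trial
$S$, the first equation inverts to
$k_0 = (e^{b_1(t_1/t_0 - 1 - t_D/t_0)} - 1)/b_1 + t_D/t_0$ — leaving a
one-dimensional residual in $S$ that is solved by bracketed root-finding
(initial bracket $S \in [1, 100]$, expanded geometrically to
$[10^{-3}, 10^4]$ if no sign change is found). This is monotone,
derivative-free and robust; a two-dimensional Newton iteration would be
faster but needs good starting values and offers nothing at this problem
size. The system is exactly determined: no least-squares averaging over
more than two gradients is attempted.

The steepness ratio $\max(b_1,b_2)/\min(b_1,b_2)$ should be at least 3
for a well-conditioned fit; `check_steepness_ratio()` flags pairs below
that. With shallow ratios the two equations become nearly collinear and
measurement noise is amplified into the parameters.

## Affine autocalibration

The instrument parameters entering the model ($t_0$, $t_D$, and $b$
through $t_G$) are never known exactly: injection and mixing are not
zero-dimensional, capillaries and valves add volume. Perturbing them,

$$ t_0 \to t_0 + \delta t_0,\quad t_D \to t_D + \delta t_D,\quad
   b \to b + \delta b, $$

and expanding $t_R$ to first order shows that every compound's prediction
moves by the *same* affine map $t_R \to \alpha t_R + \beta$, up to terms
of order $1/k_0$ (negligible for strongly retained compounds, $k_0 \sim
10^3$) and $\mathcal{O}(\delta^2)$. That one global (α, β) captures the
whole error is what makes calibration with a handful of compounds
possible.

`fit_affine()` estimates $(\alpha,\beta)$ by ordinary least squares of the
*predictions on the observations* ($t^{pred} = \alpha\, t^{obs} + \beta$),
and `apply_calibration()` returns $(t^{pred}-\beta)/\alpha$. Regressing
prediction on observation (rather than the more common other direction)
follows the definition of the transformation being undone; at the
$R^2 \approx 1$ this model operates at, the numerical difference between
the two directions is far below the annotation tolerances. The fit is
unweighted — no error model for individual calibrants is assumed.

Only compounds with *experimental* LSS parameters are eligible as
calibrants by default (`allow_qsrr_calibrants` overrides): calibrating
with in-silico predictions propagates their error into every calibrated
retention time, visibly biasing the low-retention end.

Validation measures two things on a seeded 70-compound synthetic library
under 3 % instrument perturbations: (i) perturbed predictions regressed on
unperturbed ones give $R^2 > 0.999$, confirming the affine covariance;
(ii) after a five-calibrant fit (calibrants at the 10/30/50/70/90th
retention percentiles), the remaining 65 compounds all fall below 1 %
relative error, the large majority below 0.4 %. A perturbation worth
noting: scaling $t_0$, $t_D$ *and* $t_G$ by one common factor is an exact
time rescaling of the model ($b$ and $k_0$ are invariant), which the
affine map removes identically — a degenerate test. The validation
therefore perturbs the steepness through $t_G \mapsto t_G/(1+\delta)$, so
the residual measured after calibration is the genuine second-order
remainder.

## Annotation

Each feature $(m/z, t_R^{exp})$ is compared against every (compound,
adduct) pair. A match requires both

$$ \frac{|q \cdot m/z + m_{add} - m_k|}{m_k} < tol_m
   \quad\text{and}\quad
   \frac{|t_R^{exp} - t_{R,k}^{pred}|}{t_{R,k}^{pred}} < tol_{t_R}, $$

with strict inequalities as a deliberate contract (boundary hits are
excluded; with continuous data the boundary has measure zero, but the
contract matters for reproducibility of edge cases). The retention-time
error is normalised by the *predicted* time. The adduct registry stores
`mass_shift` such that neutral mass $= q \cdot m/z + $ `mass_shift`
(−1.007276 Da for [M+H]+, +17.003288 Da for [M−H2O+H]+, ...), computed
from the CODATA proton mass, monoisotopic water, and sodium minus one
electron for [M+Na]+.

Two retention tolerances coexist: a tight one (default 0.5 %) for
compounds with experimentally measured parameters — annotation level 2+ —
and a loose one (default 5 %) for QSRR-parameterised compounds — level 2 —
whose predictions are substantially less accurate. The mass tolerance
default of 5 ppm is a conventional high-resolution-MS setting, exposed as
configuration rather than asserted as optimal. Matches within a feature
are returned sorted by the combined normalised error
$\sqrt{(\Delta m/m)^2 + (\Delta t/t)^2}$ with compound-id tie-breaking —
an arbitrary but deterministic convention; all matches are reported, and
multiple adducts of one compound on one feature are not deduplicated.

**Quality metrics.** The success rate is the fraction of distinct true
identities (among features carrying ground truth and present in the
library) recovered by at least one feature's match list. Counting
distinct identities rather than raw features keeps the ratio within
$[0,1]$ when one standard produces several adduct features. The
misattribution rate is the fraction of returned matches (over
ground-truthed features) whose proposed identity is wrong. Sweeping the
retention tolerance (`tolerance_sweep`) traces both rates; the match
count and the success rate are provably non-decreasing in the tolerance
(the match predicate is monotone in it), the misattribution rate is not.

**Multiplicity.** The number of annotations per *annotated* feature is
summarised by its mean and by 50/75/90th percentiles interpolated from a
gamma distribution fitted by maximum likelihood
(method-of-moments initialisation; `MASS::fitdistr`). The gamma family is
used because it covers most non-negative unimodal count-like shapes with
two parameters while remaining analytically tractable; when all counts are
equal the empirical value is returned directly, since the ML fit
degenerates.

## Synthetic data: what it emulates, and what it does not

`synthetic_scenario()` emulates the study design used throughout the
validation: a steroid-like library (masses uniform in 250–500 Da,
$\ln k_w \sim U(5,11)$, $S \sim U(15,40)$ — giving initial retention
$k_0 > 60$ and typically $\sim 10^3$ at $\varphi_0 = 0.02$) separated on a
2 % → 100 % organic ramp over 14 min with $t_0 = 0.8$ min and $t_D = 0.75$
min (a 0.375 mL dwell volume at 0.5 mL/min). By default 20 % of compounds
sit in isomer clusters of 2–3 sharing an exact mass with distinct LSS
parameters, because isomer disambiguation is the model's reason to exist.
Features are generated per (compound, adduct) with Gaussian retention
noise; decoys are placed beyond the largest library ion m/z by
construction (not rejection sampling), so their non-matching is
deterministic.

What passing these simulations does *not* show: the generator draws LSS
parameters independently, whereas real homologous series show strong
$\ln k_w$–$S$ correlation; retention noise is homoscedastic Gaussian,
ignoring peak asymmetry and drift; feature lists contain no in-source
fragments, isotopologues or co-eluting background, so real annotation
multiplicity and misattribution at a given tolerance will be worse than
the simulated figures. The simulations validate the *mathematics*
(model, calibration algebra, matching logic), not instrument behaviour.

## Problem sizes and determinism

The validation suite uses libraries of 25–70 compounds, feature sets up to
350 (including all five adducts and 100 decoys), 100-draw oracle
equivalence sweeps, 50-compound noisy refits, and $10^4$ draws for the
gamma-recovery check — sizes at which every check completes in seconds on
one core while keeping estimator noise well inside the asserted margins.
All stochastic steps run under explicit seeds (R's default
Mersenne-Twister); generators save and restore the caller's RNG state.

## Known limitations

* Single linear ramp plus plateau only; multi-segment and curved gradients
  are out of scope.
* No temperature or stationary-phase dependence of $(\ln k_w, S)$; a
  library is valid only for the conditions it was measured under.
* The quadratic (non-linear LSS) retention model is not implemented;
  strongly curved $\ln k(\varphi)$ compounds will show systematic error.
* QSRR prediction of parameters is consumed as data (`provenance =
  "qsrr"`), never computed.
* Per-compound calibration and non-affine (spline) retention alignment are
  deliberately excluded: the model's claim is precisely that one global
  affine map suffices for small instrument errors.
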