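---
title: "A resource-aware kinetic model of cell-free gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A resource-aware kinetic model of cell-free gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txtlsim)
```

## The model

An all-*E. coli* cell-free transcription–translation (TXTL) reaction
expressing a fluorescent reporter (deGFP) from a sigma-70 promoter shows
three kinetic phases: a transient of 30–60 min, a steady state of several
hours in which the reporter accumulates linearly, and a late plateau when
nutrients run out. `txtlsim` models the first two phases with three ODEs —
mRNA $m$, immature reporter $G_d$, mature reporter $G_m$, all in nM —

$$\dot m = k_{cat,m}\,[P_{70}]\,
  \frac{E_0 S_{70}}{K_{M,70}(K_{70}+E_0) + E_0 S_{70}}
  \;-\; k_{d,m}\frac{m}{K_{M,m}+m},$$
$$\dot G_d = k_{cat,p}\, m\,\frac{R_0}{K_{M,R}+R_0} - k_{mat} G_d,
  \qquad \dot G_m = k_{mat} G_d,$$

coupled to two algebraic conservation laws. Total core RNA polymerase
splits into free enzyme $E_0$, sigma-70 holoenzyme $E_{70}$ (fast binding
equilibrium with dissociation constant $K_{70}$), and enzymes engaged on
the template (on the promoter, plus a fraction $k_{cat,m} L_m / C_m$
elongating); total ribosomes split into a free pool $R_0$ and ribosomes on
mRNA (on the ribosome binding site, plus $k_{cat,p} L_m / C_p$
elongating). The polymerase law is solved for $E_0$ by bracketed root
finding on $[0, E_{tot}]$ — its residual is strictly increasing in $E_0$,
so the root is unique — once per run, because the template concentration
is constant. The ribosome law is a quadratic in $R_0$,

$$R_0^2 + R_0\,(K_{M,R} + m\beta - R_{tot}) - K_{M,R}R_{tot} = 0,
  \qquad \beta = 1 + k_{cat,p}\frac{L_m}{C_p},$$

whose positive root is evaluated in closed form (with the
cancellation-safe branch for large $m$) at every right-hand-side call.

The central claim the model captures is that saturation of protein
synthesis with increasing plasmid is caused by depletion of free
ribosomes onto the mRNA, not by exhaustion of the transcription
machinery: at the best-fit constants the steady-state ribosome demand
$m_{ss}\,\beta$ crosses $R_{tot}$ near 5 nM plasmid while the free
polymerase pool is still far from exhausted at 30 nM
(`saturation_onset()`, `resource_depletion_profile()`).

### Assumptions

* Michaelis–Menten terms are quasi-steady-state; nutrients and initiation
  factors are unlimited during the steady state; no component of the TX or
  TL machinery degrades.
* mRNA degradation is effectively first order with rate
  $k_{deg,m} = k_{d,m}/K_{M,m}$; the Michaelis–Menten form is retained
  only so integrated mRNA can never turn negative. `txtl_params()` warns
  when a simulation pushes $m$ within 10× of $K_{M,m}$: above ~10 nM
  plasmid the simulated mRNA pool (thousands of nM) genuinely strains this
  assumption, which is worth knowing when interpreting saturated-regime
  kinetics.
* Reporter maturation is first order; no protein degradation (the model
  deliberately excludes ClpXP, whose zeroth-order kinetics admit no
  protein steady state).
* The plateau phase is out of scope: simulated signals grow without bound
  and must not be read as 16-h endpoint yields.

## Parameters

Units are nM and seconds everywhere inside the package; hours appear only
at reporting boundaries (the part-strength table multiplies by 3600).
Defaults in `txtl_params()` are the best-fit constants for the reference
construct (strong promoter P70a, strong UTR1, 750-nt gene):
$k_{cat,m} = 6.5\times10^{-2}$/s, $K_{M,70} = 1$ nM, $K_{70} = 0.26$ nM,
$S_{70} = 30$ nM, $E_{tot} = 400$ nM, $k_{d,m} = 6.6$ nM/s,
$K_{M,m} = 8000$ nM, $k_{cat,p} = 6\times10^{-3}$/s, $K_{M,R} = 10$ nM,
$R_{tot} = 1100$ nM, $C_m = 10$ nt/s, $C_p = 2.5$ nt/s. Both catalytic
constants are capped at 0.5/s (about 30 initiations per minute); the
constructor warns past the cap.

Three defaults deserve a note:

* **`k_mat` = 1.2e-3/s is a placeholder**, a value in the physiological
  range (~14 min characteristic maturation time), not a published
  constant. No quantity the package reports depends on it: the
  steady-state synthesis rate of $G_d + G_m$ is exactly independent of
  $k_{mat}$ (maturation only shifts protein between the dark and mature
  pools; a test asserts the invariance). Fit it from a maturation assay
  with `fit_maturation()` when absolute mature-fluorescence kinetics
  matter.
* **`S70_total` = 30 nM** from the plausible 30–35 nM range. Within and
  above that range the model is insensitive to sigma-70 (holoenzyme
  occupancy is near saturation); *reducing* sigma tenfold, however, drops
  the transcription term by ~20–25%, so the insensitivity claim should
  not be extrapolated downward.
* **`C_p` = 2.5 nt/s** is kept exactly as printed alongside "1 amino
  acid/s", although 1 aa/s is 3 nt/s. We do not silently correct it: only
  the product $k_{cat,p} L_m / C_p$ enters the model, so any consistent
  convention works, but mixing conventions would change $\beta$ by 20%.
  This remains an open question of the source data.

`Lm` has two conventional values: 750 nt for simulating the reference
construct, 800 nt as the reference gene length of the load calculator;
functions take whichever their context requires.

## Numerical choices

Integration uses `deSolve::lsoda` (stiff-capable) with relative tolerance
1e-8 and absolute tolerance 1e-9 nM, writing output every 180 s to mirror
plate-reader sampling. Conservation residuals stay below 1e-6 nM at every
output point (tested). $E_0$ is solved by `uniroot` to 1e-9 nM; the
closed-form $R_0$ agrees with a bisection oracle to better than 1e-9 nM
over a 1000-point mRNA grid (tested).

"Maximum rate of synthesis" is operationalised as the largest
least-squares slope of the mature-reporter signal over a 30-min sliding
window, after a 30-min burn-in that skips the transient — the steady-state
regime spans roughly 1–6 h, so any window inside it sees a straight line.

Two routes produce a rate-versus-plasmid curve. The default
(`method = "ode"`) simulates each concentration and extracts the window
slope — the faithful emulation of the measurement. The analytic route
(`method = "steady_state"`) evaluates the regime-II rate directly
($E_0$ from its conservation law, $m_{ss}$ from the synthesis/degradation
balance, $R_0$ at $m_{ss}$, rate $= k_{cat,p} m_{ss} R_0/(K_{M,R}+R_0)$);
a test holds the two routes together within 2%. The analytic route backs
the optimizer loop of `fit_kcats_to_rate_curve()`, the sensitivity scans
and the power-law derivation, where re-integrating the ODEs thousands of
times would buy nothing but runtime. When transcription outruns the
degradation capacity $k_{d,m}$ (reachable at the $k_{cat,m}$ bound during
fitting) no finite mRNA steady state exists; the analytic route then
returns the ribosome-limited ceiling $k_{cat,p}R_{tot}/\beta$ with a
warning.

A point of the rate curve is labelled *linear* while its rate per plasmid
stays within 10% of the analytic low-concentration limit, else
*saturated*. The 10% figure is a package convention — the transition is
described only qualitatively ("sharp") in the literature — and the same
10% departure-from-linearity criterion defines the "limiting DNA
concentration" the load calculator locates.

## Fitting

`fit_exponential_decay()` runs ordinary least squares on the log signal
when all points are positive (exact under multiplicative noise), falling
back to `minpack.lm::nlsLM` otherwise; `fit_maturation()` fits the
saturating rise $F_\infty(1 - e^{-k_{mat}t})$ by `nlsLM`. Both are
invariant to amplitude rescaling, and the decay fit to time-rescaled data
returns the rescaled rate (tested).

`fit_kcats_to_rate_curve()` adjusts only $(k_{cat,m}, k_{cat,p})$, in
log space with bounds $(0, 0.5]$/s, by `optim(L-BFGS-B)` from three
starts spread a decade around an initial guess (seeded jitter); the
Michaelis constants stay fixed because the model is only weakly sensitive
to them and many $(k_{cat}, K_M)$ pairs fit equally well. When the
measured curve never leaves proportionality the two constants are not
separately identifiable — only their product is — and the fit says so in
an explicit note rather than reporting spuriously precise values.

Part strengths are through-origin regression slopes over the
linear-regime points, reported per construct in nM/h per nM plasmid and
normalised to the reference pair. Because a weaker promoter leaves
slightly more free polymerase to the rest of the system, measured
relative strengths track the generating $k_{cat}$ ratios to ~10%, not
exactly.

## Sensitivity scans

`sensitivity_scan()` multiplies one constant at a time by
{1/10, 1/3.33, 1, 3.33, 10} — the literal 3.33, not 10/3 — and re-evaluates
the rate curve; `kdeg_m` is scanned through $k_{d,m}$ with $K_{M,m}$
fixed. The summary metric is the maximum over the plasmid grid of the
relative rate change against the factor-1 curve (the source figures show
only curves, so the scalar summary is a package convention). Reproduced
behaviour: rates respond most strongly to $R_{tot}$ (and monotonically),
degradation speeds linearise the response, the Michaelis constants move
the summary several-fold less than $R_{tot}$, and sigma-70 is quiet in
the upward direction. Under the analytic rate route a $k_{mat}$ scan is
exactly flat (see above); use `method = "ode"` to expose the
finite-window maturation transient.

## The load calculator

`derive_power_law()` rebuilds the limiting-DNA equation from the model:
promoter strength $P$ sweeps scale $k_{cat,m}$, UTR strength $U$ sweeps
scale $k_{cat,p}$ (the same convention the fitting section uses), gene
length is swept directly; each swept value is mapped to the plasmid
concentration at which the steady-state rate falls 10% below its linear
extrapolation, and log–log lines are fitted. The prefactor is normalised
so the reference construct ($P = U = 1$, $L_m = 800$ nt) maps exactly to
the base model's own limiting concentration (~5.3 nM), making the
round-trip property exact by construction at the reference point.

The re-derived promoter exponent is −1.00, matching the published −0.987:
demand scales linearly with transcription output. The re-derived UTR and
length exponents (about −0.50 and −0.77) are steeper than the published
−0.352 and −0.583; both variables enter the ribosome demand through the
affine factor $\beta = 1 + k_{cat,p}L_m/C_p$ (and $L_m$ additionally
through the polymerase side), so their local log–log slope depends on the
swept range, and the published values come from a phenomenological fit
over unspecified ranges. We keep the published coefficients as the
default `txtl_power_law()` — they are the community reference — and treat
our sweeps as the model-consistency check. `budget_constructs()` adds
load fractions (planned over limiting concentration) across constructs
and warns at 100%: the calculator approximates when resources become
limiting, it does not model inter-construct regulation.

## Synthetic data and what passing tests show

`generate_kinetics()`, `generate_decay_trace()`,
`generate_maturation_trace()` and `generate_nine_combo_dataset()` emulate
the measurement process: sampling every 3 min for 16 h, calibrated-nM
fluorescence, and Gaussian multiplicative-plus-additive noise truncated
at zero (defaults 3% and 5 nM; seeds are mandatory arguments — there is
no implicit global randomness). The multiplicative component represents
well-to-well variability — pipetting, calibration, lysate batch — which
is what repeat standard deviations in this kind of experiment measure, so
it is drawn **once per well**: a kinetic trace shares one gain; each
point of a rate curve, being its own well, draws independently. Per-point
multiplicative noise would instead model an instrument whose reading
jitters by a few percent between consecutive 3-min reads, which real
plate-reader traces do not do — and on a plateau-free simulated signal it
would inflate sliding-window slope maxima severalfold, an artifact of
evaluating an unbounded signal, not a property of the estimator.

The generators reproduce the study conditions: nine promoter×UTR
combinations whose strengths (1, 0.3, 0.05 on each axis) span two orders
of magnitude, rate curves over 0.5–30 nM plasmid, strongest pair
saturating near its limiting concentration, weakest pair linear
throughout. What passing tests show: the pipeline recovers known ground
truth under the stated noise family (kcat-product median error ~4% at 5%
noise over 20 seeds). What they do not show: robustness to plateau-phase
curvature, instrument drift, well crosstalk, or mRNA levels approaching
$K_{M,m}$ — none of which the generator emulates.

## Problem sizes

Default analyses are sized so the whole test suite and the acceptance
script each run in about a minute on a single core: 4-h simulations at
180-s output for rate extraction (the 30-min-window maximum stabilises
well before 4 h), 7-point plasmid grids, 6-point sweep grids per
power-law variable, 20 seeds for recovery studies. All are arguments, not
constants.

## Known limitations

* No plateau phase, protein degradation, stochasticity, or spatial
  effects; predictions apply to batch-mode, well-mixed, microliter-scale
  reactions during the first hours.
* Above ~10 nM plasmid the first-order mRNA-degradation assumption
  weakens (see above); saturated-regime rates remain sensible, absolute
  mRNA levels less so.
* Sigmoidal rate responses (reported for one natural ribosomal-RNA
  promoter) are outside the model family.
* `fit_kcats_to_rate_curve()` reports no confidence intervals; the
  identifiability note is qualitative. Profile likelihood would be the
  natural extension.
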