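---
title: "Modelling passive polymer translocation through vesicle membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling passive polymer translocation through vesicle membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luvtrans)
```

## The system and the observables

Water-soluble amphiphilic polymers — alternating hydrophobic diacid and
hydrophilic oligo(ethylene glycol) units, or PEG-PPG-PEG triblocks as the
blocky limiting case — can cross phospholipid membranes passively.  The
experiment this package models mixes such polymers with large unilamellar
POPC vesicles (LUVs, radius 44 nm, bilayer thickness 4 nm) and follows the
amount of LUV-associated polymer over time by fixed-gradient pulsed-field
gradient (PFG) NMR: at a gradient chosen so that the fast free-polymer
diffusion is suppressed, the residual echo amplitude tracks only polymer in
or inside the vesicles.  A second, static observable is specular neutron
reflectometry of a supported bilayer, which localizes the polymer within
the membrane through its scattering-length-density (SLD) contrast.

## The three-compartment kinetic model

The sample is partitioned into outer solution, membrane, and inner vesicle
volume with volume fractions $\phi_{out}, \phi_{mem}, \phi_{in}$ derived
from the vesicle geometry and the lipid loading
(`vesicle_geometry()`; the membrane volume is identified with the lipid
volume, $\phi_{mem} = c_{lipid}/\rho_{lipid}$, with $\rho_{lipid}$ =
1.0 g/mL by default).  Writing $c_o, c_m, c_i$ for the polymer
concentrations per compartment volume, the exchange model is

$$\frac{dc_m}{dt} = k_a\,(c_o + c_i)\,S - k_d\,c_m, \qquad
S = 1 - c_m/c_{sat},$$
$$\frac{dc_i}{dt} = \frac{\phi_{mem}}{\phi_{in}}
  \left[\tfrac{k_d}{2} c_m - k_a c_i S\right], \qquad
\frac{dc_o}{dt} = \frac{\phi_{mem}}{\phi_{out}}
  \left[\tfrac{k_d}{2} c_m - k_a c_o S\right].$$

The structural assumptions, each a deliberate design choice:

* **Symmetric faces.** The same adsorption constant $k_a$ acts on both
  membrane faces, and the total desorption rate $k_d$ is split equally
  between them.  The exact flux bookkeeping (surface- versus
  volume-normalized adsorption, asymmetric desorption) is not pinned down
  by the qualitative description of the experiment, so the minimal
  symmetric form was chosen; it reproduces every qualitative feature the
  data show (two-step uptake, slope–rate correspondences, saturation
  crossover, full equilibration) with the fewest parameters, and it is
  isolated behind `rate_equations()` so an alternative form is a one-function
  swap.
* **Single saturation factor.** Adsorption from either side is blocked by
  the same factor $S$; $c_{sat}$ (the membrane saturation concentration,
  a mass fraction directly comparable to wt% membrane concentrations) is
  the third fitted parameter.
* **Units.** $k_a$ and $k_d$ are in 1/s, with fluxes expressed per
  membrane volume; concentrations are mass fractions (wt% / 100)
  throughout, times are seconds internally (minutes accepted on input).
* **Initial condition.** All polymer outside at $t=0$, matching polymer
  added to a vesicle suspension at the start of a measurement.

The phi-weighted total concentration is conserved identically (the three
fluxes cancel exactly), and detailed balance forces $c_i(\infty) =
c_o(\infty)$: passive transport cannot maintain a gradient.
`equilibrium_state()` evaluates this endpoint in closed form (a quadratic
in $c_m$), and `simulate_kinetics()` integrates the system with
`deSolve::lsoda` driving a compiled right-hand side (relative tolerance
1e-9, absolute 1e-12; the $k_a \gg k_d$ regimes are stiff).  Solver-scale
negative undershoots of $c_m, c_i$ are clipped to zero.

### A caution on equilibration horizons

The relaxation of $c_i/c_o \to 1$ is *not* governed by $k_d$ alone.  Near
equilibrium the net outer-to-inner flux is throttled by the saturation
factor $S^\ast = 1 - c_m^\ast/c_{sat}$, giving a slow eigenvalue of order
$k_a S^\ast \phi_{mem}(1/\phi_{in} + 1/\phi_{out})$.  Under deeply
saturated conditions (equilibrium membrane load close to $c_{sat}$, which
1 wt% polymer readily produces) this can be an order of magnitude smaller
than $k_d$: the homogeneous-polymer preset is still $\sim 10^{-4}$ away
from ratio 1 at $t = 50/k_d$ and reaches machine accuracy only around
$200/k_d$.  Tests of the asymptotic state therefore integrate to
$1000/k_d$; a fixed $50/k_d$ horizon is *not* a safe equilibration proxy
for this model, and the validation suite documents exactly that.

## Derived kinetic quantities

* `integrated_fraction()` — the observable: LUV-integrated amount
  normalized at the last time point,
  $f(t) = [\phi_{mem} c_m + \phi_{in} c_i]_t / [\cdot]_{t_{max}}$.
* `limiting_slopes()` — least-squares slopes of $\ln(1 - f)$ over the
  first 15% and last 25% of the finite-log points (window fractions are
  arguments; the defaults mimic how guide lines are drawn on the two
  regimes of a log plot).  The initial slope magnitude grows with $k_a$,
  the terminal one with $k_d$.
* `translocation_time()` — first time $c_i \ge (1 - 1/e)\,c_o$, located
  by bracketing on the grid and linear interpolation.  If the threshold
  is not reached the last grid time is returned flagged as a censored
  open lower bound, so "too slow for the measurement window" cases remain
  representable.
* `partition_coefficient()` — equilibrium $c_m/c_o$ ($= 2k_a/k_d$ in the
  $c_{sat}\to\infty$ linear limit).
* `molecules_per_vesicle()` — absolute per-vesicle counts, converting
  mass fractions (aqueous density 1 g/mL) through the compartment volumes
  and the molecular weight.

## The PFG-NMR layer

`echo_attenuation()` implements $I/I_0 = \exp(-q^2\Delta D)$ with
$q = \gamma\delta g$; the Stejskal–Tanner effective time
$(\Delta - \delta/3)$ is available behind a flag.  With the sequence used
here ($\delta = 2$ ms, $\Delta = 100$ ms) the correction is sub-percent,
which is why the simpler form is the default; both $\Delta$ values that
appear in practice (20 and 100 ms) are plain configuration, neither is
hard-coded.  `fit_diffusion()` performs the weighted log-linear regression
of $\ln I$ on $q^2\Delta$, refining the weights from the fitted curve
(two reweighting passes) because weighting by noisy measured intensities
correlates weights with noise and biases the slope.  `select_gradient()`
inverts the attenuation for the smallest gradient reaching a requested
free-polymer suppression (default residual 0.02, a configuration knob),
and `trace_from_trajectory()` forms the two-species signal
$A_{luv}\,\mathrm{att}(D_{luv}) + A_{free}\,\mathrm{att}(D_{free})$,
normalized at $t_{max}$ — with full suppression it reduces exactly to
`integrated_fraction()`.

## Bayesian inference

The likelihood is Gaussian and independent per point on the normalized
trace, with either the trace's per-point uncertainties or a user noise
scale — additive amplitude noise is the natural model for scan-averaged
echo amplitudes, and the scan count is typically chosen to hold the noise
roughly constant along a trace.  Parameters are sampled as
$(\log k_a, \log k_d, \log c_{sat})$ under a wide log-uniform prior
(defaults: $k_a \in [10^{-4}, 10^2]$, $k_d \in [10^{-7}, 10^{-1}]$,
$c_{sat} \in [10^{-5}, 1]$): these are scale parameters spanning decades.

`fit_mcmc()` is a Goodman–Weare affine-invariant stretch-move ensemble
sampler written for this package (stretch scale $a = 2$).  Walkers start
in a small ball (sd 0.02 in log space) around the best point of a seeded
log-uniform scatter over the prior, optionally polished by a short
Nelder–Mead ascent; a run is bit-reproducible given its seed, and the
global RNG state is restored afterwards.  `posterior_summary()` reports
medians, 16/84 and 2.5/97.5 percentiles, the MAP sample, the acceptance
fraction and a split-chain R-hat per parameter (values near 1.05 or below
indicate adequate mixing at these chain lengths).

Identifiability is a property of the data, not the sampler: when the
membrane capacity $\phi_{mem} c_{sat}$ contributes less to the normalized
signal than the noise level, the posterior for $(k_a, c_{sat})$ collapses
onto the prior — the Bayesian answer is honest width, not a point
estimate.  The validation suite probes this deliberately by truncating a
trace before the saturation crossover and checking that the $k_d$
credible interval inflates at least five-fold, mirroring the experimental
situation in which slow, weakly-loaded systems leave $k_a$ undetermined.

Cross-sample aggregation uses inverse-variance weighting
(`weighted_average()`), and `mw_extrapolate()` predicts a parameter at a
target molecular weight either as exactly that weighted average
(MW-independent mode, appropriate for $k_d$) or by a weighted linear fit
of $\ln(\text{value})$ versus MW (exponential mode, appropriate for
$k_a$ and $c_{sat}$), with uncertainties propagated through the weighted
normal equations.  `predict_filling()` pushes extrapolated parameters
(with uncertainties) through the ODE by seeded log-normal parameter-space
Monte Carlo — 200 draws by default, chosen over linearization because the
parameter-to-curve map is strongly nonlinear; non-physical draws are
skipped and counted.

## The reflectometry layer

A supported bilayer is a `slab_stack()`: Si | SiO2 | thin water | inner
heads | inner tails | outer tails | outer heads | optional polymer brush |
bulk solvent, with the first and last layers semi-infinite.  Each layer's
effective SLD mixes base material, solvent and polymer by volume fraction
(`mixed_sld()`), so one structural model serves both H2O and D2O
contrasts with only the solvent SLD changing — `joint_residual()` sums the
per-contrast chi-squares for co-refinement.  `reflectivity()` is a Parratt
recursion with Névot–Croce roughness factors; Gaussian $q$-resolution
smearing with constant relative FWHM (10%, matching a typical wavelength
spread) is available but off by default so that unit tests compare sharp
curves.  `render_profile()` draws the error-function-smoothed SLD profile,
warning (not failing) when a roughness exceeds an adjacent thickness.
`polymer_mass_fraction()` converts fitted volume fractions into the mass
concentration of polymer relative to polymer plus lipid,
thickness-weighted over a chosen set of layers; solvent is excluded from
the mass basis by default (that is the natural basis for "polymer
concentration in the membrane region"), with a flag to include it.
Shipped SLDs and densities (`nr_materials_table()`) are literature-typical
editable defaults, not measured constants.

## Synthetic data: what it does and does not emulate

Every observable has a seeded generator so the full pipeline runs without
any experimental input: `gen_kinetic_trace()` (model curve on a log-spaced
grid spanning $0.05/k_a$ to $5/k_d$, plus i.i.d. Gaussian noise),
`gen_echo_decay()` (multi-exponential attenuation plus additive noise) and
`gen_reflectivity()` (forward curves times $1 + $ Gaussian relative
noise).  Three presets mark the mechanistic regimes — homogeneous-polarity
polymer ($k_a = 0.05$/s, $k_d = 5\times10^{-4}$/s, $c_{sat} = 0.02$),
strongly amphiphilic ($0.1$, $5\times10^{-5}$, $0.08$) and triblock
($0.5$, $2\times10^{-5}$, $0.1$) — at 1 wt% polymer, 20 mg/mL lipid and
2% trace noise.  The preset numbers are illustrative regime markers
chosen once, not fitted constants.

The generators deliberately do **not** emulate relaxation ($T_1/T_2$)
weighting, convection artefacts, spectral processing, baseline drift,
correlated noise, instrument backgrounds or footprint effects.  Passing
recovery tests therefore demonstrate correctness of the estimation
machinery under the model's own statistical assumptions — they bound, but
do not measure, performance on real instrument data.

## Validation problem sizes

The shipped validation studies use 20 scenarios drawn log-uniformly over
$k_a \in [10^{-2}, 1]$/s, $k_d \in [10^{-5}, 10^{-3}]$/s,
$c_{sat} \in [0.001, 0.1]$ (100 points, 2% noise), fitted with 24 walkers
for 500 steps and 40% burn-in; interval coverage uses 30 seeded
repetitions of the homogeneous preset.  These sizes are the package's
choice of a study that a desk machine completes comfortably; the
estimator itself has no small-size assumptions.  Across that box the
aggregate median recovery error is a few percent, while the
low-$c_{sat}$ corner is structurally unidentifiable at 1 wt% (see above)
— its wide posteriors are reported as such rather than hidden.

## Known limitations

Lipid flip-flop kinetics, pore formation, endocytosis-like uptake,
charged-polymer electrostatics and the temperature dependence of the
membrane concentration are outside the model (temperature-dependent
inputs are accepted as user-supplied values).  The reflectometry layer
computes specular reflectivity only — no off-specular scattering,
magnetic SLDs or instrument footprint corrections — and does not emulate
any particular fitting program's parameterization.
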