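# luvtrans

Kinetics of passive polymer translocation through lipid-vesicle membranes.

Hydrophilic macromolecules normally cannot cross the hydrophobic interior
of a phospholipid bilayer, but suitably balanced amphiphilic polymers —
alternating hydrophobic diacid / hydrophilic oligo(ethylene glycol)
copolymers, and PEG-PPG-PEG triblocks as the blocky limiting case — do
translocate passively into large unilamellar vesicles (LUVs) on timescales
of minutes to hours.  `luvtrans` is for researchers who measure that
process by time-resolved pulsed-field-gradient (PFG) NMR and by neutron
reflectometry, and who want a tested, reproducible route from raw kinetic
traces and reflectivity curves to rate constants, membrane concentrations
and derived transport metrics.

## What it computes

**Kinetic model.**  A three-compartment (outer solution / membrane / inner
vesicle volume) exchange model with a saturating membrane:

    dc_m/dt = k_a (c_o + c_i) (1 - c_m/c_sat) - k_d c_m
    dc_i/dt = (phi_mem/phi_in)  [ (k_d/2) c_m - k_a c_i (1 - c_m/c_sat) ]
    dc_o/dt = (phi_mem/phi_out) [ (k_d/2) c_m - k_a c_o (1 - c_m/c_sat) ]

with adsorption rate `k_a`, total desorption rate `k_d` (split equally
between the two membrane faces) and membrane saturation concentration
`c_sat`.  Mass is conserved exactly and detailed balance drives
`c_i -> c_o` (passive transport cannot maintain a gradient).  Derived
quantities: the normalized LUV-integrated uptake curve `f(t)`, its
two-step log-curve limiting slopes, the effective translocation time
(first `c_i >= (1 - 1/e) c_o`), the membrane/water partition coefficient
and absolute molecule counts per vesicle.

**Inference.**  A Gaussian likelihood on the normalized trace and an
affine-invariant (Goodman-Weare stretch move) ensemble MCMC over
`(log k_a, log k_d, log c_sat)` under a wide log-uniform prior, with
credible intervals, MAP, split-chain R-hat diagnostics and seeded
reproducibility; inverse-variance averaging across samples and
molecular-weight extrapolation (exponential in MW for `k_a`/`c_sat`,
MW-independent for `k_d`) feeding predicted vesicle-filling curves with
Monte-Carlo uncertainty bands.

**PFG-NMR layer.**  Echo attenuation `exp(-q^2 Delta D)` with
`q = gamma delta g` (Stejskal-Tanner variant behind a flag), weighted
log-linear diffusion fitting, gradient selection for free-polymer
suppression, and the two-species fixed-gradient kinetic trace.

**Neutron reflectometry.**  A slab model of the supported bilayer
(Si | SiO2 | water | heads | tails | tails | heads | optional brush |
solvent) with per-layer solvent/polymer penetration, Parratt-recursion
specular reflectivity with Nevot-Croce roughness, optional Gaussian
q-resolution smearing, SLD-profile rendering, joint multi-contrast
chi-square, and polymer mass-concentration extraction per membrane region.

**Synthetic data.**  Seeded generators for all three observables plus
three mechanistic presets, so the entire pipeline is testable offline.

## Worked example

```r
library(luvtrans)

geom <- vesicle_geometry(R = 44, d = 4, c_lipid = 20)  # 20 mg/mL POPC LUVs
geom
#> <vesicle_geometry> R = 44 nm, d = 4 nm
#>   phi_out = 0.919577, phi_mem = 0.02, phi_in = 0.060423
#>   v_in = 268083 nm^3, v_mem = 88735.3 nm^3, n_ves = 2.25389e-07 /nm^3

params <- kinetic_params(k_a = 0.05, k_d = 5e-4, c_sat = 0.02)
times  <- 10^seq(-1, 4.3, length.out = 100)
traj   <- simulate_kinetics(params, geom, c_total = 0.01, times = times)

limiting_slopes(traj)           # two-step structure of ln(1 - f(t))
#> initial slope -0.0117 /s, terminal slope -0.000177 /s
translocation_time(traj)        # first c_i >= (1 - 1/e) c_o
#> effective translocation time: 8387 s (139.8 min)
partition_coefficient(params, geom, 0.01)
#> 2.020
molecules_per_vesicle(traj, mw = 2)[100, ]
#> 529 molecules in the membrane, 702 in the inner volume at t_max
```

The fast initial slope reflects adsorption (`k_a`), the ~66x slower
terminal slope reflects desorption into the vesicle interior (`k_d`), and
this 2 kg/mol polymer at 1 wt% equilibrates inner and outer solution in
about 2.3 hours.  Fitting a noisy synthetic trace recovers the generating
parameters:

```r
scn   <- scenario_preset("homogeneous", seed = 42)   # k_a 0.05, k_d 5e-4, c_sat 0.02
trace <- gen_kinetic_trace(scn, n_points = 100)      # 2% Gaussian noise
post  <- fit_mcmc(trace, prior_spec(), scn$geometry, scn$c_total,
                  n_walkers = 24, n_steps = 500, seed = 7)
posterior_summary(post, burn_in = 0.4)
#>  parameter    median       q16       q84      q025      q975
#>        k_a 0.0480916 0.0459256 0.0502018 0.0435940 0.0523003
#>        k_d 0.0004838 0.0004532 0.0005147 0.0004242 0.0005521
#>      c_sat 0.0202411 0.0195804 0.0208162 0.0188900 0.0213815
```

All three medians sit within a few percent of the generating values and
the 95% intervals cover them.

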