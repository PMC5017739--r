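---
title: "Model, estimation and planning methods in psmaplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, estimation and planning methods in psmaplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In Lu-177 PSMA radioligand therapy the injected preparation is a mixture of a
small labeled and a much larger unlabeled ("cold") peptide fraction. PSMA is
expressed not only by prostate-cancer lesions but also by the kidneys and the
salivary glands, which are therefore the dose-limiting organs. Because the
cold peptide competes for the same binding sites, the *amount* of peptide
shapes the distribution of absorbed dose between tumor and normal tissue: a
larger amount saturates the kidney receptor pool (high perfusion, moderate
density) earlier than most tumor lesions, so the tumor-to-kidney dose ratio
can improve with amount. `psmaplan` implements this reasoning quantitatively:
a whole-body PBPK model is fitted to planar time–activity measurements, the
fitted kinetics are extrapolated over a grid of peptide amounts, and for each
amount the injected activity is chosen to exhaust a kidney-BED, salivary-dose
and red-marrow-BED budget. The combination maximizing tumor BED is reported.

# The compartmental model

Every organ (kidneys, salivary/parotid glands, two tumor lesions, liver,
spleen, GI tract, prostate, muscle, fat, lungs, bone, red marrow, heart,
brain, skin, rest) has a vascular and an interstitial-free sub-compartment.
The vascular space exchanges with a central serum pool via the organ serum
flow `F_i = perfusion x mass`; transcapillary exchange is diffusion dominated
for a ~1.4 kDa peptide and modeled as a symmetric permeability–surface-area
(PS) term between the vascular and accessible-interstitial concentrations.
PSMA-positive organs additionally carry a receptor-bound and an internalized
pool:

* binding: `k_on * C_free * R_free - k_off * B`, with a shared free-receptor
  pool `R_free = R_tot - B_labeled - B_unlabeled` (receptor recycling treated
  as instantaneous, so `R_tot` is constant),
* internalization: first order with `lambda_int = 0.001/min` everywhere,
* degradation and release: first order with organ-specific `lambda_release`;
  released label enters a non-binding serum catabolite pool cleared renally.

Free serum peptide is filtered at a clearance proportional to the measured
MAG3 tubular extraction rate (factor 0.3 by default: TER tracks effective
renal plasma flow and bounds the glomerular filtration of the peptide from
above); 2% of the filtered peptide is retained as residual unspecific kidney
uptake (amino-acid co-infusion is assumed to block the rest) and is released
with the fitted kidney release rate. Labeled and unlabeled ligand obey
identical equations and are coupled by receptor competition and by physical
decay (labeled becomes unlabeled; the vial content also decays during the
10-min zero-order infusion).

Two candidate dissociation rates are carried as alternative models, Model 1
with `k_off = 0.046/min` and Model 2 with `k_off = 0.46/min`
(`k_on = 0.046 l/nmol/min` fixed), reflecting the order-of-magnitude spread
of reported affinities for PSMA ligands; the data decide by Akaike weight.

## An exact tracer factorization

Because both species share every rate constant and the infusion delivers them
in a fixed proportion (with the vial decaying at the physical rate), the
labeled amounts factorize exactly:

```
N_labeled,i(t) = labeled_fraction * exp(-lambda_phys * t) * N_total,i(t)
```

so the fraction of injected activity `a_i(t)` depends on the *amount* but not
on the *activity*. The default simulation mode therefore integrates only the
total-ligand system (53 states) and applies the decay factor; the explicit
two-species system (106 states) is also implemented and a property test
verifies the factorization to ~1e-9. This identity is also what makes
planning cheap: one kinetic simulation per amount serves all candidate
activities.

## Numerical integration

No stiff ODE solver package is available in the target environment, so the
package ships its own linearly implicit Rosenbrock(2,3) integrator
(Shampine–Reichelt ode23s scheme) with an analytic Jacobian. The iteration
matrix is block-arrow — small per-organ blocks coupled through serum,
catabolite and urine — and is factored by per-block LU plus a Schur
complement on the 3 (or 6) border states, reducing the per-step cost from
O(n^3) to O(n). Defaults: relative tolerance 1e-8, absolute tolerance 1e-12
nmol, log-spaced output grid (400 points) with a densified early segment,
horizon `T = 3e4 min`. Fitting uses a relaxed 1e-4/1e-8 tolerance pair, which
reproduces the measured observables to ~1e-5 relative — far below the
measurement noise. Mild negative undershoots (below 1e-6 nmol) are clamped to
zero; larger ones abort with an integration error.

Time integrals (time-integrated activity coefficients, absorbed doses) use a
ratio-guarded piecewise-quadratic rule on the output grid that falls back to
the trapezoid across abrupt spacing changes. The Lea–Catcheside double
integral solves the inner repair convolution exactly for piecewise-linear
dose rates (with a series expansion for `mu*h -> 0`) and applies Simpson's
rule outside; an independent nested-quadrature oracle confirms 1e-4 accuracy.

# Fixed physiological constants

Reference organ masses, perfusions, vascular/interstitial fractions and PS
densities live in `inst/extdata/default_config.yaml` (echoed into every
report). Flows and masses scale linearly with body weight; measured volumes
(kidneys, parotids, lesions) override the scaled reference; body weight is
derived from BSA by inverting Du Bois at a configured 1.75 m height when not
given. PS densities are chosen by endothelium type: high for the fenestrated
or leaky beds (kidneys 1.0, salivary glands 0.5, tumor 1.5 ml/min/g — tumor
uptake is then perfusion-limited, which is what makes the fixed tumor
perfusion `f_TU` a consequential assumption and the salivary perfusion
`f_SAL` an estimable parameter), low for continuous capillaries (muscle and
fat 0.01), and near zero for brain. The non-fitted PSMA-positive tissues
(liver, spleen, GI tract, prostate) use fixed multiples (0.08/0.12/0.08/0.5)
of the reference kidney density; the sources the original analysis cites for
these relative values do not print them, so these are package assumptions,
configurable in one place.

Tumor perfusion defaults to 0.5 ml/g/min and is deliberately *not* fitted (it
is nearly collinear with the binding-site density); `perfusion_sensitivity()`
refits under 0.01/0.1/0.5/1 ml/g/min and combines the supported rates
(Akaike weight >= 1%) into a weighted average.

# Fitting

The 10 default free parameters per patient are the binding-site densities and
release rates of kidneys, salivary glands and two tumor lesions, the salivary
perfusion, and one shared muscle-background fraction `c`. The background
accounts for planar-ROI contamination: every organ ROI prediction is
`a_region(t) + c * a_muscle(t)` (total body uses `c = 0`). A single shared
`c` keeps the parameter count at 10; per-ROI fractions would be more faithful
to ROI geometry but are under-determined by 4–5 points per region.

The error model is relative: `Var(y_rt) = phi_r * y_rt^2` with one variance
scale `phi_r` per region, profiled analytically. Weighting by the *measured*
values rather than the predictions keeps the weighted problem an ordinary
least squares for fixed `phi` and avoids the well-known bias of
prediction-based relative weights with very few points per region. The
concentrated objective is `sum_r n_r log(SSR_r / n_r)`; the iteration
alternates the `phi` update with a Levenberg–Marquardt minimization on
log-transformed parameters (positivity by construction, box bounds by
projection). The LM core refreshes its finite-difference Jacobian every few
accepted steps and applies rank-1 secant (Broyden) updates in between.
Multistart: 5 seeded log-normal perturbations around the cohort-median start
are ranked by initial objective and the best is polished (ties after
polishing break toward the smaller parameter norm). Standard errors and
correlations come from the Gauss–Newton curvature at the optimum with the
residual degrees-of-freedom scale `SSR_w/(n-k)`; CVs are mapped to the
natural scale by the log-normal delta method.

Model comparison uses `AIC = sum_r n_r log(SSR_r/n_r) + 2k` with
`k = 10 + (one estimated variance per region) = 15`, Akaike weights
`exp(-delta/2)` normalized, and an optional AICc correction. This follows the
sums-of-squares form of the AIC appropriate for least-squares fits with
estimated variances.

# Dosimetry

Kidneys, salivary glands and tumors receive self-dose only:
`Ddot_i(t) = A_inj a_i(t) S_i<-i`. Tumors and salivary glands are treated as
unit-density spheres and their S-values taken from a mass-indexed table by
log–log interpolation; the kidney self S-value scales inversely with the
measured kidney mass (Lu-177 dose is dominated by locally absorbed
electrons). The shipped sphere table is a clearly labeled *synthetic* fixture
computed from the Lu-177 mean local energy deposition (0.1479 MeV/decay) with
a surface-loss absorbed-fraction model — adequate for the package's
self-consistent arithmetic, and replaceable by a published table through the
same CSV interface. Red marrow receives self-dose plus a remainder-of-body
cross-dose (`remainder = total body - kidneys - salivary - tumors - marrow`);
its self S-value scales inversely with body weight, the remainder value with
the same inverse-mass convention.

`BED = D (1 + G D / (alpha/beta))` with the Lea–Catcheside factor computed
from each dose-rate curve and a mono-exponential repair kernel. Repair
half-times are not printed in the source analysis; the defaults are standard
molecular-radiotherapy values (kidney 2.8 h; tumor, salivary glands and
marrow 1.5 h), configurable, and BED outputs should be read as conditional on
them. With the cohort-median kinetics the kidney anchor (absorbed dose ~7.9
Gy at BED 10 Gy_2.5) is reproduced; the salivary BED at 7.5 Gy comes out
near 8.25 Gy_4.5, slightly above the 8.1 +- 0.1 the original analysis quotes
— the early vascular peak in the simulated salivary curve raises G above the
mono-exponential value, and the unpublished repair constants bound what can
be matched here.

# Planning

For each amount on the `2^1 ... 2^13` nmol grid one simulation gives the
kinetics; the kidney-limited activity comes from the closed-form positive
root of the quadratic `BED_K(A) = 10 Gy` (using the time-integrated activity
coefficient and the repair-weighted double integral), the salivary-limited
activity from `A = 7.5 / (tiac * S)`. Rows whose red-marrow BED exceeds
0.25 Gy_15 are excluded. Single-case optimization maximizes tumor BED along
one iso-constraint curve; combined mode takes per amount the minimum of the
two activities, restricts to the 32–512 nmol comparison subgrid and maximizes
tumor BED, with ties broken toward the smaller amount (less cold ligand).
`compare_actual_vs_optimal()` evaluates the actually administered amount at
its binding constraint and reports optimal/actual dose and BED ratios, which
are >= 1 by construction whenever the actual amount lies on the subgrid.
Radiochemical specific-activity limits are not imposed on the single-case
curves (the subgrid restriction plays that role in combined mode).

# The synthetic-data generator

`sample_virtual_patient()` draws true parameters inside the cohort envelopes
(densities and tumor volumes log-uniformly because they span decades,
everything else uniformly), two lesions per patient, and the measured
descriptors (volumes, TER, BSA, amount, activity) from their observed ranges.
`simulate_measurements()` evaluates the true ROI curves (including the known
background contamination) on the 0.5 h/2 h/1 d/2 d/3 d schedule — 25 values
over five regions — and applies mean-preserving multiplicative log-normal
noise with 10% fractional SD (5% for total body), inside the 3–27% range the
planar quantification exhibits. The generator emulates the *statistical*
structure the estimator assumes; it does not emulate image-level effects
(attenuation, scatter, ROI-overlap bias) or model misspecification, so green
recovery tests establish estimator correctness under the stated model, not
robustness to a wrong model. True parameters are written to a separate
sidecar file so fitting code cannot read them by accident.

# Degenerate inputs and edge behavior

Zero receptor densities leave the binding pools structurally present but
unreachable. A zero total dose makes G undefined; `lea_catcheside()` returns
`NA` with a reason attribute instead of dividing by zero. Sphere masses
outside the table range raise a range error rather than extrapolating. An
empty feasible planning set returns an explicit infeasibility result, not an
exception. Parameters that end on a box bound are flagged in the fit result.

# Known limitations

* Absolute S-values are synthetic stand-ins; planning *activities* (GBq)
  inherit their scale, while constraint-anchored absorbed doses and BEDs are
  largely insensitive to them (the S-value cancels in the inversion).
* Repair half-times and the non-fitted relative receptor densities are
  package assumptions (see above).
* Single-cycle kinetics; multi-cycle planning assumes equal biodistributions
  and simply divides the cumulative budgets.
* The linear-quadratic BED becomes questionable for the very large tumor
  doses that high-density lesions can reach on the iso-constraint curves.
* Planar-geometry effects beyond the shared background fraction are not
  modeled.
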