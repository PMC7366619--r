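---
title: "Methods: segmented moduli and Blatz constitutive fitting for phantom materials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmented moduli and Blatz constitutive fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomech)
```

# Scope and model

`phantomech` reduces uniaxial-compression (UC) records of candidate
phantom materials — soft silicone mixtures — to quantities that can be
compared against kidney-cortex elasticity targets: the low-strain
compressive modulus E1, the high-strain modulus E2, and the two Blatz
constitutive parameters (α, γ). All strains are nominal compressive
fractions ε ∈ [0, 1); the stretch ratio is λ = 1 − ε; stresses are
nominal, in kPa, stored as positive magnitudes.

## Segmented moduli (E1, E2)

Soft-silicone compression curves show several nearly linear regimes
separated by transitions: a compliant toe, a curved heel, and
progressively stiffer post-heel behavior. We model the pooled
stress–strain data of one mixture (all technical replicates concatenated,
sorted by strain, duplicates retained — this is regression data, not a
function) with a continuous piecewise-linear function with three change
points ψ₁ < ψ₂ < ψ₃:

stress = β₀ + β₁ε + Σₖ δₖ (ε − ψₖ)₊.

E1 is the slope of segment 1 (0 % strain to ψ₁); E2 the slope of segment
3 (ψ₂ to ψ₃). The fourth segment is fitted and reported but unused.

Estimation is by iterative linearization: at the current ψ the model is
augmented with gap indicators I(ε > ψₖ); regressing on hinge and gap
terms gives slope-change coefficients δ̂ₖ and gap coefficients γ̂ₖ, and
each change point moves by −γ̂ₖ/δ̂ₖ (the first-order correction from a
Taylor expansion of the hinge about the current ψ). Steps are damped:
the proposal is halved (up to 2⁻⁶) until the continuous-fit SSE does not
increase, because the SSE is only piecewise smooth in ψ — its minima
often sit at data-point kinks where an undamped update oscillates.
Standard errors come from the final linearized model,
SE(ψₖ) = SE(γ̂ₖ)/|δ̂ₖ|.

The SSE surface is nonconvex. Three devices address this, all
deterministic given a seed:

* **multi-start** over the user's ψ⁰ (default 0.30/0.40/0.60 on the
  strain axis) and every increasing triple of strain deciles;
* **bootstrap restarting**: residuals are resampled at fixed strains
  around the current solution, the bootstrap sample is refitted, and the
  real data refitted from there (`n_boot` rounds, default 10); the
  current state wanders while the best real-data objective is retained;
* **minimum spacing**: configurations leaving any segment with fewer
  than two interior observations are rejected — without this, noisy fits
  collapse ψ₂ ≈ ψ₃ onto adjacent points and the segment-3 slope is
  meaningless.

`estimate_moduli()` repeats the fit with `n_runs` (default 10)
consecutive seeds and averages segment slopes across converged runs; on
noiseless data all runs are identical. Ties among restarts resolve to
the first (lowest-seed, earliest-start) solution at equal SSE.

### Why ψ⁰ lives on the strain axis

The initial change points are specified as strain fractions
(0.30, 0.40, 0.60) although one could read the original description of
the procedure as placing them on the stress axis. Change points of a
stress-on-strain regression are values of the regressor, so the strain
reading is the only one the model supports; the choice is exposed as the
`psi0` argument.

## Blatz constitutive model

The Cauchy stress of the two-parameter Blatz model at stretch λ is

σ₀(λ) = γ/(α+1) · ( λ·e^{α(λ²−1)} − λ⁻²·e^{α(1/λ−1)} ),

with σ₀(1) = 0 exactly and small-strain tangent dσ₀/dλ|₁ = 3γ for every
α ≠ −1; σ₀ is linear in γ. Observed stress magnitudes are negated before
fitting so the compression branch (λ < 1 ⇒ σ₀ < 0) is honored; reports
show magnitudes. By default the model stress is fitted directly against
the measured nominal stress (the study's own figures plot the model over
nominal data); `true_stress = TRUE` applies the incompressible
conversion σ_true = λ·σ_nominal first, since which convention the
original fits used is not recorded.

Because γ enters linearly, it is profiled out in closed form
(γ̂(α) = Σfσ/Σf², with f the α-dependent shape factor), reducing the fit
to a 1-D search over α. The profiled objective can have a well a
fraction of a unit wide, so initialization uses a dense deterministic
scan (step 0.05 over |α| ≤ 50, excluding a 10⁻⁶ margin around the
singular α = −1), followed by Brent refinement bracketed by the
neighboring scan points. Estimates pinned near a bound are flagged
non-converged. Replicate fits aggregate into means, sample SDs (n − 1)
and type-7 quantiles (5/25/50/75/95 %); only converged fits enter the
summary.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `psi0` | (0.30, 0.40, 0.60) | strain fraction | the regimes of the published curves cluster there |
| `n_runs` | 10 | — | seed-averaged estimate, as in the original procedure |
| `n_boot` | 10 | — | bootstrap-restart rounds per run |
| `tol` | 1e-8 | strain | ψ-step convergence; gives noiseless exactness |
| SSE stabilization | 1e-12 (relative) | — | stops ψ drifting over flat landscape regions |
| `e1_coverage_strain` | 0.35 | strain | replicates must reach 35 % compression or a coverage warning is raised |
| `e1_fit_limit_strain` | 0.33 | strain | cap of the standalone toe-slope linear check; not applied to the segmented fit domain, whose initial ψ exceed it |
| α bounds | ±50 | — | generous envelope around observed silicone values (−14 to 2) |
| γ bound | 10⁴ | kPa | numeric safety |
| screening targets | (20, 500) | kPa | kidney-cortex compressive moduli, low/high strain |
| E1 acceptance range | 13.6–25.8 | kPa | published cortex Young's-modulus interval |

The screening metric is the Euclidean norm of relative errors,
√(((E1−20)/20)² + ((E2−500)/500)²): scale-free across the 25-fold gap
between targets and invariant to unit rescaling applied to moduli and
targets alike. The published per-mixture moduli rank the 5 % soft
silicone first under this metric, matching the study's stated closest
mixture. The metric is pluggable (`metric` argument) since "closest" was
never formalized.

# The synthetic world

The generator emulates what matters to the estimators, not the testing
machine:

* **Blatz curves** — forward model evaluation on a uniform strain grid
  over [0, 0.70] (200 points), magnitudes taken, then multiplicative
  Gaussian noise (SD 2 % by default; load-cell error grows with force)
  plus additive noise (SD 0.05 kPa floor), clipped at zero.
* **Bilinear curves** — toe slope E1, a C¹ cubic-Hermite heel whose
  slope ramps linearly from E1 to E2 over [heel_start, heel_end], slope
  E2 beyond; `heel_start == heel_end` degenerates to a kink, a literal
  bilinear curve.
* **Replicate sets** — `n_replicates` curves with independent noise
  streams (seeds `seed + i`) and 2 % relative jitter on the truth
  parameters, emulating specimen-to-specimen variability; fixture
  directories are written in the package's own text dialect with a
  `truth.txt` sidecar.

Everything is deterministic given the spec seed (R's Mersenne-Twister
under a locally scoped seed; the caller's RNG state is untouched).

What a green recovery test establishes — and what it does not. The
recovery batteries use worlds where the 3-change-point model is
*well-specified*: exactly piecewise-linear curves with four distinct
slopes (toe = E1, third slope = E2), or the degenerate-kink bilinear
world for noiseless pipeline exactness. They establish that the
estimator finds the global optimum (verified against an exhaustive
observed-strain grid search) and recovers truth with median relative
error well under 5 % at 2 % noise. They do *not* establish unbiasedness
on smooth curves: when the heel is a wide C¹ transition, the SSE-optimal
fit pulls change points into the heel and the segment-3 slope
underestimates the post-heel slope substantially (a dedicated test pins
this mismatch). Similarly, with continuously stiffening Blatz-type
curves the unweighted SSE is dominated by the high-stress region, so the
fitted "toe" segment can extend far up the curve and E1 then reflects
averaged stiffening rather than the initial tangent 3γ. These are
properties of the estimator itself, inherited by any faithful
implementation; real-data E1/E2 values should be read as descriptive
regression slopes, not tangent moduli.

A related identifiability caveat: on data with fewer than four
distinguishable regimes (e.g. a noisy literal-bilinear curve), the
surplus change points are noise-driven and the segment-3 slope is
unstable. The minimum-spacing rule prevents the worst collapse but
cannot create identifiability; inspect `psi_se` and the per-run spread.

# Numerical choices and degenerate inputs

* Slope changes below 10⁻⁸ × (stress range / strain range) are treated
  as absent; the affected change points freeze and the fit is flagged
  degenerate (straight-line data yields four equal slopes and a
  warning).
* Curves are canonicalized on construction: sorted by strain,
  exact-duplicate strains collapsed by stress averaging. Records whose
  strain decreases in file order (unloading segments) are rejected with
  advice to truncate at peak strain.
* Unit auto-detection treats a strain column with maximum > 1.5 as
  percent — compressive strain fractions of these materials never
  approach 1.5.
* Common truncation cuts every replicate at the smallest per-replicate
  peak strain, interpolating an end point at the cutoff where a
  sampling grid skips it, which makes the operation idempotent. A
  common maximum below 35 % raises a coverage warning but proceeds.
* All-zero stress data yield γ ≈ 0 with a flat-objective warning rather
  than an error.
* `run_pipeline` configs are JSON — plain structured text parsed by
  `jsonlite`, avoiding a hand-rolled config dialect; reruns with the
  same config and seed write byte-identical reports.

# Known limitations

* Viscoelasticity (time dependence, strain-rate sensitivity) is outside
  the model; records carry the strain rate as metadata only.
* The Blatz fit is plain least squares; no robustification. Published
  parameter tables for very high dilutions show α near −14 with SDs of
  similar magnitude — symptoms of non-identifiable fits that this
  package flags (bound warnings, SDs, quantiles) but does not attempt
  to repair.
* XLSX exports of testing machines are not parsed; convert the data
  sheet to two-column CSV/TXT (strain, stress) first.
* E1/E2 from the segmented fit are global least-squares slopes; see the
  bias discussion above before interpreting them as tangent moduli.
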