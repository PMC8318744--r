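---
title: "Kalman-filter unmixing of overlapping UV-Vis spectra and the validation calculus around it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kalman-filter unmixing of overlapping UV-Vis spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kalmanspec)
```

## The problem

Two co-formulated drugs whose UV absorption bands overlap strongly — the
canonical example being hydrochlorothiazide (HCT, absorbance maximum near
272 nm) and losartan potassium (LSP, maximum near 235 nm) in one tablet —
cannot be assayed at a single wavelength each. Under the Beer–Lambert law
the mixture's absorbance at every wavelength is a linear combination of the
component concentrations:

$$A(\lambda_i) = \sum_{j=1}^{n} h_j(\lambda_i)\, c_j + \varepsilon_i,$$

where $h_j(\lambda)$ is the absorptivity of component $j$ at unit
concentration (AU per µg/mL) and $\varepsilon_i$ is photometric noise. A
full-spectrum scan (here 220–300 nm at 1 nm, so 81 equations for 2
unknowns) over-determines the concentrations; the package estimates them
by a sequential Kalman filter and verifies the estimate against the
classical least-squares (CLS) batch solution.

## The filter

The state is the concentration vector $c$, constant across wavelengths
(static state: no process noise, identity transition). Each wavelength
contributes one scalar measurement with row $h(\lambda_i)$. The update is
the standard one: innovation $e_i = A_i - h_i^\top \hat c$, gain
$g_i = P h_i / (h_i^\top P h_i + r)$, then $\hat c \leftarrow \hat c + g_i e_i$
and $P \leftarrow P - g_i (h_i^\top P)$. `run_filter()` sweeps the spectrum
in ascending wavelength order and repeats full sweeps, carrying $\hat c$
and $P$ forward, until the largest component-wise change over a sweep falls
below a tolerance. Repeated sweeps make the recursion a recursive
least-squares pass over stacked copies of the data, whose fixed point is
the CLS solution — which is why the converged filter is testable against
`cls_oracle()`, the independent normal-equations solution
$(H^\top H)\hat c = H^\top A$ with covariance $r (H^\top H)^{-1}$.

### Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `prior_mean` | 0 | µg/mL | no prior knowledge of the content |
| `prior_variance` | 10^6 | (µg/mL)^2 | diffuse prior; washes out so the converged estimate equals CLS, the only verifiable target |
| `r` | 10^-6 | AU^2 | order of magnitude of good photometer noise (SD ~0.001 AU); only the ratio `prior_variance/r` matters for the converged estimate |
| `passes` | 50 | — | safety cap; noiseless systems converge in 2–3 sweeps |
| `tolerance` | 10^-9 | µg/mL | far below any reportable digit |
| `joseph` | FALSE | — | symmetrized covariance update, available for ill-conditioned systems; 81 scalar updates on a 2–4 component state do not need it |

`r` may also be a per-wavelength vector (heteroscedastic noise); the scalar
homoscedastic default reflects that no instrument noise model is assumed.
Measurement order is irrelevant at convergence (`order = "descending"`
reproduces the ascending result to well below 10^-6 relative), and
negative estimates are reported with a warning rather than clipped —
clipping would bias recovery and repeatability statistics computed from
replicate estimates.

The calibration is deliberately single-point: `build_sensitivity_matrix()`
divides one standard spectrum per component by its known concentration
(e.g. HCT at 5, LSP at 20 µg/mL). No calibration curve is fitted anywhere;
linearity is an assumption of the model, not an output.

## The validation calculus

The surrounding statistics are the ones a pharmaceutical QC laboratory
reports, computed at full precision and rounded (half away from zero) only
when a report is rendered:

* **RE%** `relative_error()`: $(C - C_0) \cdot 100 / C_0$.
* **RSD%** `rsd_percent()`: sample (n−1) SD × 100 / mean. The n−1
  convention is what reproduces published F/t tables from printed
  replicates, so it is used everywhere.
* **Half-Horwitz bound** `horwitz_half_rsd()`: repeatability is acceptable
  below $\tfrac12\, 2^{1 - 0.5 \log_{10} C}$ percent, with $C$ the
  dimensionless mass fraction (5 µg/mL = 5×10^-6).
* **LOD/LOQ** `lod_loq()`: 3.3 and 10 times the SD of ≥7 replicate
  estimates of a solution near the expected detection limit; fewer
  replicates are allowed with a warning.
* **Recovery** `recovery()`: $(C_2 - C_1) \cdot 100 / C_s$, pairing
  replicate k of each spiked level with replicate k of the unspiked base —
  the pairing under which published recovery tables are internally
  consistent. Values outside 85–110% are flagged at the report layer.
* **Tablet content** `tablet_content()`: the preparation chain (m mg of
  powder to 250 mL, 10 mL diluted to 100 mL) collapses to
  $2.5 \cdot C_i \cdot M/m$ mg/tablet.
* **Two-method equivalence** `compare_methods()`: variance-ratio F test
  with the larger variance in the numerator against the **two-tailed**
  critical value `qf(1 - alpha/2, df1, df2)` — this is the convention under
  which the customary F(0.05; 2; 2) = 39.00 arises (the one-tailed value
  would be 19.00) — followed by the pooled-variance two-sided t test on
  $n_1 + n_2 - 2$ degrees of freedom. Welch's correction is deliberately
  out of scope: the pooled form is the one used in analytical-chemistry
  equivalence testing after the F test has accepted equal variances.

## The synthetic study system

Real drug spectra for this system are not redistributable, so the package
ships a generator instead of data. Each component is a sum of Gaussian
bands (`band_model()`); the presets in `study_presets()` emulate the
HCT/LSP pair:

* HCT-like: bands at 225 nm (σ = 6) and 272 nm (σ = 9), peak absorptivities
  0.030 and 0.070 AU/(µg/mL);
* LSP-like: dominant band at 235 nm (σ = 13, 0.0220) with a weak shoulder
  at 262 nm (0.004).

These constants were chosen once so that (a) the customary 5 and 20 µg/mL
standards peak in a realistic 0.2–0.8 AU window, (b) the maxima sit at
272/235 nm, and (c) the two unit spectra overlap genuinely (cosine
similarity ≈ 0.38 on the grid). They are fixture constants, not measured
absorptivities.

Mixtures add the component spectra (Beer–Lambert additivity) plus i.i.d.
Gaussian absorbance noise, default σ = 0.002 AU — a typical photometric
noise figure, documented as a tuning constant. Replicates are consecutive
substreams of one seeded generator, so a whole study fixture regenerates
byte-identically from its master seed (`generate_study_fixture()`). The
fixture mirrors a complete validation campaign: two standards, seven
two-component accuracy designs (HCT 1–6 against LSP 24–4 µg/mL, plus the
tablet-like 5 + 20) in triplicate, three tablet samples, and a
spike-recovery block at a 3 + 12 µg/mL base (three fifths of a tablet)
with spikes of 0.5/1.0/1.5 µg/mL HCT and 2/4/6 µg/mL LSP.

What the generator does *not* emulate — and what green tests therefore do
not demonstrate about real instruments — are baseline drift, stray light,
wavelength jitter, excipient absorption, and any deviation from
Beer–Lambert linearity. The simulator validates the estimator and the
statistics pipeline, not the instrument model.

### Problem sizes used in the checks

The automated checks run the seven-design study at 100 noisy replicates
per design (700 filter runs on the 81-point grid) and compare the filter
with the CLS oracle on 200 randomized full-rank systems of 2–4 components
over 10–81 wavelengths. At those sizes the observed mean |RE| stays below
0.6% and every RSD sits far below its half-Horwitz bound, comfortably
inside the ≤2% accuracy expected of the assay.

## Numerical choices and degenerate inputs

* Grids must match exactly (within 10^-9 nm); interpolation is opt-in,
  linear, and refuses extrapolation. One instrument grid per study is the
  working assumption, so silent resampling would hide an acquisition error.
* Duplicate wavelengths in an input file are an error, never averaged.
* A component whose standard spectrum is all zero is unobservable and
  rejected at calibration; collinear sensitivity columns raise a
  singularity error naming the offending components.
* The covariance is re-symmetrized after every update, and each sweep
  checks the smallest eigenvalue; loss of positive semi-definiteness
  beyond −10^-10 of the prior scale aborts with advice to raise `r` or
  switch to the Joseph form.
* Blank subtraction is not assumed: the fixture manifest has roles for
  standards and samples, and a user who measures a blank can subtract it
  upstream; nothing in the filter requires it.

## Known limitations

Single-point calibration propagates any error in the standard's nominal
concentration multiplicatively into every estimate. The static-state
filter cannot absorb a drifting baseline (a state-augmented variant is out
of scope). The equivalence tests are the classical F-then-pooled-t pair,
not TOST-style equivalence with a declared margin. And since the only
verifiable target of the recursion is its least-squares fixed point, the
filter here is best understood as a sequential route to CLS with
per-wavelength diagnostics (innovations), not as something that beats CLS
in accuracy.
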