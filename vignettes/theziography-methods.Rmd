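---
title: "Jones-matrix theziography: models, phantom design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Jones-matrix theziography: models, phantom design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jtez)
```

## The problem

A sessile drop of a biological fluid (blood, in the motivating application)
dries into a thin polycrystalline film — a *facies* — whose crystal patterns
encode the fluid's molecular composition. Needle-shaped protein crystals of
the marginal albumin-rich zone carry *linear* birefringence and dichroism;
spherulitic domains formed by globulins and blood's formed elements carry
*circular* birefringence and dichroism. Mapping these four anisotropy
parameters over the film ("theziograms") yields image statistics that shift
with disease, and a pair of such maps plus a threshold classifier gives a
minimally invasive diagnostic test.

`jtez` implements the full computational chain of this method: the forward
optics, a synthetic film generator that replaces patient samples, the
holographic recording and reconstruction, phase-resolved (layer-by-layer)
analysis, map reconstruction, moment markers, and diagnostic-performance
arithmetic.

## The optical model

A non-depolarizing anisotropic layer acts on the two complex field amplitudes
through a 2x2 complex Jones matrix. For a layer with the six anisotropy
parameters $LB_{0,90}, LB_{45,135}, CB, LD_{0,90}, LD_{45,135}, CD$ we form
the complex combinations

$$B_{0,90} = LB_{0,90} - i\,LD_{0,90},\quad
  B_{45,135} = LB_{45,135} - i\,LD_{45,135},\quad
  A = CB - i\,CD,$$

their complex modulus $q = (B_{0,90}^2 + B_{45,135}^2 + A^2)^{1/2}$
(principal root), and the generator

$$G = \begin{pmatrix} -iB_{0,90} & A - iB_{45,135}\\
                      -A - iB_{45,135} & +iB_{0,90}\end{pmatrix},
\qquad W = \cos\tfrac q2\, I + \frac{\sin(q/2)}{q}\,G .$$

Because $G$ is trace-free with $G^2 = -q^2 I$, $W = \exp(G/2)$, $\det W = 1$
always, and $W$ is unitary exactly when all dichroisms vanish. The tests
verify the closed form against an independent scaling-and-squaring matrix
exponential on $10^3$ random states at $10^{-10}$.

Two inversions are provided by `jones_invert()`:

* **analytic** — the closed-form reconstruction used in the field:
  $q = 2\arccos\{\tfrac12(\mathrm{Re}\,w_{11} + \mathrm{Re}\,w_{22})\}$, then
  the four aggregates from real/imaginary parts of the elements with the
  prefactor $q/(2\sin(q/2))$. It is exact for phase-only anisotropy and a
  first-order approximation in the dichroisms. One labelling subtlety: with
  the generator above, the *circular* parameters appear in the off-diagonal
  difference with the real part carrying $CB$ and the imaginary part $CD$ —
  the assignment implemented here is the one under which the forward/inverse
  round trip closes. The alternative labelling that swaps the roles of the
  phase and amplitude channels throughout is available as
  `convention = "phase_re"`, since the printed sources are not consistent
  about it and we cannot settle the question from data.
* **matrix_log** — the exact principal matrix logarithm,
  $G = \tfrac{q}{\sin(q/2)}(W - \cos\tfrac q2 I)$ with
  $q = 2\arccos(\mathrm{tr}\,W/2)$, which inverts any state with $|q| < 2\pi$
  to machine precision and serves as the oracle for the analytic form.

Numerical guards: $\sin(q/2)/q$ and its reciprocal switch to series below
$|q| = 10^{-6}$; $\arccos$ is ill-conditioned near $\pm 1$, so the exact
inversion refines $q$ through the analytically equivalent form
$\sin^2(q/2) = \det(W - \tfrac{\mathrm{tr}W}{2}I)$ and picks the branch
nearest the $\arccos$ estimate. Beyond $|q| = 2\pi$ the forward matrices
alias exactly onto the principal sheet, so no inversion can flag such states;
only $q = 2\pi$ itself (a genuine singularity) is flagged.

A measured accuracy worth knowing: with $q \approx 1$ and dichroisms at 0.05,
the analytic inversion recovers the birefringence aggregates to about 0.2%
but the dichroism aggregates only to about 8% (its dichroism error is first
order). The often-assumed "5% for all four" holds for the phase channels
only; the package tests assert the measured behaviour.

## The synthetic facies phantom

No public data exist for this kind of recording, so the package ships a
seeded generator (`phantom_spec()`, `render_jones_field()`) that emulates the
*structure* of a facies rather than its biochemistry:

* **dendritic needles** in the outer annulus (default: outside 0.4 of the
  drop radius): capsule-shaped structures with a flat core (half-width 2 px)
  and a Gaussian skirt ($\sigma$ = 4.5 px), axis angle $\gamma$ uniform on a
  configurable range (default $[0, 2\pi)$, optionally a wrapped normal with
  concentration `gamma_kappa`), retardance $\delta$ log-normal
  (median 0.3 rad, capped at 1.5) entering as
  $lb_{0,90} += \delta\cos 2\gamma$, $lb_{45,135} += \delta\sin 2\gamma$;
  linear dichroism a fixed fraction (0.25) of linear birefringence;
* **spherulite discs** in the central region (inside 0.7 of the radius):
  flat cores of radius 2.5–4.5 px with the same skirt, circular birefringence
  amplitude log-normal (median 0.13, capped at 0.52), circular dichroism a
  0.25 fraction;
* **isotropic path phase**: every structure also adds
  $t \times \mathrm{coverage}$ to a scalar phase map, with a per-structure
  thickness $t \sim U(0.05, 1.15)$ rad drawn independently of the anisotropy
  amplitude (for discs, plus a term $0.8\,CB$ coupling optical activity to
  optical depth). The layer's Jones field is
  $e^{i\psi(a,b)}\,W_{\mathrm{aniso}}(a,b)$;
* **layers**: three by default, composed pixelwise in beam order by
  `stack_product()`; overlapping structures within a layer add their
  parameters (thin-element approximation), which keeps per-layer ground truth
  well defined.

Structure counts default to fixed densities (5 needles, 8 discs per $128^2$
pixels per layer), so phantoms are statistically comparable across grids; the
default grid is the camera format, 1120 x 960.

The isotropic path phase is the load-bearing design element. It models the
number of scattering acts a ray accumulates: pixels covered by little
material exit with small total phase, multiply covered pixels with large
phase. Because per-act thickness is independent of per-act anisotropy
amplitude, gating pixels by accumulated phase selects a *sparser* sub-image
whose anisotropy values keep their full amplitude distribution — which is
exactly what produces the scanning scenario (below). Skirts are Gaussian and
wide because the object field must fit inside the holographic sideband
window; sharp edges would alias truncation error into the reconstruction,
and the arccos inversion amplifies field errors $\varepsilon$ on
near-identity pixels into retardance errors of order $\sqrt\varepsilon$.

The default pathology variant of `cohort_spec()` narrows the needle
orientation range to $[0, \pi/3]$ (increased crystallization order) and
raises the spherulite amplitude (median 0.32) and density (x1.5) — the
direction of change reported for cancerous films: the circular-birefringence
mean and spread rise while its higher moments fall.

What the phantom does *not* emulate: dehydration dynamics, salt crystals,
depolarization, camera nonlinearity, aberrations, or any claim of clinically
realistic parameter values. Passing tests show the pipeline recovers what the
model puts in; they do not validate the clinical claims of the method.

## Recording and reconstruction

`synthesize()` implements a digital Mach-Zehnder: irradiating with x- or
y-polarized light selects the first or second column of the pixel Jones
matrix; each column is recorded through analyzers at 0 and 90 degrees against
a tilted reference plane wave polarized at 45 degrees (so both analyzer
channels beat against a reference of amplitude $r/\sqrt2$). Four intensity
images result, with optional Gaussian detector noise and quantization
(16-bit default).

`demodulate()` is standard off-axis sideband demodulation: multiply by the
conjugate carrier ramp, Hann-apodize, FFT, keep a square window about the
origin, inverse FFT, undo the apodization and the reference amplitude. The
defaults — carrier (0.27, 0.27) cycles/pixel, window half-width 0.18 — are a
deliberate spectral budget: the window must pass essentially all object
energy (Gaussian skirts of $\sigma \ge 4.5$ px put the $10^{-4}$ amplitude
tail inside 0.18 cyc/px) while staying separated from the DC lobe. With this
budget the recovered field matches the simulated one to ~0.3% RMSE and
end-to-end single-layer maps recover ground truth to 0.4% (LB/CB) and ~1.5%
(LD/CD) at 16-bit depth. A 16-pixel border is masked.

`rephase()` removes the one global piston the holographic reconstruction
cannot know, rotating **all four** components by the negated mean phase of
$\hat w_{11}$: the four channels share a single reference arm, so one piston
applies to the whole field. (A per-channel-pair piston convention based on
the determinant phase was evaluated and rejected: with isotropic path phase,
$\det W = e^{2i\psi}$ varies per pixel, and aligning its mean phase injects a
spurious relative piston that rotates linear birefringence into the circular
channel.) Piston invariance of everything downstream holds to the spectral
leakage floor (~$10^{-3}$ of the field), not to machine precision — the DC
and conjugate lobes leaking into the window do not co-rotate with the piston.

Before inversion, `theziogram_maps()` reduces each pixel matrix to
unimodular form (dividing by the principal square root of its determinant,
sign fixed by $\mathrm{Re}\,\mathrm{tr} > 0$), which strips the isotropic
phase exactly and restores the normalization both inversions assume.

## Phase-plane scanning

The interesting part of the method is computing markers not only for the
integral maps but for *phase-gated* sub-images. `pixel_phase()` scores each
pixel; `phase_section()` + `layered_field()` gate the field.

The default functional, `"path"`, is the accumulated path phase
$\arg \hat w_{11}$, measured from a robust low-phase reference: phases are
centred on their circular mean, the 1% quantile becomes zero, and values wrap
into $[0, 2\pi)$ (if fewer than 5% of pixels then fall below $\pi/2$ — a
signature of a corrupted low tail — the 10% quantile is used instead).
Optically thin pixels score near zero; multiply scattered pixels score high.
Cumulative gating at $\varphi_k \in \{\pi/2, \pi/4, \pi/8\}$ then extracts
progressively "thinner" sub-images.

Two alternative functionals are selectable: `"retardance"`
($|2\arccos(\mathrm{tr}W/2)|$ of the reduced matrix) and `"component"`
($|\arg(\hat w_{21}/\hat w_{11})|$ with an $|\arg \hat w_{11}|$ fallback).
The component-ratio reading was considered as a default and rejected: it is
discontinuous in the weak-anisotropy limit (a pure rotation by an arbitrarily
small $CB$ scores $\pi$; a 45-degree needle scores $\pi/2$ regardless of
retardance), which makes it useless as a thickness proxy. The published
description of the scanning step does not define the functional
mathematically, so this is a design choice, stated here.

With the default phantom and functional, the gates reproduce the expected
scanning scenario: as $\varphi_k$ decreases the retained sub-image becomes
background-dominated and sparse, so the first two moments of the LB and CB
maps fall while skewness and kurtosis rise:

```{r scenario, eval = FALSE}
ph <- render_jones_field(phantom_spec(seed = 1))       # 1120 x 960, ~36 s
rec <- rephase(demodulate(synthesize(ph$field)))
sapply(c(pi/2, pi/4, pi/8), function(pk) {
  maps <- theziogram_maps(layered_field(rec, phase_section(pk)))
  unlist(central_moments(maps$CB)[1, 1:4])
})
#> z1: 0.0347 0.0131 0.0040   z2: 0.0753 0.0387 0.0171
#> z3: 2.54   3.60   6.06     z4: 6.95   14.7   51.7
```

The acceptance test asserts this monotonicity on the default (camera-format)
phantom. On a $128^2$ grid the same phantom carries only ~24 structures per
layer and the third/fourth moments acquire visible Poisson wiggle; small-grid
runs are therefore used for fidelity and regression checks, not for the
scenario assertion.

## Markers and conventions

`central_moments()` computes population ($1/K$) moments of the on-mask
values: mean $Z_1$, spread $Z_2$, skewness $Z_3$, kurtosis $Z_4$. Two
conventions required a decision:

* $Z_2$ is reported as the **standard deviation**, not the variance: the
  $1/Z_2^3$ and $1/Z_2^4$ standardizations of $Z_3, Z_4$ are dimensionless
  only then (`z2_is_variance = TRUE` restores the literal variance);
* $Z_4$ is **excess** kurtosis, so a Gaussian map scores $Z_3 = Z_4 = 0$,
  matching how the method's literature describes Gaussian statistics
  (`raw_kurtosis = TRUE` restores the raw fourth moment).

A constant map has $Z_2 = 0$ and its $Z_3, Z_4$ are reported as `NA` with a
`degenerate` flag rather than NaN.

## Diagnostics

`se_sp_ac()` computes $Se = 100N/Q$, $Sp = 100H/G$ and
$Ac = 100(N + H)/(Q + G)$ — correct results over all samples, the only
reading consistent with every published accuracy we recompute — rounded
half-up to one decimal to match printed percentages. `accuracy_grade()` maps
accuracy to the five-level scale; the printed band edges (<80, 81–85, 86–90,
91–95, >95) leave gaps, closed here as half-open intervals anchored at
80/85/90/95.

`classify_loo()` is a transparent default classifier, not a reconstruction of
any published procedure: per held-out sample, the Youden-optimal threshold of
the remaining samples (ties resolved toward the midpoint of the group means)
classifies the held-out value; counts accumulate over folds. On exchangeable
groups it scores within the binomial band around 50%; on the default
synthetic cohort the spread of the circular-birefringence map separates the
groups completely. `representativeness()` reports the standard deviation of
the group-mean marker across leave-one-out folds against the 0.025 adequacy
threshold used to justify 26 samples per group.

`verify_printed_counts()` re-runs the metric arithmetic over the bundled
table of published confusion counts (24 rows: two modalities, three group
comparisons, four parameters). All sensitivities and accuracies recompute
exactly; exactly one printed specificity cell (theziography, LB, later-stage
detection: counts H=24, h=2 printed as 88.5%, recomputed 92.3%) is internally
inconsistent — and since the row's *accuracy* is consistent with its counts,
the typo is pinned to the printed percentage, not the counts. The verifier
flags it; the tests assert everything else matches.

## Problem sizes and reproducibility

Defaults were chosen once for the study conditions: grids of $128^2$ for
fidelity/regression tests and cohorts (26 + 26 samples, ~13 s), the full
1120 x 960 default phantom for the scanning scenario (~36 s), $10^3$ random
states for algebra properties, $10^6$ draws for Gaussian moment calibration.
Every random draw is seeded; rendering, marker tables and classifier output
are bit-reproducible for a fixed spec + seed. `scripts/acceptance.R` re-runs
the whole chain from an arbitrary `--seed` and writes all headline numbers as
JSON.

## Known limitations

* The forward model is a thin-stack approximation — no true volumetric
  scattering, no depolarization; "layer-by-layer" extraction is a statement
  about accumulated phase, not physical depth sectioning.
* The analytic inversion's dichroism channels are first-order accurate only;
  use `method = "exact"` when dichroism matters.
* Phase wrapping: if a phantom accumulates more than ~$2\pi$ of path-phase
  spread, the low-phase reference can misplace; the generator defaults keep
  the span below ~3 rad and `pixel_phase()` carries a fallback guard.
* Phantom parameters are free knobs emulating qualitative structure. No
  claim of clinical realism is made, and clinical tables from patient data
  are not reproducible from simulation — only their metric arithmetic is.
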