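# jtez — Jones-matrix theziography of polycrystalline biological films

`jtez` is an R toolkit for polarization-interference mapping of optically
anisotropic polycrystalline films — the dried-drop preparations ("facies")
of biological fluids whose crystal patterns encode molecular composition.
It is aimed at researchers in biomedical polarimetry and digital holography
who want a tested, fully synthetic implementation of the method: from the
optical forward model to diagnostic-performance tables, with a seeded film
phantom standing in for patient samples.

## What it computes

A non-depolarizing anisotropic layer is a 2x2 complex Jones matrix. With the
complex parameter combinations `B_0,90 = LB_0,90 - i LD_0,90`,
`B_45,135 = LB_45,135 - i LD_45,135`, `A = CB - i CD` and their modulus
`q = (B_0,90^2 + B_45,135^2 + A^2)^(1/2)`, the generalized matrix is

    W = cos(q/2) I + sin(q/2)/q * G,
    G = [ -i B_0,90          A - i B_45,135 ]
        [ -A - i B_45,135    +i B_0,90      ]

which is the matrix exponential `exp(G/2)`: always unimodular, unitary iff
the dichroisms vanish. The package provides:

* **aniso algebra** — `jones_forward()`, and `jones_invert()` with both the
  closed-form arccos reconstruction (`q = 2 acos((Re w11 + Re w22)/2)` plus
  the `q/(2 sin(q/2))` prefactor) and the exact principal matrix logarithm;
* **facies phantom** — `phantom_spec()` / `render_jones_field()` /
  `make_cohort()`: seeded dendritic needle networks (linear anisotropy,
  orientation-disordered axes), spherulite discs (circular anisotropy),
  per-structure isotropic path phase (scattering multiplicity), multi-layer
  stacking, and a healthy/pathology two-group cohort generator;
* **digital Mach-Zehnder** — `synthesize()` records four off-axis
  interference channels ({x, y} irradiation x {0, 90} analyzer against a
  tilted 45-degree reference); `demodulate()` recovers the complex
  Jones-matrix field by Fourier-sideband demodulation; `rephase()` fixes the
  piston convention;
* **phase scanning** — `pixel_phase()` + `phase_section()` +
  `layered_field()` gate pixels by accumulated path phase, extracting weakly
  scattered sub-images at planes `pi/2`, `pi/4`, `pi/8`;
* **theziograms & markers** — `theziogram_maps()` reconstructs the LB, CB,
  LD, CD maps; `central_moments()` / `marker_table()` compute the Z1–Z4
  moment markers;
* **diagnostics** — `se_sp_ac()`, `accuracy_grade()`, `classify_loo()`
  (leave-one-out Youden threshold), `representativeness()`, and
  `verify_printed_counts()` which re-derives every published
  sensitivity/specificity/accuracy from its confusion counts.

## Worked example

```r
library(jtez)

# a seeded synthetic facies, recorded and reconstructed
spec   <- phantom_spec(grid = c(128, 128), seed = 1)
sample <- render_jones_field(spec)              # 3 layers + ground truth
igs    <- synthesize(sample$field)              # four 16-bit interferograms
rec    <- rephase(demodulate(igs))              # recovered Jones field

# linear-birefringence map of the weakly scattered component
maps <- theziogram_maps(layered_field(rec, phase_section(pi/8)))
maps$LB
#> <theziogram> LB (phi_k = 0.3927), 128 x 128 px, K = 2866, dropped 0.00%
central_moments(maps$LB)
#> # A tibble: 1 x 8
#>       z1     z2    z3    z4     k degenerate parameter phase_plane
#> 1 0.0418 0.0829  3.32  12.6  2866 FALSE      LB              0.393
```

The `K = 2866` pixels are those whose accumulated phase stays below `pi/8`;
compared with the integral map the mean and spread drop while skewness and
kurtosis rise — the layer-extraction scenario the phase scan is designed to
expose. `autoplot(maps$LB)` draws the map; `plot_marker_trends()` shows the
moment trajectories across phase planes.

Diagnostic arithmetic on published confusion counts:

```r
v <- verify_printed_counts()   # bundled 24-row table, two modalities
v[v$method == "JT" & v$parameter == "CB", c("comparison","se","sp","ac","grade")]
#>   comparison    se    sp    ac grade
#> 1 stage1      92.3  88.5  90.4 very good
#> 2 stage2      96.2  96.2  96.2 excellent
#> 3 stage_diff  96.2  92.3  94.2 very good
```

i.e. circular-birefringence theziograms detect early-stage disease at 90.4%
balanced accuracy, later-stage at 96.2%, and differentiate stages at 94.2%.
The full pipeline — cohort simulation through leave-one-out diagnosis — runs
as one call: `run_pipeline(list(grid = c(128,128), n_per_group = 26))`.

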