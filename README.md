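# kmdlign

Kendrick mass-defect analysis and CHNOS molecular-formula assignment for
electrospray high-resolution mass spectra of lignin and similar complex
mixtures.

Lignin dissolved in different solvent mixtures ionizes as thousands of
singly (de)protonated oligomer peaks per spectrum. Because the material is
built from repeating phenylpropanoid units, its homologous series become
visible after the Kendrick transform, and sub-ppm mass accuracy makes
direct elemental-composition assignment possible. `kmdlign` packages that
workflow for anyone comparing extraction/ionization solvents or lignin
sources from centroided peak lists:

* read two-column ASCII (".xy") peak lists with a sample/solvent/ion-mode
  manifest;
* clean them up — blank subtraction, a signal-to-noise floor, base-peak
  normalization and the "< 1 % relative intensity" filter;
* transform to Kendrick space and gate peak groups with reproducible
  polygon files;
* assign CHNOS formulas by exact-mass decomposition and derive DBE, H/C,
  O/C and heteroatom classes;
* characterize the gated groups and rank solvent mixtures by how much of
  the mixture they recover;
* simulate lignin-like benchmark datasets with full ground truth.

## The method in brief

For a repeating unit of nominal mass `n` and monoisotopic mass `m`
(CH2: 14 / 14.01565), the Kendrick mass and mass defect of a peak are

    KM  = mz * n / m
    KMD = round(KM) - KM            (half-up; KMD in (-0.5, 0.5])

so every CH2 homologous series collapses onto one horizontal line in the
KM–KMD plane. Gated regions of that plane are peak groups (a region with
fewer than 5 peaks is not considered a group).

Formula assignment searches all compositions C(1–90) H(4–200) N(0–5)
O(1–23) S(0–1) whose neutral monoisotopic mass lies within ±0.5 ppm of
the (de)protonated peak's neutral mass, with double-bond equivalents

    DBE = C - H/2 + N/2 + 1

restricted to integers in [0, 50] and the valence cap H ≤ 2C + N + 2.
When several formulas fit, the lowest |mass error| wins (ties: fewer
heteroatoms, then lexicographic). An exhaustive full-grid reference
search (`brute_force_candidates()`) validates the production search in
the test suite.

## Worked example

Simulate a ten-solvent study of a four-component lignin-like mixture,
preprocess it, rank the solvents, and characterize one spectrum:

```r
library(kmdlign)
library(dplyr)

cfg <- synthetic_config()
ds  <- simulate_dataset(cfg, seed = 42)
pp  <- preprocess_dataset(ds)

rank_solvents(pp) |> head(5)
#>   solvent_label          organic_aqueous_ratio n_peaks score  rank
#> 1 3:1 MeOH:H2O                            0.75      76    76     1
#> 2 3:1 AcN:H2O                             0.75      67    67     2
#> 3 1:1:2 acetone:MeOH:H2O                  0.5       61    61     3
#> 4 1:1 EtOH:H2O                            0.5       57    57     4
#> 5 1:1 AcN:H2O                             0.5       55    55     5

ratio_trend(rank_solvents(pp))
#>   mean_count_high mean_count_low difference spearman
#> 1            59.8             41       18.8    0.892
```

High organic/aqueous-ratio mixtures recover the most peaks from this
simulated lignin (difference of ~19 peaks between ratio ≥ 0.5 and
< 0.5 mixtures; Spearman 0.89 between count and ratio). Assign formulas
and summarize the gated Kendrick groups of the best solvent's spectrum:

```r
pk  <- pp$peaks[[which(!pp$is_blank & pp$solvent_label == "3:1 MeOH:H2O")]]
asg <- assign_formulas(pk, elemental_limits(), "negative")
asg |> filter(assigned) |> select(mz, formula, error_ppm, dbe, het_class) |> head(4)
#>      mz formula   error_ppm   dbe het_class
#> 1  316. C18H23NO4    0.0262     8 N1O4
#> 2  330. C19H25NO4   -0.0642     8 N1O4
#> 3  331. C20H28O4     0.0479     7 O4
#> 4  345. C21H30O4     0.0418     7 O4

pts <- kendrick_transform(pk)
grp <- gate_groups(pts, library_gate_polygons(attr(ds, "library")))
summarize_groups(grp, asg) |>
  select(group_id, n_members, km_min, km_max, dbe_min, dbe_max)
#>   group_id n_members km_min km_max dbe_min dbe_max
#> 1        1        39   516.   690.      15      42
#> 2        3        21   316.   442.       7       8
#> 3        4        33   331.   565.       7      12
```

Group 2 of the design is absent here: this high-ratio solvent barely
extracts it, so its gate captures fewer than 5 peaks and is rejected —
exactly the solvent-dependent group structure the workflow is meant to
expose. `plot_kendrick()`, `plot_van_krevelen()` and
`plot_solvent_ranking()` draw the corresponding figures, and
`recovery_report()` scores assignments against the generator's ground
truth.

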