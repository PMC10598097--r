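---
title: "Kendrick mass-defect lignomics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kendrick mass-defect lignomics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmdlign)
library(dplyr)
```

`kmdlign` implements a characterization workflow for direct-infusion
ESI-HRMS of lignins: peak-list cleanup, Kendrick mass-defect analysis,
exact-mass CHNOS formula assignment, group characterization, and
solvent-mixture ranking, together with a ground-truthed synthetic
spectrum generator used to benchmark the whole chain. This vignette
explains the underlying model, every tunable parameter that matters, and
the design decisions taken where more than one reasonable choice
existed.

## Why mass-defect space

Lignin is a polydisperse aromatic polymer assembled from three
phenylpropanoid units (H: C9H10O2, G: C10H12O3, S: C11H14O4). Its ESI
spectra contain thousands of peaks, but much of that complexity is
homologous: families differing by repeated CH2 (or other units) at
otherwise constant composition. Rescaling the m/z axis by the
nominal/exact mass ratio of the repeating unit,

$$\mathrm{KM} = m/z \cdot \frac{14}{14.01565}, \qquad
  \mathrm{KMD} = \mathrm{round}(\mathrm{KM}) - \mathrm{KM},$$

makes every CH2 series share one KMD value, so series appear as
horizontal rows and compositional families as clusters in the KM–KMD
plane. Groups of peaks are then *gated* — selected as polygonal regions
of that plane — and characterized through their assigned formulas.

### KMD sign and boundary convention

`round()` here is round-half-up (`floor(x + 0.5)`), giving KMD in
$(-0.5, 0.5]$. The nearest-integer convention is used because observed
lignin groups span negative and positive defects (e.g. a highly
oxygenated group reaching KMD $-0.47$), which a floor/ceiling convention
would fold into $[0, 1)$. The `"ceiling"` convention remains available
in `kendrick_transform()` for comparison with tools that use it. A KM
landing exactly on $k + 0.5$ rounds up, so $+0.5$ is attainable and
$-0.5$ is not; this tie case is measure-zero for real data and pinned by
tests. Charge state is assumed 1 throughout — lignin oligomers in the
m/z 100–2000 range electrospray overwhelmingly as singly (de)protonated
ions; multiple charging is out of scope.

### Gating and series detection

Gates are CSV polygon files (`km,kmd` vertices), replacing interactive
lasso selection so that group definitions are reproducible artifacts.
Boundary points count as inside; gates capturing fewer than 5 points are
rejected with the count reported, following the working rule that a
sparse region is not a group. Polygons must be simple (non-adjacent
edges may not cross); validity is checked on read.

`find_series()` formalizes "horizontal rows": points are first
single-linkage clustered on KMD within `kmd_tol` (default 1 mu), and
within a cluster a series is a *maximal* set of points whose KM values
differ pairwise by integer multiples of the base's nominal mass to
within `2 * kmd_tol` — i.e. a maximal clique of the pairwise
compatibility graph, computed exactly with igraph. The exhaustive-subset
definition is mirrored by an independent bitmask-enumeration oracle in
the tests.

## Preprocessing

The cleanup chain runs **blank subtraction → S/N filter → normalization
→ relative-intensity filter**, in that order; normalizing after
subtraction guarantees the base peak used for the percent scale is a
sample peak, not a contaminant.

* **Blank subtraction** removes a sample peak when a matched blank peak
  lies within `blank_tol_ppm` (default 1 ppm). Removal — rather than
  intensity differencing — is the conservative, testable reading of
  "blanks were subtracted": a blank flags a contaminant mass. An
  optional intensity-ratio criterion (`blank_intensity_ratio`, default
  0 = off) restricts removal to peaks the blank can plausibly explain.
* **S/N filter**: the noise level is the median raw intensity of the
  lowest `noise_quantile` (default 20 %) of peaks; peaks below
  `snr_min` (default 3) times that level are removed. Both knobs are
  exposed because the threshold is inherited from formula-finding
  software that does not define its estimator. The estimate is made
  *once*, on the spectrum as given, and carried on the result as an
  attribute; a second application reuses it. Re-estimating on the
  filtered spectrum would raise the floor each pass and make the filter
  iteratively self-consuming — idempotence is the contract the rest of
  the pipeline relies on. Spectra with < 5 peaks skip the filter with a
  warning.
* **Relative-intensity filter** keeps peaks with `rel_intensity >=
  min_pct` (default 1 %): a peak at exactly 1 % survives, because the
  rule removes peaks with *less than* 1 % normalized intensity.

All three filters return subsets of their input and are idempotent;
both properties are enforced by property-style tests over random
spectra.

## Formula assignment

Peaks are read as [M−H]⁻ or [M+H]⁺ (proton mass 1.007276466 u, pinned
with the atomic masses in `atomic_masses()`); adducts and multimers are
excluded. The search space is C 1–90, H 4–200, N 0–5, O 1–23, S 0–1
within a symmetric **0.5 ppm** window on the neutral mass, DBE
($C - H/2 + N/2 + 1$) in [0, 50]. Two chemical-plausibility filters are
on by default and configurable:

* **integer DBE** (`require_integer_dbe`): even-electron neutrals only —
  the expected ionization chemistry here;
* **valence cap** (`enforce_valence`): H ≤ 2C + N + 2.

Oxygen's lower bound defaults to 1 (lignin compositions are
oxygenated); `o_min = 0` admits oxygen-free heteroatom classes such as
S1N3 where needed.

The production search (`enumerate_candidates()`) loops over S, N, O, C
and solves H from the mass residual, examining only a handful of
hydrogen counts per heteroatom combination. Candidates are ordered by
|error| ascending — the lowest-error rule — with exact ties broken by
fewer heteroatoms, then lexicographically, so selection is
deterministic. `brute_force_candidates()` enumerates the *entire*
element grid (~5 × 10⁶ combinations under the default limits, cached
per limit set, hard-capped at 10⁷), applies the same filters, and must
agree with the production search in set *and order*; the test suite and
acceptance script verify this on hundreds of random masses. Isotope
patterns and fine structure are not scored; assignment from exact mass
alone is tentative by nature, which is precisely why the package reports
mass errors and recovery rates rather than asserting identities.

## Group characterization and solvent ranking

`summarize_groups()` reports, per gated group, the KM/KMD extent, the
H/C, O/C and DBE ranges over assigned members, the heteroatom classes
present, and the classes unique to that group within its comparison set
(the other groups of the same table). Unassigned members contribute only
KM/KMD; ranges widen monotonically as members are added.

`rank_solvents()` orders solvent mixtures by recovered peak count —
whole-spectrum or restricted to one gate — with ties broken
alphabetically. Count is the default metric, summed intensity the
alternative, because the underlying field practice ("sorted according to
the number of peaks") is count-based. `top_solvents_per_group()` reports
each gate's best three nonzero solvents; `ratio_trend()` summarizes the
organic/aqueous-ratio effect descriptively (group means and a Spearman
coefficient, no significance claim — the scientific statements this
supports are qualitative). `match_groups()` pairs groups across samples
by greedy bounding-box IoU (default threshold 0.3); leftovers are the
"groups unique to one sample" that distinguish, e.g., degraded from
non-degraded lignins. Box IoU was chosen over polygon-exact overlap
because summaries carry ranges, not vertex lists, and matching by eye is
what it replaces.

## The synthetic generator

Real raw spectra for this workflow are rarely shareable, so the
package ships a generator whose statistical structure matches what the
analysis assumes, with complete ground truth.

**Chemistry.** Components are H/G/S oligomers (2–4 units) condensed with
loss of one water per linkage, then decorated: a CH2 ladder (k = 0–9,
creating exact Kendrick series), oxygen variants, ±H2 (changing DBE),
and N (added as NH, preserving integer DBE) and S heteroatoms. Every
emitted formula passes the elemental limits and valence rule by
construction, and the library is deterministic given the configuration.

**Groups.** The default four groups realize the contrast the analysis
must resolve: groups 1–2 oxygen-rich, high-DBE, low H/C; groups 3–4
higher H/C, lower O/C, low DBE. Group extraction responds logistically
to the solvent's organic/aqueous ratio $r$: component inclusion
probability $\mathrm{logit}^{-1}(\beta (r - r_0))$ with slopes
$\beta = +10, -10, -6, +12$ and midpoint $r_0 = 0.5$ — groups 1 and 4
favor organic-rich mixtures, 2 and 3 aqueous-rich ones. Group sizes
(40/25/20/30) are deliberately unequal: the ten-solvent panel has only
three distinct ratios (0.25, 0.5, 0.75 — six mixtures share 0.5), and
with symmetric sizes the aggregate expected peak count would be flat in
$r$, making whole-spectrum rank recovery ill-posed. With these sizes the
expected component counts are ~44 / 57 / 71 at $r$ = 0.25 / 0.5 / 0.75.
Because the six ratio-0.5 solvents are exchangeable by design, the
recovered ranking is random within that block and the attainable
Spearman correlation against the designed propensity has a ceiling of
about 0.88; observed means run 0.85–0.87.

**Noise model.** m/z jitter is Gaussian with `ppm_sigma = 0.15` ppm —
well inside the 0.5 ppm window, so assignment failures reflect
compositional ambiguity rather than calibration noise (raise it for
stress tests). Intensities are log-normal (meanlog log 10⁵, sdlog 0.5);
30 background peaks per spectrum at uniform 20–200 counts give the S/N
filter something real to remove; 12 fixed contaminant masses (typical
ESI background ions) appear in samples *and* blanks, jittered
independently, so blank subtraction at 1 ppm removes them with ~5σ
margin. Intensity distributions of real lignin components are unknown;
log-normal is a modeling choice, stated as such.

**What passing benchmarks does and does not show.** The generator
emulates homologous-series structure, solvent response, mass jitter,
background noise and shared contaminants. It does not emulate
isotopologues, multiply-charged ions, adducts, profile peak shapes,
dynamic-range compression, or calibration drift — so green benchmarks
demonstrate the *pipeline's* correctness under its stated assumptions,
not instrument-level robustness on arbitrary real data.

## Numerical choices and degenerate inputs

* Atomic masses pinned in `atomic_masses()` (¹²C exact, ¹H 1.00782503207,
  ¹⁴N 14.0030740048, ¹⁶O 15.9949146196, ³²S 31.97207100); m/z is never
  rounded at I/O (17 significant digits on write) because 0.5 ppm
  windows demand full double precision.
* Duplicate m/z on ingestion: keep maximum intensity, warn — duplicates
  indicate centroiding artifacts, not signal.
* Empty results are contracts, not errors: a peak with no in-window
  candidate is flagged unassigned; a gate with < 5 points is rejected
  with its count; a fully subtracted spectrum is returned empty with a
  warning.
* Mass errors are reported as signed ppm on the neutral-mass scale, the
  same scale the window is applied on.
* All generator randomness flows through explicit seeds and a local RNG
  scope, so simulations are bit-reproducible and never disturb the
  caller's random stream.

## Problem sizes

The shipped benchmarks use the ten-solvent panel with ~115 library
components (≈ 600 component peaks per simulated study), 200 random
masses for search-vs-oracle verification, 10⁵ random m/z values for KMD
range checks, and 20 replicate studies for rank-recovery statistics —
sizes chosen so the full suite characterizes the method's behavior in a
few minutes on a single core.

## Known limitations

Assignment is exact-mass-only (no isotope verification); charge 1 and
(de)protonation only; gating is axis-aligned-polygon based with no
interactive UI; solvent ranking is count-based and descriptive — no
inferential statistics are attached, by design, to claims the workflow
can only support qualitatively.
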