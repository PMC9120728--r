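---
title: "Severity-informed morphometry and atrophy network mapping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Severity-informed morphometry and atrophy network mapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical machinery in `atrophynet`, the
assumptions behind it, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
and design choices the implementation makes where the procedure left
room.

## 1. The two-stage model

### Stage one: vertex-wise morphometry

The unit of analysis is a per-subject map of cortical volume on a
common spherical surface — volume as an extensive quantity (surface
area × thickness, mm³ per vertex), already registered across
subjects. At every vertex the package fits ordinary least squares

$$\mathrm{vol}_v = \beta_0 + \beta_1\,x + \beta_2\,\mathrm{age} +
\beta_3\,\mathrm{sex} + \beta_4\,\mathrm{eTIV} + \varepsilon,$$

where $x$ is either the case/control indicator (two-class model) or
the severity score restricted to rated cases (one-class model). The
effect is reported three ways: the estimate $\hat\beta_1$, its $t$
statistic, and the partial correlation
$r = \mathrm{sign}(t)\sqrt{t^2/(t^2+\mathrm{df})}$ with
$\mathrm{df} = n - p$. Missing covariate values are a hard error —
rows must be excluded explicitly (the `severity_subset()` helper does
this and reports how many cases lack a rating), never silently
dropped. Post hoc variants re-fit the same model with extra nuisance
columns (depression + trait anxiety, antidepressant use, subtype) or
on the functional-weakness subgroup; they differ from the main model
only in the design, which the run manifest records.

Assumptions: linear, main-effects-only covariate adjustment (no
group × covariate interactions — the simplest reading of "adjusted
for"); sex coded 0/1; eTIV entered untransformed; homoscedastic
Gaussian errors per vertex. Two-sided inference throughout, with
clusters split by effect sign, since a one-sided convention was not
forced by the procedure.

### Smoothing

Surface smoothing is iterative symmetric neighbor diffusion: one step
is $x \leftarrow x + \alpha \sum_{j \sim i}(x_j - x_i)$ with a single
edge weight $\alpha = 1/(\max \mathrm{degree}+1)$. The operator is
symmetric and mass-conserving (a constant map is a fixed point; the
sum over vertices is preserved exactly), and $k$ steps approximate a
Gaussian kernel through the random-walk variance relation
$\mathrm{FWHM}^2 \approx k \cdot 8\ln 2 \cdot \bar s^2$, with
$\bar s$ the mean edge length. `fwhm_to_iterations()` inverts this,
rounding to the nearest integer — so FWHM below roughly
$0.6\,\bar s\sqrt{8\ln2}$ rounds to zero iterations and leaves the
map untouched. At the default desk-scale mesh (icosphere level 3,
$\bar s \approx 0.16$ on the unit sphere) one iteration corresponds
to FWHM ≈ 0.35–0.5 mesh units; this single-iteration regime is the
analogue of a 10 mm kernel on a ~100 mm-radius registered sphere,
where the kernel is also on the order of one inter-vertex spacing.

### Cluster-wise Monte Carlo correction

Vertices with uncorrected $p$ below the cluster-forming threshold
(default 0.001) are grouped into edge-connected, same-sign
components; cluster size is summed vertex area, robust to mesh
resolution. The null distribution of the maximum cluster size comes
from simulated smooth Gaussian fields: white standard-normal noise on
the vertices, smoothed with the analysis-matched FWHM, then
**rescaled to unit marginal variance** using the diagonal of
$S_kS_k^\top$. The rescaling matters: without it the smoothed null
field has marginal SD < 1, its suprathreshold rate falls below the
nominal normal tail, and the correction becomes conservative relative
to $t$-maps whose marginal scale is exactly 1. With it, the vertex
threshold keeps its nominal tail probability and the FWER calibration
test sits inside its band.

The null FWHM should match the *total* smoothness of the analysed
maps. The pipeline composes the smoothness already present in the
input (`data_fwhm`, the generator's noise FWHM for synthetic bundles)
with the analysis smoothing in quadrature,
$\sqrt{\mathrm{fwhm}^2 + \mathrm{data\_fwhm}^2}$ — correct for this
operator family because iteration counts add linearly and
$\mathrm{FWHM}^2 \propto k$. Residual-based smoothness estimation for
real data is deliberately out of scope; `data_fwhm` is an explicit
input.

Cluster p-values use the add-one convention
$p = (1 + \#\{\text{null maxima} \ge \text{observed}\})/(1 + n)$,
so $p = 0$ is impossible and the smallest attainable value is
$1/(n+1)$. With the desk-scale default of 1,000 iterations the floor
is ~0.001; the reference scale of 10,000 (floor $10^{-4}$) remains a
parameter. A subject-label permutation null is a recognised
alternative; the Gaussian-field simulation was chosen as the primary
implementation because it matches the cluster-wise "Monte Carlo
simulation" convention in surface-based morphometry, and the
machinery accepts any `null_cluster_distribution` with matching
metadata (a mismatch in FWHM or threshold is a hard error).

Region-level (subcortical-style) tables use Benjamini–Hochberg FDR
(`fdr_bh()`, a thin validated wrapper over `stats::p.adjust`).

### Stage two: atrophy network mapping

The severity partial-correlation map is aggregated to a bilateral
atlas by **area-weighted** parcel means (volume is extensive over
surface area; unweighted means are available). Two analyses follow:

- **Centrality similarity**: Pearson correlation between the
  region-level atrophy map and weighted-degree centrality of a
  normative connectome. Degree handling of negative edges defaults to
  `positive_only` (drop negative weights), the common practice for
  correlation-based normative connectomes; `signed` and `absolute`
  modes are switchable and the mode is recorded in every output.
- **Epicenter mapping**: for each region $j$, the correlation between
  its connectivity profile (row $j$, self-connection removed from
  both vectors — the structural zero would otherwise bias the
  estimate) and the atrophy map. Regions are ranked by $|r|$ and
  flagged at spin $p < \alpha$ with $\alpha = .01$ by default.

Inference uses spin permutations: one uniform random rotation per
permutation, applied to the left-hemisphere centroids and its
x-mirror to the right-hemisphere centroids, each original region
taking the value of the nearest rotated centroid within its
hemisphere (assignment with replacement — a rotated centroid may
serve two regions; a cost-minimising one-to-one assignment would be a
variant, not implemented because replacement is the simpler
well-defined rule and calibrates well empirically). Only the atrophy
map is rotated, never the connectome, preserving the graph structure.
Regions without spherical coordinates (e.g. subcortical) cannot enter
spin tests.

## 2. The synthetic-data generator

`simulation_config()` defaults encode the emulated study conditions:
53 cases (42 female, age 43.7 ± 10.1) vs 50 controls (36 female,
44.5 ± 10.0), three cases without a severity rating, antidepressant
use in 24/53 and 16/50, and an examiner-rated severity score on
[0, 54]. Values the study context does not pin down were fixed once
at realistic magnitudes and are documented here: severity truncated
normal with mean 15 and SD 9 (a typical outpatient FMD spread);
eTIV $\mathcal N(1.5\times10^6, (1.5\times10^5)^2)$ mm³; baseline
vertex volume 2.5 mm³ with age, sex and eTIV effects of −0.005,
0.10 and $2\times10^{-7}$ mm³ per unit; noise SD 0.30 mm³.

The planted effect controls the **partial** correlation after
covariates. Severity is drawn independently of the covariates, so
scaling the severity coefficient as
$\beta = \rho/\sqrt{1-\rho^2} \cdot \sigma_\varepsilon/\sigma_s$
(with $\sigma_s$ the analytic truncated-normal SD) makes $\rho$ the
single effect-size knob; the mean recovered partial correlation over
replicate cohorts matches $\rho$ to within Fisher-bias terms. The
effect support is either a geodesic disc (contiguous, one
hemisphere, default radius 0.35 rad) or, for coupled bundles, a
per-vertex weight profile derived from a planted epicenter: weights
proportional to a blend of the epicenter's (negated, standardised)
connectivity profile and the (negated, standardised) weighted-degree
map (`centrality_mix = 0.4`, epicenter selectable as `"hub"`). The
blend makes one cohort coherently reproduce both network findings —
severity-related atrophy that falls on densely connected cortex and
an identifiable epicenter; 0.4 was chosen from the noise-free
geometry (it yields an atrophy–degree correlation around −0.6 before
GLM sampling noise, attenuating toward the −0.4..−0.5 range at
n = 50).

Noise fields are white Gaussian maps smoothed per subject with
`noise_fwhm` (default 0.35 mesh units = one diffusion iteration at
level 3) and rescaled to unit marginal SD. Connectome weights are
$\mu_{ij}\exp(-\mathrm{decay}\cdot d_{ij})$ plus symmetric Gaussian
noise, with within/between-module means (modules from k-means on the
centroids), symmetrised, diagonal-zeroed and clipped to $[-1,1]$.
Cross-hemisphere distances — for connectome structure and for the
smooth region-level noise used in spin calibration and epicenter
planting — are computed in **mirror-consistent coordinates** (right
hemisphere x-negated), so homotopic regions are close. This is not
cosmetic: the spin null applies mirrored rotations to the two
hemispheres and therefore preserves exactly the homotopic covariance
structure; a generator that coupled hemispheres through raw
coordinates would produce maps whose cross-hemisphere dependence the
spin null cannot reproduce, and the test would be anticonservative
(we observed ~9% rejection at nominal 5% before adopting the mirror
convention, ~5% after).

What the generator does **not** emulate: cortical geometry (the mesh
is a sphere, with no folding, no area distortion from registration),
spatially varying smoothness, site or scanner effects, non-Gaussian
volume distributions, severity measurement error, and any dependence
of covariates on severity. Passing calibration and recovery tests on
these fields therefore validates the statistical machinery, not the
anatomical realism of any particular dataset.

## 3. Fixture scales and numerical choices

Default desk scale: icosphere level 3 per hemisphere (2 × 642
vertices), 34 regions per hemisphere, n = 53 + 50, 1,000 spins and
1,000 cluster-null iterations; the test suite's calibration runs use
500 iterations/spins where a distribution is resampled hundreds of
times. Every stochastic operation takes an explicit seed; the
pipeline derives stage seeds from one master seed by fixed offsets,
and two runs with the same master seed produce byte-identical result
tables. Reference-scale parameters (10,000 iterations and spins) are
plain arguments.

Numerical details worth knowing:

- Indices are 1-based everywhere internally (idiomatic R); region
  ids in I/O files are preserved as given.
- `geodesic_distance()` clamps dot products to $[-1,1]$ before
  `acos`; unit-norm violations beyond tolerance are errors, not
  warnings.
- Vertex areas are one third of each incident flat-triangle area;
  icosphere totals converge to $4\pi$ from below with subdivision
  level.
- Cluster ordering is deterministic (descending size, then peak
  vertex index); spin nearest-centroid ties break on the first
  index. Exact ties in cluster sizes are handled conservatively by
  the add-one count (`≥`).
- The smoothing operator is built once per (mesh, FWHM) and reused
  across subjects and null iterations as a dense matrix product.
- `fit_vertex_glm` treats a zero-residual vertex with a nonzero
  effect estimate as $t = \pm\infty$, $r = \pm 1$, $p = 0$ (exact
  linear dependence), rather than 0/0.

## 4. Interfaces and provenance

All inputs and outputs are plain text: OFF meshes (with a JSON
sidecar for hemisphere labels and radius), CSV atlas/cohort/matrix/
connectome tables, and a JSON run manifest recording parameters,
stage seeds, the composed null FWHM, subject counts and the variant
list — enough to regenerate every output table from the inputs. The
repository is organised as an analysis workflow: the numbered
scripts under `analysis/` are thin narrative drivers over the
exported functions, and `scripts/acceptance.R` recomputes the
headline quantities from scratch under one seed. There is no
separate command-line tool; the exported functions and these scripts
are the interface.

## 5. Known limitations

- The Monte Carlo cluster null simulates Gaussian fields while the
  data yield $t$-fields (df ≈ 46 at the default cohort); the shared
  residual-scale factor of a $t$-map induces slightly heavier
  cluster-size tails, and the measured family-wise error sits in the
  upper half of its nominal band (~6–9% at 5%). At larger df the gap
  vanishes.
- FWHM-to-iterations rounding quantises achievable smoothness at
  coarse mesh resolutions (0, 1, 2, ... iterations); requesting an
  FWHM below the one-iteration threshold silently means "no
  smoothing", which `fwhm_to_iterations()` makes inspectable.
- Spin inference assumes both maps live on (two) spheres with
  meaningful centroids; it is undefined for subcortical structures,
  which would need a uniform-relabeling null instead.
- Epicenter p-values are not corrected across regions by default
  (matching the reference convention of reporting $p_{perm} < .01$);
  `fdr_bh()` can be applied to the epicenter table when a corrected
  statement is wanted.
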