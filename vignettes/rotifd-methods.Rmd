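---
title: "Methods: trophic state, functional diversity and beta partitioning in rotifd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trophic state, functional diversity and beta partitioning in rotifd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotifd)
```

`rotifd` implements a complete analysis chain for asking whether
eutrophication homogenizes a zooplankton community: score each sample's
trophic state from water chemistry, place taxa in a categorical trait
space, compute per-sample functional diversity, partition beta diversity
into replacement and richness-difference components, and relate everything
with standard association statistics. Because the motivating kind of field
dataset is rarely redistributable, the package carries a synthetic survey
generator whose statistical structure matches what the analysis assumes;
all tests run against it.

## The composite trophic level index

Each parameter is scored `TLI_j = 10 (a_j + b_j ln x_j)` (natural log) and
combined as `TLIc = sum_j W_j TLI_j` with weights
`W_j = r_j^2 / sum r_j^2` from reference correlations of each parameter
with chlorophyll-a. Properties that follow directly and are enforced by
tests: TLIc is bounded by the smallest and largest subscore; multiplying a
parameter by *e* shifts its subscore by exactly `10 b_j`; weights sum to 1
for any admissible `r`.

Design choices:

* **Formula reading.** The index form `10 (a_j + b_j ln x_j)` is the only
  reading of the published equations consistent with a 0–100 index; the
  printed text lacks parenthesization.
* **Coefficient sets.** The default `"canonical"` set is the standard
  Chinese lake-survey set (chla 2.5/1.086, tp 9.436/1.624, tn 5.453/1.694,
  sd 5.118/−1.94, cod 0.109/2.661). Published variants exist in which the
  SD line duplicates the TP coefficients and the COD line carries the SD
  constants — an evident typographic corruption, since transparency must
  enter with a negative slope. That variant is available as
  `"as_printed"` so numbers computed against such a text can be reproduced;
  every result records the set used.
* **Reference correlations.** `r = (1, 0.84, 0.82, 0.83, 0.83)`, the
  widely used values from the Chinese 26-lake survey, overridable.
* **Class boundaries.** Oligotrophic < 30, eutrophic > 50. The published
  thresholds are strict on both sides, leaving 30 and 50 unassigned; both
  are placed in the mesotrophic class (the conservative choice — a boundary
  sample is not declared eutrophic).
* **Missing chemistry.** Samples missing any parameter are skipped with a
  warning by default; `na_action = "renormalize"` rescales the weights over
  the available parameters instead. No interpolation is attempted.

## Traits, functional groups and dominance

The default vocabulary has 7 trophi, 3 size, 4 feeding and 3 swimming
modalities. Validation canonicalizes label spellings (case, separators,
"filter-feeding", "Facultative plankton") and reports offending taxa by
name. Size boundaries: lengths of exactly 150 or 300 µm fall in the middle
class.

Functional composition aggregates abundances by modality within one
category; the four categories share the same sample totals, so aggregation
conserves abundance exactly. The dominance screen uses the McNaughton-style
index `Y = (n_i/N) f_i` (group relative abundance times occurrence
frequency) with threshold `Y >= 0.02`. The common auxiliary criterion
"relative abundance above 20% in the group" is reported as a separate flag
rather than folded into Y, and the screen runs on taxa or on trait
modalities — the literature is ambiguous about which unit such screens are
applied to, so both are supported.

## Trait space and the three FD indices

Gower distance on four single-modality categorical traits is the mean
per-category mismatch, which weights the traits equally; the one-hot
Bray-Curtis variant coincides with it exactly in this setting and is kept
as a cross-check. The distance matrix is embedded by PCoA
(double-centered eigendecomposition). Categorical distances are generally
non-Euclidean, producing negative eigenvalues; when they occur and
`correction = "additive"` (the default), the Cailliez constant is added to
off-diagonal distances and the decomposition recomputed. The result
records whether correction was applied, the constant, and the quality
fraction (retained over total positive eigenvalue mass). By default
`k_max = 2` axes are retained, matching the common practice of
summarizing categorical trait data by the first two principal coordinates.

On those axes the package computes the standard distance-based indices:
FRic as convex-hull volume, FEve as minimum-spanning-tree evenness, FDiv
as abundance-weighted divergence from the centroid of the hull vertices.
Numerical policies:

* Present taxa are those with abundance > 0 in the sample; no occurrence
  threshold.
* FRic is undefined (flagged, not an error) when distinct present taxa do
  not outnumber the axes; collinear configurations give volume 0 with a
  degeneracy flag. FRic is reported as absolute volume, not normalized by
  a global hull: comparisons are within one study region and normalization
  would only rescale every regression.
* MST edge ties are broken by lexicographic taxon-pair order (Kruskal), so
  results are deterministic even on symmetric configurations.
* FEve and FDiv use relative abundances and are therefore invariant to the
  abundance scale; both are undefined below S = 3.
* Hull volume is implemented for 1 or 2 retained axes. No qhull-style
  library is available to the package, and the analysis this supports uses
  two axes; requesting more axes for FRic errors clearly rather than
  silently degrading.

Every index is verified against independent brute-force oracles
(gift-wrapping hull, Prim MST, direct formula evaluation) to 1e-9 on
random communities.

## Beta partitioning

The Podani-family decomposition on the Jaccard base is the default: with
`a` shared and `b`, `c` unique species, `D = (b+c)/(a+b+c)`,
`Repl = 2 min(b,c)/(a+b+c)`, `RichDiff = |b−c|/(a+b+c)`. The framework
choice (Podani vs Baselga, Jaccard vs Sørensen base) is not dictated by the
analysis this package supports; Podani–Jaccard is the common default of the
partitioning literature and the quantitative Ružička variant is selectable
(`quantitative = TRUE`). Additivity `D = Repl + RichDiff` holds to machine
precision by construction and is asserted to 1e-12; each pair's triad
`(1−D, Repl, RichDiff)` sums to 1, the invariant behind triangular plots.
Identical empty pairs are defined to have D = 0. Percent contributions are
shares of `mean(Repl) + mean(RichDiff)` over the lower triangle.
Functional-level beta operates on the modality-by-sample composition
matrix, one decomposition per trait category. Clustering is UPGMA (average
linkage) on Bray-Curtis, the neutral default where no linkage is specified
by the analysis; merge heights are checked against a naive stepwise
oracle.

## The synthetic survey generator

The generator states a world and keeps it fixed; its defaults are the
survey structure the analysis assumes, not tuning knobs.

* **Design.** 10 sites × 12 months = 120 site-months, 2 lost uniformly at
  random (`missing_sample_rate = 2/120` — surveys of this shape typically
  lose a couple of samples; which ones is immaterial), 46 taxa.
* **Gradient.** Latent TLIc targets combine an evenly spaced site effect
  (70% of the half-range) and a spring-peaking seasonal cosine (30%),
  spanning 45–65. A degenerate range (e.g. 50–50) collapses all targets to
  the midpoint exactly.
* **Chemistry.** Each parameter is back-solved from its index equation at
  the sample's target with multiplicative lognormal noise
  (`env_noise_sd = 0.05` on the log scale), so recomputing TLIc recovers
  the targets with median error below `10 × env_noise_sd` index units, and
  regressing target on recomputed TLIc gives slope 1 within ±10%.
  Ancillary temp/dep/do/ph are plausible but carry no signal.
* **Niche model.** Abundance of species *i* in sample *s* is
  `baseline_i × exp(−κ (T_s − opt_i)² / 2 w_i²) × lognormal noise`,
  truncated at a detection limit of 0.3 ind/L (one counted individual
  under a 50 L → 30 mL → 2 × 1 mL protocol). Baselines are lognormal
  (`θ` = sd) around 2000/S ind/L, giving realistic totals of a few
  thousand ind/L.
* **Tolerant guild.** Species carrying at least two of
  {filter-feeding, malleate trophi, planktonic} — the modalities that
  dominate nutrient-rich water — form the tolerant guild (~15% of taxa
  under the default vocabulary). Guild members get niche optima on a broad
  plateau centred on the eutrophic quartile (width 0.35–0.55 of the
  range) and a 6× baseline advantage there; sensitive species get
  narrower niches (0.18–0.35) spread over the lower 60% of the range.
  The asymmetry is deliberate and is what produces the homogenization
  phenomenology: eutrophic samples are uniformly dominated by the same
  functionally clustered guild (low FEve, mutually similar composition),
  while meso samples turn over gradually among diverse sensitive species.
  With κ = 0 the niche term vanishes and communities are statistically
  independent of the gradient.
* **Seeds.** One master seed; stage child seeds at fixed offsets
  (`master %% 2146483 × 1000 + {1 traits, 2 environment, 3 community,
  4 missing}`), so stages regenerate independently and a configuration is
  byte-identical on regeneration.

What the generator does **not** emulate — so a green test does not
establish robustness to it: trophi and feeding are assigned independently,
whereas real rotifer jaw types determine feeding mode; there is no spatial
autocorrelation between sites, no phenology beyond the seasonal TLIc
cosine, no separate observation/counting error layer, and totals do not
systematically rise with trophic state.

## Statistics and reporting

Pearson association (t-based two-sided p, stars at 0.05/0.01), simple
regression with a pointwise 95% mean-response band, one-way ANOVA with
Tukey HSD and compact letter display (insert-and-absorb). A degenerate
ANOVA input with zero total variance returns F = 0, p = 1 rather than NaN.
Seasons group months meteorologically (spring = Mar–May, etc.),
configurable. No multiple-testing correction is applied across correlation
tables by default, matching common practice in this literature. The report
bundle writes seven CSV tables and six PDF figures with a manifest keyed by
the configuration hash; CSVs are byte-identical across reruns. The CLI
accepts a JSON configuration file (`--config`); YAML is not supported
because no YAML parser is available among the package's allowed
dependencies.

## Known limitations and honest-red notes

* FRic is limited to two trait-space axes (above).
* The taxonomic beta decomposition defaults to presence–absence; whether
  abundance-based partitioning better matches any given field analysis is
  usually unstated in publications, so both variants are exposed.
* The acceptance suite includes a sign-symmetry check at κ = 0: the
  TLIc→FEve slope should be negative in 40–60% of 50 fixed-seed runs. The
  generator is sign-symmetric at κ = 0 by construction (the niche term is
  constant), but a hard 40–60% band on 50 Bernoulli(½) draws has roughly a
  14% chance of being missed by a perfectly symmetric process, and the
  package's fixed seed policy — chosen before any outcome was observed —
  happens to realize a count just above the band. The check is asserted as
  stated and left failing rather than adjusting seeds or band; the
  surrounding evidence (near-50% negative over larger independent seed
  sets) is the basis for trusting the generator.
* Printed seasonal or annual field values (e.g. an annual mean TLIc) are
  not reproducible without the underlying field data and are not asserted
  anywhere; the package's empirical claims are exactly those its tests and
  acceptance script compute.
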