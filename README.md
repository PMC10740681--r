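# rotifd

Trait-based functional diversity and beta-diversity partitioning for
zooplankton (rotifer) communities along eutrophication gradients.

Urban-river eutrophication is thought to *homogenize* plankton communities:
as nutrient levels rise, a few tolerant, functionally similar taxa come to
dominate everywhere, so communities become more alike in their trait
composition even when taxonomic turnover stays high. `rotifd` packages the
quantitative machinery needed to test that hypothesis on a monthly
multi-site survey — or on synthetic surveys it can generate itself — for
community ecologists working with categorical trait data and water
chemistry.

## What it computes

**Composite trophic level index.** Each water-chemistry parameter *x_j*
(Chl-a in mg/m³, TP and TN in mg/L, transparency SD in m, COD_Mn in mg/L)
is scored as

    TLI_j = 10 (a_j + b_j ln x_j)

and combined with correlation-derived weights
*W_j = r_j² / Σ r_j²* into the composite

    TLIc = Σ_j W_j · TLI_j ,

classified oligotrophic (< 30), mesotrophic (30–50) or eutrophic (> 50).
Two coefficient sets ship: the standard `"canonical"` set (transparency with
a negative slope) and an `"as_printed"` set reproducing a corrupted
published variant; the result records which set was used.

**Trait space and functional diversity.** Taxa are classified by four
categorical traits (trophi 7 modalities, size 3, feeding 4, swimming 3).
Pairwise Gower distances (mean per-category mismatch) are embedded by
principal coordinate analysis with the Cailliez additive correction when
negative eigenvalues occur; on the first two axes the package computes, per
sample, the standard distance-based indices

* **FRic** — convex-hull volume of the present taxa,
* **FEve** — minimum-spanning-tree evenness of abundance, in [0, 1],
* **FDiv** — abundance-weighted divergence from the hull centroid, in [0, 1].

**Beta-diversity partitioning.** Pairwise total dissimilarity is split in
the Podani framework into species **replacement** (Repl = 2 min(b,c)/(a+b+c)
on the Jaccard base) and **richness difference** (RichDiff = |b−c|/(a+b+c)),
with D = Repl + RichDiff exactly and the triad (Sim = 1−D, Repl, RichDiff)
summing to 1 per pair — the coordinates of the classic triangular plot. A
quantitative (Ružička) variant, Bray-Curtis matrices, UPGMA dendrograms
(Newick export) and percent contributions of the two components are
included, along with Pearson/regression/ANOVA-Tukey reporting.

**Synthetic surveys.** `simulate_dataset()` generates abundance, trait and
environment tables with the structure such field studies assume: 10 sites ×
12 months (≈118 samples after losses), 46 taxa, a mesotrophic-to-eutrophic
TLIc gradient (45–65), and Gaussian-niche environmental filtering in which a
functionally clustered tolerant guild dominates eutrophic samples. The
filtering strength κ (0 = neutral) and dominance concentration θ are
configurable, and the latent truth (niche optima, trophic scores) is
returned for parameter-recovery checks.

## Worked example

```r
library(rotifd)
ds    <- simulate_dataset(sim_config(master_seed = 1L))   # 118 samples x 46 taxa
tli   <- composite_tli(ds$environment)
space <- trait_pcoa(trait_distance(ds$traits))
fd    <- fd_indices(ds$community, space)
reg   <- simple_regression(tli$tlic, fd$feve)
dec   <- decompose_beta(ds$community)
```

prints (via the objects' summaries):

```
TLIc: mean 55.01 +/- 4.98, range 45.17-65.35
  eutrophic mesotrophic
         97          21
Trait space: 46 taxa on 2 axis/axes (26.4% of positive eigenvalue mass)
Additive (Cailliez) correction applied, constant 1.066
FEve ~ TLIc: slope -0.0097, R2 = 0.198, p = 0.000
Beta decomposition (podani-jaccard), 118 samples
  mean D = 0.4128 = Repl 0.0894 + RichDiff 0.3234
  contributions: replacement 21.66%, richness difference 78.34%
```

Read: the simulated river is mostly eutrophic (mean TLIc 55); functional
evenness declines significantly as TLIc rises (the homogenization
signature); and richness difference, not replacement, carries most of the
taxonomic beta diversity. `render_report()` writes the full bundle of seven
CSV tables and six figures; the `rotifd` CLI (`inst/exec/rotifd`) exposes
`simulate`, `tli`, `traits`, `fd`, `beta`, `report` and `all` subcommands.

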