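# NicheGradients

Soil bacterial communities respond to afforestation along two distinct axes:
how *abundant* a taxon is, and how *specialized* it is on particular
habitats. `NicheGradients` implements the dual-gradient analysis used in
comparative afforestation studies: every OTU of a count table is classified
once on an **abundance gradient** and once on a **habitat-specialization
gradient**, and the resulting subgroups are then compared across stand types
(shrubland S, coniferous CF, mixed MF, broad-leaved BF) with the standard
community-ecology battery. The package is aimed at microbial ecologists who
have a QIIME-style OTU table plus quadrat metadata and want the whole
pipeline — classification, subgroup diversity, ordination and permutation
tests — reproducible from one seed.

## The two classifications

**Abundance gradient.** With per-sample relative abundances, thresholds
1% (`hi`) and 0.01% (`lo`), and m/n the per-OTU maximum/minimum across the
samples of one soil layer, each OTU falls in exactly one of six categories:

| category | rule |
|---|---|
| AAT (always abundant) | n > 1% in all samples |
| ART (always rare) | m < 0.01% in all samples |
| MT (medium) | 0.01% ≤ n, m ≤ 1% in all samples |
| CAT (conditionally abundant) | n ≥ 0.01% everywhere, m > 1% somewhere |
| CRT (conditionally rare) | n < 0.01% somewhere, never above 1% |
| CRAT (conditionally rare and abundant) | n < 0.01% somewhere **and** m > 1% somewhere |

AAT+CAT collapse to *abundant*, ART+CRT to *rare*, MT+CRAT to *medium*.

**Habitat-specialization gradient.** For OTU *i* with proportions `P_ij` of
its reads across the *r* resource states (quadrats of one layer), Levins
niche breadth is

    B_i = 1 / sum_j P_ij^2 ,   1 <= B_i <= r .

Each observed `B_i` is compared with a null distribution obtained by
redistributing the OTU's total reads over the states 1000 times by a
multinomial draw proportional to state depths ("replacement" null; a
quasiswap matrix null is also available). OTUs above the 95% null quantile
are *habitat-generalized*, below the 5% quantile *habitat-specialized*,
otherwise *habitat-neutral*.

Downstream, the subgroups get per-sample alpha diversity (Shannon, unbiased
Simpson, three evenness indices, richness) with one-way ANOVA + Tukey
letters across stand types, and community structure comparisons: Bray-Curtis
distances, NMDS, ANOSIM, Mantel tests against soil chemistry, plant
diversity, tree/shrub species composition and 3-D spatial distance, and RDA
with Monte-Carlo permutation tests and envfit-style per-variable
significance.

A synthetic-community generator (`simulateCommunity()`) emulates the field
design — 20 quadrats in 4 stand types, two soil layers, lognormal-type
abundance spectra, planted generalist/neutral/specialist archetypes and
abundant/medium/rare classes — so the whole pipeline is testable with known
ground truth.

## Worked example

```r
library(NicheGradients)

sim <- simulateCommunity(simulationParams(seed = 1L))
top <- layerSubset(sim$experiment, "topsoil", dropEmpty = TRUE)

abund <- classifyAbundance(relativeAbundance(top))
subgroupSummary(top, abund)
#>   subgroup n_otus otu_fraction  reads read_fraction
#> 1 abundant     49   0.03266667 864334     0.7217718
#> 2   medium    101   0.06733333 229952     0.1920240
#> 3     rare   1350   0.90000000 103231     0.0862042

niche <- classifyNicheTable(top, nPerm = 1000, seed = 2L)
niche
#> NicheBreadthResult: 1500 OTUs over 20 states; 1000 permutations
#>   (replacement_multinomial, seed 2)
#> generalized     neutral specialized
#>          87         414         999

d <- brayCurtis(top)
anosimTest(d, sampleData(top)$stand_type, nPerm = 999, seed = 3L)
#> ANOSIM : statistic = 1 , p = 0.001  (999 permutations, seed 3)

mantelTest(d, environmentDistance(sampleData(top), "plant_diversity"),
           nPerm = 999, seed = 4L)
#> Mantel (pearson) : statistic = 0.3501 , p = 0.001  (999 permutations, seed 4)
```

Read as: 3.3% of OTUs are abundant yet carry 72% of all reads, while the
90% rare OTUs carry under 9% — the classic abundance/occupancy asymmetry.
Two thirds of OTUs are habitat-specialized (the generator plants 65%
specialists), stand types separate completely in Bray-Curtis space
(ANOSIM R = 1), and community distances correlate with plant-diversity
distances (Mantel r = 0.35, p = 0.001).

`runPipeline()` chains all stages from one config and writes a TSV bundle
plus a manifest; `inst/scripts/nichegrad.R` is a command-line wrapper for
`simulate` and `run-all`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full default analysis from scratch — simulates the 40-sample
community, classifies both gradients per layer (1000 niche permutations),
computes subgroup summaries and diversity, and runs ANOSIM/Mantel/RDA with
999 permutations — writing the per-stage TSVs next to the JSON report.
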