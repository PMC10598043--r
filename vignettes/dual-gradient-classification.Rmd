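---
title: "Methods: dual-gradient classification of soil bacterial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-gradient classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NicheGradients)
```

This vignette is the package's own account of its methods: the two
classification models and their assumptions, the tunable parameters, what
the synthetic-community generator does and does not emulate, and the
numerical and design choices made where the underlying procedure is
ambiguous in the literature.

## The abundance gradient

All thresholds act on per-sample relative abundances (`relativeAbundance()`),
so classification is invariant to sequencing depth. With `hi = 0.01` (1%)
and `lo = 0.0001` (0.01%), and an OTU's minimum and maximum relative
abundance taken across the samples of one soil layer, the six categories
(AAT, ART, MT, CAT, CRT, CRAT) are defined by strict inequalities —
"greater than" means `>`, "less than" means `<` — so a value exactly at a
threshold falls to the middle rules (MT/CAT/CRT). This literal reading is a
convention, recorded here because it determines borderline assignments.

Two points where the common verbal definitions are ambiguous:

* **CRAT.** Verbal definitions of "conditionally rare and abundant" often
  read like MT ("between 0.01% and 1%"). The only definition that makes the
  six rules a partition — and the one used in the rare-biosphere literature —
  is: below 0.01% in some samples *and* above 1% in others. That is what the
  package implements; the six categories then provably partition every
  classified OTU (property-tested on random tables).
* **Per layer.** Classification runs per soil layer (`layerSubset()`),
  because topsoil and subsoil percentages are reported separately in this
  study design; classifying jointly over both layers is possible but mixes
  sample sets with different communities.

OTUs absent from every analysed sample are excluded (with a logged count),
not classified.

## The habitat-specialization gradient

Levins niche breadth for OTU $i$ over $r$ resource states is
$B_i = 1/\sum_j P_{ij}^2$, where $P_{ij}$ is the proportion of the OTU's
reads in state $j$ (raw count proportions, the convention of the
niche-width tools this analysis descends from). $B_i$ runs from 1 (confined
to one state) to $r$ (perfectly uniform), and is invariant to state order.

Design choices, each one switch away from its alternative:

* **Resource state = quadrat (sample) within a layer** (default).
  Aggregation to stand types (`aggregateStates(..., "stand_type")`) is
  offered for sensitivity analysis; with only 4 states the null becomes much
  coarser.
* **Read counts, not presence/absence.** $P_{ij}$ are proportions of
  abundance; an occurrence-frequency variant would discard the evenness
  information that $B$ exists to measure.
* **Null model** (default `replacement_multinomial`): each replicate
  redistributes the OTU's total reads across states by a multinomial draw
  with probabilities proportional to state total reads — literally placing
  each read at random "with replacement", respecting unequal depths. A
  whole-matrix `quasiswap` null (both margins fixed) is available. A naive
  within-row shuffle is *not* offered: $B$ is invariant to permuting the
  profile, so that null is degenerate.
* **Per-OTU confidence limits.** Each OTU is compared with the 5% and 95%
  empirical quantiles (inclusive/type-7) of *its own* null distribution,
  1000 replicates by default. Ties fall to neutral. Pooling nulls across
  OTUs would mix very different read totals.
* **No rarefaction by default.** The null conditions on the observed state
  depths, so unequal depths are modelled rather than discarded; a
  rarefy-to-minimum switch exists for comparison with rarefied workflows.
* **Seed policy.** `classifyNicheTable()` seeds each OTU's stream as
  `childSeed(seed, otu_id)`, so results are independent of OTU order and any
  single OTU is reproducible standalone via `nullBreadthDistribution()`.

## Alpha diversity

Shannon $H = -\sum P_i \ln P_i$ (nats). Simpson is implemented in the
unbiased finite-sample form $1 - \sum n_i(n_i-1)/(N(N-1))$ on integer read
counts — the form printed with $P_i$ in place of $n_i$ in some sources is
dimensionally inconsistent, and the count-based estimator is the reading
that makes it well-defined. Vegetation data (non-integer importance values)
use the plug-in form $1-\sum P_i^2$ behind `unbiased = FALSE`.

All evenness denominators use natural logs by default, which makes Shannon
evenness and Pielou evenness coincide (their defining formulas then agree);
a `logBase = 10` switch reproduces the base-10 reading. Evenness is
undefined (NA) below richness 2. Subgroup alpha diversity uses raw subgroup
counts without renormalization — every index used is scale-free within a
sample, so renormalizing the subgroup profile would change nothing.

One-way ANOVA group comparisons use Tukey HSD at $\alpha = 0.05$ with a
compact letter display (insert-and-absorb algorithm); groups with fewer than
two observations are excluded with a warning.

## Community comparisons

* **Bray-Curtis on relative abundances** (raw-count switch available),
  via `vegan::vegdist`.
* **NMDS**: Kruskal stress-1 via `vegan::monoMDS`, one metric (PCoA) start
  plus random starts, best stress kept, Procrustes-rotated to the PCoA
  configuration for orientation stability, column-centred.
* **ANOSIM**: $R = (\bar r_B - \bar r_W)/(n(n-1)/4)$ on distance ranks.
  (Some write-ups print the denominator as $M/4$ with $M = n(n-1)/2$; that
  normalization puts $R$ in $[-2, 2]$ and contradicts $R = 1$ at maximal
  separation, so the package uses the standard $n(n-1)/4$.) With
  `exact = TRUE` (n ≤ 8) all label permutations are enumerated and
  p = #{null ≥ observed}/n!, identity included.
* **Mantel**: Pearson correlation of lower triangles by default (Spearman
  optional — reported Mantel tables rarely say which; Pearson is the common
  default), null by simultaneous row/column permutation of the second
  matrix. A constant matrix is a degenerate input and errors.
* **Spatial distance**: local equirectangular projection about the centroid
  (1° lat = 111,320 m; 1° lon = 111,320·cos(mean lat) m) plus elevation,
  3-D Euclidean. Adequate for extents of a few km; do not use across large
  latitude spans.
* **Environmental distances**: Euclidean on z-standardized variables (soil
  chemistry, plant diversity) — standardization is assumed rather than
  stated in most Mantel tables, and makes distances unit-free; Bray-Curtis
  on species importance values (tree/shrub composition).
* **p-value convention**: all sampled permutation tests report
  $(1 + \#\{null \ge obs\})/(1 + n_{perm})$, which can never return 0 and
  matches the customary 999 permutations.

## Redundancy analysis

The community table is Hellinger-transformed by default (square root of
relative abundances — the standard pre-treatment that makes species data
suitable for a linear method; a raw/centred switch exists and the choice is
logged in output metadata). Explanatory variables are z-standardized;
factors expand to treatment-coded indicators; aliased columns are dropped
with a warning. Constrained axes are the PCA of the fitted values of the
multivariate regression; `constrainedFraction` equals $1 - RSS/TSS$ and the
eigenvalue sums conserve total variance to 1e-9 (validity-checked). The
model test uses pseudo-$F$ with rows of the response permuted; per-variable
significance uses envfit-style marginal $r^2$ on the constrained axes
(matching the vector-fitting tool named in the field's workflows) rather
than marginal anova-by-term — the two interpretations are one switch apart
in the code.

## What the synthetic generator emulates — and what it does not

`simulateCommunity()` states the emulated world once, as defaults: 20
quadrats (3 S / 3 CF / 3 MF / 11 BF), two soil layers per quadrat, 1500
OTUs, per-sample depths uniform on 46,595–73,284 reads, abundance classes
3% / 7% / 90% (abundant / medium / rare), archetypes 5% / 30% / 65%
(generalist / neutral / specialist). Soil covariates are drawn around
stand-and-layer-specific means and SDs calibrated to published
field measurements of these forest types; `covariateEffect` scales the
between-stand differences (0 = fully decoupled, with pooled SDs). Plant
importance vectors are Dirichlet draws over stand-specific species pools.

Key mechanisms:

* **Class-banded abundance spectrum.** Medium and rare OTUs are placed
  log-uniformly (via a lognormal rank transform) inside expected
  relative-abundance bands (medium 0.15–0.26%, rare 0.004–0.0095%); the
  abundant class absorbs the remaining read mass, keeping each sample's
  expected composition summing to 1 while planted abundant OTUs stay above
  1% and planted rare ones below 0.01%. The rare band sits just under the
  0.01% threshold deliberately: at 46–73k reads this is the realistic
  detection-limit regime after singleton removal (2–5 reads per sample),
  and it leaves planted rare specialists enough total reads (≈25+) for the
  Levins null to separate them — far rarer taxa are *undetectable as
  specialists in principle*, because a handful of reads cannot distinguish
  concentration from chance. Infeasible class targets (more OTUs forced
  above 1% than read mass allows) error before sampling.
* **Habitat filtering.** A specialist's expected abundance is multiplied by
  `habitatEffect` in its home stand(s) and divided by it elsewhere; the
  specialist pool is then renormalized within each sample so that the
  pool's total expected mass is preserved. Without this pool
  renormalization, strong effects would implicitly dilute *every* other
  OTU in specialist-rich samples and destroy the planted abundance bands.
  The default `habitatEffect = 4` keeps planted classes recoverable; the
  recovery tests for the niche gradient run at 100, where a specialist is
  essentially absent outside its home stands. At such extremes planted
  *abundant* specialists legitimately migrate to CRAT (below 0.01%
  somewhere, above 1% elsewhere) — the category exists precisely for them —
  so abundance-class recovery is evaluated at the default effect size.
* **Perfectly even generalists.** By default (`evenGeneralists = TRUE`)
  planted generalists receive a deterministic depth-proportional read
  allocation instead of a multinomial draw. This is a deliberate deviation
  from "everything multinomial", forced by a distributional fact: a
  multinomially drawn generalist is *identical in law* to the
  replacement-multinomial null, so it would exceed the null's 95% quantile
  exactly 5% of the time — generalist recovery would equal the false-positive
  rate no matter how large the community. Only sub-multinomial evenness is
  detectable as "generalized"; the flag restores multinomial generalists for
  users who want the null-calibration behaviour.
* **Layers as correlated replicates.** Both layers share the OTU plan
  (expectations, archetypes, home stands) with independent sampling noise,
  so topsoil/subsoil contrasts exist without being confounded with stand
  type.

Not emulated: sequences or read-level artifacts (chimeras, clustering),
taxonomy, phylogenetic structure, distance-decay in space (coordinates are
independent of community composition, so spatial Mantel tests are null by
construction), and any coupling between soil chemistry and the microbial
community (covariates differ by stand, but the community responds to stand
only through the planted specialists). A green recovery test therefore
establishes that the estimators find planted structure at realistic depths
and design sizes — not that real communities follow these mechanisms.

## Numerical conventions, in one place

* Empirical quantiles: inclusive (type 7).
* Ties at null quantiles: neutral; ties at abundance thresholds: middle
  categories.
* Sampled permutation p: $(1+k)/(1+n_{perm})$; exact enumeration p:
  $k/n!$ with the identity counted.
* Eigenvalue/variance conservation tolerance: 1e-9 (class validity).
* Distance-matrix validity: symmetry within 1e-12, exact zero diagonal.
* Seeds: every randomized stage takes an explicit integer seed; the
  pipeline derives per-stage seeds as `childSeed(master, stage_name)`
  (a fixed 31-bit multiplicative scheme), so adding a stage never perturbs
  another stage's stream.

## Known limitations

* The type-I error of the niche classification is what the quantile rule
  implies (about 5% generalized and 5% specialized under the null per OTU);
  no multiplicity correction is applied across OTUs, matching standard
  practice for this classification.
* ANOSIM with the very unbalanced design (11 vs 3) has limited power for
  contrasts among the small groups.
* The equirectangular spatial projection ignores Earth curvature beyond the
  cosine correction; fine at the study extent, wrong at continental scale.
* `quasiswap` nulls require tables with checkerboard units; dense tables
  without zeros cannot be randomized under fixed margins and error
  accordingly.
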