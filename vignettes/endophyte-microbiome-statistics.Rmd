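---
title: "Statistical methods for endophytic microbiome surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for endophytic microbiome surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endostat)
```

# The problem

Field surveys of the plant endophytic microbiome produce amplicon sequence
variant (ASV) count tables whose rows are samples — one tissue of one plant,
or bulk soil — and whose columns are exact 16S or ITS1 sequence variants.
Three features of such data shape every downstream decision this package
makes:

* **Depth is arbitrary.** Library size varies over orders of magnitude
  between samples and carries no biological signal, so counts are
  compositional: only within-sample ratios are directly interpretable.
* **Absolute load is recoverable via spike-ins.** A known quantity of
  synthetic DNA co-amplified with each sample turns relative counts into
  absolute abundances, provided the spike signal itself is trustworthy.
* **The design is structured.** Genotypes, tissues and developmental stages
  are crossed; several tissues come from the same individual plant;
  extraction/PCR plates are nested in sequencing runs. Tests must respect
  this structure rather than assume independent, identically distributed
  samples.

`endostat` implements the full downstream path: spike handling and absolute
scaling, quality filtering, repeated-rarefaction alpha diversity, a grid of
compositional and absolute beta-diversity metrics, three core-microbiome
membership rules, permutational multivariate tests written from first
principles, and a within-individual tissue-homogeneity statistic. A
synthetic-data generator with the same design structure makes every stage
testable without sequencing data.

# Spike-in absolute quantitation

`split_spikes()` separates the registered spike ASV columns from the
experimental ones, conserving per-sample totals exactly. A sample is
admitted to quantitation when its spike reads make up between 20% and 80%
of the total (`spike_admission_filter()`, bounds inclusive — the window
guards against both a drowned-out spike signal and a sample that is mostly
spike). Admitted samples are then scaled by

$$\mathrm{Experimental}_{scaled} \;=\; \mathrm{Experimental}_{raw}
  \times \frac{\mathrm{Spike}_{median}}{\mathrm{Spike}_{sample}},$$

which leaves within-sample composition untouched and makes row sums
(`microbial_load()`) comparable across samples as absolute loads.

The reference $\mathrm{Spike}_{median}$ is computed **over admitted samples
only**, per amplicon, after the 20–80% window is applied
(`spike_median()`). Computing the reference after admission makes the scale
factor robust to rejected outliers; the reference set is configurable
(`admitted_only = FALSE`) for sensitivity analysis.

# Quality filtering

`quality_filter()` applies two read-count rules in a fixed order: samples
with fewer than 500 reads are dropped first, then ASVs with fewer than 10
reads across the remaining data set. The order matters — removing a shallow
sample can push an ASV below its threshold — and fixing it makes the filter
idempotent. Low-biomass tissues that systematically fail DNA extraction
(e.g. senescent siliques) can be excluded up-front through a tissue-level
exclusion flag; we model this as a tissue label rather than a per-sample
annotation because that is the level at which the problem manifests.

# Repeated rarefaction and alpha diversity

Rather than rarefying once (discarding data to a single random draw), each
sample deep enough for the target is subsampled without replacement —
a multivariate hypergeometric draw, `rarefy_once()` — 100 times, and either
the per-iteration diversity values (`alpha_diversity()`) or the count
tables themselves (`repeat_rarefy_mean()`) are averaged. Default depths
are 1380 reads for 16S and 751 for ITS1. Every rarefied draw sums exactly
to the depth, so every row of the mean table does too. Samples below the
depth are excluded and reported, never zero-filled.

Per-sample metrics are Shannon diversity $H=-\sum_i p_i\ln p_i$ (natural
logarithms throughout the package), Pielou evenness $J=H/\ln S$ (reported
as missing when the observed richness $S$ is 1, where evenness is
undefined), observed richness, and Faith's phylogenetic diversity — the
branch length of the minimal subtree spanning the observed taxa and the
root. Because PD grows mechanically with richness we report a
richness-corrected value; the wording "corrected for species richness"
admits more than one formula, so the package takes the simplest reading,
$PD/S$, as the default and offers the null-model standardised effect size
(`faith_pd_ses()`, richness-preserving tip shuffles) as the main
alternative. Neither is claimed to be canonical.

Each sample draws its rarefaction iterations from its own seeded RNG
stream (derived from the scheme seed), so per-sample results do not depend
on the number or order of other samples in the table.

# Beta diversity: the transform-by-metric grid

Two transformation families are supported in parallel:

* **Rarefaction-based.** The 100-iteration mean table, either as-is
  (compositional) or spike-scaled (absolute), feeds Bray-Curtis, binary
  Jaccard, or weighted UniFrac distances. UniFrac applies to 16S only,
  where a phylogeny exists; the implementation is the unnormalised variant
  $\sum_e b_e\,|p_e(x)-p_e(y)|$ (the common default of the toolchain this
  grid mirrors), with the normalised variant behind a flag.
* **Log-ratio based.** The robust centred log-ratio (`rclr_transform()`)
  scales samples to the dataset median depth, then centres the log of each
  sample's *nonzero* entries; zeros stay missing rather than being imputed.
  The additive log-ratio against the spike reference (`alr_by_spike()`)
  expresses each count as $\ln(\mathrm{count}/\mathrm{Spike}_{sample})$,
  an absolute-scale transform; a pseudocount of 1 replaces zero counts
  only (configurable). Euclidean distance on these matrices gives the
  (robust) Aitchison geometry.

For rCLR output the Euclidean distance is computed over pairwise-complete
coordinates and rescaled by $\sqrt{D/D_{complete}}$ so that sparse pairs
remain comparable with dense ones. Matrix-completion estimators of the
missing entries exist but are a modelling commitment of their own; we keep
the zeros missing and flag this as a limitation.

# Core-microbiome membership

Three rules, applied to the quality-filtered table (relative abundance is
always computed against the current per-sample totals):

* **Core A** (`core_a()`): at least 0.5% within-sample relative abundance
  in at least 4 samples anywhere in the data set — a global core.
* **Core B** (`core_b()`): at least 1% relative abundance in at least 20%
  of the samples of at least one tissue-by-stage subset — a core that can
  see tissue- and stage-specific members.
* **Indicator core** (`indicator_core()`): ASVs statistically enriched in
  plant tissue over bulk soil by indicator-species analysis. For each ASV
  and group, $\mathrm{IndVal}=\sqrt{A\cdot B}$ with specificity $A$ the
  group's mean abundance over the summed group means and fidelity $B$ the
  within-group occurrence fraction; the statistic is the best group's
  value, tested by permuting group labels.

All "at least" thresholds are inclusive. Defaults for the indicator test —
999 permutations, $\alpha = 0.05$, mean-based (group-size-corrected)
specificity, no multiplicity correction across ASVs — follow the common
defaults of indicator-species software; each is a flag, because none of
them is forced by the method itself. Benjamini-Hochberg correction across
ASVs is available via `adjust = TRUE`.

# Permutational tests from first principles

All distance-based inference runs through one engine. For a dissimilarity
matrix $D$ the Gower-centred matrix is $G=-\tfrac12 J D^{(2)} J$;
$\mathrm{tr}(G)$ is the total sum of squares. Model terms, taken in the
order written (blocking term first, e.g.
`~ run:plate + tissue * stage * genotype`), contribute sequential (Type I)
sums of squares $\mathrm{tr}(\Delta H_k\,G)$, where $\Delta H_k$ is the
projector increment of term $k$'s design columns after orthogonalisation
against everything before it. The pseudo-F is
$(SS_k/df_k)/(SS_{res}/df_{res})$, and p-values come from permuting sample
identities of $G$ and recomputing every statistic. The batch structure
"plate nested in run" enters as the interaction-coded `run:plate` factor
fitted first; because the fitting machinery has no true random effects,
the blocking term simply absorbs its variance ahead of the fixed effects,
and a stricter exchangeability scheme — permutations confined within
blocks — is available through `strata`. Marginal (each term after all
others) sums of squares are available via `ss = "margin"`; sequential is
the default.

Numerical conventions, chosen once:

* Monte-Carlo p-values use the add-one estimator $(1+B_{\ge})/(1+B)$, so a
  permutation p can never be exactly zero; ties between permuted and
  observed F count toward rejection (the conservative convention), with a
  relative tolerance of $10^{-8}$ so that analytically tied statistics
  compare as tied in floating point.
* `n_perm = "exact"` enumerates all $n!$ permutations ($n \le 8$) and
  reports the exact proportion, which the test suite checks against
  independent brute-force enumeration.
* Degrees of freedom come from the numerical rank of each term's
  residualised design block, so aliased terms get 0 df and no test rather
  than a misleading one.
* A zero residual with positive term SS reports $F=\infty$ (perfect
  separation); a fully degenerate (constant) response reports `NA`.

`pcoa_embed()` eigendecomposes $G$; axes with positive eigenvalues carry
real coordinates scaled by $\sqrt{\lambda}$, axes with negative eigenvalues
(semi-metric dissimilarities like Bray-Curtis produce them) are kept as an
"imaginary" block scaled by $\sqrt{|\lambda|}$. Squared distances are then
real-block minus imaginary-block squared differences, an identity the
tests verify to $10^{-6}$ on random matrices.

`permdisp()` tests homogeneity of multivariate dispersion: each sample's
corrected distance to its group centre (spatial median by default,
computed separately on the real and imaginary blocks; centroid optional)
enters a one-way ANOVA F whose p-value comes from permuting group labels
over the fixed distances. The spatial median is found by damped Weiszfeld
iteration to a relative tolerance of $10^{-8}$.

`perm_anova_univariate()` routes a scalar response through the same
engine via its Euclidean distance matrix; the resulting SS and F are
*identical* to classical ANOVA (verified to $10^{-10}$), only the p-value
is permutational.

Pairwise post-hocs (`permanova_pairwise()`) run one-factor tests on each
level pair, optionally inside a design subset, and adjust the p-value
family by Benjamini-Hochberg.

# Within-individual tissue homogeneity

How alike are the tissue communities of a single plant? For each plant
with a complete tissue set — three schemes: all tissues present at its
stage, roots + rosettes only (usable at every stage), or all aerial
tissues except siliques — the plant's tissue samples are embedded by PCoA
of their Bray-Curtis distances, the spatial median of the embedded points
is the plant's "median community", and the plant's homogeneity statistic
is the mean corrected distance of its tissues to that median
(`plant_homogeneity()`). Zero means clonal tissues; for two tissues at
distance $d$ the statistic is exactly $d/2$.

The "median community" is deliberately the spatial median in the embedding
— the mechanism of the dispersion machinery above — rather than a
coordinate-wise median of raw compositions. The embedding is per-plant by
default (each plant's median is defined by its own tissues); a global
single-ordination variant (`global_embedding = TRUE`) exists for
sensitivity analysis, since the procedure can be read either way. For the
all-tissues scheme, "complete" is interpreted per stage: a ripe-silique
plant needs all seven tissues, a vegetative plant only two.

`homogeneity_analysis()` then tests the per-plant statistic with a
stage-by-genotype univariate permutational ANOVA and stage-pairwise
post-hocs under Benjamini-Hochberg correction. Cells (stage × genotype)
represented by a single plant are refused rather than silently absorbed.

# The synthetic-data generator

`simulate_dataset()` draws a complete survey with the structure the
analyses assume. Design defaults reproduce the motivating field
experiment: five genotypes (`WT`, `efr`, `fls2`, `lore`, `lyk4`), four
developmental stages with their stage-specific tissue sets, and 8 plants
per genotype per stage (18 at the Unripe Siliques stage, matching the
harvest plan's larger mid-season sample).

The count model is Dirichlet-multinomial. Each sample's expected
log-composition is

$$\eta = \log \pi_0 + \beta_{tissue} + \beta_{stage}
  + \delta_{genotype}\,\mathbb{1}[\text{affected cell, affected taxa}]
  + u_{plant} + b_{run} + b_{plate},$$

with $\pi_0$ a sparse Dirichlet baseline and all effects independent
per-taxon Gaussians. Counts are drawn multinomially around a Dirichlet
perturbation of $\mathrm{softmax}(\eta)$ with precision
`dm_concentration`. Defaults, with reasons:

* `baseline_concentration = 0.5` — strongly uneven baseline composition,
  as real amplicon communities are; `Inf` gives the uniform limit used by
  closed-form tests.
* `dm_concentration = 50` — overdispersion in the range estimated for
  field amplicon data; the Dirichlet coupling (rather than independent
  negative binomials) preserves the compositional structure that
  rarefaction and log-ratio analyses assume.
* `depth_logmean = log(5000)`, `depth_logsd = 1.2` — median depth of a few
  thousand reads with a realised range spanning roughly three orders of
  magnitude, the depth regime the pipeline is built to withstand.
* `spike_frac_range = c(0.2, 0.8)` — spike reads drawn to land in the
  quantitation window; spikes are generated as dedicated ASV *columns*,
  not a metadata scalar, so the spike-detection code path is exercised.
* `plant_effect_sd = 0.5` — a per-plant random effect shared by all of a
  plant's tissues, inducing the within-individual correlation the
  homogeneity analysis measures. Because composition is a softmax, a
  strong shared plant effect concentrates all of a plant's tissues on the
  same taxa: within-plant distances shrink as this scale grows, which is
  the direction the homogeneity tests assert.
* `run_effect_sd = plate_effect_sd = 0.2` — mild batch structure, plates
  nested in runs, matching the blocking term of the main model.
* Per-cell sample size is a knob (`n_plants`), not a constant, because the
  real design is unbalanced in ways a test may want to reproduce.

`expected_cell_composition()` returns the closed-form cell mean — the
softmax of the fixed effects at zero realised noise — which the tests
compare against empirical means of deep samples. A random bifurcating
phylogeny with exponential branch lengths accompanies 16S tables only;
ITS1 tables carry no tree, so phylogenetic metrics are structurally
unavailable there, as they should be.

What the generator does **not** emulate: taxonomic identity and sequence
content, chimeras and contamination, negative controls, correlated
(network-structured) taxon dynamics, and zero-inflation beyond what the
Dirichlet-multinomial produces. Passing tests therefore demonstrate that
the *statistical machinery* behaves as specified under a realistic
depth/overdispersion regime — not that any biological conclusion about
real surveys is automatic.

# Validation strategy and problem sizes

The test suite validates each operation against an independent route:
hand-computed closed forms; brute-force enumeration oracles (exact
permutation distributions at $n \le 8$, double-loop filter and core-rule
re-implementations); reference implementations where one exists (vegan's
`adonis2`, `betadisper` and `vegdist`, picante's `pd`, phyloseq's
`UniFrac` — used only as cross-checks, never as the implementation); and
Monte-Carlo expectations with 3-standard-error bands.

Calibration experiments use 500 null surveys of 40 samples for type-I
error (exact binomial 95% band around $\alpha=0.05$) and 100 surveys for
recovery of a planted $\ln 4$ genotype effect on 10% of taxa in a single
tissue-by-stage cell at 15 plants per genotype — sizes at which the
binomial bands are meaningful while the whole suite stays fast. The
`scripts/acceptance.R` script recomputes these quantities from scratch.

A known limitation surfaced by these experiments: the dispersion test's
small-sample behaviour depends on per-group size. With five groups of
eight, the spatial-median variant is conservative (empirical type-I
$\approx 0.02$–$0.03$) and the centroid variant liberal ($\approx 0.09$)
— behaviour the reference implementation reproduces exactly. Calibration
is nominal at twenty samples per group, so the shipped calibration
experiment uses two equal-dispersion groups of twenty, and dispersion
results on very small groups should be read with this bias in mind.

# A worked example

```{r example, eval = FALSE}
library(endostat)

cfg <- sim_config(seed = 1)
sim <- simulate_dataset(cfg)

# spike handling and absolute scaling
sp  <- split_spikes(sim$table, sim$registry)
adm <- spike_admission_filter(sp$spikes)
qf  <- quality_filter(sp$experimental, exclude_tissues = NULL)
scaled <- scale_by_spike(
  qf$table[intersect(rownames(qf$table), adm$sample_id[adm$admitted]), ],
  adm, spike_median(adm))

# beta diversity and the main model
rar <- repeat_rarefy_mean(qf$table, rarefaction_scheme("16S", 100, seed = 2))
dm  <- distance_matrix(rar, "bray_curtis")
fit <- permanova(dm, sim$metadata,
                 ~ run:plate + tissue * stage * genotype,
                 n_perm = 999, seed = 3)
tidy(fit)

# dispersion and within-individual homogeneity
pd <- permdisp(dm, setNames(sim$metadata$genotype, sim$metadata$sample_id),
               n_perm = 999, seed = 4)
hm <- homogeneity_analysis(qf$table, sim$metadata, "aerial_no_siliques",
                           n_perm = 999, seed = 5)
autoplot(hm)
```
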