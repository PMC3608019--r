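---
title: "Methods: dual-evidence inference of glacial refugia"
author: "refugia package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-evidence inference of glacial refugia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Quaternary climate oscillations repeatedly compressed temperate species into
glacial refugia and let them re-expand during interglacials. Two independent
footprints of that history are recoverable today:

1. **Genetic**: populations that persisted in refugia accumulate and retain
   haplotype diversity, while recently (re)colonised areas carry few, similar
   haplotypes — "southern richness and northern purity". Where species
   displaced one another after secondary contact, individuals of one species
   carry the mitochondrial DNA of another (asymmetric introgression).
2. **Environmental**: a species distribution model (SDM) calibrated on
   current occurrences and climate, projected onto Last Glacial Maximum
   (LGM) climate reconstructions, maps where suitable conditions persisted.

This package implements both evidence streams as a tested pipeline, plus a
synthetic-data generator that provides ground truth (true refugia, true
contact zones, planted introgression) so that every stage can be validated
quantitatively — something impossible with real data alone.

# The genetic stage

## Statistics

For one aligned mitochondrial locus (sequences of equal length, alphabet
`A,C,G,T,N,-`), identical sequences are collapsed into haplotypes, and two
spatial statistics are computed per species after introgressed mtDNA has
been removed:

* **Within-population diversity** $\pi$: the mean number of pairwise
  nucleotide differences over all unordered pairs of individuals in a
  population (units: nucleotide differences). Sites with `N` or `-` in
  either sequence of a pair are excluded (pairwise deletion). Populations
  with a single sequence are skipped — $\pi$ would be trivially zero.
* **Among-population divergence** $Z_i$: populations are joined by a planar
  Delaunay triangulation; each edge receives the mean proportion of
  mismatched nucleotide sites over all cross-population sequence pairs,
  placed at the arithmetic midpoint of the two populations.

Both point sets are interpolated over the study grid by inverse distance
weighting (IDW), cropped to the species' range polygon, and assembled into
multi-species composites under two scalings: a **global** min–max scale
(directly comparable across species, but genetically poor species flatten)
and a **species-specific** scale (full contrast within every species). Both
are produced because each answers a different question; the global scale can
hide all structure in a species whose diversity is an order of magnitude
below its neighbour's.

## Introgression detection

Haplotypes (plus an outgroup sequence) are clustered with neighbor joining
on uncorrected p-distances. No substitution-model correction is applied: the
divergences involved are shallow, and the divergence statistic itself
($Z_i$) is defined on raw mismatch proportions. Negative branch-length
estimates are clamped to zero. Bootstrap support (default 1000 column
resamples in the field's convention; 100 in the package default for speed,
configurable) annotates internal edges; the conventional significance
threshold is 80%.

After rooting on the outgroup (root placed at the midpoint of the
outgroup's pendant edge), haplotypes are assigned to mitochondrial lineages
in two steps:

1. **Cut first**: the rooted ingroup tree is cut into as many maximal
   lineages as there are species labels, by repeatedly splitting the clade
   with the largest tip-to-tip patristic diameter. With $k$ well-separated
   species this recovers the $k$ reciprocally monophyletic clusters.
2. **Match second**: each lineage is matched to a species by the majority of
   the *individuals* its haplotypes carry (greedy one-to-one matching).

An individual whose labelled species differs from its haplotype's lineage is
flagged *introgressed*; populations are classed `original` / `mixed` /
`introgressed`.

This cut-then-match design is deliberate. The more obvious rule — take, per
species, the smallest clade containing all haplotypes majority-labelled with
it — collapses under bidirectional contact-zone introgression: each species'
label set then contains haplotypes from the other species' cluster, both
clades inflate to the entire ingroup, and the assignment degenerates.
Cutting the tree before consulting the labels keeps the clusters defined by
the genetic structure alone, which is exactly the property the biology
provides (deep inter-species divergence, shallow intraspecific structure).
The limit of the method is reached when within-species structure is as deep
as between-species divergence; the monophyly report and the `ambiguous`
flags surface such cases rather than hiding them.

## Exclusion rules

Two exclusion modes are provided for the spatial statistics.
`"population"` (default) removes every population containing at least one
introgressed individual; `"individual"` removes only the introgressed
individuals. The population-level rule is the default because retention
accounting is then defined at the population level (total, kept for $Z_i$,
additionally kept for $\pi$ after dropping singletons), the format used in
classical surveys of this kind; the individual-level rule retains more data
and is available for analyses where that is preferred.

# The SDM stage

## Model

The SDM is an L1-penalised Gibbs (maximum-entropy) model restricted to
**hinge features**: for each climate variable $x$ with background range
$[x_{\min}, x_{\max}]$, forward hinges $\max(0, x-k)/(x_{\max}-k)$ and
reverse hinges $\max(0, k-x)/(k-x_{\min})$ with knots $k$ at equally spaced
quantiles of the background values (default 30 per direction; the pipeline
default uses 10 on the synthetic grids, where climate is two smooth fields
and denser knots only add redundant features). Hinge-only features produce
smooth, monotone-by-parts response curves, which transfer better across time
than wiggly feature classes — the reason to prefer them when projecting to
the LGM.

With $\eta(x) = \sum_j w_j f_j(x)$, the fit maximises

$$\sum_{i \in \text{presence}} \eta(x_i) \;-\; n \log \sum_{b \in
\text{norm}} e^{\eta(x_b)} \;-\; \sum_j \lambda_j |w_j|, \qquad
\lambda_j = \beta\, s_j / \sqrt{n},$$

where $s_j$ is the feature's standard deviation over the presence sample
(floored at 0.05) and $\beta$ defaults to 1. The normalization set is the
background sample **plus the presence cells** — the convention of the
reference maximum-entropy tool, and a mathematical necessity: without it the
objective is unbounded whenever some feature direction separates every
presence from every sampled background cell, and the weights diverge.

The background is drawn uniformly from a **200 km buffer** around all genus
localities (the area plausibly accessible to the genus), with distances
computed planarly at 111.32 km/degree with a latitude-cosine correction for
longitude. Presence localities are rasterised to cells and deduplicated.

Projection reports the **raw** output $e^{\eta(x)}/Z$ (summing to 1 over the
normalization cells of the training stack) and the **logistic** output
$c\,\mathrm{raw}/(1 + c\,\mathrm{raw})$ with $c = e^H$, $H$ the entropy of
the fitted background distribution. Values outside the training range are
clamped to it.

## Significance

Model quality is assessed without an arbitrary AUC threshold and without
sacrificing localities to a test split: the observed training AUC
(Mann–Whitney form, ties counted half) is pooled with 99 AUCs of models
fitted to the same number of localities drawn uniformly from the buffer.
The model is significant iff the observed value is **strictly greater** than
the 95th smallest of the pooled 100; ties count against significance. Under
the null the observed value is exchangeable with the replicates, so the
test's size is at most 5% by construction; the package verifies ~5%
empirically (200 Monte-Carlo repetitions) in its acceptance suite.

# The synthetic-data generator

The generator is first-class, tested code; it defines the study conditions
under which every recovery property is asserted.

* **Climate**: Gaussian-kernel-smoothed white-noise fields (autocorrelation
  length 6 cells by default), orthonormalized and mixed through a Cholesky
  factor so the realized inter-layer correlation equals the request exactly
  (default 0.2). The glacial counterpart adds a constant per-layer offset;
  the default shifts the first niche layer by −1.2 sd, which carves a
  compact refugium out of each species' range.
* **Species**: Gaussian niches (breadth 0.8 sd) on two layers; range mask =
  suitability ≥ 0.3; refugium mask = suitable under both scenarios; contact
  zone = range cells 8-adjacent to another species' range. Niche anchors are
  chosen at a target environmental distance slightly under two mask radii,
  which reliably produces parapatric ranges with a narrow contact band — the
  genus geometry the method is designed for.
* **Sequences**: 658-bp locus; a root sequence, per-species ancestors (30
  substitutions from the root, so inter-species divergence comfortably
  exceeds the 20 sites needed for clean lineage separation), one founder per
  refugium patch, coalescent-topology genealogies with Poisson(1.5)
  substitutions per branch inside refugial populations (refugial $\pi$
  roughly 3–8 differences), and 0–2 private substitutions per colonist in
  expansion populations (star-like purity). Refugial populations are placed
  away from the contact front where possible: refugia hold long-term
  residents, while introgression is a phenomenon of the recolonised margin.
  Individuals in contact-front populations carry the nearest foreign
  population's haplotype with probability 0.5; every replacement is logged.
  An outgroup sequence (80 substitutions from the root) is emitted because
  downstream rooting requires one. 55 populations × 5 individuals per
  species mirrors the sampling density of a dense multi-species survey
  (~2500 sequences over 9 species scales to ~275 per species).
* **Occurrences**: cell centers sampled without replacement with probability
  proportional to suitability.
* **Species with an empty refugium mask** (harsh glacial shift) fall back to
  a single pseudo-refugium at the best current cell, so simulation still
  runs — the real-world analogue being a species whose LGM refugium the SDM
  fails to recover.

What the generator does **not** emulate: demographically faithful
coalescence (no effective population sizes, growth, or migration matrices),
recombination or heteroplasmy, rate heterogeneity or indels, spatial error
in localities, and real palaeoclimate structure. Passing recovery tests
therefore demonstrates that the pipeline's statistics recover the planted
signal under idealised but structurally realistic conditions — not that any
real dataset will behave as cleanly.

# Numerical choices

* **IDW**: power 2, 12 nearest neighbours (the defaults of the GIS tools
  traditionally used for genetic-landscape interpolation), planar degrees; a
  cell coinciding with a data point (distance < 1e−9 deg) takes its value
  exactly. Surfaces are interpolated on the full grid and cropped
  afterwards, so midpoint values falling outside the range crop are computed
  but masked.
* **Delaunay**: Bowyer–Watson insertion with the in-circumcircle determinant
  predicate and CCW-oriented triangles; the super-triangle is 1e5 times the
  point-cloud extent (a small super-triangle demonstrably distorts hull-near
  edges). Two populations give one edge; collinear sets a path; duplicate
  coordinates are jittered by ~1e−6 degrees with a warning. Co-circular
  ties (e.g. four corners of a square) resolve to one of the equally valid
  triangulations.
* **Entropy fit**: L-BFGS-B on the positive/negative weight split, followed
  when needed by a FISTA (accelerated proximal gradient) polish; convergence
  is declared only when the maximum KKT violation is below $10^{-5} \cdot
  \max(1, n)$, and a non-converged fit is an error, never a silent result.
  Weights start at zero.
* **Composite scaling**: constant surfaces map to 0.5 by convention.
* **NJ ties and negatives**: deterministic agglomeration; negative branch
  estimates clamped to zero.
* **Problem sizes**: validation loops use a 60×60 grid, 200-cell
  backgrounds, 6 hinge knots per direction and 99 null replicates; the
  refugial-recovery loop disables bootstrap resampling, which annotates tree
  edges but enters neither the diversity surfaces nor the flagging
  decision. These sizes were chosen as the smallest at which the studied
  effects are comfortably resolved.

# Evaluating refugial recovery

The headline genetic property — interpolated diversity is higher inside
true refugia than outside — is evaluated as the **mean per-species
contrast** on species-specific-scaled surfaces (`refugial_contrast()`):
for each species, mean scaled $\pi$ inside its refugium minus outside,
averaged over species. Pooling raw cells across species instead would weight
species by range area and mix scales, and a genetically rich species with a
small refugium plus a poor species with a large one can reverse the pooled
sign even when every species individually shows the effect — the same
pathology that motivates the species-specific composite scale in the first
place.

# Known limitations

* Lineage assignment assumes inter-species divergence exceeds intraspecific
  depth; ancient introgression or incomplete lineage sorting would be
  assigned to the donor lineage indistinguishably from recent transfer.
* Planar geometry throughout; adequate for the synthetic extents (a few
  degrees) and for regional studies, but distances distort at continental
  scales. The background buffer applies a latitude-cosine correction; the
  Delaunay and IDW stages do not.
* Training AUC with background pseudo-absences is not an absolute quality
  measure; it is only used comparatively, inside the null-model rank test.
* The null-model test reuses one background sample per species rather than
  resampling backgrounds per replicate; replicates therefore share
  background noise, a documented simplification.
* GeoTIFF input/output is not supported; rasters are read and written as
  ESRI ASCII grids.
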