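---
title: "Methods: spatial proximity, module architecture and consensus labeling in gangliostat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial proximity, module architecture and consensus labeling in gangliostat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gangliostat)
```

gangliostat implements a family of statistics for sensory-ganglion
atlases: spatial organization metrics for segmented in-situ
transcriptomics, post-processing of co-expression module eigengenes,
gene-set overlap enrichment, and cross-dataset consensus labeling. This
vignette records the models, the tunable parameters and their defaults,
the numerical conventions, and the deliberate design choices, so that a
user can judge what each output does and does not mean.

## Spatial proximity

For segmented cells with centroids $(x_i, y_i)$ (µm) and volumes $v_i$,
the pairwise distance and its volume normalization are

$$d_{ij} = \sqrt{(x_i-x_j)^2 + (y_i-y_j)^2}, \qquad
  d_{ij,\mathrm{norm}} = \frac{d_{ij}}{(v_i+v_j)/2}.$$

Soma size differs systematically between neuron types, so raw distances
conflate packing density with size; dividing by the mean volume of the
pair removes the size component. The normalized distance is
unit-bearing (µm per unit volume); no further rescaling is applied, so
its absolute scale depends on the volume units of the input.

The type-distance matrix averages $d_{ij,\mathrm{norm}}$ over all pairs
of the two types. Two conventions here are genuinely open and we fixed
them as follows:

* **Within-type diagonal.** Self-pairs ($i = j$, distance 0) are
  excluded; including them would deflate within-type means by a factor
  that depends on type abundance. A type with a single cell has no
  distinct pair and its diagonal is flagged `NA` rather than 0.
* **Multi-section pooling.** Matrices are computed per section and
  pooled by unweighted mean across sections, so a large section does
  not dominate.

The **neighbor score** maps type distances to $[0,1]$ by min–max
inversion over all finite entries: the closest type pair scores 1, the
most separated 0. No formula beyond "1 = maximum co-localization, 0 = no
overlap" is canonical for this quantity, so the default uses only the
quantities already defined above; a k-nearest-neighbor composition
variant (`neighbor_score(method = "knn")`, symmetrized fraction of each
type's k spatial neighbors belonging to the other type) is provided for
users who prefer a neighborhood-composition reading. The min–max score
is invariant to affine rescaling of the distance matrix, hence also to
global volume rescaling.

Hierarchical ordering of the type matrix treats it directly as a
dissimilarity (average linkage by default). Types are sorted
lexicographically before clustering so ties in merge heights resolve
deterministically.

## Edge zonation

The tissue boundary is the convex hull of all cell centroids of a
section — neuronal and non-neuronal together, since zonation of both
compartments is compared against one common edge; a different subset (or
an explicit polygon, e.g. from image annotation) can be supplied.
Collinear hull vertices are dropped, so the ring is strictly convex, and
the hull of the hull returns the same vertex set. Each cell's edge
distance is the minimum over boundary segments of the point-to-segment
distance; points on the ring get exactly 0. Query points outside the
polygon (possible only with user-supplied polygons) get positive
distances with a warning. Per-type summaries report mean, median,
quartiles and a rank (1 = most peripheral). Concave (alpha-shape)
boundaries are deliberately out of scope: the convex hull is the
convention this statistic is defined on.

## Synthetic tissue generator

`simulate_ganglion()` emulates the measured structure of a ganglion
section — radially zonated, spatially clustered, typed and volumed cells
inside a convex outline — without claiming to be a fitted model of any
real section:

* **Zonation.** Each cell type has a target normalized edge depth
  $q \in [0,1]$; per-cell depths are Beta-distributed,
  $\mathrm{Beta}(qc, (1-q)c)$ with concentration $c = 20$ by default,
  and placed along uniformly random rays from the polygon centre.
  Published work reports measured depth distributions, not a generative
  model, so the Beta family and its concentration are a package choice:
  it is the standard two-parameter family on $[0,1]$ with a mean at $q$,
  and $c=20$ gives clearly zonated but overlapping distributions, which
  is what real sections show. No quantitative zonation effect sizes are
  available to calibrate against, so these defaults are placeholders
  defining the simulation's study conditions, not estimates.
* **Clustering.** A Thomas-type parent–offspring process per type
  (default 15 parents, 25 µm isotropic dispersion) reproduces the
  qualitative observation that same-type cells sit closer to each other
  than to other types. Offspring falling outside the boundary are
  resampled; zero dispersion degenerates to offspring coinciding with
  their parents.
* **Volumes.** Lognormal per type (default meanlog $\log 1000$, sdlog
  0.25): volumes are positive and right-skewed, and only diameters, not
  a distributional form, are typically reported.
* **Reproducibility.** One top-level seed; each generator component
  draws from a deterministic substream obtained by hashing the component
  name into a seed offset, so adding a component never perturbs the
  draws of another.

The generator plants its ground truth (depth ordering, module
memberships and levels, exact overlaps, concordant cell sets), which the
test-suite recovers end-to-end. What passing these tests shows is that
the pipeline's statistics invert the generator's assumptions correctly;
it does not show robustness to features the generator omits —
segmentation errors, anisotropic tissue, 3-D effects, non-Gaussian
expression noise, or empty space occupied by fibers.

## Module architecture

The package consumes a kME table (gene × module correlation to module
eigengenes) from an upstream co-expression pipeline; network
construction itself (metacells, soft power, TOM) is out of scope.

**Redundant assignment.** A gene joins its argmax module and every
module with kME $\ge 0.95 \cdot R_{\max}$, with a floor of 0.3 on any
assignment. Both comparisons are closed ($\ge$): the argmax then always
satisfies its own rule, and exact boundary ties are included. This
redundancy is the point — co-expressed programs overlap, and forcing
unique membership hides that.

**Eigengene.** First principal component of the per-gene standardized
module expression, rescaled to unit variance, sign-fixed so its
correlation with the module's mean standardized expression is
non-negative. A single-gene module degenerates to that gene's
standardized expression.

**Relative magnitude and selection.** For each module, group means and
SDs of the eigengene are computed per cluster and per dataset;
magnitude = max − min of group means; relative magnitude = magnitude /
mean of group SDs. Groups with a single cell have no SD and are excluded
from the SD mean with a warning. Modules are kept when the cluster
relative magnitude is ≥ 3.7 *and* exceeds the dataset relative
magnitude. The published convention excluded dataset-varying modules
without stating the rule; we implement the exclusion as
"cluster-RM ≤ dataset-RM or cluster-RM < 3.7" and report both
quantities per module so users can re-filter under a different rule.

**Digitization.** Cluster means are positioned on the min–max range of
the module: $p_c = (\bar e_c - \min_c \bar e_c)/\mathrm{magnitude}$;
level 0 for $p_c < 1/3$, 0.5 for $1/3 \le p_c \le 2/3$ (closed at both
ends), 1 above. Positions are measured from the minimum cluster mean
rather than from zero: eigengene values are centred and can be negative,
so a fraction "of the magnitude" is only well-defined on the min–max
range. Because positions are min–max normalized, digitization is exactly
invariant to affine transformations of the eigengene. Magnitudes below
$10^{-9}$ flag the profile as degenerate (all levels 0).

**Width and uniqueness.** Signal width = sum of digitized levels across
clusters; uniqueness = $w_{\max}$ − width. By default $w_{\max}$ is the
observed maximum width; fixing `w_max = 10` reproduces the convention of
a 10-wide scale. Width is weakly monotone in levels and uniqueness
anti-monotone in width, exactly.

**Bar decomposition.** Each cluster's identity bar stacks, per active
module, (number of assigned genes) × (digitized level); the per-cluster
total counts "efficient genes".

**Per-cell gene-set score.** Mean expression of set genes minus mean
expression of controls sampled from the same average-expression bins
(24 equal-frequency bins, 100 controls per set gene, with replacement,
seeded). Equal-frequency binning uses a rank with deterministic
tie-break, so the binning itself is reproducible on ties. On a constant
matrix the score is exactly 0 for every cell.

**Regulon dots.** Size = (TF expression statistic, min–max scaled across
types) × (region-set score, scaled); color = scaled gene-set score.
Whether the TF statistic is a mean expression or a percent-expressing
fraction is left to the caller — both are accepted as the input vector.
Constant vectors scale to zeros with a warning.

## Overlap enrichment

Overlap counts restrict both collections to a declared universe (default:
union of all module and regulon genes; a modules-only universe can be
passed for workflows whose background is the module gene list). The
one-sided enrichment p-value is the hypergeometric upper tail
$P(X \ge \text{overlap})$ with $X \sim
\mathrm{Hyper}(N, K{=}|{\rm module}|, n{=}|{\rm regulon}|)$; an overlap
of 0 gives exactly $p = 1$. Adjustment is Benjamini–Hochberg applied
jointly across all grid cells — the adjustment scope (per row vs whole
grid) is not canonical, and the joint scope is the more conservative
choice for the "module has at least one significant overlap" summary,
which is reported per module (grayed rows in the usual heatmap display).
Sidedness is enrichment-only by design; depletion is not a question this
grid answers.

The null calibration study in the tests uses a universe of 100 genes
with 30-gene sets because the discretely achievable test level closest
to 0.05 is then 0.0494, making the empirical rejection rate comparable
to the nominal one; much smaller sets would make the discrete test
strongly conservative and the comparison uninformative.

## Consensus labeling and cross-similarity

**Harmonization and filtering.** Per-source label maps translate every
source vocabulary into one harmonized nomenclature (`"unassigned"`
passes through). A cell is kept iff all sources agree on one harmonized
label, or all its labels fall inside a single declared exempt family —
the convention for label families (such as A-LTMRs) whose cross-dataset
assignment is known to be unreliable at the subtype level.
`"unassigned"` counts as disagreement. The kept set is exactly invariant
to source ordering.

**Classifier.** The published pipelines delegate the classifier to
external packages (mixture discriminant analysis, small neural
networks); the reproducible content is the pipeline logic — feature
selection, min–max scaling, probabilistic scores, a hard cutoff, and the
downstream consensus and similarity constructions. The classifier is
therefore an interface: any
`function(train_x, train_y, test_x) -> probability matrix` can be
plugged in; the default is a ridge-regularized multinomial logistic
model (`nnet::multinom`, decay $10^{-3}$) with softmax outputs, which is
deterministic and adequate for well-separated types. Scores are
renormalized to sum to 1 per cell; the hard label is the argmax when its
score reaches the cutoff (default 0.55), else `"unassigned"`. The cutoff
is applied to the maximum probabilistic score; no additional calibration
is performed. Feature genes default to the union of per-type ranked
markers (best rank across log2 fold change of pseudocounted means and
expressing-fraction difference) and globally most-variable genes, with
an optional user-supplied exclusion list (e.g. cell-cycle genes — no
built-in catalog is shipped).

**Cross-similarity.** Concatenated score profiles are centred and
reduced to their top principal components (default 15, capped at what
the data support with a warning). Each cell's k = 100 nearest neighbors
in that space are computed; a type pair (one type per dataset) is
"connected" when at least one cross-dataset neighbor edge links their
cells. The similarity of a connected pair is the Pearson correlation of
the two types' mean PC profiles; unconnected pairs are floored to the
minimum computed correlation. The published description uses the
neighbor graph to "construct" the correlation metric without a formula;
the gating interpretation — neighbors decide *which* pairs get a
correlation, the PC means decide its *value* — is our documented
default and uses only stated ingredients. Finally a sign-preserving
power transform $\mathrm{sign}(s)\,|s|^{1.25}$ (monotone, so
within-column rankings survive) and column z-scoring produce the display
matrix, whose columns have mean 0 and SD 1 by construction. With two
datasets the matrix is returned as first dataset's types × second
dataset's types; with more, as the full group × group matrix.

## Numerical conventions and problem sizes

* Geometry tolerances: convexity/collinearity tests use a cross-product
  threshold of $10^{-9}$ scaled by the squared coordinate range;
  point-in-polygon is closed (boundary points are inside).
* Degenerate inputs error loudly rather than guess: all-equal type
  distances (neighbor score undefined), zero-variance module genes,
  non-convex explicit polygons, infeasible overlap specifications.
* The test-suite and the acceptance script run at deliberately small
  problem sizes — 30-cell oracle comparisons, 3 000-cell sections over
  20 seeds, 500×10 kME tables, 1 000 null-enrichment replicates,
  480-cell two-dataset similarity over 10 seeds — chosen so the full
  suite completes in well under a minute on one core while keeping every
  stochastic check at 10–20 replicates.

## Known limitations

* 2-D only; no transcript-spot, image or segmentation modeling.
* The convex hull overestimates the tissue for concave sections; edge
  distances near concavities are then underestimated.
* The min–max neighbor score depends on the most extreme type pair in
  the section; comparing scores across sections compares relative, not
  absolute, co-localization.
* The default classifier is linear; strongly non-linear type boundaries
  need a plugged-in classifier.
* kNN gating with large k on small datasets connects almost all type
  pairs, making the floor inactive; with very small k sparse gating can
  floor true homologs.
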