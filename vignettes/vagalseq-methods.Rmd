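---
title: "Methods: quantifying vagal sensory neuron organisation with vagalseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying vagal sensory neuron organisation with vagalseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vagalseq)
```

# Overview

Vagal sensory neurons (VSNs) carry interoceptive signals from the visceral
organs to the brainstem. Characterising them requires joining several
measurement modalities: single-cell transcriptomes carrying exogenous
projection barcodes (UPBs) delivered retrogradely from individual organs,
in vivo calcium imaging with post-hoc in situ hybridisation, anatomical
quantification of sensory ending types, and brainstem innervation maps.
`vagalseq` implements the quantitative procedures that connect these
modalities, together with synthetic-data generators that fabricate every
input with known ground truth, so each procedure can be validated end to
end without access to any particular dataset.

This vignette documents the models and conventions behind each component,
the parameters that matter, and the choices made where the design was
genuinely open.

# Projection-barcode classification

A cell's barcode expression vector (processed, log-scale values) is
compared against a positivity cutoff, 0.8 by default, using a *strict*
inequality — a value exactly at the cutoff is negative. Cells with one
positive barcode are organ-specific; the stomach/oesophagus and
stomach/duodenum pairs are interpreted as oesophageal- and
pyloric-sphincter projections respectively, since those neurons innervate
the boundary region shared by both organs; other pairs are dual; three or
more positives are "multi" and are excluded from organ-specific
statistics. The normalisation that produces the expression scale is the
caller's responsibility; the cutoff is configurable everywhere it is
used.

Quality control retains cells with strictly more than 500 and strictly
fewer than 8,000 detected genes and strictly less than 10% mitochondrial
reads — standard bounds for sensory-ganglion droplet data. Damage
filtering operates at cluster level: dissociation and retrograde tracing
injure a subset of neurons, which form a distinct transcriptional state
marked by injury genes (Sprr1a, Ecel1). A cluster whose mean damage-marker
expression exceeds five times the grand mean (configurable) is removed
wholesale, because the damaged state displaces the cells' native identity
and their barcodes no longer report meaningful projection biology.

The organ-pair correlation matrix summarises dual labelling:
entry (i, j) is `N_dual(i,j) / sqrt(N_single(i) * N_single(j))`. The
normalisation by the geometric mean of single counts is this package's
choice — it makes the entry a dimensionless rate comparable across organ
pairs with different labelling efficiencies. An organ without
single-labelled cells yields missing entries rather than zeros, since the
rate is then undefined.

# Trajectory scoring

The **organ position score** of a cluster is the weighted mean of
normalised organ positions (fraction of body length from neck to rectum):
lung 0.241, heart 0.280, oesophagus 0.228, stomach 0.469, duodenum 0.567,
colon 0.589, pancreas 0.545. The weights are each organ's share of
single-labelled cells found in the cluster, so a cluster containing only
lung-labelled cells scores exactly 0.241.

The **trajectory score** of a cell is its normalised position along a
genetic trajectory drawn on a 2-D embedding. The trajectory is represented
as a polyline through cluster centroids in a caller-declared order, rather
than a fitted smooth curve: the score is a position along a displayed
curve, and a polyline makes the orthogonal projection well defined,
invariant under rigid motions, and exactly testable. The cell is projected
onto every segment (clamped to segment ends), the globally nearest
projection wins, and ties between equidistant segments resolve to the
smaller arc length. Scores are normalised by total path length to [0, 1];
raw embedding units would depend on an arbitrary embedding scale.

The **tissue layer index** scores ending distributions across gut wall
layers with inner-to-outer indices mucosa 0, muscle 1, connective tissue
2, and takes the count-weighted mean. It therefore equals a layer's index
when all endings lie in that layer, and 1.0 for an even mucosa/connective
split.

Relationships between scores are summarised by ordinary least squares
(no robust alternatives), reporting slope, intercept and R².

# Calcium-imaging activity

Traces are acquired at 1.72 s per frame. Baseline fluorescence F is the
mean over the ten frames from 20 to 11 frames before stimulus onset — the
half-open window [-20, -10) keeps exactly ten frames, resolving the
ambiguity in the inclusive phrasing "frame −20 to frame −10". Activity is
ΔF/F = (value − F)/F, which is invariant to positive rescaling of the raw
signal.

A cell is **responsive** to a stimulus when its peak ΔF/F inside the
stimulus window strictly exceeds 1.0 (more than 100% above baseline).
Window conventions: stretch stimuli span onset to offset; intestine
stretch uses 40 frames (68.8 s) after injection; intestine infusion uses
90 frames (154.8 s) after infusion.

**Activation kinetics** use a 10%-of-peak criterion resolved at whole
frames with no interpolation, since frame counts are reported as
integers: the activation frame is the first frame of the contiguous
run of ΔF/F ≥ 0.1 × peak that contains the peak, and the activation
duration is the length of that run. A response that never decays below
the 10% level before the trace ends is reported censored at the trace
end rather than assigned an arbitrary duration. Aligning traces at their
activation frames (column 0) makes adaptation time courses comparable
across cells with different latencies.

**Subpopulation calls** evaluate an ordered list of marker-positivity
rules (A through L) and return the first match, or "X" for unlabelled
cells. "Multiple hits" means at least two of the listed positive markers.
One listed rule is ambiguous as printed — "Runx3+ and/or Piezo2+/P2ry1+,
Tmc3−" — and is implemented as Runx3+, or Piezo2+ together with P2ry1+
(with Tmc3−): reading the slash as "or" would let any P2ry1+ Tmc3− cell
match the first rule, making the final rule (P2ry1+, Trpv1−) unreachable
under first-match evaluation, so the co-positivity reading is the only
one consistent with the rule list as a whole. Damaged cells (the E state)
are identified transcriptomically, not by this panel, so no E rule
exists.

# Landmark registration

Registration links cells between an in vivo 3-D image stack and post-hoc
serial sections using landmark cells identifiable in both modalities.
Landmark correspondence defaults to matching by cell id — landmarks are
individually identified cells — with mutual-nearest-neighbour pairing
under a starting transform available once a transform estimate exists.
The transform is the least-squares rigid fit (Kabsch), optionally with
isotropic scale (Umeyama) to absorb shrinkage between live tissue and
processed sections; the rotation is always constrained to determinant +1,
so reflected configurations surface as large residuals rather than
improper fits.

The **virtual plane** correction fits the plane minimising the total
squared projection distance of landmark cells from a section — the
smallest-spread direction of the centred point set, computed in closed
form by SVD. Sum of squared (not absolute) distances is used for the
closed-form solution.

Non-landmark cells are then registered under an explicit ambiguity gate:
a section cell is registered to the nearest transformed candidate only
when that candidate lies within radius r (default 15 μm, one cell
diameter) and the second-nearest candidate is more than ρ = 1.5 times
farther away. A close competitor makes the cell ambiguous; no candidate
within r makes it unmatched; both are dropped downstream. The (r, ρ)
formalisation of "unambiguous" is this package's, and both defaults are
configurable. The registration rate is the registered fraction of all
cells considered.

# Ending-type assignment search

Stomach VSN clusters are linked to the four gastric ending types (ME,
pIMA, cIMA, IGLE) by matching two independent fold-change profiles over
stomach regions 4, 6, 7 and 8:

* **AF** (anatomical): an ending type's innervation intensity in a region
  divided by its whole-stomach intensity. Intensities are area covered
  per total sample area for ME/pIMA/cIMA and terminal count per area for
  IGLE.
* **SF** (projection-derived): under a candidate cluster-to-type
  assignment, the summed dual-labelled percentages for the region over
  all clusters of the type, divided by the summed stomach single-labelled
  percentages of those clusters — a ratio of sums, exactly as the
  formula is stated, not a sum of per-cluster ratios.

The objective is the sum over the 4 × 4 (type, region) grid of squared
SF − AF differences. With seven free clusters each assigned independently
to one of four types, all 4⁷ = 16,384 assignments are enumerated in
deterministic lexicographic order (first cluster slowest; type order
ME < pIMA < cIMA < IGLE) and evaluated exhaustively; the minimiser wins,
with exact ties resolved to the lexicographically first assignment. The
vectorised evaluation is checked in the tests against a per-assignment
double-loop recomputation.

Enriched-cluster identification uses the barcode shares: a primary organ
cluster holds strictly more than 4% of that organ's single-labelled
cells; a region-enriched cluster additionally requires its dual-labelled
share to be at least 5 percentage points above both constituent organs'
single shares. The 5% margin is read as percentage points (additive),
matching the units of the compared quantities, and the 4% bound is
strict.

# Characteristic correlation index

Pairs of VSN characteristics (organs, tissue layers, ending types,
subpopulations, response patterns) are compared through their bipartite
connection maps. After removing unconnected variables, the normalised
connection count is C = (n − min)/(max − min), where the minimum possible
count is max(n1, n2) — every retained variable has at least one
connection — and the maximum is n1·n2. With v1 and v2 the per-side
variances of connection counts, the index is (1 − C)/((v1 + 1)(v2 + 1)).
A one-to-one pattern scores exactly 1 and an all-to-all pattern exactly
0. *Population* variance (divide by n) is used: sample variance would
break the index = 1 anchor for sides of one variable, while population
variance satisfies both anchors at every size.

# Brainstem innervation profiles

For one pathway, each (bregma level, subnucleus) cell of the measurement
grid contributes FI × A, where FI is mean fluorescence minus a
background measured where no labelled fibres run — clamped at zero, since
a negative difference means no signal, a case the source procedure does
not address — and A is the subnucleus area. Dividing by the total over
the grid and scaling by 100 yields percentage innervation (PI), which
sums to 100 by construction and is invariant to common rescaling of
fluorescence or area. Grid cells without a record count as zero signal.

Pathway dissimilarity is the summed squared PI difference over the grid;
the pathway tree is built from this matrix by average linkage (UPGMA,
the conventional default for such linkage trees; other `hclust` methods
are accepted), with tip heights at half the linkage distance, and is
serialised as newick.

# Synthetic data: what it emulates, and what it does not

All generators draw from one master seed through deterministic
substreams, so a full multi-table scene is bit-reproducible.

* **Cell tables.** True organ labels (with adjacent-organ dual labels at
  weight proportional to a configurable adjacency matrix), barcode
  expression at 1.5 plus half-normal noise for true organs and
  half-normal noise near zero otherwise — separable exactly at zero
  noise; the distributional form is a stand-in, not a claim about real
  barcode counts. Clusters sit on two orthogonal embedding axes (organ
  position, tissue layer), a configurable fraction of cells forms a
  damage cluster with high Sprr1a/Ecel1, and QC metrics carry a small
  contaminant tail. Defaults: 2,000 cells, 12 clusters, 16% dual cells,
  10% damaged (the damaged share observed after retrograde tracing is of
  this order).
* **Traces.** Four archetypes — sustained (plateau across the stimulus
  window), transient (5-frame pulse), polymodal (a second response after
  the window), non-responder — at peak ΔF/F 2.0 with Gaussian noise,
  200 frames at 1.72 s/frame, onset frame 60.
* **Landmark scenes.** Cells placed with a 40 μm minimum spacing in a
  300 μm cube, transformed by a known rigid transform, jittered on the
  section side, and tagged with their 10 μm slab index.
* **Ending tables.** Cluster label tables whose single shares start above
  4% (free clusters are primary clusters by definition) and whose
  dual-label profiles follow the true ending type's preferred region —
  the regional differential enrichment of ending types is precisely the
  structure that makes the exhaustive assignment search identifiable;
  without it the objective landscape is nearly flat and no method could
  recover the truth from noisy tables. AF grids equal the implied SF
  plus optional Gaussian noise, so the true assignment scores exactly
  zero at zero noise.

The generators emulate the *structure* the procedures rely on, not
transcriptome-wide realism: no gene-gene covariance, no read-level
sampling, no imaging artefacts, no section deformation. Passing the
synthetic suites therefore demonstrates correctness of the computations
and recoverability of ground truth under the stated noise models — not
performance on any particular real dataset.

# Numerical choices and degenerate inputs

* All threshold comparisons follow their printed inequalities: strict
  `>` for barcode positivity (0.8), QC bounds, responsiveness (1.0) and
  the 4% enrichment bound; the 5-point margin is inclusive.
* Undefined quantities are reported missing (`NA`), never silently zero:
  organ correlation entries without single-labelled cells, AF rows with
  zero whole-organ intensity, SF rows for types with no assigned
  cluster, organ position scores with all-zero weights.
* Degenerate geometry errors early: paths need two distinct consecutive
  vertices, transforms and planes need three non-collinear points,
  reflections are never returned as rotations.
* Problem sizes in the tests (hundreds to a few thousand cells, 100-seed
  recovery ensembles, 1,000-trace oracle sweeps, 20-seed noise ladders)
  were chosen to exercise every property at comfortable statistical
  margins while keeping the default suite fast.

# Known limitations

* The package consumes cluster labels and embeddings; it does not fit
  them (no graph clustering, no UMAP, no pseudotime model). The polyline
  trajectory is a deliberate simplification of fitted principal curves.
* The correlation-index minimum-connection convention and the organ
  correlation normalisation are declared conventions where the source
  procedures leave the formula open; both are configurable or documented
  at the call site.
* Registration assumes landmark identity is known or approximately
  initialised; it performs no intensity-based or nonrigid alignment.
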