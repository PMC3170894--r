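---
title: "Methods: composition-based haloadaptation analysis of marker-gene fragments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition-based haloadaptation analysis of marker-gene fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halomark)
```

# Scope and rationale

`halomark` quantifies "salt-in" haloadaptation signals in coding
fragments of functional marker genes. Organisms that balance hypersaline
media by accumulating K⁺ intracellularly evolve acidified proteomes;
the signal is visible in (i) amino-acid composition — an excess of
acidic over basic residues — and (ii) nucleotide composition — high GC,
concentrated at the degenerate third codon position. The package turns
those observations into a reproducible pipeline over aligned fragments
with group labels (site phylotypes, halophilic and nonhalophilic
homologs, clades, seasons), plus the phylogenetic and fingerprinting
context such studies report alongside.

The pipeline consumes alignments and column masks; it does not build
alignments or select conserved blocks. Both are upstream, tool-specific
steps whose outputs (an aligned FASTA, a list of kept columns) are
cheap to pass in and impossible to reproduce bit-for-bit without the
original settings, so `halomark` treats them as inputs.

# Sequence handling

**Translation.** Standard genetic code only, embedded as a constant;
frames +1..+3 read the forward strand at offsets 0–2, −1..−3 the
reverse complement. Codons containing `N` translate to `X`, all-gap
codons to `-`, stops to `*`. `best_frame()` picks the frame minimising
the *internal* stop count — a stop at the very end of the fragment is
not counted, since a fragment may legitimately end at a stop — with
ties broken in the fixed order +1, +2, +3, −1, −2, −3. When even the
best frame contains an internal stop the record is flagged rather than
dropped; downstream homology-based confirmation of frames is outside
the package.

**Redundancy filtering.** Environmental amplicon sets carry duplicate
phylotypes. `greedy_identity_cluster()` removes them with a
longest-first greedy scheme: records sorted by decreasing length join
the first cluster whose representative reaches the identity threshold,
else found a new cluster. Identity is matches over the aligned length
of a global pairwise alignment (match +1, mismatch 0, linear gap −1);
at the sizes involved (tens of sequences) all-pairs exact alignment is
affordable, so no word-filter heuristics are used. At threshold 1.0 the
scheme reduces to exact deduplication. Typical use mirrors the two-pass
convention: a 0.9 pass to thin close variants, then a 1.0 pass so each
retained phylotype is strictly distinct.

**Masks.** A mask is a strictly increasing list of 1-based amino-acid
column indices. `codon_mask()` keeps nucleotide columns
{3i−2, 3i−1, 3i} for each kept amino-acid column i, so composition and
codon statistics are computed over exactly the region that supports the
phylogeny. Amino-acid and nucleotide masks are deliberately independent
inputs: published column counts for the two views of the same fragment
do not always reconcile, and forcing consistency would misrepresent
either.

# Composition indicators

Per-sequence composition is the percentage of each of the 20 amino
acids among countable residues; gaps, `X` and `*` are excluded from
numerator and denominator, so aligned and unaligned inputs are both
meaningful (alignment input = "composition over the phylogenetic
region", the default reporting convention here). Categories are fixed:
hydrophobic {G,L,V,I,F,M,A,W,P}, polar {S,T,C,Y,Q,N}, basic {H,R,K},
acidic {E,D}.

The two indicators, both on the percentage scale:

* PAB = [Asx + Glx] − [Arg + Lys]. Sequence residues are unambiguous,
  so Asx = Asn + Asp and Glx = Gln + Glu.
* AB = [Asp + Glu] : [His + Arg + Lys]; a sequence with no basic
  residues yields `NA` (missing), never infinity.

Group summaries report mean and *sample* SD (n−1; the convention is not
universal in published tables, and n−1 is the safer default for the
small groups involved; singletons report SD 0). Reference bulk-proteome
rows (*E. coli*, *H. salinarum*, *Halomonas elongata*) ship as
constants for report context; note the published *H. elongata* PAB
(17.56) does not equal the formula applied to its own printed
components (17.03) — the constant carries the printed value and the
discrepancy is documented, not reconciled.

# Codon statistics

GC% = (G+C)/(G+C+A+T)×100, gaps and `N` excluded; positional GC uses
the column index modulo 3 and therefore requires codon-aligned input.
RSCUᵢ = Xᵢ/(family mean count); codons with gaps or `N` are skipped;
families never observed are reported missing (`NA`) rather than zero so
that downstream correspondence analysis stays well defined;
single-codon families (Met, Trp) score 1.0 whenever observed. Stop
codons are excluded by default; `include_stop = TRUE` adds a three-codon
stop family for display parity with codon-usage figures.

Group-level RSCU **pools codon counts** within a group before
normalising, rather than averaging per-sequence RSCU values. Pooling is
the natural estimator for "codon usage of this dataset" and keeps rare
families stable; whether published three-dataset comparisons pooled or
averaged is typically unstated, so pooling is the documented default
here.

Correspondence analysis is the standard one: with P the table over its
grand total, r and c its margins, the SVD of
S = (P − rcᵀ)/√(rcᵀ) gives principal coordinates (rows:
diag(1/√r)·U·D) and inertias d² whose sum is χ²/N. Axes with singular
value below 1e−12 are dropped; a table of proportional rows therefore
returns total inertia 0, and an all-zero table is an error.

# Neutrality test

`tajimas_d()` implements the classic contrast between mean pairwise
diversity π̂ and Watterson's S/a₁, with the standard constants computed
by direct summation. Decisions worth stating:

* **Complete deletion** of columns containing any gap or `N` is the
  default (the convention is rarely stated in field studies); pairwise
  deletion is available behind a flag, in which case S still comes from
  complete columns while each pair is compared over its own ungapped
  columns.
* Multi-allelic columns count once toward S; pairwise differences count
  any mismatch.
* S = 0 gives an undefined D, reported missing; fewer than 4 sequences
  is an error.

Published D values for field datasets are not asserted anywhere in the
package: they depend on the exact alignments, which are not
reconstructible from printed information. The test suite instead checks
π̂ against a brute-force all-pairs oracle and the null behaviour of D on
simulated neutral coalescent data.

# Protein distances and trees

**Model.** The JTT empirical exchangeabilities and equilibrium
frequencies are embedded as published constants; the rate matrix is
normalised to mean rate 1, so distances are expected substitutions per
site. Gamma rate variation uses the continuous transform
P(t) = U diag((1 − λt/α)^−α) U⁻¹ on the eigensystem of the symmetrised
matrix — exact for distance work, and one line to swap for a
discrete-category approximation if tree-search methods were ever added.
Gamma shapes are *inputs*, not estimated: the marker-specific values
used in the analyses this package supports are α = 0.9 (AprA) and
α = 0.8 (McrA).

**Pairwise distance.** ML over t ∈ [0, 10] of Σ log(π_a P_ab(t)) on the
site-pattern counts, pairwise deletion of columns with gap/`X`,
one-dimensional bracketed search (`optimize`) to tolerance 1e−6.
Identical comparable columns return exactly 0; the upper bound 10 acts
as a saturation cap.

**Neighbor joining** is the Saitou–Nei agglomeration with the standard
Q criterion. Ties on the minimum Q — which occur with exactly regular
matrices — are broken by the lexicographically smallest index pair in
the current matrix order, so results are deterministic. Negative branch
estimates are clamped to 0. On any additive matrix the algorithm
recovers the generating tree exactly; the suite checks this on random
trees up to 10 leaves, with an independent implementation (`ape::nj`)
as topology cross-check.

**Bootstrap.** Columns are resampled with replacement (seeded), each
replicate rebuilds the distance matrix and NJ tree, and the
majority-rule (>50%) consensus is annotated with bipartition
frequencies. Internal branches below the collapse threshold (default
60%) are contracted into polytomies; supports are integer percentages
on the remaining branches; consensus trees carry no branch lengths.
The default of 100 replicates follows the convention of inferring the
consensus from 100 pseudoreplicates; it is configurable where more are
wanted.

# DGGE fingerprints

Band tables are binary lane × band matrices. Lane dissimilarity is the
Jaccard distance 1 − |A∩B|/|A∪B|; a pair of all-zero lanes is 0 by
convention and flagged. Clustering is NJ (default) or UPGMA. This
presence/absence route deliberately replaces likelihood-based
clustering of band characters, whose settings are not reproducible from
published descriptions: the inputs (binary band calls) and the output
(a seasonal partition dendrogram) are the same, and reports label the
method explicitly.

The seasonal-partition test is a label permutation test on the
statistic mean(between-group d) − mean(within-group d). The Monte Carlo
p counts *strict* exceedances: relabelings equivalent to the observed
partition tie the statistic exactly and would otherwise impose a floor
of roughly (#equivalent relabelings)/B on p, so strict counting lets a
perfectly separated partition attain the minimal 1/(n_perm + 1). Under
heavy ties this is slightly anticonservative; with the default 999
permutations and the lane counts typical of gels the effect is
negligible, and the null calibration is checked in the test suite.

# Synthetic data: what it emulates, and what it does not

The generators exist so every stage is testable without downloads, and
their defaults are the study conditions the package targets: 20
sequences × 125 codons per group, positional GC targets
(54.2, 42.4, 76.0)% and PAB 2.87 — the Tirez-like AprA group contrast.

* `generate_coding_set()` draws codons i.i.d. from a constructed
  distribution. Amino-acid weights start uniform (1/20); the fixed
  total mass 0.30 of the six PAB residues is split
  (0.3 ± pab/100)/2 between {N,D,Q,E} and {R,K}, so expected PAB equals
  the target exactly. Within families, codons are weighted by
  independent per-position GC tilts; the third-position tilt is then
  calibrated by a monotone root solve so the *expected* GC3 equals the
  target exactly (Met/Trp force G at position 3, bounding the low end —
  targets below that floor error out naming the constraint). GC1/GC2
  tilts only reweight within-family options (position 1–2 identity is
  mostly fixed by the amino acid) and are approximate by design.
* `evolve_on_tree()` draws the root from equilibrium and samples each
  site down the branches. With a gamma-shaped model, per-site rates are
  drawn Gamma(α, α) and branch transitions use the plain exponential
  kernel — the explicit rates carry the variation; using the
  gamma-integrated kernel per site would double-count it.
* `coalescent_alignment()` is a Kingman genealogy with infinite-sites
  mutations (Poisson, rate θ/2 per lineage per unit time), each
  mutation its own column, binary states encoded A/G so E[S] = θ·a₁
  holds exactly for the downstream statistics.
* `generate_band_table()` builds two seasonal groups from a shared
  profile with a between-group flip probability and per-lane noise.

What passing tests on these data do **not** show: real fragments are
not i.i.d. codon draws (no site-wise covariation, no conserved motifs,
no indel process), coalescent nulls assume panmixia and no
recombination/selection, and band tables ignore intensity and gel
artefacts. The generators validate the *computations*, not the
biological interpretation of any particular dataset.

# Numerical choices and problem sizes

Tolerances: distance optimisation 1e−6 (bracketed search); CA singular
values below 1e−12 treated as zero; GC/RSCU/inertia identities asserted
at 1e−9 in tests; transition matrices clip tiny negative round-off to
0. Coordinates are 1-based closed intervals throughout. Seeds are
explicit arguments everywhere randomness enters; generators are pure
functions of (parameters, seed).

The test suite exercises the statistical claims at deliberately desk
scale: 100 random trees (≤ 10 leaves) for exact NJ recovery; 100
replicates × 500 sites for the t = 0.5 JTT+Γ recovery; 200 neutral
coalescent replicates (n = 10, θ = 5) for the D null and E[S]; 20-seed
calibration of the permutation test. These sizes give standard errors
small enough for 2–3 SE assertions while keeping the default test run
in well under a minute per module.

# Known limitations

* Frame selection uses the stop-count criterion alone; the
  homology-search confirmation step used in field studies is out of
  scope, and flagged frames should be reviewed.
* The greedy identity clusterer is a documented stand-in for CD-HIT;
  cluster boundaries can differ from CD-HIT's word-filtered greedy
  incremental scheme on borderline pairs.
* Maximum-parsimony and ML tree search are not implemented; NJ on
  JTT(+Γ) distances is the topology engine.
* Significance for Tajima's D (beta-distribution lookup or coalescent
  confidence intervals) is not provided; D is reported as a point
  statistic.
* Correspondence-analysis plots are left to the user; the package
  returns coordinates and inertias as data.
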