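---
title: "Inferring functional phosphosites from conservation, kinase specificity and structural flexibility"
author: "PhosCons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring functional phosphosites from conservation, kinase specificity and structural flexibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhosCons)
```

## The problem

Mass-spectrometry phosphoproteomics yields thousands of phosphorylation
sites per experiment, but only a small minority of them have any known
molecular function, and a substantial fraction may be biologically inert.
PhosCons implements three complementary, orthogonal signals for
prioritizing sites and regulatory interactions in a newly surveyed
species:

1. **Evolutionary conservation of the phosphorylation state.** A site whose
   orthologous region is also phosphorylated in many distantly related
   species is much more likely to be functional than one observed in a
   single species.
2. **Kinase specificity.** Position-specific scoring matrices (PSSMs)
   trained on known kinase substrates, scored with the Matrix Similarity
   Score (MSS), link sites to candidate upstream kinases; the conservation
   of the resulting kinase–protein interactions across species ranks them.
3. **Structural context.** Relative solvent accessibility (RSA) computed
   on several comparative models of the same protein identifies sites in
   conformationally flexible positions — candidate conformational
   switches — and flags sites that are buried in every model.

The package operates on plain tabular/FASTA inputs and ships a seeded
synthetic-cohort generator that emulates all of them, so the entire
pipeline is testable end to end without any external downloads.

## Compilation and confidence filtering

Sites are keyed by `(protein, position)`. Merging datasets keeps the
maximum SLIP localization score, the minimum search-engine expectation
value and the union of source labels; a site is flagged ambiguous only if
every contributing observation was ambiguous. Conflicting residue letters
at one key abort the merge: that situation indicates mismatched proteome
versions, and silently picking a side would corrupt provenance.

The high-confidence filter keeps sites with E-value strictly below 0.001
and SLIP score of at least 3 (inclusive). Sites missing either score fail
the filter — the filter presupposes both measurements, so an unscored site
cannot attest to its own localization. Ambiguous sites are *retained* in
the main compilation (the conservation window absorbs localization
uncertainty; see below); the flag is carried for reporting.

Composition percentages are reported as truncated whole percents (2072 of
2636 sites is reported as 78%), matching the convention of the
phosphoproteomics literature; all other fractions are reported to one
decimal.

## Orthology

Orthologs are predicted by reciprocal best hits (RBH): a query–target pair
is kept only when each sequence is the other's top-scoring match. Scores
are exact affine-gap local alignments (Smith–Waterman) under BLOSUM62 with
gap open 11 / extend 1 — the conventions of heuristic protein search, but
computed exactly, which keeps the procedure deterministic and free of
external binaries. The score matrix is computed once and reused for both
directions (the score is symmetric under a symmetric substitution matrix).
Equal best scores are broken toward the lexicographically smallest target
id, so the map is reproducible. For each kept pair the *global* alignment
is stored: conservation calling needs end-to-end position mapping, not the
best-scoring subsegment.

The minimum local score for a hit defaults to 50 — roughly the score of a
short, clearly homologous segment — and is deliberately exposed in the
configuration: no principled universal value exists, and the cohorts this
package targets differ widely in divergence.

## Conservation calling

A query site is conserved in a target species when the ortholog is known
to be phosphorylated within ±2 residues of the aligned position. Two
conventions matter and are fixed as follows:

* **The window is measured in target-sequence residues after mapping**,
  not in alignment columns. A run of gap columns would otherwise inflate
  the window arbitrarily.
* **A query position aligned over a target gap maps to the nearest
  preceding target residue.** This is deterministic and can never invent a
  match beyond the window's reach; when no residue precedes the column the
  site is simply not conserved in that species.
* **No acceptor-type match is required**: a serine site may be called
  conserved by a nearby threonine site. Phosphosite localization within a
  peptide is itself uncertain by a residue or two, which is the very
  reason for the window; insisting on the acceptor letter would discard
  genuine conservation across S/T exchanges, which are common. The
  per-species call table is exported, so a stricter post-hoc filter is a
  one-line join for users who need it.

The conservation **degree** of a site is the number of species in which it
is conserved; species without an ortholog count as not conserved, so
degrees are conservative under incomplete phosphoproteome coverage.
Function-enrichment curves tabulate, per degree threshold, the fraction of
sites with annotated function. When an anchor species is given (the
typical use: the species where functional annotation lives), only sites
conserved in the anchor are counted and the degree counts species *beyond*
the anchor — the question answered is whether deeper conservation
enriches for annotated function among the sites shared with the anchor.
Disorder stratification classifies each site by the disorder call at its
own residue.

## Kinase specificity models

Substrate windows are 15-mers (half-width `w = 7`) centered on the
acceptor and `-`-padded at sequence ends. The half-width is a package
default, not a property of the method: 7 flanking residues cover the
contact range of kinase catalytic clefts, and the same width is used for
the identical-peptide exclusion control so the two operations agree on
what "the same peptide" means.

Training counts residues per flanking position; the acceptor column is
excluded (it is constant within a kinase's positive set and would add an
uninformative constant to every score). Frequencies use a pseudocount
β = 1 spread over a uniform 20-letter background,

$$f(i,b) = \frac{\mathrm{count}(i,b) + \beta/20}{N_i + \beta},$$

which keeps every frequency positive so the information weight
$I(i) = \sum_b f(i,b)\,\ln(20 f(i,b))$ is defined over the full alphabet
(natural log; 20-letter background — the amino-acid analogue of the
original nucleotide formulation). A window $s$ scores

$$\mathrm{MSS}(s) = \frac{\sum_{i\neq 0} I(i) f(i,s_i) - \mathrm{Min}}
                         {\mathrm{Max} - \mathrm{Min}} \in [0,1],$$

where Min and Max substitute the per-column minimum and maximum
frequencies. Pads and non-standard residues contribute a neutral 1/20,
clamped into the column's frequency range so the bounds still hold.

Models are benchmarked by stratified 10-fold cross-validation (both
classes fold-split; folds seeded), reporting the median per-fold AROC
(midrank-tied Mann–Whitney). A kinase is retained when the median AROC
exceeds 0.7. The decision cutoff is then the MSS threshold maximizing
accuracy over the scored positive and negative sets, with the positive set
up-sampled with replacement (seeded) to the negative set's size first so
accuracy is not dominated by the larger class. Candidate thresholds are
the midpoints between consecutive sorted unique scores, and the smallest
maximizer wins — the most sensitive of the equally accurate thresholds.
Published cutoffs for the ten retained cell-cycle kinases ship as
constants (`defaultKinaseCutoffs()`), so predictions can be made without
access to the training compendium.

## Interaction conservation

A protein is predicted to be regulated by a kinase when at least one of
its sites passes the kinase's cutoff. The interaction is conserved in a
species when the RBH ortholog has *any* predicted target site of the same
kinase — positions are never compared, because regulatory interactions
frequently survive while the exact site drifts within disordered regions.
One cutoff per kinase is applied uniformly across species; species-wise
recalibration would entangle the conservation degree with per-species
score distributions. Species with an ortholog but no phosphorylation data
count as not conserved, so interaction degrees, like site degrees, are
under-estimates.

The degree (`n_cons`) ranks interactions; ROC analysis against annotation
sets uses midrank ties (degrees are small integers, so ties dominate), and
enrichment folds compare the annotated fraction above a degree threshold
with the annotated fraction among all predicted interactions — exactly 1
at threshold 0 by construction. The identical-peptide exclusion control
removes sites whose window equals a known training substrate window
before re-running the ranking, so the benchmark cannot be driven by sites
that literally are training data.

## Structural accessibility and flexibility

A comparative model is accepted when its template identity is at least
25% *and* at least one quality criterion holds (TSVMod NO35 ≥ 40%,
GA341 ≥ 0.7, E-value < 1e-4, or zDOPE < 0); absent fields count as not
satisfied. When several accepted models cover a site the largest
(most residues) is used; ties go to the lowest zDOPE, then the smallest
model id. A site is solvent-inaccessible when its all-atom relative RSA is
strictly below 20%.

Flexibility analysis pairs, for every unordered pair of accepted models of
a protein, the RSA values of all shared S/T/Y residues and records the
absolute difference. Observations from all pairs are pooled by default
(each model pair is an independent observation of the same conformational
contrast); because the per-site statistic with more than two templates is
genuinely ambiguous, a per-residue maximum-|ΔRSA| summary is available
behind `summary = "max"`. The overall association is summarized as the
Pearson correlation of the paired values. Residue classes (all acceptors,
phosphosites, conserved phosphosites, ordered/disordered) are compared on
their pooled |ΔRSA| distributions with two-sample Kolmogorov–Smirnov
tests; a residue may belong to several classes, and the conserved class
defaults to degree ≥ 1 but is parameterized. Residues covered by a single
accepted model contribute to accessibility classification only.

## The synthetic cohort generator

`generateCohort()` emulates the statistical structure of a real
multi-species phosphoproteomics compilation: fast site turnover with a
conserved functional minority. Defaults — the package's standard study
conditions — are 60 proteins of 150–250 residues, 8 species, 90% ortholog
retention, 5% per-residue ortholog divergence, 2 sites per protein of
which 30% are functional, per-species conservation probability 0.9 for
functional and 0.2 for background sites, and two kinases with
four-residue motifs implanted in 25% of proteins each. Conserved sites
land in the ortholog with a uniform jitter on [−2, +2], so the
conservation window is exercised at its boundary by construction. Motif
windows are protected from substitution (and their sites from jitter), so
ground-truth interactions survive divergence and remain recoverable. RSA
fixtures add per-model noise of sd 15 at phosphosites against sd 3
elsewhere on a clamped Gaussian baseline (mean 40, sd 20), and the model
metadata includes one constructed violation of each acceptance criterion.
Background residue composition is uniform over the 20 amino acids, which
makes MSS hand-calculations exact and keeps motif information content
predictable.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: insertions/deletions between orthologs
(alignments of generated pairs are trivially ungapped; alignment-heavy
code paths are instead exercised by randomized gapped alignments in the
property tests), mass-spectrometry abundance and detectability bias,
correlated noise along the sequence in RSA models, non-uniform proteome
composition, and kinase motifs with degenerate or position-coupled
preferences.

Interaction-level questions are additionally simulated directly
(`simulateInteractionCohort()`): each interaction is predicted per species
with probability 0.9 (true) versus 0.2 (background) over 8 species,
400 interactions at a time — the scale at which conservation-degree
ranking is evaluated.

## Numerical choices and degenerate inputs

* All tie-breaks are deterministic: lexicographic ids (hits, model
  selection), smaller position (nearest conserved site), smallest
  maximizer (cutoff calibration).
* Every stochastic step (fold assignment, up-sampling, generators) takes
  an explicit seed, and seeded evaluation never disturbs the caller's RNG
  state.
* Degenerate inputs fail loudly rather than silently: single-class AROC,
  empty SLIP bins, all-pad PSSM columns with β = 0, coinciding MSS score
  bounds, empty positive sets in enrichment folds, proteins without two
  accepted models in the flexibility analysis.
* Pipeline runs are byte-reproducible: outputs depend only on the input
  bundle, the analysis parameters and the seed (run metadata hashes
  exclude filesystem paths).

Default problem sizes in the shipped tests and the acceptance script — 60
proteins × 8 species for cohort-level checks, 100 proteins × 1 species
for the flexibility contrast, 400 simulated interactions, 1,100 windows
for kinase cross-validation — were chosen as the smallest cohorts at
which the relevant signals are statistically unambiguous.

## Known limitations

* RBH yields one-to-one orthologs only; recent duplicates are dropped by
  construction, and the conservation degree of sites on such proteins is
  under-estimated.
* Exact all-vs-all alignment is quadratic in proteome size; the package
  targets desk-scale cohorts and accepts externally computed alignments
  for larger ones.
* The MSS formulation here is one member of a family of min-max
  normalized PSSM scores; it is isolated in a single function
  (`mssScore()`) precisely so an alternative variant can be substituted
  without touching training, calibration or prediction.
* Interaction conservation inherits every upstream false negative
  (missing ortholog, missing phosphodata, sub-cutoff site), so absolute
  degrees should be read comparatively, not literally.
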