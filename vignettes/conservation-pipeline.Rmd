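---
title: "Conservation analysis of multi-protein complex interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservation analysis of multi-protein complex interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexcons)
```

## Scope and model

`complexcons` analyses how the components of a multi-protein (and
protein–RNA) complex diverge in sequence, and how that divergence is
distributed over the parts of each protein that matter for assembly:
inter-component interfaces, core versus rim interface regions, short
linear motifs, and annotated functional sites. The motivating system is
a spliceosomal subcomplex of roughly seven proteins clamped around an
RNA duplex, but every function is generic over components, chains and
alignments.

The pipeline has five analysis stages plus a synthetic-data stage used
for validation:

1. **Column conservation.** For each component's multiple sequence
   alignment, every column receives a Jensen–Shannon divergence (JSD)
   score between the column's weighted amino-acid distribution
   $p_c$ and a background distribution $q$ derived from the BLOSUM62
   substitution table:
   $$\mathrm{JSD}(p_c, q) = \lambda\,\mathrm{KL}(p_c \| r) +
     (1-\lambda)\,\mathrm{KL}(q \| r), \qquad
     r = \lambda p_c + (1-\lambda) q,$$
   with $\lambda = 0.5$ and base-2 logarithms so the score lies in
   $[0, 1]$; higher means more conserved. Interpretation in this
   package consistently uses thresholds on this scale (e.g. 0.4 for
   "conserved", 0.5/0.7 for stronger claims).
2. **Interfaces.** Multi-chain structures are reduced to inter-chain
   atomic contacts under explicit geometric criteria; residues with at
   least one qualifying contact form ordered (owner, partner) interface
   sets, which can be unioned across structures and mapped into
   reference numbering.
3. **Core/rim.** Interface residues are classified by relative solvent
   accessibility (rSASA) change upon complex formation, using a
   hand-written Shrake–Rupley implementation.
4. **Phylogenetic profiles.** Species × component presence/absence
   matrices are clustered (correlation distance, average linkage) to
   expose groups of components that co-occur across species — candidate
   subcomplexes.
5. **Motifs and reports.** C-terminal tails are scanned for five
   proline-rich motifs; conservation tracks, interface sets and site
   lists are aggregated into summary tables.

## Parameters that matter

### Conservation scoring

The JSD measure itself fixes no auxiliary choices, so every one is an
explicit, overridable argument of `jsd_track()`:

* `lambda = 0.5` — the symmetric mixture weight; the only value for
  which the score is bounded by 1, which the downstream thresholds
  assume.
* `use_weights = TRUE` — position-based (Henikoff) sequence weights:
  each column distributes mass $1/(r s)$ over the residue types it
  contains, damping redundant clades. Gaps and unknowns carry no mass.
* `pseudocount = 1e-7` — keeps the column distribution strictly
  positive without visibly distorting it at realistic depths.
* `gap_penalty = TRUE` — the raw score is multiplied by
  $1 - \text{gap fraction}$, so heavily gapped columns cannot appear
  conserved merely because few sequences align there. Adding gaps to a
  column therefore never increases its raw score (a property the test
  suite asserts).
* `window = 3`, `window_weight = 0.5` — the reported score blends the
  focal column with the mean raw score of up to three columns on each
  side (focal column excluded, truncated at the edges; an empty window
  falls back to the raw score). Windowing encodes the observation that
  functionally constrained positions cluster in sequence.

Whether the original analyses applied weighting and windowing is not
documented; both toggles default to on because they are the cited
measure's published defaults, and both can be switched off.

`'X'` residues are excluded from distributions but are not gaps: an
unknown residue should neither look conserved nor trigger the gap
penalty.

### Interface detection

Published interface tools delegate their criteria to program defaults;
here they are explicit numbers in `contact_params()`, chosen to
approximate those tools without hydrogen positions (cryo-EM models
rarely have them):

* generic contact: any inter-chain heavy-atom pair ≤ 5.0 Å;
* hydrogen bond: N/O pair ≤ 3.5 Å (no angle term, by design —
  hydrogen-free criteria are reproducible on any deposited model);
* ionic: charged side-chain groups (Asp/Glu vs Lys/Arg/His), or a
  protein charged group against an RNA phosphate, ≤ 6.0 Å;
* hydrophobic: apolar side-chain carbon pair ≤ 5.0 Å.

An interface residue is a residue with ≥ 1 qualifying contact of any
type. The percent-of-sequence-at-interface statistic defaults to the
residues resolved in the structure as denominator (a flagged
alternative is full sequence length, which the caller supplies).
Cross-structure unions require an explicit residue mapping — no
automatic superposition; deterministic and auditable beats convenient
here.

### Core/rim thresholds

A residue is *core* when it is exposed unbound (rSASA > 10 %) and
buried in the complex (rSASA ≤ `core_max`), *rim* when its bound rSASA
falls in (`core_max`, `rim_max`] = (7 %, 10 %]. The literature this
follows states the core bound once as "≤ 0.7 %" and elsewhere
describes rim as the 7–10 % band; the internally consistent reading is
a 7 % core bound, so `core_max = 7` is the default and both thresholds
are parameters. rSASA uses the Gly-X-Gly theoretical maxima per residue
type (embedded constants; unknown residue types fall back to the scale
mean with a warning) and is clamped at 100 %.

### Critical pairs and site reports

A contacting residue pair is *critical* when one side's JSD is > 0.5
(strict) and the other's ≥ 0.4 — a deliberately asymmetric, two-sided
rule. "Above threshold" in site reports is strict (> 0.4 by default);
both thresholds and strictness are arguments.

### Profile clustering

Distances are `1 - Pearson` on raw 0/1 columns (no normalization —
presence/absence is already the quantity of interest), agglomerated
with average linkage (UPGMA). Components are sorted lexicographically
before clustering so ties break deterministically. A component present
in every species has no defined correlation; the package fails loudly
and names the column rather than propagating NaNs into the linkage.
Flat clusters are cut at a user-supplied `k` (or height): the original
analyses read groups off a dendrogram visually, and inventing an
automatic model-selection step would add a claim the method does not
make. The exported newick tree uses branch lengths such that
leaf-to-leaf path distances equal cophenetic distances of the linkage.

### Motif scanning

The five proline-rich patterns (PPRxxP, PPPPP, PxPPxR, PPLP, PPxY; `x`
= any residue) are literal wildcard strings, so scanning is exact
matching, reporting **all** overlapping occurrences — probabilistic
motif tools add nothing for fully specified patterns and can only
disagree by error. Scanning is restricted to an annotated C-terminal
tail by default (domain boundaries are an input; domain assignment is
out of scope), with the full sequence available by passing the whole
range. Disorder is only ever an input annotation, never predicted.
Classification counts always reconcile: motif + disorder + yeast-like +
unscanned = input sequences.

## What the synthetic data emulates — and what it does not

The generators produce data with *known truth* under one explicit seed
each (no global RNG state leaks):

* `simulate_msa()` — conserved columns are near point masses (dominant
  residue in ⌈95 %⌉ of records, the rest uniform over the other 19);
  variable columns are i.i.d. BLOSUM62 background; gaps are i.i.d. per
  cell in variable columns only. This is sufficient to test score
  separation and gap penalties, but it is *not* phylogenetic sequence
  evolution: no tree, no indel blocks, no rate variation. Passing the
  AUC ≥ 0.95 recovery test shows the scorer ranks planted signal
  correctly, not that real alignments are this clean.
* `simulate_complex()` — Cα-only pseudo-residues on a lattice
  (10 Å spacing within chains, 120 Å between chains), with planted
  contacts created by moving one residue to a drawn distance in
  [3.0, 4.9] Å from its host; by construction no unplanned inter-chain
  pair lies within 6.5 Å, so the planted contact set is exactly the
  ≤ 5 Å pair set. An optional side-chain mode (one charged/apolar atom
  per residue, cycling Asp/Lys/Leu/Ser) exercises the typed
  classifiers. These toys validate geometry and bookkeeping, not
  biophysics.
* `simulate_profiles()` — components in a module share one Bernoulli
  draw per species (default presence rate 0.7, a mid-range occupancy
  that keeps both presences and absences common), then independent bit
  flips at the noise rate. Real profiles have phylogenetic
  autocorrelation between species; these do not.
* `simulate_motif_sequences()` — uniform background with a rejection
  step guaranteeing the background contains no spurious motif, then one
  planted instance per sequence; scan output equals planted truth
  exactly, by construction and by test.

## Numerical choices and degenerate inputs

* $0 \log 0 \equiv 0$ throughout the JSD; scores are clamped to
  $[0, 1]$ against floating-point drift.
* All-gap column: uniform distribution, gap fraction 1, raw score 0
  under the penalty. Entirely unknown columns are rejected at parse
  time.
* Records with no residues at all (pure gap rows) make position-based
  weights undefined and are an error, not a silent zero weight.
* Pairs of sequences with zero co-aligned columns are excluded from the
  mean identity and flagged.
* Altlocs resolve to the highest-occupancy copy, ties to the first;
  hydrogens and waters are dropped on reading.
* The overlap comparison uses a two-sided Mann–Whitney U test — exact
  when both groups have ≤ 20 values without ties, the tie-corrected
  normal approximation otherwise, and p = 1 directly when every value
  is identical (the statistic's variance vanishes there).
* Empty interface cells in the conservation matrix are `NA`, never 0;
  unmapped residues and sites are always returned, never dropped.

## Problem sizes used in validation

The shipped checks run the conservation oracle on 100 random
alignments (≤ 10 × 20), conserved-column recovery on 50 × 200
alignments over 10 seeds, contact exactness on 50 toy complexes,
module recovery on 200-species profiles over 20 seeds, and the motif
scanner against an exhaustive matcher on 1000 random sequences — sizes
at which the independent oracles are themselves fast and transparent.

## Known limitations

* Hydrogen-bond detection is distance-only; without angle terms some
  N/O pairs counted as hydrogen bonds are merely close. The generic
  contact class is unaffected.
* rSASA on Cα-only toy structures exceeds the Gly-X-Gly scale and is
  clamped; core/rim thresholds are meaningful only on full-atom
  structures.
* Homology search, alignment construction, domain assignment, disorder
  prediction and dN/dS estimation are out of scope: alignments,
  presence tables, domain boundaries, disorder calls and site lists are
  consumed as inputs.
* Whether interface-residue counts should be read from one side or both
  sides of a pair is a reporting convention; this package always emits
  both ordered sets and lets summaries state which they count.
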