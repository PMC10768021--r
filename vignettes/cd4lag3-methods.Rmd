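---
title: "Discriminating CD4 from LAG-3: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating CD4 from LAG-3: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cd4lag3)
```

## The classification model

CD4 and LAG-3 are tandem-duplicated MHC class II receptors whose
ectodomains are too diverged for reliable whole-sequence phylogeny
across jawed vertebrates.  This package instead classifies family
members from discrete features, each computed by a dedicated,
separately tested operation, and combined additively:

* **Tail clasp motif** (`clasp_motif`): the Cx(C/H) zinc clasp through
  which the CD4 tail binds the kinase LCK.  Precedence CxC > CxH > CxF:
  histidine substitutes for cysteine in tetrahedral zinc coordination
  (shark CD4 uses CxH), and CxF marks the sturgeon CD4-2f variant.
  Weight 3 (CxF: 2), CD4 lineage.
* **Inhibitory tail motif** (`classify_inhibitory_motif`): canonical
  ITIM (I/V/L)xYxx(L/V) first, then the LAG-3-typical ITIM-like
  (F/Y)xxL(D/E), then YxxM (a zebrafish/catfish variant).  The
  canonical ITIM is the strongest statement, hence the precedence.
  Weight 3 (YxxM: 2), LAG-3 lineage.  Because the functional role of
  the acidic fifth position is uncertain, the 4-mer FxxL is also
  reported as a separate tail-profile field rather than being folded
  into the 5-mer feature.
* **Tail exon count** (`tail_structure`): coding exons strictly behind
  the transmembrane-encoding exon.  One exon is LAG-3-typical (weight
  2), two or more CD4-typical (weight 2); three or more set the
  `extra_exon` flag that reflects the chondrichthyan CD4 tail, with the
  osteichthyan CD4 baseline fixed at two.
* **D1-internal intron phase** (`intron_phases` +
  `annotate_intron_domains`): phase 1 inside the D1 coding sequence is
  CD4-typical, phase 2 LAG-3-typical (weight 2 each).  "Inside" means
  the strict interior — an intron at a boundary residue is not
  D1-internal.  Sharks have no D1-internal intron at all, which yields
  the distinct value `"absent"` rather than an unknown.
* **Synteny role** (`synteny_role`): the ancestral locus keeps LAG-3
  head-to-tail upstream of CD4.  Upstream membership in such a pair is
  LAG-3 evidence, downstream membership CD4 evidence (weight 1 each).
  Up to two intervening annotated genes are tolerated, which covers the
  lungfish-type locus with a third family gene between the pair; a gene
  with tandem partners on both sides has role `none`, and a gene absent
  from the table is `unknown` — missing synteny is absent evidence,
  never negative evidence.
* **Thymus dominance** (`tissue_dominance`): CD4 is consistently
  expressed highest in the thymus; the criterion is a thymus:spleen
  ratio of at least 5 (weight 1).  Non-dominance scores nothing for
  LAG-3, because LAG-3 is merely *not consistently* thymus-high —
  absence of a pattern, not an anti-pattern.
* **EP-repeat** (`ep_repeat`): an (EP)n stretch with n ≥ 3 marks the
  acidic tail end acquired by tetrapod LAG-3 (weight 1).
* **CD4-1 C-terminal motif**: P(K/Q)P(K/R)(A/G)FY(H/K/R), searched only
  in the final 12 tail residues where it is length-conserved (weight 1).

### Labeling rule

`assign_label` first tests for the lungfish-type **HYBRID**: ectodomain
and gene-structure evidence pointing to CD4 (phase-1 D1 intron = 2
points, canonical V-C2-V-C2 architecture = 1 point) while the tail
points to LAG-3 (inhibitory motif = 3, single tail exon = 2), each side
reaching 3 points.  Otherwise the higher-scoring lineage wins if it
reaches **5 points with a margin of 3** — so no single weak feature can
decide a call.  Within the CD4 lineage, CD4-1 requires the C-terminal
motif and CD4-2 a reduced (<4 domain) architecture or the linker CxxC;
with neither ray-finned-fish cue the gene keeps the plain CD4 name, as
appropriate for chondrichthyan and tetrapod genes.  Everything else is
**AMBIGUOUS** — the honest output for borderline fragments.  All
weights and thresholds are package constants; the evidence report
records every contribution so a call can always be audited.

Unknown features (missing gene model, synteny table or expression
matrix) contribute zero to both lineages.  A frog-type LAG-3 that lost
the tail motif is still called LAG-3 from structure and synteny alone
(2 + 2 + 1 = 5 points, margin 5).

## Motif grammar and scanning

Patterns are ordered allowed-residue sets written in a small grammar
(`C` fixed residue, `x` wildcard over the 20 standard residues, `[FY]`
class).  The scanner reports **all** matches, overlapping ones
included, in ascending order; nothing in the biology restricts
occurrences to non-overlapping ones.  The unknown residue X fails every
position class including the wildcard — conservative feature
extraction.  The scanner is verified against a naive
position-by-position oracle on 1,000 random (sequence, pattern) pairs.

The Kozak context rule (`kozak_verdict`) is operationalized as:
favorable iff position −3 is a purine **or** position +4 is G.  The
disjunction is forced by the two printed verdicts it must reproduce
(`cagATGt` unfavorable, `cccATGg` favorable — the latter has only the
+4 G), so either strong position suffices.

## Domain detection

An Ig-like domain candidate is a cysteine pair (β-strands B and F)
spaced 40–80 residues apart — a window chosen to span Ig-like B–F
distances, since no numeric window is standard.  Candidates are
resolved greedily left to right with ties broken by the smaller
spacing, making detection deterministic and oracle-checkable.  The
domain start is placed 15 residues before the B cysteine, where V-set
domains show a start consensus; a domain is **C2** when the F-strand
cysteine carries the family's unusual WxC signature, otherwise **V**
when at least 3 of the 6 consensus residues ((I/V) at +3, (F/Y) at +4,
G at +8, (A/V) at +11, L at +13, P at +14) are present, otherwise
**degenerate** (rendered `V*`).  The 3-of-6 threshold balances the
degenerated-V cases seen in real LAG-3 D3 domains; behaviour on real
degenerate domains is untested by design.  Domains beyond four are
labeled `extra` (covering five-domain CD4-2.2-like variants).

## Transmembrane detection and tail features

The TM segment is the 19-residue window maximizing mean Kyte–Doolittle
hydropathy, accepted when that mean is ≥ 1.5, ties broken toward the
most C-terminal window (the tail is defined downstream of the TM, so
the later candidate is conservative).  The exon encoding the TM is
located from the **midpoint** of the detected span: hydropathy-based
detection can slip a residue or two at the edges, and the midpoint is
insensitive to that slop.

The acidic-fraction window is 17 residues — the length of the one
concrete exemplar of the acidic LAG-3 tail end
(`EPEPEPEPEPEPEPEQL`, 8/17 acidic).  The amphipathic score is the
maximum over 11-residue windows of the hydrophobic moment at
100°/residue on the Eisenberg consensus scale (no scale is canonical
for this purpose; Eisenberg is the standard choice for helical-wheel
moments), normalized by window length.  The moment is computed on
**mean-centered** hydrophobicities, so a homopolymer scores exactly 0
and the score measures periodic alternation rather than raw
hydrophobicity; note that with an 11-residue window at 100°/residue the
raw (uncentered) moment of a homopolymer would not vanish, and no
window length commensurate with the helical period exists, so strict
invariance under cyclic permutation of a window is unattainable — the
implementation is instead verified directly against the windowed
formula.

## Expression operations

TPM follows the standard definition (length-corrected rates scaled to
1e6; conservation is property-tested).  The dominance threshold of 5
operationalizes the observed five-fold thymus excess of shark CD4 and
is configurable; reports flag it as the package's operationalization,
not a published cutoff.  A pseudocount of 0.01 TPM guards the ratio
against near-zero reference values, which do occur in real tissue
tables.  qPCR relative quantification divides each replicate's target
amount by its housekeeping amount, averages per tissue, and divides by
the calibrator-tissue mean, so the calibrator reads exactly 1 — a
property the tests assert on arbitrary synthetic tables, together with
invariance under global rescaling of either amount column.

## The synthetic-data generator

`generate_gene` assembles leader (18 filler residues), two to four
domain blocks (cys spacing drawn from 45–65, WxC planted in C2 domains,
all six consensus residues in V domains), an inter-domain linker of 5
residues, a membrane-proximal linker (with CQQC for the neoteleost-type
CD4-2 template), a 19-residue hydrophobic TM, and a class-specific
tail.  Background filler is drawn from a reduced 11-letter alphabet
containing no C, W, F, Y, M, H, D, E or L, so no catalogued motif can
arise by chance and every planted feature is re-detected exactly at
mutation rate 0 — a round-trip the tests check exhaustively.  The
residue immediately preceding the TM is fixed to arginine so the
planted TM window is the unique hydropathy maximum.

Gene models place the D1-internal intron 20 residues into D1 with
cumulative coding length ≡ 1 (mod 3) for CD4-lineage templates and 30
residues into D1 with ≡ 2 (mod 3) for LAG-3 templates; phase-0 introns
separate the domain blocks, and the tail region is split over 1, 2 or 3
coding exons according to class.  Each simulated locus carries the gene
plus tandem anchor partners (upstream for CD4 classes, downstream for
LAG-3 classes, both for HYBRID), with the locus strand randomized —
the strand-flip invariance of the synteny verdict is tested.

Expression rows emulate the qualitative thymus/spleen pattern: spleen
baselines are lognormal around 1.2 TPM, CD4-class thymus:spleen ratios
lognormal around 6 with σ = 0.2, LAG-3-class ratios lognormal around 1.
Under these conditions a CD4-class row passes the five-fold criterion
in roughly 80% of draws — the pattern separates the classes cleanly in
aggregate but is deliberately not deterministic, which is why
expression carries a supportive weight of 1 and never decides a call on
its own.  Mutation (`mutate_sequence`) applies i.i.d. substitutions to
the protein only; gene models, synteny and expression stay clean, so
degradation curves isolate the sequence-feature pathway.

What the generator does **not** emulate: real residue composition
(background is uniform over a reduced alphabet), indels and length
variation, correlated substitution processes, lost Ig-domain cysteine
pairs in otherwise intact domains, pseudogene fragments, and UTR-only
exons.  Perfect label recovery on clean cohorts therefore demonstrates
the correctness of the feature extraction and the decision rule, not
expected field performance on diverged genomes.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale: the
recovery benchmark uses a 100-gene cohort (4 classes × 25) at mutation
rate 0, and the degradation curve 40-gene cohorts at rates
{0, 0.02, 0.05, 0.1} with 10 seeds per rate, sizes at which the
recovery gaps between rates are an order of magnitude larger than the
Monte-Carlo error.  All randomness flows from explicit integer seeds;
generators save and restore the caller's RNG state, and the classifier
itself is fully deterministic.

## Coordinate conventions

Gene-model intervals are 0-based half-open in transcription order
everywhere inside the package; GFF3 stays 1-based closed on disk with
conversion at the parse/write boundary, and minus-strand models are
normalized at parse time so phase arithmetic is strand-free.  Residue
positions in the R interfaces (motif hits, domain bounds, TM spans) are
1-based inclusive, the native R string convention.

## Known limitations

* The evidence weights encode a qualitative ranking; they are not
  fitted to data, and borderline real genes (pseudogene fragments,
  partial models) should be expected to land in AMBIGUOUS.
* Domain category assignment is sequence-based; structure-derived
  category evidence (β-sheet pairing) is out of scope, as are
  structural binding-residue analyses.
* The CD4-1/CD4-2 split is only attempted when a ray-finned-fish cue is
  present; the package will not invent a split for chondrichthyan or
  tetrapod genes.
* Alignment, assembly, phylogenetics and single-cell co-expression are
  out of scope; the package consumes their standard outputs instead.
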