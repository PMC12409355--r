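---
title: "ringscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ringscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological problem

Type III CRISPR-Cas systems are anchored by Cas10, whose cyclase (Palm)
domain synthesizes cyclic oligoadenylate (cOA) second messengers — cA3,
cA4 or cA6 — upon target RNA recognition; a minority of Cas10s instead or
additionally carry an HD nuclease domain. The cOA signal activates
effector proteins encoded in or near the same operon (Csx1, Csm6, Can1/2,
Cami1, Cam1, CalpL, NucC, ...), whose activation is usually toxic. Ring
nucleases (RNs) — small CARF-superfamily enzymes of families Crn1
(including Csx14), Crn2 (whose phage homologue is the anti-CRISPR
AcrIII-1), Crn3, Csx16 and Csx20, with Csx15 a candidate of uncertain
activity — degrade cOA rings and thereby switch the response off.

`ringscan` implements the comparative-genomics side of this biology as a
reusable, tested pipeline: given genome annotations and profile-HMM hit
tables, it assembles Cas10-anchored loci, bounds the search for RNs and
effectors to a neighborhood around the cas operon, applies the two
filters that keep RN calls honest (a length cutoff and a conserved-residue
screen), infers each locus's signalling molecule from its effector
content, and derives the co-occurrence statistics and exports (tables,
bipartite network, tree ring-annotation) that such surveys report.

## Pipeline model

### Locus assembly

A gene *anchors* a locus when it carries a Cas10-profile hit at or below
the e-value ceiling. The **cas span** is grown from the anchor to a
fixpoint, absorbing every gene with a cas-core-profile hit whose
intergenic gap to the current extent is at most `chain_gap`; for interval
proximity this equals the transitive closure of the pairwise gap graph
(the test suite checks this against an explicit graph-closure oracle).
Anchors whose spans overlap are merged into one locus whose anchor is the
best-scoring Cas10. The **neighborhood** is the span widened by `window`
base pairs on each side, clipped at contig ends. Membership is overlap by
at least 1 bp, strand-blind; a gene reached by two neighborhoods goes to
the locus whose cas span it is nearer (ties toward the lexicographically
smaller locus id).

Two choices here were genuinely open and are package decisions, not
field standards: the neighborhood is measured from the *cas-span edges*
rather than from the Cas10 gene alone (the locus, in cas-typing terms, is
the operon, and measuring from its edge is the conservative reading of
"within 6 kbp of a locus"); and contigs are treated as linear — no
wrap-around for circular chromosomes.

### RN and effector calls

Per candidate gene the best RN-family hit and the best effector-family
hit are taken (bit score, then e-value, then alphabetical family as
tie-breaks; profile aliases are folded into families, notably Csx14 into
Crn1). Cross-annotation between the two panels — a real hazard because
effectors share the CARF sensor domain — is arbitrated by the rule:

* protein longer than 250 aa: the effector call wins, always;
* protein within 250 aa: the RN call wins only when its bit score beats
  the effector's; otherwise effector.

The 250 aa cutoff and the 6 kbp window are the survey's stated values and
are the package defaults (`max_rn_len`, `window`); both remain
configurable.

### Conserved-residue screen

Each RN family carries a reference multiple sequence alignment. The
profile built from it retains columns with gap fraction at most `g_max`
(default 0.2 — tolerance for ragged alignment ends) and declares a
retained column *conserved* when its modal residue reaches frequency
`t_cons` among non-gap characters (default 1.0, the literal reading of
"absolutely conserved"). A candidate is globally aligned to the profile
consensus (BLOSUM62, affine gaps, open 10 / extend 1 — conventional
protein-alignment defaults; the suite verifies the scoring convention
against an independent Gotoh dynamic program) and passes only if it
carries the expected residue at every conserved column; a deleted column
counts as missing. Candidates failing the screen stay in the annotation
table with `screen_status = "fail"` and are excluded from every
downstream statistic — mirroring the removal of false positives lacking
key residues, but reproducibly and with the offending positions recorded.

The same single code path screens cellular and phage candidates, and the
250 aa cutoff is applied in the phage scan too; neither was fully pinned
down by the source methods, so both are explicit package decisions.

### Signals, Cas10 motifs, statistics

Each locus's signal set is the union of its effector families' signals
under a shipped mapping (Csx1, Can1/2, Cami1, Cam1, CalpL, Csx23 → cA4;
Csm6, Csm6-2 → cA6; NucC, TIR-SAVED → cA3; CorA-fused → SAM-AMP). The
Csx23 and TIR-SAVED entries follow companion characterization work rather
than anything this pipeline can check, and are marked provisional;
unmapped families map to `unknown` with a warning rather than silently.
Cas10 cyclase/HD domains are called by configurable motif patterns
(GGDD/GGDE/SGDD tetrads; H followed by D within 4 residues in the
N-terminal third) — deliberately simple, transparent heuristics, not
structure-based calls.

The co-occurrence stage computes per-family instance and locus counts,
the multi-RN report, the RN-by-effector locus-count matrix (exported as a
bipartite GEXF/GraphML network with same-type edges forbidden by
construction), the **restricted association** (per effector family, the
fraction of its loci carrying an RN, over loci with exactly one effector
and at most one RN — the restriction that makes the RN attributable to
that effector), the genome-level background frequency of a family outside
type III loci, phage per-genome family counts, and the Cas10-tree leaf
annotation table. An arithmetic identity ties the counts together —
instances minus RN-positive loci equals the surplus in multi-RN loci —
and is asserted across random datasets.

## The synthetic survey generator

Real surveys of this kind run over tens of thousands of genomes; the
package instead ships a generator (`sim_config()`, `generate_dataset()`,
`generate_phage_set()`) that emulates the *statistical structure* of such
a survey at desk scale, with planted ground truth, so that every stage is
testable offline.

What it emulates, with defaults chosen to be realistic for this system:

* roughly half of genomes carry 0 loci, the rest 1–3, in 30 kbp slots on
  a 100 kbp contig (loci near the contig start exercise neighborhood
  clipping);
* a cas span of Cas10 (750 aa) plus 2–4 accessory genes; ~90% of Cas10s
  cyclase-positive, ~10% HD-positive;
* 0–2 effectors per locus with Csx1 the most common family; 0–2 RNs with
  family weights proportional to the reported relative abundances
  (Csx20 78 : Csx16 68 : Crn1 44 : Crn3 37 : Csx15 18 : Crn2 7);
* RN presence conditional on the (first) effector family — defaults 0.34
  for Csx1, 0.30 Cami1, 0.66 Can1/Can2, 0.81 Cam1, 0.39 otherwise — with
  ~4% of RN-positive loci multi-RN, and ~10% of loci effector-less;
* a 30% chance that a planted Crn1 gene is reported under the Csx14
  profile alias, exercising the family merge;
* per-family reference alignments of 20 sequences derived from a family
  template with 6 absolutely conserved columns; every non-conserved
  column is forced to vary so the conserved set recovered at
  `t_cons = 1` is exactly the planted one (the families are synthetic:
  the real curated conserved-residue sets are not published);
* decoys planted where their rejection rule applies: >250 aa CARF-like
  proteins hitting both panels (length rule), RN-like proteins with one
  conserved residue knocked out (screen), true RNs just beyond the 6 kbp
  window (membership), and orphan RNs in locus-free genomes (background
  frequency). Decoys are planted as exact counts so filter checks are
  exact, not statistical;
* spurious hits at e-values drawn log-uniformly from [1e-3, 10] —
  entirely above the default 1e-4 ceiling, so threshold behaviour is
  testable; lowering the floor gives a hard-noise stress mode;
* phage proteomes in which planted RNs are heavily biased toward
  Crn2/AcrIII-1.

What it does **not** emulate: sequence evolution (proteins are random
strings except for planted motifs and family templates), codon structure,
overlapping genes, multi-contig assemblies, CRISPR arrays, or any
correlation between subtype and effector content. Passing the end-to-end
tests therefore demonstrates that the pipeline's *logic* — windowing,
chaining, arbitration, screening, counting — is correct against planted
truth; it says nothing about the sensitivity of any particular HMM
library on real proteomes, which is out of scope (profile search is
consumed as input, never run).

All generation is deterministic given `seed`; the suite asserts
byte-identical files across repeated runs.

## Numerical and interface choices

* Coordinates are 1-based inclusive (GFF3 native) everywhere; intergenic
  gap between touching genes is 0.
* Hit tables use the per-domain tabular (`domtblout`) layout with the
  protein as target (column 1) and the profile as query (column 4); the
  per-domain independent e-value and per-domain bit score are the fields
  used. The default e-value ceiling of 1e-4 is a documented assumption —
  the source methods state no threshold — and is configurable end to end.
* `chain_gap` defaults to 500 bp, typical intra-operon spacing; also an
  assumption, also configurable.
* Tie-breaks are total and documented (bit score, e-value, alphabetical
  family; lexicographic locus id for membership ties), so outputs are
  reproducible to the byte.
* Protein sequences come from a paired FASTA keyed by gene ID; genomes
  are never translated.
* Degenerate inputs: empty genome sets produce empty, schema-valid
  tables; a profile with no conserved columns refuses to screen; ragged
  alignments, duplicate tree leaves, same-type network edges and
  dangling edge endpoints abort with informative errors; a failing
  pipeline stage quarantines its partial outputs.
* Raising `t_cons` can only shrink the conserved-column set, and
  lowering the e-value ceiling can only remove annotations; both
  monotonicities are tested.

## Validation sizes

The shipped validation runs at these problem sizes: end-to-end truth
recovery on 200 noiseless genomes; filter behaviour with 50 planted
decoys of each kind across 60 single-locus genomes; count conservation
on 20 random 12-genome datasets; oracle equivalence on 100 random
fixtures per operation; restricted-association recovery at 500
single-effector loci with planted probabilities 0.30/0.66/0.81 (checked
within 3 binomial standard errors); a 160-genome run with orphan Csx15
planted so that about a quarter of Csx15-carrying genomes lack a locus;
and a 200-phage set with family weights 36:4:2 (Crn2:Csx20:Csx16).
`scripts/acceptance.R` recomputes all of these from scratch for any seed.

## Known limitations

* Subtype calling is not performed; subtypes are read from an optional
  typing table (interval overlap with the cas span) plus a manual
  override TSV, and default to `NA`.
* The conserved-residue screen is only as good as the reference
  alignment supplied per family; with no alignment a family's candidates
  are reported `not_screened`, never silently passed.
* The Cas10 motif heuristics will miss degenerate cyclase tetrads and
  unusual HD arrangements; they are meant for flagging, not mechanistic
  claims.
* Novel RN families cannot be discovered — the pipeline annotates
  configured families only.
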