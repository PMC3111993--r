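---
title: "Methods: evidence-hierarchy annotation and frameshift-tolerant alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evidence-hierarchy annotation and frameshift-tolerant alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prokannot)
```

This vignette documents the models, parameters and design choices behind
`prokannot`, in the spirit of a methods section: what is computed, under
which assumptions, and where the open design decisions were settled.

## The annotation model

Each predicted polypeptide receives exactly one functional annotation,
selected from per-evidence-type candidates by a fixed hierarchy. The
guiding principle is *specificity and reliability before coverage*:
an equivalog-level HMM (a family presumed isofunctional since its last
common ancestor) is more trustworthy than even a perfect pairwise match,
a trusted (experimentally characterized) pairwise match beats an
untrusted one, full-length agreement beats partial agreement, and
structure-only signals (membrane topology, lipoprotein signal peptides)
rank below any informative similarity but above nothing at all.

The final hierarchy has 17 ranks:

| Rank | Evidence | Criterion |
|-----:|----------|-----------|
| 1 | HMM | equivalog |
| 2 | BER | trusted, full query / full match |
| 3 | HMM | equivalog domain |
| 4 | BER | trusted, partial/full |
| 5–9 | HMM | subfamily, superfamily, subfamily domain, domain, Pfam |
| 10 | BER | trusted, full/partial |
| 11 | TMHMM | ≥ 5 membrane spans |
| 12 | LipoP | SpII prediction |
| 13 | HMM | hypothetical equivalog |
| 14–16 | BER | untrusted full/full, partial/full, full/partial |
| 17 | BER | ambiguous-sanitized |

A polypeptide with no surviving candidate is called
`hypothetical protein` and assigned the GO root terms
(`GO:0008150`, `GO:0003674`, `GO:0005575`). We represent this fallback as
a distinct sentinel (`final_rank = NA`, printed `HYPOTHETICAL`) rather
than an 18th numbered rank: the hierarchy table itself has 17 rows, and
keeping the fallback out of the rank arithmetic avoids any suggestion
that it competes with real evidence.

Two cells of the scheme deserve comment. BER matches that are *partial on
both sides* have no row in either hierarchy and therefore produce no
candidate (unless ambiguous-sanitized, which is coverage-independent):
a short local match to a fragment of a fragment carries too little signal
to transfer a name. And the two trusted rank-2 rows of the BER hierarchy
transfer annotations asymmetrically (partial-query/full-match copies GO
and roles from the subject; full-query/partial-match assigns GO roots and
the unknown-function role) — we implement the scheme exactly as printed,
since a full-length subject justifies transferring its ontology terms
while a partially covered subject does not.

### Thresholds

| Parameter | Default | Meaning |
|-----------|--------:|---------|
| `ber_min_identity_pct` | 40 | minimum % identity for a BER match to be considered |
| `full_coverage_cutoff_pct` | 80 | coverage (either side) at or above which a match is Full |
| `overlap_threshold_bp` | 60 | overlaps strictly greater trigger curation |
| `extension_nt` | 300 | extension on each side before BER alignment |
| `tmhmm_min_spans` | 5 | minimum predicted helices for a TMHMM annotation |
| `max_alignments` | 150 | retained alignments per gene |
| `blast_evalue` | 1e-5 | e-value cutoff of the seeding search |

All boundaries are inclusive on the "accept" side except the overlap rule
(strictly greater than 60 bp): identity ≥ 40 is retained, coverage ≥ 80 is
Full, ≥ 5 spans annotates. The 80% boundary itself is stated only as a
"cutoff" by the scheme; we classify exactly 80% as Full and expose the
cutoff as a parameter.

The ambiguous-term vocabulary (defaults: putative, probable, possible,
potential, predicted, uncharacterized, unknown, hypothetical, homolog,
like, related; word-boundary, case-insensitive) and the TIGR role table
are configurable. Only role 88 (*cell envelope: other*) is fixed by the
annotation scheme; the conserved-hypothetical / hypothetical /
unknown-function role ids shipped here (156, 704, 157) are editable
defaults, not a curated reconstruction.

## Frameshift-tolerant alignment

The aligner solves a local-alignment DP over states
(query nucleotide position $i$, subject residue $j$) with three matrices
(column-ending, query-gap, subject-gap; affine gaps at codon granularity,
open −11 / extend −1). Column transitions:

* **codon column**: 3 nt against 1 residue, scored by BLOSUM62, or by
  `stop_codon_score` (−10) when the codon is TAA/TAG/TGA — an in-frame
  stop event;
* **frame slip**: 1, 2, 4 or 5 nt against 1 residue, charged
  `frameshift_penalty` (−15), plus the trailing codon's substitution
  score when a full codon is consumed (4 or 5 nt) — a frameshift event.

Alignments start and end on a column (never in a gap), and traceback is
deterministic (transition order fixed, first maximum wins, best cell is
the first maximum in row-major scan), so identical inputs give identical
alignments.

The scoring parameters are package defaults, not published constants:
BLOSUM62/−11/−1 mirrors the seeding blastx configuration, and the slip
and stop penalties are deliberately stiffer than a gap open so that
disruptions are only invoked when flanking similarity strongly supports
bridging them — with the defaults, a bridge pays for itself only when
several residues match on both sides, which is the intended behaviour
for distinguishing real frameshifts from alignment noise. Gap columns do
not inspect codon content, so a stop codon deleted against a gap is not
reported as a disruption; only stops the alignment actually crosses are.

Percent identity counts identical residue pairs over all aligned columns
(gaps and slips included). Query coverage is measured against the
*unextended* gene's protein length — aligned codons in the extension do
not inflate it — while subject coverage is the aligned subject span over
subject length. Extension is applied exactly once before alignment and
never iterated; similarity running past the 300 nt window is by design a
manual-review matter, not something the aligner chases.

The DP is validated against an independent top-down memoized recursion
written directly from this scoring definition (500 random instances per
run, queries ≤ 24 nt, subjects ≤ 8 residues) and, with slip penalties set
to −∞, against a plain per-frame Smith–Waterman oracle.

Since the alignment scheme does not define a p-value, ranking uses the
seeding blast e-value when one is available and otherwise the
order-preserving surrogate $10^{-\mathrm{score}/10}$; only the ordering
of these values is ever used (vote tie-breaking, best-match selection).

## Structural curation

**Start candidates** are all in-frame ATG/GTG/TTG codons between the
nearest upstream in-frame stop (within the 300 nt extension) and the last
position leaving ≥ 30 codons of product, the annotated start always
included. An in-frame stop between a candidate and the gene's stop
disqualifies it, so a chosen start can never truncate the ORF.

**Voting** gives one vote per top-10 BER alignment whose subject residue
1 maps exactly onto a candidate (the tolerance is configurable; exact is
the default because subject starts that merely land nearby are weak
evidence), plus at most one RBS vote in total (the motif match is a
single signal, not one per alignment). Ties break by the smallest
supporting p-value, then to the annotated start. The RBS model — ≥ 4 of
6 positions of `AGGAGG` with a 4–14 nt spacer — is the canonical
Shine–Dalgarno consensus; motif, spacer window and match threshold are
parameters.

**Overlap curation** evaluates every pair overlapping by more than 60 bp
against the evidence state *before* any removal, so decisions cannot
cascade and the outcome is independent of input order. Evidence-free
genes overlapping an evidenced gene or an RNA are removed; everything
else above threshold (including pairs where both genes are evidence-free,
for which the removal rules name no victim) is flagged for manual review.
Start curation runs before overlap curation, and neither is iterated; a
second evidence round is expressed by simply re-running the evidence
stages on the curated models.

**Interevidence regions** are the complement of evidence-bearing features
within each contig, emitted at ≥ 90 nt for external re-search. rRNA and
tRNA features count as evidence-bearing here: BER and HMM evidence is
defined for polypeptides only, so treating RNAs as evidence-free would
re-report every RNA span forever. Gene addition from re-search hits is a
manual step, not automated.

## Post-processing

Name hygiene is an ordered, editable rule table (longest patterns first)
applied to a fixed point — at most 3 passes are needed for the shipped
rules, and each rule is idempotent. EC tokens (`d.d.d.d`, components
optionally `-`, final component optionally `n`-prefixed) are moved to the
EC field byte-for-byte: partial EC numbers are valid annotations and are
never "completed". Gene-symbol extraction is deliberately conservative —
only a trailing parenthesized, letter-initial token of ≤ 6 characters —
because a false symbol is worse than a missed one. Keyword-based role
backfill applies only when no informative role is present and the keyword
table is a shipped, editable fixture, not a reconstruction of any
production vocabulary. The whole stage is idempotent, which makes re-runs
safe.

## Output conventions

Internally all coordinates are 0-based half-open on the forward strand
with strand stored separately; GFF3 I/O (1-based inclusive) converts at
the boundary. Locus tags number CDS and RNA features in one shared
series — contigs by descending length (ties by id), features by start
coordinate (ties: longer first) — as `PREFIX_0001` steps of 1 by default.
Emission is deterministic to the byte.

## The synthetic fixtures, and what passing tests do not show

The fixture generator builds, from one integer seed, a two-contig
assembly whose genes are reverse-translated from random proteins with
uniform codon choice, plus matched evidence. Planted scenarios: a clean
gene (trusted full/full BER + equivalog HMM), a gene whose annotated GTG
start lies 30 nt downstream of the true ATG (upstream in-frame stop,
`AGGAGG` at 7 nt spacer, three concordant BER subjects), a gene with a
compensating +1/−1 frameshift, an evidenced gene with a nested
evidence-free decoy ORF overlapping it by 105 bp, lipoprotein-only,
membrane-only and no-evidence genes, and a minus-strand gene. BER
evidence rows are produced by actually running the aligner on the planted
gene–subject pairs, so coverages, identities, subject-start positions and
disruption events are real outputs, not typed-in numbers; sample sizes
(~10 genes, contigs of ~2–3 kb) keep a full pipeline run under a second.

The generator intentionally does **not** model realistic codon usage, GC
bias, overlapping-gene density, or the noise structure of real similarity
searches (paralogy, domain shuffling, partial database proteins). Passing
tests therefore demonstrate that the rule system and algorithms behave
exactly as specified on inputs with known truth — not that the default
thresholds are optimal for any particular genome. On real data the
thresholds, RBS consensus and ambiguous-term list are the knobs a user
should expect to revisit.

## Known limitations

* One annotation per polypeptide: bifunctional proteins receive only the
  top-ranked function (often as a `… domain protein`).
* Duplicate gene symbols across a genome are not arbitrated.
* The aligner reports disruptions for review; it does not re-call gene
  models across frameshifts.
* Similarity extending beyond the 300 nt extension window is not chased.
* No statistical significance model (Karlin–Altschul) for alignment
  scores; rankings are score/e-value orderings only.
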