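# prokannot

Evidence-hierarchy functional annotation and structural curation for
prokaryotic genomes.

## What this package does

Automated prokaryotic annotation workflows face two coupled problems after
gene prediction. First, the predicted gene *models* are imperfect: start
codons are often called too far downstream or upstream, high-GC genomes
produce long spurious ORFs that overlap real genes, and sequencing errors
introduce frameshifts and premature stops that fragment real genes. Second,
the predicted *proteins* must each receive exactly one functional
annotation — a common name, gene symbol, EC numbers, GO terms and a
TIGR functional role — from heterogeneous, partly contradictory evidence
(protein similarity searches, HMM family hits, lipoprotein-signal and
transmembrane predictions) of very different reliability.

`prokannot` implements the computational core of an evidence-driven
annotation pipeline that addresses both:

* **BER** (Blast-Extend-Repraze-style alignment): each predicted gene is
  extended by 300 nt on both sides and the extended nucleotide region is
  aligned against candidate subject proteins with a modified Smith–Waterman
  DP whose lattice runs over (query nucleotide × subject residue) states.
  Besides codon-sized diagonal moves and affine gaps, the DP admits
  *frame-slip* transitions consuming 1, 2, 4 or 5 nt per subject residue
  and *stop-codon columns*, so one alignment can run through frameshifts
  and in-frame stops — the signature of sequencing errors and pseudogenes —
  and past the annotated gene boundary. Disruption events feed a
  manual-review report.
* **Structural curation**: start sites are chosen by voting — every top
  BER alignment whose subject residue 1 lands on a candidate ATG/GTG/TTG
  contributes a vote, a Shine–Dalgarno match (≥4/6 to `AGGAGG`, 4–14 nt
  spacer) adds one, ties fall to the best p-value and then to the
  annotated start. Genes without BER/HMM evidence that overlap an
  evidenced gene or RNA by more than 60 bp are removed as false positives;
  other >60 bp overlaps are flagged. Maximal *interevidence regions*
  (intergenic sequence plus evidence-free genes) are emitted for external
  re-search.
* **pFunc**, the hierarchical annotation engine: matches below 40%
  identity are dropped; remaining BER matches are classified trusted /
  non-trusted (experimental characterization, curated experimental status,
  or GO evidence codes EXP/IDA/IPI/IMP/IGI/IEP) and Full/Partial on each
  side at 80% coverage; ambiguous non-trusted names (*putative…*,
  *probable…*) are sanitized to `conserved hypothetical protein`. Each
  evidence type is reduced to its best candidate (BER hierarchy; HMM
  isology hierarchy equivalog → … → Pfam, trusted-cutoff gated; TMHMM at
  ≥5 membrane spans; LipoP SpII), and a final 17-rank hierarchy picks the
  single winning annotation. Genes with no surviving candidate become
  `hypothetical protein` with the three GO root terms.
* **Post-processing**: suffix stutter from modifier composition is
  collapsed, embedded EC numbers and gene symbols are moved out of names
  (partial ECs kept verbatim), and high-level TIGR roles are backfilled
  from functional keywords when no role was assigned.
* **Output**: locus tags numbered sequentially from the first gene of the
  longest contig; GFF3, CDS/polypeptide FASTA and annotation TSV emission,
  byte-deterministic.

A deterministic fixture generator (`make_toy_assembly()`,
`make_evidence()`, `write_fixture_set()`) builds a two-contig toy assembly
with planted scenarios — clean gene, misannotated start, frameshifted
gene, overlapping decoy ORF, lipoprotein-only, membrane-only, no-evidence
gene — so the entire pipeline runs and is tested without any external
database.

## Worked example

```r
library(prokannot)

dir <- tempfile()
write_fixture_set(dir, seed = 1)          # toy assembly + evidence files

cfg <- run_config(
  genome        = file.path(dir, "genome.fna"),
  genes         = file.path(dir, "genes.gff3"),
  ber           = file.path(dir, "ber_evidence.tsv"),
  hmm           = file.path(dir, "hmm_evidence.tsv"),
  hmm_metadata  = file.path(dir, "hmm_metadata.tsv"),
  lipop         = file.path(dir, "lipop.txt"),
  tmhmm         = file.path(dir, "tmhmm.txt"),
  gaf           = file.path(dir, "goa.gaf"),
  characterized = file.path(dir, "characterized.txt"),
  locus_prefix  = "TOY", out = file.path(dir, "out"))
res <- run_annotate(cfg)

res$annotations[, c("gene_id", "common_name", "evidence_type", "final_rank")]
#>   gene_id                                 common_name evidence_type   final_rank
#> 1   g_c2a                        elongation factor Tu           BER            2
#> 2   g_c2b                  cell division protein FtsZ           BER            2
#> 3 g_clean                            adenylate kinase           HMM            1
#> 4 g_start                        ribosomal protein S2           BER            2
#> 5    g_fs possible DNA polymerase III subunit epsilon           BER           14
#> 6  g_ov_a         preprotein translocase subunit SecA           BER            2
#> 7  g_lipo                        putative lipoprotein         LipoP           12
#> 8  g_none                        hypothetical protein          none HYPOTHETICAL
#> 9   g_mem          putative integral membrane protein         TMHMM           11
```

Reading the output: `g_clean` carries both a trusted full/full BER match
and an above-cutoff equivalog HMM hit — the equivalog wins (final rank 1)
and transfers its name and symbol. `g_fs` has a planted +1/−1 frameshift,
so its untrusted match annotates it `possible …` (rank 14) and the gene
appears in `res$disruptions` with two frameshift events. The decoy ORF
`g_decoy` (105 bp overlap, no evidence) has been removed
(`res$removed`), and the misannotated start of `g_start` was moved 30 nt
upstream by 4 votes (3 concordant BER subject starts + the planted
Shine–Dalgarno motif, `res$start_report`).

The same pipeline is available from a shell via
`Rscript inst/cli/prokannot.R annotate --genome … --genes …` and
`… fixtures --seed 1 --out DIR`.

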