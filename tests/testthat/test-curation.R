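# build a contig with a designed upstream region around a planted ORF:
# [pad][upstream_block][ORF][pad]
planted_gene <- function(orf_aa = 40, upstream_block = "", pad = 350,
                         seed = 1) {
  set.seed(seed)
  aa <- random_aa(orf_aa)
  orf <- paste0(encode_protein(paste0("M", substr(aa, 2, orf_aa))), "TAA")
  left <- random_dna(pad)
  genome <- paste0(left, upstream_block, orf, random_dna(pad))
  start <- pad + nchar(upstream_block)
  list(contigs = Biostrings::DNAStringSet(c(c1 = genome)),
       gene = gene_table("g1", "c1", start, start + nchar(orf), "+")[1, ],
       orf = orf)
}

test_that("start candidates are in-frame starts bounded by upstream stops", {
  # upstream block: in-frame TAA immediately before the annotated ATG
  pg <- planted_gene(upstream_block = "TAA", seed = 2)
  cand <- enumerate_start_candidates(pg$contigs, pg$gene)
  expect_true(any(cand$is_annotated))
  expect_true(all(cand$codon %in% c("ATG", "GTG", "TTG")))
  # the annotated candidate has offset 0
  expect_equal(cand$offset_nt[cand$is_annotated], 0L)
  expect_equal(cand$offset_nt[cand$offset_nt >= 0][1], 0L)
  # an upstream in-frame ATG at -30 with a stop before it gives 2 upstream
  # candidates at known offsets
  blk <- paste0("TAA", "ATG", encode_protein(random_aa(9)))  # ATG at -30
  pg2 <- planted_gene(upstream_block = blk, seed = 3)
  cand2 <- enumerate_start_candidates(pg2$contigs, pg2$gene)
  expect_true(-30L %in% cand2$offset_nt)
  expect_true(0L %in% cand2$offset_nt)
  # candidate list is never empty and is ordered 5' to 3'
  expect_gte(nrow(cand2), 2)
  expect_true(all(diff(cand2$pos_ext) > 0))
})

test_that("candidate starts never sit upstream of an in-frame stop", {
  set.seed(4)
  for (rep in 1:10) {
    pg <- planted_gene(orf_aa = sample(35:60, 1), seed = 100 + rep)
    cand <- enumerate_start_candidates(pg$contigs, pg$gene)
    ext <- extend_query(pg$contigs, pg$gene)
    stop_at <- ext$upstream_pad + (pg$gene$end - pg$gene$start) - 3L
    for (p in cand$pos_ext) {
      span <- substr(ext$nt_sequence, p + 1, stop_at)
      codons <- substring(span, seq(1, nchar(span) - 2, 3),
                          seq(3, nchar(span), 3))
      expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
    }
  }
})

test_that("the RBS vote requires a 4-of-6 Shine-Dalgarno match in window", {
  # exact AGGAGG at spacer 7
  nt <- paste0(strrep("C", 50), "AGGAGG", strrep("C", 7), "ATG", strrep("C", 30))
  expect_equal(rbs_vote(nt, 63L), 1L)
  # all-T upstream: no vote
  nt0 <- paste0(strrep("T", 63), "ATG")
  expect_equal(rbs_vote(nt0, 63L), 0L)
  # AGGA core = 4 of 6 matching positions at spacer 6
  nt4 <- paste0(strrep("C", 50), "AGGACC", strrep("C", 6), "ATG")
  expect_equal(rbs_vote(nt4, 62L), 1L)
  # 3 of 6 is not enough
  nt3 <- paste0(strrep("C", 50), "AGGCCC", strrep("C", 6), "ATG")
  expect_equal(rbs_vote(nt3, 62L), 0L)
  # spacer outside 4..14 does not count
  ntfar <- paste0(strrep("C", 30), "AGGAGG", strrep("C", 20), "ATG")
  expect_equal(rbs_vote(ntfar, 56L), 0L)
})

test_that("start voting follows votes, then p-values, then the annotation", {
  cand <- data.frame(pos_ext = c(270L, 300L), offset_nt = c(-30L, 0L),
                     codon = c("ATG", "GTG"),
                     is_annotated = c(FALSE, TRUE))
  # three concordant alignments at the upstream candidate: it wins
  ber3 <- do.call(rbind, lapply(1:3, function(i)
    mk_ber("g1", paste0("S", i), ssq = 270L, p = 10^-(40 + i))))
  v <- vote_start_sites(cand, ber3)
  expect_equal(v$chosen$pos_ext, 270L)
  expect_equal(v$tally$ber_votes, c(3L, 0L))
  # zero evidence, zero RBS: annotated start is retained
  v0 <- vote_start_sites(cand, NULL)
  expect_true(v0$chosen$is_annotated)
  # 1-1 vote tie: the candidate with the better p-value wins
  ber_tie <- rbind(mk_ber("g1", "A", ssq = 270L, p = 1e-50),
                   mk_ber("g1", "B", ssq = 300L, p = 1e-10))
  vt <- vote_start_sites(cand, ber_tie)
  expect_equal(vt$chosen$pos_ext, 270L)
  vt2 <- vote_start_sites(cand, rbind(
    mk_ber("g1", "A", ssq = 270L, p = 1e-10),
    mk_ber("g1", "B", ssq = 300L, p = 1e-50)))
  expect_equal(vt2$chosen$pos_ext, 300L)
})

test_that("evidence presence applies the 40% identity and trusted-cutoff rules", {
  th <- pipeline_thresholds()
  b39 <- evidence_bundle("g1", ber = mk_ber(identity = 39.9))
  expect_false(has_evidence(b39, th))
  b40 <- evidence_bundle("g1", ber = mk_ber(identity = 40))
  expect_true(has_evidence(b40, th))
  bh <- evidence_bundle("g1", hmm = mk_hmm(score = 150, cutoff = 100))
  expect_true(has_evidence(bh, th))
  bh_low <- evidence_bundle("g1", hmm = mk_hmm(score = 99, cutoff = 100))
  expect_false(has_evidence(bh_low, th))
  expect_false(has_evidence(evidence_bundle("g1"), th))
})

overlap_features <- function(overlap_bp) {
  rbind(gene_table("gA", "c1", 0, 900, "+", partial5 = TRUE),
        gene_table("gB", "c1", 900 - overlap_bp, 1500 - overlap_bp, "+",
                   partial5 = TRUE))
}

test_that("overlap curation removes, flags or ignores by the 60 bp rule", {
  ev <- c(gA = TRUE, gB = FALSE)
  r61 <- curate_overlaps(overlap_features(61), ev)
  expect_equal(r61$removed$id, "gB")
  expect_equal(r61$decisions$action, "remove_b")
  r60 <- curate_overlaps(overlap_features(60), ev)
  expect_equal(nrow(r60$removed), 0)
  expect_equal(nrow(r60$decisions), 0)
  # both evidenced: flagged only
  r_both <- curate_overlaps(overlap_features(100), c(gA = TRUE, gB = TRUE))
  expect_equal(nrow(r_both$removed), 0)
  expect_equal(r_both$decisions$action, "flag")
  # both evidence-free: flagged, not removed
  r_none <- curate_overlaps(overlap_features(100),
                            c(gA = FALSE, gB = FALSE))
  expect_equal(nrow(r_none$removed), 0)
  expect_equal(r_none$decisions$action, "flag")
})

test_that("an evidence-free gene overlapping an RNA is removed", {
  feats <- rbind(
    gene_table("rrna1", "c1", 0, 1500, "+", feature_type = "rRNA"),
    gene_table("gB", "c1", 1400, 2000, "+", partial5 = TRUE))
  r <- curate_overlaps(feats, c(gB = FALSE))
  expect_equal(r$removed$id, "gB")
  expect_match(r$decisions$rationale, "RNA")
  # the same overlap with evidence: flagged
  r2 <- curate_overlaps(feats, c(gB = TRUE))
  expect_equal(nrow(r2$removed), 0)
  expect_equal(r2$decisions$action, "flag")
})

test_that("overlap curation conserves features and ignores input order", {
  set.seed(6)
  for (rep in 1:15) {
    n <- sample(4:9, 1)
    starts <- sort(sample.int(3000, n))
    feats <- do.call(rbind, lapply(seq_len(n), function(i)
      gene_table(paste0("g", i), "c1", starts[i],
                 starts[i] + sample(c(150L, 300L, 600L), 1), "+",
                 partial5 = TRUE)))
    ev <- stats::setNames(runif(n) < 0.5, feats$id)
    r <- curate_overlaps(feats, ev)
    expect_setequal(c(r$kept$id, r$removed$id), feats$id)
    expect_length(intersect(r$kept$id, r$removed$id), 0)
    expect_true(all(!ev[r$removed$id]))
    perm <- feats[sample.int(n), , drop = FALSE]
    r2 <- curate_overlaps(perm, ev)
    expect_setequal(r2$removed$id, r$removed$id)
    expect_equal(r2$decisions, r$decisions)
  }
})

test_that("interevidence regions span gaps plus evidence-free genes", {
  genes <- rbind(
    gene_table("g1", "c1", 100, 400, "+", partial5 = TRUE),
    gene_table("g2", "c1", 500, 800, "+", partial5 = TRUE),
    gene_table("g3", "c1", 900, 1200, "+", partial5 = TRUE))
  # all evidenced, gaps of 100 nt: regions are the short gaps + ends
  all_ev <- c(g1 = TRUE, g2 = TRUE, g3 = TRUE)
  r_all <- find_interevidence_regions("c1", 1300L, genes, all_ev,
                                      min_length = 150L)
  expect_equal(nrow(r_all), 0)
  # middle gene evidence-free: one region spanning gap+gene+gap
  mid <- c(g1 = TRUE, g2 = FALSE, g3 = TRUE)
  r_mid <- find_interevidence_regions("c1", 1300L, genes, mid,
                                      min_length = 150L)
  expect_equal(nrow(r_mid), 1)
  expect_equal(r_mid$start, 400L)
  expect_equal(r_mid$end, 900L)
  expect_equal(r_mid$member_gene_ids, "g2")
  # at a lower emission floor the contig-end gaps (100 nt) qualify too
  r_all90 <- find_interevidence_regions("c1", 1300L, genes, mid,
                                        min_length = 90L)
  expect_equal(nrow(r_all90), 3)
  # no genes at all: the whole contig is one region
  empty <- find_interevidence_regions("c1", 1300L, genes[0, ], logical(0))
  expect_equal(empty$start, 0L)
  expect_equal(empty$end, 1300L)
  # regions never intersect an evidenced gene
  for (k in seq_len(nrow(r_mid))) {
    for (i in which(unname(mid[genes$id]))) {
      expect_true(r_mid$end[k] <= genes$start[i] ||
                    r_mid$start[k] >= genes$end[i])
    }
  }
})

test_that("curated starts preserve open reading frames in the fixtures", {
  asm <- make_toy_assembly(1)
  ev <- make_evidence(asm)
  st <- curate_starts(asm$contigs, asm$genes, ev$ber)
  moved <- st$report$gene_id[st$report$moved]
  expect_true("g_start" %in% moved)
  expect_equal(st$report$chosen_offset_nt[st$report$gene_id == "g_start"],
               -30L)
  ok <- st$genes[st$genes$id != "g_fs", , drop = FALSE]
  tr <- translate_genes(asm$contigs, ok)
  expect_false(any(grepl("*", tr$aa_sequence, fixed = TRUE)))
})
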