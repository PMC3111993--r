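toy_contig <- function(seq) Biostrings::DNAStringSet(c(c1 = seq))

test_that("query extension pads 300 nt per side, clipped at contig ends", {
  set.seed(31)
  genome <- random_dna(5000)
  contigs <- toy_contig(genome)
  g <- gene_table("g1", "c1", 1000, 2000, "+", partial5 = TRUE,
                  partial3 = TRUE)
  ext <- extend_query(contigs, g[1, ])
  expect_equal(nchar(ext$nt_sequence), 1600)
  expect_equal(ext$upstream_pad, 300)
  expect_equal(ext$downstream_pad, 300)
  expect_equal(ext$original_start_offset, 300)
  expect_equal(ext$nt_sequence, substr(genome, 701, 2300))
  # edge clip at the contig start
  g2 <- gene_table("g2", "c1", 0, 300, "+", partial5 = TRUE)
  ext2 <- extend_query(contigs, g2[1, ])
  expect_equal(ext2$upstream_pad, 0)
  expect_equal(ext2$original_start_offset, 0)
  expect_equal(ext2$downstream_pad, 300)
  # minus strand: reverse complement of the forward window, pads swapped
  g3 <- gene_table("g3", "c1", 1000, 2000, "-", partial5 = TRUE,
                   partial3 = TRUE)
  ext3 <- extend_query(contigs, g3[1, ])
  expect_equal(ext3$nt_sequence,
               reverse_complement(substr(genome, 701, 2300)))
  g4 <- gene_table("g4", "c1", 100, 400, "-", partial5 = TRUE)
  ext4 <- extend_query(contigs, g4[1, ])
  expect_equal(ext4$upstream_pad, 300)    # genomic right of a minus gene
  expect_equal(ext4$downstream_pad, 100)
  expect_error(extend_query(contigs, gene_table("g5", "c9", 0, 30, "+",
                                                partial5 = TRUE)[1, ]),
               "unknown contig")
})

test_that("exact in-frame matches align with full identity, no events", {
  aa <- "MKLVNDEWFG"
  a <- align_frameshift(encode_protein(aa), aa)
  expect_equal(a$percent_identity, 100)
  expect_equal(a$n_columns, nchar(aa))
  expect_equal(nrow(a$disruptions), 0)
  expect_equal(a$subject_range, c(1L, nchar(aa)))
  expect_equal(a$subject_start_query_nt, 0L)
  expect_error(align_frameshift("ATGAAA", ""), "non-empty")
})

test_that("an inserted nucleotide is bridged by one frameshift event", {
  aa <- "MKLVNDEWFGHIKRST"           # 8 residues each side of the insert
  nt <- encode_protein(aa)
  q <- paste0(substr(nt, 1, 24), "C", substr(nt, 25, 48))
  a <- align_frameshift(q, aa)
  expect_equal(sum(a$columns$identical), nchar(aa))
  expect_equal(a$disruptions$kind, "frameshift")
  expect_equal(nrow(a$disruptions), 1)
  # score matches the independent reference recursion
  expect_equal(a$score, ref_frameshift_score(q, aa))
})

test_that("an in-frame stop codon is crossed and reported", {
  left <- "MKLVNDEW"; right <- "FGHIKRST"
  q <- paste0(encode_protein(left), "TAA", encode_protein(right))
  subject <- paste0(left, "A", right)
  a <- align_frameshift(q, subject)
  expect_true("in_frame_stop" %in% a$disruptions$kind)
  expect_equal(sum(a$columns$identical), 16)
  expect_true(any(a$columns$aa_q == "*", na.rm = TRUE))
})

test_that("DP score equals the reference recursion on random instances", {
  set.seed(42)
  schemes <- list(
    c(open = -11, ext = -1, fs = -15, stp = -10),
    c(open = -8, ext = -2, fs = -6, stp = -4)
  )
  n_ok <- 0
  for (rep in 1:500) {
    n <- sample(3:24, 1)
    m <- sample(1:8, 1)
    nt <- random_dna(n)
    aa <- random_aa(m)
    sc <- schemes[[1 + rep %% 2]]
    scheme <- scoring_scheme(gap_open = sc[["open"]],
                             gap_extend = sc[["ext"]],
                             frameshift_penalty = sc[["fs"]],
                             stop_codon_score = sc[["stp"]])
    got <- align_frameshift(nt, aa, scheme)$score
    want <- ref_frameshift_score(nt, aa, open = sc[["open"]],
                                 ext = sc[["ext"]], fs = sc[["fs"]],
                                 stp = sc[["stp"]])
    expect_equal(got, want, info = sprintf("nt=%s aa=%s", nt, aa))
    n_ok <- n_ok + (got == want)
  }
  expect_equal(n_ok, 500)
})

test_that("infinite slip penalties reduce to per-frame Smith-Waterman", {
  set.seed(43)
  scheme <- scoring_scheme(frameshift_penalty = -Inf,
                           stop_codon_score = -10)
  for (rep in 1:60) {
    nt <- random_dna(sample(9:45, 1))
    aa <- random_aa(sample(2:10, 1))
    got <- align_frameshift(nt, aa, scheme)$score
    frames <- frame_translations(nt)
    want <- max(vapply(frames, ref_sw_score, numeric(1), saa = aa))
    expect_equal(got, want, info = nt)
  }
})

test_that("appending unrelated sequence never decreases the local score", {
  set.seed(44)
  for (rep in 1:40) {
    nt <- random_dna(sample(12:36, 1))
    aa <- random_aa(sample(3:8, 1))
    s1 <- align_frameshift(nt, aa)$score
    s2 <- align_frameshift(paste0(nt, random_dna(sample(3:15, 1))),
                           aa)$score
    expect_gte(s2, s1)
  }
})

test_that("mapped query positions increase strictly along the alignment", {
  set.seed(45)
  for (rep in 1:40) {
    aa <- random_aa(sample(6:20, 1))
    nt <- encode_protein(aa)
    if (rep %% 2 == 0) {                 # plant an indel
      at <- sample(6:(nchar(nt) - 6), 1)
      nt <- paste0(substr(nt, 1, at), "G", substr(nt, at + 1, nchar(nt)))
    }
    a <- align_frameshift(nt, aa)
    qp <- a$columns$q_codon_start[!is.na(a$columns$q_codon_start)]
    expect_true(all(diff(qp) > 0))
    sp <- a$columns$s_pos[a$columns$op != 5]
    expect_true(all(diff(sp) > 0))
  }
})

test_that("alignment metrics exclude extension residues from query coverage", {
  aa <- random_aa(100)
  nt <- paste0(encode_protein(paste0("M", substr(aa, 2, 100))), "TAA")
  set.seed(46)
  genome <- paste0(random_dna(400), nt, random_dna(400))
  contigs <- toy_contig(genome)
  g <- gene_table("g1", "c1", 400, 400 + nchar(nt), "+")
  ext <- extend_query(contigs, g[1, ])
  prot <- translate_cds(nt)
  # full-length exact match: all three metrics 100
  a <- align_frameshift(ext, prot)
  met <- alignment_metrics(a, ext, g[1, ], prot)
  expect_equal(unname(met), c(100, 100, 100))
  # subject twice as long: subject coverage 50
  prot2 <- paste0(prot, random_aa(100))
  a2 <- align_frameshift(ext, prot2)
  met2 <- alignment_metrics(a2, ext, g[1, ], prot2)
  expect_equal(met2[["subject_cov"]], 50)
  # subject extending 10 residues upstream of the start: the upstream
  # residues align in the extension but do not count toward query coverage
  up <- random_aa(10)
  prot3 <- paste0(up, prot)
  genome3 <- paste0(substr(genome, 1, 400 - 30), encode_protein(up), nt,
                    random_dna(400))
  contigs3 <- toy_contig(genome3)
  g3 <- gene_table("g1", "c1", 400, 400 + nchar(nt), "+")
  ext3 <- extend_query(contigs3, g3[1, ])
  a3 <- align_frameshift(ext3, prot3)
  met3 <- alignment_metrics(a3, ext3, g3[1, ], prot3)
  expect_equal(met3[["query_cov"]], 100)
  expect_equal(met3[["subject_cov"]], 100)
  expect_equal(a3$subject_start_query_nt, ext3$upstream_pad - 30L)
})

test_that("the disruption report lists planted events and only those", {
  expect_equal(nrow(disruption_report(mk_ber("g1", nfs = 0L))), 0)
  ber <- rbind(
    mk_ber("g1", "S1"),
    mk_ber("g2", "S2", nfs = 1L, disr = "frameshift:75"),
    mk_ber("g3", "S3", nstops = 1L, disr = "in_frame_stop:120"))
  rep <- disruption_report(ber)
  expect_equal(rep$gene_id, c("g2", "g3"))
  expect_equal(rep$kind, c("frameshift", "in_frame_stop"))
  expect_equal(rep$query_nt_position, c(75L, 120L))
})
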