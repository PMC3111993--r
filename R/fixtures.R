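## Deterministic synthetic fixtures: a toy assembly with planted scenarios
## (clean gene, upstream start variant, frameshifted gene, overlapping decoy
## ORF, lipoprotein-only, membrane-only, no-evidence gene) plus matched
## evidence files, so every pipeline stage is testable without downloads.
## A single integer seed drives one RNG stream; same seed, same bytes.

with_fixture_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

codons_for <- function() {
  gc11 <- GENETIC_CODE_11
  split(names(gc11), gc11)
}

random_protein <- function(n_aa, first_m = TRUE) {
  aas <- setdiff(unique(GENETIC_CODE_11), "*")
  p <- sample(aas, n_aa, replace = TRUE)
  if (first_m) p[1] <- "M"
  paste(p, collapse = "")
}

## reverse-translate a protein with random synonymous codons; start codon
## fixed to ATG, one stop appended
reverse_translate <- function(aa, codon_table = codons_for(),
                              stop_codon = "TAA") {
  res <- vapply(strsplit(aa, "")[[1]], function(a) {
    opts <- codon_table[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  res[1] <- "ATG"
  paste0(paste(res, collapse = ""), stop_codon)
}

random_spacer <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(.3, .2, .2, .3)), collapse = "")
}

#' Generate the toy assembly with planted curation scenarios
#'
#' Two contigs (the longer listed second, exercising longest-first locus
#' numbering). Planted scenarios: a clean gene with strong evidence; a gene
#' whose annotated GTG start sits 30 nt downstream of the true ATG start
#' (with an upstream in-frame stop and a Shine-Dalgarno AGGAGG 7 nt before
#' the ATG); a gene carrying a compensating +1/-1 frameshift relative to
#' its subject protein; an evidenced gene with a nested evidence-free decoy
#' ORF overlapping it by 105 bp; a lipoprotein-signal-only gene; a
#' membrane-protein-only gene; a gene with no evidence at all; and two
#' clean genes (one minus strand) on the second contig.
#'
#' @param seed Integer seed.
#' @return List with `contigs` (named `DNAStringSet`), `genes` (gene-model
#'   table), `proteins` (named list of the true protein sequences) and
#'   `scenarios` (named list of per-gene scenario descriptors).
#' @export
make_toy_assembly <- function(seed = 1L) {
  with_fixture_seed(seed, {
    ct <- codons_for()
    scen <- list()
    proteins <- list()

    ## --- scenario proteins -------------------------------------------
    p_clean <- random_protein(120)
    p_start_full <- random_protein(81)           # from the true ATG
    sp <- strsplit(p_start_full, "")[[1]]
    sp[11] <- "V"                                 # annotated start codon GTG
    p_start_full <- paste(sp, collapse = "")
    p_fs <- random_protein(60)
    p_ov <- random_protein(80)
    po <- strsplit(p_ov, "")[[1]]
    po[47] <- "M"                                 # decoy start inside the ORF
    p_ov <- paste(po, collapse = "")
    p_lipo <- random_protein(90)
    p_mem <- random_protein(110)
    p_none <- random_protein(50)
    p_c2a <- random_protein(100)
    p_c2b <- random_protein(70)

    nt_clean <- reverse_translate(p_clean, ct)
    nt_start <- reverse_translate(p_start_full, ct)
    ## force codon 11 (the annotated start) to GTG
    substr(nt_start, 31, 33) <- "GTG"
    nt_fs0 <- reverse_translate(p_fs, ct)
    ## +1 insertion after codon 25, -1 deletion at codon 51
    nt_fs <- paste0(substr(nt_fs0, 1, 75), "A", substr(nt_fs0, 76, 150),
                    substr(nt_fs0, 152, nchar(nt_fs0)))
    nt_ov <- reverse_translate(p_ov, ct)
    nt_lipo <- reverse_translate(p_lipo, ct)
    nt_mem <- reverse_translate(p_mem, ct)
    nt_none <- reverse_translate(p_none, ct)
    nt_c2a <- reverse_translate(p_c2a, ct)
    nt_c2b <- reverse_translate(p_c2b, ct)

    ## upstream block of the start-variant gene, relative to its true ATG:
    ## in-frame TAA, 5 nt filler, AGGAGG, 7 nt spacer (21 nt, multiple of 3)
    up_start <- paste0("TAA", "CCCCC", "AGGAGG", "CTTCTTC")
    stopifnot(nchar(up_start) %% 3L == 0L)

    ## --- contig 1 (long) ----------------------------------------------
    spacers <- replicate(8, random_spacer(150L + sample.int(40L, 1L)))
    genes <- list()
    seqs <- character(0)
    pos <- 0L
    add <- function(piece) {
      seqs <<- c(seqs, piece)
      at <- pos
      pos <<- pos + nchar(piece)
      at
    }
    add(spacers[1])
    g_clean_start <- add(nt_clean)
    add(spacers[2])
    add(up_start)
    start_atg <- add(nt_start)          # true ATG position
    add(spacers[3])
    g_fs_start <- add(nt_fs)
    add(spacers[4])
    g_ov_start <- add(nt_ov)
    add(spacers[5])
    g_lipo_start <- add(nt_lipo)
    add(spacers[6])
    g_none_start <- add(nt_none)
    add(spacers[7])
    g_mem_start <- add(nt_mem)
    add(spacers[8])
    contig1 <- paste(seqs, collapse = "")

    ## --- contig 2 (short; listed first in the assembly) ---------------
    sp2 <- replicate(3, random_spacer(400L + sample.int(60L, 1L)))
    seqs <- character(0); pos <- 0L
    add(sp2[1])
    g_c2a_start <- add(nt_c2a)
    add(sp2[2])
    g_c2b_start <- add(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(nt_c2b))))
    add(sp2[3])
    contig2 <- paste(seqs, collapse = "")
    stopifnot(nchar(contig2) < nchar(contig1))

    contigs <- Biostrings::DNAStringSet(c(ctg_short = contig2,
                                          ctg_long = contig1))

    mk <- function(id, contig, start, len, strand = "+") {
      data.frame(id = id, contig_id = contig, start = as.integer(start),
                 end = as.integer(start + len), strand = strand,
                 feature_type = "CDS", locus_tag = NA_character_,
                 partial5 = FALSE, partial3 = FALSE,
                 stringsAsFactors = FALSE)
    }
    genes <- rbind(
      mk("g_c2a", "ctg_short", g_c2a_start, nchar(nt_c2a)),
      mk("g_c2b", "ctg_short", g_c2b_start, nchar(nt_c2b), "-"),
      mk("g_clean", "ctg_long", g_clean_start, nchar(nt_clean)),
      ## annotated start is the GTG 30 nt into the true ORF
      mk("g_start", "ctg_long", start_atg + 30L, nchar(nt_start) - 30L),
      mk("g_fs", "ctg_long", g_fs_start, nchar(nt_fs)),
      mk("g_ov_a", "ctg_long", g_ov_start, nchar(nt_ov)),
      ## nested decoy: 102 nt of ORF tail + the shared stop codon
      mk("g_decoy", "ctg_long", g_ov_start + nchar(nt_ov) - 105L, 105L),
      mk("g_lipo", "ctg_long", g_lipo_start, nchar(nt_lipo)),
      mk("g_none", "ctg_long", g_none_start, nchar(nt_none)),
      mk("g_mem", "ctg_long", g_mem_start, nchar(nt_mem))
    )
    validate_gene_table(genes, contigs)

    proteins <- list(
      g_clean = p_clean, g_start_full = p_start_full, g_fs = p_fs,
      g_ov_a = p_ov, g_lipo = p_lipo, g_mem = p_mem, g_none = p_none,
      g_c2a = p_c2a, g_c2b = p_c2b)

    scen <- list(
      clean_gene = "g_clean", upstream_start_variant = "g_start",
      frameshifted_gene = "g_fs", overlapping_pair = c("g_ov_a", "g_decoy"),
      lipoprotein_only = "g_lipo", membrane_only = "g_mem",
      no_evidence = c("g_none", "g_decoy"),
      disrupted = "g_fs", start_offset_nt = -30L)

    list(contigs = contigs, genes = genes, proteins = proteins,
         scenarios = scen)
  })
}

#' Generate matched synthetic evidence for the toy assembly
#'
#' Subject proteins are the planted true proteins; BER evidence rows are
#' produced by actually running the frameshift-tolerant aligner on the
#' seeded gene-subject pairs, so coverages, identities, subject-start
#' positions and disruption events are real alignment output. HMM, LipoP,
#' TMHMM, GAF and characterized-list inputs are written per scenario.
#'
#' @param assembly Output of [make_toy_assembly()].
#' @param thresholds [pipeline_thresholds()].
#' @return List with `ber`, `hmm_hits` (raw TSV shape), `hmm_metadata`,
#'   `lipop_lines`, `tmhmm_lines`, `gaf_lines`, `characterized`,
#'   `subjects`, `subject_info`, `seeds`.
#' @export
make_evidence <- function(assembly, thresholds = pipeline_thresholds()) {
  subjects <- c(
    S_clean = assembly$proteins$g_clean,
    S_start1 = assembly$proteins$g_start_full,
    S_start2 = assembly$proteins$g_start_full,
    S_start3 = assembly$proteins$g_start_full,
    S_fs = assembly$proteins$g_fs,
    S_ov = assembly$proteins$g_ov_a,
    S_c2a = assembly$proteins$g_c2a,
    S_c2b = assembly$proteins$g_c2b)
  subject_info <- data.frame(
    subject_id = c("S_clean", "S_start1", "S_start2", "S_start3", "S_fs",
                   "S_ov", "S_c2a", "S_c2b"),
    name = c("adenylate kinase", "ribosomal protein S2",
             "ribosomal protein S2", "30S ribosomal protein S2",
             "DNA polymerase III subunit epsilon",
             "preprotein translocase subunit SecA",
             "elongation factor Tu", "cell division protein FtsZ"),
    symbol = c("adk", "rpsB", "rpsB", "rpsB", "dnaQ", "secA", "tuf", "ftsZ"),
    ecs = c("2.7.4.3", "", "", "", "2.7.7.7", "", "", ""),
    go = c("GO:0004017|IDA", "GO:0003735|IDA", "GO:0003735|IDA",
           "GO:0003735|IDA", "GO:0003887|IEA", "GO:0015450|IDA",
           "GO:0003746|IDA", "GO:0003924|IDA"),
    tigr_roles = c("120", "133", "133", "133", "132", "64", "133", "101"),
    stringsAsFactors = FALSE)
  seeds <- data.frame(
    gene_id = c("g_clean", "g_start", "g_start", "g_start", "g_fs",
                "g_ov_a", "g_c2a", "g_c2b"),
    subject_id = c("S_clean", "S_start1", "S_start2", "S_start3", "S_fs",
                   "S_ov", "S_c2a", "S_c2b"),
    evalue = c(1e-80, 1e-60, 1e-55, 1e-50, 1e-40, 1e-70, 1e-65, 1e-45),
    stringsAsFactors = FALSE)
  ## minimal 12-column blast-shaped seed table
  seeds$percent_identity <- 100
  seeds$alignment_length <- 0L; seeds$mismatches <- 0L
  seeds$gap_opens <- 0L; seeds$query_start <- 0L; seeds$query_end <- 0L
  seeds$subject_start <- 0L; seeds$subject_end <- 0L
  seeds$subject_frame <- 1L; seeds$bit_score <- 0

  gaf_lines <- c(
    "!gaf-version: 2.1",
    vapply(c("S_start1", "S_start2", "S_start3"), function(s)
      paste("FIXDB", s, "rpsB", "", "GO:0003735", "FIX:0001", "IDA", "",
            "F", "ribosomal protein S2", "", "protein", "taxon:562",
            "20260101", "FIXDB", sep = "\t"), character(1)),
    paste("FIXDB", "S_fs", "dnaQ", "", "GO:0003887", "FIX:0002", "IEA", "",
          "F", "DNA polymerase III subunit epsilon", "", "protein",
          "taxon:562", "20260101", "FIXDB", sep = "\t"))
  characterized <- c("S_clean", "S_ov", "S_c2a", "S_c2b")

  ber <- ber_search(assembly$contigs, assembly$genes, subjects,
                    subject_info = subject_info, seeds = seeds,
                    gaf = parse_gaf(gaf_lines),
                    characterized = characterized,
                    thresholds = thresholds)

  hmm_metadata <- data.frame(
    accession = c("TGR0001", "TGR0002", "PF00010"),
    name = c("adenylate kinase", "two-component sensor histidine kinase",
             "helix-turn-helix"),
    isology = c("equivalog", "subfamily", "pfam"),
    trusted_cutoff = c(100, 120, 25),
    symbol = c("adk", "", ""),
    ecs = c("2.7.4.3", "2.7.13.3", ""),
    go = c("GO:0004017|IEA", "GO:0000155|IEA", ""),
    tigr_roles = c("120", "129", ""),
    stringsAsFactors = FALSE)
  hmm_hits <- data.frame(
    gene_id = c("g_clean", "g_none"),
    accession = c("TGR0001", "TGR0002"),
    total_score = c(150, 50),          # g_none's hit is below cutoff
    stringsAsFactors = FALSE)

  lipop_lines <- c(
    "# g_lipo SpII score=17.06 margin=10.51 cleavage=18-19",
    "# g_clean CYT score=-0.20")
  tmhmm_lines <- c(
    paste0("g_mem\tlen=110\tExpAA=151.2\tFirst60=22.4\tPredHel=7\t",
           "Topology=o10-29i41-60o75-94i106-125o140-159i170-189o200-219i"),
    "g_clean\tlen=120\tExpAA=0.05\tFirst60=0.01\tPredHel=0\tTopology=o")

  list(ber = ber, hmm_hits = hmm_hits, hmm_metadata = hmm_metadata,
       lipop_lines = lipop_lines, tmhmm_lines = tmhmm_lines,
       gaf_lines = gaf_lines, characterized = characterized,
       subjects = subjects, subject_info = subject_info, seeds = seeds)
}

#' Write a complete fixture set to a directory
#'
#' Emits `genome.fna`, `genes.gff3`, `ber_evidence.tsv`,
#' `hmm_evidence.tsv`, `hmm_metadata.tsv`, `lipop.txt`, `tmhmm.txt`,
#' `goa.gaf`, `characterized.txt` and `subjects.faa`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  asm <- make_toy_assembly(seed)
  ev <- make_evidence(asm)
  Biostrings::writeXStringSet(asm$contigs, file.path(dir, "genome.fna"),
                              width = 70L)
  g <- asm$genes
  con <- file(file.path(dir, "genes.gff3"), open = "wt")
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(g))) {
    co <- internal_to_gff(g$start[i], g$end[i])
    writeLines(paste(g$contig_id[i], "fixture", g$feature_type[i],
                     co$start, co$end, ".", g$strand[i],
                     if (g$feature_type[i] == "CDS") "0" else ".",
                     paste0("ID=", g$id[i]), sep = "\t"), con)
  }
  close(con)
  write_ber_evidence(ev$ber, file.path(dir, "ber_evidence.tsv"))
  utils::write.table(ev$hmm_hits, file.path(dir, "hmm_evidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ev$hmm_metadata, file.path(dir, "hmm_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(ev$lipop_lines, file.path(dir, "lipop.txt"))
  writeLines(ev$tmhmm_lines, file.path(dir, "tmhmm.txt"))
  writeLines(ev$gaf_lines, file.path(dir, "goa.gaf"))
  writeLines(ev$characterized, file.path(dir, "characterized.txt"))
  aa <- Biostrings::AAStringSet(ev$subjects)
  Biostrings::writeXStringSet(aa, file.path(dir, "subjects.faa"),
                              width = 70L)
  invisible(dir)
}
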