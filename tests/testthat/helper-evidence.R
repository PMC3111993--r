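# Row constructors for synthetic evidence used across tests.

mk_ber <- function(gene_id = "g1", subject_id = "S1",
                   name = "preprotein translocase subunit SecA",
                   symbol = "", ecs = "", go = "", roles = "",
                   identity = 95, qcov = 95, scov = 95, p = 1e-50,
                   trusted = TRUE, nfs = 0L, nstops = 0L,
                   ssq = NA_integer_, disr = "") {
  data.frame(gene_id = gene_id, subject_id = subject_id,
             subject_name = name, subject_symbol = symbol,
             subject_ecs = ecs, subject_go = go,
             subject_tigr_roles = roles, percent_identity = identity,
             query_coverage_pct = qcov, subject_coverage_pct = scov,
             p_value = p, trusted = trusted, n_frameshifts = nfs,
             n_stops = nstops, subject_start_query_nt = ssq,
             disruptions = disr, stringsAsFactors = FALSE)
}

mk_hmm <- function(gene_id = "g1", accession = "T0001", score = 150,
                   cutoff = 100, isology = "equivalog",
                   name = "adenylate kinase", symbol = "", ecs = "",
                   go = "", roles = "") {
  data.frame(gene_id = gene_id, accession = accession,
             total_score = score, trusted_cutoff = cutoff,
             isology = isology, hmm_name = name, hmm_symbol = symbol,
             hmm_ecs = ecs, hmm_go = go, hmm_tigr_roles = roles,
             passes_trusted = score >= cutoff, stringsAsFactors = FALSE)
}

mk_lipop <- function(gene_id = "g1", best_class = "SpII", score = 15) {
  data.frame(gene_id = gene_id, best_class = best_class, score = score,
             predicted_lipoprotein = best_class == "SpII",
             stringsAsFactors = FALSE)
}

mk_tmhmm <- function(gene_id = "g1", helices = 7L) {
  data.frame(gene_id = gene_id, predicted_helices = as.integer(helices),
             topology = "o", stringsAsFactors = FALSE)
}

# a random evidence bundle for property tests; returns list(bundle parts)
random_bundle <- function(gene_id = "g1") {
  ber <- NULL
  if (runif(1) < 0.7) {
    k <- sample(1:3, 1)
    ber <- do.call(rbind, lapply(seq_len(k), function(i) {
      mk_ber(gene_id, subject_id = paste0("S", i),
             name = sample(c("alcohol dehydrogenase", "putative kinase",
                             "elongation factor Tu"), 1),
             identity = runif(1, 20, 100), qcov = runif(1, 40, 100),
             scov = runif(1, 40, 100),
             p = 10^-runif(1, 5, 80), trusted = runif(1) < 0.5)
    }))
  }
  hmm <- NULL
  if (runif(1) < 0.6) {
    k <- sample(1:2, 1)
    hmm <- do.call(rbind, lapply(seq_len(k), function(i) {
      iso <- sample(c("equivalog", "equivalog_domain", "subfamily",
                      "superfamily", "subfamily_domain", "domain", "pfam",
                      "hypothetical_equivalog"), 1)
      mk_hmm(gene_id, accession = paste0("T", i),
             score = runif(1, 50, 200), cutoff = 100, isology = iso)
    }))
  }
  lipop <- if (runif(1) < 0.3) mk_lipop(gene_id) else NULL
  tmhmm <- if (runif(1) < 0.3) mk_tmhmm(gene_id, sample(3:9, 1)) else NULL
  list(ber = ber, hmm = hmm, lipop = lipop, tmhmm = tmhmm)
}

ann_key <- function(ann) {
  paste(ann$common_name, ann$gene_symbol, ann$evidence_type,
        ann$final_rank, ann$provenance,
        paste(ann$go_terms, collapse = ","),
        paste(ann$tigr_roles, collapse = ","), sep = "|")
}
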