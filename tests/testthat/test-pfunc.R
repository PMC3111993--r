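th <- pipeline_thresholds()

test_that("the identity filter keeps exactly matches at or above 40%", {
  ber <- rbind(mk_ber(identity = 10), mk_ber(subject_id = "S2",
                                             identity = 39.99),
               mk_ber(subject_id = "S3", identity = 40),
               mk_ber(subject_id = "S4", identity = 95))
  kept <- filter_ber(ber, th)
  expect_setequal(kept$subject_id, c("S3", "S4"))
  expect_equal(nrow(filter_ber(ber[0, ], th)), 0)
  expect_equal(filter_ber(kept, th), kept)       # idempotent
})

test_that("coverage classifies Full exactly at the 80% cutoff", {
  expect_equal(coverage_class(c(79.99, 80, 80.01, 100), th),
               c("Partial", "Full", "Full", "Full"))
})

test_that("ambiguous non-trusted names are sanitized, trusted never", {
  b <- sanitize_ambiguous(mk_ber(name = "putative kinase",
                                 trusted = FALSE, go = "GO:0016301|IEA",
                                 roles = "130"))
  expect_true(b$ambiguous)
  expect_equal(b$subject_name, "conserved hypothetical protein")
  expect_setequal(sub("\\|.*$", "", strsplit(b$subject_go, ",")[[1]]),
                  c("GO:0008150", "GO:0003674", "GO:0005575"))
  expect_equal(b$subject_tigr_roles,
               as.character(default_tigr_roles()$conserved_hypothetical))
  t <- sanitize_ambiguous(mk_ber(name = "putative kinase", trusted = TRUE))
  expect_false(t$ambiguous)
  expect_equal(t$subject_name, "putative kinase")
  # word boundary: an embedded fragment does not trigger sanitization
  wb <- sanitize_ambiguous(mk_ber(name = "computative-style kinase",
                                  trusted = FALSE),
                           ambiguous_terms = "putative")
  expect_false(wb$ambiguous)
  # case-insensitive
  up <- sanitize_ambiguous(mk_ber(name = "Probable transporter",
                                  trusted = FALSE))
  expect_true(up$ambiguous)
})

test_that("the BER hierarchy maps every printed row exactly", {
  cases <- list(
    #    trusted qcov scov  within final  name                    copied
    list(TRUE,  95, 95, 1L,  2L, "preprotein translocase subunit SecA",
         TRUE),
    list(TRUE,  95, 60, 2L, 10L,
         "preprotein translocase subunit SecA domain protein", FALSE),
    list(TRUE,  60, 95, 2L,  4L,
         "preprotein translocase subunit SecA domain protein", TRUE),
    list(FALSE, 95, 95, 3L, 14L,
         "possible preprotein translocase subunit SecA", TRUE),
    list(FALSE, 60, 95, 4L, 15L,
         "possible preprotein translocase subunit SecA domain protein",
         FALSE),
    list(FALSE, 95, 60, 4L, 16L,
         "possible preprotein translocase subunit SecA domain protein",
         FALSE)
  )
  for (cs in cases) {
    m <- sanitize_ambiguous(mk_ber(trusted = cs[[1]], qcov = cs[[2]],
                                   scov = cs[[3]], go = "GO:0015450|IDA",
                                   roles = "64"))
    cand <- rank_ber(m, th)
    expect_equal(cand$within_type_rank, cs[[4]])
    expect_equal(cand$final_rank, cs[[5]])
    expect_equal(cand$common_name, cs[[6]])
    if (cs[[7]]) {
      expect_equal(cand$go_terms, "GO:0015450")
      expect_equal(cand$tigr_roles, 64L)
    } else {
      expect_setequal(cand$go_terms,
                      c("GO:0008150", "GO:0003674", "GO:0005575"))
      expect_equal(cand$tigr_roles,
                   default_tigr_roles()$unknown_function)
    }
  }
  # ambiguous-sanitized: within rank 5, final rank 17, fixed name
  amb <- sanitize_ambiguous(mk_ber(name = "putative kinase",
                                   trusted = FALSE))
  ca <- rank_ber(amb, th)
  expect_equal(ca$within_type_rank, 5L)
  expect_equal(ca$final_rank, 17L)
  expect_equal(ca$common_name, "conserved hypothetical protein")
  # partial/partial has no hierarchy row
  pp <- sanitize_ambiguous(mk_ber(qcov = 60, scov = 60))
  expect_null(rank_ber(pp, th))
})

test_that("the best BER match minimizes rank, then p-value, then id", {
  ber <- rbind(mk_ber(subject_id = "S1", qcov = 60, scov = 95, p = 1e-90),
               mk_ber(subject_id = "S2", qcov = 95, scov = 95, p = 1e-20))
  expect_equal(best_ber(ber, th)$provenance, "S2")      # rank 1 < rank 2
  tie <- rbind(mk_ber(subject_id = "S1", p = 1e-80),
               mk_ber(subject_id = "S2", p = 1e-20))
  expect_equal(best_ber(tie, th)$provenance, "S1")      # smaller p
  same <- rbind(mk_ber(subject_id = "S2", p = 1e-50),
                mk_ber(subject_id = "S1", p = 1e-50))
  expect_equal(best_ber(same, th)$provenance, "S1")     # lexicographic
  expect_null(best_ber(mk_ber()[0, ], th))
})

test_that("the HMM hierarchy maps isologies, suffixes and cutoffs exactly", {
  rows <- list(
    list("equivalog", 1L, 1L, ""),
    list("equivalog_domain", 2L, 3L, ""),
    list("subfamily", 3L, 5L, " family protein"),
    list("superfamily", 4L, 6L, " family protein"),
    list("subfamily_domain", 5L, 7L, " domain protein"),
    list("domain", 6L, 8L, " domain protein"),
    list("pfam", 7L, 9L, " family protein"),
    list("hypothetical_equivalog", 7L, 13L, "")
  )
  for (r in rows) {
    cand <- filter_and_rank_hmm(mk_hmm(isology = r[[1]],
                                       name = "sensor histidine kinase"))
    expect_equal(cand$within_type_rank, r[[2]])
    expect_equal(cand$final_rank, r[[3]])
    expect_equal(cand$common_name, paste0("sensor histidine kinase",
                                          r[[4]]))
  }
  # below-cutoff hits are never considered
  expect_null(filter_and_rank_hmm(mk_hmm(score = 99.9, cutoff = 100)))
  # best = minimum rank; pfam outranks hypothetical_equivalog on a tie
  pick <- filter_and_rank_hmm(rbind(
    mk_hmm(accession = "H1", isology = "hypothetical_equivalog"),
    mk_hmm(accession = "P1", isology = "pfam")))
  expect_equal(pick$provenance, "P1")
  expect_error(filter_and_rank_hmm(mk_hmm(isology = "mystery")),
               "isology")
})

test_that("LipoP and TMHMM candidates carry the membrane annotation", {
  lp <- annotate_lipop(mk_lipop())
  expect_equal(lp$common_name, "putative lipoprotein")
  expect_equal(lp$go_terms, "GO:0016020")
  expect_equal(lp$tigr_roles, 88L)
  expect_equal(lp$final_rank, 12L)
  expect_null(annotate_lipop(mk_lipop(best_class = "CYT")))
  tm <- annotate_tmhmm(mk_tmhmm(helices = 5L), th)
  expect_equal(tm$common_name, "putative integral membrane protein")
  expect_equal(tm$final_rank, 11L)
  expect_equal(tm$go_terms, "GO:0016020")
  expect_equal(tm$tigr_roles, 88L)
  expect_null(annotate_tmhmm(mk_tmhmm(helices = 4L), th))
})

test_that("the final hierarchy picks the smallest rank across evidence", {
  # HMM equivalog beats a trusted full/full BER match
  b <- evidence_bundle("g1", ber = mk_ber(), hmm = mk_hmm())
  a <- pfunc_final(b, th)
  expect_equal(a$evidence_type, "HMM")
  expect_equal(a$final_rank, 1L)
  # empty bundle: hypothetical protein with GO roots
  e <- pfunc_final(evidence_bundle("g1"), th)
  expect_equal(e$common_name, "hypothetical protein")
  expect_setequal(e$go_terms, c("GO:0008150", "GO:0003674", "GO:0005575"))
  expect_true(is.na(e$final_rank))
  # TMHMM (11) beats LipoP (12)
  m <- pfunc_final(evidence_bundle("g1", lipop = mk_lipop(),
                                   tmhmm = mk_tmhmm(helices = 6L)), th)
  expect_equal(m$common_name, "putative integral membrane protein")
  # every output carries at least one GO term
  expect_gte(length(m$go_terms), 1)
})

test_that("all 17 final ranks are reachable and ordered as printed", {
  mk_bundle_for_rank <- list(
    `1` = function() evidence_bundle("g1", hmm = mk_hmm()),
    `2` = function() evidence_bundle("g1", ber = mk_ber()),
    `3` = function() evidence_bundle("g1", hmm = mk_hmm(
      isology = "equivalog_domain")),
    `4` = function() evidence_bundle("g1", ber = mk_ber(qcov = 60)),
    `5` = function() evidence_bundle("g1", hmm = mk_hmm(
      isology = "subfamily")),
    `6` = function() evidence_bundle("g1", hmm = mk_hmm(
      isology = "superfamily")),
    `7` = function() evidence_bundle("g1", hmm = mk_hmm(
      isology = "subfamily_domain")),
    `8` = function() evidence_bundle("g1", hmm = mk_hmm(
      isology = "domain")),
    `9` = function() evidence_bundle("g1", hmm = mk_hmm(isology = "pfam")),
    `10` = function() evidence_bundle("g1", ber = mk_ber(scov = 60)),
    `11` = function() evidence_bundle("g1", tmhmm = mk_tmhmm(helices = 7L)),
    `12` = function() evidence_bundle("g1", lipop = mk_lipop()),
    `13` = function() evidence_bundle("g1", hmm = mk_hmm(
      isology = "hypothetical_equivalog")),
    `14` = function() evidence_bundle("g1", ber = mk_ber(trusted = FALSE)),
    `15` = function() evidence_bundle("g1", ber = mk_ber(trusted = FALSE,
                                                        qcov = 60)),
    `16` = function() evidence_bundle("g1", ber = mk_ber(trusted = FALSE,
                                                        scov = 60)),
    `17` = function() evidence_bundle("g1", ber = mk_ber(
      trusted = FALSE, name = "putative kinase"))
  )
  for (r in 1:17) {
    ann <- pfunc_final(mk_bundle_for_rank[[as.character(r)]](), th)
    expect_equal(ann$final_rank, r, info = paste("rank", r))
  }
})

test_that("evidence order never changes the outcome", {
  set.seed(77)
  for (rep in 1:200) {
    rb <- random_bundle()
    b1 <- evidence_bundle("g1", rb$ber, rb$hmm, rb$lipop, rb$tmhmm)
    shuffle <- function(df) if (is.null(df) || nrow(df) < 2) df
                            else df[sample.int(nrow(df)), , drop = FALSE]
    b2 <- evidence_bundle("g1", shuffle(rb$ber), shuffle(rb$hmm),
                          rb$lipop, rb$tmhmm)
    expect_identical(ann_key(pfunc_final(b1, th)),
                     ann_key(pfunc_final(b2, th)))
  }
})

test_that("adding a worse-ranked candidate never changes the winner", {
  set.seed(78)
  for (rep in 1:200) {
    rb <- random_bundle()
    b1 <- evidence_bundle("g1", rb$ber, rb$hmm, rb$lipop, rb$tmhmm)
    a1 <- pfunc_final(b1, th)
    if (!is.na(a1$final_rank) && a1$final_rank < 17L) {
      worse <- mk_ber("g1", subject_id = "Szz", trusted = FALSE,
                      name = "putative extra protein", p = 1)
      b2 <- evidence_bundle("g1", rbind(rb$ber, worse), rb$hmm,
                            rb$lipop, rb$tmhmm)
      expect_identical(ann_key(pfunc_final(b2, th)), ann_key(a1))
    }
  }
})

test_that("no non-trusted ambiguous name ever appears in output", {
  set.seed(79)
  for (rep in 1:100) {
    rb <- random_bundle()
    b <- evidence_bundle("g1", rb$ber, rb$hmm, rb$lipop, rb$tmhmm)
    a <- pfunc_final(b, th)
    if (a$evidence_type == "BER" && !is.null(rb$ber)) {
      src <- rb$ber[rb$ber$subject_id == a$provenance, ]
      if (nrow(src) && !src$trusted[1] &&
          grepl("\\bputative\\b", src$subject_name[1])) {
        expect_equal(a$common_name, "conserved hypothetical protein")
      }
    }
    expect_gte(length(a$go_terms), 1)
  }
})
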