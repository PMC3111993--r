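## pFunc: hierarchical functional annotation. Each evidence type is first
## reduced to its best candidate (BER hierarchy, HMM isology hierarchy,
## LipoP, TMHMM), then a final cross-evidence hierarchy of 17 ranks picks
## the annotation; polypeptides with no surviving candidate fall back to
## "hypothetical protein" with the GO root terms.

## final-hierarchy ranks, by evidence type and criterion
FINAL_RANKS <- list(
  hmm = c(equivalog = 1L, equivalog_domain = 3L, subfamily = 5L,
          superfamily = 6L, subfamily_domain = 7L, domain = 8L,
          pfam = 9L, hypothetical_equivalog = 13L),
  ber_trusted = c(FullFull = 2L, PartialFull = 4L, FullPartial = 10L),
  ber_untrusted = c(FullFull = 14L, PartialFull = 15L, FullPartial = 16L),
  ber_ambiguous = 17L,
  tmhmm = 11L,
  lipop = 12L
)

## evidence-type precedence for (never expected) final-rank ties, in order
## of first appearance in the final hierarchy
EVIDENCE_TYPE_ORDER <- c("HMM", "BER", "TMHMM", "LipoP")

#' Coverage class of an alignment side
#'
#' `"Full"` when coverage is at or above the cutoff (default 80%), else
#' `"Partial"`.
#'
#' @param coverage_pct Coverage percent.
#' @param thresholds [pipeline_thresholds()].
#' @return `"Full"` or `"Partial"` (vectorized).
#' @export
coverage_class <- function(coverage_pct,
                           thresholds = pipeline_thresholds()) {
  ifelse(coverage_pct >= thresholds$full_coverage_cutoff_pct,
         "Full", "Partial")
}

#' Identity filter for BER matches
#'
#' Matches below the minimum identity (default 40%) are removed from
#' consideration for annotation. Idempotent.
#'
#' @param ber BER evidence table.
#' @param thresholds [pipeline_thresholds()].
#' @return The retained rows.
#' @export
filter_ber <- function(ber, thresholds = pipeline_thresholds()) {
  ber[ber$percent_identity >= thresholds$ber_min_identity_pct, ,
      drop = FALSE]
}

#' Sanitize ambiguous common names on non-trusted BER matches
#'
#' A non-trusted match whose transferred common name contains an ambiguous
#' term (word boundary, case insensitive) is replaced with
#' `"conserved hypothetical protein"`, the GO root terms and the
#' conserved-hypothetical TIGR role, and marked `ambiguous` so it ranks at
#' the bottom of both hierarchies. Trusted matches are never modified.
#'
#' @param ber BER evidence table.
#' @param ambiguous_terms Character vector of terms
#'   ([default_ambiguous_terms()]).
#' @param roles TIGR role table ([default_tigr_roles()]).
#' @return The table with an added logical `ambiguous` column and sanitized
#'   fields.
#' @export
sanitize_ambiguous <- function(ber,
                               ambiguous_terms = default_ambiguous_terms(),
                               roles = default_tigr_roles()) {
  if (!nrow(ber)) { ber$ambiguous <- logical(0); return(ber) }
  pat <- paste0("\\b(", paste(ambiguous_terms, collapse = "|"), ")\\b")
  hit <- !ber$trusted & grepl(pat, ber$subject_name, ignore.case = TRUE)
  ber$ambiguous <- hit
  ber$subject_name[hit] <- "conserved hypothetical protein"
  ber$subject_symbol[hit] <- ""
  ber$subject_ecs[hit] <- ""
  ber$subject_go[hit] <- join_field(paste0(GO_ROOTS, "|ND"))
  ber$subject_tigr_roles[hit] <- as.character(roles$conserved_hypothetical)
  ber
}

candidate_annotation <- function(evidence_type, within_rank, final_rank,
                                 name, symbol = "", ecs = character(0),
                                 go = character(0), tigr_roles = integer(0),
                                 provenance = "", tie_break = Inf,
                                 go_copied = NA) {
  structure(list(evidence_type = evidence_type,
                 within_type_rank = as.integer(within_rank),
                 final_rank = as.integer(final_rank),
                 common_name = name, gene_symbol = symbol,
                 ec_numbers = ecs, go_terms = go,
                 tigr_roles = as.integer(tigr_roles),
                 provenance = provenance, tie_break = tie_break,
                 go_copied = go_copied),
            class = "candidate_annotation")
}

go_ids_of <- function(go_field) {
  df <- split_go_field(go_field)
  df$go_id
}

#' Rank one BER match on the BER hierarchy
#'
#' Maps (trusted, query coverage class, match coverage class) to the BER
#' hierarchy's within-type rank, composes the name modifier, and copies GO
#' terms and TIGR roles from the match where the hierarchy says so (GO root
#' terms and the unknown-function role otherwise). Matches that are Partial
#' on both sides have no hierarchy row and yield `NULL` unless
#' ambiguous-sanitized.
#'
#' @param match One sanitized BER evidence row (see [sanitize_ambiguous()]).
#' @param thresholds [pipeline_thresholds()].
#' @param roles TIGR role table.
#' @return A `candidate_annotation`, or `NULL`.
#' @export
rank_ber <- function(match, thresholds = pipeline_thresholds(),
                     roles = default_tigr_roles()) {
  stopifnot(NROW(match) == 1)
  qc <- coverage_class(match$query_coverage_pct, thresholds)
  mc <- coverage_class(match$subject_coverage_pct, thresholds)
  amb <- isTRUE(match$ambiguous)
  if (amb) {
    return(candidate_annotation(
      "BER", within_rank = 5L, final_rank = FINAL_RANKS$ber_ambiguous,
      name = "conserved hypothetical protein",
      go = GO_ROOTS, tigr_roles = roles$conserved_hypothetical,
      provenance = match$subject_id, tie_break = match$p_value,
      go_copied = FALSE))
  }
  key <- paste0(qc, mc)
  if (key == "PartialPartial") return(NULL)
  spec <- if (match$trusted) {
    switch(key,
      FullFull = list(rank = 1L, prefix = "", suffix = "", copy = TRUE),
      FullPartial = list(rank = 2L, prefix = "", suffix = " domain protein",
                         copy = FALSE),
      PartialFull = list(rank = 2L, prefix = "", suffix = " domain protein",
                         copy = TRUE))
  } else {
    switch(key,
      FullFull = list(rank = 3L, prefix = "possible ", suffix = "",
                      copy = TRUE),
      PartialFull = list(rank = 4L, prefix = "possible ",
                         suffix = " domain protein", copy = FALSE),
      FullPartial = list(rank = 4L, prefix = "possible ",
                         suffix = " domain protein", copy = FALSE))
  }
  final <- if (match$trusted) FINAL_RANKS$ber_trusted[[key]]
           else FINAL_RANKS$ber_untrusted[[key]]
  name <- paste0(spec$prefix, match$subject_name, spec$suffix)
  if (spec$copy) {
    go <- go_ids_of(match$subject_go)
    if (!length(go)) go <- GO_ROOTS
    tr <- as.integer(split_field(match$subject_tigr_roles))
  } else {
    go <- GO_ROOTS
    tr <- roles$unknown_function
  }
  candidate_annotation(
    "BER", within_rank = spec$rank, final_rank = final, name = name,
    symbol = if (nzchar(match$subject_symbol)) match$subject_symbol else "",
    ecs = split_field(match$subject_ecs), go = go, tigr_roles = tr,
    provenance = match$subject_id, tie_break = match$p_value,
    go_copied = spec$copy)
}

#' Best BER candidate of a gene
#'
#' Filters by identity, sanitizes ambiguous names, ranks every remaining
#' match on the BER hierarchy and returns the best: minimum within-type
#' rank, ties by smallest p-value, then lexicographic subject id.
#'
#' @param ber BER evidence rows of one gene.
#' @param thresholds [pipeline_thresholds()].
#' @param ambiguous_terms,roles Configuration tables.
#' @return A `candidate_annotation`, or `NULL`.
#' @export
best_ber <- function(ber, thresholds = pipeline_thresholds(),
                     ambiguous_terms = default_ambiguous_terms(),
                     roles = default_tigr_roles()) {
  if (is.null(ber) || !nrow(ber)) return(NULL)
  ber <- filter_ber(ber, thresholds)
  if (!nrow(ber)) return(NULL)
  if (is.null(ber$ambiguous)) {
    ber <- sanitize_ambiguous(ber, ambiguous_terms, roles)
  }
  cands <- lapply(seq_len(nrow(ber)), function(i)
    rank_ber(ber[i, , drop = FALSE], thresholds, roles))
  cands <- Filter(Negate(is.null), cands)
  if (!length(cands)) return(NULL)
  key <- vapply(cands, function(cc)
    sprintf("%04d|%.17e|%s", cc$within_type_rank, cc$tie_break,
            cc$provenance), character(1))
  ord <- order(vapply(cands, `[[`, integer(1), "within_type_rank"),
               vapply(cands, `[[`, numeric(1), "tie_break"),
               vapply(cands, `[[`, character(1), "provenance"))
  cands[[ord[1]]]
}

HMM_WITHIN_RANK <- c(equivalog = 1L, equivalog_domain = 2L, subfamily = 3L,
                     superfamily = 4L, subfamily_domain = 5L, domain = 6L,
                     pfam = 7L, hypothetical_equivalog = 7L)
HMM_SUFFIX <- c(equivalog = "", equivalog_domain = "",
                subfamily = " family protein", superfamily = " family protein",
                subfamily_domain = " domain protein",
                domain = " domain protein", pfam = " family protein",
                hypothetical_equivalog = "")

#' Best HMM candidate of a gene
#'
#' Hits below their trusted cutoff are dropped; isology maps to the HMM
#' hierarchy's rank and name suffix. Best = minimum rank, ties by largest
#' margin above cutoff; the within-type tie between pfam and
#' hypothetical-equivalog (both rank 7) is broken toward pfam, matching the
#' final hierarchy's ordering.
#'
#' @param hmm Joined HMM hit rows of one gene (see [read_hmm_hits()]).
#' @return A `candidate_annotation`, or `NULL`.
#' @export
filter_and_rank_hmm <- function(hmm) {
  if (is.null(hmm) || !nrow(hmm)) return(NULL)
  bad <- !hmm$isology %in% names(HMM_WITHIN_RANK)
  if (any(bad)) stop("unknown isology value(s): ",
                     paste(unique(hmm$isology[bad]), collapse = ", "),
                     call. = FALSE)
  hmm <- hmm[hmm$passes_trusted, , drop = FALSE]
  if (!nrow(hmm)) return(NULL)
  rank <- HMM_WITHIN_RANK[hmm$isology]
  margin <- hmm$total_score - hmm$trusted_cutoff
  pfam_first <- ifelse(hmm$isology == "hypothetical_equivalog", 1L, 0L)
  ord <- order(rank, pfam_first, -margin, hmm$accession)
  h <- hmm[ord[1], , drop = FALSE]
  iso <- h$isology
  go <- go_ids_of(h$hmm_go)
  if (!length(go)) go <- GO_ROOTS
  candidate_annotation(
    "HMM", within_rank = HMM_WITHIN_RANK[[iso]],
    final_rank = FINAL_RANKS$hmm[[iso]],
    name = paste0(h$hmm_name, HMM_SUFFIX[[iso]]),
    symbol = if (nzchar(h$hmm_symbol)) h$hmm_symbol else "",
    ecs = split_field(h$hmm_ecs), go = go,
    tigr_roles = as.integer(split_field(h$hmm_tigr_roles)),
    provenance = h$accession,
    tie_break = -(h$total_score - h$trusted_cutoff),
    go_copied = TRUE)
}

#' LipoP candidate
#'
#' A predicted lipoprotein signal peptide (best class SpII) yields the
#' candidate "putative lipoprotein" with GO:0016020 (component: membrane)
#' and the TIGR role "cell envelope: other" (88).
#'
#' @param lipop One LipoP prediction row ([parse_lipop()]), or `NULL`.
#' @param roles TIGR role table.
#' @return A `candidate_annotation`, or `NULL`.
#' @export
annotate_lipop <- function(lipop, roles = default_tigr_roles()) {
  if (is.null(lipop) || !NROW(lipop) || !isTRUE(lipop$predicted_lipoprotein))
    return(NULL)
  candidate_annotation(
    "LipoP", within_rank = 1L, final_rank = FINAL_RANKS$lipop,
    name = "putative lipoprotein", go = "GO:0016020",
    tigr_roles = roles$cell_envelope_other,
    provenance = "LipoP:SpII",
    tie_break = if (is.null(lipop$score) || is.na(lipop$score)) 0
                else -lipop$score,
    go_copied = FALSE)
}

#' TMHMM candidate
#'
#' A protein with at least `thresholds$tmhmm_min_spans` (default 5)
#' predicted membrane-spanning regions yields the candidate "putative
#' integral membrane protein" with GO:0016020 and TIGR role 88.
#'
#' @param tmhmm One TMHMM prediction row ([parse_tmhmm()]), or `NULL`.
#' @param thresholds [pipeline_thresholds()].
#' @param roles TIGR role table.
#' @return A `candidate_annotation`, or `NULL`.
#' @export
annotate_tmhmm <- function(tmhmm, thresholds = pipeline_thresholds(),
                           roles = default_tigr_roles()) {
  if (is.null(tmhmm) || !NROW(tmhmm) ||
      tmhmm$predicted_helices < thresholds$tmhmm_min_spans) return(NULL)
  candidate_annotation(
    "TMHMM", within_rank = 1L, final_rank = FINAL_RANKS$tmhmm,
    name = "putative integral membrane protein", go = "GO:0016020",
    tigr_roles = roles$cell_envelope_other,
    provenance = sprintf("TMHMM:%d_helices", tmhmm$predicted_helices),
    tie_break = -tmhmm$predicted_helices, go_copied = FALSE)
}

#' Final annotation of one polypeptide
#'
#' Collects the best candidate of each evidence type and applies the final
#' 17-rank hierarchy: the candidate with the smallest final rank wins (ties
#' by evidence-type precedence, then tie-break key). With no candidate at
#' all, the gene is called "hypothetical protein" with the GO root terms
#' and the hypothetical-protein TIGR role (final rank `NA`, reported as
#' `HYPOTHETICAL`).
#'
#' @param bundle An `evidence_bundle`.
#' @param thresholds [pipeline_thresholds()].
#' @param ambiguous_terms,roles Configuration tables.
#' @return A `functional_annotation`: list with `gene_id`, `common_name`,
#'   `gene_symbol`, `ec_numbers`, `go_terms`, `tigr_roles`,
#'   `evidence_type`, `final_rank` (`NA` = hypothetical), `provenance`.
#' @export
pfunc_final <- function(bundle, thresholds = pipeline_thresholds(),
                        ambiguous_terms = default_ambiguous_terms(),
                        roles = default_tigr_roles()) {
  cands <- list(
    best_ber(bundle$ber, thresholds, ambiguous_terms, roles),
    filter_and_rank_hmm(bundle$hmm),
    annotate_tmhmm(bundle$tmhmm, thresholds, roles),
    annotate_lipop(bundle$lipop, roles)
  )
  cands <- Filter(Negate(is.null), cands)
  if (!length(cands)) {
    return(structure(list(
      gene_id = bundle$gene_id, common_name = "hypothetical protein",
      gene_symbol = "", ec_numbers = character(0), go_terms = GO_ROOTS,
      tigr_roles = roles$hypothetical, evidence_type = "none",
      final_rank = NA_integer_, provenance = ""),
      class = "functional_annotation"))
  }
  ord <- order(vapply(cands, `[[`, integer(1), "final_rank"),
               match(vapply(cands, `[[`, character(1), "evidence_type"),
                     EVIDENCE_TYPE_ORDER),
               vapply(cands, `[[`, numeric(1), "tie_break"))
  w <- cands[[ord[1]]]
  go <- w$go_terms
  if (!length(go)) go <- GO_ROOTS
  structure(list(
    gene_id = bundle$gene_id, common_name = w$common_name,
    gene_symbol = w$gene_symbol, ec_numbers = w$ec_numbers, go_terms = go,
    tigr_roles = w$tigr_roles, evidence_type = w$evidence_type,
    final_rank = w$final_rank, provenance = w$provenance),
    class = "functional_annotation")
}

#' Annotate every CDS gene of an assembly
#'
#' Builds an evidence bundle per gene and runs the final hierarchy,
#' producing exactly one annotation per polypeptide.
#'
#' @param gene_ids Character vector of CDS gene ids.
#' @param ber,hmm,lipop,tmhmm Evidence tables (any may be `NULL`).
#' @param thresholds [pipeline_thresholds()].
#' @param ambiguous_terms,roles Configuration tables.
#' @return Annotation data.frame: one row per gene with `gene_id`,
#'   `common_name`, `gene_symbol`, `ec_numbers`, `go_terms`, `tigr_roles`
#'   (comma-joined), `evidence_type`, `final_rank` (`"HYPOTHETICAL"` for the
#'   fallback), `provenance`.
#' @export
pfunc_annotate <- function(gene_ids, ber = NULL, hmm = NULL, lipop = NULL,
                           tmhmm = NULL,
                           thresholds = pipeline_thresholds(),
                           ambiguous_terms = default_ambiguous_terms(),
                           roles = default_tigr_roles()) {
  rows <- lapply(gene_ids, function(g) {
    ann <- pfunc_final(evidence_bundle(g, ber, hmm, lipop, tmhmm),
                       thresholds, ambiguous_terms, roles)
    data.frame(
      gene_id = ann$gene_id, common_name = ann$common_name,
      gene_symbol = ann$gene_symbol,
      ec_numbers = join_field(ann$ec_numbers),
      go_terms = join_field(ann$go_terms),
      tigr_roles = join_field(ann$tigr_roles),
      evidence_type = ann$evidence_type,
      final_rank = if (is.na(ann$final_rank)) "HYPOTHETICAL"
                   else as.character(ann$final_rank),
      provenance = ann$provenance, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame(
    gene_id = character(0), common_name = character(0),
    gene_symbol = character(0), ec_numbers = character(0),
    go_terms = character(0), tigr_roles = character(0),
    evidence_type = character(0), final_rank = character(0),
    provenance = character(0), stringsAsFactors = FALSE)
  out
}
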