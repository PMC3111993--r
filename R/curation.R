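## Evidence-directed structural curation: start-site selection by voting
## (BER subject-start concordance + ribosome-binding-site motif support),
## removal of evidence-free genes that overlap evidenced features by more
## than 60 bp, and detection of interevidence regions for re-search.

#' Enumerate candidate start codons for a gene
#'
#' All in-frame ATG/GTG/TTG codons between the nearest upstream in-frame
#' stop (bounded by the extension window) and the last position that leaves
#' a product of at least `min_product_aa` residues. The annotated start is
#' always included. Candidates are expressed in extended-query coordinates
#' (0-based nt in the strand-oriented extended sequence) with
#' `offset_nt = position - annotated start` (negative = upstream).
#'
#' @param contigs Named `DNAStringSet`.
#' @param gene Gene-model row (complete CDS).
#' @param thresholds [pipeline_thresholds()].
#' @param min_product_aa Minimum product length for a candidate (default 30).
#' @return data.frame `pos_ext`, `offset_nt`, `codon`, `is_annotated`,
#'   ordered 5' to 3'.
#' @export
enumerate_start_candidates <- function(contigs, gene,
                                       thresholds = pipeline_thresholds(),
                                       min_product_aa = 30L) {
  if (gene$feature_type != "CDS" || isTRUE(gene$partial5))
    stop("start candidates require a complete CDS", call. = FALSE)
  ext <- extend_query(contigs, gene, thresholds)
  nt <- ext$nt_sequence
  u <- ext$upstream_pad
  glen <- gene$end - gene$start
  ## in-frame positions share u's residue class mod 3
  stop_pos <- u + glen - 3L          # the gene's stop codon (0-based)
  lo <- u %% 3L                      # in-frame scan start within the window
  upstream <- if (u >= 3L) seq(u - 3L, lo, by = -3L) else integer(0)
  for (p in upstream) {
    if (substr(nt, p + 1L, p + 3L) %in% STOP_CODONS) { lo <- p + 3L; break }
  }
  hi <- stop_pos - 3L * min_product_aa   # product of >= min_product_aa aa
  cand <- integer(0)
  if (hi >= lo) {
    for (p in seq(lo, hi, by = 3L)) {
      codon <- substr(nt, p + 1L, p + 3L)
      ## an in-frame stop invalidates every candidate upstream of it
      if (codon %in% STOP_CODONS) { cand <- integer(0); next }
      if (codon %in% START_CODONS) cand <- c(cand, p)
    }
  }
  if (!u %in% cand) cand <- sort(unique(c(cand, u)))
  data.frame(pos_ext = cand, offset_nt = cand - u,
             codon = vapply(cand, function(p) substr(nt, p + 1L, p + 3L),
                            character(1)),
             is_annotated = cand == u, stringsAsFactors = FALSE)
}

#' Ribosome-binding-site vote for a start candidate
#'
#' Returns 1 when a window 4-14 nt upstream of the candidate contains a
#' match of at least `min_match` of the 6 consensus positions (default
#' AGGAGG, 4 of 6), the classic Shine-Dalgarno signal.
#'
#' @param ext_nt Extended-query DNA string.
#' @param pos_ext Candidate start position (0-based, extended-query).
#' @param consensus Consensus motif (default `"AGGAGG"`).
#' @param spacer_range Allowed gap, in nt, between motif end and candidate
#'   start (default `c(4, 14)`).
#' @param min_match Minimum matching positions (default 4).
#' @return Integer 0 or 1.
#' @export
rbs_vote <- function(ext_nt, pos_ext, consensus = "AGGAGG",
                     spacer_range = c(4L, 14L), min_match = 4L) {
  k <- nchar(consensus)
  cons <- strsplit(toupper(consensus), "")[[1]]
  for (spacer in seq(spacer_range[1], spacer_range[2])) {
    start <- pos_ext - spacer - k      # 0-based motif start
    if (start < 0) next
    win <- strsplit(substr(ext_nt, start + 1L, start + k), "")[[1]]
    if (length(win) < k) next
    if (sum(win == cons) >= min_match) return(1L)
  }
  0L
}

#' Choose a start site by evidence voting
#'
#' Each of the top BER alignments (best `top_n` by p-value) whose subject
#' residue 1 aligns at a candidate position contributes one vote to that
#' candidate; a ribosome-binding-site match adds one vote. The candidate
#' with the most votes wins; ties are broken by the smallest supporting
#' p-value, and any remaining tie keeps the annotated start.
#'
#' @param candidates data.frame from [enumerate_start_candidates()].
#' @param ber BER evidence rows for this gene (needs
#'   `subject_start_query_nt`, `p_value`).
#' @param rbs_votes Integer vector of 0/1 RBS votes, one per candidate.
#' @param top_n Number of best alignments considered (default 10).
#' @param tolerance_codons Codon tolerance for subject-start concordance
#'   (default 0 = exact).
#' @return List with `chosen` (one-row data.frame) and `tally` (candidates
#'   plus `ber_votes`, `rbs_vote`, `total_votes`, `best_p`).
#' @export
vote_start_sites <- function(candidates, ber, rbs_votes = NULL,
                             top_n = 10L, tolerance_codons = 0L) {
  stopifnot(nrow(candidates) >= 1)
  if (is.null(rbs_votes)) rbs_votes <- rep(0L, nrow(candidates))
  stopifnot(length(rbs_votes) == nrow(candidates))
  if (!is.null(ber) && nrow(ber)) {
    ber <- ber[order(ber$p_value, ber$subject_id), , drop = FALSE]
    ber <- utils::head(ber, top_n)
  }
  nb <- integer(nrow(candidates))
  bp <- rep(Inf, nrow(candidates))
  if (!is.null(ber)) {
    for (i in seq_len(NROW(ber))) {
      s <- ber$subject_start_query_nt[i]
      if (is.na(s)) next
      d <- abs(candidates$pos_ext - s)
      hit <- which(d <= 3L * tolerance_codons)
      if (length(hit)) {
        hit <- hit[which.min(d[hit])]
        nb[hit] <- nb[hit] + 1L
        bp[hit] <- min(bp[hit], ber$p_value[i])
      }
    }
  }
  tally <- candidates
  tally$ber_votes <- nb
  tally$rbs_vote <- as.integer(rbs_votes)
  tally$total_votes <- nb + tally$rbs_vote
  tally$best_p <- bp
  top <- which(tally$total_votes == max(tally$total_votes))
  if (length(top) > 1) {
    best <- top[tally$best_p[top] == min(tally$best_p[top])]
    if (length(best) > 1) {
      ann <- best[candidates$is_annotated[best]]
      best <- if (length(ann)) ann[1] else {
        best[order(abs(candidates$offset_nt[best]),
                   candidates$offset_nt[best])][1]
      }
    }
    top <- best[1]
  }
  list(chosen = candidates[top, , drop = FALSE], tally = tally)
}

#' Curate start sites of all complete CDS genes
#'
#' Runs candidate enumeration, RBS scoring and evidence voting per gene and
#' moves starts accordingly (strand aware). Genes with no BER evidence keep
#' their annotated start (the RBS signal alone never moves a start away
#' from a zero-vote tie with the annotated candidate unless it is the sole
#' vote).
#'
#' @param contigs Named `DNAStringSet`.
#' @param genes Gene-model table.
#' @param ber BER evidence table.
#' @param thresholds [pipeline_thresholds()].
#' @param ... Passed to [enumerate_start_candidates()] and
#'   [vote_start_sites()].
#' @return List with `genes` (updated table) and `report` (one row per
#'   evaluated gene: `gene_id`, `chosen_offset_nt`, `moved`, `votes`).
#' @export
curate_starts <- function(contigs, genes, ber,
                          thresholds = pipeline_thresholds(), ...) {
  report <- list()
  out <- genes
  idx <- which(genes$feature_type == "CDS" & !genes$partial5 &
                 !genes$partial3)
  for (i in idx) {
    gene <- genes[i, , drop = FALSE]
    cands <- enumerate_start_candidates(contigs, gene, thresholds)
    ext <- extend_query(contigs, gene, thresholds)
    rbs <- vapply(cands$pos_ext, function(p) rbs_vote(ext$nt_sequence, p),
                  integer(1))
    gb <- ber[ber$gene_id == gene$id, , drop = FALSE]
    v <- vote_start_sites(cands, gb, rbs)
    off <- v$chosen$offset_nt
    if (off != 0L) {
      if (gene$strand == "+") out$start[i] <- gene$start + off
      else out$end[i] <- gene$end - off
    }
    report[[length(report) + 1L]] <- data.frame(
      gene_id = gene$id, chosen_offset_nt = off, moved = off != 0L,
      votes = v$tally$total_votes[v$tally$pos_ext == v$chosen$pos_ext][1],
      stringsAsFactors = FALSE)
  }
  list(genes = out,
       report = if (length(report)) do.call(rbind, report) else
         data.frame(gene_id = character(0), chosen_offset_nt = integer(0),
                    moved = logical(0), votes = integer(0)))
}

#' Does a gene carry annotation-grade evidence?
#'
#' True when the gene has at least one BER match at or above the minimum
#' identity, or at least one HMM hit passing its trusted cutoff.
#'
#' @param bundle An `evidence_bundle` (see [evidence_bundle()]).
#' @param thresholds [pipeline_thresholds()].
#' @return Logical scalar.
#' @export
has_evidence <- function(bundle, thresholds = pipeline_thresholds()) {
  if (NROW(bundle$ber) &&
      any(bundle$ber$percent_identity >= thresholds$ber_min_identity_pct))
    return(TRUE)
  if (NROW(bundle$hmm) && any(bundle$hmm$passes_trusted)) return(TRUE)
  FALSE
}

#' Remove or flag overlapping false-positive gene predictions
#'
#' Every pair of features overlapping by more than
#' `thresholds$overlap_threshold_bp` (default 60 bp) is evaluated against
#' the original evidence state: an evidence-free gene overlapping an
#' evidenced gene is removed; an evidence-free gene overlapping a predicted
#' RNA is removed; every other such pair is flagged for manual review.
#' Overlaps of at most the threshold trigger no action. Decisions do not
#' cascade within a pass and are independent of input order.
#'
#' @param features Gene-model table (CDS + RNAs).
#' @param evidence Named logical vector: `has_evidence` per CDS id (RNAs are
#'   not evaluated), or a list of `evidence_bundle`s.
#' @param thresholds [pipeline_thresholds()].
#' @return List with `kept`, `removed` (gene-model tables) and `decisions`
#'   (data.frame `feature_a`, `feature_b`, `overlap_bp`, `action`,
#'   `rationale`).
#' @export
curate_overlaps <- function(features, evidence,
                            thresholds = pipeline_thresholds()) {
  if (is.list(evidence) && !is.logical(evidence)) {
    evidence <- vapply(evidence, has_evidence, logical(1),
                       thresholds = thresholds)
  }
  ord <- order(features$contig_id, features$start, features$end,
               features$id)
  f <- features[ord, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = f$contig_id,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end))
  ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                    drop.redundant = TRUE)
  a <- S4Vectors::queryHits(ov); b <- S4Vectors::subjectHits(ov)
  olap <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr)[a],
                                             IRanges::ranges(gr)[b]))
  keep <- olap > thresholds$overlap_threshold_bp
  a <- a[keep]; b <- b[keep]; olap <- olap[keep]
  decide_one <- function(ia, ib, bp) {
    ta <- f$feature_type[ia]; tb <- f$feature_type[ib]
    ea <- isTRUE(unname(evidence[f$id[ia]])[1])
    eb <- isTRUE(unname(evidence[f$id[ib]])[1])
    is_rna_a <- ta != "CDS"; is_rna_b <- tb != "CDS"
    if (ta == "CDS" && !ea && (eb || is_rna_b)) {
      list(action = "remove_a",
           rationale = if (is_rna_b) "evidence-free gene overlaps RNA"
                       else "evidence-free gene overlaps evidenced gene")
    } else if (tb == "CDS" && !eb && (ea || is_rna_a)) {
      list(action = "remove_b",
           rationale = if (is_rna_a) "evidence-free gene overlaps RNA"
                       else "evidence-free gene overlaps evidenced gene")
    } else {
      list(action = "flag", rationale = "overlap > threshold, manual review")
    }
  }
  dec <- lapply(seq_along(a), function(k) decide_one(a[k], b[k], olap[k]))
  decisions <- data.frame(
    feature_a = f$id[a], feature_b = f$id[b], overlap_bp = olap,
    action = vapply(dec, `[[`, character(1), "action"),
    rationale = vapply(dec, `[[`, character(1), "rationale"),
    stringsAsFactors = FALSE)
  decisions <- decisions[order(decisions$feature_a, decisions$feature_b), ,
                         drop = FALSE]
  rownames(decisions) <- NULL
  removed_ids <- unique(c(decisions$feature_a[decisions$action == "remove_a"],
                          decisions$feature_b[decisions$action == "remove_b"]))
  list(kept = features[!features$id %in% removed_ids, , drop = FALSE],
       removed = features[features$id %in% removed_ids, , drop = FALSE],
       decisions = decisions)
}

#' Find interevidence regions of a contig
#'
#' Maximal contiguous spans made of intergenic sequence plus evidence-free
#' genes, bounded by evidenced features and contig ends. These spans are
#' re-searched externally to catch missed genes. RNA features count as
#' evidenced (they are never re-searched).
#'
#' @param contig_id Contig id.
#' @param contig_length Contig length (nt).
#' @param genes Gene-model table (this contig's features are selected).
#' @param evidence Named logical vector of per-CDS evidence.
#' @param min_length Minimum emitted region length in nt (default 90).
#' @return data.frame `contig_id`, `start`, `end` (0-based half-open),
#'   `member_gene_ids` (comma-joined, possibly empty).
#' @export
find_interevidence_regions <- function(contig_id, contig_length, genes,
                                       evidence, min_length = 90L) {
  g <- genes[genes$contig_id == contig_id, , drop = FALSE]
  ev <- g$feature_type != "CDS" |
    vapply(g$id, function(id) isTRUE(unname(evidence[id])[1]), logical(1))
  if (!length(ev)) ev <- logical(0)
  covered <- IRanges::reduce(IRanges::IRanges(start = g$start[ev] + 1L,
                                              end = g$end[ev]))
  gaps <- IRanges::gaps(covered, start = 1L, end = contig_length)
  gaps <- gaps[IRanges::width(gaps) >= min_length]
  if (!length(gaps)) {
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), member_gene_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  members <- vapply(seq_along(gaps), function(k) {
    s <- IRanges::start(gaps)[k] - 1L; e <- IRanges::end(gaps)[k]
    inside <- !ev & g$start >= s & g$end <= e
    join_field(sort(g$id[inside]))
  }, character(1))
  data.frame(contig_id = contig_id, start = IRanges::start(gaps) - 1L,
             end = IRanges::end(gaps), member_gene_ids = members,
             stringsAsFactors = FALSE)
}
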