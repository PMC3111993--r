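## BER: extend a predicted gene's nucleotide region by up to 300 nt on each
## side, then align its translation to each candidate subject protein with a
## frameshift- and stop-tolerant local DP. Disruption events (frameshifts,
## in-frame stops) observed in retained alignments feed a manual-review
## report; extension lets genuine similarity run past the predicted
## boundaries, which downstream start-site voting exploits.

#' Scoring scheme for frameshift-tolerant alignment
#'
#' @param substitution_matrix Amino-acid substitution matrix with dimnames;
#'   default BLOSUM62 (from Biostrings).
#' @param gap_open Score charged when opening a gap (per first gapped
#'   position; negative).
#' @param gap_extend Score per additional gapped position (negative).
#' @param frameshift_penalty Score charged per frame-slip column (negative).
#'   Chosen stiffer than a gap open so slips are only used when strongly
#'   supported.
#' @param stop_codon_score Score of a column that aligns a stop codon
#'   (negative).
#' @return Object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(substitution_matrix = NULL, gap_open = -11,
                           gap_extend = -1, frameshift_penalty = -15,
                           stop_codon_score = -10) {
  if (is.null(substitution_matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    substitution_matrix <- e$BLOSUM62
  }
  pens <- c(gap_open = gap_open, gap_extend = gap_extend,
            frameshift_penalty = frameshift_penalty,
            stop_codon_score = stop_codon_score)
  if (any(!is.finite(pens) & pens != -Inf) || any(pens >= 0)) {
    stop("all alignment penalties must be negative", call. = FALSE)
  }
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 frameshift_penalty = frameshift_penalty,
                 stop_codon_score = stop_codon_score),
            class = "scoring_scheme")
}

#' Extend a gene's region for BER alignment
#'
#' Adds up to `thresholds$extension_nt` (default 300) nucleotides on each
#' side of the gene, clipped at contig bounds; minus-strand genes are
#' returned reverse complemented so the gene reads 5' to 3'.
#'
#' @param contigs Named `DNAStringSet`.
#' @param gene One row of a gene-model table.
#' @param thresholds [pipeline_thresholds()].
#' @return Object of class `extended_query`: list with `gene_id`,
#'   `nt_sequence` (strand oriented), `upstream_pad`, `downstream_pad`,
#'   `original_start_offset` (= `upstream_pad`).
#' @export
extend_query <- function(contigs, gene, thresholds = pipeline_thresholds()) {
  if (!gene$contig_id %in% names(contigs)) {
    stop("gene ", gene$id, " lies on unknown contig ", gene$contig_id,
         call. = FALSE)
  }
  clen <- Biostrings::width(contigs)[match(gene$contig_id, names(contigs))]
  if (gene$start < 0 || gene$end > clen) {
    stop("gene ", gene$id, " outside contig bounds", call. = FALSE)
  }
  ext <- as.integer(thresholds$extension_nt)
  left_pad <- min(ext, gene$start)
  right_pad <- min(ext, clen - gene$end)
  window <- as.character(Biostrings::subseq(
    contigs[[gene$contig_id]],
    start = gene$start - left_pad + 1L, end = gene$end + right_pad))
  if (gene$strand == "+") {
    up <- left_pad; down <- right_pad
  } else {
    window <- reverse_complement(window)
    up <- right_pad; down <- left_pad
  }
  structure(list(gene_id = gene$id, nt_sequence = window,
                 upstream_pad = up, downstream_pad = down,
                 original_start_offset = up),
            class = "extended_query")
}

#' Frameshift-tolerant local alignment of a nucleotide query to a protein
#'
#' Modified Smith-Waterman over a lattice of (query nucleotide, subject
#' residue) states. Besides codon-sized diagonal steps and affine gaps, the
#' DP permits frame-slip transitions consuming 1, 2, 4 or 5 nt per subject
#' residue (each charged `frameshift_penalty` and recorded as a frameshift
#' event) and columns aligning a stop codon (charged `stop_codon_score`,
#' recorded as an in-frame-stop event). Traceback is deterministic.
#'
#' @param query An `extended_query`, or a DNA string.
#' @param subject_aa Subject protein string (non-empty).
#' @param scoring [scoring_scheme()].
#' @return Object of class `frameshift_alignment`: list with `score`,
#'   `columns` (per-column data.frame: `op`, `q_codon_start` 0-based,
#'   `q_nt_end`, `s_pos` 1-based, `aa_q`, `aa_s`, `identical`, `frame`),
#'   `disruptions` (data.frame `kind`, `query_nt_position`,
#'   `frames_involved`), `percent_identity`, `n_columns`,
#'   `query_nt_range` (0-based half-open), `subject_range` (1-based
#'   inclusive), `subject_start_query_nt`.
#' @export
align_frameshift <- function(query, subject_aa,
                             scoring = scoring_scheme()) {
  nt <- if (inherits(query, "extended_query")) query$nt_sequence else query
  nt <- check_dna_alphabet(nt)
  if (!nzchar(subject_aa)) stop("subject protein must be non-empty",
                                call. = FALSE)
  if (nchar(nt) < 3) stop("query must be at least 3 nt", call. = FALSE)
  aa_at <- codon_translations(nt)
  is_stop <- vapply(seq_along(aa_at), function(p)
    substr(nt, p, p + 2L) %in% STOP_CODONS, logical(1))
  if (!length(aa_at)) { aa_at <- character(0); is_stop <- logical(0) }
  res <- .align_frameshift_cpp(
    n = nchar(nt), aa_at = aa_at, is_stop = is_stop,
    subject = subject_aa, submat = scoring$substitution_matrix,
    gap_open = scoring$gap_open, gap_extend = scoring$gap_extend,
    frameshift_penalty = scoring$frameshift_penalty,
    stop_score = scoring$stop_codon_score)
  ops <- as.data.frame(res$ops)
  subj <- strsplit(subject_aa, "")[[1]]
  slip_nt <- c(`1` = 1L, `2` = 2L, `3` = 4L, `4` = 5L)
  if (nrow(ops) == 0) {
    cols <- data.frame(op = integer(0), q_codon_start = integer(0),
                       q_nt_end = integer(0), s_pos = integer(0),
                       aa_q = character(0), aa_s = character(0),
                       identical = logical(0), frame = integer(0),
                       stringsAsFactors = FALSE)
    disr <- data.frame(kind = character(0), query_nt_position = integer(0),
                       frames_involved = character(0),
                       stringsAsFactors = FALSE)
    return(structure(list(score = 0, columns = cols, disruptions = disr,
                          percent_identity = NA_real_, n_columns = 0L,
                          query_nt_range = c(NA_integer_, NA_integer_),
                          subject_range = c(NA_integer_, NA_integer_),
                          subject_start_query_nt = NA_integer_),
                     class = "frameshift_alignment"))
  }
  op <- ops$op
  nt_used <- ifelse(op == 0L, 3L,
             ifelse(op %in% 1:4, slip_nt[as.character(op)],
             ifelse(op == 5L, 3L, 0L)))
  q_codon_start <- ifelse(op %in% c(0L, 3L, 4L, 5L), ops$q_nt_end - 3L,
                   ifelse(op %in% c(1L, 2L), ops$q_nt_end - nt_used,
                          NA_integer_))
  aa_q <- ifelse(op %in% c(0L, 3L, 4L, 5L),
                 aa_at[pmax(q_codon_start, 0L) + 1L], NA_character_)
  aa_q[op %in% c(1L, 2L, 6L)] <- NA_character_
  stop_col <- op %in% c(0L, 3L, 4L) &
    is_stop[pmax(q_codon_start, 0L) + 1L]
  aa_q[op %in% c(0L, 3L, 4L) & stop_col] <- "*"
  aa_s <- ifelse(op %in% c(0:4, 6L), subj[ops$s_pos], NA_character_)
  identical_col <- !is.na(aa_q) & !is.na(aa_s) & aa_q == aa_s &
    op %in% c(0L, 3L, 4L) & !stop_col
  frame <- ifelse(is.na(q_codon_start), NA_integer_, q_codon_start %% 3L)
  cols <- data.frame(op = op, q_codon_start = q_codon_start,
                     q_nt_end = ops$q_nt_end, s_pos = ops$s_pos,
                     aa_q = aa_q, aa_s = aa_s, identical = identical_col,
                     frame = frame, stringsAsFactors = FALSE)
  ## disruption events
  slip_rows <- which(op %in% 1:4)
  stop_rows <- which(stop_col)
  disr <- rbind(
    if (length(slip_rows)) data.frame(
      kind = "frameshift",
      query_nt_position = ops$q_nt_end[slip_rows],
      frames_involved = vapply(slip_rows, function(r) {
        prev <- frame[seq_len(r - 1L)]
        prev <- prev[!is.na(prev)]
        paste(c(if (length(prev)) prev[length(prev)] else NA_integer_,
                frame[r]), collapse = ">")
      }, character(1)), stringsAsFactors = FALSE),
    if (length(stop_rows)) data.frame(
      kind = "in_frame_stop",
      query_nt_position = q_codon_start[stop_rows],
      frames_involved = as.character(frame[stop_rows]),
      stringsAsFactors = FALSE)
  )
  if (is.null(disr)) disr <- data.frame(
    kind = character(0), query_nt_position = integer(0),
    frames_involved = character(0), stringsAsFactors = FALSE)
  disr <- disr[order(disr$query_nt_position), , drop = FALSE]
  rownames(disr) <- NULL
  ## metrics over the alignment itself
  ncol_aln <- nrow(cols)
  pid <- 100 * sum(identical_col) / ncol_aln
  q_start <- ops$q_nt_end[1] - nt_used[1]
  q_end <- ops$q_nt_end[nrow(ops)]
  s_used <- ops$s_pos[op != 5L]
  s_range <- c(min(s_used), max(s_used))
  s1 <- which(ops$s_pos == 1L & op %in% 0:4)
  ssq <- if (length(s1)) {
    r <- s1[1]
    if (is.na(q_codon_start[r])) ops$q_nt_end[r] - nt_used[r]
    else q_codon_start[r]
  } else NA_integer_
  structure(list(score = res$score, columns = cols, disruptions = disr,
                 percent_identity = pid, n_columns = ncol_aln,
                 query_nt_range = c(q_start, q_end),
                 subject_range = s_range,
                 subject_start_query_nt = as.integer(ssq)),
            class = "frameshift_alignment")
}

#' Identity and dual coverages of a BER alignment
#'
#' Query coverage is measured against the unextended gene's protein length:
#' aligned codon columns falling outside the annotated span (in the
#' extension) do not count. Subject coverage is the aligned subject span
#' over the subject length.
#'
#' @param aln A `frameshift_alignment`.
#' @param ext The `extended_query` the alignment was computed on.
#' @param gene The gene-model row.
#' @param subject_aa Subject protein string.
#' @return Named numeric vector `c(identity, query_cov, subject_cov)`,
#'   percent.
#' @export
alignment_metrics <- function(aln, ext, gene, subject_aa) {
  plen <- (gene$end - gene$start) %/% 3L - 1L
  if (plen <= 0) stop("gene too short for a protein product", call. = FALSE)
  cols <- aln$columns
  inside <- cols$op %in% c(0L, 3L, 4L) & !is.na(cols$q_codon_start) &
    cols$q_codon_start >= ext$upstream_pad &
    cols$q_codon_start < ext$upstream_pad + (gene$end - gene$start)
  qcov <- min(100, 100 * length(unique(cols$q_codon_start[inside])) / plen)
  m <- nchar(subject_aa)
  scov <- if (is.na(aln$subject_range[1])) 0 else
    100 * (aln$subject_range[2] - aln$subject_range[1] + 1) / m
  c(identity = aln$percent_identity, query_cov = qcov, subject_cov = scov)
}

#' Run BER against a set of subject proteins
#'
#' For each CDS gene, candidate subjects come from the seeding blast table
#' when given (e-value filtered at `thresholds$blast_evalue`, best first,
#' capped at `thresholds$max_alignments`), otherwise every subject is tried.
#' Each retained alignment becomes one row of the canonical BER evidence
#' table; the ranking p-value is the seed e-value when available, otherwise
#' the order-preserving surrogate `10^(-score/10)`.
#'
#' @param contigs Named `DNAStringSet`.
#' @param genes Gene-model table.
#' @param subjects Named character vector (or `AAStringSet`) of subject
#'   proteins.
#' @param subject_info Optional data.frame (`subject_id`, `name`, `symbol`,
#'   `ecs`, `go`, `tigr_roles`) supplying transferred annotation fields.
#' @param seeds Optional parsed blast tabular table ([parse_blast_tabular()]).
#' @param gaf Optional parsed GAF map ([parse_gaf()]).
#' @param characterized,uniprot_experimental Id sets for trusted
#'   determination.
#' @param thresholds [pipeline_thresholds()].
#' @param scoring [scoring_scheme()].
#' @return Canonical BER evidence data.frame (see [read_ber_evidence()]).
#' @export
ber_search <- function(contigs, genes, subjects, subject_info = NULL,
                       seeds = NULL, gaf = NULL,
                       characterized = character(0),
                       uniprot_experimental = character(0),
                       thresholds = pipeline_thresholds(),
                       scoring = scoring_scheme()) {
  nm <- names(subjects)
  subjects <- stats::setNames(as.character(subjects), nm)
  if (is.null(names(subjects)) || any(!nzchar(names(subjects)))) {
    stop("subjects must be named by subject id", call. = FALSE)
  }
  cds <- genes[genes$feature_type == "CDS", , drop = FALSE]
  rows <- list()
  for (gi in seq_len(nrow(cds))) {
    gene <- cds[gi, , drop = FALSE]
    if (!is.null(seeds)) {
      sd <- seeds[seeds$gene_id == gene$id &
                  seeds$evalue <= thresholds$blast_evalue, , drop = FALSE]
      sd <- sd[order(sd$evalue, sd$subject_id), , drop = FALSE]
      sd <- sd[!duplicated(sd$subject_id), , drop = FALSE]
      sids <- utils::head(sd$subject_id, thresholds$max_alignments)
      seed_eval <- stats::setNames(sd$evalue, sd$subject_id)
    } else {
      sids <- utils::head(sort(names(subjects)), thresholds$max_alignments)
      seed_eval <- numeric(0)
    }
    sids <- sids[sids %in% names(subjects)]
    if (!length(sids)) next
    ext <- extend_query(contigs, gene, thresholds)
    for (sid in sids) {
      aln <- align_frameshift(ext, subjects[[sid]], scoring)
      if (aln$n_columns == 0) next
      met <- alignment_metrics(aln, ext, gene, subjects[[sid]])
      info <- subject_row(subject_info, sid)
      go_df <- if (!is.null(gaf)) gaf[[sid]] else NULL
      trusted <- determine_trusted(sid, go_df, characterized,
                                   uniprot_experimental)
      pval <- if (sid %in% names(seed_eval)) max(seed_eval[[sid]], 1e-300)
              else 10^(-aln$score / 10)
      nfs <- sum(aln$disruptions$kind == "frameshift")
      nst <- sum(aln$disruptions$kind == "in_frame_stop")
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene$id, subject_id = sid,
        subject_name = info$name, subject_symbol = info$symbol,
        subject_ecs = info$ecs, subject_go = info$go,
        subject_tigr_roles = info$tigr_roles,
        percent_identity = met[["identity"]],
        query_coverage_pct = met[["query_cov"]],
        subject_coverage_pct = met[["subject_cov"]],
        p_value = pval, trusted = trusted,
        n_frameshifts = nfs, n_stops = nst,
        subject_start_query_nt = aln$subject_start_query_nt,
        disruptions = paste(sprintf("%s:%d", aln$disruptions$kind,
                                    aln$disruptions$query_nt_position),
                            collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_ber_table())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

subject_row <- function(subject_info, sid) {
  default <- list(name = sid, symbol = "", ecs = "", go = "",
                  tigr_roles = "")
  if (is.null(subject_info)) return(default)
  i <- match(sid, subject_info$subject_id)
  if (is.na(i)) return(default)
  get <- function(col, fb) {
    v <- subject_info[[col]]
    if (is.null(v) || is.na(v[i])) fb else as.character(v[i])
  }
  list(name = get("name", sid), symbol = get("symbol", ""),
       ecs = get("ecs", ""), go = get("go", ""),
       tigr_roles = get("tigr_roles", ""))
}

#' Report genes whose BER alignments contain disruptions
#'
#' Lists, for manual review, every gene with at least one frameshift or
#' in-frame stop event in any retained BER alignment.
#'
#' @param ber Canonical BER evidence table.
#' @return data.frame with `gene_id`, `subject_id`, `kind`,
#'   `query_nt_position` (0-based, extended-query coordinates), one row per
#'   event.
#' @export
disruption_report <- function(ber) {
  hit <- ber[ber$n_frameshifts > 0 | ber$n_stops > 0, , drop = FALSE]
  out <- data.frame(gene_id = character(0), subject_id = character(0),
                    kind = character(0), query_nt_position = integer(0),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(hit))) {
    evs <- split_field(hit$disruptions[i])
    if (!length(evs)) next
    parts <- strsplit(evs, ":", fixed = TRUE)
    out <- rbind(out, data.frame(
      gene_id = hit$gene_id[i], subject_id = hit$subject_id[i],
      kind = vapply(parts, `[`, character(1), 1),
      query_nt_position = as.integer(vapply(parts, `[`, character(1), 2)),
      stringsAsFactors = FALSE))
  }
  out[order(out$gene_id, out$subject_id, out$query_nt_position), ,
      drop = FALSE]
}
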