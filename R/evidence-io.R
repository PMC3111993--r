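## Evidence I/O: parsers for external evidence formats (BLAST tabular,
## GAF 2.x, LipoP short, TMHMM short, HMM hit tables) and the canonical
## evidence TSVs that the pipeline stages exchange, plus trusted-match
## determination for BER subjects.

## Canonical BER evidence table: 16 named columns. List-ish fields
## (EC numbers, GO terms, TIGR roles, disruptions) are comma-joined strings;
## empty string means none.
BER_EVIDENCE_COLUMNS <- c(
  "gene_id", "subject_id", "subject_name", "subject_symbol", "subject_ecs",
  "subject_go", "subject_tigr_roles", "percent_identity",
  "query_coverage_pct", "subject_coverage_pct", "p_value", "trusted",
  "n_frameshifts", "n_stops", "subject_start_query_nt", "disruptions"
)

empty_ber_table <- function() {
  df <- data.frame(
    gene_id = character(0), subject_id = character(0),
    subject_name = character(0), subject_symbol = character(0),
    subject_ecs = character(0), subject_go = character(0),
    subject_tigr_roles = character(0), percent_identity = numeric(0),
    query_coverage_pct = numeric(0), subject_coverage_pct = numeric(0),
    p_value = numeric(0), trusted = logical(0), n_frameshifts = integer(0),
    n_stops = integer(0), subject_start_query_nt = integer(0),
    disruptions = character(0), stringsAsFactors = FALSE
  )
  df
}

#' Read / write the canonical BER evidence TSV
#'
#' The table has 16 named columns (`gene_id`, `subject_id`, `subject_name`,
#' `subject_symbol`, `subject_ecs`, `subject_go`, `subject_tigr_roles`,
#' `percent_identity`, `query_coverage_pct`, `subject_coverage_pct`,
#' `p_value`, `trusted`, `n_frameshifts`, `n_stops`,
#' `subject_start_query_nt`, `disruptions`). GO terms are encoded as
#' `GOID|evidence_code` pairs, comma-separated; `subject_start_query_nt` is
#' the 0-based position, in the strand-oriented extended query, at which
#' subject residue 1 aligns (`NA` when residue 1 is not aligned).
#'
#' @param path TSV file.
#' @return `read_ber_evidence`: a data.frame with the columns above.
#' @export
read_ber_evidence <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = "NA", colClasses = NA)
  miss <- setdiff(BER_EVIDENCE_COLUMNS, names(df))
  if (length(miss)) stop("BER evidence table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df <- df[BER_EVIDENCE_COLUMNS]
  for (col in c("subject_name", "subject_symbol", "subject_ecs",
                "subject_go", "subject_tigr_roles", "disruptions")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "", as.character(df[[col]]))
  }
  df$trusted <- as.logical(df$trusted)
  df$subject_start_query_nt <- as.integer(df$subject_start_query_nt)
  bad <- df$percent_identity < 0 | df$percent_identity > 100 |
    df$query_coverage_pct < 0 | df$query_coverage_pct > 100 |
    df$subject_coverage_pct < 0 | df$subject_coverage_pct > 100 |
    df$p_value <= 0
  if (any(bad)) stop("BER evidence out of range on row(s): ",
                     paste(which(bad), collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_ber_evidence
#' @param ber BER evidence data.frame.
#' @export
write_ber_evidence <- function(ber, path) {
  stopifnot(all(BER_EVIDENCE_COLUMNS %in% names(ber)))
  utils::write.table(ber[BER_EVIDENCE_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Parse 12-column BLAST tabular output (outfmt 6)
#'
#' Alignment coordinates are normalized to 0-based half-open with
#' `start < end`; a reversed subject interval (minus-frame hit) is recorded
#' in `subject_frame = -1`.
#'
#' @param path File, or a character vector of lines.
#' @return data.frame with columns `gene_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end`,
#'   `subject_frame`, `evalue`, `bit_score`.
#' @export
parse_blast_tabular <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else as.character(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- data.frame(
    gene_id = character(0), subject_id = character(0),
    percent_identity = numeric(0), alignment_length = integer(0),
    mismatches = integer(0), gap_opens = integer(0),
    query_start = integer(0), query_end = integer(0),
    subject_start = integer(0), subject_end = integer(0),
    subject_frame = integer(0), evalue = numeric(0),
    bit_score = numeric(0), stringsAsFactors = FALSE
  )
  if (!length(lines)) return(out)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(fields)
  if (any(nc != 12L)) {
    stop("malformed BLAST tabular line ", which(nc != 12L)[1],
         ": expected 12 columns, found ", nc[nc != 12L][1], call. = FALSE)
  }
  m <- do.call(rbind, fields)
  qs <- as.integer(m[, 7]); qe <- as.integer(m[, 8])
  ss <- as.integer(m[, 9]); se <- as.integer(m[, 10])
  frame <- ifelse(ss <= se, 1L, -1L)
  s_lo <- pmin(ss, se); s_hi <- pmax(ss, se)
  q_lo <- pmin(qs, qe); q_hi <- pmax(qs, qe)
  data.frame(
    gene_id = m[, 1], subject_id = m[, 2],
    percent_identity = as.numeric(m[, 3]),
    alignment_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    query_start = q_lo - 1L, query_end = q_hi,
    subject_start = s_lo - 1L, subject_end = s_hi,
    subject_frame = frame, evalue = as.numeric(m[, 11]),
    bit_score = as.numeric(m[, 12]), stringsAsFactors = FALSE
  )
}

#' Parse a GO association file (GAF 2.x)
#'
#' Comment lines starting with `!` are skipped. Rows are aggregated per
#' database object id (column 2).
#'
#' @param path File, or a character vector of lines.
#' @return Named list mapping object id to a data.frame with columns
#'   `go_id`, `evidence_code`, `aspect`.
#' @export
parse_gaf <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else as.character(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) return(structure(list(), names = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(fields)
  if (any(nc < 15L)) {
    stop("malformed GAF line ", which(nc < 15L)[1], ": expected >= 15 columns",
         call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, function(x) x[1:15]))
  df <- data.frame(object_id = m[, 2], go_id = m[, 5],
                   evidence_code = m[, 7], aspect = m[, 9],
                   stringsAsFactors = FALSE)
  split(df[c("go_id", "evidence_code", "aspect")], df$object_id)
}

## GAF evidence codes that mark experimental support
EXPERIMENTAL_GO_CODES <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")

#' Is a BER subject protein a trusted (experimentally supported) match?
#'
#' A subject is trusted when it (a) appears in the characterized-protein
#' list, (b) appears in the set of proteins with curated experimental
#' support, or (c) carries at least one GO association with an experimental
#' evidence code (EXP, IDA, IPI, IMP, IGI, IEP).
#'
#' @param subject_id Subject protein id.
#' @param subject_go data.frame of GO associations for this subject
#'   (`go_id`, `evidence_code`), or `NULL`.
#' @param characterized Character vector of literature-characterized ids.
#' @param uniprot_experimental Character vector of ids with curated
#'   experimental support.
#' @return Logical scalar.
#' @export
determine_trusted <- function(subject_id, subject_go = NULL,
                              characterized = character(0),
                              uniprot_experimental = character(0)) {
  if (subject_id %in% characterized) return(TRUE)
  if (subject_id %in% uniprot_experimental) return(TRUE)
  if (!is.null(subject_go) && NROW(subject_go) > 0 &&
      any(subject_go$evidence_code %in% EXPERIMENTAL_GO_CODES)) return(TRUE)
  FALSE
}

#' Read HMM hits and join them to profile metadata
#'
#' @param path Canonical HMM hit TSV with columns `gene_id`, `accession`,
#'   `total_score` (or a data.frame of the same shape).
#' @param metadata HMM metadata table, see [read_hmm_metadata()].
#' @return data.frame with one row per hit: `gene_id`, `accession`,
#'   `total_score`, `trusted_cutoff`, `isology`, `hmm_name`, `hmm_symbol`,
#'   `hmm_ecs`, `hmm_go`, `hmm_tigr_roles`, `passes_trusted`.
#' @export
read_hmm_hits <- function(path, metadata) {
  hits <- if (is.data.frame(path)) path
          else utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "accession", "total_score")
  miss <- setdiff(req, names(hits))
  if (length(miss)) stop("HMM hit table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(hits) == 0) {
    return(data.frame(gene_id = character(0), accession = character(0),
                      total_score = numeric(0), trusted_cutoff = numeric(0),
                      isology = character(0), hmm_name = character(0),
                      hmm_symbol = character(0), hmm_ecs = character(0),
                      hmm_go = character(0), hmm_tigr_roles = character(0),
                      passes_trusted = logical(0), stringsAsFactors = FALSE))
  }
  idx <- match(hits$accession, metadata$accession)
  if (anyNA(idx)) {
    stop("HMM hit(s) with accession absent from metadata: ",
         paste(unique(hits$accession[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    gene_id = as.character(hits$gene_id),
    accession = as.character(hits$accession),
    total_score = as.numeric(hits$total_score),
    trusted_cutoff = metadata$trusted_cutoff[idx],
    isology = metadata$isology[idx],
    hmm_name = metadata$name[idx],
    hmm_symbol = metadata$symbol[idx],
    hmm_ecs = metadata$ecs[idx],
    hmm_go = metadata$go[idx],
    hmm_tigr_roles = metadata$tigr_roles[idx],
    stringsAsFactors = FALSE
  )
  out$passes_trusted <- out$total_score >= out$trusted_cutoff
  out
}

HMM_ISOLOGIES <- c("equivalog", "equivalog_domain", "subfamily",
                   "superfamily", "subfamily_domain", "domain", "pfam",
                   "hypothetical_equivalog")

#' Read the HMM metadata table
#'
#' Columns: `accession`, `name`, `isology`, `trusted_cutoff`, `symbol`,
#' `ecs`, `go`, `tigr_roles` (the last four may be empty). Isology is one of
#' equivalog, equivalog_domain, subfamily, superfamily, subfamily_domain,
#' domain, pfam, hypothetical_equivalog.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_hmm_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("accession", "name", "isology", "trusted_cutoff")
  miss <- setdiff(req, names(md))
  if (length(miss)) stop("HMM metadata lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("symbol", "ecs", "go", "tigr_roles")) {
    if (is.null(md[[col]])) md[[col]] <- ""
    md[[col]] <- ifelse(is.na(md[[col]]), "", as.character(md[[col]]))
  }
  md$isology <- tolower(gsub("[ -]", "_", md$isology))
  bad <- !md$isology %in% HMM_ISOLOGIES
  if (any(bad)) stop("unknown isology value(s): ",
                     paste(unique(md$isology[bad]), collapse = ", "),
                     call. = FALSE)
  if (anyDuplicated(md$accession)) stop("duplicate HMM accession in metadata",
                                        call. = FALSE)
  md
}

#' Parse a LipoP short-format report
#'
#' Tolerant line-oriented reader: recognizes lines of the form
#' `# <id> <class> score=<x>` (class one of SpI, SpII, TMH, CYT); other
#' lines produce a warning and are skipped. A lipoprotein signal peptide is
#' predicted when the best class is SpII.
#'
#' @param path File, or character vector of lines.
#' @return data.frame with `gene_id`, `best_class`, `score`,
#'   `predicted_lipoprotein`.
#' @export
parse_lipop <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else as.character(path)
  lines <- lines[nzchar(trimws(lines))]
  pat <- "^#\\s*(\\S+)\\s+(SpII|SpI|TMH|CYT)\\b\\s*(?:score=)?(-?[0-9.]+)?"
  m <- regmatches(lines, regexec(pat, lines))
  ok <- lengths(m) > 0
  if (any(!ok)) {
    warning("skipping ", sum(!ok), " unrecognized LipoP line(s)",
            call. = FALSE)
  }
  m <- m[ok]
  if (!length(m)) {
    return(data.frame(gene_id = character(0), best_class = character(0),
                      score = numeric(0), predicted_lipoprotein = logical(0),
                      stringsAsFactors = FALSE))
  }
  gene_id <- vapply(m, `[`, character(1), 2)
  best <- vapply(m, `[`, character(1), 3)
  score <- suppressWarnings(as.numeric(vapply(m, `[`, character(1), 4)))
  data.frame(gene_id = gene_id, best_class = best, score = score,
             predicted_lipoprotein = best == "SpII", stringsAsFactors = FALSE)
}

#' Parse a TMHMM short-format report
#'
#' One line per protein: whitespace-separated `key=value` fields including
#' `PredHel=` and `Topology=`. Lines without a `PredHel=` field produce a
#' warning and are skipped.
#'
#' @param path File, or character vector of lines.
#' @return data.frame with `gene_id`, `predicted_helices`, `topology`.
#' @export
parse_tmhmm <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else as.character(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  hel <- regmatches(lines, regexec("PredHel=([0-9]+)", lines))
  ok <- lengths(hel) == 2L
  if (any(!ok)) {
    warning("skipping ", sum(!ok), " unrecognized TMHMM line(s)",
            call. = FALSE)
  }
  lines <- lines[ok]
  if (!length(lines)) {
    return(data.frame(gene_id = character(0), predicted_helices = integer(0),
                      topology = character(0), stringsAsFactors = FALSE))
  }
  gene_id <- sub("^(\\S+).*$", "\\1", lines)
  helices <- as.integer(vapply(hel[ok], `[`, character(1), 2))
  topo <- rep(NA_character_, length(lines))
  tm <- regmatches(lines, regexec("Topology=(\\S+)", lines))
  has <- lengths(tm) == 2L
  topo[has] <- vapply(tm[has], `[`, character(1), 2)
  data.frame(gene_id = gene_id, predicted_helices = helices,
             topology = topo, stringsAsFactors = FALSE)
}

## ---- list-field helpers for the comma-joined TSV columns -----------------

join_field <- function(x) paste(x, collapse = ",")

split_field <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ",")[[1]]
}

## GO fields are encoded "GOID|code" pairs
split_go_field <- function(x) {
  toks <- split_field(x)
  if (!length(toks)) {
    return(data.frame(go_id = character(0), evidence_code = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(toks, "|", fixed = TRUE)
  data.frame(go_id = vapply(parts, `[`, character(1), 1),
             evidence_code = vapply(parts, function(p)
               if (length(p) > 1) p[2] else NA_character_, character(1)),
             stringsAsFactors = FALSE)
}

#' Collect all evidence for one gene into a bundle
#'
#' @param gene_id Gene id.
#' @param ber BER evidence table (rows for other genes are dropped).
#' @param hmm Joined HMM hit table (see [read_hmm_hits()]).
#' @param lipop LipoP prediction table (see [parse_lipop()]).
#' @param tmhmm TMHMM prediction table (see [parse_tmhmm()]).
#' @return An `evidence_bundle`: list with `gene_id`, `ber`, `hmm`, `lipop`
#'   (one-row data.frame or `NULL`), `tmhmm` (likewise).
#' @export
evidence_bundle <- function(gene_id, ber = NULL, hmm = NULL, lipop = NULL,
                            tmhmm = NULL) {
  pick <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(df[0, , drop = FALSE])
    df[df$gene_id == gene_id, , drop = FALSE]
  }
  one <- function(df) {
    if (is.null(df)) return(NULL)
    df <- df[df$gene_id == gene_id, , drop = FALSE]
    if (nrow(df) == 0) NULL else df[1, , drop = FALSE]
  }
  structure(list(
    gene_id = gene_id,
    ber = if (is.null(ber)) empty_ber_table() else pick(ber),
    hmm = pick(if (is.null(hmm))
      read_hmm_hits(data.frame(gene_id = character(0),
                               accession = character(0),
                               total_score = numeric(0)),
                    data.frame(accession = character(0), name = character(0),
                               isology = character(0),
                               trusted_cutoff = numeric(0)))
      else hmm),
    lipop = one(lipop),
    tmhmm = one(tmhmm)
  ), class = "evidence_bundle")
}
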