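## Domain model: an assembly is a named DNAStringSet; gene models are rows of
## a validated data.frame. Internal coordinates are 0-based half-open on the
## forward strand, with strand stored separately; GFF3 I/O converts at the
## boundary. This removes off-by-one ambiguity from all overlap arithmetic.

#' Construct a gene-model table
#'
#' @param id Feature ids (unique, non-empty).
#' @param contig_id Contig each feature lies on.
#' @param start,end 0-based half-open forward-strand nucleotide coordinates.
#' @param strand `"+"` or `"-"`.
#' @param feature_type One of `"CDS"`, `"rRNA"`, `"tRNA"`.
#' @param locus_tag Optional locus tags (`NA` when unassigned).
#' @param partial5,partial3 Logical: is the model missing its 5' or 3' end?
#' @return A `data.frame` with one row per feature.
#' @export
gene_table <- function(id, contig_id, start, end, strand,
                       feature_type = "CDS", locus_tag = NA_character_,
                       partial5 = FALSE, partial3 = FALSE) {
  df <- data.frame(
    id = as.character(id), contig_id = as.character(contig_id),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand), feature_type = as.character(feature_type),
    locus_tag = as.character(locus_tag),
    partial5 = as.logical(partial5), partial3 = as.logical(partial3),
    stringsAsFactors = FALSE
  )
  validate_gene_table(df)
  df
}

#' Validate a gene-model table against an assembly
#'
#' Checks coordinate sanity, strand/type vocabulary, id uniqueness and — when
#' `contigs` is supplied — that every feature fits on its contig and that
#' every complete CDS has length divisible by 3.
#'
#' @param genes Gene-model table (see [gene_table()]).
#' @param contigs Optional named `DNAStringSet` assembly.
#' @return `genes`, invisibly.
#' @export
validate_gene_table <- function(genes, contigs = NULL) {
  req <- c("id", "contig_id", "start", "end", "strand", "feature_type")
  miss <- setdiff(req, names(genes))
  if (length(miss)) stop("gene table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(genes$id)) stop("duplicate feature id(s): ",
    paste(unique(genes$id[duplicated(genes$id)]), collapse = ", "),
    call. = FALSE)
  if (any(!genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  if (any(!genes$feature_type %in% c("CDS", "rRNA", "tRNA")))
    stop("feature_type must be CDS, rRNA or tRNA", call. = FALSE)
  if (any(genes$start < 0L) || any(genes$start >= genes$end))
    stop("require 0 <= start < end for every feature", call. = FALSE)
  cds <- genes$feature_type == "CDS"
  if (!is.null(genes$partial5)) {
    complete <- cds & !(genes$partial5 | genes$partial3)
    bad <- complete & ((genes$end - genes$start) %% 3L != 0L)
    if (any(bad)) stop("complete CDS length not divisible by 3: ",
                       paste(genes$id[bad], collapse = ", "), call. = FALSE)
  }
  if (!is.null(contigs)) {
    unk <- setdiff(genes$contig_id, names(contigs))
    if (length(unk)) stop("feature(s) on unknown contig(s): ",
                          paste(unk, collapse = ", "), call. = FALSE)
    len <- Biostrings::width(contigs)[match(genes$contig_id, names(contigs))]
    if (any(genes$end > len))
      stop("feature(s) extend past contig end: ",
           paste(genes$id[genes$end > len], collapse = ", "), call. = FALSE)
  }
  invisible(genes)
}

#' Convert between GFF3 1-based inclusive and internal 0-based half-open
#'
#' @param start,end Coordinates in the source convention.
#' @return A list with `start` and `end` in the target convention.
#' @export
gff_to_internal <- function(start, end) {
  list(start = as.integer(start) - 1L, end = as.integer(end))
}

#' @rdname gff_to_internal
#' @export
internal_to_gff <- function(start, end) {
  list(start = as.integer(start) + 1L, end = as.integer(end))
}

#' Extract the strand-oriented nucleotide sequence of a feature
#'
#' Minus-strand features are reverse complemented so the gene reads 5' to 3'.
#'
#' @param contigs Named `DNAStringSet`.
#' @param gene One row of a gene-model table.
#' @return DNA string.
#' @export
gene_sequence <- function(contigs, gene) {
  seqc <- as.character(Biostrings::subseq(
    contigs[[gene$contig_id]], start = gene$start + 1L, end = gene$end))
  if (gene$strand == "-") seqc <- reverse_complement(seqc)
  seqc
}

#' Translate every CDS in a gene table
#'
#' @inheritParams gene_sequence
#' @param genes Gene-model table.
#' @return A `data.frame` with `gene_id`, `aa_sequence`, `length_aa`.
#' @export
translate_genes <- function(contigs, genes) {
  cds <- genes[genes$feature_type == "CDS", , drop = FALSE]
  aa <- vapply(seq_len(nrow(cds)), function(i) {
    translate_cds(gene_sequence(contigs, cds[i, ]),
                  partial5 = isTRUE(cds$partial5[i]))
  }, character(1))
  data.frame(gene_id = cds$id, aa_sequence = aa, length_aa = nchar(aa),
             stringsAsFactors = FALSE)
}
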