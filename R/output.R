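## Locus-tag assignment and standard-format emission. Tags number all
## features in one shared series: contigs ordered by length (longest first,
## ties by id), features within a contig by start coordinate (ties: longer
## feature first). Output is deterministic — identical inputs give
## byte-identical files.

#' Locus-tag policy
#'
#' @param prefix Tag prefix (required, non-empty).
#' @param separator Separator between prefix and number (default `"_"`).
#' @param pad_width Zero-padding width of the number (default 4).
#' @param step Numbering step (default 1; numbering starts at `step`).
#' @return Object of class `locus_tag_policy`.
#' @export
locus_tag_policy <- function(prefix, separator = "_", pad_width = 4L,
                             step = 1L) {
  stopifnot(is.character(prefix), nzchar(prefix), step >= 1)
  structure(list(prefix = prefix, separator = separator,
                 pad_width = as.integer(pad_width), step = as.integer(step)),
            class = "locus_tag_policy")
}

#' Assign locus tags to all features of an assembly
#'
#' @param contigs Named `DNAStringSet`.
#' @param features Gene-model table (CDS + RNAs share one series).
#' @param policy [locus_tag_policy()].
#' @return The feature table, reordered into tag order, with `locus_tag`
#'   filled in.
#' @export
assign_locus_tags <- function(contigs, features, policy) {
  validate_gene_table(features, contigs)
  if (!nrow(features)) return(features)
  clen <- stats::setNames(Biostrings::width(contigs), names(contigs))
  contig_rank <- order(-clen, names(clen))
  contig_pos <- stats::setNames(seq_along(contig_rank),
                                names(clen)[contig_rank])
  ord <- order(contig_pos[features$contig_id], features$start,
               -(features$end - features$start), features$id)
  out <- features[ord, , drop = FALSE]
  n <- seq_len(nrow(out)) * policy$step
  out$locus_tag <- sprintf(paste0("%s%s%0", policy$pad_width, "d"),
                           policy$prefix, policy$separator, n)
  rownames(out) <- NULL
  out
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x
}

#' Write curated, annotated features as GFF3
#'
#' Emits one `gene` line plus one child `CDS`/`rRNA`/`tRNA` line per
#' feature, 1-based inclusive coordinates, with `locus_tag`, `product` and
#' `Dbxref` (GO terms, EC numbers, TIGR roles) attributes where available.
#'
#' @param features Gene-model table with locus tags assigned.
#' @param annotations Annotation table ([pfunc_annotate()]); every CDS must
#'   have a row.
#' @param path Output file.
#' @param source Column-2 source string (default `"prokannot"`).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, annotations, path, source = "prokannot") {
  cds_ids <- features$id[features$feature_type == "CDS"]
  miss <- setdiff(cds_ids, annotations$gene_id)
  if (length(miss)) stop("missing annotation for gene(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    co <- internal_to_gff(f$start, f$end)
    gene_attrs <- sprintf("ID=gene-%s;locus_tag=%s", gff3_escape(f$id),
                          gff3_escape(f$locus_tag))
    writeLines(paste(f$contig_id, source, "gene", co$start, co$end, ".",
                     f$strand, ".", gene_attrs, sep = "\t"), con)
    attrs <- sprintf("ID=%s;Parent=gene-%s;locus_tag=%s",
                     gff3_escape(f$id), gff3_escape(f$id),
                     gff3_escape(f$locus_tag))
    if (f$feature_type == "CDS") {
      a <- annotations[annotations$gene_id == f$id, , drop = FALSE][1, ]
      attrs <- paste0(attrs, ";product=", gff3_escape(a$common_name))
      if (nzchar(a$gene_symbol)) {
        attrs <- paste0(attrs, ";gene=", gff3_escape(a$gene_symbol))
      }
      dbx <- c(split_field(a$go_terms),
               if (nzchar(a$ec_numbers))
                 paste0("EC:", split_field(a$ec_numbers)),
               if (nzchar(a$tigr_roles))
                 paste0("TIGR_role:", split_field(a$tigr_roles)))
      if (length(dbx)) {
        attrs <- paste0(attrs, ";Dbxref=",
                        paste(vapply(dbx, gff3_escape, character(1)),
                              collapse = ","))
      }
    }
    phase <- if (f$feature_type == "CDS") "0" else "."
    writeLines(paste(f$contig_id, source, f$feature_type, co$start, co$end,
                     ".", f$strand, phase, attrs, sep = "\t"), con)
  }
  invisible(path)
}

fasta_headers <- function(features, annotations) {
  vapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    a <- annotations[annotations$gene_id == f$id, , drop = FALSE]
    prod <- if (nrow(a)) a$common_name[1] else ""
    trimws(paste(f$locus_tag, prod))
  }, character(1))
}

#' Write CDS and polypeptide FASTA files
#'
#' Headers are `locus_tag product`. CDS sequences are strand oriented;
#' polypeptides are their table-11 translations.
#'
#' @param contigs Named `DNAStringSet`.
#' @param features Gene-model table with locus tags.
#' @param annotations Annotation table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(contigs, features, annotations, path) {
  cds <- features[features$feature_type == "CDS", , drop = FALSE]
  seqs <- vapply(seq_len(nrow(cds)), function(i)
    gene_sequence(contigs, cds[i, ]), character(1))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- fasta_headers(cds, annotations)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' @rdname write_cds_fasta
#' @export
write_polypeptide_fasta <- function(contigs, features, annotations, path) {
  cds <- features[features$feature_type == "CDS", , drop = FALSE]
  seqs <- vapply(seq_len(nrow(cds)), function(i)
    translate_cds(gene_sequence(contigs, cds[i, ]),
                  partial5 = isTRUE(cds$partial5[i])), character(1))
  x <- Biostrings::AAStringSet(seqs)
  names(x) <- fasta_headers(cds, annotations)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Write the final annotation TSV
#'
#' One row per CDS: locus tag, common name, gene symbol, EC numbers, GO
#' terms, TIGR roles, evidence type, final rank, provenance.
#'
#' @param features Gene-model table with locus tags.
#' @param annotations Annotation table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(features, annotations, path) {
  cds <- features[features$feature_type == "CDS", , drop = FALSE]
  miss <- setdiff(cds$id, annotations$gene_id)
  if (length(miss)) stop("missing annotation for gene(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  a <- annotations[match(cds$id, annotations$gene_id), , drop = FALSE]
  out <- cbind(data.frame(locus_tag = cds$locus_tag,
                          stringsAsFactors = FALSE), a)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write interevidence regions as FASTA for external re-search
#'
#' @param contigs Named `DNAStringSet`.
#' @param regions data.frame from [find_interevidence_regions()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_interevidence_fasta <- function(contigs, regions, path) {
  if (!nrow(regions)) {
    x <- Biostrings::DNAStringSet()
    Biostrings::writeXStringSet(x, path)
    return(invisible(path))
  }
  seqs <- vapply(seq_len(nrow(regions)), function(i) {
    as.character(Biostrings::subseq(contigs[[regions$contig_id[i]]],
                                    start = regions$start[i] + 1L,
                                    end = regions$end[i]))
  }, character(1))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("%s:%d-%d", regions$contig_id, regions$start + 1L,
                      regions$end)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
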