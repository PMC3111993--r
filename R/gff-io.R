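## GFF3 / FASTA input. Reading goes through rtracklayer (GFF3) and
## Biostrings (FASTA); coordinates are converted to the internal 0-based
## half-open convention at this boundary.

#' Read an assembly from a nucleotide FASTA file
#'
#' @param path FASTA file of contigs.
#' @return Named `DNAStringSet`; names are the first whitespace-delimited
#'   token of each header.
#' @export
read_assembly <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  names(dna) <- sub("\\s.*$", "", names(dna))
  if (anyDuplicated(names(dna))) stop("duplicate contig id in ", path,
                                      call. = FALSE)
  dna
}

#' Read gene models from a GFF3 file
#'
#' CDS, rRNA and tRNA features are kept; coordinates are converted from GFF3
#' 1-based inclusive to internal 0-based half-open.
#'
#' @param path GFF3 file.
#' @return Gene-model table (see [gene_table()]).
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% c("CDS", "rRNA", "tRNA")]
  md <- S4Vectors::mcols(gr)
  get_chr <- function(col, default = NA_character_) {
    if (col %in% names(md)) as.character(md[[col]]) else
      rep(default, length(gr))
  }
  id <- get_chr("ID")
  if (anyNA(id)) {
    nm <- get_chr("Name")
    id[is.na(id)] <- nm[is.na(id)]
  }
  if (anyNA(id)) id[is.na(id)] <- paste0("feature_", which(is.na(id)))
  partial <- get_chr("partial", default = "")
  partial[is.na(partial)] <- ""
  co <- gff_to_internal(BiocGenerics::start(gr), BiocGenerics::end(gr))
  gene_table(
    id = id,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = co$start, end = co$end,
    strand = as.character(BiocGenerics::strand(gr)),
    feature_type = as.character(gr$type),
    locus_tag = get_chr("locus_tag"),
    partial5 = grepl("(^|,)5", partial),
    partial3 = grepl("(^|,)3", partial)
  )
}
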