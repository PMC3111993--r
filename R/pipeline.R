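## Pipeline orchestration, in evidence order: start-site curation ->
## overlap curation -> interevidence regions -> functional annotation ->
## post-processing -> locus tags and output files.

#' Run configuration
#'
#' Validates paths and thresholds for [run_annotate()].
#'
#' @param genome Path to the contig FASTA.
#' @param genes Path to the gene-model GFF3.
#' @param ber Path to the canonical BER evidence TSV (optional).
#' @param hmm,hmm_metadata Paths to the HMM hit and metadata TSVs
#'   (optional, required together).
#' @param lipop,tmhmm,gaf,characterized Optional evidence paths.
#' @param locus_prefix Locus-tag prefix.
#' @param out Output directory.
#' @param thresholds [pipeline_thresholds()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(genome, genes, ber = NULL, hmm = NULL,
                       hmm_metadata = NULL, lipop = NULL, tmhmm = NULL,
                       gaf = NULL, characterized = NULL,
                       locus_prefix = "LOCUS", out = "annotation_out",
                       thresholds = pipeline_thresholds()) {
  must_exist <- function(p, what) {
    if (!is.null(p) && !file.exists(p)) {
      stop(what, " file not found: ", p, call. = FALSE)
    }
    p
  }
  must_exist(genome, "genome"); must_exist(genes, "genes")
  for (nm in c("ber", "hmm", "hmm_metadata", "lipop", "tmhmm", "gaf",
               "characterized")) {
    must_exist(get(nm), nm)
  }
  if (is.null(hmm) != is.null(hmm_metadata)) {
    stop("hmm and hmm_metadata must be given together", call. = FALSE)
  }
  validate_thresholds(thresholds)
  structure(list(genome = genome, genes = genes, ber = ber, hmm = hmm,
                 hmm_metadata = hmm_metadata, lipop = lipop, tmhmm = tmhmm,
                 gaf = gaf, characterized = characterized,
                 locus_prefix = locus_prefix, out = out,
                 thresholds = thresholds), class = "run_config")
}

#' Run the annotation pipeline
#'
#' Executes, in order: start-site curation, overlap curation,
#' interevidence-region detection, hierarchical functional annotation,
#' common-name post-processing, locus-tag assignment and output emission
#' (`annotation.gff3`, `cds.fna`, `polypeptides.faa`, `annotation.tsv`,
#' `curation_report.tsv`, `disruption_report.tsv`, `interevidence.fna`).
#' Missing optional evidence degrades gracefully (with a warning for a
#' missing GAF: no GO-code-based trusted matches can then be recomputed).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the output directory and the main
#'   in-memory results (`genes`, `annotations`, `decisions`, `regions`,
#'   `disruptions`).
#' @export
run_annotate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  th <- config$thresholds
  contigs <- read_assembly(config$genome)
  genes <- read_genes_gff3(config$genes)
  validate_gene_table(genes, contigs)
  ber <- if (!is.null(config$ber)) read_ber_evidence(config$ber)
         else empty_ber_table()
  hmm <- if (!is.null(config$hmm)) {
    read_hmm_hits(config$hmm, read_hmm_metadata(config$hmm_metadata))
  } else NULL
  lipop <- if (!is.null(config$lipop)) parse_lipop(config$lipop) else NULL
  tmhmm <- if (!is.null(config$tmhmm)) parse_tmhmm(config$tmhmm) else NULL
  if (is.null(config$gaf)) {
    warning("no GAF supplied: GO-evidence-based trusted status cannot be ",
            "recomputed; using the trusted flags in the evidence table",
            call. = FALSE)
  }

  ## 1. start sites
  st <- curate_starts(contigs, genes, ber, th)
  genes <- st$genes

  ## 2. overlaps, against the original evidence state
  evid <- vapply(genes$id, function(id) {
    has_evidence(evidence_bundle(id, ber, hmm), th)
  }, logical(1))
  names(evid) <- genes$id
  ov <- curate_overlaps(genes, evid, th)
  genes <- ov$kept

  ## 3. interevidence regions
  regions <- do.call(rbind, lapply(names(contigs), function(cid) {
    find_interevidence_regions(cid, Biostrings::width(contigs)[
      match(cid, names(contigs))], genes, evid)
  }))

  ## 4. functional annotation + 5. post-processing
  cds_ids <- genes$id[genes$feature_type == "CDS"]
  ann <- pfunc_annotate(cds_ids, ber, hmm, lipop, tmhmm, th)
  ann <- post_process(ann)

  ## 6. locus tags and outputs
  tagged <- assign_locus_tags(contigs, genes,
                              locus_tag_policy(config$locus_prefix))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out, f)
  write_gff3(tagged, ann, outp("annotation.gff3"))
  write_cds_fasta(contigs, tagged, ann, outp("cds.fna"))
  write_polypeptide_fasta(contigs, tagged, ann, outp("polypeptides.faa"))
  write_annotation_tsv(tagged, ann, outp("annotation.tsv"))
  utils::write.table(ov$decisions, outp("curation_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(st$report, outp("start_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  disr <- disruption_report(ber)
  utils::write.table(disr, outp("disruption_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (is.null(regions)) {
    regions <- data.frame(contig_id = character(0), start = integer(0),
                          end = integer(0), member_gene_ids = character(0))
  }
  write_interevidence_fasta(contigs, regions, outp("interevidence.fna"))
  utils::write.table(regions, outp("interevidence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(out = config$out, genes = tagged, annotations = ann,
                 decisions = ov$decisions, removed = ov$removed,
                 regions = regions, disruptions = disr,
                 start_report = st$report))
}
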