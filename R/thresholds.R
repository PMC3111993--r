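#' Pipeline thresholds
#'
#' Registry of every numeric knob used by the annotation workflow. The
#' defaults are the working values of the pipeline: BER matches below 40%
#' identity are discarded, coverage of at least 80% classifies an alignment
#' side as Full, overlaps of more than 60 bp trigger curation, gene regions
#' are extended by 300 nt on each side before frameshift-tolerant alignment,
#' TMHMM annotation requires at least 5 membrane-spanning helices, at most
#' 150 alignments are retained per gene, and the seeding blast search uses an
#' e-value cutoff of 1e-5.
#'
#' @param ber_min_identity_pct Minimum percent identity for a BER match to be
#'   considered for annotation (percent, default 40).
#' @param full_coverage_cutoff_pct Coverage at or above which an alignment
#'   side is classified Full rather than Partial (percent, default 80).
#' @param overlap_threshold_bp Overlaps strictly greater than this many base
#'   pairs are evaluated for curation (default 60).
#' @param extension_nt Nucleotides added upstream and downstream of a gene
#'   before extended alignment (default 300).
#' @param tmhmm_min_spans Minimum predicted membrane-spanning regions for a
#'   TMHMM-based annotation (default 5).
#' @param max_alignments Maximum number of retained alignments per gene
#'   (default 150).
#' @param blast_evalue E-value cutoff of the seeding blast search
#'   (default 1e-5).
#' @return An object of class `pipeline_thresholds` (a validated named list).
#' @examples
#' th <- pipeline_thresholds()
#' th$overlap_threshold_bp
#' @export
pipeline_thresholds <- function(ber_min_identity_pct = 40,
                                full_coverage_cutoff_pct = 80,
                                overlap_threshold_bp = 60,
                                extension_nt = 300,
                                tmhmm_min_spans = 5,
                                max_alignments = 150,
                                blast_evalue = 1e-5) {
  th <- list(
    ber_min_identity_pct = ber_min_identity_pct,
    full_coverage_cutoff_pct = full_coverage_cutoff_pct,
    overlap_threshold_bp = overlap_threshold_bp,
    extension_nt = extension_nt,
    tmhmm_min_spans = tmhmm_min_spans,
    max_alignments = max_alignments,
    blast_evalue = blast_evalue
  )
  validate_thresholds(th)
  structure(th, class = "pipeline_thresholds")
}

validate_thresholds <- function(th) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(th)) {
    if (!num1(th[[nm]]) || th[[nm]] <= 0) {
      stop("threshold '", nm, "' must be a single positive finite number",
           call. = FALSE)
    }
  }
  for (nm in c("ber_min_identity_pct", "full_coverage_cutoff_pct")) {
    if (th[[nm]] > 100) {
      stop("threshold '", nm, "' must lie in (0, 100]", call. = FALSE)
    }
  }
  invisible(th)
}

#' @export
print.pipeline_thresholds <- function(x, ...) {
  cat("pipeline thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %g\n", nm, x[[nm]]))
  invisible(x)
}

## GO root terms assigned when no informative evidence survives filtering
GO_ROOTS <- c("GO:0008150", "GO:0003674", "GO:0005575")

## TIGR role ids used by the naming rules.  Only `cell_envelope_other` (88)
## is fixed by the annotation scheme; the rest come from the configurable
## role table and these are the shipped defaults.
#' Default TIGR role ids used by the annotation rules
#'
#' @return Named list with elements `cell_envelope_other` (88),
#'   `conserved_hypothetical`, `hypothetical` and `unknown_function`.
#' @export
default_tigr_roles <- function() {
  list(
    cell_envelope_other = 88L,
    conserved_hypothetical = 156L,
    hypothetical = 704L,
    unknown_function = 157L
  )
}

#' Default ambiguous common-name terms
#'
#' Word-boundary, case-insensitive terms that mark a transferred common name
#' as too vague to trust on a non-trusted match (e.g. "putative", "probable").
#'
#' @return Character vector of terms.
#' @export
default_ambiguous_terms <- function() {
  c("putative", "probable", "possible", "potential", "predicted",
    "uncharacterized", "unknown", "hypothetical", "homolog", "like",
    "related")
}
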