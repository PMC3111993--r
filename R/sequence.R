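## Sequence primitives: thin, validated wrappers around Biostrings with the
## conventions used throughout the package (genetic code table 11; ATG/GTG/TTG
## initiators render 'M' on complete CDS; internal stops render '*').

GENETIC_CODE_11 <- NULL  # populated at load time (needs Biostrings)

.onLoad <- function(libname, pkgname) {
  gc11 <- Biostrings::getGeneticCode("11")
  assign("GENETIC_CODE_11", gc11, envir = topenv())
}

check_dna_alphabet <- function(nt) {
  if (length(nt) != 1L || !is.character(nt)) {
    stop("expected a single character string of DNA", call. = FALSE)
  }
  bad <- gsub("[ACGTN]", "", toupper(nt))
  if (nzchar(bad)) {
    stop("invalid nucleotide character(s): ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
         call. = FALSE)
  }
  invisible(toupper(nt))
}

#' Translate a coding nucleotide sequence (genetic code table 11)
#'
#' Internal stop codons are rendered as `*`. For a complete CDS the initiator
#' codon is rendered `M` even when it is GTG or TTG; for a 5'-partial CDS the
#' first codon is translated like any other. A terminal stop codon, when
#' present, is trimmed from the returned peptide.
#'
#' @param nt DNA string over `{A,C,G,T,N}`.
#' @param partial5 Is the CDS 5'-partial (no initiator-codon rule)?
#' @param trim_terminal_stop Drop a trailing `*`? Default `TRUE`.
#' @return Amino-acid string.
#' @examples
#' translate_cds("ATGAAATAA")  # "MK"
#' translate_cds("GTGAAATAA")  # "MK" (GTG initiator)
#' @export
translate_cds <- function(nt, partial5 = FALSE, trim_terminal_stop = TRUE) {
  nt <- check_dna_alphabet(nt)
  if (nchar(nt) %% 3L != 0L) {
    stop("CDS length ", nchar(nt), " is not divisible by 3", call. = FALSE)
  }
  if (nchar(nt) == 0L) return("")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = GENETIC_CODE_11,
    if.fuzzy.codon = "solve",
    no.init.codon = partial5
  ))
  if (trim_terminal_stop) aa <- sub("\\*$", "", aa)
  aa
}

#' Reverse complement of a DNA string
#'
#' @param nt DNA string over `{A,C,G,T,N}`.
#' @return The reverse complement, same length.
#' @examples
#' reverse_complement("ACGT")  # "ACGT"
#' @export
reverse_complement <- function(nt) {
  nt <- check_dna_alphabet(nt)
  if (nchar(nt) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

## Amino acid of every codon start position of `nt` (one frame shift apart);
## position p (1-based) gives the residue for codon nt[p..p+2]. Used by the
## frameshift DP, which needs all three frames at once.
codon_translations <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n < 3L) return(character(0))
  aa <- character(n - 2L)
  for (f in 0:2) {
    sub <- substr(nt, f + 1L, f + 1L + ((n - f) %/% 3L) * 3L - 1L)
    if (nchar(sub) < 3L) next
    tr <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(sub), genetic.code = GENETIC_CODE_11,
      if.fuzzy.codon = "solve", no.init.codon = TRUE)), "")[[1]]
    aa[f + 1L + 3L * (seq_along(tr) - 1L)] <- tr
  }
  aa
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")
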