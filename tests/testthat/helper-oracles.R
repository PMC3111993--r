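# Independent reference implementations used as oracles. These share no
# code with the package's aligner: the frameshift reference is a top-down
# memoized recursion written directly from the scoring-model definition,
# and the per-frame Smith-Waterman is a plain affine local aligner over
# amino acids.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

gc11 <- Biostrings::getGeneticCode("11")

aa_of_codon <- function(codon) {
  if (grepl("N", codon)) return("X")
  unname(gc11[[codon]])
}

# best local frameshift-alignment score by top-down recursion with
# memoization; model: codon columns (3 nt / 1 aa; stop codons score
# `stp`), slip columns (1, 2, 4, 5 nt / 1 aa; penalty `fs`, plus the
# trailing codon's substitution score when >= 4 nt), affine gaps in codon
# units; alignments start and end on a column.
ref_frameshift_score <- function(nt, subject, mat = blosum62,
                                 open = -11, ext = -1, fs = -15,
                                 stp = -10) {
  n <- nchar(nt); s <- strsplit(subject, "")[[1]]; m <- length(s)
  colscore <- function(p, j) {      # codon starting at 0-based p
    codon <- substr(nt, p + 1, p + 3)
    if (codon %in% c("TAA", "TAG", "TGA")) return(stp)
    a <- aa_of_codon(codon)
    if (!a %in% rownames(mat)) a <- "X"
    sj <- if (s[j] %in% colnames(mat)) s[j] else "X"
    mat[a, sj]
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(state, i, j) {
    if (j < 1 || i < 0) return(-Inf)
    key <- paste0(state, ".", i, ".", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- -Inf
    if (state == "M") {
      for (k in c(3L, 1L, 2L, 4L, 5L)) {
        if (i - k < 0) next
        add <- if (k == 3L) colscore(i - 3, j)
               else fs + (if (k >= 4L) colscore(i - 3, j) else 0)
        prev <- max(0, rec("M", i - k, j - 1), rec("X", i - k, j - 1),
                    rec("Y", i - k, j - 1))
        val <- max(val, prev + add)
      }
    } else if (state == "X") {
      if (i - 3 >= 0) {
        val <- max(rec("M", i - 3, j) + open, rec("X", i - 3, j) + ext)
      }
    } else {
      val <- max(rec("M", i, j - 1) + open, rec("Y", i, j - 1) + ext)
    }
    memo[[key]] <- val
    val
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    best <- max(best, rec("M", i, j))
  }
  best
}

# plain affine local Smith-Waterman over amino-acid strings; '*' columns
# score `stp`; alignments end on a match column
ref_sw_score <- function(qaa, saa, mat = blosum62, open = -11, ext = -1,
                         stp = -10) {
  q <- strsplit(qaa, "")[[1]]; s <- strsplit(saa, "")[[1]]
  n <- length(q); m <- length(s)
  if (n == 0 || m == 0) return(0)
  M <- matrix(-Inf, n + 1, m + 1); X <- M; Y <- M
  sub <- function(a, b) {
    if (a == "*") return(stp)
    if (!a %in% rownames(mat)) a <- "X"
    if (!b %in% colnames(mat)) b <- "X"
    mat[a, b]
  }
  best <- 0
  for (i in 1:n) for (j in 1:m) {
    prev <- max(0, M[i, j], X[i, j], Y[i, j])
    M[i + 1, j + 1] <- prev + sub(q[i], s[j])
    X[i + 1, j + 1] <- max(M[i, j + 1] + open, X[i, j + 1] + ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] + open, Y[i + 1, j] + ext)
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# three-frame translation of a nucleotide string; stops rendered '*'
frame_translations <- function(nt) {
  vapply(0:2, function(f) {
    n <- nchar(nt)
    k <- (n - f) %/% 3
    if (k < 1) return("")
    codons <- substring(nt, f + 3 * (seq_len(k) - 1) + 1,
                        f + 3 * seq_len(k))
    paste(vapply(codons, function(cd)
      if (cd %in% c("TAA", "TAG", "TGA")) "*" else aa_of_codon(cd),
      character(1)), collapse = "")
  }, character(1))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_aa <- function(n) {
  paste(sample(setdiff(rownames(blosum62), c("*", "B", "J", "Z", "X")), n,
               replace = TRUE), collapse = "")
}

# encode a protein with one deterministic codon per residue
encode_protein <- function(aa) {
  pick <- vapply(strsplit(aa, "")[[1]], function(a)
    names(gc11)[gc11 == a][1], character(1))
  paste(pick, collapse = "")
}
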