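## Post-processing: final hygiene on transferred common names. Suffix
## stutter introduced by modifier composition is collapsed, embedded
## assertions (EC numbers, gene symbols) are moved out of the name into
## their proper fields, and high-level TIGR roles are backfilled from
## functional keywords when no role was assigned.

#' Default common-name rewrite rules
#'
#' Ordered, editable table of word-boundary regex rules collapsing
#' nonsensical suffix stutter ("protein domain protein", "family protein
#' family protein", "protein protein", ...). Each rule is idempotent.
#' An editable TSV copy ships in `inst/extdata/name_rules.tsv`.
#'
#' @return data.frame with `pattern`, `replacement`, `rule_id`.
#' @export
default_name_rules <- function() {
  ## longer (more specific) patterns first, so a doubled suffix collapses
  ## before the generic protein-suffix rules can bite into it
  data.frame(
    pattern = c(
      "\\bfamily protein family protein\\b",
      "\\bdomain protein domain protein\\b",
      "\\bfamily protein domain protein\\b",
      "\\bdomain protein family protein\\b",
      "\\bprotein domain protein\\b",
      "\\bprotein family protein\\b",
      "\\bprotein protein\\b"
    ),
    replacement = c(
      "family protein",
      "domain protein",
      "family domain protein",
      "domain family protein",
      "domain protein",
      "family protein",
      "protein"
    ),
    rule_id = paste0("suffix_", 1:7),
    stringsAsFactors = FALSE
  )
}

#' Clean a common name
#'
#' Applies the rewrite rules repeatedly (at most `max_passes`) until a fixed
#' point, then collapses duplicate whitespace and trims.
#'
#' @param name Common name (non-empty).
#' @param rules Rule table ([default_name_rules()]).
#' @param max_passes Passes before giving up (default 3; the default rules
#'   reach their fixed point within this bound).
#' @return Cleaned name.
#' @examples
#' fix_name("kinase protein domain protein")  # "kinase domain protein"
#' @export
fix_name <- function(name, rules = default_name_rules(), max_passes = 3L) {
  stopifnot(is.character(name), nzchar(name))
  for (pass in seq_len(max_passes)) {
    before <- name
    for (r in seq_len(nrow(rules))) {
      name <- gsub(rules$pattern[r], rules$replacement[r], name)
    }
    name <- trimws(gsub("[ \t]+", " ", name))
    if (identical(name, before)) break
  }
  name
}

#' Extract embedded gene symbols and EC numbers from a common name
#'
#' EC tokens (`d.d.d.d`, trailing components optionally `-`) are moved,
#' unmodified, into `ec_numbers` — partial EC numbers remain valid
#' annotations. A trailing parenthesized short token (letter-initial,
#' alphanumeric, at most 6 characters) becomes the gene symbol. The name is
#' cleaned of the moved tokens.
#'
#' @param name Common name.
#' @return List with `name`, `gene_symbol` (`""` when none), `ec_numbers`
#'   (character vector).
#' @examples
#' extract_embedded("alcohol dehydrogenase (EC 1.1.1.1) (adhA)")
#' @export
extract_embedded <- function(name) {
  ec_pat <- "[0-9]+\\.(?:[0-9]+|-)\\.(?:[0-9]+|-)\\.(?:[0-9n]+|-)"
  ecs <- character(0)
  m <- gregexpr(ec_pat, name, perl = TRUE)[[1]]
  if (m[1] != -1) {
    ecs <- regmatches(name, gregexpr(ec_pat, name, perl = TRUE))[[1]]
    ## strip parenthesized/bracketed or bare EC mentions around each token
    name <- gsub(paste0("\\(\\s*(EC|ec)?[ :]*", ec_pat, "\\s*\\)"), "",
                 name, perl = TRUE)
    name <- gsub(paste0("\\[\\s*(EC|ec)?[ :]*", ec_pat, "\\s*\\]"), "",
                 name, perl = TRUE)
    name <- gsub(paste0("\\b(EC|ec)[ :]*", ec_pat), "", name, perl = TRUE)
    name <- gsub(ec_pat, "", name, perl = TRUE)
  }
  symbol <- ""
  sym_pat <- "\\(([A-Za-z][A-Za-z0-9]{1,5})\\)\\s*$"
  sm <- regexec(sym_pat, trimws(name))[[1]]
  if (sm[1] != -1) {
    symbol <- regmatches(trimws(name), regexec(sym_pat, trimws(name)))[[1]][2]
    name <- sub(sym_pat, "", trimws(name))
  }
  name <- trimws(gsub("[ \t]+", " ", name))
  list(name = name, gene_symbol = symbol, ec_numbers = ecs)
}

#' Default functional keyword to TIGR role table
#'
#' Longest-match-first keyword vocabulary used to backfill a high-level
#' role when no role has been assigned. Shipped as an editable fixture —
#' not a curated reconstruction of any production vocabulary; a TSV copy
#' lives in `inst/extdata/keyword_roles.tsv`.
#'
#' @return data.frame with `keyword`, `role_id`.
#' @export
default_keyword_roles <- function() {
  data.frame(
    keyword = c("abc transporter", "transporter", "permease",
                "transcriptional regulator", "regulator", "kinase",
                "phosphatase", "dehydrogenase", "reductase", "oxidase",
                "synthase", "synthetase", "ligase", "protease", "peptidase",
                "ribosomal protein", "polymerase", "helicase", "transposase",
                "integrase"),
    role_id = c(64L, 64L, 64L, 129L, 129L, 130L, 130L, 109L, 109L, 109L,
                131L, 131L, 131L, 138L, 138L, 133L, 132L, 132L, 154L, 154L),
    stringsAsFactors = FALSE
  )
}

#' Backfill a TIGR role from functional keywords
#'
#' Applied only when `current_roles` is empty or holds only the
#' unknown-function role; the first matching keyword in longest-match order
#' assigns its role.
#'
#' @param name Common name.
#' @param current_roles Integer vector of assigned roles.
#' @param keyword_table Keyword table ([default_keyword_roles()]).
#' @param roles TIGR role table ([default_tigr_roles()]).
#' @return Possibly updated integer vector of roles.
#' @export
keyword_role <- function(name, current_roles,
                         keyword_table = default_keyword_roles(),
                         roles = default_tigr_roles()) {
  eligible <- length(current_roles) == 0 ||
    all(current_roles %in% roles$unknown_function)
  if (!eligible) return(current_roles)
  kt <- keyword_table[order(-nchar(keyword_table$keyword),
                            keyword_table$keyword), , drop = FALSE]
  low <- tolower(name)
  for (i in seq_len(nrow(kt))) {
    if (grepl(paste0("\\b", kt$keyword[i], "\\b"), low, fixed = FALSE)) {
      return(kt$role_id[i])
    }
  }
  current_roles
}

#' Post-process an annotation table
#'
#' Runs [fix_name()], [extract_embedded()] and [keyword_role()] over every
#' row of a pFunc annotation table (see [pfunc_annotate()]). Embedded
#' assertions never overwrite an already-assigned symbol or EC list. The
#' whole stage is idempotent.
#'
#' @param annotations Annotation data.frame.
#' @param rules,keyword_table,roles Configuration tables.
#' @return The post-processed table.
#' @export
post_process <- function(annotations, rules = default_name_rules(),
                         keyword_table = default_keyword_roles(),
                         roles = default_tigr_roles()) {
  for (i in seq_len(nrow(annotations))) {
    emb <- extract_embedded(annotations$common_name[i])
    nm <- emb$name
    if (!nzchar(nm)) nm <- annotations$common_name[i]
    annotations$common_name[i] <- fix_name(nm, rules)
    if (!nzchar(annotations$gene_symbol[i]) && nzchar(emb$gene_symbol)) {
      annotations$gene_symbol[i] <- emb$gene_symbol
    }
    if (length(emb$ec_numbers)) {
      have <- split_field(annotations$ec_numbers[i])
      annotations$ec_numbers[i] <- join_field(
        unique(c(have, emb$ec_numbers)))
    }
    cur <- as.integer(split_field(annotations$tigr_roles[i]))
    annotations$tigr_roles[i] <- join_field(
      keyword_role(annotations$common_name[i], cur, keyword_table, roles))
  }
  annotations
}
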