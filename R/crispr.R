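#' Combine per-guide knockout scores under independence
#'
#' If guide i disrupts its target locus (frameshift or premature stop) with
#' probability `k_i` and the guides act independently, the probability that
#' a locus is disrupted by at least one guide is `1 - prod(1 - k_i)`. The
#' percent form is rounded half-up to an integer, the convention of printed
#' crispant efficacy tables.
#'
#' @param scores Numeric vector of per-guide knockout scores as fractions in
#'   `[0, 1]`; an empty vector combines to 0.
#' @return List with `combined` (fraction) and `percent` (integer).
#' @export
combine_knockout_scores <- function(scores) {
  if (length(scores) && (any(is.na(scores)) || any(scores < 0 | scores > 1)))
    stop("knockout scores must lie in [0, 1]")
  combined <- 1 - prod(1 - scores)
  list(combined = combined,
       percent = as.integer(round_half_up(100 * combined)))
}

#' Read a per-guide CRISPR outcome table
#'
#' Tab-separated table with columns `guide_id`, `target_gene`, optional
#' `crrna_sequence` (20 nt) and `pam` (3 nt), `pct_non_frameshift`,
#' `pct_frameshift` and `knockout_score_pct`. Validates the outcome
#' invariants: percentages in `[0, 100]`,
#' `pct_non_frameshift + pct_frameshift <= 100`, and
#' `knockout_score_pct >= pct_frameshift` (premature stops add to
#' frameshifts).
#'
#' @param path Path to the TSV file.
#' @return Validated data frame.
#' @export
read_guide_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  validate_guide_table(tab)
}

#' Validate a per-guide outcome table
#'
#' @param tab Data frame in the layout of [read_guide_table()].
#' @return The validated data frame, invisibly usable.
#' @export
validate_guide_table <- function(tab) {
  req <- c("guide_id", "target_gene", "pct_non_frameshift", "pct_frameshift",
           "knockout_score_pct")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("guide table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  pct <- c("pct_non_frameshift", "pct_frameshift", "knockout_score_pct")
  for (col in pct)
    if (any(tab[[col]] < 0 | tab[[col]] > 100))
      stop(col, " must lie in [0, 100]")
  if (any(tab$pct_non_frameshift + tab$pct_frameshift > 100 + 1e-9))
    stop("pct_non_frameshift + pct_frameshift exceeds 100 for guide ",
         tab$guide_id[which(tab$pct_non_frameshift + tab$pct_frameshift >
                              100 + 1e-9)[1]])
  if (any(tab$knockout_score_pct < tab$pct_frameshift - 1e-9))
    stop("knockout_score_pct below pct_frameshift for guide ",
         tab$guide_id[which(tab$knockout_score_pct <
                              tab$pct_frameshift - 1e-9)[1]])
  for (col in c("crrna_sequence", "pam")) {
    if (!col %in% names(tab)) next
    seqs <- tab[[col]][!is.na(tab[[col]]) & nzchar(tab[[col]])]
    if (length(seqs) && !all(grepl("^[ACGT]+$", seqs)))
      stop(col, " entries must match [ACGT]+")
  }
  if ("crrna_sequence" %in% names(tab)) {
    seqs <- tab$crrna_sequence[!is.na(tab$crrna_sequence) &
                                 nzchar(tab$crrna_sequence)]
    if (length(seqs) && !all(nchar(seqs) == 20))
      stop("crrna_sequence entries must be 20 nt")
  }
  if ("pam" %in% names(tab)) {
    seqs <- tab$pam[!is.na(tab$pam) & nzchar(tab$pam)]
    if (length(seqs) && !all(nchar(seqs) == 3))
      stop("pam entries must be 3 nt")
  }
  tab
}

#' Summarise per-gene combined knockout totals
#'
#' For each target gene, combines the per-guide knockout scores and,
#' separately, the per-guide frameshift percentages under independence.
#' Printed efficacy tables sometimes derive a quoted total from one column
#' and sometimes from the other; genes whose two rounded totals disagree
#' are flagged rather than reconciled.
#'
#' @param tab Validated guide table (see [read_guide_table()]); every gene
#'   must have at least one guide row.
#' @return Data frame with one row per gene: `target_gene`, `n_guides`,
#'   `combined_knockout_frac`, `knockout_pct`, `combined_frameshift_frac`,
#'   `frameshift_pct`, `totals_disagree`.
#' @export
summarize_guide_table <- function(tab) {
  validate_guide_table(tab)
  if (!nrow(tab)) stop("guide table has no rows")
  genes <- unique(tab$target_gene)
  rows <- lapply(genes, function(g) {
    sub <- tab[tab$target_gene == g, ]
    ko <- combine_knockout_scores(sub$knockout_score_pct / 100)
    fs <- combine_knockout_scores(sub$pct_frameshift / 100)
    data.frame(target_gene = g, n_guides = nrow(sub),
               combined_knockout_frac = ko$combined,
               knockout_pct = ko$percent,
               combined_frameshift_frac = fs$combined,
               frameshift_pct = fs$percent,
               totals_disagree = ko$percent != fs$percent,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
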