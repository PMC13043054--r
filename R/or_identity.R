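#' Tabulate odorant-receptor detections per cell
#'
#' Restricts the matrix to OR genes and categorises each cell by the number
#' of ORs detected (count >= 1): `none`, `single` (exactly one) or `multi`
#' (two or more). The top and second OR counts are recorded for the
#' predominant-OR rule.
#'
#' @param x A [count_matrix()] (QC-passed, immune cells removed).
#' @param annotation Gene annotation with OR flags and clades.
#' @return An `or_call_table` data frame with columns `barcode`,
#'   `n_or_detected`, `category`, `top_or`, `top_count`, `second_or`,
#'   `second_count`, `predominant_or` (`NA` until assigned) and `clade`.
#'   The OR count submatrix and clade map travel in attributes for
#'   downstream use.
#' @export
tabulate_or_calls <- function(x, annotation) {
  stopifnot(inherits(x, "count_matrix"))
  or_ids <- annotation$gene_id[annotation$is_or]
  or_ids <- intersect(x$gene_ids, or_ids)
  if (!length(or_ids)) stop("no OR genes present in the matrix")
  sub <- as.matrix(x$counts[match(or_ids, x$gene_ids), , drop = FALSE])
  n_det <- colSums(sub >= 1)
  category <- ifelse(n_det == 0, "none", ifelse(n_det == 1, "single", "multi"))
  top_i <- apply(sub, 2, which.max)
  top_count <- sub[cbind(top_i, seq_len(ncol(sub)))]
  second_count <- apply(sub, 2, function(v) sort(v, decreasing = TRUE)[2])
  second_or <- apply(sub, 2, function(v) {
    o <- order(v, decreasing = TRUE)
    if (length(v) > 1 && v[o[2]] >= 1) or_ids[o[2]] else NA_character_
  })
  tab <- data.frame(
    barcode = x$barcodes,
    n_or_detected = as.integer(n_det),
    category = category,
    top_or = ifelse(top_count >= 1, or_ids[top_i], NA_character_),
    top_count = as.numeric(top_count),
    second_or = second_or,
    second_count = as.numeric(ifelse(is.na(second_count), 0, second_count)),
    predominant_or = NA_character_,
    clade = NA_character_,
    stringsAsFactors = FALSE)
  attr(tab, "or_counts") <- sub
  attr(tab, "clade_map") <- setNames(
    annotation$clade[match(or_ids, annotation$gene_id)], or_ids)
  class(tab) <- c("or_call_table", "data.frame")
  tab
}

#' Assign each cell a predominant OR
#'
#' A cell is assigned an OR identity if it detects exactly one OR, or if its
#' most highly expressed OR has a raw count at least `dominance_ratio` times
#' that of the second most highly expressed OR (boundary inclusive). Cells
#' failing the rule remain unassigned and are dropped from clade-level
#' analysis. The comparison uses raw counts; the assigned clade is that of
#' the assigned OR.
#'
#' @param table An `or_call_table` from [tabulate_or_calls()].
#' @param dominance_ratio Positive dominance factor (default 5).
#' @return The table with `predominant_or` and `clade` filled in.
#' @export
assign_predominant_or <- function(table, dominance_ratio = 5) {
  stopifnot(inherits(table, "or_call_table"))
  if (!is.numeric(dominance_ratio) || dominance_ratio <= 0)
    stop("dominance_ratio must be positive")
  assigned <- table$category == "single" |
    (table$category == "multi" &
       table$top_count >= dominance_ratio * table$second_count)
  table$predominant_or <- ifelse(assigned, table$top_or, NA_character_)
  clade_map <- attr(table, "clade_map")
  table$clade <- ifelse(assigned, clade_map[table$top_or], NA_character_)
  table
}

# genomic ordering of OR genes: chromosome (lexicographic), then start
or_genomic_order <- function(annotation) {
  ors <- annotation[annotation$is_or, ]
  ors[order(ors$chromosome, ors$start_bp), ]
}

# midranks along rows of a dense matrix
row_midranks <- function(m) {
  t(apply(m, 1, rank, ties.method = "average"))
}

#' Spearman co-expression matrix over multi-OR cells
#'
#' Computes tie-corrected Spearman rank correlations for every pair of OR
#' genes across the cells that detect two or more ORs; zeros for undetected
#' ORs in those cells are retained. Genes are ordered genomically
#' (chromosome, then start coordinate). A pair's entry is missing when
#' either gene's counts are constant across the cells used, or when fewer
#' than `min_cells_nonzero` of those cells detect at least one member of the
#' pair.
#'
#' @param x A [count_matrix()] (QC-passed, immune cells removed).
#' @param annotation Gene annotation.
#' @param min_cells_nonzero Minimum number of multi-OR cells detecting at
#'   least one member of a pair for its correlation to be defined.
#' @return A `coexpression_result`: list with `or_ids` (genomic order),
#'   `rho` (symmetric matrix, `NA` where undefined), `n_cells_used`,
#'   `blocks` and `cross_subfamily_pairs` (both `NULL` until
#'   [detect_coexpression_blocks()] runs), plus the ordered OR annotation.
#' @export
spearman_coexpression_matrix <- function(x, annotation,
                                         min_cells_nonzero = 3L) {
  stopifnot(inherits(x, "count_matrix"))
  calls <- tabulate_or_calls(x, annotation)
  multi <- calls$barcode[calls$category == "multi"]
  if (length(multi) < 2)
    stop("insufficient data: fewer than 2 multi-OR cells")
  ors <- or_genomic_order(annotation)
  ors <- ors[ors$gene_id %in% x$gene_ids, ]
  sub <- as.matrix(x$counts[match(ors$gene_id, x$gene_ids),
                            match(multi, x$barcodes), drop = FALSE])
  n <- ncol(sub)
  r <- row_midranks(sub)
  rc <- r - rowMeans(r)
  denom <- sqrt(rowSums(rc^2))
  rho <- tcrossprod(rc) / outer(denom, denom)
  rho[denom == 0, ] <- NA
  rho[, denom == 0] <- NA
  nz <- (sub > 0) * 1
  both <- tcrossprod(nz)
  n_nz <- rowSums(nz)
  either <- outer(n_nz, n_nz, `+`) - both
  rho[either < min_cells_nonzero] <- NA
  diag(rho) <- 1
  dimnames(rho) <- list(ors$gene_id, ors$gene_id)
  structure(list(or_ids = ors$gene_id, rho = rho, n_cells_used = n,
                 blocks = NULL, cross_subfamily_pairs = NULL,
                 or_annotation = ors),
            class = "coexpression_result")
}

#' Detect genomically contiguous co-expression blocks
#'
#' Declares a pair of ORs co-expressed when its Spearman coefficient is at
#' least `rho_min` and its one-sided t-approximation p-value survives
#' Benjamini-Hochberg correction at `alpha` across all defined pairs.
#' Blocks are maximal runs of genomically consecutive same-subfamily ORs in
#' which every adjacent pair is co-expressed; significant pairs spanning
#' subfamilies are reported separately (such pairs never join blocks).
#'
#' @param result A `coexpression_result`.
#' @param rho_min Minimum correlation for a co-expression call, in (0,1).
#' @param alpha BH false-discovery level, in (0,1).
#' @return The result with `blocks` (data frame: `subfamily`, `members`
#'   comma-joined in genomic order, `n_genes`, `mean_rho` over all within-
#'   block pairs) and `cross_subfamily_pairs` (data frame: `or_i`, `or_j`,
#'   `rho`, `q`).
#' @export
detect_coexpression_blocks <- function(result, rho_min = 0.1, alpha = 0.05) {
  stopifnot(inherits(result, "coexpression_result"))
  if (rho_min <= 0 || rho_min >= 1) stop("rho_min must lie in (0,1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  rho <- result$rho
  n <- result$n_cells_used
  ids <- result$or_ids
  p <- npair <- NULL
  ut <- which(upper.tri(rho) & !is.na(rho), arr.ind = TRUE)
  r <- rho[ut]
  # one-sided (positive association) t approximation
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pvals <- pt(tstat, df = n - 2, lower.tail = FALSE)
  q <- bh_adjust(pmin(pmax(pvals, .Machine$double.xmin), 1))
  sig <- r >= rho_min & q <= alpha
  sig_mat <- matrix(FALSE, nrow(rho), ncol(rho), dimnames = dimnames(rho))
  sig_mat[ut[sig, , drop = FALSE]] <- TRUE
  sig_mat <- sig_mat | t(sig_mat)

  ann <- result$or_annotation
  sf <- ann$subfamily
  # blocks: scan runs of consecutive same-subfamily genes
  blocks <- list()
  i <- 1L
  while (i < length(ids)) {
    j <- i
    while (j < length(ids) && sf[j + 1] == sf[i] &&
           ann$chromosome[j + 1] == ann$chromosome[i] &&
           sig_mat[j, j + 1]) j <- j + 1L
    if (j > i) {
      members <- ids[i:j]
      pairs <- utils::combn(i:j, 2)
      blocks[[length(blocks) + 1L]] <- data.frame(
        subfamily = sf[i],
        members = paste(members, collapse = ","),
        n_genes = length(members),
        mean_rho = mean(rho[t(pairs)], na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
    i <- j + 1L
  }
  result$blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(subfamily = character(0), members = character(0),
               n_genes = integer(0), mean_rho = numeric(0))
  cross <- sig & sf[ut[, 1]] != sf[ut[, 2]]
  result$cross_subfamily_pairs <- data.frame(
    or_i = ids[ut[cross, 1]], or_j = ids[ut[cross, 2]],
    rho = r[cross], q = q[cross], stringsAsFactors = FALSE)
  result
}
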