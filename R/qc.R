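#' Quality-control thresholds
#'
#' The default thresholds follow the study design for larval OSN droplet
#' data: 800-7000 genes detected (both bounds inclusive), fewer than 50,000
#' total counts per cell (strict), and less than 10% of counts from
#' mitochondrial genes (strict). The stated gene range carries no
#' inclusivity in its source convention, so inclusivity is an explicit,
#' configurable choice here.
#'
#' @param min_genes,max_genes Inclusive bounds on genes detected per cell.
#' @param max_reads Exclusive upper bound on total counts per cell.
#' @param max_mito_fraction Exclusive upper bound on the mitochondrial count
#'   fraction.
#' @return A validated list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 800L, max_genes = 7000L,
                          max_reads = 50000L, max_mito_fraction = 0.10) {
  if (min_genes > max_genes) stop("min_genes must be <= max_genes")
  if (max_reads <= 0) stop("max_reads must be positive")
  if (max_mito_fraction <= 0 || max_mito_fraction > 1)
    stop("max_mito_fraction must lie in (0,1]")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_reads = max_reads,
                 max_mito_fraction = max_mito_fraction),
            class = "qc_thresholds")
}

#' Compute per-cell QC metrics
#'
#' For every cell: the number of genes with at least one count, the total
#' counts, and the fraction of counts belonging to genes flagged
#' mitochondrial in the annotation (0 for empty cells).
#'
#' @param x A [count_matrix()].
#' @param annotation Gene annotation covering every gene id in `x`.
#' @return Data frame with columns `barcode`, `genes_detected`,
#'   `total_counts`, `mito_fraction`.
#' @export
compute_cell_metrics <- function(x, annotation) {
  stopifnot(inherits(x, "count_matrix"))
  unknown <- setdiff(x$gene_ids, annotation$gene_id)
  if (length(unknown))
    stop("gene ids absent from annotation: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  m <- x$counts
  total <- Matrix::colSums(m)
  detected <- Matrix::colSums(m > 0)
  mito <- annotation$is_mito[match(x$gene_ids, annotation$gene_id)]
  mito_counts <- if (any(mito)) Matrix::colSums(m[mito, , drop = FALSE])
    else numeric(ncol(m))
  mito_fraction <- ifelse(total > 0, mito_counts / total, 0)
  data.frame(barcode = x$barcodes,
             genes_detected = as.integer(detected),
             total_counts = as.integer(total),
             mito_fraction = as.numeric(mito_fraction),
             stringsAsFactors = FALSE)
}

#' Filter cells on QC metrics
#'
#' A cell passes when `min_genes <= genes_detected <= max_genes`,
#' `total_counts < max_reads` and `mito_fraction < max_mito_fraction`.
#' Empty cells (zero counts) additionally fail with reason `empty`.
#'
#' @param records Output of [compute_cell_metrics()].
#' @param thresholds A [qc_thresholds()].
#' @return List with `passed` (barcodes of passing cells), `records` (the
#'   input with `passed` and `fail_reasons` columns; reasons are
#'   semicolon-joined), and `failure_counts` (named integer vector of
#'   per-reason failure counts).
#' @export
filter_cells <- function(records, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  reasons <- list(
    empty = records$total_counts == 0,
    min_genes = records$genes_detected < thresholds$min_genes,
    max_genes = records$genes_detected > thresholds$max_genes,
    max_reads = records$total_counts >= thresholds$max_reads,
    max_mito = records$mito_fraction >= thresholds$max_mito_fraction)
  fail_reasons <- apply(do.call(cbind, reasons), 1, function(r)
    paste(names(reasons)[r], collapse = ";"))
  records$passed <- fail_reasons == ""
  records$fail_reasons <- fail_reasons
  list(passed = records$barcode[records$passed],
       records = records,
       failure_counts = vapply(reasons, sum, 0L))
}

# counts-per-10k, log1p, per-gene z-score across cells
normalized_zscores <- function(m) {
  total <- Matrix::colSums(m)
  scale_f <- ifelse(total > 0, 1e4 / total, 0)
  norm <- log1p(sweep(as.matrix(m), 2, scale_f, `*`))
  mu <- rowMeans(norm)
  sd <- apply(norm, 1, stats::sd)
  z <- (norm - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Stage cells by maturity-marker programs and flag immune contaminants
#'
#' Scores each cell against the annotated maturity marker classes: a class
#' score is the mean, over that class's markers, of per-gene z-scored
#' log1p counts-per-10k. Transitional markers (axonal outgrowth program)
#' contribute to the early-mature score. The maturity stage is the argmax of
#' the three stage scores, with ties broken toward the less mature stage
#' (developmental ordering). A cell is flagged immune when its immune score
#' exceeds every stage score and at least one immune marker is detected;
#' immune cells carry no stage downstream.
#'
#' @param x A [count_matrix()] (QC-passed cells).
#' @param annotation Annotation assigning `marker_class` to at least one
#'   gene per stage and for the immune class.
#' @return Data frame with `barcode`, `stage`, the four class scores and
#'   `is_immune`.
#' @export
stage_and_flag_cells <- function(x, annotation) {
  stopifnot(inherits(x, "count_matrix"))
  ann <- annotation[match(x$gene_ids, annotation$gene_id), ]
  classes <- list(
    immature = which(ann$marker_class == "immature"),
    early_mature = which(ann$marker_class %in% c("early_mature",
                                                 "transitional")),
    mature = which(ann$marker_class == "mature"),
    immune = which(ann$marker_class == "immune"))
  empty <- names(classes)[vapply(classes, length, 0L) == 0]
  if (length(empty))
    stop("no annotated markers for class: ", paste(empty, collapse = ", "))
  z <- normalized_zscores(x$counts)
  scores <- vapply(classes, function(idx)
    colMeans(z[idx, , drop = FALSE]), numeric(ncol(x$counts)))
  scores <- matrix(scores, ncol = 4,
                   dimnames = list(NULL, names(classes)))
  stage_order <- c("immature", "early_mature", "mature")
  stage_scores <- scores[, stage_order, drop = FALSE]
  stage <- stage_order[apply(stage_scores, 1, which.max)]  # first max: tie
  # breaks toward the less mature stage by column order
  immune_detected <- Matrix::colSums(
    x$counts[classes$immune, , drop = FALSE] > 0) > 0
  is_immune <- scores[, "immune"] > apply(stage_scores, 1, max) &
    immune_detected
  data.frame(barcode = x$barcodes, stage = stage,
             score_immature = scores[, "immature"],
             score_early_mature = scores[, "early_mature"],
             score_mature = scores[, "mature"],
             score_immune = scores[, "immune"],
             is_immune = is_immune, stringsAsFactors = FALSE)
}

#' Subset a count matrix by barcodes and/or genes
#'
#' @param x A [count_matrix()].
#' @param barcodes,genes Optional character vectors to retain (order kept).
#' @return A [count_matrix()].
#' @export
subset_count_matrix <- function(x, barcodes = NULL, genes = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts
  gi <- x$gene_ids
  bc <- x$barcodes
  if (!is.null(genes)) {
    keep <- match(genes, gi)
    if (anyNA(keep)) stop("unknown gene ids in subset")
    m <- m[keep, , drop = FALSE]; gi <- gi[keep]
  }
  if (!is.null(barcodes)) {
    keep <- match(barcodes, bc)
    if (anyNA(keep)) stop("unknown barcodes in subset")
    m <- m[, keep, drop = FALSE]; bc <- bc[keep]
  }
  count_matrix(m, gi, bc)
}
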