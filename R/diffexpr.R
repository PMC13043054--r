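ALPHA_FLOOR <- 1e-8
LOG_EPS <- 1e-8

#' Fit the negative-binomial count model for differential expression
#'
#' Size factors are per-cell totals divided by the median total (median size
#' factor is therefore 1). Per-gene dispersions are method-of-moments
#' estimates on size-factor-normalized counts,
#' `alpha = max((s^2 - m) / m^2, alpha_floor)`, shrunk halfway (weight 0.5)
#' toward a mean-dispersion trend `alpha_trend(m) = a1/m + a0` fitted by
#' least squares over genes. Group means are size-factor-normalized
#' averages.
#'
#' @param counts Genes x cells matrix (dense or sparse) of raw counts, or a
#'   [count_matrix()].
#' @param groups Factor or character vector of group labels, one per cell.
#' @param min_cells_per_group Minimum group size (default 20).
#' @return A `de_model`: list with `size_factors`, `dispersions` (shrunk),
#'   `dispersions_mom` (raw method-of-moments), `group_means` (genes x
#'   groups), `group_sizes` and `gene_ids`.
#' @export
fit_de_model <- function(counts, groups, min_cells_per_group = 20L) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts))
    stop("groups length must equal the number of cells")
  sizes <- table(groups)
  if (length(sizes) < 2)
    stop("at least two groups are required")
  if (any(sizes < min_cells_per_group))
    stop("insufficient data: group(s) below ", min_cells_per_group,
         " cells: ", paste(names(sizes)[sizes < min_cells_per_group],
                           collapse = ", "))
  total <- colSums(counts)
  sf <- total / median(total)
  if (any(sf <= 0)) stop("cells with zero total counts cannot be modelled")
  norm <- sweep(counts, 2, sf, `/`)
  m <- rowMeans(norm)
  s2 <- apply(norm, 1, stats::var)
  alpha_mom <- ifelse(m > 0, pmax((s2 - m) / m^2, ALPHA_FLOOR), ALPHA_FLOOR)
  ok <- m > 0
  if (sum(ok) >= 2) {
    fit <- stats::lm.fit(cbind(1, 1 / m[ok]), alpha_mom[ok])
    a0 <- fit$coefficients[1]; a1 <- fit$coefficients[2]
    alpha_trend <- pmax(a1 / m + a0, ALPHA_FLOOR)
    alpha_trend[!ok] <- ALPHA_FLOOR
  } else {
    alpha_trend <- alpha_mom
  }
  alpha <- pmax(0.5 * alpha_mom + 0.5 * alpha_trend, ALPHA_FLOOR)
  gm <- vapply(levels(groups), function(g)
    rowMeans(norm[, groups == g, drop = FALSE]), numeric(nrow(norm)))
  gene_ids <- rownames(counts) %||% sprintf("gene%d", seq_len(nrow(counts)))
  structure(list(size_factors = sf, dispersions = alpha,
                 dispersions_mom = alpha_mom,
                 group_means = matrix(gm, ncol = nlevels(groups),
                                      dimnames = list(gene_ids,
                                                      levels(groups))),
                 group_sizes = setNames(as.integer(sizes), names(sizes)),
                 gene_ids = gene_ids),
            class = "de_model")
}

#' Negative-binomial Wald test between two groups
#'
#' The effect is `b = log((mu1 + eps) / (mu2 + eps))` with `eps = 1e-8`; its
#' delta-method standard error is
#' `SE^2 = sum_g (mu_g + alpha*mu_g^2) / (n_g * mu_g^2)` over the two
#' groups, `wald_z = b / SE`, `p` the two-sided normal tail, and
#' `log2fc = b / ln 2` (positive when the first-listed group is higher).
#' Genes with both group means zero are untestable (`p = 1`,
#' `log2fc = 0`).
#'
#' @param params A `de_model` from [fit_de_model()].
#' @param group1,group2 Group labels to contrast (log2fc > 0 means higher in
#'   `group1`).
#' @param genes Optional subset of gene ids (default all).
#' @return Data frame with `gene_id`, `comparison`, `log2fc`, `wald_z`,
#'   `p`, `higher_group` and `untestable`.
#' @export
nb_wald_test <- function(params, group1, group2, genes = NULL) {
  stopifnot(inherits(params, "de_model"))
  for (g in c(group1, group2))
    if (!g %in% colnames(params$group_means))
      stop("unknown group: ", g)
  idx <- if (is.null(genes)) seq_along(params$gene_ids)
    else match(genes, params$gene_ids)
  if (anyNA(idx)) stop("unknown gene id requested")
  mu1 <- params$group_means[idx, group1]
  mu2 <- params$group_means[idx, group2]
  a <- params$dispersions[idx]
  n1 <- params$group_sizes[[group1]]
  n2 <- params$group_sizes[[group2]]
  b <- log((mu1 + LOG_EPS) / (mu2 + LOG_EPS))
  term <- function(mu, n) {
    mu_f <- pmax(mu, LOG_EPS)
    (mu_f + a * mu_f^2) / (n * mu_f^2)
  }
  se <- sqrt(term(mu1, n1) + term(mu2, n2))
  z <- b / se
  p <- 2 * pnorm(-abs(z))
  untestable <- mu1 == 0 & mu2 == 0
  z[untestable] <- 0
  p[untestable] <- 1
  b[untestable] <- 0
  p <- pmax(p, .Machine$double.xmin)  # p in (0, 1]
  data.frame(gene_id = params$gene_ids[idx],
             comparison = paste0(group1, "v", group2),
             log2fc = b / log(2),
             wald_z = z,
             p = p,
             higher_group = ifelse(mu1 >= mu2, group1, group2),
             untestable = untestable,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1 and mapped back to
#' input order.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(rev(cummin(rev(m * p[o] / seq_len(m)))), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Run clade-versus-clade differential expression
#'
#' Convenience wrapper: maps assigned cells to their OR clade, fits one
#' model per comparison and applies the Wald test with per-comparison BH
#' correction. The combined comparison `ABvC` pools clades A and B against
#' C.
#'
#' @param x A [count_matrix()] (QC-passed, immune removed).
#' @param clades Named character vector (or factor) of clade labels
#'   (`A`/`B`/`C`) indexed by barcode; unassigned cells may be `NA` and are
#'   dropped.
#' @param comparisons Subset of `c("AvB", "AvC", "BvC", "ABvC")`.
#' @param min_cells_per_group Passed to [fit_de_model()].
#' @return Data frame of Wald results with a `q` column (BH within each
#'   comparison).
#' @export
clade_de <- function(x, clades, comparisons = c("AvB", "AvC", "BvC", "ABvC"),
                     min_cells_per_group = 20L) {
  stopifnot(inherits(x, "count_matrix"))
  comparisons <- match.arg(comparisons, several.ok = TRUE)
  clades <- clades[x$barcodes]
  keep <- !is.na(clades)
  counts <- as.matrix(x$counts[, keep, drop = FALSE])
  cl <- as.character(clades[keep])
  out <- list()
  for (cmp in comparisons) {
    if (cmp == "ABvC") {
      grp <- ifelse(cl %in% c("A", "B"), "AB", cl)
      pair <- c("AB", "C")
    } else {
      pair <- strsplit(cmp, "v")[[1]]
      grp <- cl
    }
    use <- grp %in% pair
    model <- fit_de_model(counts[, use, drop = FALSE], grp[use],
                          min_cells_per_group = min_cells_per_group)
    res <- nb_wald_test(model, pair[1], pair[2])
    res$comparison <- cmp
    res$q <- bh_adjust(res$p)
    out[[cmp]] <- res
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Curate membrane/secreted differential-expression candidates
#'
#' Filters results to genes significant at `q <= alpha` that carry a signal
#' peptide or a transmembrane domain (candidate guidance cues and
#' receptors), ranked by decreasing `-log10 q`, each labeled with the clade
#' in which it is higher. An alternative flag set (e.g. a DNA-binding flag
#' for transcription factors) may be supplied.
#'
#' @param results Data frame from [clade_de()] (must contain `q`).
#' @param annotation Gene annotation.
#' @param alpha Significance level on the BH q-value.
#' @param flags Annotation columns, any of which qualifies a gene.
#' @return Ranked candidate data frame with `gene_id`, `comparison`,
#'   `log2fc`, `q`, `neg_log10_q`, `higher_group`.
#' @export
build_candidate_table <- function(results, annotation, alpha = 0.05,
                                  flags = c("has_signal_peptide",
                                            "has_tm_domain")) {
  if (!nrow(results))
    return(data.frame(gene_id = character(0), comparison = character(0),
                      log2fc = numeric(0), q = numeric(0),
                      neg_log10_q = numeric(0),
                      higher_group = character(0)))
  if (!"q" %in% names(results)) stop("results must carry a q column")
  flag_hit <- Reduce(`|`, lapply(flags, function(f)
    annotation[[f]][match(results$gene_id, annotation$gene_id)]))
  keep <- !is.na(flag_hit) & flag_hit & results$q <= alpha
  out <- results[keep, c("gene_id", "comparison", "log2fc", "q",
                         "higher_group")]
  out$neg_log10_q <- -log10(out$q)
  out <- out[order(-out$neg_log10_q), ]
  rownames(out) <- NULL
  out[c("gene_id", "comparison", "log2fc", "q", "neg_log10_q",
        "higher_group")]
}
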