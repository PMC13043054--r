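#' Configure a synthetic OSN experiment
#'
#' Builds the configuration object for the synthetic-data generator. The
#' generator emulates the structure the downstream analysis assumes: OR genes
#' laid out in chromosomal subfamily clusters assigned to homology clades A,
#' B and C; each maturing cell dominated by one OR, with transient
#' co-expression confined to genomically adjacent genes of the same
#' subfamily (an "enhancer hub"); maturity-stage marker programs plus an
#' immune contaminant population; clade-linked differentially expressed
#' genes with stated log2 fold-changes; and negative-binomial counts with
#' per-cell sequencing-depth and mitochondrial-fraction variation.
#'
#' @param seed Master integer seed. Sub-stage streams are derived by fixed
#'   offsets so that identical configurations give identical output.
#' @param n_cells_per_stage Named integer vector over
#'   `immature`/`early_mature`/`mature`; the relative values set the stage
#'   composition and the sum sets the number of cells.
#' @param n_subfamilies,genes_per_subfamily Size of the OR repertoire; each
#'   subfamily is a run of consecutive genes on one chromosome.
#' @param clade_of_subfamily Character vector mapping each subfamily to a
#'   clade (`"A"`, `"B"` or `"C"`); default cycles A, B, C.
#' @param hub_span Number of genomically adjacent same-subfamily ORs
#'   co-activated by one enhancer hub (each subfamily is partitioned into
#'   consecutive windows of this size).
#' @param secondary_or_expression_ratio Mean expression of co-activated
#'   secondary ORs relative to the dominant OR, in (0,1). The value is a free
#'   parameter of the generator, not an empirical estimate.
#' @param multi_or_cell_fraction Fraction of non-immune cells that co-express
#'   their full hub rather than the dominant OR alone.
#' @param n_background_genes Number of non-OR, non-marker genes.
#' @param clade_de_genes Data frame with columns `gene`, `higher_clade`,
#'   `log2fc` describing planted clade-linked differential expression;
#'   default plants four protocadherin-like membrane genes and two guidance
#'   receptors at log2 fold-change 1.5.
#' @param nb_dispersion Negative-binomial dispersion alpha in the variance
#'   function `mu + alpha * mu^2`.
#' @param mean_depth Mean total counts per cell; per-cell depth is lognormal
#'   around this with sdlog 0.3.
#' @param mito_fraction_mean Mean per-cell mitochondrial count fraction;
#'   per-cell fractions are Beta-distributed (concentration 30) so that some
#'   cells deliberately fail the mitochondrial QC rule.
#' @param immune_cell_fraction Probability that a cell is an immune
#'   contaminant (no OR, immune marker program).
#' @param leak_pair Either `TRUE` (auto-select the first gene of the first
#'   two subfamilies), `FALSE` (none), or a length-2 character vector of OR
#'   gene ids: a declared cross-subfamily co-expression "leak" pair used as a
#'   negative control for block detection.
#' @param dominant_or_share Relative transcriptome share of the dominant OR.
#' @param marker_boost Fold elevation of a stage's markers in cells of that
#'   stage.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cells_per_stage = c(immature = 260L,
                                             early_mature = 470L,
                                             mature = 270L),
                       n_subfamilies = 20L,
                       genes_per_subfamily = 4L,
                       clade_of_subfamily = NULL,
                       hub_span = 3L,
                       secondary_or_expression_ratio = 0.3,
                       multi_or_cell_fraction = 0.4,
                       n_background_genes = 1500L,
                       clade_de_genes = default_clade_de_genes(),
                       nb_dispersion = 0.3,
                       mean_depth = 8000,
                       mito_fraction_mean = 0.05,
                       immune_cell_fraction = 0.05,
                       leak_pair = TRUE,
                       dominant_or_share = 0.01,
                       marker_boost = 8) {
  if (is.null(clade_of_subfamily))
    clade_of_subfamily <- rep(c("A", "B", "C"), length.out = n_subfamilies)
  stages <- c("immature", "early_mature", "mature")
  if (!all(stages %in% names(n_cells_per_stage)))
    stop("n_cells_per_stage must name immature, early_mature and mature")
  if (length(clade_of_subfamily) != n_subfamilies)
    stop("clade_of_subfamily must map every one of the ", n_subfamilies,
         " subfamilies")
  if (!all(clade_of_subfamily %in% c("A", "B", "C")))
    stop("clades must be A, B or C")
  if (hub_span < 1 || hub_span > genes_per_subfamily)
    stop("hub_span must lie in [1, genes_per_subfamily]")
  if (secondary_or_expression_ratio <= 0 || secondary_or_expression_ratio >= 1)
    stop("secondary_or_expression_ratio must lie in (0,1)")
  for (f in c("multi_or_cell_fraction", "mito_fraction_mean"))
    if (get(f) < 0 || get(f) > 1) stop(f, " must lie in [0,1]")
  if (immune_cell_fraction < 0 || immune_cell_fraction >= 1)
    stop("immune_cell_fraction must lie in [0,1)")
  if (nb_dispersion <= 0 || mean_depth <= 0)
    stop("nb_dispersion and mean_depth must be positive")
  structure(list(
    seed = as.integer(seed),
    n_cells_per_stage = n_cells_per_stage[stages],
    n_subfamilies = as.integer(n_subfamilies),
    genes_per_subfamily = as.integer(genes_per_subfamily),
    clade_of_subfamily = clade_of_subfamily,
    hub_span = as.integer(hub_span),
    secondary_or_expression_ratio = secondary_or_expression_ratio,
    multi_or_cell_fraction = multi_or_cell_fraction,
    n_background_genes = as.integer(n_background_genes),
    clade_de_genes = clade_de_genes,
    nb_dispersion = nb_dispersion,
    mean_depth = mean_depth,
    mito_fraction_mean = mito_fraction_mean,
    immune_cell_fraction = immune_cell_fraction,
    leak_pair = leak_pair,
    dominant_or_share = dominant_or_share,
    marker_boost = marker_boost), class = "sim_config")
}

#' Default planted clade-linked differential expression
#'
#' Four membrane (transmembrane-domain) protocadherin-like genes and two
#' guidance receptors, planted at log2 fold-change 1.5 in their higher
#' clade: two higher in clade C cells, two higher in clade A, one each for
#' the remaining guidance receptors.
#'
#' @return Data frame with columns `gene`, `higher_clade`, `log2fc`.
#' @export
default_clade_de_genes <- function() {
  data.frame(
    gene = c("pcdh7b", "pcdh11", "pcdh10b", "pcdh17", "robo2", "nrp1a"),
    higher_clade = c("C", "C", "A", "A", "C", "A"),
    log2fc = rep(1.5, 6),
    stringsAsFactors = FALSE)
}

marker_panel <- function() {
  data.frame(
    gene = c("neurod1", "ascl1a", "gap43", "gng8", "ompb", "vamp2",
             "malb", "krt4", "cfl1l", "cldne", "tnfb", "cxcr3.3", "CD83"),
    marker_class = c("immature", "immature", "transitional", "early_mature",
                     "early_mature", "early_mature", "mature", "mature",
                     "mature", "mature", "immune", "immune", "immune"),
    stringsAsFactors = FALSE)
}

#' Simulate an OR repertoire and gene annotation
#'
#' Lays OR genes out in subfamily blocks of consecutive coordinates on a
#' small set of chromosomes, assigns clades from the configuration,
#' interleaves background genes, designates maturity/immune marker genes and
#' mitochondrial genes, and gives the planted differentially expressed genes
#' membrane annotations (transmembrane-domain flag).
#'
#' @param config A [sim_config()].
#' @return A validated gene annotation data frame.
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  n_sf <- config$n_subfamilies
  gps <- config$genes_per_subfamily
  or_chroms <- c("chr6", "chr10", "chr14", "chr15", "chr21")
  sf_chrom <- or_chroms[((seq_len(n_sf) - 1L) %% length(or_chroms)) + 1L]
  sf_slot <- ave(seq_len(n_sf), sf_chrom, FUN = seq_along)
  rows <- list()
  for (sf in seq_len(n_sf)) {
    sf_name <- sprintf("or%03d", 100L + sf)
    start0 <- 1000000L * sf_slot[sf]
    starts <- start0 + (seq_len(gps) - 1L) * 2000L
    rows[[sf]] <- data.frame(
      gene_id = sprintf("%s-%d", sf_name, seq_len(gps)),
      symbol = sprintf("%s-%d", sf_name, seq_len(gps)),
      chromosome = sf_chrom[sf],
      start_bp = starts,
      end_bp = starts + 999L,
      is_or = TRUE,
      clade = config$clade_of_subfamily[sf],
      subfamily = sf_name,
      is_mito = FALSE,
      has_signal_peptide = FALSE,
      has_tm_domain = TRUE,
      marker_class = "none",
      stringsAsFactors = FALSE)
  }
  or_ann <- do.call(rbind, rows)

  mk <- marker_panel()
  marker_ann <- data.frame(
    gene_id = mk$gene, symbol = mk$gene, chromosome = "chr2",
    start_bp = 100000L + (seq_len(nrow(mk)) - 1L) * 5000L,
    end_bp = 100000L + (seq_len(nrow(mk)) - 1L) * 5000L + 999L,
    is_or = FALSE, clade = "none", subfamily = NA_character_,
    is_mito = FALSE, has_signal_peptide = FALSE, has_tm_domain = FALSE,
    marker_class = mk$marker_class, stringsAsFactors = FALSE)

  mito_genes <- c("mt-nd1", "mt-nd2", "mt-co1", "mt-co2", "mt-cytb")
  mito_ann <- data.frame(
    gene_id = mito_genes, symbol = mito_genes, chromosome = "chrM",
    start_bp = 1L + (seq_along(mito_genes) - 1L) * 2000L,
    end_bp = (seq_along(mito_genes)) * 2000L - 1L,
    is_or = FALSE, clade = "none", subfamily = NA_character_,
    is_mito = TRUE, has_signal_peptide = FALSE, has_tm_domain = FALSE,
    marker_class = "none", stringsAsFactors = FALSE)

  de <- config$clade_de_genes
  de_ann <- if (nrow(de)) data.frame(
    gene_id = de$gene, symbol = de$gene, chromosome = "chr3",
    start_bp = 200000L + (seq_len(nrow(de)) - 1L) * 10000L,
    end_bp = 200000L + (seq_len(nrow(de)) - 1L) * 10000L + 999L,
    is_or = FALSE, clade = "none", subfamily = NA_character_,
    is_mito = FALSE, has_signal_peptide = FALSE, has_tm_domain = TRUE,
    marker_class = "none", stringsAsFactors = FALSE)

  nbg <- config$n_background_genes
  bg_chrom <- sprintf("chr%d", ((seq_len(nbg) - 1L) %% 5L) + 16L)
  bg_slot <- ave(seq_len(nbg), bg_chrom, FUN = seq_along)
  bg_ann <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(nbg)),
    symbol = sprintf("gene%04d", seq_len(nbg)),
    chromosome = bg_chrom,
    start_bp = 1L + (bg_slot - 1L) * 3000L,
    end_bp = bg_slot * 3000L - 1L,
    is_or = FALSE, clade = "none", subfamily = NA_character_,
    is_mito = FALSE,
    has_signal_peptide = runif(nbg) < 0.10,
    has_tm_domain = runif(nbg) < 0.15,
    marker_class = "none", stringsAsFactors = FALSE)

  ann <- rbind(or_ann, marker_ann, mito_ann, de_ann, bg_ann)
  rownames(ann) <- NULL
  validate_gene_annotation(ann)
  ann
}

# resolve the configured leak pair to two OR gene ids (or NULL)
resolve_leak_pair <- function(config, annotation) {
  lp <- config$leak_pair
  ors <- annotation[annotation$is_or, ]
  if (isFALSE(lp)) return(NULL)
  if (isTRUE(lp)) {
    sfs <- unique(ors$subfamily)
    if (length(sfs) < 2) return(NULL)
    return(c(ors$gene_id[ors$subfamily == sfs[1]][1],
             ors$gene_id[ors$subfamily == sfs[2]][1]))
  }
  if (!all(lp %in% ors$gene_id))
    stop("leak_pair genes not found among OR genes")
  sf <- ors$subfamily[match(lp, ors$gene_id)]
  if (sf[1] == sf[2]) stop("leak_pair must span two subfamilies")
  lp
}

# partition each subfamily into consecutive hubs of size hub_span;
# returns data.frame(gene_id, subfamily, rank_in_subfamily, hub)
hub_partition <- function(config, annotation) {
  ors <- annotation[annotation$is_or, ]
  ord <- order(ors$chromosome, ors$start_bp)
  ors <- ors[ord, ]
  rank_in_sf <- ave(seq_len(nrow(ors)), ors$subfamily, FUN = seq_along)
  data.frame(gene_id = ors$gene_id, subfamily = ors$subfamily,
             rank_in_subfamily = rank_in_sf,
             hub = paste0(ors$subfamily, ".h",
                          ceiling(rank_in_sf / config$hub_span)),
             stringsAsFactors = FALSE)
}

#' Simulate an OSN count matrix with ground truth
#'
#' Each non-immune cell draws one dominant OR uniformly from the repertoire;
#' with probability `multi_or_cell_fraction` it co-expresses the remaining
#' members of that OR's enhancer hub (adjacent same-subfamily genes) at
#' `secondary_or_expression_ratio` of the dominant mean. Cells dominated by a
#' declared leak-pair member additionally co-express the partner across
#' subfamilies. Stage marker programs are elevated in cells of the matching
#' stage, planted differentially expressed genes are shifted by their log2
#' fold-change in cells of the higher clade, immune cells express immune
#' markers and no OR, and counts are negative binomial with variance
#' `mu + alpha * mu^2` around per-cell depth and mitochondrial-fraction
#' draws.
#'
#' @param config A [sim_config()].
#' @param annotation Annotation from [simulate_repertoire()] (regenerated
#'   from `config` when omitted).
#' @return A list with elements `matrix` (a [count_matrix()]), `truth` (data
#'   frame with `barcode`, `stage`, `dominant_or`, `clade`, `is_multi` and a
#'   list-column `secondary_ors`), and `hubs` (the planted hub partition
#'   with one row per OR gene).
#' @export
simulate_osn_counts <- function(config, annotation = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(annotation)) annotation <- simulate_repertoire(config)
  hubs <- hub_partition(config, annotation)
  leak <- resolve_leak_pair(config, annotation)

  n <- sum(config$n_cells_per_stage)
  barcodes <- sprintf("cell-%05d", seq_len(n))
  stages <- names(config$n_cells_per_stage)

  set.seed(config$seed + 202L)  # cell-identity stream
  is_immune <- runif(n) < config$immune_cell_fraction
  stage <- rep(NA_character_, n)
  stage[!is_immune] <- sample(stages, sum(!is_immune), replace = TRUE,
                              prob = config$n_cells_per_stage)
  stage[is_immune] <- "immune"
  or_ids <- hubs$gene_id
  dominant <- rep(NA_character_, n)
  dominant[!is_immune] <- sample(or_ids, sum(!is_immune), replace = TRUE)
  is_multi <- !is_immune & runif(n) < config$multi_or_cell_fraction
  secondary <- vector("list", n)
  for (i in which(is_multi)) {
    members <- hubs$gene_id[hubs$hub == hubs$hub[hubs$gene_id == dominant[i]]]
    sec <- setdiff(members, dominant[i])
    if (!is.null(leak) && dominant[i] %in% leak)
      sec <- union(sec, setdiff(leak, dominant[i]))
    secondary[[i]] <- sec
  }
  secondary[!is_multi] <- list(character(0))
  clade <- rep("none", n)
  clade[!is_immune] <- annotation$clade[match(dominant[!is_immune],
                                              annotation$gene_id)]

  set.seed(config$seed + 303L)  # expression stream
  g <- nrow(annotation)
  gene_id <- annotation$gene_id
  base_weight <- numeric(g)
  bg <- !annotation$is_or & !annotation$is_mito
  base_weight[bg] <- rlnorm(sum(bg), meanlog = 0, sdlog = 1)
  # markers keep a low constitutive level so z-scores are informative
  mk_rows <- annotation$marker_class != "none"
  base_weight[mk_rows] <- 0.5
  immune_rows <- annotation$marker_class == "immune"
  base_weight[immune_rows] <- 0.02

  depth <- rlnorm(n, meanlog = log(config$mean_depth) - 0.3^2 / 2, sdlog = 0.3)
  mfm <- config$mito_fraction_mean
  mito_frac <- if (mfm > 0)
    rbeta(n, shape1 = mfm * 30, shape2 = (1 - mfm) * 30) else numeric(n)
  mito_rows <- which(annotation$is_mito)
  mito_w <- rlnorm(length(mito_rows), 0, 0.5)
  mito_w <- mito_w / sum(mito_w)

  de <- config$clade_de_genes
  de_idx <- match(de$gene, gene_id)
  if (nrow(de) && anyNA(de_idx))
    stop("clade_de_genes name genes absent from the annotation")

  class_of <- annotation$marker_class
  stage_of_class <- c(immature = "immature", transitional = "early_mature",
                      early_mature = "early_mature", mature = "mature",
                      immune = "immune")
  dominant_w <- config$dominant_or_share *
    sum(base_weight[bg]) / max(1, 1 - config$dominant_or_share)

  mu <- matrix(0, nrow = g, ncol = n)
  for (i in seq_len(n)) {
    w <- base_weight
    boosted <- class_of != "none" &
      stage_of_class[class_of] == stage[i]
    w[boosted] <- w[boosted] * config$marker_boost
    if (is_immune[i]) w[immune_rows] <- 5
    if (!is_immune[i]) {
      w[match(dominant[i], gene_id)] <- dominant_w
      if (length(secondary[[i]]))
        w[match(secondary[[i]], gene_id)] <-
          dominant_w * config$secondary_or_expression_ratio
      if (nrow(de)) {
        hit <- de$higher_clade == clade[i]
        w[de_idx[hit]] <- w[de_idx[hit]] * 2^de$log2fc[hit]
      }
    }
    w[mito_rows] <- 0
    mu_i <- depth[i] * (1 - mito_frac[i]) * w / sum(w)
    mu_i[mito_rows] <- depth[i] * mito_frac[i] * mito_w
    mu[, i] <- mu_i
  }
  counts <- matrix(rnbinom(g * n, mu = as.vector(mu),
                           size = 1 / config$nb_dispersion),
                   nrow = g, ncol = n)
  truth <- data.frame(barcode = barcodes, stage = stage,
                      dominant_or = dominant, clade = clade,
                      is_multi = is_multi, stringsAsFactors = FALSE)
  truth$secondary_ors <- I(secondary)
  list(matrix = count_matrix(counts, gene_id, barcodes),
       truth = truth, hubs = hubs)
}

#' Simulate a two-group negative-binomial count matrix
#'
#' Direct group-level simulator used for calibration and power studies of
#' the differential-expression test: genes have lognormal base means, group
#' 1 means are shifted by per-gene log2 fold-changes, and counts are
#' negative binomial with variance `mu + dispersion * mu^2` after scaling by
#' lognormal per-cell depth factors (sdlog 0.2).
#'
#' @param n_genes Number of genes.
#' @param n_per_group Cells in each of the two groups.
#' @param dispersion NB dispersion alpha.
#' @param log2fc Per-gene log2 fold-change of group 1 over group 2 (recycled;
#'   default 0, a global null).
#' @param base_means Optional per-gene base means; default lognormal with
#'   meanlog `log(5)`, sdlog 1.
#' @param depth_sdlog sdlog of the per-cell depth factors (0 gives constant
#'   per-group gene means).
#' @param seed Integer seed.
#' @return List with `counts` (genes x cells integer matrix with dimnames),
#'   `groups` (factor `g1`/`g2` per cell), `log2fc` and `base_means`.
#' @export
simulate_de_matrix <- function(n_genes, n_per_group, dispersion,
                               log2fc = 0, base_means = NULL,
                               depth_sdlog = 0.2, seed = 1L) {
  set.seed(seed)
  if (is.null(base_means))
    base_means <- rlnorm(n_genes, meanlog = log(5), sdlog = 1)
  log2fc <- rep_len(log2fc, n_genes)
  n <- 2L * n_per_group
  groups <- factor(rep(c("g1", "g2"), each = n_per_group))
  depth_factor <- rlnorm(n, meanlog = -depth_sdlog^2 / 2, sdlog = depth_sdlog)
  mu <- cbind(matrix(base_means * 2^log2fc, n_genes, n_per_group),
              matrix(base_means, n_genes, n_per_group))
  mu <- sweep(mu, 2, depth_factor, `*`)
  counts <- matrix(rnbinom(n_genes * n, mu = as.vector(mu),
                           size = 1 / dispersion),
                   nrow = n_genes, ncol = n,
                   dimnames = list(sprintf("gene%05d", seq_len(n_genes)),
                                   sprintf("cell-%05d", seq_len(n))))
  list(counts = counts, groups = groups, log2fc = log2fc,
       base_means = base_means)
}

#' Simulate per-guide CRISPR editing outcomes
#'
#' Turns per-guide true editing fractions into a guide-outcome table in the
#' layout of a crispant efficacy summary (percent non-frameshift, percent
#' frameshift, knockout score), retaining the per-gene combined knockout
#' truth under independence for recovery tests. The transformation is
#' deterministic: the table reports the truth fractions on the percent
#' scale.
#'
#' @param truth Data frame with columns `target_gene`, `non_frameshift_frac`,
#'   `frameshift_frac` and `knockout_frac` (per-guide fractions in `[0,1]`,
#'   with `knockout_frac >= frameshift_frac` because premature stops add to
#'   frameshifts) and optionally `guide_id`.
#' @return A guide-outcome data frame with percent columns; attribute
#'   `truth` holds the per-gene combined knockout fractions.
#' @export
simulate_guide_outcomes <- function(truth) {
  req <- c("target_gene", "non_frameshift_frac", "frameshift_frac",
           "knockout_frac")
  if (!all(req %in% names(truth)))
    stop("truth must have columns ", paste(req, collapse = ", "))
  fr <- truth[c("non_frameshift_frac", "frameshift_frac", "knockout_frac")]
  if (any(unlist(fr) < 0 | unlist(fr) > 1))
    stop("editing fractions must lie in [0,1]")
  if (any(truth$knockout_frac < truth$frameshift_frac - 1e-9))
    stop("knockout_frac must be >= frameshift_frac")
  if (any(truth$non_frameshift_frac + truth$frameshift_frac > 1 + 1e-9))
    stop("non_frameshift_frac + frameshift_frac must be <= 1")
  guide_id <- truth$guide_id %||%
    paste0(truth$target_gene, "_g",
           ave(seq_len(nrow(truth)), truth$target_gene, FUN = seq_along))
  out <- data.frame(guide_id = guide_id,
                    target_gene = truth$target_gene,
                    pct_non_frameshift = 100 * truth$non_frameshift_frac,
                    pct_frameshift = 100 * truth$frameshift_frac,
                    knockout_score_pct = 100 * truth$knockout_frac,
                    stringsAsFactors = FALSE)
  combined <- vapply(split(truth$knockout_frac, truth$target_gene),
                     function(k) 1 - prod(1 - k), 0)
  attr(out, "truth") <- combined
  out
}

#' Simulate a blinded axon-targeting experiment
#'
#' Draws control and knockdown targeting tables: each scored axon terminates
#' correctly or makes an error in one of six anatomical directions, with the
#' per-direction error probabilities given per arm (a multinomial draw, so
#' the direction probabilities must sum to at most 1). Truth probabilities
#' are retained.
#'
#' @param n_control,n_knockdown Axons scored per arm.
#' @param p_error_control,p_error_knockdown Named numeric vectors of
#'   per-direction error probabilities (names among `dorsal`, `ventral`,
#'   `anterior`, `posterior`, `medial`, `lateral`).
#' @param line Reporter-line label shared by both tables.
#' @param seed Integer seed.
#' @return List with `control` and `knockdown` [targeting_table()] objects
#'   and a `truth` list of the input probabilities.
#' @export
simulate_targeting_experiment <- function(n_control, n_knockdown,
                                          p_error_control,
                                          p_error_knockdown,
                                          line = "BAC:OR130-1", seed = 1L) {
  directions <- c("dorsal", "ventral", "anterior", "posterior", "medial",
                  "lateral")
  expand_p <- function(p) {
    if (is.null(names(p)) || !all(names(p) %in% directions))
      stop("error probabilities must be named with anatomical directions")
    full <- setNames(numeric(length(directions)), directions)
    full[names(p)] <- p
    if (any(full < 0) || sum(full) > 1)
      stop("direction error probabilities must be nonnegative and sum to <= 1")
    full
  }
  pc <- expand_p(p_error_control)
  pk <- expand_p(p_error_knockdown)
  set.seed(seed)
  draw <- function(n, p) {
    counts <- as.vector(stats::rmultinom(1, n, c(1 - sum(p), p)))
    list(correct = counts[1], errors = setNames(counts[-1], directions))
  }
  dc <- draw(n_control, pc)
  dk <- draw(n_knockdown, pk)
  list(control = targeting_table("uninjected", line, n_control, dc$correct,
                                 dc$errors),
       knockdown = targeting_table("knockdown", line, n_knockdown,
                                   dk$correct, dk$errors),
       truth = list(p_error_control = pc, p_error_knockdown = pk))
}
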