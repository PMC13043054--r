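qc_ann <- rbind(ann_row("geneA"), ann_row("mitoB", is_mito = TRUE))

test_that("per-cell metrics follow their definitions", {
  m <- matrix(c(2, 1, 0, 0), nrow = 2,
              dimnames = list(c("geneA", "mitoB"), NULL))
  cm <- count_matrix(m, c("geneA", "mitoB"), c("bc1", "bc2"))
  met <- compute_cell_metrics(cm, qc_ann)
  expect_equal(met$genes_detected, c(2L, 0L))
  expect_equal(met$total_counts, c(3L, 0L))
  expect_equal(met$mito_fraction, c(1 / 3, 0))
  flt <- filter_cells(met, qc_thresholds(min_genes = 1, max_genes = 10,
                                         max_reads = 100,
                                         max_mito_fraction = 0.5))
  expect_match(flt$records$fail_reasons[2], "empty")
  expect_error(compute_cell_metrics(cm, qc_ann[1, , drop = FALSE]),
               "absent")
})

test_that("metrics agree with a naive per-cell recomputation", {
  set.seed(4)
  m <- matrix(rpois(100 * 50, 1), nrow = 100)
  ids <- sprintf("g%03d", 1:100)
  ann <- do.call(rbind, lapply(seq_along(ids), function(i)
    ann_row(ids[i], is_mito = i <= 7)))
  cm <- count_matrix(m, ids, sprintf("bc%02d", 1:50))
  met <- compute_cell_metrics(cm, ann)
  for (j in seq_len(50)) {
    col <- m[, j]
    expect_equal(met$total_counts[j], sum(col))
    expect_equal(met$genes_detected[j], sum(col >= 1))
    expect_equal(met$mito_fraction[j],
                 if (sum(col) > 0) sum(col[1:7]) / sum(col) else 0)
  }
})

test_that("the QC rule is inclusive on gene bounds and strict elsewhere", {
  rec <- data.frame(
    barcode = sprintf("c%d", 1:7),
    genes_detected = c(800L, 799L, 7000L, 7001L, 1000L, 1000L, 1000L),
    total_counts = c(49999L, 10000L, 10000L, 10000L, 50000L, 10000L,
                     10000L),
    mito_fraction = c(0.099, 0.01, 0.01, 0.01, 0.01, 0.1, 0.0999),
    stringsAsFactors = FALSE)
  flt <- filter_cells(rec, qc_thresholds())
  expect_equal(flt$records$passed,
               c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(flt$records$fail_reasons[2], "min_genes")
  expect_equal(flt$records$fail_reasons[4], "max_genes")
  expect_equal(flt$records$fail_reasons[5], "max_reads")
  expect_equal(flt$records$fail_reasons[6], "max_mito")
  expect_equal(unname(flt$failure_counts["max_mito"]), 1L)
})

test_that("relaxing any threshold never shrinks the passed set", {
  set.seed(11)
  rec <- data.frame(
    barcode = sprintf("c%03d", 1:300),
    genes_detected = sample(0:9000, 300, replace = TRUE),
    total_counts = sample(0:60000, 300, replace = TRUE),
    mito_fraction = runif(300, 0, 0.3), stringsAsFactors = FALSE)
  base <- filter_cells(rec, qc_thresholds())$passed
  relaxed <- list(
    qc_thresholds(min_genes = 400),
    qc_thresholds(max_genes = 8000),
    qc_thresholds(max_reads = 80000),
    qc_thresholds(max_mito_fraction = 0.2))
  for (th in relaxed)
    expect_true(all(base %in% filter_cells(rec, th)$passed))
})

test_that("the passed set equals brute-force rule application on simulation", {
  cfg <- small_sim_config(seed = 17)
  sim <- simulate_osn_counts(cfg)
  ann <- simulate_repertoire(cfg)
  met <- compute_cell_metrics(sim$matrix, ann)
  th <- qc_thresholds(min_genes = 50, max_genes = 5000, max_reads = 6000,
                      max_mito_fraction = 0.10)
  got <- filter_cells(met, th)$passed
  m <- as.matrix(sim$matrix$counts)
  mito <- ann$is_mito[match(sim$matrix$gene_ids, ann$gene_id)]
  expected <- character(0)
  for (j in seq_len(ncol(m))) {
    gd <- sum(m[, j] >= 1); tot <- sum(m[, j])
    mf <- if (tot > 0) sum(m[mito, j]) / tot else 0
    if (gd >= th$min_genes && gd <= th$max_genes && tot < th$max_reads &&
        mf < th$max_mito_fraction && tot > 0)
      expected <- c(expected, sim$matrix$barcodes[j])
  }
  expect_identical(got, expected)
})

test_that("marker programs drive staging and immune flagging", {
  markers <- c("neurod1", "ascl1a", "gap43", "gng8", "ompb", "vamp2",
               "malb", "krt4", "tnfb", "cxcr3.3", "CD83", "filler")
  classes <- c("immature", "immature", "transitional", "early_mature",
               "early_mature", "early_mature", "mature", "mature",
               "immune", "immune", "immune", "none")
  ann <- do.call(rbind, lapply(seq_along(markers), function(i)
    ann_row(markers[i], marker_class = classes[i])))
  m <- matrix(0, length(markers), 4,
              dimnames = list(markers, NULL))
  m["filler", ] <- 5  # shared constitutive gene
  m[c("neurod1", "ascl1a"), 1] <- 10
  m[c("gng8", "ompb", "vamp2"), 2] <- 10
  m[c("malb", "krt4"), 3] <- 10
  m[c("tnfb", "cxcr3.3", "CD83"), 4] <- 10
  cm <- count_matrix(m, markers, sprintf("bc%d", 1:4))
  st <- stage_and_flag_cells(cm, ann)
  expect_equal(st$stage[1], "immature")
  expect_equal(st$stage[2], "early_mature")
  expect_equal(st$stage[3], "mature")
  expect_true(st$is_immune[4])
  expect_false(any(st$is_immune[1:3]))

  # transitional markers count toward the early-mature score
  m2 <- m; m2[, 2] <- 0; m2["gap43", 2] <- 10; m2["filler", 2] <- 5
  st2 <- stage_and_flag_cells(count_matrix(m2, markers,
                                           sprintf("bc%d", 1:4)), ann)
  expect_equal(st2$stage[2], "early_mature")

  expect_error(stage_and_flag_cells(cm, ann[ann$marker_class != "immune", ]),
               "immune")
})

test_that("stage calls recover simulated maturity with high accuracy", {
  cfg <- small_sim_config(seed = 23)
  sim <- simulate_osn_counts(cfg)
  ann <- simulate_repertoire(cfg)
  st <- stage_and_flag_cells(sim$matrix, ann)
  truth <- sim$truth[match(st$barcode, sim$truth$barcode), ]
  neur <- truth$stage != "immune" & !st$is_immune
  expect_gte(mean(st$stage[neur] == truth$stage[neur]), 0.9)
  expect_gte(mean(st$is_immune[truth$stage == "immune"]), 0.9)
})

test_that("immune-flagged cells are excluded from downstream analysis", {
  cfg <- small_sim_config(seed = 29, immune_cell_fraction = 0.15)
  sim <- simulate_osn_counts(cfg)
  ann <- simulate_repertoire(cfg)
  met <- compute_cell_metrics(sim$matrix, ann)
  flt <- filter_cells(met, qc_thresholds(min_genes = 50, max_genes = 5000,
                                         max_reads = 60000,
                                         max_mito_fraction = 0.25))
  qc_pass <- subset_count_matrix(sim$matrix, barcodes = flt$passed)
  st <- stage_and_flag_cells(qc_pass, ann)
  retained <- st$barcode[!st$is_immune]
  osn <- subset_count_matrix(qc_pass, barcodes = retained)
  calls <- tabulate_or_calls(osn, ann)
  expect_true(all(calls$barcode %in% retained))
  flagged <- st$barcode[st$is_immune]
  expect_length(intersect(calls$barcode, flagged), 0)
})
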