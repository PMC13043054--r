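two_or_ann <- rbind(
  ann_row("orX-1", is_or = TRUE, clade = "A", subfamily = "orX",
          chromosome = "chr6", start_bp = 1000L, end_bp = 1999L),
  ann_row("orX-2", is_or = TRUE, clade = "A", subfamily = "orX",
          chromosome = "chr6", start_bp = 3000L, end_bp = 3999L),
  ann_row("geneBg", chromosome = "chr1"))

or_matrix <- function(m, ann = two_or_ann) {
  ids <- rownames(m)
  count_matrix(m, ids, sprintf("bc%02d", seq_len(ncol(m))))
}

test_that("cells are categorised by the number of ORs detected", {
  m <- rbind("orX-1" = c(0, 3, 3), "orX-2" = c(0, 0, 1),
             "geneBg" = c(5, 5, 5))
  calls <- tabulate_or_calls(or_matrix(m), two_or_ann)
  expect_equal(calls$category, c("none", "single", "multi"))
  expect_equal(calls$n_or_detected, c(0L, 1L, 2L))
})

test_that("the 5x dominance rule assigns predominant ORs inclusively", {
  m <- rbind("orX-1" = c(10, 10, 7), "orX-2" = c(2, 3, 0),
             "geneBg" = c(1, 1, 1))
  calls <- assign_predominant_or(tabulate_or_calls(or_matrix(m), two_or_ann))
  # 10 >= 5*2 assigned; 10 < 5*3 unassigned; single-OR cell assigned
  expect_equal(calls$predominant_or, c("orX-1", NA, "orX-1"))
  expect_equal(calls$clade, c("A", NA, "A"))
  expect_error(assign_predominant_or(
    tabulate_or_calls(or_matrix(m), two_or_ann), dominance_ratio = 0),
    "positive")
})

test_that("perfectly monotone OR pairs give rho of +/-1", {
  m <- rbind("orX-1" = c(1, 2, 3, 4), "orX-2" = c(1, 2, 3, 4),
             "geneBg" = c(0, 0, 0, 0))
  cx <- spearman_coexpression_matrix(or_matrix(m), two_or_ann)
  expect_equal(cx$rho["orX-1", "orX-2"], 1)
  m2 <- rbind("orX-1" = c(1, 2, 3), "orX-2" = c(3, 2, 1),
              "geneBg" = c(0, 0, 0))
  cx2 <- spearman_coexpression_matrix(or_matrix(m2), two_or_ann)
  expect_equal(cx2$rho["orX-1", "orX-2"], -1)
})

test_that("rho equals the naive tie-corrected recomputation on random data", {
  set.seed(31)
  n_or <- 6
  ids <- sprintf("orY-%d", 1:n_or)
  ann <- do.call(rbind, lapply(seq_len(n_or), function(i)
    ann_row(ids[i], is_or = TRUE, clade = "B", subfamily = "orY",
            chromosome = "chr7", start_bp = 1000L * i,
            end_bp = 1000L * i + 500L)))
  m <- matrix(rnbinom(n_or * 200, mu = 3, size = 1), nrow = n_or,
              dimnames = list(ids, NULL))
  cm <- count_matrix(m, ids, sprintf("bc%03d", 1:200))
  cx <- spearman_coexpression_matrix(cm, ann, min_cells_nonzero = 1)
  multi <- colSums(m >= 1) >= 2
  oracle <- cor(t(m[, multi]), method = "spearman")
  defined <- !is.na(cx$rho)
  expect_lt(max(abs(cx$rho[defined] - oracle[defined])), 1e-12)
  # symmetry and bounds
  expect_identical(cx$rho, t(cx$rho))
  expect_true(all(abs(cx$rho[defined]) <= 1 + 1e-12))
  # permuting cells leaves the matrix unchanged
  perm <- sample(ncol(m))
  cmp <- count_matrix(m[, perm], ids, sprintf("bc%03d", 1:200)[perm])
  cxp <- spearman_coexpression_matrix(cmp, ann, min_cells_nonzero = 1)
  expect_equal(cx$rho, cxp$rho)
})

test_that("degenerate pairs are reported as missing", {
  ids <- c("orZ-1", "orZ-2", "orZ-3")
  ann <- do.call(rbind, lapply(1:3, function(i)
    ann_row(ids[i], is_or = TRUE, clade = "C", subfamily = "orZ",
            chromosome = "chr9", start_bp = 1000L * i,
            end_bp = 1000L * i + 10L)))
  # orZ-3 constant zero; orZ-1/orZ-2 detected in only 2 cells together
  m <- rbind("orZ-1" = c(2, 1, 0, 0, 0, 0), "orZ-2" = c(1, 2, 0, 0, 0, 0),
             "orZ-3" = c(1, 1, 1, 1, 1, 1))
  cm <- count_matrix(m, ids, sprintf("bc%d", 1:6))
  cx <- spearman_coexpression_matrix(cm, ann, min_cells_nonzero = 3)
  expect_true(is.na(cx$rho["orZ-1", "orZ-2"]))  # under the cell floor
  # constant vector across used cells
  m2 <- rbind("orZ-1" = c(2, 1, 3, 1), "orZ-2" = c(1, 2, 1, 3),
              "orZ-3" = c(1, 1, 1, 1))
  cx2 <- spearman_coexpression_matrix(
    count_matrix(m2, ids, sprintf("bc%d", 1:4)), ann)
  expect_true(is.na(cx2$rho["orZ-1", "orZ-3"]))
  # fewer than two multi-OR cells is an error
  m3 <- rbind("orZ-1" = c(2, 0), "orZ-2" = c(0, 1), "orZ-3" = c(0, 0))
  expect_error(spearman_coexpression_matrix(
    count_matrix(m3, ids, c("a", "b")), ann), "insufficient")
})

test_that("planted hubs are recovered as genomic blocks; leaks stay out", {
  cfg <- small_sim_config(seed = 37)
  sim <- simulate_osn_counts(cfg)
  ann <- simulate_repertoire(cfg)
  cx <- detect_coexpression_blocks(
    spearman_coexpression_matrix(sim$matrix, ann))
  hubs <- sim$hubs
  planted <- split(hubs$gene_id, hubs$hub)
  planted <- planted[vapply(planted, length, 0L) >= 2]
  found <- strsplit(cx$blocks$members, ",")
  hits <- vapply(planted, function(p)
    any(vapply(found, identical, TRUE, y = p)), TRUE)
  expect_gte(mean(hits), 0.9)
  # blocks never span subfamilies
  for (i in seq_len(nrow(cx$blocks))) {
    sfs <- hubs$subfamily[match(found[[i]], hubs$gene_id)]
    expect_equal(length(unique(sfs)), 1L)
  }
  # the declared cross-subfamily leak pair is reported separately
  leak <- c("or101-1", "or102-1")
  in_cross <- any((cx$cross_subfamily_pairs$or_i %in% leak) &
                    (cx$cross_subfamily_pairs$or_j %in% leak))
  expect_true(in_cross)
  expect_false(any(vapply(found, function(b) all(leak %in% b), TRUE)))
})

test_that("independent ORs produce no blocks", {
  set.seed(41)
  ids <- c(sprintf("orP-%d", 1:3), sprintf("orQ-%d", 1:3))
  ann <- rbind(
    do.call(rbind, lapply(1:3, function(i)
      ann_row(sprintf("orP-%d", i), is_or = TRUE, clade = "A",
              subfamily = "orP", chromosome = "chr4",
              start_bp = 1000L * i, end_bp = 1000L * i + 10L))),
    do.call(rbind, lapply(1:3, function(i)
      ann_row(sprintf("orQ-%d", i), is_or = TRUE, clade = "C",
              subfamily = "orQ", chromosome = "chr8",
              start_bp = 1000L * i, end_bp = 1000L * i + 10L))))
  m <- matrix(rnbinom(6 * 150, mu = 2, size = 1), nrow = 6,
              dimnames = list(ids, NULL))
  cm <- count_matrix(m, ids, sprintf("bc%03d", 1:150))
  cx <- detect_coexpression_blocks(
    spearman_coexpression_matrix(cm, ann))
  expect_equal(nrow(cx$blocks), 0L)
})

test_that("assigned clades match simulation truth", {
  cfg <- small_sim_config(seed = 43)
  sim <- simulate_osn_counts(cfg)
  ann <- simulate_repertoire(cfg)
  calls <- assign_predominant_or(tabulate_or_calls(sim$matrix, ann))
  truth <- sim$truth[match(calls$barcode, sim$truth$barcode), ]
  use <- !is.na(calls$predominant_or) & truth$stage != "immune"
  expect_gte(mean(calls$clade[use] == truth$clade[use]), 0.95)
})
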