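#' Construct a validated count matrix
#'
#' Bundles a sparse genes x cells matrix of unique-molecule counts with its
#' gene identifiers and cell barcodes. All entries must be nonnegative
#' integers; barcodes must be unique.
#'
#' @param counts A matrix or Matrix (genes in rows, cells in columns) of
#'   nonnegative integer counts.
#' @param gene_ids Character vector of gene identifiers, one per row.
#' @param barcodes Character vector of unique cell barcodes, one per column.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (a `dgCMatrix`), `gene_ids` and `barcodes`.
#' @export
count_matrix <- function(counts, gene_ids, barcodes) {
  if (!methods::is(counts, "Matrix"))
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != length(gene_ids))
    stop("gene_ids length (", length(gene_ids), ") does not match row count (",
         nrow(counts), ")")
  if (ncol(counts) != length(barcodes))
    stop("barcodes length (", length(barcodes), ") does not match column count (",
         ncol(counts), ")")
  if (anyDuplicated(barcodes))
    stop("barcodes must be unique")
  bad <- which(counts@x < 0 | counts@x != round(counts@x))
  if (length(bad)) {
    ij <- matrix_entry_index(counts, bad[1])
    stop("count entries must be nonnegative integers; offending entry at row ",
         ij[1], ", column ", ij[2])
  }
  rownames(counts) <- gene_ids
  colnames(counts) <- barcodes
  structure(
    list(counts = counts,
         gene_ids = as.character(gene_ids),
         barcodes = as.character(barcodes)),
    class = "count_matrix")
}

# locate (row, col) of the k-th stored entry of a dgCMatrix
matrix_entry_index <- function(m, k) {
  col <- which(m@p[-1] >= k & m@p[-length(m@p)] < k)[1]
  c(m@i[k] + 1L, col)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells, ", length(x$counts@x), " nonzero entries\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

read_lines_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    readLines(con)
  } else {
    readLines(path)
  }
}

#' Read a 10x-style Matrix Market count matrix
#'
#' Reads a sparse genes x cells matrix stored as a Matrix Market coordinate
#' file with features and barcodes sidecar files (one record per line; the
#' first tab-separated field of each features line is taken as the gene id).
#' Gzip-compressed files are accepted transparently. Entries absent from the
#' triplet file are zero.
#'
#' @param matrix_path Path to the `.mtx` (or `.mtx.gz`) file.
#' @param features_path Path to the features/genes sidecar file.
#' @param barcodes_path Path to the barcodes sidecar file.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(matrix_path, features_path, barcodes_path) {
  m <- tryCatch(Matrix::readMM(matrix_path), error = function(e)
    stop("format error in matrix file '", matrix_path, "': ",
         conditionMessage(e), call. = FALSE))
  features <- read_lines_maybe_gz(features_path)
  features <- features[nzchar(features)]
  gene_ids <- vapply(strsplit(features, "\t", fixed = TRUE), `[[`, "", 1L)
  barcodes <- read_lines_maybe_gz(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(m) != length(gene_ids))
    stop("format error: matrix file '", matrix_path, "' declares ", nrow(m),
         " genes but features file '", features_path, "' has ",
         length(gene_ids), " records")
  if (ncol(m) != length(barcodes))
    stop("format error: matrix file '", matrix_path, "' declares ", ncol(m),
         " cells but barcodes file '", barcodes_path, "' has ",
         length(barcodes), " records")
  count_matrix(m, gene_ids, barcodes)
}

#' Write a count matrix as a Matrix Market triplet trio
#'
#' Emits `matrix.mtx` in the Matrix Market integer coordinate dialect with
#' 1-based indices (entries ordered by column, then row), plus
#' `features.tsv` and `barcodes.tsv` sidecars. Output is deterministic and
#' lossless under [read_count_matrix()].
#'
#' @param x A [count_matrix()].
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the three paths written.
#' @export
write_count_matrix <- function(x, out_dir) {
  stopifnot(inherits(x, "count_matrix"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory '", out_dir, "'")
  m <- methods::as(x$counts, "TsparseMatrix")
  ord <- order(m@j, m@i)
  header <- c("%%MatrixMarket matrix coordinate integer general",
              paste(nrow(m), ncol(m), length(m@x)))
  triplets <- if (length(m@x))
    paste(m@i[ord] + 1L, m@j[ord] + 1L, format(m@x[ord], scientific = FALSE,
                                               trim = TRUE))
  else character(0)
  paths <- c(matrix = file.path(out_dir, "matrix.mtx"),
             features = file.path(out_dir, "features.tsv"),
             barcodes = file.path(out_dir, "barcodes.tsv"))
  writeLines(c(header, triplets), paths[["matrix"]])
  writeLines(x$gene_ids, paths[["features"]])
  writeLines(x$barcodes, paths[["barcodes"]])
  paths
}

annotation_columns <- c("gene_id", "symbol", "chromosome", "start_bp",
                        "end_bp", "is_or", "clade", "subfamily", "is_mito",
                        "has_signal_peptide", "has_tm_domain", "marker_class")

marker_classes <- c("immature", "transitional", "early_mature", "mature",
                    "immune", "none")

#' Validate a gene annotation table
#'
#' Checks the invariants of the flat gene annotation schema: unique gene ids,
#' `start_bp <= end_bp`, OR genes carry a clade in A/B/C and a subfamily,
#' non-OR genes carry neither, and marker classes are drawn from the known
#' set (`immature`, `transitional`, `early_mature`, `mature`, `immune`,
#' `none`).
#'
#' @param ann A data frame with the annotation columns.
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_gene_annotation <- function(ann) {
  missing_cols <- setdiff(annotation_columns, names(ann))
  if (length(missing_cols))
    stop("annotation is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene_id: ",
         ann$gene_id[duplicated(ann$gene_id)][1])
  if (any(ann$start_bp < 1) || any(ann$end_bp < 1))
    stop("coordinates must be positive (1-based)")
  if (any(ann$start_bp > ann$end_bp))
    stop("start_bp exceeds end_bp for gene ",
         ann$gene_id[which(ann$start_bp > ann$end_bp)[1]])
  or <- ann$is_or
  if (any(or & !ann$clade %in% c("A", "B", "C")))
    stop("OR gene without a clade in {A,B,C}: ",
         ann$gene_id[which(or & !ann$clade %in% c("A", "B", "C"))[1]])
  if (any(or & (is.na(ann$subfamily) | ann$subfamily == "none")))
    stop("OR gene without a subfamily: ",
         ann$gene_id[which(or & (is.na(ann$subfamily) | ann$subfamily == "none"))[1]])
  if (any(!or & ann$clade != "none"))
    stop("non-OR gene with a clade: ",
         ann$gene_id[which(!or & ann$clade != "none")[1]])
  if (any(!or & !(is.na(ann$subfamily) | ann$subfamily == "none")))
    stop("non-OR gene with a subfamily: ",
         ann$gene_id[which(!or & !(is.na(ann$subfamily) | ann$subfamily == "none"))[1]])
  if (any(!ann$marker_class %in% marker_classes))
    stop("unknown marker_class: ",
         ann$marker_class[which(!ann$marker_class %in% marker_classes)[1]])
  invisible(ann)
}

#' Read a gene annotation table
#'
#' Reads a tab-separated annotation table whose header names every field of
#' the schema (`gene_id`, `symbol`, `chromosome`, `start_bp`, `end_bp`,
#' `is_or`, `clade`, `subfamily`, `is_mito`, `has_signal_peptide`,
#' `has_tm_domain`, `marker_class`) and validates every invariant. The string
#' "none" in the `subfamily` column is converted to `NA`.
#'
#' @param path Path to the TSV file.
#' @return A data frame, rows in file order.
#' @export
read_gene_annotation <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(start_bp = "integer", end_bp = "integer",
                                   is_or = "logical", is_mito = "logical",
                                   has_signal_peptide = "logical",
                                   has_tm_domain = "logical"))
  if ("subfamily" %in% names(ann))
    ann$subfamily[!is.na(ann$subfamily) & ann$subfamily == "none"] <- NA
  validate_gene_annotation(ann)
  ann
}

#' Write a gene annotation table
#'
#' @param ann Validated annotation data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(ann, path) {
  validate_gene_annotation(ann)
  out <- ann[annotation_columns]
  out$subfamily[is.na(out$subfamily)] <- "none"
  lines <- c(paste(annotation_columns, collapse = "\t"),
             do.call(paste, c(lapply(out, as.character), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

format_sig6 <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    formatC(signif(v, 6), digits = 6, format = "g")
  }, "")
  out
}

#' Write a results table deterministically
#'
#' Writes a data frame as CSV or JSON with a fixed field order and floats
#' formatted to 6 significant digits, so repeated writes of the same records
#' are byte-identical.
#'
#' @param records A data frame (or list of records sharing one schema).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(records)) {
    if (length(records)) {
      schemas <- lapply(records, names)
      if (!all(vapply(schemas, identical, TRUE, schemas[[1]])))
        stop("records do not share a field schema")
      records <- do.call(rbind, lapply(records, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
    } else {
      records <- data.frame()
    }
  }
  num <- vapply(records, is.double, TRUE)
  formatted <- records
  formatted[num] <- lapply(records[num], format_sig6)
  if (format == "csv") {
    lines <- paste(names(records), collapse = ",")
    if (nrow(records))
      lines <- c(lines, do.call(paste, c(lapply(formatted, as.character),
                                         sep = ",")))
    writeLines(lines, path)
  } else {
    rounded <- records
    rounded[num] <- lapply(records[num], signif, 6)
    json <- jsonlite::toJSON(rounded, dataframe = "rows", digits = NA,
                             na = "null", pretty = TRUE)
    writeLines(json, path)
  }
  invisible(path)
}
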