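targeting_directions <- c("dorsal", "ventral", "anterior", "posterior",
                          "medial", "lateral")

#' Construct a validated axon-targeting table
#'
#' Per-condition counts from a scored axon-targeting experiment: the number
#' of axons scored, the number terminating correctly in their protoglomerular
#' target, and counts of error events per anatomical direction. An axon may
#' contribute error events in more than one direction, so directional counts
#' may sum to more than `n_scored - n_correct`.
#'
#' @param condition Condition label (e.g. `"uninjected"`, `"knockdown"`).
#' @param line Reporter-line label (which OSN population is visualised).
#' @param n_scored Number of axons scored (>= 0).
#' @param n_correct Number terminating correctly (`<= n_scored`).
#' @param errors_by_direction Named nonnegative integer vector over the
#'   anatomical directions (missing directions count 0).
#' @return An object of class `targeting_table`.
#' @export
targeting_table <- function(condition, line, n_scored, n_correct,
                            errors_by_direction = integer(0)) {
  if (n_scored < 0 || n_correct < 0 || n_correct > n_scored)
    stop("need 0 <= n_correct <= n_scored")
  errs <- setNames(integer(length(targeting_directions)),
                   targeting_directions)
  if (length(errors_by_direction)) {
    if (is.null(names(errors_by_direction)) ||
        !all(names(errors_by_direction) %in% targeting_directions))
      stop("error directions must be named among: ",
           paste(targeting_directions, collapse = ", "))
    if (any(errors_by_direction < 0))
      stop("directional error counts must be nonnegative")
    errs[names(errors_by_direction)] <- as.integer(errors_by_direction)
  }
  structure(list(condition = condition, line = line,
                 n_scored = as.integer(n_scored),
                 n_correct = as.integer(n_correct),
                 errors_by_direction = errs),
            class = "targeting_table")
}

#' Read axon-targeting tables from a TSV file
#'
#' Expects columns `condition`, `line`, `n_scored`, `n_correct` and one
#' column per error direction present.
#'
#' @param path Path to the TSV file.
#' @return List of [targeting_table()] objects, one per row.
#' @export
read_targeting_tables <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("condition", "line", "n_scored", "n_correct")
  if (!all(req %in% names(tab)))
    stop("targeting file must have columns ", paste(req, collapse = ", "))
  dirs <- intersect(names(tab), targeting_directions)
  lapply(seq_len(nrow(tab)), function(i)
    targeting_table(tab$condition[i], tab$line[i], tab$n_scored[i],
                    tab$n_correct[i],
                    setNames(as.integer(tab[i, dirs]), dirs)))
}

#' Consolidate blinded dual-scorer calls
#'
#' Scoring is performed independently by two blinded scorers; agreeing calls
#' pass through, disagreements take a supplied resolution, and unresolved
#' disagreements are flagged and excluded from downstream tables, with a
#' count reported.
#'
#' @param calls_1,calls_2 Named vectors of calls indexed by the same unit
#'   ids.
#' @param resolutions Optional named vector of consensus calls for
#'   disagreeing units.
#' @return Data frame with `unit`, `call_scorer_1`, `call_scorer_2`,
#'   `consensus` (`NA` when unresolved) and `unresolved`; attribute
#'   `n_unresolved` carries the excluded count.
#' @export
consensus_scores <- function(calls_1, calls_2, resolutions = NULL) {
  if (is.null(names(calls_1)) || is.null(names(calls_2)))
    stop("calls must be named by unit id")
  if (!setequal(names(calls_1), names(calls_2)))
    stop("the two scorers must index the same units")
  units <- names(calls_1)
  c2 <- calls_2[units]
  agree <- calls_1 == c2
  consensus <- ifelse(agree, calls_1, NA)
  if (!is.null(resolutions)) {
    res_units <- intersect(names(resolutions), units[!agree])
    consensus[res_units] <- resolutions[res_units]
  }
  unresolved <- is.na(consensus)
  out <- data.frame(unit = units, call_scorer_1 = unname(calls_1),
                    call_scorer_2 = unname(c2),
                    consensus = unname(consensus),
                    unresolved = unname(unresolved),
                    stringsAsFactors = FALSE)
  attr(out, "n_unresolved") <- sum(unresolved)
  out
}

#' One-tailed Fisher's exact test
#'
#' Exact hypergeometric tail probability for a 2x2 table with fixed
#' margins, computed by log-factorial accumulation over every table at
#' least as extreme as observed in the stated direction of the (1,1) cell.
#' Degenerate margins (an all-zero row or column) give `p = 1`.
#'
#' @param a,b,c_,d Nonnegative integer cell counts of the table
#'   `rbind(c(a, b), c(c_, d))`.
#' @param alternative `"greater"` or `"less"`, on the (1,1) cell.
#' @return The p-value, in (0, 1].
#' @export
fisher_exact_one_tailed <- function(a, b, c_, d,
                                    alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c_, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers")
  r1 <- a + b; r2 <- c_ + d; col1 <- a + c_; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || col1 == 0 || col1 == n) return(1)
  lf <- lgamma(seq_len(n + 1))  # lf[k+1] = log(k!)
  lfact <- function(k) lf[k + 1]
  log_p_table <- function(x) {
    # hypergeometric probability of (1,1) cell = x given the margins
    lfact(r1) + lfact(r2) + lfact(col1) + lfact(n - col1) - lfact(n) -
      (lfact(x) + lfact(r1 - x) + lfact(col1 - x) + lfact(r2 - col1 + x))
  }
  k_min <- max(0, col1 - r2)
  k_max <- min(r1, col1)
  ks <- if (alternative == "greater") a:k_max else k_min:a
  lp <- vapply(ks, log_p_table, 0)
  mx <- max(lp)
  min(1, exp(mx) * sum(exp(lp - mx)))
}

#' Significance stars for a p-value
#'
#' Inclusive thresholds: `****` for p <= 1e-4, `***` for p <= 1e-3, `**`
#' for p <= 0.01, `*` for p <= 0.05, otherwise `ns`.
#'
#' @param p A p-value.
#' @return A star string.
#' @export
star_label <- function(p) {
  if (p <= 1e-4) "****" else if (p <= 1e-3) "***" else if (p <= 0.01) "**"
  else if (p <= 0.05) "*" else "ns"
}

#' Compare control and knockdown targeting tables
#'
#' Builds 2x2 tables for (i) correct-versus-not terminations per condition,
#' tested one-tailed for reduced correct targeting in the knockdown, and
#' (ii) each error direction versus the rest, tested one-tailed for
#' elevated errors in the knockdown — the directional hypotheses of a
#' loss-of-function experiment. Each test is annotated with its p-value and
#' star string. No multiplicity correction is applied across directions by
#' default; `adjust = TRUE` applies BH across the directional tests.
#'
#' @param control,knockdown [targeting_table()] objects sharing a line
#'   label.
#' @param adjust Apply BH across the directional tests (default `FALSE`).
#' @return Data frame with `test`, `control_count`, `control_n`,
#'   `knockdown_count`, `knockdown_n`, `p` and `stars`.
#' @export
compare_conditions <- function(control, knockdown, adjust = FALSE) {
  stopifnot(inherits(control, "targeting_table"),
            inherits(knockdown, "targeting_table"))
  if (!identical(control$line, knockdown$line))
    stop("control and knockdown tables must share a line label")
  rows <- list(data.frame(
    test = "correct_targeting",
    control_count = control$n_correct, control_n = control$n_scored,
    knockdown_count = knockdown$n_correct, knockdown_n = knockdown$n_scored,
    p = fisher_exact_one_tailed(
      control$n_correct, control$n_scored - control$n_correct,
      knockdown$n_correct, knockdown$n_scored - knockdown$n_correct,
      alternative = "greater"),
    stringsAsFactors = FALSE))
  for (dir in targeting_directions) {
    ec <- control$errors_by_direction[[dir]]
    ek <- knockdown$errors_by_direction[[dir]]
    rows[[length(rows) + 1L]] <- data.frame(
      test = paste0("error_", dir),
      control_count = ec, control_n = control$n_scored,
      knockdown_count = ek, knockdown_n = knockdown$n_scored,
      p = fisher_exact_one_tailed(
        ek, knockdown$n_scored - ek, ec, control$n_scored - ec,
        alternative = "greater"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (adjust) {
    dir_rows <- out$test != "correct_targeting"
    out$p[dir_rows] <- bh_adjust(out$p[dir_rows])
  }
  out$stars <- vapply(out$p, star_label, "")
  out
}
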