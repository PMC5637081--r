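#' Half-up rounding
#'
#' Rounds halves away from zero (`0.5 -> 1`), unlike R's banker's rounding.
#' Used wherever printed tables are reconstructed from rounded proportions.
#'
#' @param x Numeric vector.
#' @param digits Integer number of decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build a 2x2 contingency table from a retrieval result
#'
#' Cross-tabulates a filter's retrieval set against the gold-standard
#' labels of a fully screened reference set:
#' \describe{
#'   \item{a}{relevant records retrieved}
#'   \item{b}{irrelevant records retrieved}
#'   \item{c}{relevant records not retrieved}
#'   \item{d}{irrelevant records not retrieved}
#' }
#' Every retrieved id must carry a label: performance against a partially
#' screened set is meaningless, so unknown ids are an error, not a silent
#' drop.
#'
#' @param retrieved Character vector of retrieved record ids (a set).
#' @param gold A [gold_standard].
#' @return An object of class `contingency_table` with integer elements
#'   `a`, `b`, `c`, `d`.
#' @export
contingency <- function(retrieved, gold) {
  stopifnot(inherits(gold, "gold_standard"))
  retrieved <- unique(as.character(retrieved))
  unknown <- setdiff(retrieved, names(gold))
  if (length(unknown))
    stop("retrieved ids absent from gold standard: ",
         paste(utils::head(unknown, 5L), collapse = ", "),
         if (length(unknown) > 5L) ", ...", call. = FALSE)
  rel <- relevant_ids(gold)
  irr <- irrelevant_ids(gold)
  a <- length(intersect(retrieved, rel))
  b <- length(intersect(retrieved, irr))
  contingency_table(a, b, length(rel) - a, length(irr) - b)
}

#' @rdname contingency
#' @param a,b,c,d Non-negative integer cell counts.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("contingency cells must be non-negative integers", call. = FALSE)
  structure(as.list(stats::setNames(as.integer(cells), names(cells))),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2L, 2L,
              dimnames = list(c("retrieved", "not retrieved"),
                              c("relevant", "irrelevant")))
  print(m)
  invisible(x)
}

#' @export
as.data.frame.contingency_table <- function(x, ...) {
  data.frame(a = x$a, b = x$b, c = x$c, d = x$d)
}

#' Diagnostic performance of a filter
#'
#' Computes the standard retrieval statistics from a 2x2 table:
#' sensitivity `a/(a+c)` (proportion of relevant records retrieved),
#' specificity `d/(b+d)` (proportion of irrelevant records correctly not
#' retrieved), precision `a/(a+b)`, number needed to read `NNR =
#' 1/precision` (how many retrieved records must be screened to find one
#' relevant record), and accuracy `(a+d)/(a+b+c+d)`.
#'
#' When the filter retrieves nothing (`a+b = 0`), precision and NNR are
#' undefined and reported as `NA` with `nnr_defined = FALSE` — never as 0
#' or infinity. Raw values are stored unrounded; the print method displays
#' percentages to 1 decimal place and NNR to 2.
#'
#' @param table A `contingency_table`; requires `a+c > 0` and `b+d > 0`.
#' @return An object of class `performance_report`: list with elements
#'   `sensitivity`, `specificity`, `precision`, `nnr`, `accuracy`,
#'   `nnr_defined` and `table`.
#' @export
performance <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if (a + c == 0L) stop("no relevant records in the reference set (a+c = 0)",
                        call. = FALSE)
  if (b + d == 0L) stop("no irrelevant records in the reference set (b+d = 0)",
                        call. = FALSE)
  defined <- (a + b) > 0L
  precision <- if (defined) a / (a + b) else NA_real_
  nnr <- if (defined && precision > 0) 1 / precision else NA_real_
  structure(
    list(sensitivity = a / (a + c),
         specificity = d / (b + d),
         precision = precision,
         nnr = nnr,
         accuracy = (a + d) / (a + b + c + d),
         nnr_defined = defined && precision > 0,
         table = table),
    class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  fmt_pct <- function(p) sprintf("%.1f%%", 100 * p)
  cat("<performance>",
      " sensitivity ", fmt_pct(x$sensitivity),
      "  specificity ", fmt_pct(x$specificity),
      "  precision ", if (is.na(x$precision)) "undefined"
        else sprintf("%.3f", x$precision),
      "  NNR ", if (x$nnr_defined) sprintf("%.2f", x$nnr) else "undefined",
      "  accuracy ", fmt_pct(x$accuracy), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.performance_report <- function(x, ...) {
  data.frame(sensitivity = x$sensitivity, specificity = x$specificity,
             precision = x$precision, nnr = x$nnr, accuracy = x$accuracy,
             a = x$table$a, b = x$table$b, c = x$table$c, d = x$table$d)
}

#' Reconstruct a contingency table from printed class sizes and rates
#'
#' The inverse of the performance formulas, used to validate published
#' figures: given the reference-set class sizes and the reported
#' sensitivity and specificity, rebuilds the four cells with half-up
#' rounding (`a = round(n_relevant x sensitivity)`, `d = round(n_irrelevant
#' x specificity)`, `c` and `b` by difference).
#'
#' @param n_relevant,n_irrelevant Positive class sizes.
#' @param sensitivity,specificity Proportions in `[0, 1]`.
#' @return A `contingency_table`.
#' @export
#' @examples
#' reconstruct_table(431, 1671, 0.984, 0.743)
reconstruct_table <- function(n_relevant, n_irrelevant,
                              sensitivity, specificity) {
  stopifnot(n_relevant > 0, n_irrelevant > 0,
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  a <- round_half_up(n_relevant * sensitivity)
  d <- round_half_up(n_irrelevant * specificity)
  contingency_table(a, n_irrelevant - d, n_relevant - a, d)
}

#' Summarise a set of single-term performance results
#'
#' Mean and sample standard deviation (n-1 denominator) of sensitivity and
#' specificity on the percent scale, and the range of NNR over the results
#' where NNR is defined.
#'
#' @param results A `single_term_results` data frame (from
#'   [single_term_analysis()]), a list of `performance_report`s, or a data
#'   frame with columns `sensitivity`, `specificity`, `nnr`.
#' @return A list of class `single_term_summary`: `n_terms`,
#'   `mean_sensitivity_pct`, `sd_sensitivity_pct`, `mean_specificity_pct`,
#'   `sd_specificity_pct`, `nnr_min`, `nnr_max`, `n_nnr_defined`. With a
#'   single result the standard deviations are `NA` (sample-SD convention)
#'   and `sd_defined` is `FALSE`.
#' @export
summarize_single_terms <- function(results) {
  if (is.list(results) && !is.data.frame(results) &&
      all(vapply(results, inherits, logical(1), "performance_report"))) {
    results <- do.call(rbind, lapply(results, as.data.frame))
  }
  if (!is.data.frame(results) ||
      !all(c("sensitivity", "specificity", "nnr") %in% names(results)))
    stop("results must carry sensitivity, specificity and nnr", call. = FALSE)
  if (nrow(results) == 0L) stop("no results to summarise", call. = FALSE)
  nnr <- results$nnr[!is.na(results$nnr)]
  structure(
    list(n_terms = nrow(results),
         mean_sensitivity_pct = 100 * mean(results$sensitivity),
         sd_sensitivity_pct = 100 * stats::sd(results$sensitivity),
         mean_specificity_pct = 100 * mean(results$specificity),
         sd_specificity_pct = 100 * stats::sd(results$specificity),
         nnr_min = if (length(nnr)) min(nnr) else NA_real_,
         nnr_max = if (length(nnr)) max(nnr) else NA_real_,
         n_nnr_defined = length(nnr),
         sd_defined = nrow(results) > 1L),
    class = "single_term_summary")
}

#' @export
print.single_term_summary <- function(x, ...) {
  cat("<single-term summary> ", x$n_terms, " terms\n",
      sprintf("  sensitivity: mean %.1f%% (SD %s)\n", x$mean_sensitivity_pct,
              if (x$sd_defined) sprintf("%.1f", x$sd_sensitivity_pct)
              else "undefined"),
      sprintf("  specificity: mean %.1f%% (SD %s)\n", x$mean_specificity_pct,
              if (x$sd_defined) sprintf("%.1f", x$sd_specificity_pct)
              else "undefined"),
      if (x$n_nnr_defined)
        sprintf("  NNR range: %.2f - %.2f (%d terms with defined NNR)\n",
                x$nnr_min, x$nnr_max, x$n_nnr_defined)
      else "  NNR: undefined for all terms\n",
      sep = "")
  invisible(x)
}
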