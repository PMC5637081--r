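#' Single-term analysis against a screened reference set
#'
#' Evaluates each candidate term as a one-term filter over the corpus,
#' crossing its retrieval set against the gold standard. This is the first
#' stage of second-generation filter development: it shows which terms are
#' individually sensitive or specific before any OR-combination.
#'
#' @param pool Non-empty list of [filter_term]s (or a `filter_expr` whose
#'   leaves are taken).
#' @param corpus A [corpus], completely screened.
#' @param gold A [gold_standard] covering `corpus`.
#' @return A data frame of class `single_term_results`, one row per term,
#'   sorted by decreasing sensitivity (ties: decreasing specificity, then
#'   term text). Columns: `term` (canonical Ovid text), `field`,
#'   `truncated`, the four cell counts, `sensitivity`, `specificity`,
#'   `precision`, `nnr`, `accuracy`.
#' @export
single_term_analysis <- function(pool, corpus, gold) {
  pool <- .as_term_pool(pool)
  if (length(pool) == 0L) stop("candidate pool is empty", call. = FALSE)
  check_gold_coverage(gold, corpus)
  rows <- lapply(pool, function(term) {
    tab <- contingency(retrieve(term, corpus), gold)
    rep <- performance(tab)
    cbind(data.frame(term = serialize_filter(term), field = term$field,
                     truncated = term$truncated, stringsAsFactors = FALSE),
          as.data.frame(rep))
  })
  df <- do.call(rbind, rows)
  ord <- order(-df$sensitivity, -df$specificity, df$term)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "terms") <- pool[ord]
  class(df) <- c("single_term_results", "data.frame")
  df
}

.as_term_pool <- function(pool) {
  if (inherits(pool, "filter_expr")) pool <- filter_terms(pool)
  if (inherits(pool, "filter_term")) pool <- list(pool)
  stopifnot(is.list(pool))
  for (t in pool)
    if (!inherits(t, "filter_term"))
      stop("pool must contain filter_term objects", call. = FALSE)
  pool
}

#' Configuration for combined-term filter development
#'
#' @param objective `"sensitivity_maximising"` (broad, for researchers) or
#'   `"specificity_maximising"` (narrow, for clinicians).
#' @param floor Minimum acceptable value of the non-objective metric, in
#'   `[0, 1]`: a specificity floor when maximising sensitivity, a
#'   sensitivity floor (target recall) when maximising specificity.
#' @param max_terms Cap on the number of OR-ed terms.
#' @param candidate_pool Non-empty list of [filter_term]s.
#' @param seed Integer kept for interface completeness; the builder is
#'   fully deterministic (ties break by fixed rules, never by shuffling).
#' @return A list of class `development_config`.
#' @export
development_config <- function(objective = c("sensitivity_maximising",
                                             "specificity_maximising"),
                               candidate_pool,
                               floor = if (objective == "sensitivity_maximising")
                                 0.5 else 0.9,
                               max_terms = 25L, seed = 0L) {
  objective <- match.arg(objective)
  candidate_pool <- .as_term_pool(candidate_pool)
  if (length(candidate_pool) == 0L) stop("candidate pool is empty",
                                         call. = FALSE)
  stopifnot(floor >= 0, floor <= 1, max_terms >= 1)
  structure(list(objective = objective, floor = floor,
                 max_terms = as.integer(max_terms),
                 candidate_pool = candidate_pool, seed = as.integer(seed)),
            class = "development_config")
}

# precompute logical hit matrix: records x terms (fast OR algebra)
.hit_matrix <- function(pool, corpus) {
  ids <- record_ids(corpus)
  m <- vapply(pool, function(term)
    vapply(corpus$records, function(r) match_term(term, r), logical(1)),
    logical(length(ids)))
  m <- matrix(m, nrow = length(ids),
              dimnames = list(ids, vapply(pool, serialize_filter,
                                          character(1))))
  m
}

.subset_metrics <- function(hits, sel, is_rel, n_rel, n_irr) {
  retrieved <- if (length(sel)) rowSums(hits[, sel, drop = FALSE]) > 0
  else rep(FALSE, nrow(hits))
  a <- sum(retrieved & is_rel)
  b <- sum(retrieved & !is_rel)
  c(sensitivity = a / n_rel, specificity = (n_irr - b) / n_irr,
    n_retrieved = a + b)
}

#' Greedy OR-combination filter development
#'
#' Formalises the iterative "add and subtract terms until performance is
#' optimal" procedure of second-generation filter development as a greedy
#' forward selection with backward pruning over pure-OR filters.
#'
#' Starting from the empty filter, terms are OR-added one at a time:
#' \itemize{
#'   \item `sensitivity_maximising`: add the candidate with the largest
#'     sensitivity gain among those keeping specificity at or above
#'     `floor`; stop when no candidate strictly improves sensitivity (or
#'     all would breach the floor).
#'   \item `specificity_maximising`: OR-additions can only lower
#'     specificity, so the builder runs in constraint-satisfaction mode:
#'     while sensitivity is below `floor`, add the candidate that costs the
#'     least specificity; stop as soon as the sensitivity floor is met.
#' }
#' Ties break by greater improvement in the non-objective metric, then
#' fewer retrieved records, then lexicographic term text. After each
#' addition any term whose deletion leaves neither metric worse and
#' strictly improves one is pruned (the "subtract" step). `max_terms`
#' caps the filter length.
#'
#' If the floor cannot be met (sensitivity objective: no admissible first
#' term; specificity objective: pool exhausted below the sensitivity
#' floor), the result is explicitly marked infeasible rather than silently
#' returning an empty filter.
#'
#' @param config A [development_config].
#' @param corpus A [corpus], completely screened.
#' @param gold A [gold_standard] covering `corpus`.
#' @return A list of class `filter_development`:
#'   \describe{
#'     \item{filter}{the final pure-OR `filter_expr`, or `NULL` when no
#'       term was selected.}
#'     \item{feasible}{logical; `FALSE` when the floor could not be met.}
#'     \item{report}{`performance_report` of the final filter (`NULL` when
#'       empty).}
#'     \item{trace}{data frame of add/remove steps with the metrics before
#'       and after each step.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
greedy_develop <- function(config, corpus, gold) {
  stopifnot(inherits(config, "development_config"))
  check_gold_coverage(gold, corpus)
  pool <- config$candidate_pool
  hits <- .hit_matrix(pool, corpus)
  ids <- rownames(hits)
  is_rel <- unclass(gold)[ids] == "relevant"
  n_rel <- sum(is_rel); n_irr <- sum(!is_rel)
  if (n_rel == 0L || n_irr == 0L)
    stop("gold standard must contain both classes", call. = FALSE)
  sens_obj <- config$objective == "sensitivity_maximising"
  term_text <- colnames(hits)

  sel <- integer(0)
  trace <- list()
  cur <- .subset_metrics(hits, sel, is_rel, n_rel, n_irr)
  feasible <- TRUE

  add_step <- function() {
    cand <- setdiff(seq_along(pool), sel)
    if (length(cand) == 0L) return(NULL)
    mets <- t(vapply(cand, function(j)
      .subset_metrics(hits, c(sel, j), is_rel, n_rel, n_irr), numeric(3)))
    if (sens_obj) {
      ok <- mets[, "specificity"] >= config$floor &
        mets[, "sensitivity"] > cur[["sensitivity"]]
      if (!any(ok)) return(NULL)
      cand <- cand[ok]; mets <- mets[ok, , drop = FALSE]
      ord <- order(-mets[, "sensitivity"], -mets[, "specificity"],
                   mets[, "n_retrieved"], term_text[cand])
    } else {
      ok <- mets[, "sensitivity"] > cur[["sensitivity"]]
      if (!any(ok)) return(NULL)
      cand <- cand[ok]; mets <- mets[ok, , drop = FALSE]
      ord <- order(-mets[, "specificity"], -mets[, "sensitivity"],
                   mets[, "n_retrieved"], term_text[cand])
    }
    cand[ord[1L]]
  }

  record_step <- function(action, j, before, after) {
    trace[[length(trace) + 1L]] <<- data.frame(
      step = length(trace) + 1L, action = action, term = term_text[j],
      sensitivity_before = before[["sensitivity"]],
      specificity_before = before[["specificity"]],
      sensitivity_after = after[["sensitivity"]],
      specificity_after = after[["specificity"]],
      n_retrieved = after[["n_retrieved"]],
      stringsAsFactors = FALSE)
  }

  repeat {
    if (length(sel) >= config$max_terms) break
    if (!sens_obj && cur[["sensitivity"]] >= config$floor) break
    j <- add_step()
    if (is.null(j)) break
    before <- cur
    sel <- c(sel, j)
    cur <- .subset_metrics(hits, sel, is_rel, n_rel, n_irr)
    record_step("add", j, before, cur)
    # backward pruning: drop any term whose deletion leaves neither metric
    # worse and strictly improves one
    repeat {
      pruned <- FALSE
      for (k in sel) {
        rest <- setdiff(sel, k)
        m2 <- .subset_metrics(hits, rest, is_rel, n_rel, n_irr)
        no_worse <- m2[["sensitivity"]] >= cur[["sensitivity"]] &&
          m2[["specificity"]] >= cur[["specificity"]]
        better <- m2[["sensitivity"]] > cur[["sensitivity"]] ||
          m2[["specificity"]] > cur[["specificity"]]
        if (no_worse && better) {
          before <- cur
          sel <- rest
          cur <- m2
          record_step("remove", k, before, cur)
          pruned <- TRUE
          break
        }
      }
      if (!pruned) break
    }
  }

  if (sens_obj && length(sel) == 0L) feasible <- FALSE
  if (!sens_obj && cur[["sensitivity"]] < config$floor) feasible <- FALSE

  filter <- if (length(sel) == 1L) pool[[sel]]
  else if (length(sel) >= 2L) .filter_node("OR", pool[sel])
  else NULL
  report <- if (!is.null(filter))
    performance(contingency(ids[rowSums(hits[, sel, drop = FALSE]) > 0],
                            gold))
  else NULL
  trace_df <- if (length(trace)) do.call(rbind, trace)
  else data.frame(step = integer(0), action = character(0),
                  term = character(0), sensitivity_before = numeric(0),
                  specificity_before = numeric(0),
                  sensitivity_after = numeric(0),
                  specificity_after = numeric(0), n_retrieved = numeric(0))
  structure(list(filter = filter, feasible = feasible, report = report,
                 trace = trace_df, config = config),
            class = "filter_development")
}

#' @export
print.filter_development <- function(x, ...) {
  cat("<filter_development> objective: ", x$config$objective,
      ", floor ", x$config$floor, "\n", sep = "")
  if (!x$feasible)
    cat("  INFEASIBLE: the floor on the non-objective metric cannot be met\n")
  if (is.null(x$filter)) {
    cat("  (empty filter)\n")
  } else {
    cat("  ", serialize_filter(x$filter), "\n", sep = "")
    print(x$report)
  }
  invisible(x)
}

#' Exhaustive search over small OR-combinations
#'
#' Brute-force reference for [greedy_develop()]: enumerates every OR-subset
#' of the pool up to `max_terms` terms and returns the best under the same
#' objective/floor rules. Exponential in the pool size — intended for pools
#' of at most ~12 terms as an oracle, not as a production builder.
#'
#' @inheritParams greedy_develop
#' @param pool List of [filter_term]s.
#' @param objective,floor,max_terms As in [development_config()].
#' @return List: `terms` (canonical texts of the best subset), `sensitivity`,
#'   `specificity`, `objective_value`, `feasible`.
#' @export
exhaustive_or_search <- function(pool, corpus, gold,
                                 objective = c("sensitivity_maximising",
                                               "specificity_maximising"),
                                 floor = 0, max_terms = 4L) {
  objective <- match.arg(objective)
  pool <- .as_term_pool(pool)
  check_gold_coverage(gold, corpus)
  hits <- .hit_matrix(pool, corpus)
  ids <- rownames(hits)
  is_rel <- unclass(gold)[ids] == "relevant"
  n_rel <- sum(is_rel); n_irr <- sum(!is_rel)
  sens_obj <- objective == "sensitivity_maximising"
  best <- NULL
  for (k in seq_len(min(max_terms, length(pool)))) {
    combos <- utils::combn(seq_along(pool), k, simplify = FALSE)
    for (sel in combos) {
      m <- .subset_metrics(hits, sel, is_rel, n_rel, n_irr)
      ok <- if (sens_obj) m[["specificity"]] >= floor
      else m[["sensitivity"]] >= floor
      if (!ok) next
      val <- if (sens_obj) m[["sensitivity"]] else m[["specificity"]]
      if (is.null(best) || val > best$objective_value) {
        best <- list(terms = colnames(hits)[sel],
                     sensitivity = m[["sensitivity"]],
                     specificity = m[["specificity"]],
                     objective_value = val, feasible = TRUE)
      }
    }
  }
  if (is.null(best))
    best <- list(terms = character(0), sensitivity = NA_real_,
                 specificity = NA_real_, objective_value = NA_real_,
                 feasible = FALSE)
  best
}
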