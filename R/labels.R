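#' Construct a gold standard of relevance labels
#'
#' A gold standard maps every record id of a screened reference set to a
#' definitive `"relevant"` or `"irrelevant"` label. Filter performance
#' statistics are only meaningful against a completely screened set, so
#' [contingency()] refuses retrieved ids that carry no label.
#'
#' @param labels Named character vector (names = record ids) or a two-column
#'   data frame with columns `record_id` and `label`. Labels are matched
#'   case-insensitively against `"relevant"` / `"irrelevant"`.
#' @return An object of class `gold_standard`: a named character vector of
#'   `"relevant"`/`"irrelevant"` labels.
#' @export
#' @examples
#' gold_standard(c(`1` = "relevant", `2` = "irrelevant"))
gold_standard <- function(labels) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("record_id", "label") %in% names(labels)))
    labs <- stats::setNames(as.character(labels$label),
                            as.character(labels$record_id))
  } else {
    labs <- labels
  }
  if (is.null(names(labs)) || any(!nzchar(names(labs))))
    stop("labels must be named by record id", call. = FALSE)
  if (anyDuplicated(names(labs))) {
    dup <- unique(names(labs)[duplicated(names(labs))])
    stop("duplicate record_id in labels: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  labs <- tolower(trimws(labs))
  bad <- !labs %in% c("relevant", "irrelevant")
  if (any(bad))
    stop("labels must be 'relevant' or 'irrelevant'; offending ids: ",
         paste(names(labs)[bad], collapse = ", "), call. = FALSE)
  structure(labs, class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("<gold_standard> ", length(x), " labelled records (",
      sum(x == "relevant"), " relevant, ", sum(x == "irrelevant"),
      " irrelevant)\n", sep = "")
  invisible(x)
}

#' Ids labelled relevant / irrelevant
#' @param gold A [gold_standard].
#' @return Character vector of record ids.
#' @export
relevant_ids <- function(gold) {
  stopifnot(inherits(gold, "gold_standard"))
  names(gold)[gold == "relevant"]
}

#' @rdname relevant_ids
#' @export
irrelevant_ids <- function(gold) {
  stopifnot(inherits(gold, "gold_standard"))
  names(gold)[gold == "irrelevant"]
}

#' Check that a gold standard completely covers a corpus
#'
#' Performance statistics assume complete screening: every record of the
#' evaluation corpus carries exactly one label and no label points outside
#' the corpus. Violations are hard errors.
#'
#' @param gold A [gold_standard].
#' @param corpus A [corpus].
#' @return `TRUE`, invisibly, if coverage is complete.
#' @export
check_gold_coverage <- function(gold, corpus) {
  stopifnot(inherits(gold, "gold_standard"), inherits(corpus, "corpus"))
  ids <- record_ids(corpus)
  unlabelled <- setdiff(ids, names(gold))
  extraneous <- setdiff(names(gold), ids)
  if (length(unlabelled))
    stop("unscreened records in corpus: ",
         paste(utils::head(unlabelled, 5L), collapse = ", "),
         if (length(unlabelled) > 5L) ", ...", call. = FALSE)
  if (length(extraneous))
    stop("labels for records absent from corpus: ",
         paste(utils::head(extraneous, 5L), collapse = ", "),
         if (length(extraneous) > 5L) ", ...", call. = FALSE)
  invisible(TRUE)
}

#' Read / write relevance labels as delimited text
#'
#' Labels travel as two-column delimited text (`record_id`, `label`) with a
#' header row; an optional third column `reviewer` tags the screener.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return `read_labels()`: a data frame with columns `record_id`, `label`
#'   and, when present in the file, `reviewer`.
#' @export
read_labels <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("record_id", "label") %in% names(df)))
    stop("label file must have columns 'record_id' and 'label'", call. = FALSE)
  df$label <- tolower(trimws(df$label))
  df
}

#' @rdname read_labels
#' @param labels A [gold_standard] or a data frame with `record_id`/`label`.
#' @export
write_labels <- function(labels, path, sep = ",") {
  if (inherits(labels, "gold_standard"))
    labels <- data.frame(record_id = names(labels),
                         label = as.character(labels),
                         stringsAsFactors = FALSE)
  utils::write.table(labels, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Reconcile two reviewers' screening decisions
#'
#' Dual independent screening produces two label lists over (nominally) the
#' same records. Agreements become final labels; disagreements go to a
#' third-party adjudicator. Ids screened by only one reviewer are reported,
#' never guessed.
#'
#' @param labels_a,labels_b Data frames with columns `record_id` and `label`
#'   (values `relevant`/`irrelevant`, case-insensitive), one per reviewer. A
#'   record labelled twice by the same reviewer with conflicting values is
#'   an error.
#' @return A list of class `reconciliation`:
#'   \describe{
#'     \item{agreed}{[gold_standard] over the ids both reviewers agreed on.}
#'     \item{conflicts}{character vector of ids the reviewers disagreed on.}
#'     \item{only_a, only_b}{ids screened by a single reviewer.}
#'   }
#' @seealso [apply_adjudication()] to fold in the third reviewer's decisions.
#' @export
reconcile_labels <- function(labels_a, labels_b) {
  a <- .reviewer_map(labels_a, "labels_a")
  b <- .reviewer_map(labels_b, "labels_b")
  shared <- intersect(names(a), names(b))
  agree <- shared[a[shared] == b[shared]]
  conflicts <- setdiff(shared, agree)
  structure(
    list(agreed = gold_standard(a[agree]),
         conflicts = conflicts,
         only_a = setdiff(names(a), names(b)),
         only_b = setdiff(names(b), names(a))),
    class = "reconciliation")
}

.reviewer_map <- function(df, who) {
  if (is.data.frame(df)) {
    stopifnot(all(c("record_id", "label") %in% names(df)))
    ids <- as.character(df$record_id)
    labs <- tolower(trimws(as.character(df$label)))
  } else {
    ids <- names(df)
    labs <- tolower(trimws(df))
  }
  bad <- !labs %in% c("relevant", "irrelevant")
  if (any(bad))
    stop(who, ": labels must be 'relevant' or 'irrelevant'", call. = FALSE)
  if (anyDuplicated(ids)) {
    for (id in unique(ids[duplicated(ids)]))
      if (length(unique(labs[ids == id])) > 1L)
        stop(who, ": record ", id,
             " labelled twice with conflicting values", call. = FALSE)
    keep <- !duplicated(ids)
    ids <- ids[keep]; labs <- labs[keep]
  }
  stats::setNames(labs, ids)
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("<reconciliation> ", length(x$agreed), " agreed, ",
      length(x$conflicts), " conflicts", sep = "")
  if (length(x$only_a) || length(x$only_b))
    cat(", singly screened: ", length(x$only_a), " (A only), ",
        length(x$only_b), " (B only)", sep = "")
  cat("\n")
  invisible(x)
}

#' Fold adjudicated decisions into a reconciliation
#'
#' @param reconciliation Result of [reconcile_labels()].
#' @param adjudication Data frame (`record_id`, `label`) or named character
#'   vector carrying the third reviewer's decision for every conflict.
#' @return A complete [gold_standard] over agreed plus adjudicated ids.
#' @export
apply_adjudication <- function(reconciliation, adjudication) {
  stopifnot(inherits(reconciliation, "reconciliation"))
  adj <- .reviewer_map(adjudication, "adjudication")
  missing <- setdiff(reconciliation$conflicts, names(adj))
  if (length(missing))
    stop("conflicts without adjudication: ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(adj), reconciliation$conflicts)
  if (length(extra))
    stop("adjudication for non-conflicted ids: ",
         paste(extra, collapse = ", "), call. = FALSE)
  gold_standard(c(unclass(reconciliation$agreed),
                  adj[reconciliation$conflicts]))
}
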