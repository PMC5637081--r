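#' Boolean search-filter expressions in Ovid MEDLINE syntax
#'
#' A search filter (hedge) is a Boolean expression over field-tagged,
#' optionally truncated terms, e.g. `paramedic*.tw OR Ambulances.sh`.
#' Supported field tags: `.tw` (text word: title or abstract) and `.sh`
#' (subject heading: an assigned MeSH heading, unexploded). A trailing `*`
#' on the final token of a term marks truncation (prefix match within one
#' document token). Operators `OR`, `AND` and unary `NOT` are
#' case-insensitive, with precedence `NOT > AND > OR` and left association;
#' parentheses group.
#'
#' @param text Term text (one or more tokens); case-folded on construction.
#' @param field `"tw"` or `"sh"`.
#' @param truncated Logical: trailing-`*` truncation on the final token.
#' @return `filter_term()`: a leaf node of class
#'   `c("filter_term", "filter_expr")`.
#' @name filter_lang
#' @export
filter_term <- function(text, field = c("tw", "sh"), truncated = FALSE) {
  field <- match.arg(field)
  text <- tolower(trimws(gsub("[[:space:]]+", " ", text)))
  if (!nzchar(text)) stop("term text must be non-empty", call. = FALSE)
  if (grepl("\\*", text))
    stop("'*' must appear only as the final character of the term ",
         "(use truncated = TRUE)", call. = FALSE)
  structure(list(text = text, field = field, truncated = isTRUE(truncated)),
            class = c("filter_term", "filter_expr"))
}

.filter_node <- function(op, children) {
  if (op %in% c("OR", "AND") && length(children) < 2L)
    stop(op, " node needs at least 2 children", call. = FALSE)
  if (op == "NOT" && length(children) != 1L)
    stop("NOT node needs exactly 1 child", call. = FALSE)
  structure(list(op = op, children = children),
            class = c("filter_node", "filter_expr"))
}

#' Combine filter expressions
#'
#' `or_filter()`, `and_filter()` and `not_filter()` build expression nodes
#' programmatically; same-operator children are flattened so `OR(OR(a,b),c)`
#' and `OR(a,b,c)` are one structure, matching what [parse_filter()]
#' produces for left-associated chains.
#'
#' @param ... Filter expressions ([filter_term] or nodes).
#' @param x A filter expression.
#' @return A `filter_expr`.
#' @export
or_filter <- function(...) .assoc_node("OR", list(...))

#' @rdname or_filter
#' @export
and_filter <- function(...) .assoc_node("AND", list(...))

#' @rdname or_filter
#' @export
not_filter <- function(x) {
  stopifnot(inherits(x, "filter_expr"))
  .filter_node("NOT", list(x))
}

.assoc_node <- function(op, children) {
  for (ch in children)
    if (!inherits(ch, "filter_expr"))
      stop("all arguments must be filter expressions", call. = FALSE)
  flat <- list()
  for (ch in children) {
    if (inherits(ch, "filter_node") && ch$op == op)
      flat <- c(flat, ch$children)
    else flat <- c(flat, list(ch))
  }
  if (length(flat) == 1L) return(flat[[1L]])
  .filter_node(op, flat)
}

#' @export
print.filter_expr <- function(x, ...) {
  cat("<filter> ", serialize_filter(x), "\n", sep = "")
  invisible(x)
}

#' Leaf terms of a filter expression
#' @param expr A `filter_expr`.
#' @return List of [filter_term] leaves, left-to-right.
#' @export
filter_terms <- function(expr) {
  stopifnot(inherits(expr, "filter_expr"))
  if (inherits(expr, "filter_term")) return(list(expr))
  do.call(c, lapply(expr$children, filter_terms))
}

## ---- lexer -----------------------------------------------------------------

.lex_filter <- function(text) {
  toks <- list(); i <- 1L; n <- nchar(text)
  push <- function(type, val, pos)
    toks[[length(toks) + 1L]] <<- list(type = type, text = val, pos = pos)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch == "(") { push("LPAREN", "(", i); i <- i + 1L; next }
    if (ch == ")") { push("RPAREN", ")", i); i <- i + 1L; next }
    m <- regexpr("^[^()[:space:]]+", substr(text, i, n))
    word <- regmatches(substr(text, i, n), m)
    up <- toupper(word)
    if (up %in% c("OR", "AND", "NOT")) push(paste0("OP_", up), up, i)
    else push("WORD", word, i)
    i <- i + nchar(word)
  }
  toks
}

.parse_error <- function(msg, pos) {
  stop(sprintf("filter parse error at position %d: %s", pos, msg),
       call. = FALSE)
}

## ---- recursive-descent parser ---------------------------------------------

#' Parse an Ovid-syntax filter string
#'
#' Grammar: atoms are terms with an optional `.tw`/`.sh` field tag on the
#' final word (untagged atoms default to `.tw`); multi-word atoms are
#' allowed (words accumulate until the tagged word); `*` is permitted only
#' as the final character of an atom's last word; operators `OR`/`AND`/
#' unary `NOT` (case-insensitive) with precedence `NOT > AND > OR`, left
#' association, and parentheses. Unknown field tags, dangling operators and
#' unbalanced parentheses are parse errors that report a character
#' position.
#'
#' @param text Ovid-syntax filter string.
#' @return A `filter_expr` tree.
#' @export
#' @examples
#' parse_filter("paramedic*.tw OR ems.tw")
parse_filter <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    .parse_error("empty filter string", 1L)
  toks <- .lex_filter(text)
  state <- new.env(parent = emptyenv())
  state$toks <- toks; state$i <- 1L; state$end <- nchar(text) + 1L
  expr <- .parse_or(state)
  if (state$i <= length(state$toks)) {
    t <- state$toks[[state$i]]
    .parse_error(paste0("unexpected '", t$text, "'"), t$pos)
  }
  expr
}

.peek <- function(s) if (s$i <= length(s$toks)) s$toks[[s$i]] else NULL
.advance <- function(s) { t <- s$toks[[s$i]]; s$i <- s$i + 1L; t }

.parse_or <- function(s) {
  parts <- list(.parse_and(s))
  while (!is.null(t <- .peek(s)) && t$type == "OP_OR") {
    .advance(s)
    parts <- c(parts, list(.parse_and(s)))
  }
  if (length(parts) == 1L) parts[[1L]] else .filter_node("OR", parts)
}

.parse_and <- function(s) {
  parts <- list(.parse_not(s))
  while (!is.null(t <- .peek(s)) && t$type == "OP_AND") {
    .advance(s)
    parts <- c(parts, list(.parse_not(s)))
  }
  if (length(parts) == 1L) parts[[1L]] else .filter_node("AND", parts)
}

.parse_not <- function(s) {
  t <- .peek(s)
  if (!is.null(t) && t$type == "OP_NOT") {
    .advance(s)
    child <- .parse_not(s)
    return(.filter_node("NOT", list(child)))
  }
  .parse_atom(s)
}

.parse_atom <- function(s) {
  t <- .peek(s)
  if (is.null(t)) .parse_error("dangling operator: expected a term", s$end)
  if (t$type == "LPAREN") {
    .advance(s)
    expr <- .parse_or(s)
    close <- .peek(s)
    if (is.null(close) || close$type != "RPAREN")
      .parse_error("unbalanced parentheses: expected ')'",
                   if (is.null(close)) s$end else close$pos)
    .advance(s)
    return(expr)
  }
  if (t$type != "WORD")
    .parse_error(paste0("expected a term, found '", t$text, "'"), t$pos)
  words <- character(0); pos <- t$pos
  repeat {
    w <- .peek(s)
    if (is.null(w) || w$type != "WORD") {
      if (length(words) == 0L)
        .parse_error("expected a term", if (is.null(w)) s$end else w$pos)
      # untagged atom: default field .tw
      return(.make_term(words, "tw", pos))
    }
    .advance(s)
    tagm <- regexpr("\\.([A-Za-z]{1,4})$", w$text)
    if (tagm > 0L) {
      tag <- tolower(substr(w$text, tagm + 1L, nchar(w$text)))
      if (!tag %in% c("tw", "sh"))
        .parse_error(paste0("unknown field tag '.", tag, "'"),
                     w$pos + tagm - 1L)
      words <- c(words, substr(w$text, 1L, tagm - 1L))
      return(.make_term(words, tag, pos))
    }
    words <- c(words, w$text)
  }
}

.make_term <- function(words, field, pos) {
  truncated <- FALSE
  last <- words[length(words)]
  stars <- gregexpr("\\*", paste(words, collapse = " "))[[1L]]
  if (stars[1L] > 0L) {
    atom <- paste(words, collapse = " ")
    if (length(stars) > 1L || stars[1L] != nchar(atom))
      .parse_error("'*' is only allowed as the final character of a term",
                   pos)
    truncated <- TRUE
    words[length(words)] <- sub("\\*$", "", last)
  }
  if (!nzchar(trimws(paste(words, collapse = " "))))
    .parse_error("empty term", pos)
  filter_term(paste(words, collapse = " "), field, truncated)
}

## ---- serializer ------------------------------------------------------------

.op_prec <- c(OR = 1L, AND = 2L, NOT = 3L)

#' Serialize a filter expression to canonical Ovid syntax
#'
#' Single spaces, upper-case operators, lower-case term text, parentheses
#' only where precedence requires them. `parse_filter(serialize_filter(e))`
#' is structurally identical to `e`.
#'
#' @param expr A `filter_expr`.
#' @return Ovid-syntax string.
#' @export
serialize_filter <- function(expr) {
  stopifnot(inherits(expr, "filter_expr"))
  if (inherits(expr, "filter_term"))
    return(paste0(expr$text, if (expr$truncated) "*", ".", expr$field))
  prec <- .op_prec[[expr$op]]
  wrap <- function(child) {
    s <- serialize_filter(child)
    if (inherits(child, "filter_node") && .op_prec[[child$op]] < prec)
      paste0("(", s, ")") else s
  }
  if (expr$op == "NOT") {
    child <- expr$children[[1L]]
    s <- serialize_filter(child)
    if (inherits(child, "filter_node") && .op_prec[[child$op]] <= prec &&
        child$op != "NOT")
      s <- paste0("(", s, ")")
    return(paste0("NOT ", s))
  }
  paste(vapply(expr$children, wrap, character(1)),
        collapse = paste0(" ", expr$op, " "))
}

## ---- matching --------------------------------------------------------------

#' Tokenize free text for filter matching
#'
#' Case-folds and splits on every non-alphanumeric character, so hyphenated
#' forms split (`pre-hospital` -> `pre`, `hospital`) while the fused
#' spelling `prehospital` stays one token — the reason published filters
#' carry both spellings as separate terms. Digits are kept.
#'
#' @param text Character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize_text <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1L]]
  toks[nzchar(toks)]
}

.strip_qualifier <- function(heading) {
  tolower(trimws(sub("/.*$", "", sub("^\\*", "", heading))))
}

# normalized single-space token string, used for regex phrase search
.norm_field <- function(text) paste(tokenize_text(text), collapse = " ")

.term_pattern <- function(term) {
  toks <- tokenize_text(term$text)
  if (length(toks) == 0L) return(NULL)
  body <- paste(toks, collapse = " ")
  if (term$truncated) body <- paste0(body, "[a-z0-9]*")
  paste0("(^|\\s)", body, "(\\s|$)")
}

#' Match a single term against a record
#'
#' `.tw` terms match when the term's token sequence occurs contiguously in
#' the tokenised title or the tokenised abstract. `.sh` terms match when
#' the term equals (case-insensitively) any assigned MeSH heading after
#' stripping a `/qualifier` suffix (unexploded matching). Truncation makes
#' the final token a prefix match against a single document token;
#' non-truncated tokens match whole tokens only.
#'
#' @param term A [filter_term].
#' @param record A [bib_record].
#' @return Logical.
#' @export
match_term <- function(term, record) {
  stopifnot(inherits(term, "filter_term"), inherits(record, "bib_record"))
  if (term$field == "sh") {
    if (length(record$mesh_headings) == 0L) return(FALSE)
    headings <- vapply(record$mesh_headings, .strip_qualifier, character(1))
    if (term$truncated) return(any(startsWith(headings, term$text)))
    return(term$text %in% headings)
  }
  pat <- .term_pattern(term)
  if (is.null(pat)) return(FALSE)
  grepl(pat, .norm_field(record$title), perl = TRUE) ||
    grepl(pat, .norm_field(record$abstract), perl = TRUE)
}

#' Evaluate a Boolean filter against one record
#'
#' Standard Boolean semantics over [match_term()] leaf values.
#'
#' @param expr A `filter_expr`.
#' @param record A [bib_record].
#' @return Logical.
#' @export
evaluate_filter <- function(expr, record) {
  stopifnot(inherits(expr, "filter_expr"))
  if (inherits(expr, "filter_term")) return(match_term(expr, record))
  vals <- vapply(expr$children, evaluate_filter, logical(1), record = record)
  switch(expr$op, OR = any(vals), AND = all(vals), NOT = !vals[1L])
}

#' Run a filter over a corpus
#'
#' @param expr A `filter_expr`.
#' @param corpus A [corpus].
#' @return Character vector (a set) of the record ids for which
#'   [evaluate_filter()] is `TRUE`.
#' @export
retrieve <- function(expr, corpus) {
  stopifnot(inherits(expr, "filter_expr"), inherits(corpus, "corpus"))
  hits <- vapply(corpus$records, function(r) evaluate_filter(expr, r),
                 logical(1))
  unname(record_ids(corpus)[hits])
}
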