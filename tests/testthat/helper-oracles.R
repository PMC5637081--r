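# Shared fixtures and independent oracles for the test suite.

rec <- function(id, title = "", abstract = "lorem ipsum", mesh = character(),
                year = 2012L) {
  bib_record(id, title = title, abstract = abstract, mesh_headings = mesh,
             year = year)
}

# Six-record fixture exercising titles, abstracts, MeSH qualifiers,
# hyphenation and truncation edge cases.
tiny_corpus <- function() {
  corpus(list(
    rec("1", "Paramedics respond faster", "a study of ems analgesia",
        mesh = "Emergency Medical Technicians/education"),
    rec("2", "Emsworth community care", "general practice report"),
    rec("3", "Prehospital care systems", "review of pre-hospital triage"),
    rec("4", "Hospital admissions", "routine inpatient data",
        mesh = "Ambulances"),
    rec("5", "Air ambulance dispatch", "helicopter emergency medical services",
        mesh = c("Air Ambulances/statistics", "Emergency Medical Services")),
    rec("6", "Cardiology outcomes", "stent trial results")))
}

tiny_gold <- function() {
  gold_standard(c(`1` = "relevant", `2` = "irrelevant", `3` = "relevant",
                  `4` = "irrelevant", `5` = "relevant", `6` = "irrelevant"))
}

# ---- independent regex-free matching oracle --------------------------------
# Pure token-loop scan; deliberately shares no code with match_term(), which
# works on a regex over a normalised token string.

oracle_tokens <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  out <- character(0); cur <- ""
  for (ch in strsplit(tolower(text), "")[[1L]]) {
    if (grepl("[a-z0-9]", ch)) {
      cur <- paste0(cur, ch)
    } else if (nzchar(cur)) {
      out <- c(out, cur); cur <- ""
    }
  }
  if (nzchar(cur)) out <- c(out, cur)
  out
}

oracle_phrase_in <- function(phrase_toks, doc_toks, truncated) {
  k <- length(phrase_toks)
  if (k == 0L || length(doc_toks) < k) return(FALSE)
  for (start in seq_len(length(doc_toks) - k + 1L)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      dt <- doc_toks[start + j - 1L]
      pt <- phrase_toks[j]
      hit <- if (j == k && truncated)
        nchar(dt) >= nchar(pt) && substr(dt, 1L, nchar(pt)) == pt
      else dt == pt
      if (!hit) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

oracle_match_term <- function(term, record) {
  if (term$field == "sh") {
    for (h in record$mesh_headings) {
      h <- tolower(trimws(strsplit(sub("^\\*", "", h), "/")[[1L]][1L]))
      if (term$truncated) {
        if (nchar(h) >= nchar(term$text) &&
            substr(h, 1L, nchar(term$text)) == term$text) return(TRUE)
      } else if (h == term$text) return(TRUE)
    }
    return(FALSE)
  }
  toks <- oracle_tokens(term$text)
  oracle_phrase_in(toks, oracle_tokens(record$title), term$truncated) ||
    oracle_phrase_in(toks, oracle_tokens(record$abstract), term$truncated)
}

oracle_evaluate <- function(expr, record) {
  if (inherits(expr, "filter_term")) return(oracle_match_term(expr, record))
  vals <- vapply(expr$children, oracle_evaluate, logical(1), record = record)
  switch(expr$op, OR = any(vals), AND = all(vals), NOT = !vals[1L])
}

oracle_retrieve <- function(expr, corp) {
  ids <- record_ids(corp)
  ids[vapply(corp$records, function(r) oracle_evaluate(expr, r), logical(1))]
}

# ---- random generators for property tests ----------------------------------

random_pool <- function(n_terms, prefix = "term") {
  lapply(seq_len(n_terms), function(i) {
    field <- sample(c("tw", "sh"), 1L)
    filter_term(paste0(prefix, letters[i]), field,
                truncated = field == "tw" && stats::runif(1) < 0.3)
  })
}

random_profiles <- function(pool) {
  lapply(pool, function(t)
    term_profile(t, p_relevant = stats::runif(1, 0.05, 0.9),
                 p_irrelevant = stats::runif(1, 0, 0.3)))
}

random_expr <- function(pool, depth = 2L) {
  if (depth == 0L || stats::runif(1) < 0.4)
    return(pool[[sample.int(length(pool), 1L)]])
  op <- sample(c("or", "and", "not"), 1L, prob = c(0.45, 0.35, 0.2))
  if (op == "not") return(not_filter(random_expr(pool, depth - 1L)))
  kids <- lapply(seq_len(sample(2:3, 1L)), function(i)
    random_expr(pool, depth - 1L))
  if (op == "or") do.call(or_filter, kids) else do.call(and_filter, kids)
}
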