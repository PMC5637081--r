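#' Term occurrence profile for synthetic corpora
#'
#' Describes how often a candidate term appears in relevant versus
#' irrelevant records, and where it is placed. Text-word (`.tw`) terms are
#' inserted into the title or abstract; subject-heading (`.sh`) terms only
#' ever appear as MeSH headings.
#'
#' @param term A [filter_term] (or an Ovid string parsed as one term).
#' @param p_relevant Probability the term occurs in a relevant record.
#' @param p_irrelevant Probability the term occurs in an irrelevant record.
#' @param placement Named numeric weights over `c(title, abstract)` for
#'   `.tw` terms; ignored for `.sh` terms (always `mesh`).
#' @return A list of class `term_profile`.
#' @export
term_profile <- function(term, p_relevant, p_irrelevant,
                         placement = c(title = 0.3, abstract = 0.7)) {
  if (is.character(term)) term <- parse_filter(term)
  if (!inherits(term, "filter_term"))
    stop("term must be a single filter_term", call. = FALSE)
  stopifnot(p_relevant >= 0, p_relevant <= 1,
            p_irrelevant >= 0, p_irrelevant <= 1)
  if (term$field == "sh") {
    placement <- c(mesh = 1)
  } else {
    placement <- placement[names(placement) %in% c("title", "abstract")]
    if (length(placement) == 0L || sum(placement) <= 0)
      stop("tw terms need positive weights over title/abstract",
           call. = FALSE)
    placement <- placement / sum(placement)
  }
  structure(list(term = term, p_relevant = p_relevant,
                 p_irrelevant = p_irrelevant, placement = placement),
            class = "term_profile")
}

#' Specification of a synthetic labelled corpus
#'
#' Defines the study conditions a generated reference set emulates: the
#' two class sizes (defaults reproduce a 2102-record screened set with
#' 20.5% prevalence of relevant records), the term occurrence profiles,
#' and a mandatory seed for exact reproducibility.
#'
#' @param n_relevant,n_irrelevant Class sizes (non-negative).
#' @param profiles List of [term_profile]s; may be empty.
#' @param filler_vocabulary_size Size of the neutral vocabulary used to pad
#'   titles and abstracts. Filler words all start with the reserved stem
#'   `"vx"`, so they can never collide with ordinary candidate terms even
#'   under truncation; a profile term starting with `"vx"` is an error at
#'   generation time.
#' @param seed Integer RNG seed (required).
#' @return A list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_relevant = 431L, n_irrelevant = 1671L,
                        profiles = list(), filler_vocabulary_size = 100L,
                        seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility",
                          call. = FALSE)
  stopifnot(n_relevant >= 0, n_irrelevant >= 0, filler_vocabulary_size >= 1)
  for (p in profiles)
    if (!inherits(p, "term_profile"))
      stop("profiles must be term_profile objects", call. = FALSE)
  structure(list(n_relevant = as.integer(n_relevant),
                 n_irrelevant = as.integer(n_irrelevant),
                 profiles = profiles,
                 filler_vocabulary_size = as.integer(filler_vocabulary_size),
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

.filler_vocab <- function(n) sprintf("vx%03dq", seq_len(n))

.synthetic_journals <- paste("Synthetic Journal", LETTERS[1:6])

#' Generate a labelled MEDLINE-like corpus
#'
#' Emits `n_relevant + n_irrelevant` records with sequential synthetic ids.
#' For each record, every profile term is independently inserted with the
#' class-appropriate probability at a placement drawn from its weights
#' (`.tw` terms as a contiguous token run inside the title or abstract,
#' `.sh` terms as a MeSH heading, sometimes with a `/qualifier` to exercise
#' qualifier stripping). Filler tokens from a reserved neutral vocabulary
#' guarantee non-empty titles and abstracts. The generation is fully
#' reproducible from the spec's seed: the same spec yields byte-identical
#' [write_medline()] output.
#'
#' Under this occurrence model a single-term filter has expected
#' sensitivity `p_relevant` and expected specificity `1 - p_irrelevant`
#' ([expected_single_term_performance()]), which is exact provided the
#' profile terms share no tokens (insertions of one term can then never
#' complete a phrase of another).
#'
#' @param spec A [corpus_spec].
#' @return List with elements `corpus` (a [corpus]) and `gold` (a
#'   [gold_standard]); prevalence is exact by construction.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  vocab <- .filler_vocab(spec$filler_vocabulary_size)
  for (p in spec$profiles) {
    toks <- tokenize_text(p$term$text)
    last <- toks[length(toks)]
    collides <- any(toks %in% vocab) ||
      (p$term$truncated && any(startsWith(vocab, last)))
    if (collides)
      stop("profile term '", p$term$text,
           "' collides with the filler vocabulary under truncation",
           call. = FALSE)
  }
  n <- spec$n_relevant + spec$n_irrelevant
  labels <- rep(c("relevant", "irrelevant"),
                c(spec$n_relevant, spec$n_irrelevant))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    title_toks <- sample(vocab, sample(4:8, 1L), replace = TRUE)
    abstract_toks <- sample(vocab, sample(15:30, 1L), replace = TRUE)
    mesh <- character(0)
    relevant <- labels[i] == "relevant"
    for (p in spec$profiles) {
      prob <- if (relevant) p$p_relevant else p$p_irrelevant
      if (stats::runif(1) >= prob) next
      surface <- p$term$text
      where <- names(p$placement)[
        sample.int(length(p$placement), 1L, prob = p$placement)]
      if (where == "mesh") {
        heading <- surface
        if (stats::runif(1) < 0.3) heading <- paste0(heading, "/methods")
        mesh <- c(mesh, heading)
      } else if (where == "title") {
        pos <- sample.int(length(title_toks) + 1L, 1L) - 1L
        title_toks <- append(title_toks, surface, after = pos)
      } else {
        pos <- sample.int(length(abstract_toks) + 1L, 1L) - 1L
        abstract_toks <- append(abstract_toks, surface, after = pos)
      }
    }
    records[[i]] <- bib_record(
      record_id = sprintf("SYN%05d", i),
      title = paste(title_toks, collapse = " "),
      abstract = paste(abstract_toks, collapse = " "),
      mesh_headings = mesh,
      journal = sample(.synthetic_journals, 1L),
      year = sample(c(2006L, 2009L, 2012L, 2015L), 1L))
  }
  corp <- corpus(records,
                 provenance = sprintf(
                   "generate_corpus(seed = %d, %d relevant + %d irrelevant)",
                   spec$seed, spec$n_relevant, spec$n_irrelevant))
  gold <- gold_standard(stats::setNames(labels, record_ids(corp)))
  list(corpus = corp, gold = gold)
}

#' Closed-form expected performance of a single-term filter
#'
#' Under the independent-occurrence generation model a term that appears in
#' relevant records with probability `p_relevant` and in irrelevant records
#' with probability `p_irrelevant` yields, in expectation, sensitivity
#' `p_relevant` and specificity `1 - p_irrelevant`.
#'
#' @param profile A [term_profile].
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @export
expected_single_term_performance <- function(profile) {
  stopifnot(inherits(profile, "term_profile"))
  c(sensitivity = profile$p_relevant,
    specificity = 1 - profile$p_irrelevant)
}

#' Write a generated corpus to disk
#'
#' Convenience wrapper emitting exactly what the reading side consumes: a
#' MEDLINE tagged file (`<prefix>.medline`) and a label CSV
#' (`<prefix>_labels.csv`).
#'
#' @param generated Result of [generate_corpus()].
#' @param prefix Output path prefix.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_generated_corpus <- function(generated, prefix) {
  stopifnot(is.list(generated), inherits(generated$corpus, "corpus"),
            inherits(generated$gold, "gold_standard"))
  medline_path <- paste0(prefix, ".medline")
  labels_path <- paste0(prefix, "_labels.csv")
  write_medline(generated$corpus, medline_path)
  write_labels(generated$gold, labels_path)
  invisible(c(medline_path, labels_path))
}
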