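#' Construct a bibliographic record
#'
#' A `bib_record` holds the fields of one MEDLINE-indexed article that matter
#' for filter evaluation: the unique identifier (PMID where available), the
#' free-text title and abstract, the assigned MeSH headings (each optionally
#' carrying a `/qualifier` suffix), and light metadata (journal, year).
#'
#' @param record_id Non-empty identifier string (PMID when available).
#' @param title Title text.
#' @param abstract Abstract text; may be empty.
#' @param mesh_headings Character vector of MeSH headings, possibly with
#'   `/qualifier` suffixes. Empty headings are dropped after trimming.
#' @param journal Journal title, or `NA`.
#' @param year Integer publication year, or `NA`.
#'
#' @return An object of class `bib_record`.
#' @export
#' @examples
#' bib_record("1", "Paramedic pain relief.", "Study of EMS analgesia.",
#'            mesh_headings = "Emergency Medical Technicians/education")
bib_record <- function(record_id, title = "", abstract = "",
                       mesh_headings = character(), journal = NA_character_,
                       year = NA_integer_) {
  record_id <- as.character(record_id)
  if (length(record_id) != 1L || is.na(record_id) || !nzchar(trimws(record_id)))
    stop("record_id must be a single non-empty string", call. = FALSE)
  mesh_headings <- trimws(as.character(mesh_headings))
  mesh_headings <- mesh_headings[nzchar(mesh_headings)]
  structure(
    list(record_id = record_id,
         title = as.character(title)[1L],
         abstract = as.character(abstract)[1L],
         mesh_headings = mesh_headings,
         journal = as.character(journal)[1L],
         year = suppressWarnings(as.integer(year)[1L])),
    class = "bib_record")
}

#' @export
print.bib_record <- function(x, ...) {
  cat("<bib_record ", x$record_id, "> ", x$title, "\n", sep = "")
  invisible(x)
}

#' Construct a corpus of bibliographic records
#'
#' @param records List of [bib_record] objects with unique `record_id`s.
#' @param provenance Free-text note on where the records came from and what
#'   preparation steps were applied.
#'
#' @return An object of class `corpus`: a list with elements `records` (named
#'   by record id) and `provenance`.
#' @export
corpus <- function(records = list(), provenance = "") {
  stopifnot(is.list(records))
  for (r in records)
    if (!inherits(r, "bib_record"))
      stop("all elements of 'records' must be bib_record objects", call. = FALSE)
  ids <- vapply(records, `[[`, character(1), "record_id")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate record_id in corpus: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  names(records) <- ids
  structure(list(records = records, provenance = as.character(provenance)[1L]),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat("<corpus> ", length(x$records), " records\n", sep = "")
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
length.corpus <- function(x) length(x$records)

#' Record ids of a corpus
#' @param x A [corpus].
#' @return Character vector of record ids.
#' @export
record_ids <- function(x) {
  stopifnot(inherits(x, "corpus"))
  names(x$records)
}

# MEDLINE tagged dialect: "TAG - value" with the tag padded to 4 characters,
# continuation lines indented; records separated by blank lines.
.medline_tags <- c(id = "PMID", title = "TI", abstract = "AB", mesh = "MH",
                   journal_full = "JT", journal_abbrev = "TA", date = "DP")

#' Read a MEDLINE tagged file into a corpus
#'
#' Parses the standard MEDLINE/PubMed tagged export dialect (as also written
#' by `.nbib` files): a 4-character tag field, a dash, a space, then the
#' value, with continuation lines indented and records separated by blank
#' lines. Tags used: `PMID`, `TI`, `AB`, `MH` (one heading per line),
#' `JT`/`TA`, `DP`. Multi-line titles and abstracts are joined with single
#' spaces; the year is taken as the first 4-digit run in `DP`. Leading `*`
#' (major-topic marker) on MeSH headings is stripped.
#'
#' A block without a `PMID` is rejected with a warning, not an error; two
#' blocks sharing a PMID raise an error naming the PMID.
#'
#' @param path Path to a MEDLINE tagged text file.
#' @return A [corpus].
#' @export
read_medline <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  # split into blank-line-separated blocks
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(blank)
  blocks <- split(lines[!blank], grp[!blank])
  records <- list()
  for (block in blocks) {
    rec <- .parse_medline_block(block)
    if (is.null(rec)) next
    if (rec$record_id %in% names(records))
      stop("duplicate PMID in file: ", rec$record_id, call. = FALSE)
    records[[rec$record_id]] <- rec
  }
  corpus(unname(records), provenance = paste0("read_medline(", path, ")"))
}

.parse_medline_block <- function(block) {
  is_tagline <- grepl("^[A-Z0-9]{1,4}\\s*- ", block)
  # fold continuation lines into the preceding tag line
  idx <- cumsum(is_tagline)
  if (any(idx == 0L)) {
    warning("MEDLINE block starts with a continuation line; skipped",
            call. = FALSE)
    return(NULL)
  }
  tags <- sub("\\s*- .*$", "", block[is_tagline])
  vals <- vapply(split(block, idx), function(ls) {
    ls[1L] <- sub("^[A-Z0-9]{1,4}\\s*- ", "", ls[1L])
    paste(trimws(ls), collapse = " ")
  }, character(1))
  pmid <- vals[tags == "PMID"]
  if (length(pmid) == 0L || !nzchar(trimws(pmid[1L]))) {
    warning("MEDLINE block without PMID skipped (first line: ",
            substr(block[1L], 1L, 40L), ")", call. = FALSE)
    return(NULL)
  }
  journal <- vals[tags == "JT"]
  if (length(journal) == 0L) journal <- vals[tags == "TA"]
  dp <- vals[tags == "DP"]
  year <- if (length(dp) && grepl("\\d{4}", dp[1L]))
    as.integer(regmatches(dp[1L], regexpr("\\d{4}", dp[1L]))) else NA_integer_
  mh <- sub("^\\*", "", vals[tags == "MH"])
  bib_record(
    record_id = trimws(pmid[1L]),
    title = if (any(tags == "TI")) vals[tags == "TI"][1L] else "",
    abstract = if (any(tags == "AB")) vals[tags == "AB"][1L] else "",
    mesh_headings = mh,
    journal = if (length(journal)) journal[1L] else NA_character_,
    year = year)
}

#' Write a corpus as a MEDLINE tagged file
#'
#' Emits the tags `read_medline()` consumes (`PMID`, `TI`, `AB`, `MH`, `JT`,
#' `DP`), one value per line without wrapping, so that reading the file back
#' reproduces record ids, titles, abstracts and MeSH heading lists exactly.
#'
#' @param x A [corpus].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_medline <- function(x, path) {
  stopifnot(inherits(x, "corpus"))
  fmt <- function(tag, value) sprintf("%-4s- %s", tag, value)
  out <- character(0)
  for (rec in x$records) {
    lines <- fmt("PMID", rec$record_id)
    if (nzchar(rec$title)) lines <- c(lines, fmt("TI", rec$title))
    if (nzchar(rec$abstract)) lines <- c(lines, fmt("AB", rec$abstract))
    if (!is.na(rec$journal) && nzchar(rec$journal))
      lines <- c(lines, fmt("JT", rec$journal))
    if (!is.na(rec$year)) lines <- c(lines, fmt("DP", rec$year))
    for (mh in rec$mesh_headings) lines <- c(lines, fmt("MH", mh))
    out <- c(out, lines, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Prepare a retrieval set for screening
#'
#' Applies the standard reference-set preparation steps before hand
#' screening: duplicate records are removed (primary key: record id —
#' already unique within a corpus; secondary key: case-folded,
#' punctuation-stripped title plus year, keeping the first occurrence), and
#' records whose abstract is empty or whitespace-only are removed. The
#' counts of each exclusion reason are attached to the result.
#'
#' The operation is idempotent: applying it to its own output changes
#' nothing.
#'
#' @param x A [corpus].
#' @return A new [corpus] with attribute `exclusions`, a named integer
#'   vector with elements `duplicate` and `no_abstract`.
#' @export
prepare_retrieval_set <- function(x) {
  stopifnot(inherits(x, "corpus"))
  recs <- x$records
  n_dup <- 0L
  if (length(recs)) {
    key <- vapply(recs, function(r) {
      t <- gsub("[^a-z0-9 ]+", "", gsub("[[:space:]]+", " ", tolower(r$title)))
      paste0(trimws(t), "|", r$year)
    }, character(1))
    dup <- duplicated(key)
    n_dup <- sum(dup)
    recs <- recs[!dup]
  }
  no_ab <- vapply(recs, function(r) !nzchar(trimws(r$abstract)), logical(1))
  n_noab <- sum(no_ab)
  recs <- recs[!no_ab]
  out <- corpus(unname(recs),
                provenance = paste0(x$provenance,
                                    "; prepare_retrieval_set: removed ",
                                    n_dup, " duplicate, ", n_noab,
                                    " without abstract"))
  attr(out, "exclusions") <- c(duplicate = n_dup, no_abstract = n_noab)
  out
}
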