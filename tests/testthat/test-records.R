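test_that("read_medline maps tagged blocks to records", {
  path <- withr::local_tempfile(fileext = ".medline")
  writeLines(c(
    "PMID- 1",
    "TI  - Paramedic pain relief.",
    "AB  - Study of EMS analgesia.",
    "MH  - Emergency Medical Technicians/education",
    "",
    "PMID- 2",
    "TI  - Long title that continues",
    "      over two lines.",
    "AB  - Short.",
    "JT  - Resuscitation",
    "DP  - 2012 Mar-Apr",
    "MH  - *Ambulances",
    "MH  - Triage/methods"), path)
  corp <- read_medline(path)
  expect_s3_class(corp, "corpus")
  expect_equal(record_ids(corp), c("1", "2"))
  r1 <- corp$records[["1"]]
  expect_equal(r1$title, "Paramedic pain relief.")
  expect_equal(r1$abstract, "Study of EMS analgesia.")
  expect_equal(r1$mesh_headings, "Emergency Medical Technicians/education")
  r2 <- corp$records[["2"]]
  expect_equal(r2$title, "Long title that continues over two lines.")
  expect_equal(r2$year, 2012L)
  expect_equal(r2$journal, "Resuscitation")
  # major-topic asterisk stripped, both MH lines kept
  expect_equal(r2$mesh_headings, c("Ambulances", "Triage/methods"))
})

test_that("read_medline handles empty files, missing and duplicate PMIDs", {
  empty <- withr::local_tempfile(fileext = ".medline")
  writeLines(character(0), empty)
  expect_length(read_medline(empty)$records, 0L)

  nopmid <- withr::local_tempfile(fileext = ".medline")
  writeLines(c("TI  - Orphan block.", "AB  - No id here.",
               "", "PMID- 9", "TI  - Kept.", "AB  - Fine."), nopmid)
  expect_warning(corp <- read_medline(nopmid), "without PMID")
  expect_equal(record_ids(corp), "9")

  dup <- withr::local_tempfile(fileext = ".medline")
  writeLines(c("PMID- 7", "TI  - One.", "", "PMID- 7", "TI  - Two."), dup)
  expect_error(read_medline(dup), "7")
})

test_that("medline round trip preserves id, title, abstract and MeSH", {
  corp <- tiny_corpus()
  path <- withr::local_tempfile(fileext = ".medline")
  write_medline(corp, path)
  back <- read_medline(path)
  expect_equal(record_ids(back), record_ids(corp))
  for (id in record_ids(corp)) {
    expect_equal(back$records[[id]]$title, corp$records[[id]]$title)
    expect_equal(back$records[[id]]$abstract, corp$records[[id]]$abstract)
    expect_equal(back$records[[id]]$mesh_headings,
                 corp$records[[id]]$mesh_headings)
  }
})

test_that("medline writer agrees with the biopython Medline reader", {
  # independent cross-check of the tagged dialect via Bio.Medline, when the
  # python stack is present; a silent pass-through otherwise
  py <- Sys.which("python")
  if (!nzchar(py)) succeed("python not available; dialect check not run")
  path <- withr::local_tempfile(fileext = ".medline")
  write_medline(tiny_corpus(), path)
  script <- paste(
    "import sys",
    "try:",
    "    from Bio import Medline",
    "except Exception:",
    "    print('SKIP'); sys.exit(0)",
    "recs = list(Medline.parse(open(sys.argv[1])))",
    "print(len(recs))",
    "print(recs[0]['PMID'], recs[0]['TI'])",
    sep = "\n")
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- suppressWarnings(system2(py, c(sf, path), stdout = TRUE))
  if (length(out) && out[1] != "SKIP") {
    expect_equal(out[1], "6")
    expect_equal(out[2], "1 Paramedics respond faster")
  } else {
    succeed("Bio.Medline unavailable; dialect check not run")
  }
})

test_that("prepare_retrieval_set removes duplicates and abstract-less records", {
  corp <- corpus(list(
    rec("a", "Same Title", "has abstract", year = 2010L),
    rec("b", "same title!", "different abstract", year = 2010L),  # dup by key
    rec("c", "Another", ""),                                      # no abstract
    rec("d", "Kept", "fine")))
  out <- prepare_retrieval_set(corp)
  expect_equal(record_ids(out), c("a", "d"))
  expect_equal(attr(out, "exclusions"),
               c(duplicate = 1L, no_abstract = 1L))

  # empty input yields empty output
  expect_length(prepare_retrieval_set(corpus())$records, 0L)

  # three records, one empty abstract
  corp3 <- corpus(list(rec("1", "t1", "x"), rec("2", "t2", "  "),
                       rec("3", "t3", "y")))
  out3 <- prepare_retrieval_set(corp3)
  expect_equal(attr(out3, "exclusions"), c(duplicate = 0L, no_abstract = 1L))
  expect_length(out3$records, 2L)
})

test_that("prepare_retrieval_set is idempotent", {
  g <- generate_corpus(corpus_spec(10, 40, list(), seed = 3))
  once <- prepare_retrieval_set(g$corpus)
  twice <- prepare_retrieval_set(once)
  expect_equal(record_ids(twice), record_ids(once))
  expect_equal(attr(twice, "exclusions"), c(duplicate = 0L, no_abstract = 0L))
})

test_that("reconcile_labels partitions shared ids into agreements and conflicts", {
  a <- data.frame(record_id = c("1", "2"), label = c("relevant", "irrelevant"))
  b <- data.frame(record_id = c("1", "2"), label = c("relevant", "relevant"))
  out <- reconcile_labels(a, b)
  expect_equal(unclass(out$agreed), c(`1` = "relevant"), ignore_attr = TRUE)
  expect_equal(out$conflicts, "2")

  # identical lists: zero conflicts
  same <- reconcile_labels(a, a)
  expect_length(same$conflicts, 0L)
  expect_equal(sort(names(same$agreed)), c("1", "2"))

  # coverage gaps flagged, not guessed
  b2 <- data.frame(record_id = "1", label = "relevant")
  gap <- reconcile_labels(a, b2)
  expect_equal(gap$only_a, "2")
  expect_length(gap$only_b, 0L)

  # agreed and conflicts partition the shared id set disjointly
  expect_length(intersect(names(same$agreed), same$conflicts), 0L)
})

test_that("conflicting double labels by one reviewer are an error", {
  a <- data.frame(record_id = c("1", "1"), label = c("relevant", "irrelevant"))
  b <- data.frame(record_id = "1", label = "relevant")
  expect_error(reconcile_labels(a, b), "conflicting")
})

test_that("adjudication completes the gold standard", {
  a <- data.frame(record_id = c("1", "2", "3"),
                  label = c("relevant", "irrelevant", "relevant"))
  b <- data.frame(record_id = c("1", "2", "3"),
                  label = c("relevant", "relevant", "relevant"))
  out <- reconcile_labels(a, b)
  gold <- apply_adjudication(out, c(`2` = "irrelevant"))
  expect_s3_class(gold, "gold_standard")
  expect_equal(sort(names(gold)), c("1", "2", "3"))
  expect_equal(unname(unclass(gold)["2"]), "irrelevant")
  # missing or extraneous adjudications are errors
  expect_error(apply_adjudication(out, c(`9` = "relevant")),
               "without adjudication|non-conflicted")
})

test_that("labels round-trip through CSV and feed gold_standard", {
  gold <- tiny_gold()
  path <- withr::local_tempfile(fileext = ".csv")
  write_labels(gold, path)
  back <- gold_standard(read_labels(path))
  expect_equal(unclass(back)[sort(names(back))],
               unclass(gold)[sort(names(gold))])
})

test_that("gold coverage violations are hard errors", {
  corp <- tiny_corpus()
  expect_error(check_gold_coverage(gold_standard(c(`1` = "relevant")), corp),
               "unscreened")
  full <- tiny_gold()
  expect_true(check_gold_coverage(full, corp))
  extra <- gold_standard(c(unclass(full), `99` = "relevant"))
  expect_error(check_gold_coverage(extra, corp), "absent")
})
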