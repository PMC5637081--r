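test_that("single_term_analysis evaluates and sorts candidate terms", {
  corp <- tiny_corpus()
  gold <- tiny_gold()
  pool <- list(filter_term("paramedic", truncated = TRUE),
               filter_term("ems"),
               filter_term("unicorn"),
               filter_term("ambulances", "sh"))
  res <- single_term_analysis(pool, corp, gold)
  expect_s3_class(res, "single_term_results")
  expect_equal(nrow(res), 4L)
  # sorted by sensitivity desc, ties by specificity then text
  expect_true(all(diff(res$sensitivity) <= 0))

  # a term absent from every record: sensitivity 0, specificity 1, NNR NA
  row <- res[res$term == "unicorn.tw", ]
  expect_equal(row$sensitivity, 0)
  expect_equal(row$specificity, 1)
  expect_true(is.na(row$nnr))

  expect_error(single_term_analysis(list(), corp, gold), "empty")
})

test_that("degenerate terms hit the sensitivity/specificity extremes", {
  g <- generate_corpus(corpus_spec(
    10, 30,
    list(term_profile("everywhere.tw", 1, 1),
         term_profile("nowhere.tw", 0, 0),
         term_profile("marker.tw", 1, 0)),
    seed = 41))
  res <- single_term_analysis(
    list(filter_term("everywhere"), filter_term("nowhere"),
         filter_term("marker")), g$corpus, g$gold)
  ev <- res[res$term == "everywhere.tw", ]
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 0)
  nw <- res[res$term == "nowhere.tw", ]
  expect_equal(nw$sensitivity, 0)
  expect_equal(nw$specificity, 1)
  # p_relevant = 1, p_irrelevant = 0 forces a perfect single-term filter
  mk <- res[res$term == "marker.tw", ]
  expect_equal(mk$sensitivity, 1)
  expect_equal(mk$specificity, 1)
  expect_equal(mk$nnr, 1)
})

test_that("empirical single-term sensitivity recovers the generating probability", {
  # parameter-recovery at the fixture scale: each term's empirical
  # sensitivity within the binomial 99% CI of its p_relevant (seed 42)
  profiles <- list(term_profile("alpha.tw", 0.60, 0.05),
                   term_profile("bravo.tw", 0.25, 0.02),
                   term_profile("charlie.sh", 0.80, 0.10))
  g <- generate_corpus(corpus_spec(400, 400, profiles, seed = 42))
  res <- single_term_analysis(lapply(profiles, `[[`, "term"),
                              g$corpus, g$gold)
  for (p in profiles) {
    row <- res[res$term == serialize_filter(p$term), ]
    ci <- stats::binom.test((row$a), row$a + row$c,
                            conf.level = 0.99)$conf.int
    expect_true(p$p_relevant >= ci[1] && p$p_relevant <= ci[2],
                label = sprintf("%s: p_rel %.2f in [%.3f, %.3f]",
                                row$term, p$p_relevant, ci[1], ci[2]))
  }
})

test_that("greedy_develop selects a sensible pure-OR filter with a replayable trace", {
  profiles <- list(term_profile("broad.tw", 0.9, 0.3),
                   term_profile("narrow.tw", 0.5, 0.01),
                   term_profile("extra.tw", 0.4, 0.05),
                   term_profile("noise.tw", 0.05, 0.25))
  pool <- lapply(profiles, `[[`, "term")
  g <- generate_corpus(corpus_spec(80, 220, profiles, seed = 7))

  cfg <- development_config("sensitivity_maximising", pool, floor = 0)
  dev <- greedy_develop(cfg, g$corpus, g$gold)
  expect_true(dev$feasible)
  expect_s3_class(dev$filter, "filter_expr")
  # pure OR of pool terms
  expect_true(all(vapply(filter_terms(dev$filter), serialize_filter,
                         character(1)) %in%
                    vapply(pool, serialize_filter, character(1))))

  # final sensitivity at least the best single term's (OR-monotonicity)
  best_single <- max(single_term_analysis(pool, g$corpus,
                                          g$gold)$sensitivity)
  expect_gte(dev$report$sensitivity, best_single)

  # trace replay reproduces the returned term set
  state <- character(0)
  for (i in seq_len(nrow(dev$trace))) {
    if (dev$trace$action[i] == "add")
      state <- c(state, dev$trace$term[i])
    else state <- setdiff(state, dev$trace$term[i])
  }
  expect_setequal(state, vapply(filter_terms(dev$filter), serialize_filter,
                                character(1)))

  # determinism: identical inputs give identical filters
  dev2 <- greedy_develop(cfg, g$corpus, g$gold)
  expect_identical(serialize_filter(dev2$filter),
                   serialize_filter(dev$filter))
  expect_identical(dev2$trace, dev$trace)
})

test_that("a pool of one useful term yields that term", {
  g <- generate_corpus(corpus_spec(20, 40,
                                   list(term_profile("solo.tw", 0.7, 0.05)),
                                   seed = 9))
  cfg <- development_config("sensitivity_maximising",
                            list(filter_term("solo")), floor = 0)
  dev <- greedy_develop(cfg, g$corpus, g$gold)
  expect_identical(serialize_filter(dev$filter), "solo.tw")
})

test_that("specificity objective reaches its sensitivity floor frugally", {
  profiles <- list(term_profile("broad.tw", 0.95, 0.4),
                   term_profile("clean.tw", 0.75, 0.02),
                   term_profile("fill.tw", 0.5, 0.03))
  pool <- lapply(profiles, `[[`, "term")
  g <- generate_corpus(corpus_spec(100, 300, profiles, seed = 21))
  cfg <- development_config("specificity_maximising", pool, floor = 0.7)
  dev <- greedy_develop(cfg, g$corpus, g$gold)
  expect_true(dev$feasible)
  expect_gte(dev$report$sensitivity, 0.7)

  # the two objectives bracket each other, mirroring the published pair
  cfg_s <- development_config("sensitivity_maximising", pool, floor = 0)
  dev_s <- greedy_develop(cfg_s, g$corpus, g$gold)
  expect_gte(dev_s$report$sensitivity, dev$report$sensitivity)
  expect_gte(dev$report$specificity, dev_s$report$specificity)
})

test_that("an unreachable floor is an explicit infeasibility, not an empty filter", {
  g <- generate_corpus(corpus_spec(20, 40,
                                   list(term_profile("weak.tw", 0.3, 0.5)),
                                   seed = 15))
  # sensitivity objective: no term keeps specificity >= 0.99
  cfg <- development_config("sensitivity_maximising",
                            list(filter_term("weak")), floor = 0.99)
  dev <- greedy_develop(cfg, g$corpus, g$gold)
  expect_false(dev$feasible)
  expect_null(dev$filter)

  # specificity objective: pool cannot reach sensitivity 0.95
  cfg2 <- development_config("specificity_maximising",
                             list(filter_term("weak")), floor = 0.95)
  dev2 <- greedy_develop(cfg2, g$corpus, g$gold)
  expect_false(dev2$feasible)
})

test_that("greedy matches or reports its gap against exhaustive search", {
  set.seed(7)
  pool <- random_pool(8L)
  g <- generate_corpus(corpus_spec(60, 140, random_profiles(pool), seed = 7))
  cfg <- development_config("sensitivity_maximising", pool, floor = 0,
                            max_terms = 4L)
  dev <- greedy_develop(cfg, g$corpus, g$gold)
  ex <- exhaustive_or_search(pool, g$corpus, g$gold,
                             "sensitivity_maximising", floor = 0,
                             max_terms = 4L)
  expect_true(ex$feasible)
  gap <- ex$objective_value - dev$report$sensitivity
  expect_gte(gap, 0)       # exhaustive is an upper bound by construction
  expect_lte(gap, 0.10)    # greedy should be near-optimal on OR filters
})

test_that("max_terms caps the filter length", {
  set.seed(3)
  pool <- random_pool(6L)
  g <- generate_corpus(corpus_spec(50, 100, random_profiles(pool), seed = 33))
  cfg <- development_config("sensitivity_maximising", pool, floor = 0,
                            max_terms = 2L)
  dev <- greedy_develop(cfg, g$corpus, g$gold)
  expect_lte(length(filter_terms(dev$filter)), 2L)
})
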