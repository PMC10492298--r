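test_that("quality filter requires randomization and participant blinding", {
  rec <- function(alloc, masking) {
    list(nct_id = "NCT1", allocation = alloc, masking_roles = masking,
         arms = list())
  }
  expect_true(passes_quality_filter(rec("randomized", c("participant", "investigator"))))
  expect_false(passes_quality_filter(rec("randomized", character())))        # open label
  expect_false(passes_quality_filter(rec("non_randomized", "participant")))
  expect_false(passes_quality_filter(rec("unspecified", "participant")))
  expect_false(passes_quality_filter(rec("randomized", "investigator")))
})

test_that("small-arm filter keeps exactly the arms at or above the cutoff", {
  arm <- function(n) list(label = "x", n_participants = n, adverse_events = list())
  rec <- list(nct_id = "NCT1", allocation = "randomized",
              masking_roles = "participant",
              arms = list(arm(99L), arm(100L), arm(250L)))
  kept <- filter_small_arms(rec)
  expect_equal(vapply(kept$arms, `[[`, integer(1), "n_participants"),
               c(100L, 250L))
  expect_identical(filter_small_arms(kept), kept)            # all above: identity
  none <- filter_small_arms(rec, min_n = 1000L)
  expect_length(none$arms, 0)
  # monotonicity: raising min_n never increases survivors
  sizes <- c(1L, 50L, 100L, 150L, 500L)
  n_kept <- vapply(sizes, function(m) length(filter_small_arms(rec, m)$arms),
                   integer(1))
  expect_true(all(diff(n_kept) <= 0))
})

test_that("label-to-ingredient mapping applies the 50% token rule and rejections", {
  lex <- fixture_lexicon()
  # inclusive threshold: 1 of 2 tokens is enough
  hit <- map_arm_to_ingredient("Sitagliptin phosphate", lex)
  expect_equal(hit$ingredient, "A10BH01")
  expect_true(is.na(hit$reason))
  # case-insensitive, punctuation split into alphanumeric runs
  expect_equal(map_arm_to_ingredient("GLIPIZIDE", lex)$ingredient, "A10BB07")
  expect_equal(map_arm_to_ingredient("Aspirin + Dipyridamole", lex)$reason,
               "plus_sign")
  expect_equal(map_arm_to_ingredient("Nicotine patch 21 mg daily", lex)$reason,
               "low_overlap")                               # 1 of 5 tokens
  expect_equal(map_arm_to_ingredient("Aspirin dipyridamole combo", lex)$reason,
               "multi_ingredient")                          # 2/3 match, 2 ingredients
  expect_equal(map_arm_to_ingredient("Tocilizumab infusion", lex)$reason,
               "no_match")
})

test_that("adverse-event terms map by case-normalized exact lookup", {
  m <- data.frame(term = "hiccups", icd10 = "R06.6")
  expect_equal(map_ae_term("Hiccups", m), "R06.6")
  expect_equal(map_ae_term("HICCUPS", m), "R06.6")
  expect_true(is.na(map_ae_term("nausea", m)))
})

test_that("extraction drops filtered trials and merges duplicate ICD10 terms", {
  lex <- fixture_lexicon()
  aem <- fixture_ae_map()
  bad <- list(nct_id = "NCTX", allocation = "non_randomized",
              masking_roles = "participant",
              arms = list(list(label = "Glipizide", n_participants = 200L,
                               adverse_events = list(
                                 list(term = "Nausea", affected = 3L, at_risk = 100L)))))
  expect_length(extract_ingredient_arms(bad, lex, aem), 0)
  off <- extract_ingredient_arms(bad, lex, aem, apply_quality_filter = FALSE)
  expect_length(off, 1)

  # two terms with one code: affected summed, denominator not double-counted
  rec <- list(nct_id = "NCTY", allocation = "randomized",
              masking_roles = "participant",
              arms = list(list(label = "Glipizide", n_participants = 200L,
                               adverse_events = list(
                                 list(term = "Nausea", affected = 3L, at_risk = 100L),
                                 list(term = "Feeling queasy", affected = 2L, at_risk = 100L)))))
  arms <- extract_ingredient_arms(rec, lex, aem)
  expect_equal(arms[[1]]$ae$affected, 5L)
  expect_equal(arms[[1]]$ae$at_risk, 100L)
  # capping binds when the sum exceeds the denominator
  rec$arms[[1]]$adverse_events[[2]]$affected <- 99L
  expect_warning(arms <- extract_ingredient_arms(rec, lex, aem), "capped")
  expect_equal(arms[[1]]$ae$affected, 100L)
})

test_that("extraction is invariant to arm order and filter-off is a superset", {
  lex <- fixture_lexicon()
  aem <- fixture_ae_map()
  for (seed in c(1L, 42L, 99L)) {
    recs <- generate_fixture_trials(seed)
    arms <- ingest_trials(recs, lex, aem)
    ids <- sort(build_reference_comparisons(arms)$comparison_id)
    recs1 <- generate_fixture_trials(1L)
    arms1 <- ingest_trials(recs1, lex, aem)
    expect_equal(sort(build_reference_comparisons(arms1)$comparison_id), ids)
  }
  recs <- generate_fixture_trials(1L)
  on_ids <- build_reference_comparisons(ingest_trials(recs, lex, aem))$comparison_id
  off_ids <- build_reference_comparisons(
    ingest_trials(recs, lex, aem, apply_quality_filter = FALSE))$comparison_id
  expect_true(all(on_ids %in% off_ids))
  expect_gt(length(off_ids), length(on_ids))
  # all extracted arms satisfy affected <= at_risk
  arms <- ingest_trials(recs, lex, aem, apply_quality_filter = FALSE)
  for (a in arms) expect_true(all(a$ae$affected <= a$ae$at_risk))
})

test_that("trial records round-trip through the JSON schema", {
  recs <- generate_fixture_trials(5L)
  path <- withr::local_tempfile(fileext = ".json")
  write_trial_records(recs, path)
  expect_equal(load_trial_records(path), recs)
})

test_that("schema violations are reported with record and field", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"allocation": "randomized", "masking_roles": [], "arms": []}]',
             path)
  expect_error(load_trial_records(path), "record 1.*nct_id")
  writeLines(paste0('[{"nct_id": "N1", "allocation": "randomized", ',
                    '"masking_roles": [], "arms": [{"label": "x", ',
                    '"n_participants": 10, "adverse_events": ',
                    '[{"term": "t", "affected": 5, "at_risk": 2}]}]}]'), path)
  expect_error(load_trial_records(path), "arm 1")
  writeLines('[{"nct_id": ', path)
  expect_error(load_trial_records(path))
})
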