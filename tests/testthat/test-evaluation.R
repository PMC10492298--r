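make_results <- function(ids, p, dir) {
  data.frame(comparison_id = ids, p_value = p, direction = dir,
             stringsAsFactors = FALSE)
}

test_that("significance uses an inclusive p <= alpha cutoff", {
  res <- make_results(c("a", "b", "c"), c(0.049, 0.05, 0.051), c("A", "A", "B"))
  expect_setequal(significant_results(res), c("a", "b"))   # 0.05 included
  expect_length(significant_results(make_results("a", 0.051, "A")), 0)
  expect_error(significant_results(make_results(c("a", "a"), c(0.1, 0.2),
                                                c("A", "B"))), "duplicate")
  expect_error(significant_results(make_results("a", 1.2, "A")), "p_value")
  expect_error(significant_results(make_results("a", 0.2, "up")), "direction")
})

test_that("concordant sign rate counts agreement among significant subset members", {
  sub <- structure(list(threshold = 2, member_ids = sprintf("c%02d", 1:8)),
                   class = "reference_subset")
  res <- make_results(sprintf("c%02d", 1:8), rep(0.01, 8),
                      c(rep("A", 6), rep("B", 2)))
  expect_equal(concordant_sign_rate(sub, res), 0.75)       # 6 of 8
  expect_equal(concordant_sign_rate(sub, make_results(sub$member_ids,
                                                      rep(0.01, 8),
                                                      rep("A", 8))), 1)
  # empty intersection is missing, not zero
  expect_true(is.na(concordant_sign_rate(sub, make_results(sub$member_ids,
                                                           rep(0.9, 8),
                                                           rep("A", 8)))))
  # invariant to results outside the subset
  extra <- rbind(res, make_results(sprintf("x%02d", 1:5), rep(0.001, 5),
                                   rep("B", 5)))
  expect_equal(concordant_sign_rate(sub, extra), 0.75)
})

test_that("recovery is the significant-and-concordant share of the subset", {
  sub <- structure(list(threshold = 2, member_ids = sprintf("c%02d", 1:10)),
                   class = "reference_subset")
  res <- make_results(sprintf("c%02d", 1:10),
                      c(rep(0.01, 4), rep(0.5, 6)),
                      rep("A", 10))
  expect_equal(recovery_fraction(sub, res), 0.4)
  expect_equal(recovery_fraction(sub, make_results(sub$member_ids, rep(0.5, 10),
                                                   rep("A", 10))), 0)
  expect_equal(recovery_fraction(sub, make_results(sub$member_ids, rep(0.01, 10),
                                                   rep("A", 10))), 1)
  # discordant significant results never count toward recovery
  disc <- make_results(sub$member_ids, rep(0.01, 10), rep("B", 10))
  expect_equal(recovery_fraction(sub, disc), 0)
  expect_error(recovery_fraction(structure(list(threshold = 2,
                                                member_ids = character()),
                                           class = "reference_subset"), res),
               "empty")
})

test_that("fraction significant matches the cardinality of significant_results", {
  res <- make_results(sprintf("c%d", 1:4), c(0.01, 0.03, 0.2, 0.04),
                      c("A", "B", "A", "A"))
  expect_equal(fraction_significant(res), 0.75)
  expect_equal(fraction_significant(res),
               length(significant_results(res)) / nrow(res))
  expect_equal(fraction_significant(make_results("a", 0.9, "A")), 0)
})

test_that("the evaluation curve reproduces the scalar metrics per threshold", {
  eff <- data.frame(comparison_id = sprintf("c%02d", 1:20),
                    or_eb = seq(1, 4, length.out = 20))
  res <- make_results(eff$comparison_id,
                      rep(c(0.01, 0.5), 10),
                      rep(c("A", "A", "B", "A"), 5))
  curve <- evaluation_curve(eff, res, thresholds = c(1, 2, 3))
  expect_equal(names(curve),
               c("threshold", "n_subset", "n_significant", "csr", "recovery"))
  for (k in seq_len(nrow(curve))) {
    sub <- subset_at_threshold(eff, curve$threshold[k])
    expect_equal(curve$n_subset[k], length(sub$member_ids))
    expect_equal(curve$csr[k], concordant_sign_rate(sub, res))
    expect_equal(curve$recovery[k], recovery_fraction(sub, res))
  }
  expect_true(all(diff(curve$n_subset) <= 0))  # nestedness
  # recovery never exceeds the significant share of the subset
  expect_true(all(curve$recovery <= curve$n_significant / curve$n_subset))
  expect_error(evaluation_curve(eff, res, thresholds = c(2, 1)))
})

test_that("per-comparison reports flag concordance only when significant", {
  sub <- structure(list(threshold = 2, member_ids = c("c1", "c2", "c3", "c4")),
                   class = "reference_subset")
  m1 <- make_results(c("c1", "c2", "c3"), c(0.01, 0.01, 0.2), c("A", "B", "B"))
  rep_df <- per_comparison_report(sub, list(cox = m1))
  expect_equal(rep_df$status, c("concordant", "discordant", "not_significant",
                                "absent"))
  # two methods give one block each
  rep2 <- per_comparison_report(sub, list(cox = m1, psm = m1))
  expect_equal(nrow(rep2), 8)
  expect_setequal(unique(rep2$method), c("cox", "psm"))
})

test_that("method results round-trip through TSV", {
  res <- make_results(sprintf("c%d", 1:3), c(0.01, 0.2, 0.05), c("A", "B", "A"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_method_results(res, path)
  expect_equal(read_method_results(path), res)
})
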