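#' Comparisons called significant by a non-experimental method
#'
#' @param results Method-result data frame: columns `comparison_id`,
#'   `p_value` (in \[0, 1\]) and `direction` (`"A"` or `"B"`, relative to the
#'   oriented reference comparison). Duplicate comparison ids are an error —
#'   a method must return one verdict per comparison.
#' @param alpha Significance level; inclusive (`p_value <= alpha`).
#' @return Character vector of significant comparison ids.
#' @export
significant_results <- function(results, alpha = 0.05) {
  validate_method_results(results)
  results$comparison_id[results$p_value <= alpha]
}

validate_method_results <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("comparison_id", "p_value", "direction") %in% names(results)))
  if (anyDuplicated(results$comparison_id)) {
    stop("duplicate comparison_id in method results: ",
         results$comparison_id[duplicated(results$comparison_id)][1])
  }
  if (any(results$p_value < 0 | results$p_value > 1)) {
    stop("p_value outside [0, 1] in method results")
  }
  if (!all(results$direction %in% c("A", "B"))) {
    stop("direction must be 'A' or 'B'")
  }
  invisible(results)
}

#' Concordant sign rate of a method against a reference subset
#'
#' Among comparisons that are both in the subset and significant under the
#' method, the fraction whose predicted direction agrees with the reference
#' direction. Orientation makes the reference direction "A" (drug A has the
#' higher event odds) for every entry. An empty intersection yields `NA`
#' (undefined, not zero), so threshold sweeps can show gaps.
#'
#' @param subset A [subset_at_threshold()] / [fisher_exact_subset()] result.
#' @param results Method-result data frame.
#' @param alpha Significance level for the method's p-values.
#' @return Fraction in \[0, 1\], or `NA` when no subset member is significant.
#' @export
concordant_sign_rate <- function(subset, results, alpha = 0.05) {
  validate_method_results(results)
  sig <- results$p_value <= alpha
  in_sub <- results$comparison_id %in% subset$member_ids
  denom <- sig & in_sub
  if (!any(denom)) return(NA_real_)
  mean(results$direction[denom] == "A")
}

#' Fraction of a reference subset recovered by a method
#'
#' The share of subset entries the method marks significant with the
#' concordant direction — the method's power on the reference set.
#'
#' @inheritParams concordant_sign_rate
#' @return Fraction in \[0, 1\]. Errors on an empty subset.
#' @export
recovery_fraction <- function(subset, results, alpha = 0.05) {
  validate_method_results(results)
  n_sub <- length(subset$member_ids)
  if (n_sub == 0) stop("recovery is undefined for an empty subset")
  hit <- results$comparison_id %in% subset$member_ids &
    results$p_value <= alpha & results$direction == "A"
  sum(hit) / n_sub
}

#' Fraction of method results that are statistically significant
#'
#' @inheritParams concordant_sign_rate
#' @return Share of results with `p_value <= alpha`.
#' @export
fraction_significant <- function(results, alpha = 0.05) {
  validate_method_results(results)
  stopifnot(nrow(results) > 0)
  mean(results$p_value <= alpha)
}

#' Concordance and recovery as functions of the effect-size threshold
#'
#' Sweeps the reference-subset threshold and computes, at each value, the
#' subset size, the number of significant subset members, the concordant sign
#' rate and the recovery fraction. Thresholds where no subset member is
#' significant have `csr = NA`; thresholds with an empty subset also have
#' `recovery = NA`.
#'
#' @param effects Denoised comparison data frame.
#' @param results Method-result data frame.
#' @param thresholds Ascending odds-ratio thresholds (default 1.00 to 4.00 by
#'   0.05).
#' @param alpha Significance level.
#' @return Data frame of class `evaluation_curve` with columns `threshold`,
#'   `n_subset`, `n_significant`, `csr`, `recovery`.
#' @export
evaluation_curve <- function(effects, results,
                             thresholds = seq(1, 4, by = 0.05),
                             alpha = 0.05) {
  stopifnot(!is.unsorted(thresholds))
  validate_method_results(results)
  rows <- lapply(thresholds, function(t) {
    sub <- subset_at_threshold(effects, t)
    sig_in <- results$comparison_id %in% sub$member_ids &
      results$p_value <= alpha
    data.frame(
      threshold = t,
      n_subset = length(sub$member_ids),
      n_significant = sum(sig_in),
      csr = concordant_sign_rate(sub, results, alpha),
      recovery = if (length(sub$member_ids) == 0) NA_real_ else
        recovery_fraction(sub, results, alpha)
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_curve", class(out))
  out
}

#' Per-comparison concordance report across methods
#'
#' One row per subset member and method, with the method's p-value, predicted
#' direction and a status: `concordant` or `discordant` when significant,
#' `not_significant` otherwise, and `absent` when the method returned no
#' result for the comparison.
#'
#' @param subset A `reference_subset`.
#' @param results_by_method Named list of method-result data frames.
#' @param alpha Significance level.
#' @return Data frame with columns `comparison_id`, `method`, `p_value`,
#'   `direction`, `status`.
#' @export
per_comparison_report <- function(subset, results_by_method, alpha = 0.05) {
  stopifnot(is.list(results_by_method), length(names(results_by_method)) ==
              length(results_by_method))
  rows <- list()
  for (method in names(results_by_method)) {
    res <- validate_method_results(results_by_method[[method]])
    idx <- match(subset$member_ids, res$comparison_id)
    status <- ifelse(is.na(idx), "absent",
              ifelse(res$p_value[idx] > alpha, "not_significant",
              ifelse(res$direction[idx] == "A", "concordant", "discordant")))
    rows[[method]] <- data.frame(
      comparison_id = subset$member_ids,
      method = method,
      p_value = res$p_value[idx],
      direction = res$direction[idx],
      status = status,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write method-result TSV files
#'
#' Tab-separated, header `comparison_id`, `p_value`, `direction` ("A" or
#' "B").
#'
#' @param results Method-result data frame.
#' @param path File path.
#' @export
write_method_results <- function(results, path) {
  validate_method_results(results)
  utils::write.table(results[, c("comparison_id", "p_value", "direction")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_method_results
#' @export
read_method_results <- function(path) {
  res <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_method_results(res)
}
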