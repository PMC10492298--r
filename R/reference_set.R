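#' Rank denoised comparisons by effect size
#'
#' Descending by denoised odds ratio, with ties broken by `comparison_id` so
#' the order is deterministic and permutation-invariant.
#'
#' @param effects Data frame from [denoise_comparisons()] (needs `or_eb` and
#'   `comparison_id`).
#' @return The data frame reordered.
#' @export
rank_by_effect <- function(effects) {
  stopifnot(all(c("or_eb", "comparison_id") %in% names(effects)))
  effects[order(-effects$or_eb, effects$comparison_id), , drop = FALSE]
}

#' Reference subset at a denoised odds-ratio threshold
#'
#' The nested family of reference sets: \eqn{S_t} holds every comparison
#' whose denoised odds ratio is at least `t` (inclusive). Larger `t` gives a
#' smaller, higher-confidence subset; `t = 0` returns everything.
#'
#' @param effects Denoised comparison data frame.
#' @param t Threshold on the odds-ratio scale, `t >= 0`.
#' @return Object of class `reference_subset`: list with `threshold` and
#'   `member_ids` (character vector of comparison ids).
#' @export
subset_at_threshold <- function(effects, t) {
  stopifnot(t >= 0, all(c("or_eb", "comparison_id") %in% names(effects)))
  structure(
    list(threshold = t,
         member_ids = effects$comparison_id[effects$or_eb >= t]),
    class = "reference_subset"
  )
}

#' @export
print.reference_subset <- function(x, ...) {
  cat(sprintf("<reference_subset> threshold %s: %d members\n",
              format(x$threshold), length(x$member_ids)))
  invisible(x)
}

#' Two-sided Fisher exact p-value of a 2x2 table
#'
#' The point-probability convention: the sum of central-hypergeometric
#' probabilities of all outcomes no more probable than the observed one
#' (as in [stats::fisher.test()], which performs the computation).
#'
#' @param x_a,y_a,x_b,y_b Table cells.
#' @return p-value in (0, 1]. Degenerate tables (single-point support)
#'   return 1.
#' @export
fisher_exact_pvalue <- function(x_a, y_a, x_b, y_b) {
  m <- matrix(c(x_a, y_a, x_b, y_b), nrow = 2)
  if (sum(m) == 0) return(1)
  stats::fisher.test(m)$p.value
}

#' Fisher-significance ablation subset
#'
#' The ablated reference set used to contrast plain statistical significance
#' against posterior-mean effect-size thresholds: members are the comparisons
#' whose two-sided Fisher exact p-value is at most `alpha`.
#'
#' @param effects Denoised (or plain) comparison data frame with table cells.
#' @param alpha Significance level in (0, 1); inclusive cutoff.
#' @return A `reference_subset` with `threshold` marker `"fisher_p<=alpha"`.
#' @export
fisher_exact_subset <- function(effects, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  p <- mapply(fisher_exact_pvalue, effects$x_a, effects$y_a,
              effects$x_b, effects$y_b)
  structure(
    list(threshold = sprintf("fisher_p<=%g", alpha),
         member_ids = effects$comparison_id[p <= alpha]),
    class = "reference_subset"
  )
}

#' Write a reference subset as TSV
#'
#' Columns `comparison_id`, `threshold`.
#'
#' @param subset A `reference_subset`.
#' @param path File path.
#' @export
write_subset <- function(subset, path) {
  utils::write.table(
    data.frame(comparison_id = subset$member_ids,
               threshold = subset$threshold),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
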