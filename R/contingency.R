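#' Merge dosage arms of the same ingredient within one trial
#'
#' Registry records often evaluate one drug at several doses in separate
#' arms. Arms sharing an ingredient are pooled: enrolment is summed and, per
#' ICD10 code, affected and at-risk counts are summed (distinct arms are
#' disjoint patient sets, so summing denominators is correct here, unlike the
#' within-arm duplicate-term merge).
#'
#' @param arms List of ingredient arms from one trial (shared `nct_id`).
#' @return List of ingredient arms with unique ingredients, ordered by
#'   ingredient code.
#' @export
merge_dose_arms <- function(arms) {
  if (length(arms) <= 1L) return(arms)
  ids <- unique(vapply(arms, `[[`, character(1), "nct_id"))
  if (length(ids) > 1L) stop("merge_dose_arms expects arms from a single trial")
  ingredients <- vapply(arms, `[[`, character(1), "ingredient")
  out <- lapply(sort(unique(ingredients)), function(ing) {
    grp <- arms[ingredients == ing]
    ae <- do.call(rbind, lapply(grp, `[[`, "ae"))
    if (!is.null(ae) && nrow(ae) > 0) {
      affected <- tapply(ae$affected, ae$icd10, sum)
      at_risk <- tapply(ae$at_risk, ae$icd10, sum)
      ae <- data.frame(icd10 = names(affected),
                       affected = as.integer(affected),
                       at_risk = as.integer(at_risk),
                       row.names = NULL, stringsAsFactors = FALSE)
    } else {
      ae <- data.frame(icd10 = character(), affected = integer(),
                       at_risk = integer(), stringsAsFactors = FALSE)
    }
    list(nct_id = grp[[1]]$nct_id, ingredient = ing,
         n_participants = sum(vapply(grp, `[[`, integer(1), "n_participants")),
         ae = ae)
  })
  out
}

comparison_id <- function(drug_a, drug_b, ae) {
  pair <- sort(c(drug_a, drug_b))
  paste(ae, pair[1], pair[2], sep = "|")
}

#' Build drug-vs-drug adverse-event comparisons from ingredient arms
#'
#' For every trial, every unordered pair of distinct-ingredient arms, and
#' every ICD10 code reported in both arms, emits one comparison row with the
#' 2x2 contingency table `x = affected`, `y = at_risk - affected` per drug.
#' Arms must already be dose-merged (see [merge_dose_arms()]); [ingest_trials()]
#' does this. Entries with a zero at-risk denominator are skipped.
#'
#' @param arms List of ingredient arms (possibly spanning many trials).
#' @return Data frame with columns `comparison_id`, `ae_icd10`, `drug_a`,
#'   `drug_b`, `nct_ids`, `x_a`, `y_a`, `x_b`, `y_b`. One trial contributes
#'   one row per (pair, code); use [aggregate_trials()] to pool across trials.
#' @export
build_comparisons <- function(arms) {
  rows <- list()
  nct <- vapply(arms, `[[`, character(1), "nct_id")
  for (id in unique(nct)) {
    trial_arms <- arms[nct == id]
    k <- length(trial_arms)
    if (k < 2L) next
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        a <- trial_arms[[i]]
        b <- trial_arms[[j]]
        if (a$ingredient == b$ingredient) {
          stop("arms must be dose-merged before building comparisons")
        }
        shared <- intersect(a$ae$icd10, b$ae$icd10)
        for (code in shared) {
          ia <- match(code, a$ae$icd10)
          ib <- match(code, b$ae$icd10)
          if (a$ae$at_risk[ia] < 1L || b$ae$at_risk[ib] < 1L) next
          rows[[length(rows) + 1L]] <- data.frame(
            comparison_id = comparison_id(a$ingredient, b$ingredient, code),
            ae_icd10 = code,
            drug_a = a$ingredient,
            drug_b = b$ingredient,
            nct_ids = id,
            x_a = a$ae$affected[ia],
            y_a = a$ae$at_risk[ia] - a$ae$affected[ia],
            x_b = b$ae$affected[ib],
            y_b = b$ae$at_risk[ib] - b$ae$affected[ib],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(rows) == 0) return(empty_comparisons())
  do.call(rbind, rows)
}

empty_comparisons <- function() {
  data.frame(comparison_id = character(), ae_icd10 = character(),
             drug_a = character(), drug_b = character(),
             nct_ids = character(), x_a = integer(), y_a = integer(),
             x_b = integer(), y_b = integer(), stringsAsFactors = FALSE)
}

#' Pool comparisons of the same drug pair and adverse event across trials
#'
#' Rows sharing a (unordered drug pair, ICD10 code) key are summed cell-wise
#' after aligning each row's drug orientation to the pair's lexicographic
#' order, and the contributing registry ids are unioned. Pooling therefore
#' does not depend on input row order or on any prior orientation of the
#' inputs. Orientation of the pooled tables (sample OR >= 1) is applied
#' afterwards, by [orient_comparisons()].
#'
#' @param comparisons Data frame from [build_comparisons()].
#' @return Data frame with one row per comparison key, `nct_ids`
#'   semicolon-joined and sorted, ordered by `comparison_id`.
#' @export
aggregate_trials <- function(comparisons) {
  if (nrow(comparisons) == 0) return(empty_comparisons())
  # align every row to lexicographic drug order before summing
  swap <- comparisons$drug_a > comparisons$drug_b
  aligned <- comparisons
  aligned[swap, c("drug_a", "drug_b", "x_a", "y_a", "x_b", "y_b")] <-
    comparisons[swap, c("drug_b", "drug_a", "x_b", "y_b", "x_a", "y_a")]
  key <- comparison_id_vec(aligned$drug_a, aligned$drug_b, aligned$ae_icd10)
  out <- lapply(sort(unique(key)), function(k) {
    grp <- aligned[key == k, , drop = FALSE]
    ids <- sort(unique(unlist(strsplit(grp$nct_ids, ";", fixed = TRUE))))
    data.frame(
      comparison_id = k,
      ae_icd10 = grp$ae_icd10[1],
      drug_a = grp$drug_a[1],
      drug_b = grp$drug_b[1],
      nct_ids = paste(ids, collapse = ";"),
      x_a = sum(grp$x_a), y_a = sum(grp$y_a),
      x_b = sum(grp$x_b), y_b = sum(grp$y_b),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

comparison_id_vec <- function(drug_a, drug_b, ae) {
  mapply(comparison_id, drug_a, drug_b, ae, USE.NAMES = FALSE)
}

#' Sample odds ratio of a 2x2 table
#'
#' \eqn{((x_a + c)(y_b + c)) / ((x_b + c)(y_a + c))} with continuity
#' correction `c`. With `continuity = 0` a zero denominator cell gives `Inf`
#' (or 0 when the numerator is also zero-celled); the 0.5 correction keeps
#' the ratio finite for tables with empty cells and is used for ordering and
#' display only — likelihood computations always use the raw counts.
#'
#' @param x_a,y_a,x_b,y_b Table cells.
#' @param continuity Nonnegative continuity correction added to each cell.
#' @return Positive real (possibly `Inf`).
#' @export
sample_odds_ratio <- function(x_a, y_a, x_b, y_b, continuity = 0.5) {
  stopifnot(continuity >= 0)
  num <- (x_a + continuity) * (y_b + continuity)
  den <- (x_b + continuity) * (y_a + continuity)
  if (den == 0) {
    if (num == 0) 0 else Inf
  } else {
    num / den
  }
}

#' Orient comparisons so the sample odds ratio is at least 1
#'
#' In an active-comparator design neither arm is a natural baseline; the roles
#' of the two drugs are symmetric. Each pooled comparison is therefore
#' reordered so that drug A is the arm with the higher event odds: when the
#' continuity-corrected (0.5) sample odds ratio is below 1 the drugs and table
#' columns are swapped. Exact ties keep the lexicographically smaller drug
#' code as drug A. Idempotent.
#'
#' @param comparisons Data frame of (pooled) comparisons. A simulation-truth
#'   `omega_true` column, when present, is negated for swapped rows so it
#'   stays expressed relative to the oriented drug A.
#' @return The data frame with columns reordered per row as needed.
#' @export
orient_comparisons <- function(comparisons) {
  if (nrow(comparisons) == 0) return(comparisons)
  or <- mapply(sample_odds_ratio, comparisons$x_a, comparisons$y_a,
               comparisons$x_b, comparisons$y_b,
               MoreArgs = list(continuity = 0.5))
  swap <- or < 1 | (or == 1 & comparisons$drug_a > comparisons$drug_b)
  comparisons[swap, c("drug_a", "drug_b", "x_a", "y_a", "x_b", "y_b")] <-
    comparisons[swap, c("drug_b", "drug_a", "x_b", "y_b", "x_a", "y_a")]
  if ("omega_true" %in% names(comparisons)) {
    comparisons$omega_true[swap] <- -comparisons$omega_true[swap]
  }
  comparisons
}

#' Full comparison-building pipeline from ingredient arms
#'
#' [build_comparisons()], then [aggregate_trials()], then
#' [orient_comparisons()].
#'
#' @param arms List of dose-merged ingredient arms.
#' @return Oriented, pooled comparison data frame.
#' @export
build_reference_comparisons <- function(arms) {
  orient_comparisons(aggregate_trials(build_comparisons(arms)))
}

#' Read / write the comparisons TSV dialect
#'
#' Tab-separated, header `comparison_id`, `ae_icd10`, `drug_a`, `drug_b`,
#' `nct_ids` (semicolon-joined), `x_a`, `y_a`, `x_b`, `y_b`. Files written by
#' [write_comparisons()] (and by [denoise_comparisons()] consumers, which
#' append `sample_or`, `log_or_eb`, `or_eb`) round-trip through
#' [read_comparisons()].
#'
#' @param comparisons Data frame to write.
#' @param path File path.
#' @return `read_comparisons()` returns the data frame; `write_comparisons()`
#'   returns `path` invisibly.
#' @export
write_comparisons <- function(comparisons, path) {
  utils::write.table(comparisons, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_comparisons
#' @export
read_comparisons <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
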