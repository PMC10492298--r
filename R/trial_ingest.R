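#' Load normalized clinical-trial result records
#'
#' Reads a JSON array of trial result records in the package's normalized
#' schema (a stand-in for registry exports; a thin adapter is expected for
#' real registry XML/API dialects). Each record is an object with fields
#' `nct_id` (string), `allocation` (`"randomized"`, `"non_randomized"` or
#' `"unspecified"`), `masking_roles` (array of role strings) and `arms`, an
#' array of `{label, n_participants, adverse_events: [{term, affected,
#' at_risk}]}` objects.
#'
#' @param path Path to the JSON file.
#' @return List of validated trial records, in file order. Malformed JSON
#'   raises a parse error (with position information from the JSON parser);
#'   schema violations raise an error naming the offending record and field.
#' @export
load_trial_records <- function(path) {
  stopifnot(file.exists(path))
  records <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(records)) stop("trial file must contain a JSON array of records")
  records <- lapply(seq_along(records), function(i) {
    validate_trial_record(records[[i]], sprintf("record %d", i))
  })
  ids <- vapply(records, `[[`, character(1), "nct_id")
  if (anyDuplicated(ids)) {
    stop("duplicate nct_id in trial file: ", ids[duplicated(ids)][1])
  }
  records
}

validate_trial_record <- function(rec, where) {
  fail <- function(field, why) {
    stop(sprintf("%s: invalid field '%s' (%s)", where, field, why), call. = FALSE)
  }
  if (is.null(rec$nct_id) || !is.character(rec$nct_id) || !nzchar(rec$nct_id)) {
    fail("nct_id", "missing or empty")
  }
  where <- sprintf("%s (%s)", where, rec$nct_id)
  if (is.null(rec$allocation) ||
      !rec$allocation %in% c("randomized", "non_randomized", "unspecified")) {
    fail("allocation", "must be randomized|non_randomized|unspecified")
  }
  rec$masking_roles <- as.character(unlist(rec$masking_roles))
  if (is.null(rec$arms)) rec$arms <- list()
  rec$arms <- lapply(seq_along(rec$arms), function(j) {
    arm <- rec$arms[[j]]
    aw <- sprintf("%s arm %d", where, j)
    if (is.null(arm$label) || !is.character(arm$label)) {
      stop(aw, ": invalid field 'label'", call. = FALSE)
    }
    n <- arm$n_participants
    if (is.null(n) || !is.numeric(n) || n < 0 || n != round(n)) {
      stop(aw, ": invalid field 'n_participants'", call. = FALSE)
    }
    if (is.null(arm$adverse_events)) arm$adverse_events <- list()
    arm$adverse_events <- lapply(arm$adverse_events, function(ae) {
      if (is.null(ae$term) || is.null(ae$affected) || is.null(ae$at_risk) ||
          ae$affected < 0 || ae$at_risk < 0 || ae$affected > ae$at_risk) {
        stop(aw, ": invalid adverse_events entry (need term, ",
             "0 <= affected <= at_risk)", call. = FALSE)
      }
      list(term = ae$term, affected = as.integer(ae$affected),
           at_risk = as.integer(ae$at_risk))
    })
    list(label = arm$label, n_participants = as.integer(n),
         adverse_events = arm$adverse_events)
  })
  rec[c("nct_id", "allocation", "masking_roles", "arms")]
}

#' Write trial records back to the normalized JSON schema
#'
#' Inverse of [load_trial_records()]; round-trips losslessly.
#'
#' @param records List of trial records.
#' @param path Output path.
#' @export
write_trial_records <- function(records, path) {
  jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Trial quality filter: randomized with participant blinding
#'
#' Keeps only trials whose design makes the comparison trustworthy: allocation
#' must be randomized and the masking roles must include the participant.
#' Open-label and non-randomized trials fail.
#'
#' @param record A trial record.
#' @return `TRUE` iff the record passes.
#' @export
passes_quality_filter <- function(record) {
  identical(record$allocation, "randomized") &&
    "participant" %in% record$masking_roles
}

#' Drop treatment arms below a minimum enrolment
#'
#' Small arms rarely have the power to support a stable odds-ratio estimate;
#' arms with fewer than `min_n` enrolled participants are removed. The cutoff
#' applies to enrolment (`n_participants`), not to per-event at-risk counts.
#'
#' @param record A trial record.
#' @param min_n Minimum arm size retained (default 100; an arm of 99 is
#'   dropped, an arm of 100 kept).
#' @return The record with small arms removed, otherwise unchanged.
#' @export
filter_small_arms <- function(record, min_n = 100L) {
  stopifnot(min_n >= 1)
  keep <- vapply(record$arms, function(a) a$n_participants >= min_n, logical(1))
  record$arms <- record$arms[keep]
  record
}

tokenize_label <- function(x) {
  unique(regmatches(tolower(x), gregexpr("[a-z0-9]+", tolower(x)))[[1]])
}

#' Map a free-text intervention label to a single drug ingredient
#'
#' Matches an arm label against a drug-name lexicon by token overlap. The
#' label is lower-cased and split into alphanumeric token runs; the lexicon
#' entry maximizing (shared tokens) / (label tokens) wins, and is accepted
#' only when that fraction is at least 0.5 and the entry maps to exactly one
#' ingredient. Labels containing a plus sign are rejected outright: they
#' usually denote combination treatments that name matching cannot resolve
#' reliably.
#'
#' @param label Free-text intervention description.
#' @param lexicon Data frame with columns `name`, `ingredient_code`,
#'   `n_ingredients` (see [read_lexicon()]).
#' @return A list with `ingredient` (the code, or `NA`) and `reason` (`NA` on
#'   success, else one of `"plus_sign"`, `"low_overlap"`,
#'   `"multi_ingredient"`, `"no_match"`).
#' @examples
#' lex <- data.frame(name = "sitagliptin", ingredient_code = "A10BH01",
#'                   n_ingredients = 1)
#' map_arm_to_ingredient("Sitagliptin phosphate", lex)  # 1/2 tokens: accepted
#' @export
map_arm_to_ingredient <- function(label, lexicon) {
  stopifnot(is.data.frame(lexicon), nrow(lexicon) >= 1)
  reject <- function(reason) list(ingredient = NA_character_, reason = reason)
  if (grepl("+", label, fixed = TRUE)) return(reject("plus_sign"))
  toks <- tokenize_label(label)
  if (length(toks) == 0) return(reject("no_match"))
  overlap <- vapply(lexicon$name, function(nm) {
    length(intersect(toks, tokenize_label(nm))) / length(toks)
  }, numeric(1), USE.NAMES = FALSE)
  if (max(overlap) == 0) return(reject("no_match"))
  best <- which.max(overlap)
  if (overlap[best] < 0.5) return(reject("low_overlap"))
  if (lexicon$n_ingredients[best] != 1) return(reject("multi_ingredient"))
  list(ingredient = lexicon$ingredient_code[best], reason = NA_character_)
}

#' Map an adverse-event vocabulary term to an ICD10 code
#'
#' Exact lookup after case normalization; terms absent from the map return
#' `NA` and are dropped (and tallied) downstream.
#'
#' @param term Adverse-event term as reported.
#' @param ae_map Data frame with columns `term`, `icd10` (see [read_ae_map()]).
#' @return ICD10 code string, or `NA_character_` when unmapped.
#' @export
map_ae_term <- function(term, ae_map) {
  stopifnot(is.data.frame(ae_map))
  hit <- match(tolower(trimws(term)), tolower(trimws(ae_map$term)))
  if (is.na(hit)) NA_character_ else ae_map$icd10[hit]
}

#' Read a drug-name lexicon TSV
#'
#' Tab-separated with header `name`, `ingredient_code`, `n_ingredients`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_lexicon <- function(path) {
  lex <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "ingredient_code", "n_ingredients") %in% names(lex)))
  lex
}

#' Read an adverse-event term map TSV
#'
#' Tab-separated with header `term`, `icd10`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_ae_map <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("term", "icd10") %in% names(m)))
  m
}

#' Extract ingredient-coded arms from one trial record
#'
#' Applies the full per-trial pipeline: the quality filter (optional, for
#' ablation runs), the minimum-arm-size filter, label-to-ingredient mapping
#' (arms that fail to map are dropped), and adverse-event term mapping to
#' ICD10. When several reported terms in one arm map to the same ICD10 code,
#' their affected counts are summed and the at-risk denominator is taken as
#' the largest of the entries (the entries describe overlapping subsets of
#' one arm; summing denominators would double-count patients), with the
#' summed affected count capped at that denominator (a warning reports when
#' the cap binds).
#'
#' @param record A trial record.
#' @param lexicon Drug-name lexicon data frame.
#' @param ae_map Adverse-event map data frame.
#' @param apply_quality_filter If `TRUE` (default), a record failing
#'   [passes_quality_filter()] yields no arms. Set `FALSE` for ablation runs
#'   without the quality filter.
#' @param min_arm_size Minimum arm enrolment (see [filter_small_arms()]).
#' @return List of ingredient arms: each a list with `nct_id`, `ingredient`,
#'   `n_participants` and `ae` (data frame `icd10`, `affected`, `at_risk`).
#'   The result carries an attribute `drop_log`, a named integer vector
#'   counting arms dropped per reason and unmapped adverse-event terms.
#' @export
extract_ingredient_arms <- function(record, lexicon, ae_map,
                                    apply_quality_filter = TRUE,
                                    min_arm_size = 100L) {
  log <- c(quality_filter = 0L, small_arm = 0L, plus_sign = 0L,
           low_overlap = 0L, multi_ingredient = 0L, no_match = 0L,
           unmapped_ae_terms = 0L)
  if (apply_quality_filter && !passes_quality_filter(record)) {
    log["quality_filter"] <- length(record$arms)
    return(structure(list(), drop_log = log))
  }
  n_before <- length(record$arms)
  record <- filter_small_arms(record, min_arm_size)
  log["small_arm"] <- n_before - length(record$arms)

  out <- list()
  for (arm in record$arms) {
    mapped <- map_arm_to_ingredient(arm$label, lexicon)
    if (is.na(mapped$ingredient)) {
      log[mapped$reason] <- log[mapped$reason] + 1L
      next
    }
    codes <- vapply(arm$adverse_events, function(ae) map_ae_term(ae$term, ae_map),
                    character(1))
    log["unmapped_ae_terms"] <- log["unmapped_ae_terms"] + sum(is.na(codes))
    keep <- !is.na(codes)
    ae_df <- data.frame(
      icd10 = codes[keep],
      affected = vapply(arm$adverse_events[keep], `[[`, integer(1), "affected"),
      at_risk = vapply(arm$adverse_events[keep], `[[`, integer(1), "at_risk"),
      stringsAsFactors = FALSE
    )
    if (nrow(ae_df) > 0 && anyDuplicated(ae_df$icd10)) {
      ae_df <- merge_duplicate_codes(ae_df)
    }
    out[[length(out) + 1L]] <- list(
      nct_id = record$nct_id,
      ingredient = mapped$ingredient,
      n_participants = arm$n_participants,
      ae = ae_df
    )
  }
  # canonical order: by ingredient, so output is invariant to input arm order
  if (length(out) > 1L) {
    out <- out[order(vapply(out, `[[`, character(1), "ingredient"))]
  }
  structure(out, drop_log = log)
}

merge_duplicate_codes <- function(ae_df) {
  affected <- tapply(ae_df$affected, ae_df$icd10, sum)
  at_risk <- tapply(ae_df$at_risk, ae_df$icd10, max)
  if (any(affected > at_risk)) {
    warning("affected count capped at at-risk denominator after merging ",
            "duplicate ICD10 terms within an arm")
    affected <- pmin(affected, at_risk)
  }
  data.frame(icd10 = names(affected),
             affected = as.integer(affected),
             at_risk = as.integer(at_risk),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the ingest pipeline over a set of trial records
#'
#' Convenience wrapper: extracts ingredient arms from every record, merging
#' each trial's dose arms, and accumulates the per-filter drop log.
#'
#' @inheritParams extract_ingredient_arms
#' @param records List of trial records from [load_trial_records()].
#' @param verbose If `TRUE`, print drop counts per filter to standard error.
#' @return List of ingredient arms (all trials), with attribute `drop_log`.
#' @export
ingest_trials <- function(records, lexicon, ae_map,
                          apply_quality_filter = TRUE, min_arm_size = 100L,
                          verbose = FALSE) {
  total_log <- NULL
  arms <- list()
  for (rec in records) {
    a <- extract_ingredient_arms(rec, lexicon, ae_map,
                                 apply_quality_filter = apply_quality_filter,
                                 min_arm_size = min_arm_size)
    lg <- attr(a, "drop_log")
    total_log <- if (is.null(total_log)) lg else total_log + lg
    arms <- c(arms, merge_dose_arms(a))
  }
  if (verbose) {
    message("ingest: ", length(records), " trials -> ", length(arms),
            " ingredient arms; dropped [",
            paste(names(total_log), total_log, sep = "=", collapse = ", "), "]")
  }
  structure(arms, drop_log = total_log)
}
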