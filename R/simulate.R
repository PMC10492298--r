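#' Specification for a seeded reference-set simulation
#'
#' Bundles the generative conditions under which synthetic comparisons are
#' drawn: the number of comparisons, a symmetric discrete prior over log odds
#' ratios (default the spike-and-slab 0.8 at 0, 0.1 at each of
#' \eqn{\pm\log 4}), the per-arm size range and baseline event-rate range,
#' and the root seed. The same seed yields identical output.
#'
#' @param m_comparisons Number of comparisons to simulate.
#' @param prior_spec Data frame with columns `atom` (log odds ratio) and
#'   `weight`; must be symmetric about 0 with weights summing to 1.
#' @param arm_size_range Integer interval for per-arm enrolment.
#' @param base_rate_range Interval for the drug-B event probability.
#' @param seed Root seed; all randomness derives from it.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(m_comparisons = 5000L,
                            prior_spec = data.frame(
                              atom = c(-log(4), 0, log(4)),
                              weight = c(0.1, 0.8, 0.1)),
                            arm_size_range = c(200L, 2000L),
                            base_rate_range = c(0.01, 0.3),
                            seed = 1L) {
  stopifnot(m_comparisons >= 1,
            all(c("atom", "weight") %in% names(prior_spec)),
            abs(sum(prior_spec$weight) - 1) < 1e-8,
            all(prior_spec$weight >= 0),
            length(arm_size_range) == 2, arm_size_range[1] >= 1,
            arm_size_range[1] <= arm_size_range[2],
            length(base_rate_range) == 2, base_rate_range[1] > 0,
            base_rate_range[2] < 1,
            base_rate_range[1] <= base_rate_range[2])
  # symmetry: every atom's mirror carries the same weight
  o <- order(prior_spec$atom)
  ps <- prior_spec[o, , drop = FALSE]
  if (!isTRUE(all.equal(ps$atom, -rev(ps$atom))) ||
      !isTRUE(all.equal(ps$weight, rev(ps$weight)))) {
    stop("prior_spec must be symmetric about 0")
  }
  structure(list(m_comparisons = as.integer(m_comparisons), prior_spec = ps,
                 arm_size_range = as.integer(arm_size_range),
                 base_rate_range = base_rate_range, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Draw true log-odds-ratio effects from the simulation prior
#'
#' @param spec A [simulation_spec()].
#' @return Numeric vector of `m_comparisons` i.i.d. draws from the discrete
#'   prior (seeded; same spec, same draws).
#' @export
sample_prior_effects <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, {
    idx <- sample.int(nrow(spec$prior_spec), spec$m_comparisons,
                      replace = TRUE, prob = spec$prior_spec$weight)
    spec$prior_spec$atom[idx]
  })
}

#' Event probability of drug A given the baseline rate and a log odds ratio
#'
#' `plogis(qlogis(base_rate) + omega)`: the drug-A event probability whose
#' odds are `exp(omega)` times the drug-B odds.
#'
#' @param base_rate Drug-B event probability.
#' @param omega Log odds ratio.
#' @return Drug-A event probability.
#' @export
effect_event_prob <- function(base_rate, omega) {
  stats::plogis(stats::qlogis(base_rate) + omega)
}

#' Simulate a single drug-vs-drug comparison
#'
#' Two binomial arms: drug-B events with probability `base_rate`, drug-A
#' events with the odds shifted by `omega` (see [effect_event_prob()]). Under
#' this generative model the conditional law of the table given its margins
#' is exactly the noncentral hypergeometric likelihood the package fits, so
#' parameter recovery on simulated data is a faithful end-to-end test. The
#' returned record is not pre-oriented.
#'
#' @param omega True log odds ratio (drug A vs drug B).
#' @param n_a,n_b Arm sizes.
#' @param base_rate Drug-B event probability.
#' @param seed Seed for the two binomial draws.
#' @param id Comparison index used to synthesize codes.
#' @return One-row comparison data frame (see [build_comparisons()]) with an
#'   extra `omega_true` column.
#' @export
simulate_comparison <- function(omega, n_a, n_b, base_rate, seed,
                                id = 1L) {
  stopifnot(n_a >= 1, n_b >= 1, base_rate > 0, base_rate < 1)
  p_a <- effect_event_prob(base_rate, omega)
  xs <- withr::with_seed(seed, {
    c(stats::rbinom(1L, n_a, p_a), stats::rbinom(1L, n_b, base_rate))
  })
  drug_a <- sprintf("DA%05d", id)
  drug_b <- sprintf("DB%05d", id)
  ae <- sprintf("AE%05d", id)
  data.frame(
    comparison_id = comparison_id(drug_a, drug_b, ae),
    ae_icd10 = ae, drug_a = drug_a, drug_b = drug_b,
    nct_ids = sprintf("SIM%05d", id),
    x_a = xs[1], y_a = n_a - xs[1], x_b = xs[2], y_b = n_b - xs[2],
    omega_true = omega,
    stringsAsFactors = FALSE
  )
}

#' Simulate a full synthetic reference dataset
#'
#' Draws true effects from the spec's prior, arm sizes and base rates
#' uniformly from their ranges, and one table per comparison via
#' [simulate_comparison()]. Seed substreams are derived deterministically
#' from the root seed (root for the effect draws, root + comparison index for
#' each table), so output is reproducible element-wise.
#'
#' @param spec A [simulation_spec()].
#' @return Comparison data frame with `omega_true`, not oriented.
#' @export
simulate_reference_data <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  omega <- sample_prior_effects(spec)
  m <- spec$m_comparisons
  pars <- withr::with_seed(spec$seed + 1L, {
    list(
      n_a = sample(spec$arm_size_range[1]:spec$arm_size_range[2], m,
                   replace = TRUE),
      n_b = sample(spec$arm_size_range[1]:spec$arm_size_range[2], m,
                   replace = TRUE),
      base_rate = stats::runif(m, spec$base_rate_range[1],
                               spec$base_rate_range[2])
    )
  })
  p_a <- effect_event_prob(pars$base_rate, omega)
  xs <- withr::with_seed(spec$seed + 2L, {
    cbind(stats::rbinom(m, pars$n_a, p_a),
          stats::rbinom(m, pars$n_b, pars$base_rate))
  })
  idx <- seq_len(m)
  drug_a <- sprintf("DA%05d", idx)
  drug_b <- sprintf("DB%05d", idx)
  ae <- sprintf("AE%05d", idx)
  data.frame(
    comparison_id = paste(ae, drug_a, drug_b, sep = "|"),
    ae_icd10 = ae, drug_a = drug_a, drug_b = drug_b,
    nct_ids = sprintf("SIM%05d", idx),
    x_a = xs[, 1], y_a = pars$n_a - xs[, 1],
    x_b = xs[, 2], y_b = pars$n_b - xs[, 2],
    omega_true = omega,
    stringsAsFactors = FALSE
  )
}

#' Simulate a non-experimental method's per-comparison outputs
#'
#' A stand-in for an observational pipeline with controllable power and
#' systematic bias: for each comparison an independent 2x2 study is drawn
#' with true log odds ratio `omega_true + bias` and `power_n` patients per
#' arm, and the method reports the two-sided normal-approximation p-value of
#' the continuity-corrected (0.5) log odds ratio together with the direction
#' of its sign ("A" when positive). `bias = 0` models an unconfounded method;
#' `|bias| > 0` models systematic confounding (e.g. `bias = -2 * omega_true`
#' flips the expected direction).
#'
#' @param comparisons Data frame with `comparison_id` and `omega_true`
#'   (aligned to the oriented reference direction; [orient_comparisons()]
#'   flips `omega_true` when it swaps a row).
#' @param power_n Patients per arm in the synthetic observational study.
#' @param bias Additive log-odds-ratio confounding bias (scalar or
#'   per-comparison vector).
#' @param base_rate Baseline (drug-B) event probability of the synthetic
#'   study.
#' @param seed Seed.
#' @return Method-result data frame (`comparison_id`, `p_value`,
#'   `direction`).
#' @export
simulate_method_results <- function(comparisons, power_n, bias = 0,
                                    base_rate = 0.1, seed = 1L) {
  stopifnot(all(c("comparison_id", "omega_true") %in% names(comparisons)),
            power_n >= 1)
  m <- nrow(comparisons)
  p_a <- effect_event_prob(base_rate, comparisons$omega_true + bias)
  xs <- withr::with_seed(seed, {
    cbind(stats::rbinom(m, power_n, p_a),
          stats::rbinom(m, power_n, base_rate))
  })
  xa <- xs[, 1] + 0.5
  ya <- power_n - xs[, 1] + 0.5
  xb <- xs[, 2] + 0.5
  yb <- power_n - xs[, 2] + 0.5
  lor <- log(xa * yb / (xb * ya))
  se <- sqrt(1 / xa + 1 / ya + 1 / xb + 1 / yb)
  data.frame(
    comparison_id = comparisons$comparison_id,
    p_value = 2 * stats::pnorm(-abs(lor) / se),
    direction = ifelse(lor >= 0, "A", "B"),
    stringsAsFactors = FALSE
  )
}

#' Deterministic fixture trial records exercising every ingest rule
#'
#' A small, fully enumerable set of trial records covering each filter of the
#' ingest pipeline: a non-randomized trial and an open-label trial (quality
#' filter), a 99-participant arm (size boundary), a plus-sign label, a
#' multi-ingredient label, a low-token-overlap label, an unmappable label, an
#' unmapped adverse-event term, two terms mapping to one ICD10 code within an
#' arm, two trials sharing a drug pair and adverse event (cross-trial
#' pooling), and duplicate-dose arms within one trial (dose merging). The
#' seed only shuffles the order of arms within each record (the extraction is
#' order-invariant); content is fixed.
#'
#' With the companion [fixture_lexicon()] and [fixture_ae_map()], full
#' ingestion with the quality filter yields 4 pooled comparisons
#' (glipizide-sitagliptin for nausea and headache, alprazolam-diazepam for
#' headache and dizziness); without the quality filter, 6 (adding
#' nicotine-bupropion hiccups and dizziness).
#'
#' @param seed Seed for the within-record arm shuffle.
#' @return List of trial records.
#' @export
generate_fixture_trials <- function(seed = 1L) {
  ae <- function(term, affected, at_risk) {
    list(term = term, affected = as.integer(affected),
         at_risk = as.integer(at_risk))
  }
  arm <- function(label, n, aes) {
    list(label = label, n_participants = as.integer(n), adverse_events = aes)
  }
  records <- list(
    list(nct_id = "NCT0000001", allocation = "randomized",
         masking_roles = c("participant", "investigator"),
         arms = list(
           arm("Glipizide", 200, list(ae("Nausea", 10, 200),
                                      ae("Feeling queasy", 2, 200),
                                      ae("Headache", 5, 200),
                                      ae("Strange dreams", 3, 200))),
           arm("Sitagliptin phosphate", 210, list(ae("Nausea", 4, 210),
                                                  ae("Headache", 6, 210)))
         )),
    list(nct_id = "NCT0000002", allocation = "randomized",
         masking_roles = "participant",
         arms = list(
           arm("Glipizide", 150, list(ae("Nausea", 3, 150))),
           arm("Sitagliptin", 160, list(ae("Nausea", 2, 160)))
         )),
    list(nct_id = "NCT0000003", allocation = "non_randomized",
         masking_roles = "participant",
         arms = list(
           arm("Nicotine", 300, list(ae("Hiccups", 20, 300))),
           arm("Bupropion", 300, list(ae("Hiccups", 1, 300)))
         )),
    list(nct_id = "NCT0000004", allocation = "randomized",
         masking_roles = character(),
         arms = list(
           arm("Nicotine", 400, list(ae("Dizziness", 8, 400))),
           arm("Bupropion", 400, list(ae("Dizziness", 9, 400)))
         )),
    list(nct_id = "NCT0000005", allocation = "randomized",
         masking_roles = c("participant", "care_provider"),
         arms = list(
           arm("Alprazolam tablets 1 mg", 120, list(ae("Headache", 6, 120),
                                                    ae("Dizziness", 2, 120))),
           arm("Alprazolam tablets 2 mg", 130, list(ae("Headache", 9, 130),
                                                    ae("Dizziness", 4, 130))),
           arm("Diazepam", 140, list(ae("Headache", 7, 140),
                                     ae("Dizziness", 3, 140))),
           arm("Diazepam oral", 99, list(ae("Headache", 2, 99))),
           arm("Aspirin + Dipyridamole", 200, list(ae("Headache", 10, 200))),
           arm("Aspirin dipyridamole combo", 180, list(ae("Headache", 9, 180))),
           arm("Tocilizumab infusion", 150, list(ae("Headache", 5, 150))),
           arm("Nicotine patch 21 mg daily", 110, list(ae("Headache", 4, 110)))
         ))
  )
  withr::with_seed(seed, {
    lapply(records, function(rec) {
      rec$arms <- rec$arms[sample.int(length(rec$arms))]
      rec
    })
  })
}

#' @rdname generate_fixture_trials
#' @export
fixture_lexicon <- function() {
  data.frame(
    name = c("glipizide", "sitagliptin", "nicotine", "bupropion",
             "alprazolam tablets", "diazepam", "aspirin dipyridamole"),
    ingredient_code = c("A10BB07", "A10BH01", "N07BA01", "N06AX12",
                        "N05BA12", "N05BA01", "B01AC30"),
    n_ingredients = c(1L, 1L, 1L, 1L, 1L, 1L, 2L),
    stringsAsFactors = FALSE
  )
}

#' @rdname generate_fixture_trials
#' @export
fixture_ae_map <- function() {
  data.frame(
    term = c("nausea", "feeling queasy", "headache", "hiccups", "dizziness"),
    icd10 = c("R11.0", "R11.0", "R51", "R06.6", "R42"),
    stringsAsFactors = FALSE
  )
}
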