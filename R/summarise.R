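#' Tabulate rubric categories per evidence column
#'
#' @param grades Output of [grade_approvals()].
#' @return One row per (column, category): `count`, `denominator` (approvals
#'   for which the column was required), `fraction` and `percent`
#'   (half-away-from-zero integer rounding; `NA` for `not_required` rows and
#'   when the denominator is zero). The raw fraction is always emitted
#'   because integer rounding of dossier percentages is lossy (21/26 prints
#'   as both 80% and 81% depending on the rounding rule).
#' @export
summarise_grades <- function(grades) {
  if (nrow(grades) == 0) {
    return(tibble::tibble(column = character(), category = character(),
                          count = integer(), denominator = integer(),
                          fraction = double(), percent = double()))
  }
  denoms <- grades |>
    dplyr::group_by(.data$column) |>
    dplyr::summarise(
      denominator = sum(.data$category != "not_required"), .groups = "drop"
    )
  grades |>
    dplyr::count(.data$column, .data$category, name = "count") |>
    dplyr::left_join(denoms, by = "column") |>
    dplyr::mutate(
      fraction = dplyr::if_else(
        .data$category == "not_required" | .data$denominator == 0,
        NA_real_, .data$count / .data$denominator
      ),
      percent = round_half_up(100 * .data$fraction)
    ) |>
    dplyr::arrange(.data$column, .data$category)
}

#' Reporting-completeness triage of a corpus
#'
#' Counts how many arm comparisons fall in each reporting tier after
#' derivation (a `p_and_n_only` comparison without a direction is counted as
#' insufficient, since it cannot be signed), and how many comparisons and
#' studies are analyzable — a study is analyzable when at least one of its
#' comparisons is.
#'
#' @inheritParams pool_effects
#' @param effects Effect estimates from [derive_effects()]; derived with
#'   `approved_doses_only = TRUE` when omitted, matching the convention that
#'   the analyzable denominator covers approved doses only.
#' @return A list of two tibbles: `$tiers` (per-tier comparison and study
#'   counts with fractions) and `$analyzable` (comparison- and study-level
#'   analyzable counts, fractions and integer percents).
#' @export
triage_report <- function(corpus, effects = NULL) {
  effects <- effects %||% derive_effects(corpus, approved_doses_only = TRUE)
  tier_levels <- CORPUS_ENUMS$reporting_tier
  tiers <- effects |>
    dplyr::mutate(tier_used = factor(.data$tier_used,
                                     levels = tier_levels)) |>
    dplyr::group_by(.data$tier_used, .drop = FALSE) |>
    dplyr::summarise(
      n_comparisons = dplyr::n(),
      n_studies = dplyr::n_distinct(.data$trial_id),
      .groups = "drop"
    ) |>
    dplyr::rename(tier = "tier_used") |>
    dplyr::mutate(
      tier = as.character(.data$tier),
      fraction_comparisons = ifelse(
        nrow(effects) > 0, .data$n_comparisons / nrow(effects), NA_real_
      )
    )
  n_cmp <- nrow(effects)
  n_std <- dplyr::n_distinct(effects$trial_id)
  n_cmp_ok <- sum(effects$usable)
  n_std_ok <- dplyr::n_distinct(effects$trial_id[effects$usable])
  analyzable <- tibble::tibble(
    unit = c("comparisons", "studies"),
    n_analyzable = c(n_cmp_ok, n_std_ok),
    n_total = c(n_cmp, n_std),
    fraction = ifelse(c(n_cmp, n_std) > 0,
                      c(n_cmp_ok, n_std_ok) / c(n_cmp, n_std), NA_real_),
    percent = round_half_up(100 * .data$fraction)
  )
  list(tiers = tiers, analyzable = analyzable)
}

#' Tally statistical significance within strata
#'
#' Works on study-level effect estimates (columns `d`, `p_two_sided`) or on
#' pooled estimates (`d_pooled`, `p_two_sided`). Significance is two-sided at
#' `alpha`; under the sign convention, a significant negative effect favours
#' the investigational drug.
#'
#' @param x A tibble of effect or pooled estimates.
#' @param by Character vector of stratification columns (default design
#'   phase by comparator class).
#' @param alpha Two-sided significance threshold.
#' @return One row per stratum: `n_total`, `n_significant`, `n_favour_drug`,
#'   `n_favour_comparator`.
#' @export
significance_tally <- function(x, by = c("design_phase", "comparator_class"),
                               alpha = 0.05) {
  d_col <- if ("d" %in% names(x)) "d" else "d_pooled"
  if ("usable" %in% names(x)) x <- dplyr::filter(x, .data$usable)
  x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_significant = sum(.data$p_two_sided < alpha, na.rm = TRUE),
      n_favour_drug = sum(.data$p_two_sided < alpha &
                            .data[[d_col]] < 0, na.rm = TRUE),
      n_favour_comparator = sum(.data$p_two_sided < alpha &
                                  .data[[d_col]] > 0, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(by)))
}

#' Effect-size versus p-value scatter data
#'
#' The working display of a dossier meta-assessment: every analyzable
#' comparison (top) and every pooled drug/dose (bottom) as a (d, p) point,
#' stratified by design phase and comparator class. The p-values are emitted
#' raw; plotting on a log scale is a display concern.
#'
#' @param effects Effect estimates from [derive_effects()].
#' @param pooled Pooled estimates from [pool_effects()].
#' @return A list of two tibbles, `$study` and `$meta`, each with
#'   `design_phase`, `comparator_class`, identifying columns, `d` and `p`,
#'   in a deterministic row order.
#' @export
scatter_data <- function(effects, pooled) {
  study <- effects |>
    dplyr::filter(.data$usable) |>
    dplyr::transmute(
      design_phase = .data$design_phase,
      comparator_class = .data$comparator_class,
      trial_id = .data$trial_id,
      investigational_arm_id = .data$investigational_arm_id,
      d = .data$d,
      p = .data$p_two_sided
    ) |>
    dplyr::arrange(.data$design_phase, .data$comparator_class,
                   .data$trial_id, .data$investigational_arm_id)
  key_cols <- intersect(c("approval_id", "drug", "daily_dose"),
                        names(pooled))
  meta <- pooled |>
    dplyr::transmute(
      design_phase = .data$design_phase,
      comparator_class = .data$comparator_class,
      dplyr::across(dplyr::all_of(key_cols)),
      d = .data$d_pooled,
      p = .data$p_two_sided
    ) |>
    dplyr::arrange(.data$design_phase, .data$comparator_class,
                   dplyr::across(dplyr::all_of(key_cols)))
  list(study = study, meta = meta)
}

#' Qualitative Cohen benchmark labels
#'
#' The conventional small/medium/large anchors at |d| = 0.2, 0.5, 0.8.
#' Purely descriptive; no decision logic in the package uses them.
#'
#' @param d Numeric vector of standardized mean differences.
#' @return Character vector: `"negligible"`, `"small"`, `"medium"`,
#'   `"large"`.
#' @export
cohen_label <- function(d) {
  a <- abs(d)
  dplyr::case_when(
    a < 0.2 ~ "negligible",
    a < 0.5 ~ "small",
    a < 0.8 ~ "medium",
    TRUE ~ "large"
  )
}

#' One-call corpus appraisal
#'
#' Runs the full pipeline — derivation cascade, dose-filtered pooling,
#' grading, triage and tallies — and returns every intermediate table.
#'
#' @inheritParams pool_effects
#' @return A list: `effects` (all comparisons), `effects_pooled_subset`
#'   (approved doses only), `pooled`, `grades`, `grades_summary`, `triage`,
#'   `significance_study`, `significance_pooled`, `medians` (pooled-effect
#'   median and range per stratum).
#' @export
summarise_corpus <- function(corpus, alpha = 0.05, by_indication = TRUE) {
  effects_all <- derive_effects(corpus, approved_doses_only = FALSE)
  effects_dosed <- derive_effects(corpus, approved_doses_only = TRUE)
  pooled <- pool_effects(corpus, effects = effects_dosed,
                         by_indication = by_indication, alpha = alpha)
  grades <- grade_approvals(corpus, effects = effects_all, alpha = alpha)
  strata <- expand.grid(
    design_phase = CORPUS_ENUMS$design_phase,
    comparator_class = CORPUS_ENUMS$comparator_class,
    stringsAsFactors = FALSE
  )
  medians <- purrr::pmap(strata, function(design_phase, comparator_class) {
    dplyr::bind_cols(
      tibble::tibble(design_phase = design_phase,
                     comparator_class = comparator_class),
      median_pooled_effect(pooled, design_phase, comparator_class)
    )
  }) |> dplyr::bind_rows()
  list(
    effects = effects_all,
    effects_pooled_subset = effects_dosed,
    pooled = pooled,
    grades = grades,
    grades_summary = summarise_grades(grades),
    triage = triage_report(corpus, effects = effects_dosed),
    significance_study = significance_tally(effects_dosed, alpha = alpha),
    significance_pooled = significance_tally(pooled, alpha = alpha),
    medians = medians
  )
}
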