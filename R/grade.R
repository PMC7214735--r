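GRADE_COLUMNS <- c(
  "superiority_vs_active_initiation", "non_inferiority_vs_active",
  "superiority_vs_placebo_initiation", "continuation_vs_active",
  "continuation_vs_placebo", "active_grouped", "placebo_grouped"
)

#' Grade every trial's verdict per comparator class
#'
#' Applies the trial-level rubric. For superiority comparisons a trial is
#' `positive` when its primary comparison is statistically significant
#' (two-sided p < `alpha`) in the investigational drug's favour, `negative`
#' when a comparison was reported but was not significant (or favoured the
#' comparator), and `uncompared` when a comparator arm was randomised but no
#' drug-vs-comparator comparison was reported — the "internal positive
#' control for assay sensitivity" pattern. For non-inferiority hypotheses the
#' dossier's reported verdict is used; when no verdict was recorded but an
#' outcome-scale contrast CI and a non-inferiority boundary are available,
#' the trial is positive when the CI bound on the unfavourable side stays
#' within the boundary.
#'
#' @inheritParams pool_effects
#' @param effects Effect estimates from [derive_effects()]; derived without
#'   the dose filter when omitted (grading reflects the evidence as
#'   presented, not the meta-analysable subset).
#' @return One row per (trial, comparator class) for which the trial
#'   randomised an arm of that class: `approval_id`, `trial_id`,
#'   `design_phase`, `hypothesis`, `pooled_analysis`, `comparator_class`,
#'   `verdict` (`positive` / `negative` / `uncompared`).
#' @export
grade_trials <- function(corpus, effects = NULL, alpha = 0.05) {
  effects <- effects %||% derive_effects(corpus, approved_doses_only = FALSE)
  classes_present <- corpus$arms |>
    dplyr::mutate(comparator_class = dplyr::case_when(
      .data$role == "active_comparator" ~ "active",
      .data$role == "placebo" ~ "placebo",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(.data$comparator_class)) |>
    dplyr::distinct(.data$trial_id, .data$comparator_class)

  grid <- corpus$trials |>
    dplyr::select("trial_id", "approval_id", "design_phase", "hypothesis",
                  "pooled_analysis", "reported_ni_verdict",
                  "non_inferiority_boundary") |>
    dplyr::inner_join(classes_present, by = "trial_id")

  eff_sum <- effects |>
    dplyr::group_by(.data$trial_id, .data$comparator_class) |>
    dplyr::summarise(
      n_cmp = dplyr::n(),
      any_sig_favour = any(.data$usable & .data$p_two_sided < alpha &
                             .data$d < 0, na.rm = TRUE),
      .groups = "drop"
    )

  ni_ci <- ni_contrast_ci(corpus)

  grid |>
    dplyr::left_join(eff_sum, by = c("trial_id", "comparator_class")) |>
    dplyr::left_join(ni_ci, by = c("trial_id", "comparator_class")) |>
    dplyr::mutate(
      n_cmp = dplyr::coalesce(.data$n_cmp, 0L),
      verdict = dplyr::case_when(
        .data$n_cmp == 0 ~ "uncompared",
        .data$hypothesis == "non_inferiority" &
          .data$comparator_class == "active" &
          .data$reported_ni_verdict %in% c("positive", "negative") ~
          .data$reported_ni_verdict,
        .data$hypothesis == "non_inferiority" &
          .data$comparator_class == "active" &
          !is.na(.data$ni_within_boundary) ~
          ifelse(.data$ni_within_boundary, "positive", "negative"),
        .data$any_sig_favour %in% TRUE ~ "positive",
        TRUE ~ "negative"
      )
    ) |>
    dplyr::select("approval_id", "trial_id", "design_phase", "hypothesis",
                  "pooled_analysis", "comparator_class", "verdict") |>
    dplyr::arrange(.data$approval_id, .data$trial_id, .data$comparator_class)
}

# outcome-scale contrast CI for the fallback non-inferiority decision
ni_contrast_ci <- function(corpus, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  ar <- corpus$arms
  cmp <- corpus$comparisons |>
    dplyr::inner_join(
      dplyr::filter(corpus$trials, .data$hypothesis == "non_inferiority",
                    !is.na(.data$non_inferiority_boundary)) |>
        dplyr::select("trial_id", "non_inferiority_boundary"),
      by = "trial_id"
    )
  if (nrow(cmp) == 0) {
    return(tibble::tibble(trial_id = character(),
                          comparator_class = character(),
                          ni_within_boundary = logical()))
  }
  stat <- function(ids, col) ar[[col]][match(ids, ar$arm_id)]
  est <- cmp$contrast_value
  se <- cmp$contrast_se
  mi <- stat(cmp$investigational_arm_id, "mean_change")
  mc <- stat(cmp$comparator_arm_id, "mean_change")
  si <- stat(cmp$investigational_arm_id, "sd_change")
  sc <- stat(cmp$comparator_arm_id, "sd_change")
  ni <- stat(cmp$investigational_arm_id, "n_randomised")
  nc <- stat(cmp$comparator_arm_id, "n_randomised")
  from_arms <- is.na(est) & !is.na(mi) & !is.na(mc) & !is.na(si) & !is.na(sc)
  est[from_arms] <- (mi - mc)[from_arms]
  se[from_arms] <- sqrt(si^2 / ni + sc^2 / nc)[from_arms]
  lo <- est - z * se
  hi <- est + z * se
  nib <- cmp$non_inferiority_boundary
  within <- ifelse(cmp$better_is == "lower", hi <= nib, lo >= nib)
  tibble::tibble(
    trial_id = cmp$trial_id,
    comparator_class = cmp$comparator_class,
    ni_within_boundary = within
  ) |>
    dplyr::filter(!is.na(.data$ni_within_boundary)) |>
    dplyr::distinct(.data$trial_id, .data$comparator_class,
                    .keep_all = TRUE)
}

category_from_counts <- function(n_positive) {
  dplyr::case_when(
    n_positive >= 2 ~ "robust",
    n_positive == 1 ~ "single",
    TRUE ~ "none"
  )
}

#' Grade each approval's evidence per rubric column
#'
#' Aggregates trial verdicts into the rubric categories per evidence column:
#' `robust` (at least two positive studies), `single` (exactly one positive
#' study, negatives allowed), `none` (only negative studies, a comparator
#' never compared, or no study at all) or `not_required` (the dossier
#' explicitly waived that comparison class). The grouped columns merge
#' initiation and continuation evidence by taking the stronger category.
#'
#' @inheritParams grade_trials
#' @return One row per approval and rubric column: `approval_id`, `column`,
#'   `category`, `n_positive`, `n_negative`, `n_uncompared`.
#' @export
grade_approvals <- function(corpus, effects = NULL, alpha = 0.05) {
  verdicts <- grade_trials(corpus, effects, alpha)
  ap <- corpus$approvals

  count_block <- function(v, column) {
    base <- tibble::tibble(approval_id = ap$approval_id)
    counts <- v |>
      dplyr::group_by(.data$approval_id) |>
      dplyr::summarise(
        n_positive = sum(.data$verdict == "positive"),
        n_negative = sum(.data$verdict == "negative"),
        n_uncompared = sum(.data$verdict == "uncompared"),
        .groups = "drop"
      )
    base |>
      dplyr::left_join(counts, by = "approval_id") |>
      dplyr::mutate(
        dplyr::across(dplyr::starts_with("n_"),
                      ~ dplyr::coalesce(.x, 0L)),
        column = column,
        category = category_from_counts(.data$n_positive)
      )
  }

  blocks <- list(
    count_block(
      dplyr::filter(verdicts, .data$design_phase == "initiation",
                    .data$hypothesis == "superiority",
                    .data$comparator_class == "active"),
      "superiority_vs_active_initiation"
    ),
    count_block(
      dplyr::filter(verdicts, .data$design_phase == "initiation",
                    .data$hypothesis == "non_inferiority",
                    .data$comparator_class == "active"),
      "non_inferiority_vs_active"
    ),
    count_block(
      dplyr::filter(verdicts, .data$design_phase == "initiation",
                    .data$comparator_class == "placebo"),
      "superiority_vs_placebo_initiation"
    ),
    count_block(
      dplyr::filter(verdicts, .data$design_phase == "continuation",
                    .data$comparator_class == "active"),
      "continuation_vs_active"
    ),
    count_block(
      dplyr::filter(verdicts, .data$design_phase == "continuation",
                    .data$comparator_class == "placebo"),
      "continuation_vs_placebo"
    )
  )
  grades <- dplyr::bind_rows(blocks)

  # requirement flags switch categories to not_required
  flags <- ap[c("approval_id", "comparative_evidence_required",
                "continuation_evidence_required")]
  grades <- grades |>
    dplyr::left_join(flags, by = "approval_id") |>
    dplyr::mutate(
      category = dplyr::case_when(
        !.data$comparative_evidence_required &
          .data$column %in% c("superiority_vs_active_initiation",
                              "non_inferiority_vs_active",
                              "continuation_vs_active") ~ "not_required",
        !.data$continuation_evidence_required &
          .data$column %in% c("continuation_vs_active",
                              "continuation_vs_placebo") ~ "not_required",
        TRUE ~ .data$category
      )
    )

  grouped <- function(init_col, cont_col, column) {
    wide <- grades |>
      dplyr::filter(.data$column %in% c(init_col, cont_col)) |>
      dplyr::group_by(.data$approval_id) |>
      dplyr::summarise(
        n_positive = sum(.data$n_positive[.data$category != "not_required"]),
        n_negative = sum(.data$n_negative[.data$category != "not_required"]),
        n_uncompared = sum(
          .data$n_uncompared[.data$category != "not_required"]
        ),
        all_not_required = all(.data$category == "not_required"),
        # the stronger of the two constituent categories, not their sum:
        # one positive initiation and one positive continuation trial remain
        # "single" evidence for either design
        best = max(c(0L, 1L, 2L)[match(
          .data$category[.data$category != "not_required"],
          c("none", "single", "robust")
        )], -1L, na.rm = TRUE),
        .groups = "drop"
      )
    wide |>
      dplyr::mutate(
        column = column,
        category = dplyr::case_when(
          .data$all_not_required ~ "not_required",
          .data$best >= 2 ~ "robust",
          .data$best == 1 ~ "single",
          TRUE ~ "none"
        )
      ) |>
      dplyr::select("approval_id", "n_positive", "n_negative",
                    "n_uncompared", "column", "category")
  }

  grades <- dplyr::bind_rows(
    grades |>
      dplyr::select("approval_id", "n_positive", "n_negative",
                    "n_uncompared", "column", "category"),
    grouped("superiority_vs_active_initiation", "continuation_vs_active",
            "active_grouped"),
    grouped("superiority_vs_placebo_initiation", "continuation_vs_placebo",
            "placebo_grouped")
  )

  grades |>
    dplyr::mutate(
      column = factor(.data$column, levels = GRADE_COLUMNS),
      dplyr::across(dplyr::starts_with("n_"), as.integer)
    ) |>
    dplyr::select("approval_id", "column", "category", "n_positive",
                  "n_negative", "n_uncompared") |>
    dplyr::arrange(.data$approval_id, .data$column) |>
    dplyr::mutate(column = as.character(.data$column))
}

HEATMAP_EVIDENCE_CODES <- c(robust = 2, single = 1, none = 0)

#' Build the 12-column category heatmap matrix
#'
#' Rows are approvals; columns 1-7 are the evidence columns (codes
#' 2 = two or more positive studies, 1 = one, 0 = none, `NA` = not required)
#' and columns 8-12 the dossier flags (subgroup basis, bias assessment,
#' safety issue, tolerance issue, divergent opinion) coded 2 = green,
#' 1 = orange, 0 = red.
#'
#' @inheritParams grade_trials
#' @param grades Output of [grade_approvals()]; recomputed when omitted.
#' @return A tibble with `approval_id` plus the 12 coded columns.
#' @seealso [heatmap_legend()] for the code-to-colour semantics.
#' @export
heatmap_matrix <- function(corpus, grades = NULL) {
  grades <- grades %||% grade_approvals(corpus)
  evidence <- grades |>
    dplyr::mutate(code = unname(
      HEATMAP_EVIDENCE_CODES[.data$category]
    )) |>
    dplyr::select("approval_id", "column", "code") |>
    tidyr::pivot_wider(names_from = "column", values_from = "code")
  flags <- corpus$approvals |>
    dplyr::transmute(
      approval_id = .data$approval_id,
      subgroup_basis = dplyr::case_when(
        .data$subgroup_basis == "none" ~ 2,
        .data$subgroup_basis == "pre_specified" ~ 1,
        .data$subgroup_basis == "post_hoc" ~ 0
      ),
      bias_assessment = dplyr::case_when(
        .data$bias_assessment == "reported_no_bias" ~ 2,
        .data$bias_assessment == "none_reported" ~ 1,
        .data$bias_assessment == "reported_bias_found" ~ 0
      ),
      safety_issue = dplyr::case_when(
        .data$safety_issue == "no" ~ 2,
        .data$safety_issue == "possible" ~ 1,
        .data$safety_issue == "yes" ~ 0
      ),
      tolerance_issue = dplyr::case_when(
        .data$tolerance_issue == "no" ~ 2,
        .data$tolerance_issue == "possible" ~ 1,
        .data$tolerance_issue == "yes" ~ 0
      ),
      divergent_opinion = ifelse(.data$divergent_opinion, 0, 2)
    )
  evidence |>
    dplyr::left_join(flags, by = "approval_id") |>
    dplyr::select(dplyr::all_of(c("approval_id", GRADE_COLUMNS,
                                  "subgroup_basis", "bias_assessment",
                                  "safety_issue", "tolerance_issue",
                                  "divergent_opinion"))) |>
    dplyr::arrange(.data$approval_id)
}

#' Heatmap code legend
#'
#' @return A named list mapping each heatmap column to its code-to-colour
#'   semantics, suitable for serialisation as JSON alongside the matrix CSV.
#' @export
heatmap_legend <- function() {
  evidence <- list(`2` = "green: 2 or more positive studies",
                   `1` = "orange: one positive study",
                   `0` = "red: no positive study",
                   `NA` = "grey: not required")
  legend <- c(
    setNames(rep(list(evidence), length(GRADE_COLUMNS)), GRADE_COLUMNS),
    list(
      subgroup_basis = list(
        `2` = "green: not based on subgroup analyses",
        `1` = "orange: pre-specified subgroup analysis",
        `0` = "red: based on a posteriori subgroup analyses"
      ),
      bias_assessment = list(
        `2` = "green: no bias was identified",
        `1` = "orange: bias assessment not presented",
        `0` = "red: identification of bias"
      ),
      safety_issue = list(
        `2` = "green: no issue was identified",
        `1` = "orange: issue presented as possible",
        `0` = "red: identification of an issue"
      ),
      tolerance_issue = list(
        `2` = "green: no issue was identified",
        `1` = "orange: issue presented as possible",
        `0` = "red: identification of an issue"
      ),
      divergent_opinion = list(
        `2` = "green: no divergent opinion",
        `0` = "red: divergent opinion"
      )
    )
  )
  legend
}
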