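#' Derive one effect estimate per arm comparison
#'
#' Walks every comparison in the corpus through the derivation cascade,
#' dispatching on its reporting tier in priority order
#' `arm_stats > contrast_only > p_and_n_only`. Comparisons in the
#' `insufficient` tier — and `p_and_n_only` comparisons whose direction was
#' not reported, which cannot be signed — come back with `usable = FALSE`
#' and are counted in the insufficient tier downstream.
#'
#' @param corpus A valid [epar_corpus()].
#' @param approved_doses_only Keep only comparisons whose investigational arm
#'   dose lies within the approval's `[approved_dose_min, approved_dose_max]`
#'   (the convention for effect-size work: unapproved doses do not speak to
#'   the approved product). Arms without a recorded dose are retained; an
#'   approval with dose-bearing arms but no dose bounds triggers a warning
#'   and its arms are retained.
#' @return A tibble with one row per (retained) comparison: linkage columns
#'   (`approval_id`, `trial_id`, arm ids, `comparator_class`, `design_phase`,
#'   `hypothesis`, `drug`, `daily_dose`, `indication`), the effect columns of
#'   [d_from_continuous_arms()], and `usable`/`unusable_reason`.
#' @export
derive_effects <- function(corpus, approved_doses_only = FALSE) {
  cmp <- corpus$comparisons
  base_cols <- c("approval_id", "trial_id", "investigational_arm_id",
                 "comparator_arm_id", "comparator_class", "design_phase",
                 "hypothesis", "drug", "daily_dose", "indication")
  eff_cols <- c("d", "var_d", "se_d", "p_two_sided", "n_inv", "n_comp",
                "tier_used", "outcome_type", "degenerate", "usable",
                "unusable_reason")
  if (nrow(cmp) == 0) {
    empty <- tibble::as_tibble(setNames(
      lapply(c(base_cols, eff_cols), function(x) logical(0)),
      c(base_cols, eff_cols)
    ))
    return(empty)
  }

  arm_cols <- c("arm_id", "daily_dose", "n_randomised", "outcome_type",
                "mean_change", "sd_change", "events", "drug")
  inv <- corpus$arms[arm_cols]
  names(inv) <- paste0("inv_", names(inv))
  com <- corpus$arms[arm_cols]
  names(com) <- paste0("comp_", names(com))
  dat <- cmp |>
    dplyr::left_join(corpus$trials[c("trial_id", "approval_id",
                                     "design_phase", "hypothesis")],
                     by = "trial_id") |>
    dplyr::left_join(
      corpus$approvals[c("approval_id", "indication", "approved_dose_min",
                         "approved_dose_max")],
      by = "approval_id"
    ) |>
    dplyr::left_join(inv, by = c(investigational_arm_id = "inv_arm_id")) |>
    dplyr::left_join(com, by = c(comparator_arm_id = "comp_arm_id"))

  if (approved_doses_only) {
    no_bounds <- !is.na(dat$inv_daily_dose) & is.na(dat$approved_dose_min) &
      is.na(dat$approved_dose_max)
    if (any(no_bounds)) {
      warn(sprintf(
        paste0("%d comparison(s) have dose-bearing arms but the approval ",
               "records no dose bounds; retained (approvals: %s)."),
        sum(no_bounds),
        paste(unique(dat$approval_id[no_bounds]), collapse = ", ")
      ))
    }
    lo <- ifelse(is.na(dat$approved_dose_min), -Inf, dat$approved_dose_min)
    hi <- ifelse(is.na(dat$approved_dose_max), Inf, dat$approved_dose_max)
    keep <- is.na(dat$inv_daily_dose) |
      (dat$inv_daily_dose >= lo & dat$inv_daily_dose <= hi)
    dat <- dat[keep, ]
  }
  if (nrow(dat) == 0) return(derive_effects(
    epar_corpus(corpus$approvals, corpus$trials, corpus$arms,
                corpus$comparisons[0, ])
  ))

  check_tier_consistency(dat)

  dat$.row <- seq_len(nrow(dat))
  pieces <- lapply(split(dat, dat$reporting_tier), derive_tier_block)
  est <- dplyr::bind_rows(pieces) |> dplyr::arrange(.data$.row)
  dat <- dplyr::arrange(dat, .data$.row)

  out <- tibble::tibble(
    approval_id = dat$approval_id,
    trial_id = dat$trial_id,
    investigational_arm_id = dat$investigational_arm_id,
    comparator_arm_id = dat$comparator_arm_id,
    comparator_class = dat$comparator_class,
    design_phase = dat$design_phase,
    hypothesis = dat$hypothesis,
    drug = dat$inv_drug,
    daily_dose = dat$inv_daily_dose,
    indication = dat$indication
  )
  dplyr::bind_cols(out, est[setdiff(names(est), ".row")])
}

check_tier_consistency <- function(dat) {
  tier <- dat$reporting_tier
  cont <- dat$inv_outcome_type == "continuous"
  have_stats <- ifelse(
    cont,
    !is.na(dat$inv_mean_change) & !is.na(dat$inv_sd_change) &
      !is.na(dat$comp_mean_change) & !is.na(dat$comp_sd_change),
    !is.na(dat$inv_events) & !is.na(dat$comp_events)
  )
  bad <- (tier == "arm_stats" & !have_stats) |
    (tier == "contrast_only" &
       (is.na(dat$contrast_value) | is.na(dat$contrast_se))) |
    (tier == "p_and_n_only" & is.na(dat$reported_p))
  if (any(bad)) {
    stop_integrity(paste0(
      "Reporting tier inconsistent with available fields for comparison(s): ",
      paste(dat$trial_id[bad], dat$investigational_arm_id[bad], sep = "/",
            collapse = ", ")
    ))
  }
}

derive_tier_block <- function(block) {
  tier <- block$reporting_tier[1]
  n <- nrow(block)
  if (tier == "insufficient") {
    est <- effect_tibble(NA_real_, NA_real_, NA_real_, rep(NA_integer_, n),
                         NA_integer_, "insufficient", NA_character_)
    est$usable <- FALSE
    est$unusable_reason <- "insufficient_reporting"
  } else if (tier == "arm_stats") {
    cont <- block$inv_outcome_type == "continuous"
    parts <- list()
    if (any(cont)) {
      b <- block[cont, ]
      e <- d_from_continuous_arms(b$inv_mean_change, b$inv_sd_change,
                                  b$inv_n_randomised, b$comp_mean_change,
                                  b$comp_sd_change, b$comp_n_randomised,
                                  better_is = b$better_is)
      e$.row <- b$.row
      parts$continuous <- e
    }
    if (any(!cont)) {
      b <- block[!cont, ]
      e <- d_from_binary_arms(b$inv_events, b$inv_n_randomised,
                              b$comp_events, b$comp_n_randomised,
                              event_is_good = b$better_is == "higher")
      e$.row <- b$.row
      parts$binary <- e
    }
    est <- dplyr::bind_rows(parts)
    est <- est[order(match(est$.row, block$.row)), ]
    est$usable <- !est$degenerate
    est$unusable_reason <- ifelse(est$degenerate, "degenerate_table",
                                  NA_character_)
    return(est)
  } else if (tier == "contrast_only") {
    est <- d_from_contrast(block$contrast_value, block$contrast_se,
                           block$inv_n_randomised, block$comp_n_randomised,
                           better_is = block$better_is)
    est$usable <- TRUE
    est$unusable_reason <- NA_character_
  } else { # p_and_n_only
    have_dir <- !is.na(block$direction)
    parts <- list()
    if (any(have_dir)) {
      b <- block[have_dir, ]
      e <- d_from_p_n(b$reported_p, b$inv_n_randomised,
                      b$comp_n_randomised, b$direction)
      e$.row <- b$.row
      e$usable <- TRUE
      e$unusable_reason <- NA_character_
      parts$signed <- e
    }
    if (any(!have_dir)) {
      # a bare p-value cannot be signed: counted with the insufficient tier
      b <- block[!have_dir, ]
      e <- effect_tibble(NA_real_, NA_real_, NA_real_,
                         rep(NA_integer_, nrow(b)), NA_integer_,
                         "insufficient", "continuous")
      e$.row <- b$.row
      e$usable <- FALSE
      e$unusable_reason <- "missing_direction"
      parts$unsigned <- e
    }
    est <- dplyr::bind_rows(parts)
    est <- est[order(match(est$.row, block$.row)), ]
    return(est)
  }
  est$.row <- block$.row
  est
}
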