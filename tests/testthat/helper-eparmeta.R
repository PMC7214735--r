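`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force implementation of the DerSimonian-Laird moment
# estimator, written directly from the defining formulas; kept free of any
# package internals so it can serve as the oracle for dl_pool().
dl_oracle <- function(d, v) {
  k <- length(d)
  w <- 1 / v
  mu_fe <- sum(w * d) / sum(w)
  q <- sum(w * (d - mu_fe)^2)
  tau2 <- if (k == 1) 0 else {
    max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  }
  ws <- 1 / (v + tau2)
  mu <- sum(ws * d) / sum(ws)
  se <- sqrt(1 / sum(ws))
  list(mu = mu, se = se, tau2 = tau2, q = q,
       ci = mu + c(-1, 1) * qnorm(0.975) * se,
       p = 2 * pnorm(-abs(mu / se)))
}

# one-approval corpus with explicitly specified trials, for grading and
# keying tests; each trial spec is a list:
#   list(phase=, hyp=, arms=<tibble role/dose/mean/sd>, cmp=<tibble>)
mini_corpus <- function(trials, comparative_required = TRUE,
                        continuation_required = TRUE,
                        dose_min = 5, dose_max = 20,
                        ni_verdicts = NULL, nibs = NULL) {
  approvals <- tibble::tibble(
    approval_id = "AP1", drug = "testdrug", route = "oral",
    indication = "testing", year = 2010L, manufacturer = NA_character_,
    comparative_evidence_required = comparative_required,
    continuation_evidence_required = continuation_required,
    subgroup_basis = "none", bias_assessment = "none_reported",
    safety_comparison_active = "quantitative",
    safety_comparison_placebo = "quantitative", safety_issue = "no",
    tolerance_comparison_active = "quantitative",
    tolerance_comparison_placebo = "quantitative", tolerance_issue = "no",
    divergent_opinion = FALSE, n_exposed_presubmission = 1000L,
    approved_dose_min = dose_min, approved_dose_max = dose_max
  )
  trial_rows <- list(); arm_rows <- list(); cmp_rows <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    tid <- paste0("T", i)
    trial_rows[[i]] <- tibble::tibble(
      trial_id = tid, approval_id = "AP1",
      design_phase = tr$phase %||% "initiation",
      hypothesis = tr$hyp %||% "superiority",
      duration_weeks = 8,
      non_inferiority_boundary = tr$nib %||% NA_real_,
      primary_outcome_kind = "symptom_scale",
      suicidal_excluded = "not_stated",
      reported_ni_verdict = tr$ni_verdict %||% "not_applicable",
      pooled_analysis = isTRUE(tr$pooled)
    )
    for (a in seq_len(nrow(tr$arms))) {
      sp <- tr$arms[a, ]
      arm_rows[[length(arm_rows) + 1]] <- tibble::tibble(
        arm_id = paste0(tid, "-a", a), trial_id = tid, role = sp$role,
        drug = ifelse(sp$role == "placebo", NA_character_, "testdrug"),
        daily_dose = sp$dose, n_randomised = sp$n %||% 100L,
        n_withdrawn = NA_integer_, n_discontinued_ae = NA_integer_,
        outcome_type = "continuous", mean_change = sp$mean,
        sd_change = sp$sd, events = NA_integer_
      )
    }
    if (!is.null(tr$cmp)) {
      for (ci in seq_len(nrow(tr$cmp))) {
        sp <- tr$cmp[ci, ]
        cmp_rows[[length(cmp_rows) + 1]] <- tibble::tibble(
          trial_id = tid,
          investigational_arm_id = paste0(tid, "-a", sp[["inv"]]),
          comparator_arm_id = paste0(tid, "-a", sp[["comp"]]),
          comparator_class = sp[["class"]],
          reporting_tier = sp[["tier"]] %||% "arm_stats",
          contrast_value = sp[["contrast"]] %||% NA_real_,
          contrast_se = sp[["contrast_se"]] %||% NA_real_,
          reported_p = sp[["p"]] %||% NA_real_,
          direction = sp[["direction"]] %||% NA_character_,
          better_is = "lower"
        )
      }
    }
  }
  epar_corpus(approvals, dplyr::bind_rows(trial_rows),
              dplyr::bind_rows(arm_rows), dplyr::bind_rows(cmp_rows))
}

arm_spec <- function(role, mean, sd = 1, dose = NA_real_, n = 100L) {
  tibble::tibble(role = role, mean = mean, sd = sd, dose = dose, n = n)
}

cmp_spec <- function(inv, comp, class, tier = "arm_stats", ...) {
  tibble::tibble(inv = inv, comp = comp, class = class, tier = tier, ...)
}

# a standard 2-arm placebo superiority trial spec with planned effect d
placebo_trial <- function(d, phase = "initiation", dose = 10) {
  list(
    phase = phase,
    arms = dplyr::bind_rows(
      arm_spec("investigational", mean = d, dose = dose),
      arm_spec("placebo", mean = 0)
    ),
    cmp = cmp_spec(1, 2, "placebo")
  )
}
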