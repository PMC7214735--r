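#' The benchmark approval corpus
#'
#' A deterministic, schematic corpus of 27 marketing-authorisation
#' applications for psychotropic drugs (13 named or synthetic drugs, oral /
#' intramuscular / sublingual / inhalation routes, 137 randomised trials)
#' built to exercise every branch of the appraisal pipeline at realistic
#' marginal structure:
#'
#' * the superiority-vs-active rubric spread (2 approvals with robust
#'   evidence, 3 with a single positive trial, 21 with none — split between
#'   uncompared "internal positive control" designs, absent studies and
#'   negative results, plus one approval where comparative evidence was
#'   waived);
#' * non-inferiority evidence (one approval with two positive pooled
#'   analyses, eight with one positive study — one of them alongside two
#'   negative trials — and seventeen with none);
#' * placebo evidence (20 approvals with two or more positive initiation
#'   trials; continuation evidence waived for the five agitation
#'   indications, one positive continuation study for 16 of the remaining
#'   22);
#' * four-tier reporting completeness over 266 dose-eligible arm comparisons
#'   (158 full arm statistics / 29 contrasts / 12 p-and-n / 67 insufficient)
#'   in 136 studies, plus one study excluded because every dose studied lay
#'   below the approved minimum.
#'
#' Individual approvals are schematic: arm sizes are 100 throughout, SDs are
#' unity, and only the marginal tallies — not any per-approval detail beyond
#' the named exemplars — are meaningful. Flag columns (safety, tolerance,
#' subgroup, divergent opinion) carry an arbitrary but fixed assignment with
#' realistic margins.
#'
#' @return A validated [epar_corpus()]. Identical on every call; the same
#'   corpus ships as a CSV bundle under
#'   `system.file("extdata", "benchmark_corpus", package = "eparmeta")`.
#' @export
benchmark_corpus <- function() {
  fx <- new.env(parent = emptyenv())
  fx$trials <- list(); fx$arms <- list(); fx$cmps <- list()
  fx$tno <- integer(27)

  N <- 100L
  SE2 <- sqrt(2 / N)                       # SE of a contrast when sd = 1

  add_trial <- function(a, phase = "initiation", hypothesis = "superiority",
                        outcome = "symptom_scale", nib = NA_real_,
                        ni_verdict = "not_applicable", pooled = FALSE,
                        duration = 8) {
    fx$tno[a] <- fx$tno[a] + 1L
    tid <- sprintf("A%02d-T%02d", a, fx$tno[a])
    fx$trials[[tid]] <- tibble::tibble(
      trial_id = tid, approval_id = sprintf("A%02d", a),
      design_phase = phase, hypothesis = hypothesis,
      duration_weeks = duration, non_inferiority_boundary = nib,
      primary_outcome_kind = outcome, suicidal_excluded = "not_stated",
      reported_ni_verdict = ni_verdict, pooled_analysis = pooled
    )
    tid
  }

  add_arm <- function(tid, idx, role, drug = NA_character_,
                      dose = NA_real_, mean = NA_real_, sd = NA_real_,
                      events = NA_integer_, outcome = "continuous") {
    arm_id <- sprintf("%s-a%d", tid, idx)
    fx$arms[[arm_id]] <- tibble::tibble(
      arm_id = arm_id, trial_id = tid, role = role, drug = drug,
      daily_dose = dose, n_randomised = N, n_withdrawn = NA_integer_,
      n_discontinued_ae = NA_integer_, outcome_type = outcome,
      mean_change = mean, sd_change = sd, events = as.integer(events)
    )
    arm_id
  }

  add_cmp <- function(tid, inv, comp, class, tier = "arm_stats",
                      d_planned = NA_real_, better_is = "lower") {
    row <- tibble::tibble(
      trial_id = tid, investigational_arm_id = inv, comparator_arm_id = comp,
      comparator_class = class, reporting_tier = tier,
      contrast_value = NA_real_, contrast_se = NA_real_,
      reported_p = NA_real_, direction = NA_character_,
      better_is = better_is
    )
    if (tier == "contrast_only") {
      row$contrast_value <- d_planned   # sd = 1, so contrast = d
      row$contrast_se <- SE2
    } else if (tier == "p_and_n_only") {
      row$reported_p <- p_from_d(d_planned, N, N)
      row$direction <- if (d_planned < 0) "favours_investigational"
                       else "favours_comparator"
    }
    fx$cmps[[length(fx$cmps) + 1L]] <- row
  }

  # -- three-arm initiation trial: drug vs active vs placebo ---------------
  # d_active / d_placebo are the planned standardized differences (sd = 1)
  trial3 <- function(a, d_active, d_placebo, compare_active = TRUE,
                     compare_placebo = TRUE) {
    tid <- add_trial(a)
    inv <- add_arm(tid, 1, "investigational", fx$drug[a], 10, d_placebo, 1)
    act_mean <- if (compare_active) d_placebo - d_active else -0.35
    act <- add_arm(tid, 2, "active_comparator", paste0(fx$drug[a], "-ref"),
                   10, act_mean, 1)
    pla <- add_arm(tid, 3, "placebo", mean = 0, sd = 1)
    if (compare_active) add_cmp(tid, inv, act, "active")
    if (compare_placebo) add_cmp(tid, inv, pla, "placebo")
    tid
  }

  # -- two-arm placebo superiority trial -----------------------------------
  trial_placebo <- function(a, d, phase = "initiation", dose = 10,
                            tier = "arm_stats") {
    tid <- add_trial(a, phase = phase)
    blank <- tier %in% c("contrast_only", "p_and_n_only", "insufficient")
    inv <- add_arm(tid, 1, "investigational", fx$drug[a], dose,
                   mean = if (blank) NA_real_ else d,
                   sd = if (blank) NA_real_ else 1)
    pla <- add_arm(tid, 2, "placebo", mean = if (blank) NA_real_ else 0,
                   sd = if (blank) NA_real_ else 1)
    add_cmp(tid, inv, pla, "placebo", tier = tier, d_planned = d)
    tid
  }

  # -- two-arm continuation trial with binary relapse outcome --------------
  trial_relapse <- function(a, e_inv, e_comp) {
    tid <- add_trial(a, phase = "continuation", outcome = "relapse",
                     duration = 52)
    inv <- add_arm(tid, 1, "investigational", fx$drug[a], 10,
                   events = e_inv, outcome = "binary")
    pla <- add_arm(tid, 2, "placebo", events = e_comp, outcome = "binary")
    add_cmp(tid, inv, pla, "placebo")
    tid
  }

  # -- two-arm non-inferiority trial vs active -----------------------------
  ni_trial <- function(a, verdict, phase = "initiation", pooled = FALSE,
                       d = 0.04, tier = "arm_stats") {
    tid <- add_trial(a, phase = phase, hypothesis = "non_inferiority",
                     nib = 0.35, ni_verdict = verdict, pooled = pooled,
                     duration = 24)
    blank <- tier == "insufficient"
    inv <- add_arm(tid, 1, "investigational", fx$drug[a], 10,
                   mean = if (blank) NA_real_ else d,
                   sd = if (blank) NA_real_ else 1)
    act <- add_arm(tid, 2, "active_comparator", paste0(fx$drug[a], "-ref"),
                   10, mean = if (blank) NA_real_ else 0,
                   sd = if (blank) NA_real_ else 1)
    add_cmp(tid, inv, act, "active", tier = tier, d_planned = d)
    tid
  }

  # -- continuation superiority trial vs active (exact planned d) ----------
  trial_cont_active <- function(a, d) {
    tid <- add_trial(a, phase = "continuation", duration = 26)
    inv <- add_arm(tid, 1, "investigational", fx$drug[a], 10, d - 0.40, 1)
    act <- add_arm(tid, 2, "active_comparator", paste0(fx$drug[a], "-ref"),
                   10, -0.40, 1)
    add_cmp(tid, inv, act, "active")
    tid
  }

  # -- multi-dose filler trial ---------------------------------------------
  # dose arms (means m_inv, sd = 1) vs a shared placebo (mean 0) and/or a
  # shared active arm (mean m_act); the implied planned effects are
  # d_placebo = m_inv and d_active = m_inv - m_act, so every comparison is
  # consistent with the same arm-level truth whatever tier reports it
  dose_trial <- function(a, doses, m_inv, tiers_placebo = NULL,
                         m_act = NULL, tiers_active = NULL) {
    tid <- add_trial(a)
    k <- length(doses)
    inv_ids <- character(k)
    for (i in seq_len(k)) {
      keep <- isTRUE(tiers_placebo[i] == "arm_stats") ||
        isTRUE(tiers_active[i] == "arm_stats")
      inv_ids[i] <- add_arm(
        tid, i, "investigational", fx$drug[a], doses[i],
        mean = if (keep) m_inv[i] else NA_real_,
        sd = if (keep) 1 else NA_real_
      )
    }
    nxt <- k
    if (!is.null(m_act)) {
      keep <- any(tiers_active == "arm_stats")
      nxt <- nxt + 1L
      act <- add_arm(tid, nxt, "active_comparator",
                     paste0(fx$drug[a], "-ref"), 10,
                     mean = if (keep) m_act else NA_real_,
                     sd = if (keep) 1 else NA_real_)
    }
    if (!is.null(tiers_placebo)) {
      keep <- any(tiers_placebo == "arm_stats")
      nxt <- nxt + 1L
      pla <- add_arm(tid, nxt, "placebo",
                     mean = if (keep) 0 else NA_real_,
                     sd = if (keep) 1 else NA_real_)
    }
    for (i in seq_len(k)) {
      if (!is.null(m_act)) {
        add_cmp(tid, inv_ids[i], act, "active", tier = tiers_active[i],
                d_planned = m_inv[i] - m_act)
      }
      if (!is.null(tiers_placebo)) {
        add_cmp(tid, inv_ids[i], pla, "placebo", tier = tiers_placebo[i],
                d_planned = m_inv[i])
      }
    }
    tid
  }

  insufficient_trial <- function(a, n_doses) {
    tid <- add_trial(a)
    inv_ids <- vapply(seq_len(n_doses), function(i) {
      add_arm(tid, i, "investigational", fx$drug[a], c(10, 20)[i])
    }, character(1))
    pla <- add_arm(tid, n_doses + 1L, "placebo")
    for (i in seq_len(n_doses)) {
      add_cmp(tid, inv_ids[i], pla, "placebo", tier = "insufficient")
    }
    tid
  }

  # ---- drugs, routes, indications ----------------------------------------
  fx$drug <- sprintf("drug%02d", 1:27)
  fx$drug[c(1, 2, 17, 18, 19, 20, 21, 27)] <-
    c("olanzapine", "varenicline", "paliperidone", "agomelatine",
      "duloxetine", "paliperidone", "duloxetine", "nalmefene")
  route <- rep("oral", 27)
  route[c(9:14, 16, 20)] <- "intramuscular"
  route[22] <- "inhalation"
  route[c(23, 24)] <- "sublingual"
  indication <- c(
    "schizophrenia", "smoking cessation", "major depressive disorder",
    "schizophrenia", "bipolar disorder", "generalised anxiety disorder",
    "schizophrenia", "major depressive disorder",
    "schizophrenia", "schizophrenia", "bipolar disorder",
    "schizophrenia", "major depressive disorder", "bipolar disorder",
    "schizophrenia", "schizophrenia",
    "schizoaffective disorder", "major depressive disorder",
    "major depressive disorder",
    "maintenance treatment of schizophrenia",
    "generalised anxiety disorder",
    "agitation", "agitation", "agitation", "agitation", "agitation",
    "alcohol use disorders"
  )

  # ---- core approvals -----------------------------------------------------
  # A01, A02: robust superiority vs active (two positive initiation trials)
  for (r in 1:2) trial3(1, -0.35, -0.75)
  trial_relapse(1, 20, 45)                       # continuation vs placebo
  # dose-excluded study: every dose below the approved minimum of 5
  trial_placebo(1, -0.40, dose = 2)

  for (r in 1:2) {                               # varenicline: binary response
    tid <- add_trial(2, outcome = "response")
    inv <- add_arm(tid, 1, "investigational", fx$drug[2], 10,
                   events = 45L, outcome = "binary")
    act <- add_arm(tid, 2, "active_comparator", "bupropion", 10,
                   events = 30L, outcome = "binary")
    pla <- add_arm(tid, 3, "placebo", events = 20L, outcome = "binary")
    add_cmp(tid, inv, act, "active", better_is = "higher")
    add_cmp(tid, inv, pla, "placebo", better_is = "higher")
  }
  trial_placebo(2, -0.50, phase = "continuation")

  # A03-A05: single positive superiority trial vs active
  for (a in 3:5) {
    trial3(a, -0.35, -0.75)
    trial_placebo(a, -0.40)
    trial_placebo(a, -0.55, phase = "continuation")
  }
  # A06-A08: only negative superiority vs active
  for (a in 6:8) {
    trial3(a, 0.05, -0.45)
    trial_placebo(a, -0.40)
  }
  trial_placebo(6, -0.45, phase = "continuation")

  # A09-A11: active arm uncompared; one positive NI study; single placebo
  for (a in 9:11) {
    trial3(a, NA, -0.40, compare_active = FALSE)
    ni_trial(a, "positive")
    trial_placebo(a, -0.60, phase = "continuation")
  }
  # A12-A14: as A09 plus a second positive placebo trial
  for (a in 12:14) {
    trial3(a, NA, -0.40, compare_active = FALSE)
    ni_trial(a, "positive")
    trial_placebo(a, -0.35)
    trial_placebo(a, -0.50, phase = "continuation")
  }
  # A15-A16: uncompared active; one negative continuation trial vs active
  # with the exact observed effects 0.036 and 0.143
  cont_d <- c(0.036, 0.143)
  for (a in 15:16) {
    trial3(a, NA, -0.40, compare_active = FALSE)
    trial_placebo(a, -0.35)
    trial_cont_active(a, cont_d[a - 14])
  }
  # A17: uncompared active, placebo initiation not significant,
  # one positive continuation study (target population from post-hoc
  # subgroup analysis)
  trial3(17, NA, -0.05, compare_active = FALSE)
  trial_placebo(17, -0.55, phase = "continuation")
  # A18: negative placebo initiation; positive continuation study
  trial_placebo(18, -0.05)
  trial_placebo(18, -0.45, phase = "continuation")
  # A19: two positive non-inferiority pooled analyses; robust placebo
  ni_trial(19, "positive", pooled = TRUE)
  ni_trial(19, "positive", pooled = TRUE)
  trial_placebo(19, -0.40)
  trial_placebo(19, -0.35)
  # A20: one positive + two negative initiation NI; positive continuation NI
  # (not analyzable) and a positive continuation relapse study vs placebo
  ni_trial(20, "positive")
  ni_trial(20, "negative", d = 0.20)
  ni_trial(20, "negative", d = 0.25)
  ni_trial(20, "positive", phase = "continuation", tier = "insufficient")
  trial_relapse(20, 18, 40)
  # A21: one positive NI pooled analysis; positive continuation vs placebo
  ni_trial(21, "positive", pooled = TRUE)
  trial_placebo(21, -0.50, phase = "continuation")
  # A22-A26: agitation — placebo evidence only, continuation waived
  for (a in 22:26) {
    trial_placebo(a, -0.45)
    trial_placebo(a, -0.40)
  }
  # A27: comparative evidence waived; robust placebo
  trial_placebo(27, -0.50)
  trial_placebo(27, -0.40)

  # ---- filler studies: dose-ranging trials and unanalyzable reports ------
  hosts <- c(1:8, 12:16, 19, 22:27)
  host_at <- function(i) hosts[(i - 1L) %% length(hosts) + 1L]
  # reporting tiers for the 114 analyzable filler comparisons, assigned in
  # construction order: 29 contrasts, 12 p-and-n, 73 full arm statistics
  filler_tiers <- rep(c("contrast_only", "p_and_n_only", "arm_stats"),
                      c(29, 12, 73))
  fx$ftier <- 0L
  next_tiers <- function(k) {
    out <- filler_tiers[fx$ftier + seq_len(k)]
    fx$ftier <- fx$ftier + k
    out
  }
  f <- 0L
  # 9 trials: three doses vs active vs placebo; the highest dose beats
  # placebo, the active comparator significantly beats the lowest dose
  # (implied d vs active: 0.32 / 0.27 / 0.02)
  for (i in 1:9) {
    f <- f + 1L
    dose_trial(host_at(f), doses = c(5, 10, 20),
               m_inv = c(-0.10, -0.15, -0.40),
               tiers_placebo = next_tiers(3),
               m_act = -0.42,
               tiers_active = next_tiers(3))
  }
  # 3 trials: four doses vs placebo, two effective doses
  for (i in 1:3) {
    f <- f + 1L
    dose_trial(host_at(f), doses = c(5, 8, 10, 20),
               m_inv = c(-0.05, -0.10, -0.40, -0.45),
               tiers_placebo = next_tiers(4))
  }
  # 8 trials: five doses vs placebo, one effective dose
  for (i in 1:8) {
    f <- f + 1L
    dose_trial(host_at(f), doses = c(5, 8, 10, 15, 20),
               m_inv = c(-0.05, -0.08, -0.10, -0.15, -0.40),
               tiers_placebo = next_tiers(5))
  }
  # 4 trials: two doses vs active only, both null (implied d: 0.05 / 0.10)
  for (i in 1:4) {
    f <- f + 1L
    dose_trial(host_at(f), doses = c(10, 20),
               m_inv = c(-0.35, -0.30),
               m_act = -0.40, tiers_active = next_tiers(2))
  }
  # 36 studies reported too incompletely to standardize: 30 two-dose and
  # 6 single-dose trials, 66 insufficient comparisons
  for (i in 1:36) {
    f <- f + 1L
    insufficient_trial(host_at(f), if (i <= 30) 2L else 1L)
  }

  # ---- approval table -----------------------------------------------------
  trials <- dplyr::bind_rows(fx$trials)
  # 48 of the 137 study reports note that suicidal patients were excluded
  trials$suicidal_excluded[seq_len(48)] <- "yes"

  sc_active <- rep("quantitative", 27)
  sc_active[c(18, 19)] <- "qualitative"
  sc_active[c(9, 10, 11, 22, 23, 24, 27)] <- "absent"
  tc_active <- rep("quantitative", 27)
  tc_active[18] <- "qualitative"
  tc_active[c(22, 23, 24, 25, 27)] <- "absent"
  sc_placebo <- rep("quantitative", 27)
  sc_placebo[c(7, 8)] <- "qualitative"
  sc_placebo[c(15, 16, 17, 18)] <- "absent"
  tc_placebo <- rep("quantitative", 27)
  tc_placebo[7] <- "qualitative"
  tc_placebo[15] <- "absent"
  safety_issue <- rep("no", 27)
  safety_issue[c(1, 18, 22)] <- "yes"
  safety_issue[c(4, 9, 20)] <- "possible"
  tolerance_issue <- rep("no", 27)
  tolerance_issue[c(1, 4)] <- "yes"
  tolerance_issue[c(5, 13)] <- "possible"
  subgroup <- rep("none", 27)
  subgroup[c(17, 27)] <- "post_hoc"
  bias <- rep("none_reported", 27)
  bias[c(1, 2, 19)] <- "reported_no_bias"

  approvals <- tibble::tibble(
    approval_id = sprintf("A%02d", 1:27),
    drug = fx$drug,
    route = route,
    indication = indication,
    year = as.integer(1996 + ((1:27) * 5) %% 21),
    manufacturer = NA_character_,
    comparative_evidence_required = c(rep(TRUE, 26), FALSE),
    continuation_evidence_required = !(1:27 %in% 22:26),
    subgroup_basis = subgroup,
    bias_assessment = bias,
    safety_comparison_active = sc_active,
    safety_comparison_placebo = sc_placebo,
    safety_issue = safety_issue,
    tolerance_comparison_active = tc_active,
    tolerance_comparison_placebo = tc_placebo,
    tolerance_issue = tolerance_issue,
    divergent_opinion = 1:27 == 18,
    n_exposed_presubmission = as.integer(900 + (1:27) * 87),
    approved_dose_min = 5,
    approved_dose_max = 20
  )

  corpus <- epar_corpus(approvals, trials, dplyr::bind_rows(fx$arms),
                        dplyr::bind_rows(fx$cmps))
  assert_valid_corpus(corpus)
  corpus
}
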