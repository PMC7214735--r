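#' Distribution specifications for the corpus generator
#'
#' @param k Fixed value.
#' @param mean Poisson mean.
#' @param min Lower truncation bound for the Poisson draw.
#' @return A list understood by [generate_corpus()].
#' @export
dist_fixed <- function(k) list(kind = "fixed", k = k)

#' @rdname dist_fixed
#' @export
dist_poisson <- function(mean, min = 1) {
  list(kind = "poisson", mean = mean, min = min)
}

draw_dist <- function(spec, n) {
  if (is.numeric(spec)) return(rep(spec, n))
  switch(spec$kind,
    fixed = rep(spec$k, n),
    poisson = pmax(spec$min, stats::rpois(n, spec$mean)),
    stop_value("Unknown distribution spec.")
  )
}

#' Configure the synthetic corpus generator
#'
#' Defaults encode the study conditions the generator is meant to emulate: a
#' modest true benefit over placebo (d = -0.3) with between-trial
#' heterogeneity tau2 = 0.05, no true difference against active comparators,
#' 100 subjects per arm, five trials per approval, mostly continuous
#' outcomes, and a reporting-completeness mix matching the observed
#' four-tier triage of real dossiers (about 60% full arm statistics, 10%
#' contrasts, 5% p-and-n only, 25% insufficient).
#'
#' @param n_approvals Number of approvals to simulate.
#' @param trials_per_approval [dist_fixed()] / [dist_poisson()] spec or a
#'   number.
#' @param arms_per_trial Arms per trial (>= 2); arms beyond the comparator
#'   are investigational dose arms sharing the trial's true effect.
#' @param n_per_arm Subjects per arm: spec or number.
#' @param true_effect_by_comparator Named numeric,
#'   `c(placebo = ..., active = ...)`: true standardized effect (negative
#'   favours the drug).
#' @param tau2 Between-trial variance of the true effect.
#' @param outcome_mix Proportion of trials with a continuous outcome; the
#'   rest use a binary outcome.
#' @param tier_probabilities Named simplex over the four reporting tiers.
#' @param active_comparator_prob Probability a trial compares against an
#'   active drug rather than placebo.
#' @param binary_control_rate Comparator event rate for binary outcomes
#'   (the drug rate is set so the log-OR conversion equals the true effect).
#' @param seed Root seed; every approval derives its own substream so adding
#'   approvals does not perturb earlier ones.
#' @return A validated config list of class `corpus_config`.
#' @export
corpus_config <- function(n_approvals = 10,
                          trials_per_approval = dist_fixed(5),
                          arms_per_trial = 2,
                          n_per_arm = dist_fixed(100),
                          true_effect_by_comparator = c(placebo = -0.3,
                                                        active = 0),
                          tau2 = 0.05,
                          outcome_mix = 0.8,
                          tier_probabilities = c(arm_stats = 0.6,
                                                 contrast_only = 0.1,
                                                 p_and_n_only = 0.05,
                                                 insufficient = 0.25),
                          active_comparator_prob = 0.3,
                          binary_control_rate = 0.4,
                          seed = 1L) {
  cfg <- list(
    n_approvals = n_approvals, trials_per_approval = trials_per_approval,
    arms_per_trial = arms_per_trial, n_per_arm = n_per_arm,
    true_effect_by_comparator = true_effect_by_comparator, tau2 = tau2,
    outcome_mix = outcome_mix, tier_probabilities = tier_probabilities,
    active_comparator_prob = active_comparator_prob,
    binary_control_rate = binary_control_rate, seed = as.integer(seed)
  )
  tp <- cfg$tier_probabilities
  if (!setequal(names(tp), CORPUS_ENUMS$reporting_tier) || any(tp < 0) ||
      abs(sum(tp) - 1) > 1e-8) {
    stop_value(paste0("`tier_probabilities` must be a nonnegative simplex ",
                      "over the four reporting tiers."))
  }
  if (cfg$arms_per_trial < 2) stop_value("`arms_per_trial` must be >= 2.")
  if (cfg$outcome_mix < 0 || cfg$outcome_mix > 1) {
    stop_value("`outcome_mix` must lie in [0, 1].")
  }
  if (cfg$binary_control_rate <= 0 || cfg$binary_control_rate >= 1) {
    stop_value("`binary_control_rate` must lie in (0, 1).")
  }
  if (!all(c("placebo", "active") %in%
             names(cfg$true_effect_by_comparator))) {
    stop_value(paste0("`true_effect_by_comparator` needs named elements ",
                      "'placebo' and 'active'."))
  }
  if (cfg$tau2 < 0) stop_value("`tau2` must be nonnegative.")
  structure(cfg, class = "corpus_config")
}

#' Generate a synthetic approval corpus
#'
#' Simulates a corpus with the statistical structure the appraisal pipeline
#' assumes. Each trial draws a true standardized effect
#' `delta_i ~ Normal(true_effect, tau2)` for its comparator class.
#' Continuous outcomes have unit true SD with the drug arm mean shifted by
#' `delta_i` (lower is better); binary outcomes fix the comparator event rate
#' and set the drug rate so the log-OR-to-d conversion equals `delta_i`.
#' Sampling noise enters through the per-arm summary statistics. Each
#' comparison then has its reporting censored to a tier drawn from
#' `tier_probabilities`: `contrast_only` keeps the observed difference and
#' its SE, `p_and_n_only` keeps the realised two-sided p, the group sizes
#' and the direction, `insufficient` keeps none of these. Arm statistics are
#' blanked when no retained comparison needs them.
#'
#' @param config A [corpus_config()].
#' @return A validated [epar_corpus()], fully reproducible from
#'   `config$seed`.
#' @export
generate_corpus <- function(config = corpus_config()) {
  if (!inherits(config, "corpus_config")) {
    config <- do.call(corpus_config, config)
  }
  approvals <- vector("list", config$n_approvals)
  trials <- list(); arms <- list(); comps <- list()
  for (j in seq_len(config$n_approvals)) {
    old <- .Random.seed_save()
    set.seed(derive_seed(config$seed, j))
    block <- generate_approval(config, j)
    .Random.seed_restore(old)
    approvals[[j]] <- block$approval
    trials[[j]] <- block$trials
    arms[[j]] <- block$arms
    comps[[j]] <- block$comparisons
  }
  corpus <- epar_corpus(
    dplyr::bind_rows(approvals), dplyr::bind_rows(trials),
    dplyr::bind_rows(arms), dplyr::bind_rows(comps)
  )
  assert_valid_corpus(corpus)
  corpus
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

generate_approval <- function(config, j) {
  aid <- sprintf("SYN-A%03d", j)
  approval <- tibble::tibble(
    approval_id = aid,
    drug = sprintf("syndrug%03d", j),
    route = "oral",
    indication = "synthetic indication",
    year = 2010L,
    manufacturer = NA_character_,
    comparative_evidence_required = TRUE,
    continuation_evidence_required = TRUE,
    subgroup_basis = "none",
    bias_assessment = "none_reported",
    safety_comparison_active = "quantitative",
    safety_comparison_placebo = "quantitative",
    safety_issue = "no",
    tolerance_comparison_active = "quantitative",
    tolerance_comparison_placebo = "quantitative",
    tolerance_issue = "no",
    divergent_opinion = FALSE,
    n_exposed_presubmission = 1500L,
    approved_dose_min = 5,
    approved_dose_max = 20
  )
  n_trials <- draw_dist(config$trials_per_approval, 1)
  tr <- list(); ar <- list(); cm <- list()
  for (i in seq_len(n_trials)) {
    tid <- sprintf("%s-T%02d", aid, i)
    comp_class <- if (stats::runif(1) < config$active_comparator_prob) {
      "active"
    } else {
      "placebo"
    }
    continuous <- stats::runif(1) < config$outcome_mix
    delta <- stats::rnorm(
      1, config$true_effect_by_comparator[[comp_class]], sqrt(config$tau2)
    )
    n_inv_arms <- config$arms_per_trial - 1L
    ns <- draw_dist(config$n_per_arm, n_inv_arms + 1L)
    trial_arms <- list(); trial_cmps <- list()
    comp_arm_id <- sprintf("%s-a%d", tid, n_inv_arms + 1L)

    if (continuous) {
      arm_obs <- function(mu, n) {
        list(mean = stats::rnorm(1, mu, 1 / sqrt(n)),
             sd = sqrt(stats::rchisq(1, n - 1) / (n - 1)))
      }
      comp_obs <- arm_obs(0, ns[n_inv_arms + 1L])
    } else {
      p_comp <- config$binary_control_rate
      odds_drug <- exp(delta * pi / sqrt(3)) * p_comp / (1 - p_comp)
      p_drug <- odds_drug / (1 + odds_drug)
      comp_events <- stats::rbinom(1, ns[n_inv_arms + 1L], p_comp)
    }

    arm_row <- function(arm_id, role, drug, dose, n, mean, sd, events) {
      tibble::tibble(
        arm_id = arm_id, trial_id = tid, role = role, drug = drug,
        daily_dose = dose, n_randomised = as.integer(n),
        n_withdrawn = NA_integer_, n_discontinued_ae = NA_integer_,
        outcome_type = if (continuous) "continuous" else "binary",
        mean_change = mean, sd_change = sd, events = events
      )
    }

    trial_arms$comp <- arm_row(
      comp_arm_id,
      if (comp_class == "active") "active_comparator" else "placebo",
      if (comp_class == "active") sprintf("syncomp%03d", j) else NA_character_,
      if (comp_class == "active") 10 else NA_real_,
      ns[n_inv_arms + 1L],
      if (continuous) comp_obs$mean else NA_real_,
      if (continuous) comp_obs$sd else NA_real_,
      if (continuous) NA_integer_ else as.integer(comp_events)
    )

    tiers <- sample(CORPUS_ENUMS$reporting_tier, n_inv_arms, replace = TRUE,
                    prob = config$tier_probabilities)
    doses <- c(10, 5, 20, 15, 8)[(seq_len(n_inv_arms) - 1L) %% 5 + 1L]
    for (a in seq_len(n_inv_arms)) {
      arm_id <- sprintf("%s-a%d", tid, a)
      n_a <- ns[a]
      n_c <- ns[n_inv_arms + 1L]
      if (continuous) {
        obs <- arm_obs(delta, n_a)
        est <- d_from_continuous_arms(obs$mean, obs$sd, n_a, comp_obs$mean,
                                      comp_obs$sd, n_c)
        contrast <- obs$mean - comp_obs$mean
        contrast_se <- sqrt(obs$sd^2 / n_a + comp_obs$sd^2 / n_c)
        trial_arms[[paste0("inv", a)]] <- arm_row(
          arm_id, "investigational", approval$drug, doses[a], n_a,
          obs$mean, obs$sd, NA_integer_
        )
      } else {
        ev <- stats::rbinom(1, n_a, p_drug)
        est <- d_from_binary_arms(ev, n_a, comp_events, n_c,
                                  event_is_good = FALSE)
        contrast <- NA_real_
        contrast_se <- NA_real_
        trial_arms[[paste0("inv", a)]] <- arm_row(
          arm_id, "investigational", approval$drug, doses[a], n_a,
          NA_real_, NA_real_, as.integer(ev)
        )
      }
      tier <- tiers[a]
      # a binary result cannot be censored into an outcome-scale contrast;
      # such draws report full arm statistics instead
      if (!continuous && tier == "contrast_only") tier <- "arm_stats"
      trial_cmps[[a]] <- tibble::tibble(
        trial_id = tid, investigational_arm_id = arm_id,
        comparator_arm_id = comp_arm_id, comparator_class = comp_class,
        reporting_tier = tier,
        contrast_value = if (tier == "contrast_only") contrast else NA_real_,
        contrast_se = if (tier == "contrast_only") contrast_se else NA_real_,
        reported_p = if (tier == "p_and_n_only") est$p_two_sided
                     else NA_real_,
        direction = if (tier == "p_and_n_only") {
          if (isTRUE(est$d < 0)) "favours_investigational"
          else if (isTRUE(est$d > 0)) "favours_comparator" else "null"
        } else NA_character_,
        better_is = "lower"
      )
    }

    arms_tbl <- dplyr::bind_rows(trial_arms)
    cmps_tbl <- dplyr::bind_rows(trial_cmps)
    # blank statistics that no surviving arm_stats comparison needs
    needed <- unique(unlist(
      cmps_tbl[cmps_tbl$reporting_tier == "arm_stats",
               c("investigational_arm_id", "comparator_arm_id")]
    ))
    censor <- !arms_tbl$arm_id %in% needed
    arms_tbl$mean_change[censor] <- NA_real_
    arms_tbl$sd_change[censor] <- NA_real_
    arms_tbl$events[censor] <- NA_integer_

    tr[[i]] <- tibble::tibble(
      trial_id = tid, approval_id = aid, design_phase = "initiation",
      hypothesis = "superiority", duration_weeks = 8,
      non_inferiority_boundary = NA_real_,
      primary_outcome_kind = if (continuous) "symptom_scale" else "response",
      suicidal_excluded = "not_stated",
      reported_ni_verdict = "not_applicable", pooled_analysis = FALSE
    )
    ar[[i]] <- arms_tbl
    cm[[i]] <- cmps_tbl
  }
  list(approval = approval, trials = dplyr::bind_rows(tr),
       arms = dplyr::bind_rows(ar), comparisons = dplyr::bind_rows(cm))
}
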