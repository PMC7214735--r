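#' Standardized mean differences from trial summaries
#'
#' Approval dossiers report trial results with very uneven completeness. The
#' functions below form a three-tier derivation cascade that converts whatever
#' is reported into a Cohen's d with variance and a two-sided p-value:
#'
#' * `d_from_continuous_arms()` / `d_from_binary_arms()` — full arm statistics
#'   (tier `arm_stats`): mean changes with SDs, or event counts.
#' * `d_from_contrast()` — an arm contrast with its standard error
#'   (tier `contrast_only`).
#' * `d_from_p_n()` — only a p-value, group sizes and a direction
#'   (tier `p_and_n_only`): the t statistic is recovered by inverting the
#'   central t distribution.
#'
#' Sign convention: **negative d favours the investigational drug**, whatever
#' the orientation of the outcome scale (`better_is`) or the meaning of a
#' binary event (`event_is_good`). All p-values use the t reference with
#' `df = n_inv + n_comp - 2`, so the imputation tier inverts exactly the
#' calculation the richer tiers perform.
#'
#' @param m_inv,m_comp Mean change in the investigational / comparator arm.
#' @param sd_inv,sd_comp Standard deviation of the change in each arm (> 0).
#' @param n_inv,n_comp Number of subjects per arm (>= 2).
#' @param better_is `"lower"` if smaller outcome values are clinically better
#'   (symptom scales), `"higher"` otherwise.
#' @param hedges Apply the small-sample (Hedges) correction factor
#'   `1 - 3/(4 df - 1)` to d. Default `FALSE`: dossier appraisal conventionally
#'   reports plain Cohen's d.
#' @return A one-row [tibble::tibble()] (vectorised inputs give one row each)
#'   with columns `d`, `var_d`, `se_d`, `p_two_sided`, `n_inv`, `n_comp`,
#'   `tier_used`, `outcome_type`, `degenerate`.
#' @examples
#' d_from_continuous_arms(10, 2, 50, 11, 2, 50, better_is = "lower")
#' d_from_binary_arms(30, 50, 20, 50, event_is_good = TRUE)
#' d_from_contrast(-2, 1, 50, 50)
#' d_from_p_n(0.05, 50, 50, direction = "favours_investigational")
#' @name effect_cascade
NULL

effect_tibble <- function(d, var_d, p, n_inv, n_comp, tier, outcome_type,
                          degenerate = FALSE) {
  tibble::tibble(
    d = d,
    var_d = var_d,
    se_d = sqrt(var_d),
    p_two_sided = p,
    n_inv = as.integer(n_inv),
    n_comp = as.integer(n_comp),
    tier_used = tier,
    outcome_type = outcome_type,
    degenerate = degenerate
  )
}

# variance of Cohen's d shared by the continuous, contrast and imputation tiers
var_cohen_d <- function(d, n_inv, n_comp) {
  (n_inv + n_comp) / (n_inv * n_comp) + d^2 / (2 * (n_inv + n_comp))
}

# two-sided p from the realised two-sample t statistic,
# t = d / sqrt(1/n_inv + 1/n_comp): exactly the mapping the p-and-n
# imputation tier inverts, so derivation and imputation agree
p_from_d <- function(d, n_inv, n_comp) {
  t_stat <- d / sqrt(1 / n_inv + 1 / n_comp)
  df <- n_inv + n_comp - 2
  2 * pt(-abs(t_stat), df = df)
}

check_orientation <- function(better_is) {
  if (!all(better_is %in% c("lower", "higher"))) {
    stop_value("`better_is` must be \"lower\" or \"higher\".")
  }
}

#' @rdname effect_cascade
#' @export
d_from_continuous_arms <- function(m_inv, sd_inv, n_inv, m_comp, sd_comp,
                                   n_comp, better_is = "lower",
                                   hedges = FALSE) {
  if (!all(is.finite(m_inv), is.finite(m_comp), is.finite(sd_inv),
           is.finite(sd_comp))) {
    stop_value("Arm means and SDs must be finite.")
  }
  if (any(sd_inv <= 0) || any(sd_comp <= 0)) {
    stop_value("Arm SDs must be positive.")
  }
  if (any(n_inv < 2) || any(n_comp < 2)) {
    stop_value("At least 2 subjects per arm are required.")
  }
  check_orientation(better_is)
  df <- n_inv + n_comp - 2
  s_pooled <- sqrt(((n_inv - 1) * sd_inv^2 + (n_comp - 1) * sd_comp^2) / df)
  d <- (m_inv - m_comp) / s_pooled
  d <- ifelse(better_is == "higher", -d, d)
  if (hedges) d <- d * (1 - 3 / (4 * df - 1))
  v <- var_cohen_d(d, n_inv, n_comp)
  effect_tibble(d, v, p_from_d(d, n_inv, n_comp), n_inv, n_comp,
                "arm_stats", "continuous")
}

#' @param e_inv,e_comp Event counts per arm (0 <= events <= n).
#' @param event_is_good `TRUE` when the counted event is desirable (response,
#'   remission), `FALSE` when it is undesirable (relapse, dropout).
#' @rdname effect_cascade
#' @export
d_from_binary_arms <- function(e_inv, n_inv, e_comp, n_comp,
                               event_is_good = FALSE) {
  if (any(e_inv > n_inv) || any(e_comp > n_comp)) {
    stop_value("Event counts cannot exceed arm sizes.")
  }
  if (any(e_inv < 0) || any(e_comp < 0)) {
    stop_value("Event counts must be nonnegative.")
  }
  a <- e_inv
  b <- n_inv - e_inv
  cc <- e_comp
  dd <- n_comp - e_comp
  # both arms all-events or both all-non-events: the 2x2 table carries no
  # comparative information even after continuity correction
  degenerate <- (a == 0 & cc == 0) | (b == 0 & dd == 0)
  zero <- a == 0 | b == 0 | cc == 0 | dd == 0
  a <- a + 0.5 * zero
  b <- b + 0.5 * zero
  cc <- cc + 0.5 * zero
  dd <- dd + 0.5 * zero
  log_or <- log((a * dd) / (b * cc))
  d <- log_or * sqrt(3) / pi
  # more events in the drug arm is good news iff the event is good; flip so
  # negative d always favours the investigational arm
  d <- ifelse(event_is_good, -d, d)
  v <- (3 / pi^2) * (1 / a + 1 / b + 1 / cc + 1 / dd)
  df <- n_inv + n_comp - 2
  p <- 2 * pt(-abs(d / sqrt(v)), df = df)
  out <- effect_tibble(d, v, p, n_inv, n_comp, "arm_stats", "binary",
                       degenerate)
  out$d[degenerate] <- NA_real_
  out$var_d[degenerate] <- NA_real_
  out$se_d[degenerate] <- NA_real_
  out$p_two_sided[degenerate] <- NA_real_
  out
}

#' @param contrast Reported difference between arms, on the outcome scale
#'   (investigational minus comparator).
#' @param se Standard error of `contrast` (> 0).
#' @rdname effect_cascade
#' @export
d_from_contrast <- function(contrast, se, n_inv, n_comp,
                            better_is = "lower") {
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop_value("`se` must be positive and finite.")
  }
  if (any(!is.finite(contrast))) stop_value("`contrast` must be finite.")
  check_orientation(better_is)
  t_stat <- contrast / se
  d <- t_stat * sqrt(1 / n_inv + 1 / n_comp)
  d <- ifelse(better_is == "higher", -d, d)
  v <- var_cohen_d(d, n_inv, n_comp)
  effect_tibble(d, v, p_from_d(d, n_inv, n_comp), n_inv, n_comp,
                "contrast_only", "continuous")
}

#' @param p_two_sided Reported two-sided p-value, in (0, 1].
#' @param direction `"favours_investigational"`, `"favours_comparator"` or
#'   `"null"`; which arm the reported result favoured. A comparison reported
#'   only as a p-value without a direction cannot be signed and is treated as
#'   insufficient upstream.
#' @rdname effect_cascade
#' @export
d_from_p_n <- function(p_two_sided, n_inv, n_comp, direction) {
  if (any(!is.finite(p_two_sided)) || any(p_two_sided <= 0) ||
      any(p_two_sided > 1)) {
    stop_value("`p_two_sided` must lie in (0, 1].")
  }
  ok <- direction %in% c("favours_investigational", "favours_comparator",
                         "null")
  if (!all(ok)) {
    abort("Missing or unknown `direction`: cannot sign an imputed effect.",
          class = "eparmeta_error_imputation")
  }
  df <- n_inv + n_comp - 2
  # upper-tail form keeps full precision for very small p
  t_abs <- qt(p_two_sided / 2, df = df, lower.tail = FALSE)
  sgn <- c(favours_investigational = -1, favours_comparator = 1, null = 0)
  d <- unname(sgn[direction]) * t_abs * sqrt(1 / n_inv + 1 / n_comp)
  v <- var_cohen_d(d, n_inv, n_comp)
  effect_tibble(d, v, p_two_sided, n_inv, n_comp, "p_and_n_only", "continuous")
}
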