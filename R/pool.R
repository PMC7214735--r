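#' DerSimonian-Laird random-effects pooling
#'
#' Pools k standardized mean differences with the classic moment estimator of
#' the between-study variance. With fixed-effect weights `w_i = 1/var_i`,
#' the heterogeneity statistic is `Q = sum w_i (d_i - d_FE)^2` and
#' `tau2 = max(0, (Q - (k - 1)) / (sum w - sum w^2 / sum w))`; the pooled
#' effect then uses random-effects weights `1/(var_i + tau2)` with a Wald
#' normal confidence interval and p-value. With `k = 1` the input study is
#' returned unchanged and `tau2 = 0`.
#'
#' @param d Numeric vector of study effects (Cohen's d).
#' @param var_d Numeric vector of their variances (> 0).
#' @param conf_level Confidence level for the Wald interval (default 0.95).
#' @return An object of class `dl_pool` with elements `k`, `d_pooled`,
#'   `se_pooled`, `ci_low`, `ci_high`, `p_two_sided`, `tau2`, `Q`, and the
#'   per-study inputs and random-effects `weights`.
#' @examples
#' fit <- dl_pool(c(0.1, 0.5), c(0.04, 0.04))
#' tidy(fit)
#' glance(fit)
#' @export
dl_pool <- function(d, var_d, conf_level = 0.95) {
  if (length(d) == 0) stop_value("Cannot pool an empty set of estimates.")
  if (length(d) != length(var_d)) {
    stop_value("`d` and `var_d` must have equal length.")
  }
  if (any(!is.finite(d)) || any(!is.finite(var_d)) || any(var_d <= 0)) {
    stop_value("Effects must be finite with positive variances.")
  }
  k <- length(d)
  w <- 1 / var_d
  d_fe <- sum(w * d) / sum(w)
  q <- sum(w * (d - d_fe)^2)
  tau2 <- if (k == 1) 0 else {
    max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  }
  w_star <- 1 / (var_d + tau2)
  d_pooled <- sum(w_star * d) / sum(w_star)
  se <- 1 / sqrt(sum(w_star))
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      k = k, d_pooled = d_pooled, se_pooled = se,
      ci_low = d_pooled - z * se, ci_high = d_pooled + z * se,
      p_two_sided = 2 * pnorm(-abs(d_pooled / se)),
      tau2 = tau2, Q = q, conf_level = conf_level,
      d = d, var_d = var_d, weights = w_star
    ),
    class = "dl_pool"
  )
}

#' @export
print.dl_pool <- function(x, ...) {
  cat(sprintf(
    "DerSimonian-Laird pool of %d stud%s\n  d = %.4f [%.4f, %.4f], p = %.4g\n  tau2 = %.4f, Q = %.4f\n",
    x$k, if (x$k == 1) "y" else "ies", x$d_pooled, x$ci_low, x$ci_high,
    x$p_two_sided, x$tau2, x$Q
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname dl_pool
#' @param x A `dl_pool` object.
#' @param ... Unused.
#' @export
tidy.dl_pool <- function(x, ...) {
  tibble::tibble(
    study = seq_len(x$k),
    d = x$d,
    var_d = x$var_d,
    weight = x$weights / sum(x$weights)
  )
}

#' @rdname dl_pool
#' @export
glance.dl_pool <- function(x, ...) {
  tibble::tibble(
    k = x$k, d_pooled = x$d_pooled, se_pooled = x$se_pooled,
    ci_low = x$ci_low, ci_high = x$ci_high, p_two_sided = x$p_two_sided,
    tau2 = x$tau2, Q = x$Q
  )
}

classify_pooled <- function(d, p, alpha = 0.05) {
  dplyr::case_when(
    p < alpha & d < 0 ~ "favours_drug",
    p < alpha & d > 0 ~ "favours_comparator",
    TRUE ~ "no_evidence_of_difference"
  )
}

#' Pool a corpus per drug, daily dose, design phase and comparator class
#'
#' Builds the pooling keys and runs [dl_pool()] on each: only usable effect
#' estimates from investigational arms at an approved dose contribute;
#' initiation and continuation studies are pooled separately, as are active
#' and placebo comparators; each dose arm of a multi-arm trial contributes to
#' its own key.
#'
#' @param corpus A valid [epar_corpus()].
#' @param effects Effect estimates from [derive_effects()]; derived with
#'   `approved_doses_only = TRUE` when omitted.
#' @param by_indication Keep approvals (and hence indications) apart
#'   (default). With `FALSE`, studies of the same drug/dose are pooled across
#'   indications.
#' @param alpha Two-sided significance threshold used for the qualitative
#'   classification (default 0.05).
#' @return One row per pooling key: the key columns, `k`, `d_pooled`,
#'   `se_pooled`, `ci_low`, `ci_high`, `p_two_sided`, `tau2`, `Q` and a
#'   `classification` in `favours_drug` / `favours_comparator` /
#'   `no_evidence_of_difference`.
#' @export
pool_effects <- function(corpus, effects = NULL, by_indication = TRUE,
                         alpha = 0.05) {
  effects <- effects %||% derive_effects(corpus, approved_doses_only = TRUE)
  usable <- dplyr::filter(effects, .data$usable)
  key_cols <- c(if (by_indication) c("approval_id", "indication"),
                "drug", "daily_dose", "design_phase", "comparator_class")
  if (nrow(usable) == 0) {
    return(tibble::as_tibble(setNames(
      lapply(c(key_cols, "k", "d_pooled", "se_pooled", "ci_low", "ci_high",
               "p_two_sided", "tau2", "Q", "classification"),
             function(x) logical(0)),
      c(key_cols, "k", "d_pooled", "se_pooled", "ci_low", "ci_high",
        "p_two_sided", "tau2", "Q", "classification")
    )))
  }
  usable |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) |>
    dplyr::group_modify(function(g, key) {
      fit <- dl_pool(g$d, g$var_d)
      glance(fit)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      classification = classify_pooled(.data$d_pooled, .data$p_two_sided,
                                       alpha)
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(key_cols)))
}

#' Median and range of pooled effects in a stratum
#'
#' @param pooled Output of [pool_effects()].
#' @param design_phase `"initiation"` or `"continuation"`, or `NULL` for both.
#' @param comparator_class `"active"` or `"placebo"`, or `NULL` for both.
#' @return A one-row tibble (`median`, `min`, `max`, `n_keys`); when the
#'   stratum is empty, `n_keys = 0` and the statistics are `NA` — an empty
#'   stratum is not a zero effect.
#' @export
median_pooled_effect <- function(pooled, design_phase = NULL,
                                 comparator_class = NULL) {
  x <- pooled
  if (!is.null(design_phase)) {
    x <- dplyr::filter(x, .data$design_phase == .env$design_phase)
  }
  if (!is.null(comparator_class)) {
    x <- dplyr::filter(x, .data$comparator_class == .env$comparator_class)
  }
  if (nrow(x) == 0) {
    return(tibble::tibble(median = NA_real_, min = NA_real_, max = NA_real_,
                          n_keys = 0L))
  }
  tibble::tibble(
    median = median(x$d_pooled),
    min = min(x$d_pooled),
    max = max(x$d_pooled),
    n_keys = nrow(x)
  )
}
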