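test_that("dl_pool matches hand-evaluated DerSimonian-Laird formulas", {
  # d = {0.1, 0.5}, var = {0.04, 0.04}: Q = 2, tau2 = 0.04,
  # pooled d = 0.3, se = sqrt(1/(2 * 12.5)) = 0.2
  fit <- dl_pool(c(0.1, 0.5), c(0.04, 0.04))
  expect_equal(fit$Q, 2, tolerance = 1e-12)
  expect_equal(fit$tau2, 0.04, tolerance = 1e-12)
  expect_equal(fit$d_pooled, 0.3, tolerance = 1e-12)
  expect_equal(fit$se_pooled, 0.2, tolerance = 1e-12)

  # homogeneous studies: no heterogeneity, inverse-variance se
  hom <- dl_pool(c(0.3, 0.3), c(0.04, 0.04))
  expect_equal(hom$d_pooled, 0.3)
  expect_equal(hom$Q, 0)
  expect_equal(hom$tau2, 0)
  expect_equal(hom$se_pooled, sqrt(0.02), tolerance = 1e-12)

  # k = 1 identity
  one <- dl_pool(-0.2, 0.05)
  expect_equal(one$d_pooled, -0.2)
  expect_equal(one$tau2, 0)
  expect_equal(one$se_pooled, sqrt(0.05), tolerance = 1e-12)
  expect_true(one$ci_low < -0.2 && one$ci_high > -0.2)

  expect_error(dl_pool(numeric(), numeric()),
               class = "eparmeta_error_value")
  expect_error(dl_pool(c(0.1, 0.2), c(0.04, -0.01)),
               class = "eparmeta_error_value")
})

test_that("dl_pool agrees with metafor's DL estimator", {
  skip_if_not_installed("metafor")
  set.seed(11)
  for (i in 1:20) {
    k <- sample(2:12, 1)
    d <- rnorm(k, 0, 0.5)
    v <- runif(k, 0.01, 0.2)
    fit <- dl_pool(d, v)
    ref <- metafor::rma(yi = d, vi = v, method = "DL")
    expect_equal(fit$d_pooled, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(fit$se_pooled, as.numeric(ref$se), tolerance = 1e-8)
    expect_equal(fit$tau2, ref$tau2, tolerance = 1e-8)
    expect_equal(fit$Q, ref$QE, tolerance = 1e-8)
    expect_equal(fit$p_two_sided, ref$pval, tolerance = 1e-8)
  }
})

test_that("pooling is convex and reduces to fixed effects when homogeneous", {
  set.seed(3)
  for (i in 1:10) {
    k <- sample(2:8, 1)
    d <- rnorm(k, -0.3, 0.3)
    v <- runif(k, 0.02, 0.1)
    fit <- dl_pool(d, v)
    # the pooled estimate is a convex combination of the inputs
    expect_gte(fit$d_pooled, min(d))
    expect_lte(fit$d_pooled, max(d))
    # when tau2 truncates to zero the pool is inverse-variance fixed-effect
    if (fit$tau2 == 0) {
      w <- 1 / v
      expect_equal(fit$d_pooled, sum(w * d) / sum(w), tolerance = 1e-12)
      expect_equal(fit$se_pooled, sqrt(1 / sum(w)), tolerance = 1e-12)
    }
  }
  # with tau2 held at zero by construction (identical studies), adding a
  # study at the pooled value leaves the estimate unchanged; in general the
  # re-estimated tau2 shifts the weights, so this holds only for the
  # homogeneous case
  fit <- dl_pool(c(0.3, 0.3, 0.3), c(0.04, 0.05, 0.06))
  fit2 <- dl_pool(c(0.3, 0.3, 0.3, fit$d_pooled), c(0.04, 0.05, 0.06, 0.05))
  expect_equal(fit2$d_pooled, fit$d_pooled, tolerance = 1e-12)
})

test_that("tidy and glance return one row per study / per fit", {
  fit <- dl_pool(c(0.1, 0.5, -0.2), c(0.04, 0.05, 0.06))
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_equal(sum(td$weight), 1, tolerance = 1e-12)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_named(gl, c("k", "d_pooled", "se_pooled", "ci_low", "ci_high",
                     "p_two_sided", "tau2", "Q"))
})

test_that("pooling keys separate dose, design phase and comparator class", {
  # one trial, two approved doses vs a shared placebo: two keys of k = 1
  two_dose <- list(list(
    arms = dplyr::bind_rows(
      arm_spec("investigational", mean = -0.4, dose = 10),
      arm_spec("investigational", mean = -0.3, dose = 20),
      arm_spec("placebo", mean = 0)
    ),
    cmp = dplyr::bind_rows(
      cmp_spec(1, 3, "placebo"),
      cmp_spec(2, 3, "placebo")
    )
  ))
  pooled <- pool_effects(mini_corpus(two_dose))
  expect_equal(nrow(pooled), 2)
  expect_setequal(pooled$daily_dose, c(10, 20))
  expect_true(all(pooled$k == 1))

  # same drug/dose in initiation and continuation: never the same key
  phases <- list(placebo_trial(-0.4, phase = "initiation"),
                 placebo_trial(-0.4, phase = "continuation"))
  pooled2 <- pool_effects(mini_corpus(phases))
  expect_equal(nrow(pooled2), 2)
  expect_setequal(pooled2$design_phase, c("initiation", "continuation"))

  # identical keys pool together
  pooled3 <- pool_effects(mini_corpus(list(placebo_trial(-0.45),
                                           placebo_trial(-0.35))))
  expect_equal(nrow(pooled3), 1)
  expect_equal(pooled3$k, 2)
})

test_that("doses outside the approved window are excluded from pooling", {
  corpus <- mini_corpus(list(placebo_trial(-0.4, dose = 2),
                             placebo_trial(-0.4, dose = 10)),
                        dose_min = 5, dose_max = 20)
  pooled <- pool_effects(corpus)
  expect_equal(nrow(pooled), 1)
  expect_equal(pooled$daily_dose, 10)

  # missing dose bounds: retained with a warning, not silently dropped
  nb <- mini_corpus(list(placebo_trial(-0.4, dose = 2)),
                    dose_min = NA_real_, dose_max = NA_real_)
  expect_warning(eff <- derive_effects(nb, approved_doses_only = TRUE),
                 "no dose bounds")
  expect_equal(nrow(eff), 1)
})

test_that("classification follows significance and sign", {
  sig_neg <- pool_effects(mini_corpus(list(placebo_trial(-0.5),
                                           placebo_trial(-0.5))))
  expect_identical(sig_neg$classification, "favours_drug")
  null <- pool_effects(mini_corpus(list(placebo_trial(-0.05))))
  expect_identical(null$classification, "no_evidence_of_difference")
})

test_that("median_pooled_effect reports median, range and stratum size", {
  pooled <- tibble::tibble(
    design_phase = "initiation", comparator_class = "placebo",
    d_pooled = c(-1, 0, 1)
  )
  m <- median_pooled_effect(pooled, "initiation", "placebo")
  expect_equal(m$median, 0)
  expect_equal(c(m$min, m$max), c(-1, 1))
  expect_equal(m$n_keys, 3)
  # an empty stratum is explicit, never a zero
  e <- median_pooled_effect(pooled, "continuation", "active")
  expect_equal(e$n_keys, 0)
  expect_true(is.na(e$median))
  # even count: mean of the middle two
  m2 <- median_pooled_effect(
    tibble::tibble(design_phase = "initiation",
                   comparator_class = "placebo",
                   d_pooled = c(0.1, 0.2, 0.6, 0.7)),
    "initiation", "placebo"
  )
  expect_equal(m2$median, 0.4)
})
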