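test_that("continuous-arm Cohen's d matches hand-computed values", {
  # m_inv=10, m_comp=11, common sd 2, n=50/50, lower is better:
  # d = -1/2 = -0.5, var = 100/2500 + 0.25/200 = 0.04125
  est <- d_from_continuous_arms(10, 2, 50, 11, 2, 50, better_is = "lower")
  expect_equal(est$d, -0.5, tolerance = 1e-12)
  expect_equal(est$var_d, 0.04125, tolerance = 1e-12)
  expect_equal(est$se_d, sqrt(0.04125), tolerance = 1e-12)
  # p from the realised two-sample t statistic, t = d / sqrt(1/n1 + 1/n2)
  expect_equal(est$p_two_sided,
               2 * pt(-abs(-0.5 / sqrt(0.04)), df = 98),
               tolerance = 1e-12)
  expect_identical(est$tier_used, "arm_stats")

  # equal means: d exactly 0, p exactly 1
  null <- d_from_continuous_arms(7, 1.3, 40, 7, 1.1, 60)
  expect_equal(null$d, 0)
  expect_equal(null$p_two_sided, 1)

  # unequal SDs use the bias-free pooled SD
  sp <- sqrt((29 * 1.5^2 + 19 * 2.5^2) / 48)
  est2 <- d_from_continuous_arms(4, 1.5, 30, 5, 2.5, 20)
  expect_equal(est2$d, -1 / sp, tolerance = 1e-12)
})

test_that("continuous d is antisymmetric, orientation-aware and scale-free", {
  set.seed(42)
  for (i in 1:20) {
    m1 <- rnorm(1); m2 <- rnorm(1)
    s1 <- runif(1, 0.5, 3); s2 <- runif(1, 0.5, 3)
    n1 <- sample(5:200, 1); n2 <- sample(5:200, 1)
    a <- d_from_continuous_arms(m1, s1, n1, m2, s2, n2)
    b <- d_from_continuous_arms(m2, s2, n2, m1, s1, n1)
    expect_equal(b$d, -a$d, tolerance = 1e-12)
    expect_equal(b$p_two_sided, a$p_two_sided, tolerance = 1e-12)
    # var depends on d only through d^2, so swap preserves it up to the
    # (n_inv, n_comp) symmetry of the formula
    expect_equal(b$var_d, a$var_d, tolerance = 1e-12)
    # flipping the scale orientation flips the sign
    f <- d_from_continuous_arms(m1, s1, n1, m2, s2, n2,
                                better_is = "higher")
    expect_equal(f$d, -a$d, tolerance = 1e-12)
    # rescaling all means and SDs leaves d unchanged
    k <- runif(1, 0.1, 10)
    sc <- d_from_continuous_arms(k * m1, k * s1, n1, k * m2, k * s2, n2)
    expect_equal(sc$d, a$d, tolerance = 1e-10)
  }
})

test_that("the Hedges option applies the small-sample correction factor", {
  plain <- d_from_continuous_arms(10, 2, 10, 12, 2, 10)
  corr <- d_from_continuous_arms(10, 2, 10, 12, 2, 10, hedges = TRUE)
  expect_equal(corr$d, plain$d * (1 - 3 / (4 * 18 - 1)), tolerance = 1e-12)
})

test_that("binary-arm d implements the log-OR sqrt(3)/pi conversion", {
  # 30/50 vs 20/50 with a desirable event:
  # OR = (30*30)/(20*20), d = -(sqrt(3)/pi) ln(OR)
  est <- d_from_binary_arms(30, 50, 20, 50, event_is_good = TRUE)
  expect_equal(est$d, -(sqrt(3) / pi) * log(900 / 400), tolerance = 1e-12)
  expect_equal(est$var_d,
               (3 / pi^2) * (1 / 30 + 1 / 20 + 1 / 20 + 1 / 30),
               tolerance = 1e-12)
  expect_identical(est$outcome_type, "binary")

  # equal proportions: d = 0 regardless of orientation
  expect_equal(d_from_binary_arms(10, 50, 10, 50)$d, 0)

  # undesirable event (relapse): fewer events in the drug arm gives d < 0
  rel <- d_from_binary_arms(10, 50, 25, 50, event_is_good = FALSE)
  expect_lt(rel$d, 0)

  # a zero cell triggers the 0.5 continuity correction on all four cells
  cc <- d_from_binary_arms(0, 10, 5, 10)
  expect_equal(cc$d,
               (sqrt(3) / pi) * log((0.5 * 5.5) / (10.5 * 5.5)),
               tolerance = 1e-12)
  expect_false(cc$degenerate)

  # no events (or all events) in both arms carries no information
  expect_true(d_from_binary_arms(0, 10, 0, 10)$degenerate)
  expect_true(d_from_binary_arms(10, 10, 12, 12)$degenerate)
  expect_true(is.na(d_from_binary_arms(0, 10, 0, 10)$d))

  expect_error(d_from_binary_arms(60, 50, 10, 50),
               class = "eparmeta_error_value")
})

test_that("contrast-based d matches hand evaluation and the arm-stats path", {
  # t = -2, d = t * sqrt(1/50 + 1/50) = -0.4
  est <- d_from_contrast(-2, 1, 50, 50)
  expect_equal(est$d, -2 * sqrt(0.04), tolerance = 1e-12)
  expect_identical(est$tier_used, "contrast_only")
  expect_equal(d_from_contrast(0, 1, 30, 40)$d, 0)
  expect_equal(d_from_contrast(0, 1, 30, 40)$p_two_sided, 1)

  # cross-path consistency: contrast and SE computed from the same arm
  # statistics give nearly the same d at large n (the pooled-SD and
  # Welch-type SE differ only in finite samples)
  m1 <- -1.2; m2 <- -0.7; s1 <- 1.1; s2 <- 0.9; n <- 500
  full <- d_from_continuous_arms(m1, s1, n, m2, s2, n)
  ct <- d_from_contrast(m1 - m2, sqrt(s1^2 / n + s2^2 / n), n, n)
  expect_equal(ct$d, full$d, tolerance = 0.02)

  expect_error(d_from_contrast(1, 0, 10, 10),
               class = "eparmeta_error_value")
})

test_that("p-and-n imputation inverts the t reference", {
  # p = 0.05, 50/50: |t| = qt(0.975, 98), d = -|t| * 0.2
  est <- d_from_p_n(0.05, 50, 50, "favours_investigational")
  expect_equal(est$d, -qt(0.975, 98) * sqrt(1 / 50 + 1 / 50),
               tolerance = 1e-10)
  expect_identical(est$tier_used, "p_and_n_only")
  expect_equal(d_from_p_n(1, 30, 30, "favours_comparator")$d, 0)

  # direction decides the sign only
  up <- d_from_p_n(0.05, 50, 50, "favours_comparator")
  expect_equal(up$d, -est$d, tolerance = 1e-12)

  expect_error(d_from_p_n(0.05, 50, 50, NA_character_),
               class = "eparmeta_error_imputation")
  expect_error(d_from_p_n(0, 50, 50, "null"),
               class = "eparmeta_error_value")
})

test_that("imputation from p and n round-trips the richer tiers", {
  set.seed(7)
  for (i in 1:25) {
    m1 <- rnorm(1); m2 <- rnorm(1)
    s <- runif(1, 0.5, 2)
    n1 <- sample(10:150, 1); n2 <- sample(10:150, 1)
    full <- d_from_continuous_arms(m1, s, n1, m2, s, n2)
    dir <- if (full$d < 0) "favours_investigational" else "favours_comparator"
    back <- d_from_p_n(full$p_two_sided, n1, n2, dir)
    expect_equal(back$d, full$d, tolerance = 1e-6)
  }
})

test_that("input validation rejects impossible arm summaries", {
  expect_error(d_from_continuous_arms(1, 0, 50, 2, 1, 50),
               class = "eparmeta_error_value")
  expect_error(d_from_continuous_arms(1, 1, 1, 2, 1, 50),
               class = "eparmeta_error_value")
  expect_error(d_from_continuous_arms(NaN, 1, 50, 2, 1, 50),
               class = "eparmeta_error_value")
  expect_error(d_from_continuous_arms(1, 1, 50, 2, 1, 50, better_is = "up"),
               class = "eparmeta_error_value")
  expect_error(d_from_p_n(1.2, 50, 50, "null"),
               class = "eparmeta_error_value")
})
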