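test_that("trial verdicts follow the superiority rubric", {
  # an active arm randomised but never compared with the drug: uncompared
  uncomp <- mini_corpus(list(list(
    arms = dplyr::bind_rows(
      arm_spec("investigational", mean = -0.4, dose = 10),
      arm_spec("active_comparator", mean = -0.35),
      arm_spec("placebo", mean = 0)
    ),
    cmp = cmp_spec(1, 3, "placebo")
  )))
  v <- grade_trials(uncomp)
  expect_identical(v$verdict[v$comparator_class == "active"], "uncompared")
  expect_identical(v$verdict[v$comparator_class == "placebo"], "positive")

  # significant in the drug's favour: positive; otherwise negative
  sig <- mini_corpus(list(list(
    arms = dplyr::bind_rows(
      arm_spec("investigational", mean = -0.45, dose = 10),
      arm_spec("active_comparator", mean = 0)
    ),
    cmp = cmp_spec(1, 2, "active")
  )))
  expect_identical(grade_trials(sig)$verdict, "positive")

  ns <- mini_corpus(list(list(
    arms = dplyr::bind_rows(
      arm_spec("investigational", mean = -0.05, dose = 10),
      arm_spec("active_comparator", mean = 0)
    ),
    cmp = cmp_spec(1, 2, "active")
  )))
  expect_identical(grade_trials(ns)$verdict, "negative")

  # significant against the drug is negative evidence, not positive
  against <- mini_corpus(list(list(
    arms = dplyr::bind_rows(
      arm_spec("investigational", mean = 0.45, dose = 10),
      arm_spec("active_comparator", mean = 0)
    ),
    cmp = cmp_spec(1, 2, "active")
  )))
  expect_identical(grade_trials(against)$verdict, "negative")
})

test_that("non-inferiority verdicts use the report, then the CI-vs-NIB rule", {
  ni <- function(verdict, d = 0.04, nib = NA_real_) {
    list(
      hyp = "non_inferiority", ni_verdict = verdict, nib = nib,
      arms = dplyr::bind_rows(
        arm_spec("investigational", mean = d, dose = 10),
        arm_spec("active_comparator", mean = 0)
      ),
      cmp = cmp_spec(1, 2, "active")
    )
  }
  expect_identical(grade_trials(mini_corpus(list(ni("negative"))))$verdict,
                   "negative")
  expect_identical(grade_trials(mini_corpus(list(ni("positive"))))$verdict,
                   "positive")

  # no reported verdict: CI upper bound inside the boundary is positive
  # (d = 0.04, sd = 1, n = 100/arm: upper CI approx 0.32 < 0.5)
  expect_identical(
    grade_trials(mini_corpus(list(ni("not_applicable", d = 0.04,
                                     nib = 0.5))))$verdict,
    "positive"
  )
  # wide CI crossing the boundary is negative
  expect_identical(
    grade_trials(mini_corpus(list(ni("not_applicable", d = 0.45,
                                     nib = 0.5))))$verdict,
    "negative"
  )
})

test_that("approval grades aggregate trial verdicts into rubric categories", {
  robust <- mini_corpus(list(
    list(arms = dplyr::bind_rows(
      arm_spec("investigational", mean = -0.45, dose = 10),
      arm_spec("active_comparator", mean = 0)
    ), cmp = cmp_spec(1, 2, "active")),
    list(arms = dplyr::bind_rows(
      arm_spec("investigational", mean = -0.5, dose = 10),
      arm_spec("active_comparator", mean = 0)
    ), cmp = cmp_spec(1, 2, "active"))
  ))
  g <- grade_approvals(robust)
  sup <- g[g$column == "superiority_vs_active_initiation", ]
  expect_identical(sup$category, "robust")
  expect_equal(sup$n_positive, 2L)

  # one positive NI study alongside two negative ones: single
  ni_mixed <- mini_corpus(list(
    list(hyp = "non_inferiority", ni_verdict = "positive",
         arms = dplyr::bind_rows(
           arm_spec("investigational", mean = 0.04, dose = 10),
           arm_spec("active_comparator", mean = 0)
         ), cmp = cmp_spec(1, 2, "active")),
    list(hyp = "non_inferiority", ni_verdict = "negative",
         arms = dplyr::bind_rows(
           arm_spec("investigational", mean = 0.2, dose = 10),
           arm_spec("active_comparator", mean = 0)
         ), cmp = cmp_spec(1, 2, "active")),
    list(hyp = "non_inferiority", ni_verdict = "negative",
         arms = dplyr::bind_rows(
           arm_spec("investigational", mean = 0.25, dose = 10),
           arm_spec("active_comparator", mean = 0)
         ), cmp = cmp_spec(1, 2, "active"))
  ))
  gni <- grade_approvals(ni_mixed)
  ni_row <- gni[gni$column == "non_inferiority_vs_active", ]
  expect_identical(ni_row$category, "single")
  expect_equal(ni_row$n_negative, 2L)

  # waived comparative evidence: every vs-active column not_required
  waived <- mini_corpus(list(placebo_trial(-0.4)),
                        comparative_required = FALSE)
  gw <- grade_approvals(waived)
  for (col in c("superiority_vs_active_initiation",
                "non_inferiority_vs_active", "continuation_vs_active",
                "active_grouped")) {
    expect_identical(gw$category[gw$column == col], "not_required")
  }
  expect_identical(
    gw$category[gw$column == "superiority_vs_placebo_initiation"], "single"
  )
})

test_that("grades are invariant to trial ordering", {
  corpus <- mini_corpus(list(placebo_trial(-0.45), placebo_trial(-0.05),
                             placebo_trial(-0.5)))
  shuffled <- corpus
  shuffled$trials <- shuffled$trials[c(3, 1, 2), ]
  shuffled$arms <- shuffled$arms[rev(seq_len(nrow(shuffled$arms))), ]
  expect_equal(grade_approvals(corpus), grade_approvals(shuffled))
})

test_that("grouped columns take the stronger category, not the sum", {
  # one positive initiation + one positive continuation placebo trial:
  # grouped placebo evidence stays single
  corpus <- mini_corpus(list(placebo_trial(-0.45),
                             placebo_trial(-0.5, phase = "continuation")))
  g <- grade_approvals(corpus)
  expect_identical(g$category[g$column == "placebo_grouped"], "single")
  expect_equal(g$n_positive[g$column == "placebo_grouped"], 2L)
})

test_that("the heatmap codes evidence and flags per the legend", {
  corpus <- mini_corpus(list(placebo_trial(-0.45), placebo_trial(-0.5)),
                        comparative_required = FALSE)
  corpus$approvals$divergent_opinion <- TRUE
  corpus$approvals$subgroup_basis <- "post_hoc"
  corpus$approvals$safety_issue <- "possible"
  mat <- heatmap_matrix(corpus)
  expect_equal(mat$superiority_vs_placebo_initiation, 2)
  # not_required is NA, never 0
  expect_true(is.na(mat$superiority_vs_active_initiation))
  expect_equal(mat$divergent_opinion, 0)
  expect_equal(mat$subgroup_basis, 0)
  expect_equal(mat$safety_issue, 1)
  expect_named(
    mat,
    c("approval_id", "superiority_vs_active_initiation",
      "non_inferiority_vs_active", "superiority_vs_placebo_initiation",
      "continuation_vs_active", "continuation_vs_placebo",
      "active_grouped", "placebo_grouped", "subgroup_basis",
      "bias_assessment", "safety_issue", "tolerance_issue",
      "divergent_opinion")
  )
  # legend covers every matrix column
  expect_setequal(names(heatmap_legend()),
                  setdiff(names(mat), "approval_id"))
})

test_that("category counts per column cover all required approvals", {
  corpus <- benchmark_corpus()
  g <- grade_approvals(corpus)
  tallies <- summarise_grades(g)
  by_col <- tallies |>
    dplyr::filter(category != "not_required") |>
    dplyr::group_by(column) |>
    dplyr::summarise(total = sum(count), denom = denominator[1])
  expect_true(all(by_col$total == by_col$denom))
})
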