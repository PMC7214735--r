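#' The approval-dossier corpus
#'
#' A corpus is the machine form of a dossier-extraction sheet: four linked
#' tables joined by id columns.
#'
#' * `approvals` — one row per marketing-authorisation application (drug,
#'   route, indication) with its evidence-requirement and reporting flags.
#' * `trials` — one row per randomised study: design phase
#'   (initiation/continuation), hypothesis (superiority/non-inferiority),
#'   duration, non-inferiority boundary (NIB), primary outcome kind.
#' * `arms` — one row per trial arm with the raw reported numbers.
#' * `comparisons` — one row per investigational-vs-comparator contrast with
#'   its reporting tier and whatever the dossier printed (contrast + SE,
#'   p-value + direction, or nothing usable).
#'
#' Missing values are encoded as empty cells (CSV) or `null` (JSON), never as
#' sentinel numbers: a dose or NIB the dossier did not report is not zero.
#'
#' @param approvals,trials,arms,comparisons Data frames with the columns
#'   listed in [corpus_schema()].
#' @return An object of class `epar_corpus`: a named list of the four tibbles
#'   with a `schema_version` attribute.
#' @seealso [read_corpus()], [write_corpus()], [validate_corpus()]
#' @export
epar_corpus <- function(approvals, trials, arms, comparisons) {
  sch <- corpus_schema()
  tabs <- list(approvals = approvals, trials = trials, arms = arms,
               comparisons = comparisons)
  tabs <- purrr::imap(tabs, function(tab, name) {
    tab <- tibble::as_tibble(tab)
    spec <- sch[[name]]
    missing_cols <- setdiff(names(spec), names(tab))
    for (col in missing_cols) tab[[col]] <- empty_col(spec[[col]])
    for (col in names(spec)) tab[[col]] <- coerce_col(tab[[col]], spec[[col]])
    tab[names(spec)]
  })
  structure(tabs, class = "epar_corpus", schema_version = CORPUS_SCHEMA_VERSION)
}

CORPUS_SCHEMA_VERSION <- "1.0"

CORPUS_ENUMS <- list(
  route = c("oral", "intramuscular", "sublingual", "inhalation", "other"),
  subgroup_basis = c("none", "pre_specified", "post_hoc"),
  bias_assessment = c("none_reported", "reported_no_bias",
                      "reported_bias_found"),
  comparison_reporting = c("quantitative", "qualitative", "absent"),
  issue = c("yes", "possible", "no"),
  design_phase = c("initiation", "continuation"),
  hypothesis = c("superiority", "non_inferiority"),
  primary_outcome_kind = c("symptom_scale", "clinical_global_impression",
                           "global_functioning", "quality_of_life", "relapse",
                           "response", "remission", "other"),
  suicidal_excluded = c("yes", "not_stated"),
  reported_ni_verdict = c("positive", "negative", "not_applicable"),
  role = c("investigational", "active_comparator", "placebo"),
  outcome_type = c("continuous", "binary"),
  comparator_class = c("active", "placebo"),
  reporting_tier = c("arm_stats", "contrast_only", "p_and_n_only",
                     "insufficient"),
  direction = c("favours_investigational", "favours_comparator", "null"),
  better_is = c("lower", "higher")
)

#' Corpus column schema
#'
#' @return A named list (one element per table) of named column type strings
#'   (`"chr"`, `"int"`, `"dbl"`, `"lgl"`).
#' @export
corpus_schema <- function() {
  list(
    approvals = c(
      approval_id = "chr", drug = "chr", route = "chr", indication = "chr",
      year = "int", manufacturer = "chr",
      comparative_evidence_required = "lgl",
      continuation_evidence_required = "lgl",
      subgroup_basis = "chr", bias_assessment = "chr",
      safety_comparison_active = "chr", safety_comparison_placebo = "chr",
      safety_issue = "chr",
      tolerance_comparison_active = "chr", tolerance_comparison_placebo = "chr",
      tolerance_issue = "chr",
      divergent_opinion = "lgl", n_exposed_presubmission = "int",
      approved_dose_min = "dbl", approved_dose_max = "dbl"
    ),
    trials = c(
      trial_id = "chr", approval_id = "chr", design_phase = "chr",
      hypothesis = "chr", duration_weeks = "dbl",
      non_inferiority_boundary = "dbl", primary_outcome_kind = "chr",
      suicidal_excluded = "chr", reported_ni_verdict = "chr",
      pooled_analysis = "lgl"
    ),
    arms = c(
      arm_id = "chr", trial_id = "chr", role = "chr", drug = "chr",
      daily_dose = "dbl", n_randomised = "int", n_withdrawn = "int",
      n_discontinued_ae = "int", outcome_type = "chr", mean_change = "dbl",
      sd_change = "dbl", events = "int"
    ),
    comparisons = c(
      trial_id = "chr", investigational_arm_id = "chr",
      comparator_arm_id = "chr", comparator_class = "chr",
      reporting_tier = "chr", contrast_value = "dbl", contrast_se = "dbl",
      reported_p = "dbl", direction = "chr", better_is = "chr"
    )
  )
}

empty_col <- function(type) {
  switch(type, chr = character(), int = integer(), dbl = double(),
         lgl = logical())
}

coerce_col <- function(x, type) {
  switch(type,
    chr = as.character(x),
    int = as.integer(x),
    dbl = as.double(x),
    lgl = as.logical(x)
  )
}

#' @export
print.epar_corpus <- function(x, ...) {
  cat("<epar_corpus> schema", attr(x, "schema_version"), "\n")
  cat(sprintf(
    "  %d approvals, %d trials, %d arms, %d comparisons\n",
    nrow(x$approvals), nrow(x$trials), nrow(x$arms), nrow(x$comparisons)
  ))
  invisible(x)
}

enum_violations <- function(tab, table_name, id_col, cols) {
  out <- list()
  for (col in names(cols)) {
    if (!col %in% names(tab)) next
    bad <- !is.na(tab[[col]]) & !tab[[col]] %in% CORPUS_ENUMS[[cols[[col]]]]
    if (any(bad)) {
      out[[col]] <- tibble::tibble(
        table = table_name, id = tab[[id_col]][bad], field = col,
        problem = paste0("value '", tab[[col]][bad],
                         "' outside the documented vocabulary"),
        class = "value"
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Validate a corpus against its invariants
#'
#' Collects every violation rather than stopping at the first, so a whole
#' extraction sheet can be repaired in one pass.
#'
#' @param corpus An [epar_corpus()].
#' @return A tibble of violations (`table`, `id`, `field`, `problem`,
#'   `class`); zero rows when the corpus is valid.
#' @export
validate_corpus <- function(corpus) {
  ap <- corpus$approvals
  tr <- corpus$trials
  ar <- corpus$arms
  cmp <- corpus$comparisons
  v <- list()
  add <- function(ids, table, field, problem, class) {
    if (length(ids) == 0) return()
    v[[length(v) + 1]] <<- tibble::tibble(
      table = table, id = as.character(ids), field = field,
      problem = problem, class = class
    )
  }

  dup <- ap$approval_id[duplicated(ap$approval_id)]
  add(unique(dup), "approvals", "approval_id", "duplicated id", "integrity")
  dup <- tr$trial_id[duplicated(tr$trial_id)]
  add(unique(dup), "trials", "trial_id", "duplicated id", "integrity")
  dup <- ar$arm_id[duplicated(ar$arm_id)]
  add(unique(dup), "arms", "arm_id", "duplicated id", "integrity")

  bad <- !is.na(ap$approved_dose_min) & !is.na(ap$approved_dose_max) &
    ap$approved_dose_min > ap$approved_dose_max
  add(ap$approval_id[bad], "approvals", "approved_dose_min",
      "approved_dose_min exceeds approved_dose_max", "value")

  add(tr$trial_id[!tr$approval_id %in% ap$approval_id], "trials",
      "approval_id", "references an unknown approval", "integrity")
  add(ar$arm_id[!ar$trial_id %in% tr$trial_id], "arms", "trial_id",
      "references an unknown trial", "integrity")
  add(cmp$investigational_arm_id[!cmp$trial_id %in% tr$trial_id],
      "comparisons", "trial_id", "references an unknown trial", "integrity")

  n_arms <- table(ar$trial_id)
  few <- tr$trial_id[!tr$trial_id %in% names(n_arms)[n_arms >= 2]]
  add(few, "trials", "arms", "fewer than 2 arms", "integrity")

  bad <- !is.na(ar$events) & ar$events > ar$n_randomised
  add(ar$arm_id[bad], "arms", "events",
      "events exceed n_randomised", "integrity")

  bad <- ar$outcome_type %in% "binary" &
    (!is.na(ar$mean_change) | !is.na(ar$sd_change))
  add(ar$arm_id[bad], "arms", "outcome_type",
      "binary outcome with continuous statistics", "value")
  bad <- ar$outcome_type %in% "continuous" & !is.na(ar$events)
  add(ar$arm_id[bad], "arms", "outcome_type",
      "continuous outcome with event counts", "value")
  bad <- !is.na(ar$sd_change) & ar$sd_change <= 0
  add(ar$arm_id[bad], "arms", "sd_change", "non-positive SD", "value")

  bad <- !is.na(tr$non_inferiority_boundary) &
    tr$hypothesis %in% "superiority"
  add(tr$trial_id[bad], "trials", "non_inferiority_boundary",
      "NIB present on a superiority trial", "value")

  # comparison-level integrity against the arm table
  role_of <- setNames(ar$role, ar$arm_id)
  trial_of <- setNames(ar$trial_id, ar$arm_id)
  bad <- !cmp$investigational_arm_id %in% ar$arm_id
  add(cmp$investigational_arm_id[bad], "comparisons",
      "investigational_arm_id", "references an unknown arm", "integrity")
  bad <- !cmp$comparator_arm_id %in% ar$arm_id
  add(cmp$comparator_arm_id[bad], "comparisons", "comparator_arm_id",
      "references an unknown arm", "integrity")
  known <- cmp$investigational_arm_id %in% ar$arm_id &
    cmp$comparator_arm_id %in% ar$arm_id
  bad <- known & role_of[cmp$investigational_arm_id] != "investigational"
  add(cmp$investigational_arm_id[bad], "comparisons",
      "investigational_arm_id", "arm is not an investigational arm",
      "integrity")
  expected_role <- ifelse(cmp$comparator_class == "active",
                          "active_comparator", "placebo")
  bad <- known & role_of[cmp$comparator_arm_id] != expected_role
  add(cmp$comparator_arm_id[bad], "comparisons", "comparator_arm_id",
      "comparator arm role does not match comparator_class", "integrity")
  bad <- known & (trial_of[cmp$investigational_arm_id] != cmp$trial_id |
                    trial_of[cmp$comparator_arm_id] != cmp$trial_id)
  add(cmp$investigational_arm_id[bad], "comparisons", "trial_id",
      "arms belong to a different trial", "integrity")

  bad <- !is.na(cmp$reported_p) & (cmp$reported_p <= 0 | cmp$reported_p > 1)
  add(cmp$investigational_arm_id[bad], "comparisons", "reported_p",
      "p-value outside (0, 1]", "value")
  bad <- cmp$reporting_tier %in% "p_and_n_only" &
    (is.na(cmp$reported_p) | is.na(cmp$direction))
  add(cmp$investigational_arm_id[bad], "comparisons", "reporting_tier",
      "p_and_n_only comparison lacking reported_p or direction", "value")

  if (nrow(cmp) > 0) {
    complete_arm <- function(ids) {
      idx <- match(ids, ar$arm_id)
      ifelse(ar$outcome_type[idx] == "continuous",
             !is.na(ar$mean_change[idx]) & !is.na(ar$sd_change[idx]),
             !is.na(ar$events[idx]))
    }
    tier_as <- cmp$reporting_tier %in% "arm_stats" & known
    bad <- tier_as & !(complete_arm(cmp$investigational_arm_id) &
                         complete_arm(cmp$comparator_arm_id))
    add(cmp$investigational_arm_id[bad], "comparisons", "reporting_tier",
        "arm_stats comparison whose arms lack complete outcome statistics",
        "value")
    bad <- cmp$reporting_tier %in% "contrast_only" &
      (is.na(cmp$contrast_value) | is.na(cmp$contrast_se))
    add(cmp$investigational_arm_id[bad], "comparisons", "reporting_tier",
        "contrast_only comparison lacking contrast or SE", "value")
  }

  v[[length(v) + 1]] <- enum_violations(
    ap, "approvals", "approval_id",
    c(route = "route", subgroup_basis = "subgroup_basis",
      bias_assessment = "bias_assessment",
      safety_comparison_active = "comparison_reporting",
      safety_comparison_placebo = "comparison_reporting",
      safety_issue = "issue",
      tolerance_comparison_active = "comparison_reporting",
      tolerance_comparison_placebo = "comparison_reporting",
      tolerance_issue = "issue")
  )
  v[[length(v) + 1]] <- enum_violations(
    tr, "trials", "trial_id",
    c(design_phase = "design_phase", hypothesis = "hypothesis",
      primary_outcome_kind = "primary_outcome_kind",
      suicidal_excluded = "suicidal_excluded",
      reported_ni_verdict = "reported_ni_verdict")
  )
  v[[length(v) + 1]] <- enum_violations(
    ar, "arms", "arm_id", c(role = "role", outcome_type = "outcome_type")
  )
  v[[length(v) + 1]] <- enum_violations(
    cmp, "comparisons", "investigational_arm_id",
    c(comparator_class = "comparator_class",
      reporting_tier = "reporting_tier", direction = "direction",
      better_is = "better_is")
  )

  out <- dplyr::bind_rows(v)
  if (nrow(out) == 0) {
    tibble::tibble(table = character(), id = character(), field = character(),
                   problem = character(), class = character())
  } else {
    out
  }
}

assert_valid_corpus <- function(corpus) {
  issues <- validate_corpus(corpus)
  if (nrow(issues) > 0) {
    msgs <- utils::head(
      sprintf("%s[%s] %s: %s", issues$table, issues$id, issues$field,
              issues$problem),
      20
    )
    cls <- if (any(issues$class == "integrity")) "eparmeta_error_integrity"
           else "eparmeta_error_value"
    abort(
      c(sprintf("Corpus fails validation (%d problem%s):", nrow(issues),
                if (nrow(issues) == 1) "" else "s"),
        setNames(msgs, rep("x", length(msgs)))),
      class = cls, issues = issues
    )
  }
  invisible(corpus)
}

sort_corpus <- function(corpus) {
  corpus$approvals <- dplyr::arrange(corpus$approvals, .data$approval_id)
  corpus$trials <- dplyr::arrange(corpus$trials, .data$approval_id,
                                  .data$trial_id)
  corpus$arms <- dplyr::arrange(corpus$arms, .data$trial_id, .data$arm_id)
  corpus$comparisons <- dplyr::arrange(
    corpus$comparisons, .data$trial_id, .data$investigational_arm_id,
    .data$comparator_arm_id
  )
  corpus
}

readr_type <- function(type) {
  switch(type, chr = readr::col_character(), int = readr::col_integer(),
         dbl = readr::col_double(), lgl = readr::col_logical())
}

#' Read a corpus from disk
#'
#' @param path Directory containing the four-table CSV bundle
#'   (`approvals.csv`, `trials.csv`, `arms.csv`, `comparisons.csv` plus a
#'   `schema.json` marker), or a single `.json` file.
#' @param format `"csv_bundle"` or `"json"`; guessed from `path` when `NULL`.
#' @return A validated [epar_corpus()].
#' @export
read_corpus <- function(path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv_bundle")
  corpus <- switch(format,
    csv_bundle = read_corpus_csv(path),
    json = read_corpus_json(path),
    stop_value("`format` must be \"csv_bundle\" or \"json\".")
  )
  assert_valid_corpus(corpus)
  corpus
}

read_corpus_csv <- function(path) {
  if (!dir.exists(path)) stop_io(paste0("No such directory: ", path))
  meta_path <- file.path(path, "schema.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    check_schema_version(meta$schema_version)
  }
  sch <- corpus_schema()
  tabs <- purrr::imap(sch, function(spec, name) {
    f <- file.path(path, paste0(name, ".csv"))
    if (!file.exists(f)) stop_io(paste0("Missing bundle file: ", f))
    header <- names(readr::read_csv(f, n_max = 0, show_col_types = FALSE))
    missing_cols <- setdiff(names(spec), header)
    if (length(missing_cols) > 0) {
      stop_schema(paste0(name, ".csv is missing required column(s): ",
                         paste(missing_cols, collapse = ", ")))
    }
    readr::read_csv(f, col_types = do.call(
      readr::cols, lapply(spec, readr_type)
    ), na = c(""), progress = FALSE)
  })
  epar_corpus(tabs$approvals, tabs$trials, tabs$arms, tabs$comparisons)
}

check_schema_version <- function(version) {
  if (is.null(version) || !identical(as.character(version),
                                     CORPUS_SCHEMA_VERSION)) {
    stop_schema(paste0(
      "Unknown corpus schema version '", version %||% "<none>",
      "'; this package reads version ", CORPUS_SCHEMA_VERSION, "."
    ))
  }
}

read_corpus_json <- function(path) {
  if (!file.exists(path)) stop_io(paste0("No such file: ", path))
  doc <- jsonlite::read_json(path)
  check_schema_version(doc$schema_version)
  sch <- corpus_schema()
  row_from <- function(rec, spec, drop) {
    rec <- rec[setdiff(names(rec), drop)]
    vals <- lapply(names(spec), function(col) {
      x <- rec[[col]]
      if (is.null(x)) NA else x
    })
    tibble::as_tibble(setNames(vals, names(spec)))
  }
  approvals <- list(); trials <- list(); arms <- list(); comps <- list()
  for (ap in doc$approvals) {
    approvals[[length(approvals) + 1]] <-
      row_from(ap, sch$approvals, "trials")
    for (tr in ap$trials) {
      row <- row_from(tr, sch$trials, c("arms", "comparisons"))
      row$approval_id <- ap$approval_id
      trials[[length(trials) + 1]] <- row
      for (arm in tr$arms) {
        arow <- row_from(arm, sch$arms, character())
        arow$trial_id <- tr$trial_id
        arms[[length(arms) + 1]] <- arow
      }
      for (cm in tr$comparisons) {
        crow <- row_from(cm, sch$comparisons, character())
        crow$trial_id <- tr$trial_id
        comps[[length(comps) + 1]] <- crow
      }
    }
  }
  bind_or_empty <- function(rows, spec) {
    if (length(rows) == 0) {
      tibble::as_tibble(lapply(spec, empty_col))
    } else {
      dplyr::bind_rows(rows)
    }
  }
  epar_corpus(bind_or_empty(approvals, sch$approvals),
              bind_or_empty(trials, sch$trials),
              bind_or_empty(arms, sch$arms),
              bind_or_empty(comps, sch$comparisons))
}

#' Write a corpus to disk
#'
#' Output is byte-stable for a fixed corpus: records are sorted by id and
#' field order follows [corpus_schema()], so writing the same corpus twice
#' yields identical files.
#'
#' @inheritParams read_corpus
#' @param corpus A valid [epar_corpus()].
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = NULL) {
  assert_valid_corpus(corpus)
  format <- format %||%
    (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv_bundle")
  corpus <- sort_corpus(corpus)
  switch(format,
    csv_bundle = write_corpus_csv(corpus, path),
    json = write_corpus_json(corpus, path),
    stop_value("`format` must be \"csv_bundle\" or \"json\".")
  )
  invisible(path)
}

write_corpus_csv <- function(corpus, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop_io(paste0("Cannot create directory: ", path))
  jsonlite::write_json(
    list(schema_version = CORPUS_SCHEMA_VERSION),
    file.path(path, "schema.json"), auto_unbox = TRUE
  )
  for (name in names(corpus_schema())) {
    readr::write_csv(corpus[[name]], file.path(path, paste0(name, ".csv")),
                     na = "", progress = FALSE)
  }
}

write_corpus_json <- function(corpus, path) {
  strip_na <- function(row) {
    row <- as.list(row)
    row[!vapply(row, function(x) length(x) == 1 && is.na(x), logical(1))]
  }
  doc <- list(
    schema_version = CORPUS_SCHEMA_VERSION,
    approvals = purrr::pmap(corpus$approvals, function(...) {
      ap <- strip_na(list(...))
      tr_rows <- dplyr::filter(corpus$trials,
                               .data$approval_id == ap$approval_id)
      ap$trials <- purrr::pmap(tr_rows, function(...) {
        tr <- strip_na(list(...))
        tr$approval_id <- NULL
        arm_rows <- dplyr::filter(corpus$arms, .data$trial_id == tr$trial_id)
        cmp_rows <- dplyr::filter(corpus$comparisons,
                                  .data$trial_id == tr$trial_id)
        tr$arms <- purrr::pmap(arm_rows, function(...) {
          a <- strip_na(list(...)); a$trial_id <- NULL; a
        })
        tr$comparisons <- purrr::pmap(cmp_rows, function(...) {
          cm <- strip_na(list(...)); cm$trial_id <- NULL; cm
        })
        tr
      })
      ap
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}
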