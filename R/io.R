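#' @importFrom utils read.csv write.csv modifyList
NULL

log_stage <- function(fmt, ...) message(sprintf(paste0("[scrinhf] ", fmt), ...))

#' Cohort CSV column schema
#'
#' One row per column of the cohort file: name, type (`integer`,
#' `numeric`, `character`), whether it is required, and the valid range
#' for bounded integers. The missing-value sentinel is `"NA"`. Optional
#' columns (`latent_trait`, `planned_procedures`, ...) are carried
#' through when present.
#'
#' @return Data frame describing the schema.
#' @export
cohort_schema <- function() {
  items <- data.frame(
    name = pih_item_names(), type = "integer", required = TRUE,
    min = 0, max = 8
  )
  rest <- data.frame(
    name = c("id", "age", "sex", "comorbidity_count",
             "sf_ma", "sf_mx", "sf_mse",
             "unplanned_cv_admissions", "hf_admissions", "non_cv_admissions",
             "planned_procedures", "died", "ltfu", "follow_up_months",
             "booked_appointments", "attended_appointments",
             "dose_reduced", "ceased",
             "egfr_baseline", "egfr_followup", "scr_baseline", "scr_followup",
             "latent_trait"),
    type = c("integer", "integer", "character", "integer",
             "integer", "integer", "integer",
             "integer", "integer", "integer",
             "integer", "integer", "integer", "integer",
             "integer", "integer",
             "integer", "integer",
             "numeric", "numeric", "numeric", "numeric",
             "numeric"),
    required = c(TRUE, TRUE, TRUE, TRUE,
                 TRUE, TRUE, TRUE,
                 TRUE, TRUE, TRUE,
                 FALSE, TRUE, TRUE, FALSE,
                 TRUE, TRUE,
                 TRUE, TRUE,
                 TRUE, TRUE, TRUE, TRUE,
                 FALSE),
    min = c(1, 18, NA, 0,  0, 0, 0,  0, 0, 0,  0, 0, 0, 0,  0, 0,  0, 0,
            NA, NA, NA, NA, NA),
    max = c(NA, 120, NA, NA,  1, 1, 1,  NA, NA, NA,  NA, 1, 1, 12,  NA, NA,
            1, 1,  NA, NA, NA, NA, NA)
  )
  rbind(rest[1:4, ], items, rest[-(1:4), ])
}

#' Read and validate a cohort CSV
#'
#' Reads the UTF-8, comma-separated cohort file, checks it against
#' [cohort_schema()], and reports every row-level violation together
#' (row and column named) rather than stopping at the first.
#'
#' @param path Path to the cohort CSV.
#' @return Validated cohort data frame. An empty data section yields an
#'   empty cohort with a warning.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  cohort <- read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  schema <- cohort_schema()
  required <- schema$name[schema$required]
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    stop("cohort file missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(cohort) == 0) {
    warning("cohort file has no data rows")
    return(cohort)
  }
  errors <- character(0)
  present <- schema[schema$name %in% names(cohort), ]
  for (i in seq_len(nrow(present))) {
    col <- present$name[i]
    v <- cohort[[col]]
    bad <- rep(FALSE, length(v))
    if (present$type[i] %in% c("integer", "numeric")) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- bad | is.na(vn)
      if (present$type[i] == "integer") bad <- bad | (!is.na(vn) & vn != round(vn))
      if (!is.na(present$min[i])) bad <- bad | (!is.na(vn) & vn < present$min[i])
      if (!is.na(present$max[i])) bad <- bad | (!is.na(vn) & vn > present$max[i])
    } else if (col == "sex") {
      bad <- !v %in% c("male", "female")
    }
    for (r in which(bad)) {
      errors <- c(errors, sprintf("row %d, %s: invalid value '%s'", r, col, v[r]))
    }
  }
  bad_att <- which(cohort$attended_appointments > cohort$booked_appointments)
  for (r in bad_att) {
    errors <- c(errors, sprintf("row %d, attended_appointments: exceeds booked_appointments", r))
  }
  if (length(errors)) {
    stop("cohort file failed validation:\n  ",
         paste(utils::head(errors, 20), collapse = "\n  "),
         if (length(errors) > 20) sprintf("\n  ... and %d more", length(errors) - 20))
  }
  int_cols <- present$name[present$type == "integer"]
  for (col in int_cols) cohort[[col]] <- as.integer(cohort[[col]])
  log_stage("read %d patient records from %s", nrow(cohort), path)
  cohort
}

#' Write a cohort CSV
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "NA")
  log_stage("wrote %d patient records to %s", nrow(cohort), path)
  invisible(path)
}

#' Default analysis configuration
#'
#' Collects every tunable analysis decision in one list so all of them
#' can be overridden from a YAML file without code change: the banding
#' schemes, the short-form pass-rule variant, the worsening-renal-
#' function thresholds, the chi-squared continuity-correction flag, the
#' concordance endpoint, and the generator parameters.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    sf_mapping = "composite",
    wrf = list(egfr_drop = 0.25, scr_rise = 0.25),
    chi2_continuity_correction = FALSE,
    concordance_endpoint = 0.80,
    alpha = 0.01,
    banding_schemes_file = system.file("extdata", "banding_schemes.yaml",
                                       package = "scrinhf"),
    generator = unclass(cohort_params())
  )
}

#' Read a configuration file, merged over the defaults
#'
#' @param path Path to a YAML configuration file; `NULL` returns the
#'   defaults unchanged.
#' @return Configuration list as from [default_config()].
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- modifyList(cfg, user)
  }
  cfg
}

#' Run the full pipeline and assemble the study-style report
#'
#' Scores the cohort, bands every long-form scale, cross-tabulates the
#' short form against the long form, computes concordance against the
#' primary endpoint, summarises 12-month outcomes per category, and
#' tests the good-vs-poor readmission contrast with the uncorrected
#' chi-squared (1 df) and the enumeration exact test.
#'
#' @param cohort Cohort data frame.
#' @param sf_source `"nurse"` or `"derived"` short-form scores.
#' @param config Configuration list ([read_config()]).
#' @return An `sm_report` with a banding/distribution table (one block
#'   per scale), the outcome summary, the concordance report and the
#'   contingency test results.
#' @export
render_report <- function(cohort, sf_source = c("nurse", "derived"),
                          config = default_config()) {
  sf_source <- match.arg(sf_source)
  if (!is.data.frame(cohort) || nrow(cohort) == 0) stop("empty cohort")
  n <- nrow(cohort)
  log_stage("scoring %d records (%s short-form scores)", n, sf_source)
  schemes <- banding_schemes(config$banding_schemes_file)
  scores <- score_pih(cohort)
  lf_cats <- categorize_lf(scores, schemes)
  sf_cat <- cohort_sf_category(cohort, sf_source)

  scales <- c(names(LF_SCALE_BY_COLUMN), "SF")
  banding <- do.call(rbind, lapply(scales, function(sc) {
    if (sc == "SF") {
      cat_counts <- as.integer(table(sf_cat))
      vals <- category_code(sf_cat)
    } else {
      cat_counts <- as.integer(table(lf_cats[[sc]]))
      vals <- scores[[sc]]
    }
    data.frame(
      scale = sc, category = SM_LEVELS, count = cat_counts,
      pct = round(100 * cat_counts / n, 1),
      mean = round(mean(vals), 2), sd = round(sd(vals), 2),
      min = min(vals), max = max(vals)
    )
  }))
  log_stage("assigned categories on %d scales", length(scales))

  tab <- sf_lf_crosstab(sf_cat, lf_cats$lf_category)
  conc <- concordance_proportion(tab, endpoint = config$concordance_endpoint)
  mace <- mace_summary(cohort, sf_source = sf_source)

  event <- readmission_flag(cohort$unplanned_cv_admissions,
                            cohort$hf_admissions, cohort$died)
  good <- sf_cat == "good"; poor <- sf_cat == "poor"
  contingency <- NULL; chi2 <- NULL; exact_p <- NA_real_
  if (any(good) && any(poor)) {
    contingency <- contingency_2x2(sum(event[good]), sum(!event[good]),
                                   sum(event[poor]), sum(!event[poor]))
    exact_p <- exact_test_2x2(contingency)
    chi2 <- tryCatch(
      pearson_chi2_2x2(contingency,
                       correct = isTRUE(config$chi2_continuity_correction)),
      error = function(e) NULL)
    log_stage("good-vs-poor readmission contrast: %d vs %d events",
              contingency[1, 1], contingency[2, 1])
  }

  structure(
    list(n = n, sf_source = sf_source, banding_table = banding,
         crosstab = tab, concordance = conc, mace = mace,
         contingency = contingency, chi2 = chi2, exact_p = exact_p,
         alpha = config$alpha),
    class = "sm_report"
  )
}

#' @export
print.sm_report <- function(x, ...) {
  cat(sprintf("Self-management scoring report (n = %d, %s short-form scores)\n\n",
              x$n, x$sf_source))
  cat("Category distribution per scale:\n")
  print(x$banding_table, row.names = FALSE)
  cat("\n")
  print(x$crosstab)
  cat("\n")
  print(x$concordance)
  cat("\n")
  print(x$mace)
  if (!is.null(x$chi2)) {
    cat(sprintf(
      "\nGood-vs-poor readmission composite: chi-squared = %.3f (1 df), p = %.4g %s alpha = %.2g; exact p = %.4g\n",
      x$chi2$statistic, x$chi2$p_value,
      ifelse(x$chi2$p_value < x$alpha, "<", ">="), x$alpha, x$exact_p))
  }
  invisible(x)
}

#' Write a report's tables to CSV and text
#'
#' @param report An `sm_report` ([render_report()]).
#' @param dir Output directory (created if absent).
#' @return Character vector of file paths written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "sm_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    banding = file.path(dir, "banding_distribution.csv"),
    crosstab = file.path(dir, "sf_lf_crosstab.csv"),
    outcomes = file.path(dir, "outcomes_by_category.csv"),
    summary = file.path(dir, "report.txt")
  )
  write.csv(report$banding_table, paths[["banding"]], row.names = FALSE)
  write.csv(as.data.frame.matrix(report$crosstab$counts), paths[["crosstab"]])
  write.csv(report$mace$per_category, paths[["outcomes"]], row.names = FALSE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, paths[["summary"]])
  log_stage("report written to %s", dir)
  invisible(paths)
}
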