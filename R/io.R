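# Tabular interchange and configuration.
#
# CSV (UTF-8, header row, "." decimal) is the sole tabular format; units are
# encoded in column names (e.g. total_25ohd_ng_ml) so they cannot silently
# drift. YAML carries the pipeline configuration.

# canonical cohort schema: name -> storage type
cohort_schema <- function() {
  c(id = "character", sex = "character", age_yr = "numeric",
    season = "character", pubertal = "logical",
    height_z = "numeric", weight_z = "numeric", bmi_z = "numeric",
    diplotype = "character",
    total_25ohd_ng_ml = "numeric", d24_25ohd3_ng_ml = "numeric",
    vdbp_ug_ml = "numeric", albumin_g_dl = "numeric",
    measured_free_pg_ml = "numeric", ipth_pg_ml = "numeric",
    ca_mg_dl = "numeric", p_mg_dl = "numeric", alp_iu_l = "numeric",
    vitd_intake_iu_day = "numeric", ca_intake_mg_day = "numeric",
    daylight_hr_wk = "numeric",
    activity_days_wk = "numeric", activity_min_day = "numeric",
    fm_z = "numeric", lm_z = "numeric",
    bmc_tb_g = "numeric", bmd_tb_g_cm2 = "numeric", bmd_ls_g_cm2 = "numeric",
    bmc_trunk_g = "numeric", bmc_upper_g = "numeric", bmc_lower_g = "numeric",
    area_trunk_cm2 = "numeric", area_upper_cm2 = "numeric",
    area_lower_cm2 = "numeric")
}

.ANALYTE_COLS <- c("total_25ohd_ng_ml", "d24_25ohd3_ng_ml", "vdbp_ug_ml",
                   "albumin_g_dl", "measured_free_pg_ml", "ipth_pg_ml",
                   "ca_mg_dl", "p_mg_dl", "alp_iu_l")

#' Read a cohort CSV
#'
#' Reads and validates a cohort table in the canonical schema (units encoded
#' in column names). Rows failing validation (negative analytes, unknown
#' season or diplotype) are dropped; their line numbers and reasons are
#' reported in a warning and attached as the `"rejected"` attribute. Unknown
#' extra columns are preserved.
#'
#' @param path CSV file path.
#' @return A typed cohort data.frame (possibly with zero rows).
#' @export
read_cohort <- function(path) {
  schema <- cohort_schema()
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(names(schema), names(raw))
  if (length(missing)) {
    stop("cohort file lacks required columns: ", paste(missing, collapse = ", "))
  }
  for (nm in names(schema)) {
    raw[[nm]] <- switch(schema[[nm]],
                        character = as.character(raw[[nm]]),
                        logical = as.logical(raw[[nm]]),
                        numeric = as.numeric(raw[[nm]]))
  }
  if (!nrow(raw)) return(raw)

  problems <- character(0)
  bad <- rep(FALSE, nrow(raw))
  for (col in .ANALYTE_COLS) {
    neg <- !is.na(raw[[col]]) & raw[[col]] < 0
    if (any(neg)) {
      problems <- c(problems, sprintf("line %d: negative %s (%g)",
                                      which(neg) + 1L, col, raw[[col]][neg]))
      bad <- bad | neg
    }
  }
  bad_season <- !is.na(raw$season) & !raw$season %in% c("summer", "winter")
  if (any(bad_season)) {
    problems <- c(problems, sprintf("line %d: unknown season '%s'",
                                    which(bad_season) + 1L,
                                    raw$season[bad_season]))
    bad <- bad | bad_season
  }
  dip_ok <- vapply(raw$diplotype, function(d) {
    is.na(d) || !inherits(try(normalize_diplotype(d), silent = TRUE), "try-error")
  }, logical(1))
  if (any(!dip_ok)) {
    problems <- c(problems, sprintf("line %d: invalid diplotype '%s'",
                                    which(!dip_ok) + 1L, raw$diplotype[!dip_ok]))
    bad <- bad | !dip_ok
  }
  if (length(problems)) {
    warning("rejected ", sum(bad), " row(s):\n  ",
            paste(problems, collapse = "\n  "))
  }
  out <- raw[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out$diplotype[!is.na(out$diplotype)] <-
    normalize_diplotype(out$diplotype[!is.na(out$diplotype)])
  attr(out, "rejected") <- problems
  out
}

#' Write a cohort CSV
#'
#' Deterministic writer: the same table always produces byte-identical
#' output (full precision, no row names, no timestamps).
#'
#' @param cohort A cohort data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Write an analysis report to a directory
#'
#' Emits one CSV per report table plus a `summary.md` overview. Output is
#' deterministic: re-running on identical input overwrites byte-identically.
#'
#' @param report A `vitd_report` from [run_table_suite()].
#' @param dir Output directory (created if absent).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "vitd_report")) stop("not a vitd_report object")
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  tables <- c("comparisons", "correlations", "isoform_kw",
              "isoform_pairwise", "interactions", "regressions")
  files <- character(0)
  for (tb in tables) {
    df <- report[[tb]]
    if (is.null(df)) next
    f <- file.path(dir, paste0(tb, ".csv"))
    utils::write.csv(df, f, row.names = FALSE, na = "")
    files <- c(files, f)
  }
  summary_file <- file.path(dir, "summary.md")
  lines <- c("# Analysis report",
             "",
             sprintf("- subjects analyzed: %d", report$meta$n),
             sprintf("- metabolites: %s",
                     paste(report$meta$metabolites, collapse = ", ")),
             sprintf("- tables: %s",
                     paste(basename(files), collapse = ", ")))
  writeLines(lines, summary_file)
  invisible(c(files, summary_file))
}

#' Default pipeline configuration
#'
#' Aggregates the binding block and the clinical thresholds (deficiency
#' cut-off, BMI percentile boundaries, activity definition, VIF limit,
#' Bonferroni family size) in one serializable list.
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    binding = default_binding_config(),
    thresholds = list(deficiency_ng_ml = 20,
                      bmi_overweight_pct = 85, bmi_obese_pct = 95,
                      activity_min_per_day = 60, activity_days_per_week = 3,
                      vif = 3, isoform_groups = 6),
    seed = 1
  )
}

#' Read / write a pipeline configuration (YAML)
#'
#' Configurations round-trip unchanged through serialization.
#'
#' @param path YAML file path.
#' @return `read_config()`: the configuration list. `write_config()`:
#'   `path`, invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  thr <- unlist(cfg$thresholds)
  if (any(thr <= 0)) stop("all configured thresholds must be positive")
  cfg
}

#' @rdname read_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}
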