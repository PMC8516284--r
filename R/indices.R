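# Per-subject derived indices: vitamin D metabolite ratio, deficiency flag,
# DXA Z-scores, BMI / intake / activity categories, and the panel derivation
# that applies the constant and diplotype-specific binding schemes to a
# cohort table.

#' Vitamin D metabolite ratio (x100)
#'
#' The VMR is the 24,25-dihydroxyvitamin D3 level divided by the total 25OHD
#' level, conventionally reported multiplied by 100.
#'
#' @param d24_ng_ml 24,25(OH)2D3 (ng/mL).
#' @param total_ng_ml Total 25OHD (ng/mL).
#' @return `100 * d24 / total`; `NA` (with a warning) where total is zero.
#' @export
#' @examples
#' vmr(1.1, 19.8)  # 5.6 at one decimal
vmr <- function(d24_ng_ml, total_ng_ml) {
  out <- 100 * d24_ng_ml / total_ng_ml
  zero <- !is.na(total_ng_ml) & total_ng_ml == 0
  if (any(zero)) {
    warning("VMR undefined where total 25OHD is zero; returning NA")
    out[zero] <- NA_real_
  }
  out
}

#' Vitamin D deficiency classification
#'
#' Deficiency is a total 25OHD concentration strictly below the threshold
#' (default 20 ng/mL).
#'
#' @param total_ng_ml Total 25OHD (ng/mL).
#' @param threshold_ng_ml Deficiency cut-off (ng/mL).
#' @return Logical vector.
#' @export
classify_deficiency <- function(total_ng_ml, threshold_ng_ml = 20) {
  total_ng_ml < threshold_ng_ml
}

#' Z-score against a matched reference
#'
#' `(measured - reference mean) / reference SD`.
#'
#' @param x Measured value.
#' @param ref_mean,ref_sd Age/sex-matched reference mean and SD (`ref_sd > 0`).
#' @return Numeric Z-score.
#' @export
z_score <- function(x, ref_mean, ref_sd) {
  if (any(ref_sd <= 0, na.rm = TRUE)) stop("reference SD must be > 0")
  (x - ref_mean) / ref_sd
}

#' BMI category from percentile
#'
#' Normal weight below the 85th percentile, overweight from the 85th up to
#' (but not including) the 95th, obese at or above the 95th.
#'
#' @param percentile BMI percentile in `[0, 100]`.
#' @return Factor with levels `normal`, `overweight`, `obese`.
#' @export
#' @examples
#' classify_bmi(c(50, 85, 95))
classify_bmi <- function(percentile) {
  if (any(percentile < 0 | percentile > 100, na.rm = TRUE)) {
    stop("BMI percentile must lie in [0, 100]")
  }
  cut(percentile, breaks = c(-Inf, 85, 95, Inf), right = FALSE,
      labels = c("normal", "overweight", "obese"))
}

#' BMI percentile from a BMI Z-score
#'
#' When only the Z-score is available the percentile is obtained through the
#' normal CDF.
#'
#' @param bmi_z BMI Z-score.
#' @return Percentile in `[0, 100]`.
#' @export
bmi_percentile_from_z <- function(bmi_z) 100 * stats::pnorm(bmi_z)

#' Daily recommended intake (DRI) adequacy
#'
#' Vitamin D: 200 IU/day through age 11 and 400 IU/day for ages 12-18.
#' Calcium: 700 mg/day at 6-8 y, 800 mg/day at 9-11 y, and at 12-14 y
#' 1,000 mg/day for boys and 900 mg/day for girls. Ages are floored to whole
#' years before banding; for calcium, age 5 maps to the 6-8 band and ages
#' above 14 map to the 12-14 band (with a warning), since the published
#' bands leave those ages uncovered.
#'
#' @param nutrient `"vitD"` or `"Ca"`.
#' @param intake Intake in IU/day (vitamin D) or mg/day (calcium).
#' @param age_yr Age in years.
#' @param sex `"M"` or `"F"` (needed only for calcium at 12-14 y).
#' @return Logical: intake at or above the band's DRI. `NA` intake gives `NA`.
#' @export
#' @examples
#' intake_meets_dri("vitD", 250, 10)        # TRUE  (200 IU band)
#' intake_meets_dri("vitD", 250, 13)        # FALSE (400 IU band)
#' intake_meets_dri("Ca", 900, 13, "F")     # TRUE  (900 mg band)
intake_meets_dri <- function(nutrient = c("vitD", "Ca"), intake, age_yr, sex = NA) {
  nutrient <- match.arg(nutrient)
  n <- max(length(intake), length(age_yr), length(sex))
  intake <- rep_len(intake, n)
  age_yr <- rep_len(age_yr, n)
  sex <- rep_len(as.character(sex), n)
  yrs <- floor(age_yr)
  if (any(yrs < 0 | yrs > 18, na.rm = TRUE)) {
    stop("age outside the covered DRI bands (0-18 y for vitamin D, 5-18 y for calcium)")
  }
  dri <- if (nutrient == "vitD") {
    ifelse(yrs <= 11, 200, 400)
  } else {
    if (any(yrs < 5, na.rm = TRUE)) {
      stop("calcium DRI bands do not cover ages below 5 y")
    }
    if (any(yrs > 14, na.rm = TRUE)) {
      warning("ages above 14 y mapped to the 12-14 y calcium band")
    }
    ifelse(yrs <= 8, 700,
           ifelse(yrs <= 11, 800,
                  ifelse(sex == "F", 900, 1000)))
  }
  intake >= dri
}

#' Regular physical activity flag
#'
#' Moderate-to-vigorous activity for at least 60 min/day on at least 3 days
#' per week.
#'
#' @param days_per_week Days of activity per week.
#' @param min_per_day Minutes per active day.
#' @return Logical vector.
#' @export
regular_activity <- function(days_per_week, min_per_day) {
  days_per_week >= 3 & min_per_day >= 60
}

#' Total-body-less-head BMD
#'
#' Sum of the bone mineral content of the trunk, upper limbs and lower limbs
#' divided by the summed area of the same regions; the head is excluded by
#' construction.
#'
#' @param bmc_by_region Numeric vector of regional BMC (g).
#' @param area_by_region Numeric vector of regional areas (cm^2), all > 0.
#' @return BMD in g/cm^2.
#' @export
#' @examples
#' bmd_tblh(c(100, 50, 150), c(80, 40, 120))  # 1.25
bmd_tblh <- function(bmc_by_region, area_by_region) {
  if (length(bmc_by_region) != length(area_by_region)) {
    stop("regional BMC and area vectors must have equal length")
  }
  if (any(area_by_region <= 0, na.rm = TRUE)) {
    stop("regional areas must be strictly positive")
  }
  sum(bmc_by_region) / sum(area_by_region)
}

#' Derive the per-subject computed panel for a cohort
#'
#' Applies the genotype-constant and diplotype-specific binding schemes, the
#' VMR, the deficiency flag, the BMI/intake/activity categories, and the
#' four bone Z-scores (recomputed from raw DXA values against the reference
#' table). Missing inputs propagate to the derived fields they feed; nothing
#' is imputed.
#'
#' @param cohort A cohort data.frame in the [read_cohort()] schema.
#' @param config A binding configuration block ([default_binding_config()]).
#' @param reference A bone reference table ([load_reference()]).
#' @return The cohort with derived columns appended: `spe_bioa_ng_ml`,
#'   `con_bioa_ng_ml`, `spe_free_pg_ml`, `con_free_pg_ml`, `vmr_x100`,
#'   `deficient`, `bmi_category`, `dri_vitd_met`, `dri_ca_met`,
#'   `regular_activity`, `bmd_tblh_g_cm2`, `bmc_tb_z`, `bmd_tb_z`,
#'   `bmd_ls_z`, `bmd_tblh_z`.
#' @export
derive_panel <- function(cohort, config = default_binding_config(),
                         reference = load_reference()) {
  required <- c("diplotype", "total_25ohd_ng_ml", "d24_25ohd3_ng_ml",
                "vdbp_ug_ml", "albumin_g_dl")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    stop("cohort lacks required columns: ", paste(missing, collapse = ", "))
  }
  out <- cohort
  n <- nrow(cohort)
  if (n == 0L) {
    for (col in c("spe_bioa_ng_ml", "con_bioa_ng_ml", "spe_free_pg_ml",
                  "con_free_pg_ml", "vmr_x100", "bmd_tblh_g_cm2",
                  "bmc_tb_z", "bmd_tb_z", "bmd_ls_z", "bmd_tblh_z")) {
      out[[col]] <- numeric(0)
    }
    out$deficient <- logical(0)
    out$bmi_category <- classify_bmi(numeric(0))
    for (col in c("dri_vitd_met", "dri_ca_met", "regular_activity")) {
      out[[col]] <- logical(0)
    }
    return(out)
  }

  con <- free_25ohd(cohort$total_25ohd_ng_ml, cohort$vdbp_ug_ml,
                    cohort$albumin_g_dl, scheme_from_config(config))
  spe_scheme <- scheme_from_config(config, cohort$diplotype)
  spe <- free_25ohd(cohort$total_25ohd_ng_ml, cohort$vdbp_ug_ml,
                    cohort$albumin_g_dl, spe_scheme)
  if (identical(config$mode, "exact")) {
    con <- free_25ohd_exact(cohort$total_25ohd_ng_ml, cohort$vdbp_ug_ml,
                            cohort$albumin_g_dl, scheme_from_config(config))
    spe <- free_25ohd_exact(cohort$total_25ohd_ng_ml, cohort$vdbp_ug_ml,
                            cohort$albumin_g_dl, spe_scheme)
  }
  out$spe_bioa_ng_ml <- spe$bioavailable_ng_ml
  out$con_bioa_ng_ml <- con$bioavailable_ng_ml
  out$spe_free_pg_ml <- spe$free_pg_ml
  out$con_free_pg_ml <- con$free_pg_ml

  out$vmr_x100 <- vmr(cohort$d24_25ohd3_ng_ml, cohort$total_25ohd_ng_ml)
  out$deficient <- classify_deficiency(cohort$total_25ohd_ng_ml)
  out$bmi_category <- classify_bmi(bmi_percentile_from_z(cohort$bmi_z))
  out$dri_vitd_met <- intake_meets_dri("vitD", cohort$vitd_intake_iu_day,
                                       cohort$age_yr, cohort$sex)
  out$dri_ca_met <- intake_meets_dri("Ca", cohort$ca_intake_mg_day,
                                     cohort$age_yr, cohort$sex)
  out$regular_activity <- regular_activity(cohort$activity_days_wk,
                                           cohort$activity_min_day)

  region_bmc <- as.matrix(cohort[c("bmc_trunk_g", "bmc_upper_g", "bmc_lower_g")])
  region_area <- as.matrix(cohort[c("area_trunk_cm2", "area_upper_cm2",
                                    "area_lower_cm2")])
  out$bmd_tblh_g_cm2 <- vapply(seq_len(n), function(i) {
    if (anyNA(region_bmc[i, ]) || anyNA(region_area[i, ])) return(NA_real_)
    bmd_tblh(region_bmc[i, ], region_area[i, ])
  }, numeric(1))

  raw_cols <- c(bmc_tb = "bmc_tb_g", bmd_tb = "bmd_tb_g_cm2",
                bmd_ls = "bmd_ls_g_cm2", bmd_tblh = "bmd_tblh_g_cm2")
  for (m in names(raw_cols)) {
    ref <- ref_lookup(reference, m, cohort$age_yr, cohort$sex)
    out[[paste0(m, "_z")]] <- z_score(out[[raw_cols[[m]]]], ref$mean, ref$sd)
  }
  out
}
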