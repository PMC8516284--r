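# Statistical pipeline: normality-gated two-group comparisons, six-group
# diplotype tests with Bonferroni-corrected pairwise follow-up, Pearson
# correlation tables, BMI-by-metabolite interaction scans, and covariate-
# adjusted regressions with variance-inflation screening.

#' Normality gate with optional log transform
#'
#' Shapiro-Wilk at `alpha`; a skewed, strictly positive variable is
#' ln-transformed and re-tested, and the transform is recorded so downstream
#' tables can report it. For samples above 5000 the test runs on a
#' deterministic evenly-spaced subsample of the sorted values (the test
#' statistic is undefined beyond that size).
#'
#' @param x Numeric vector (at least 3 non-missing, non-constant values).
#' @param alpha Gate significance level.
#' @return A list: `is_normal` (after any transform), `transformed_x`,
#'   `transform_applied` (`"none"` or `"ln"`), `shapiro_p` (raw scale),
#'   `shapiro_p_final`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x_obs <- x[!is.na(x)]
  if (length(x_obs) < 3) stop("normality gate needs at least 3 non-missing values")
  if (stats::sd(x_obs) == 0) stop("normality gate undefined for a constant vector")
  sw <- function(v) {
    if (length(v) > 5000) {
      v <- sort(v)[round(seq(1, length(v), length.out = 5000))]
    }
    stats::shapiro.test(v)$p.value
  }
  p_raw <- sw(x_obs)
  if (p_raw >= alpha) {
    return(list(is_normal = TRUE, transformed_x = x,
                transform_applied = "none", shapiro_p = p_raw,
                shapiro_p_final = p_raw))
  }
  if (all(x_obs > 0)) {
    lx <- log(x)
    p_log <- sw(log(x_obs))
    return(list(is_normal = p_log >= alpha, transformed_x = lx,
                transform_applied = "ln", shapiro_p = p_raw,
                shapiro_p_final = p_log))
  }
  list(is_normal = FALSE, transformed_x = x, transform_applied = "none",
       shapiro_p = p_raw, shapiro_p_final = p_raw)
}

#' Compare a variable between two groups
#'
#' Numeric variables pass through the normality gate: Student's t-test if the
#' (possibly ln-transformed) variable is compatible with normality, otherwise
#' the Mann-Whitney U-test on the raw values. Logical/factor variables are
#' compared with the chi-squared test. All p-values two-sided.
#'
#' @param x Numeric, logical or factor variable.
#' @param group Two-level grouping factor.
#' @param variable Label used in the output.
#' @param alpha Normality-gate level.
#' @return A one-row data.frame: `variable`, `grouping`, `test`, `statistic`,
#'   `p`, `summary_g1`, `summary_g2`, `transform`, `n`.
#' @export
compare_two_groups <- function(x, group, variable = deparse1(substitute(x)),
                               alpha = 0.05) {
  group <- droplevels(factor(group))
  keep <- !is.na(x) & !is.na(group)
  x <- x[keep]; group <- group[keep]
  lv <- levels(group)
  if (length(lv) != 2 || any(table(group) == 0)) {
    stop("exactly two non-empty groups are required")
  }
  grouping <- paste(lv, collapse = " vs ")

  if (is.logical(x) || is.factor(x)) {
    tab <- table(x, group)
    ct <- suppressWarnings(stats::chisq.test(tab))
    pct <- function(g) {
      t1 <- table(x[group == g])
      sprintf("%s", paste(sprintf("%s: %.1f%%", names(t1),
                                  100 * t1 / sum(t1)), collapse = ", "))
    }
    return(data.frame(variable = variable, grouping = grouping,
                      test = "chi-squared", statistic = unname(ct$statistic),
                      p = ct$p.value, summary_g1 = pct(lv[1]),
                      summary_g2 = pct(lv[2]), transform = "none",
                      n = length(x), stringsAsFactors = FALSE))
  }

  gate <- normality_gate(x, alpha)
  if (gate$is_normal) {
    xt <- gate$transformed_x
    tt <- stats::t.test(xt[group == lv[1]], xt[group == lv[2]],
                        var.equal = TRUE)
    test <- "t"; statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- stats::wilcox.test(x[group == lv[1]], x[group == lv[2]],
                             exact = FALSE, correct = TRUE)
    test <- "Mann-Whitney"; statistic <- unname(wt$statistic); p <- wt$p.value
  }
  msd <- function(g) sprintf("%.2f ± %.2f", mean(x[group == g]),
                             stats::sd(x[group == g]))
  data.frame(variable = variable, grouping = grouping, test = test,
             statistic = statistic, p = p,
             summary_g1 = msd(lv[1]), summary_g2 = msd(lv[2]),
             transform = gate$transform_applied, n = length(x),
             stringsAsFactors = FALSE)
}

#' Bonferroni-corrected pairwise significance level
#'
#' For `k` groups there are `choose(k, 2)` pairwise comparisons; with six Gc
#' diplotypes this gives `0.05 / 15 = 0.0033` (4 dp).
#'
#' @param k Number of groups.
#' @param alpha Family-wise level.
#' @return Corrected per-comparison threshold.
#' @export
#' @examples
#' bonferroni_alpha(6)  # 0.003333...
bonferroni_alpha <- function(k = 6, alpha = 0.05) alpha / choose(k, 2)

#' Compare a variable across the six Gc diplotype groups
#'
#' Kruskal-Wallis omnibus test over the six diplotypes, followed by all 15
#' pairwise Mann-Whitney tests flagged at the Bonferroni-corrected threshold
#' `0.05 / 15`.
#'
#' @param x Numeric variable.
#' @param diplotype Diplotype labels (any allele order).
#' @param alpha Family-wise level for the pairwise correction.
#' @param min_per_group Minimum group size required.
#' @return A list: `kw_p`, `kw_statistic`, `alpha_pairwise`, and `pairwise`
#'   (data.frame with `group1`, `group2`, `p`, `significant`, `n1`, `n2`).
#' @export
compare_isoform_groups <- function(x, diplotype, alpha = 0.05,
                                   min_per_group = 2) {
  keep <- !is.na(x) & !is.na(diplotype)
  x <- x[keep]
  dip <- normalize_diplotype(diplotype[keep])
  groups <- gc_diplotypes()
  counts <- table(factor(dip, levels = groups))
  short <- names(counts)[counts < min_per_group]
  if (length(short)) {
    stop("diplotype groups missing or too small (< ", min_per_group, "): ",
         paste(short, collapse = ", "))
  }
  kw <- stats::kruskal.test(x, factor(dip, levels = groups))
  pairs <- utils::combn(groups, 2)
  thr <- bonferroni_alpha(length(groups), alpha)
  pw <- apply(pairs, 2, function(pr) {
    wt <- stats::wilcox.test(x[dip == pr[1]], x[dip == pr[2]],
                             exact = FALSE, correct = TRUE)
    wt$p.value
  })
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         p = pw, significant = pw < thr,
                         n1 = as.integer(counts[pairs[1, ]]),
                         n2 = as.integer(counts[pairs[2, ]]),
                         stringsAsFactors = FALSE)
  list(kw_p = kw$p.value, kw_statistic = unname(kw$statistic),
       alpha_pairwise = thr, pairwise = pairwise)
}

#' Pearson correlation table
#'
#' Pairwise-complete Pearson correlations of each clinical variable with
#' each metabolite, with per-variable ln transforms applied where requested.
#'
#' @param data A data.frame.
#' @param variables Clinical/biochemical column names (rows of the table).
#' @param metabolites Metabolite column names (columns of the table).
#' @param transform Character vector of column names to ln-transform
#'   (non-positive values become `NA` before transforming).
#' @return A long data.frame: `variable`, `metabolite`, `r`, `p`, `n`.
#' @export
correlation_table <- function(data, variables, metabolites,
                              transform = character()) {
  get_col <- function(nm) {
    v <- data[[nm]]
    if (is.null(v)) stop("column not found: ", nm)
    if (nm %in% transform) {
      v <- ifelse(!is.na(v) & v > 0, v, NA_real_)
      v <- log(v)
    }
    v
  }
  rows <- lapply(variables, function(vn) {
    v <- get_col(vn)
    do.call(rbind, lapply(metabolites, function(mn) {
      m <- get_col(mn)
      ok <- stats::complete.cases(v, m)
      if (sum(ok) < 3) {
        return(data.frame(variable = vn, metabolite = mn, r = NA_real_,
                          p = NA_real_, n = sum(ok), stringsAsFactors = FALSE))
      }
      ct <- stats::cor.test(v[ok], m[ok], method = "pearson")
      data.frame(variable = vn, metabolite = mn, r = unname(ct$estimate),
                 p = ct$p.value, n = sum(ok), stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

.bmi_binary <- function(bmi_category) {
  factor(ifelse(as.character(bmi_category) == "normal", "normal",
                "overweight_obese"),
         levels = c("normal", "overweight_obese"))
}

#' BMI-category-by-metabolite interaction scan
#'
#' Fits `outcome ~ metabolite * BMI_group + covariates` with BMI as a binary
#' normal vs overweight-or-obese indicator and returns the p-value of the
#' product term: a small p indicates the metabolite's slope on the bone
#' outcome differs across BMI groups.
#'
#' @param data A derived-panel data.frame (needs `bmi_category`).
#' @param outcome,metabolite Column names.
#' @param covariates Adjustment covariate column names.
#' @return A list: `p_interaction`, `beta_interaction`, `n`, `model`.
#' @export
interaction_scan <- function(data, outcome, metabolite,
                             covariates = c("age_yr", "sex", "fm_z", "lm_z")) {
  cols <- c(outcome, metabolite, "bmi_category", covariates)
  missing <- setdiff(cols, names(data))
  if (length(missing)) stop("columns not found: ", paste(missing, collapse = ", "))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  d$bmi_group <- .bmi_binary(d$bmi_category)
  if (nlevels(droplevels(d$bmi_group)) < 2) {
    stop("both BMI groups (normal and overweight-or-obese) must be present")
  }
  fml <- stats::reformulate(c(paste(metabolite, "*", "bmi_group"), covariates),
                            response = outcome)
  fit <- stats::lm(fml, data = d)
  coefs <- summary(fit)$coefficients
  int_row <- grep(":", rownames(coefs), fixed = TRUE)
  list(p_interaction = coefs[int_row, "Pr(>|t|)"],
       beta_interaction = coefs[int_row, "Estimate"],
       n = nrow(d), model = fit)
}

#' Covariate-adjusted regression with collinearity screening
#'
#' Ordinary least squares of a bone outcome on one vitamin D metabolite,
#' adjusted for age, sex, fat-mass and lean-mass Z-scores (the standard
#' adjustment set), on complete cases. Variance inflation factors are
#' computed for all predictors and flagged when any reaches the threshold.
#'
#' @param data A data.frame.
#' @param outcome,predictor Column names.
#' @param covariates Adjustment covariate column names.
#' @param vif_threshold Collinearity flag threshold (default 3).
#' @return A list of class `vitd_regression`: `outcome`, `predictor`,
#'   `beta`, `se`, `p`, `r_squared`, `ci` (95% for the predictor), `vif`
#'   (named), `vif_flag`, `n`, `model`.
#' @export
adjusted_regression <- function(data, outcome, predictor,
                                covariates = c("age_yr", "sex", "fm_z", "lm_z"),
                                vif_threshold = 3) {
  cols <- c(outcome, predictor, covariates)
  missing <- setdiff(cols, names(data))
  if (length(missing)) stop("columns not found: ", paste(missing, collapse = ", "))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  if (nrow(d) < length(cols) + 2) stop("too few complete cases for the model")
  fml <- stats::reformulate(c(predictor, covariates), response = outcome)
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)
  # the predictor's row (factors expand to dummies; metabolites are numeric)
  row <- which(rownames(sm$coefficients) == predictor)
  if (!length(row)) row <- grep(paste0("^", predictor), rownames(sm$coefficients))[1]
  vifs <- tryCatch(car::vif(fit), error = function(e) NULL)
  if (is.matrix(vifs)) vifs <- stats::setNames(vifs[, 1], rownames(vifs))
  ci <- stats::confint(fit, level = 0.95)[row, ]
  structure(list(outcome = outcome, predictor = predictor,
                 covariates = covariates,
                 beta = sm$coefficients[row, "Estimate"],
                 se = sm$coefficients[row, "Std. Error"],
                 p = sm$coefficients[row, "Pr(>|t|)"],
                 r_squared = sm$r.squared, ci = ci,
                 vif = vifs,
                 vif_flag = !is.null(vifs) && any(vifs >= vif_threshold),
                 n = nrow(d), model = fit),
            class = "vitd_regression")
}

#' @export
print.vitd_regression <- function(x, ...) {
  cat("<vitd_regression> ", x$outcome, " ~ ", x$predictor, " + ",
      paste(x$covariates, collapse = " + "), "\n",
      sprintf("  beta = %.4f (SE %.4f), p = %.4g, R^2 = %.3f, n = %d\n",
              x$beta, x$se, x$p, x$r_squared, x$n),
      if (x$vif_flag) "  WARNING: VIF >= threshold for at least one predictor\n"
      else "", sep = "")
  invisible(x)
}

.METABOLITES <- c("total_25ohd_ng_ml", "spe_bioa_ng_ml", "con_bioa_ng_ml",
                  "spe_free_pg_ml", "con_free_pg_ml", "measured_free_pg_ml",
                  "d24_25ohd3_ng_ml", "vmr_x100", "vdbp_ug_ml")
.BONE_OUTCOMES <- c("bmc_tb_z", "bmd_tb_z", "bmd_ls_z", "bmd_tblh_z")

#' Run the full analysis suite on a derived cohort
#'
#' Orchestrates, in order: group comparisons of every metabolite by sex,
#' season, puberty, BMI group, intake adequacy and activity; Pearson
#' correlations of clinical variables with metabolites; Kruskal-Wallis +
#' Bonferroni pairwise diplotype tests; the BMI-by-metabolite interaction
#' scan over the bone outcomes; and BMI-stratified covariate-adjusted
#' regressions of each bone outcome on each metabolite (plus the deficiency
#' flag). Each cell records the n actually used.
#'
#' @param cohort A cohort with the derived panel appended ([derive_panel()]).
#' @param ln_transform Columns ln-transformed in the correlation table.
#' @return A list of class `vitd_report` with data.frames `comparisons`,
#'   `correlations`, `isoform_kw`, `isoform_pairwise`, `interactions`,
#'   `regressions`, plus `meta`.
#' @export
run_table_suite <- function(cohort,
                            ln_transform = c("total_25ohd_ng_ml",
                                             "ipth_pg_ml")) {
  if (!nrow(cohort)) stop("cannot analyze an empty cohort")
  if (!all(c("con_free_pg_ml", "bmi_category") %in% names(cohort))) {
    stop("derived panel missing; run derive_panel() first")
  }
  mets <- intersect(.METABOLITES, names(cohort))

  groupings <- list(
    sex = factor(cohort$sex),
    season = factor(cohort$season),
    puberty = factor(ifelse(cohort$pubertal, "pubertal", "prepubertal")),
    bmi_group = .bmi_binary(cohort$bmi_category),
    ca_intake_dri = factor(ifelse(cohort$dri_ca_met, "meets", "below")),
    vitd_intake_dri = factor(ifelse(cohort$dri_vitd_met, "meets", "below")),
    activity = factor(ifelse(cohort$regular_activity, "regular", "irregular"))
  )
  comparisons <- do.call(rbind, lapply(names(groupings), function(g) {
    do.call(rbind, lapply(mets, function(m) {
      res <- tryCatch(compare_two_groups(cohort[[m]], groupings[[g]],
                                         variable = m),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      res$grouping <- g
      res
    }))
  }))

  clin_vars <- intersect(c("age_yr", "bmi_z", "vitd_intake_iu_day",
                           "ca_intake_mg_day", "daylight_hr_wk", "ca_mg_dl",
                           "p_mg_dl", "alp_iu_l", "ipth_pg_ml"),
                         names(cohort))
  correlations <- correlation_table(cohort, clin_vars, mets,
                                    transform = intersect(ln_transform,
                                                          names(cohort)))

  iso <- lapply(mets, function(m) {
    tryCatch(compare_isoform_groups(cohort[[m]], cohort$diplotype),
             error = function(e) NULL)
  })
  names(iso) <- mets
  ok <- !vapply(iso, is.null, logical(1))
  isoform_kw <- data.frame(
    metabolite = mets[ok],
    kw_p = vapply(iso[ok], `[[`, numeric(1), "kw_p"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  isoform_pairwise <- do.call(rbind, lapply(mets[ok], function(m) {
    pw <- iso[[m]]$pairwise
    pw$metabolite <- m
    pw
  }))

  interactions <- do.call(rbind, lapply(.BONE_OUTCOMES, function(o) {
    do.call(rbind, lapply(mets, function(m) {
      res <- tryCatch(interaction_scan(cohort, o, m), error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(outcome = o, metabolite = m,
                 p_interaction = res$p_interaction,
                 beta_interaction = res$beta_interaction, n = res$n,
                 stringsAsFactors = FALSE)
    }))
  }))

  cohort$deficient_num <- as.numeric(cohort$deficient)
  predictors <- c("deficient_num", mets)
  strata <- list(normal = cohort$bmi_category == "normal",
                 overweight_obese = cohort$bmi_category != "normal")
  regressions <- do.call(rbind, lapply(names(strata), function(s) {
    d <- cohort[strata[[s]] & !is.na(cohort$bmi_category), , drop = FALSE]
    do.call(rbind, lapply(.BONE_OUTCOMES, function(o) {
      do.call(rbind, lapply(predictors, function(pr) {
        res <- tryCatch(adjusted_regression(d, o, pr),
                        error = function(e) NULL)
        if (is.null(res)) return(NULL)
        data.frame(stratum = s, outcome = o, predictor = pr,
                   beta = res$beta, se = res$se, p = res$p,
                   r_squared = res$r_squared, vif_flag = res$vif_flag,
                   n = res$n, stringsAsFactors = FALSE)
      }))
    }))
  }))

  structure(list(comparisons = comparisons, correlations = correlations,
                 isoform_kw = isoform_kw, isoform_pairwise = isoform_pairwise,
                 interactions = interactions, regressions = regressions,
                 meta = list(n = nrow(cohort), metabolites = mets)),
            class = "vitd_report")
}

#' @export
print.vitd_report <- function(x, ...) {
  cat("<vitd_report> n =", x$meta$n, "\n",
      " comparisons:", nrow(x$comparisons), "rows\n",
      " correlations:", nrow(x$correlations), "rows\n",
      " isoform tests:", nrow(x$isoform_kw), "metabolites\n",
      " interactions:", nrow(x$interactions), "rows\n",
      " regressions:", nrow(x$regressions), "rows\n")
  invisible(x)
}
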