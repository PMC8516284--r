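# Equilibrium free-hormone model for 25-hydroxyvitamin D.
#
# Circulating 25OHD partitions between VDBP (high affinity, ~85-90%),
# albumin (low affinity, ~10-15%) and a free pool (<0.1%). The linear
# (binder-total) model treats both carriers as far from saturation, so
#
#   free fraction = 1 / (1 + K_alb[Alb] + K_dbp[VDBP])
#
# with concentrations in mol/L and affinities in M^-1. Bioavailable 25OHD is
# the free plus albumin-bound pool: BioA = Free * (1 + K_alb[Alb]).
# The exact mass-action solver accounts for binder depletion and serves as
# the validation oracle; under physiologic conditions (ligand << binder) the
# two agree to within ~2%.

.GC_ALLELES <- c("Gc1f", "Gc1s", "Gc2")

#' Canonical Gc diplotype labels
#'
#' The three common VDBP (Gc globulin) alleles, Gc1f, Gc1s and Gc2, form six
#' unordered diplotypes. Labels are returned in decreasing order of mean
#' allele affinity under the default allele table, i.e. from the tightest
#' binder (`Gc1f/Gc1f`) to the weakest (`Gc2/Gc2`).
#'
#' @return Character vector of the six diplotype labels.
#' @export
#' @examples
#' gc_diplotypes()
gc_diplotypes <- function() {
  c("Gc1f/Gc1f", "Gc1f/Gc1s", "Gc1f/Gc2",
    "Gc1s/Gc1s", "Gc1s/Gc2", "Gc2/Gc2")
}

#' Normalize a Gc diplotype label
#'
#' Diplotypes are unordered pairs: `"Gc2/Gc1f"` and `"Gc1f/Gc2"` denote the
#' same genotype. This puts the two alleles in canonical allele order.
#'
#' @param diplotype Character vector of `"allele/allele"` labels.
#' @return Character vector of canonical labels (one of [gc_diplotypes()]).
#' @export
#' @examples
#' normalize_diplotype("Gc2/Gc1f")  # "Gc1f/Gc2"
normalize_diplotype <- function(diplotype) {
  out <- vapply(as.character(diplotype), function(d) {
    if (is.na(d)) return(NA_character_)
    alleles <- strsplit(d, "/", fixed = TRUE)[[1]]
    if (length(alleles) != 2L || !all(alleles %in% .GC_ALLELES)) {
      bad <- setdiff(alleles, .GC_ALLELES)
      stop("unknown Gc allele(s) in diplotype '", d, "': ",
           paste(if (length(bad)) bad else d, collapse = ", "), call. = FALSE)
    }
    paste(alleles[order(match(alleles, .GC_ALLELES))], collapse = "/")
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Default allele-specific VDBP affinity constants
#'
#' Association constants (M^-1) of 25OHD for the three common Gc alleles.
#' The literature branch that reports genotype-specific binding gives the
#' Gc1f product the tightest and Gc2 the weakest affinity.
#'
#' @return Named numeric vector over `Gc1f`, `Gc1s`, `Gc2` (M^-1).
#' @export
default_allele_affinity <- function() {
  c(Gc1f = 1.12e9, Gc1s = 0.60e9, Gc2 = 0.36e9)
}

#' Diplotype-averaged VDBP affinity
#'
#' The affinity assigned to a diplotype is the arithmetic mean of its two
#' allele affinities (homozygotes keep the allele value); it is symmetric in
#' allele order.
#'
#' @param diplotype Character vector of diplotype labels (any allele order).
#' @param allele_table Named numeric vector of allele affinities (M^-1)
#'   covering `Gc1f`, `Gc1s`, `Gc2`; defaults to [default_allele_affinity()].
#' @return Numeric vector of affinities (M^-1).
#' @export
#' @examples
#' diplotype_affinity("Gc1f/Gc2")  # mean of 1.12e9 and 0.36e9
diplotype_affinity <- function(diplotype, allele_table = default_allele_affinity()) {
  if (!all(.GC_ALLELES %in% names(allele_table))) {
    stop("allele_table must name all of: ", paste(.GC_ALLELES, collapse = ", "))
  }
  if (any(allele_table[.GC_ALLELES] <= 0)) {
    stop("allele affinities must be strictly positive")
  }
  vapply(as.character(diplotype), function(d) {
    if (is.na(d)) return(NA_real_)
    alleles <- strsplit(normalize_diplotype(d), "/", fixed = TRUE)[[1]]
    mean(allele_table[alleles])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Construct a binding scheme
#'
#' A binding scheme bundles the two association constants and the molar
#' masses that parameterize one free-hormone calculation. The genotype-
#' constant scheme applies one VDBP affinity to everyone; genotype-specific
#' schemes use [diplotype_affinity()] per subject.
#'
#' @param k_dbp VDBP-25OHD association constant (M^-1).
#' @param k_alb Albumin-25OHD association constant (M^-1).
#' @param mw_25ohd,mw_vdbp,mw_albumin Molar masses (g/mol). The VDBP mass
#'   materially shifts absolute free values and is deliberately configurable.
#' @param label Scheme label, e.g. `"constant"` or `"specific:Gc2/Gc2"`.
#' @return An object of class `binding_scheme`.
#' @export
#' @examples
#' binding_scheme()  # genotype-constant defaults
binding_scheme <- function(k_dbp = 0.7e9, k_alb = 6e5,
                           mw_25ohd = 400.64, mw_vdbp = 58000,
                           mw_albumin = 66500, label = "constant") {
  vals <- c(k_dbp = k_dbp, k_alb = k_alb, mw_25ohd = mw_25ohd,
            mw_vdbp = mw_vdbp, mw_albumin = mw_albumin)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all binding-scheme constants must be finite and strictly positive")
  }
  structure(list(k_dbp = k_dbp, k_alb = k_alb, mw_25ohd = mw_25ohd,
                 mw_vdbp = mw_vdbp, mw_albumin = mw_albumin, label = label),
            class = "binding_scheme")
}

#' @export
print.binding_scheme <- function(x, ...) {
  cat("<binding_scheme> ", x$label, "\n",
      "  k_dbp = ", format(x$k_dbp, scientific = TRUE),
      " M^-1, k_alb = ", format(x$k_alb, scientific = TRUE), " M^-1\n",
      "  MW (g/mol): 25OHD ", x$mw_25ohd, ", VDBP ", x$mw_vdbp,
      ", albumin ", x$mw_albumin, "\n", sep = "")
  invisible(x)
}

# native unit -> g/L factors for the three analytes
.UNIT_TO_G_L <- c("25ohd" = 1e-6,   # ng/mL
                  "vdbp" = 1e-3,    # ug/mL
                  "albumin" = 10)   # g/dL

#' Convert an analyte concentration to molar units
#'
#' Analytes are reported in their customary clinical units (total 25OHD in
#' ng/mL, VDBP in ug/mL, albumin in g/dL); the equilibrium formulae need
#' mol/L.
#'
#' @param value Concentration in the analyte's native unit (non-negative).
#' @param analyte One of `"25ohd"`, `"vdbp"`, `"albumin"`.
#' @param scheme A [binding_scheme()] supplying the molar mass.
#' @return Concentration in mol/L.
#' @export
#' @examples
#' to_molar(226.5, "vdbp")    # ~3.9e-6 M
#' to_molar(4.3, "albumin")   # ~6.5e-4 M
to_molar <- function(value, analyte = c("25ohd", "vdbp", "albumin"),
                     scheme = binding_scheme()) {
  analyte <- match.arg(analyte)
  if (any(value < 0, na.rm = TRUE)) {
    stop("negative concentration supplied for ", analyte)
  }
  mw <- switch(analyte, "25ohd" = scheme$mw_25ohd, "vdbp" = scheme$mw_vdbp,
               "albumin" = scheme$mw_albumin)
  value * .UNIT_TO_G_L[[analyte]] / mw
}

.check_panel <- function(total_ng_ml, vdbp_ug_ml, albumin_g_dl) {
  if (any(c(total_ng_ml, vdbp_ug_ml, albumin_g_dl) < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative")
  }
}

#' Free and bioavailable 25OHD (linear binder-total model)
#'
#' Computes the free fraction `1 / (1 + k_alb[Alb] + k_dbp[VDBP])` with total
#' (undepleted) binder concentrations, the standard calculation used when
#' deriving free and bioavailable 25OHD from total 25OHD, VDBP and albumin.
#' Fractions are independent of total in this model. Vectorized over all
#' concentration arguments.
#'
#' @param total_ng_ml Total 25OHD (ng/mL).
#' @param vdbp_ug_ml VDBP (ug/mL).
#' @param albumin_g_dl Albumin (g/dL).
#' @param scheme A [binding_scheme()].
#' @return A data.frame with columns `free_pg_ml`, `bioavailable_ng_ml`,
#'   `frac_dbp`, `frac_alb`, `frac_free` (fractions sum to 1).
#' @export
#' @examples
#' free_25ohd(19.8, 226.5, 4.3)  # free ~6.3 pg/mL, bioavailable ~2.5 ng/mL
free_25ohd <- function(total_ng_ml, vdbp_ug_ml, albumin_g_dl,
                       scheme = binding_scheme()) {
  .check_panel(total_ng_ml, vdbp_ug_ml, albumin_g_dl)
  dbp_m <- to_molar(vdbp_ug_ml, "vdbp", scheme)
  alb_m <- to_molar(albumin_g_dl, "albumin", scheme)
  denom <- 1 + scheme$k_alb * alb_m + scheme$k_dbp * dbp_m
  frac_free <- 1 / denom
  frac_alb <- scheme$k_alb * alb_m / denom
  frac_dbp <- scheme$k_dbp * dbp_m / denom
  free_pg <- total_ng_ml * 1000 * frac_free
  bioa_ng <- bioavailable_25ohd(free_pg, alb_m, scheme$k_alb)
  data.frame(free_pg_ml = free_pg, bioavailable_ng_ml = bioa_ng,
             frac_dbp = frac_dbp, frac_alb = frac_alb, frac_free = frac_free)
}

#' Bioavailable 25OHD from the free concentration
#'
#' Bioavailable 25OHD is the free plus albumin-bound pool:
#' `BioA = Free * (1 + k_alb * [Alb])`, reported in ng/mL.
#'
#' @param free_pg_ml Free 25OHD (pg/mL).
#' @param albumin_molar Albumin concentration (mol/L).
#' @param k_alb Albumin association constant (M^-1).
#' @return Bioavailable 25OHD (ng/mL).
#' @export
bioavailable_25ohd <- function(free_pg_ml, albumin_molar, k_alb) {
  if (any(c(free_pg_ml, albumin_molar, k_alb) < 0, na.rm = TRUE)) {
    stop("inputs must be non-negative")
  }
  free_pg_ml / 1000 * (1 + k_alb * albumin_molar)
}

#' Bound and free fractions of circulating 25OHD
#'
#' Under the linear model the partition is independent of the total:
#' `dbp_bound = k_dbp[VDBP]/D`, `alb_bound = k_alb[Alb]/D`, `free = 1/D`
#' with `D` the shared denominator.
#'
#' @inheritParams free_25ohd
#' @return A data.frame with columns `frac_dbp`, `frac_alb`, `frac_free`.
#' @export
#' @examples
#' bound_fractions(226.5, 4.3)  # ~0.875 / 0.124 / 3.2e-4
bound_fractions <- function(vdbp_ug_ml, albumin_g_dl, scheme = binding_scheme()) {
  res <- free_25ohd(rep(1, length.out = max(length(vdbp_ug_ml), length(albumin_g_dl))),
                    vdbp_ug_ml, albumin_g_dl, scheme)
  res[c("frac_dbp", "frac_alb", "frac_free")]
}

#' Free 25OHD by exact mass-action equilibrium (oracle)
#'
#' Solves the full mass balance with binder depletion,
#' `Total = F * (1 + k_dbp P_dbp/(1 + k_dbp F) + k_alb P_alb/(1 + k_alb F))`,
#' for the free molar concentration `F` by deterministic bisection on
#' `[0, Total]`. The left side is strictly increasing in `F`, so the bracket
#' always holds. Because the linear model overstates available binder, the
#' linear free value is a lower bound on the exact one.
#'
#' @inheritParams free_25ohd
#' @param tol Relative bisection tolerance on `F` (> 0).
#' @return As [free_25ohd()]; fractions here are depletion-corrected.
#' @export
free_25ohd_exact <- function(total_ng_ml, vdbp_ug_ml, albumin_g_dl,
                             scheme = binding_scheme(), tol = 1e-10) {
  .check_panel(total_ng_ml, vdbp_ug_ml, albumin_g_dl)
  stopifnot(tol > 0)
  n <- max(length(total_ng_ml), length(vdbp_ug_ml), length(albumin_g_dl))
  total_ng_ml <- rep_len(total_ng_ml, n)
  vdbp_ug_ml <- rep_len(vdbp_ug_ml, n)
  albumin_g_dl <- rep_len(albumin_g_dl, n)

  t_m <- to_molar(total_ng_ml, "25ohd", scheme)
  p_dbp <- to_molar(vdbp_ug_ml, "vdbp", scheme)
  p_alb <- to_molar(albumin_g_dl, "albumin", scheme)
  kd <- scheme$k_dbp
  ka <- scheme$k_alb

  solve_one <- function(total, pd, pa) {
    if (is.na(total) || is.na(pd) || is.na(pa)) return(NA_real_)
    if (total == 0) return(0)
    balance <- function(f) {
      f * (1 + kd * pd / (1 + kd * f) + ka * pa / (1 + ka * f)) - total
    }
    lo <- 0
    hi <- total
    stopifnot(balance(lo) <= 0, balance(hi) >= 0)
    while ((hi - lo) > tol * total) {
      mid <- (lo + hi) / 2
      if (balance(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  f_m <- mapply(solve_one, t_m, p_dbp, p_alb)

  dbp_bound <- kd * p_dbp * f_m / (1 + kd * f_m)
  alb_bound <- ka * p_alb * f_m / (1 + ka * f_m)
  frac_free <- ifelse(t_m > 0, f_m / t_m, 1)
  frac_dbp <- ifelse(t_m > 0, dbp_bound / t_m, 0)
  frac_alb <- ifelse(t_m > 0, alb_bound / t_m, 0)
  free_pg <- f_m * scheme$mw_25ohd * 1e9
  bioa_ng <- (f_m + alb_bound) * scheme$mw_25ohd * 1e6
  data.frame(free_pg_ml = free_pg, bioavailable_ng_ml = bioa_ng,
             frac_dbp = frac_dbp, frac_alb = frac_alb, frac_free = frac_free)
}

#' Default binding configuration block
#'
#' All affinity constants and molar masses used by the pipeline live in this
#' configuration (they never appear as literals inside operations), so an
#' analysis can swap affinity literatures without touching code.
#'
#' @return A named list: `k_dbp_constant`, `k_alb`, `allele_k_dbp`,
#'   `mw_25ohd`, `mw_vdbp`, `mw_albumin`, `mode` (`"linear"` or `"exact"`).
#' @export
default_binding_config <- function() {
  list(
    k_dbp_constant = 0.7e9,
    k_alb = 6e5,
    allele_k_dbp = as.list(default_allele_affinity()),
    mw_25ohd = 400.64,
    mw_vdbp = 58000,
    mw_albumin = 66500,
    mode = "linear"
  )
}

#' Build binding schemes from a configuration block
#'
#' @param config A list shaped like [default_binding_config()].
#' @param diplotype `NULL` for the genotype-constant scheme, or a diplotype
#'   label for the genotype-specific scheme.
#' @return A [binding_scheme()].
#' @export
scheme_from_config <- function(config = default_binding_config(), diplotype = NULL) {
  if (is.null(diplotype)) {
    binding_scheme(k_dbp = config$k_dbp_constant, k_alb = config$k_alb,
                   mw_25ohd = config$mw_25ohd, mw_vdbp = config$mw_vdbp,
                   mw_albumin = config$mw_albumin, label = "constant")
  } else {
    k <- diplotype_affinity(diplotype, unlist(config$allele_k_dbp))
    binding_scheme(k_dbp = k, k_alb = config$k_alb,
                   mw_25ohd = config$mw_25ohd, mw_vdbp = config$mw_vdbp,
                   mw_albumin = config$mw_albumin,
                   label = paste0("specific:", normalize_diplotype(diplotype)))
  }
}
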