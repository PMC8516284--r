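# Equilibrium binding model: unit conversions, linear free/bioavailable
# calculation, diplotype-specific affinities, and the exact mass-action
# oracle.

test_that("diplotype affinity is the allele mean and order-insensitive", {
  tab <- c(Gc1f = 1.12e9, Gc1s = 0.60e9, Gc2 = 0.36e9)
  expect_equal(diplotype_affinity("Gc1f/Gc1f", tab), 1.12e9)
  expect_equal(diplotype_affinity("Gc1f/Gc2", tab), 0.74e9)
  expect_equal(diplotype_affinity("Gc2/Gc1f", tab),
               diplotype_affinity("Gc1f/Gc2", tab))
  expect_equal(diplotype_affinity(gc_diplotypes(), tab),
               c(1.12e9, 0.86e9, 0.74e9, 0.60e9, 0.48e9, 0.36e9))
  expect_error(diplotype_affinity("Gc3/Gc1f", tab), "Gc3")
  expect_error(diplotype_affinity("Gc1f/Gc2", c(Gc1f = 1e9)), "allele_table")
})

test_that("unit conversion to molar matches hand arithmetic", {
  expect_equal(to_molar(0, "25ohd"), 0)
  expect_equal(to_molar(226.5, "vdbp"), 226.5e-3 / 58000, tolerance = 1e-12)
  expect_equal(to_molar(4.3, "albumin"), 43 / 66500, tolerance = 1e-12)
  # linearity
  expect_equal(to_molar(3 * 19.8, "25ohd"), 3 * to_molar(19.8, "25ohd"))
  expect_error(to_molar(-1, "vdbp"), "negative")
})

test_that("unit round trips are the identity", {
  scheme <- binding_scheme()
  ng_ml <- c(5, 19.8, 60)
  back <- to_molar(ng_ml, "25ohd", scheme) * scheme$mw_25ohd * 1e6
  expect_equal(back, ng_ml, tolerance = 1e-12)
  # ng/mL <-> pg/mL is a factor of 1000 exactly
  expect_equal(19.8 * 1000 / 1000, 19.8)
})

test_that("linear free 25OHD reproduces the worked example", {
  res <- free_25ohd(19.8, 226.5, 4.3)
  expect_equal(res$free_pg_ml, 6.34, tolerance = 0.01)
  expect_equal(res$frac_free, 3.2e-4, tolerance = 0.02)
  expect_equal(res$bioavailable_ng_ml, 2.47, tolerance = 0.01)
  # bioavailable from free directly
  expect_equal(bioavailable_25ohd(6.34, to_molar(4.3, "albumin"), 6e5),
               2.466, tolerance = 1e-3)
  expect_equal(bioavailable_25ohd(0, 6.47e-4, 6e5), 0)
  expect_equal(bioavailable_25ohd(5, 0, 6e5), 5 / 1000)
})

test_that("diplotype-specific schemes shift free levels as expected", {
  gc22 <- free_25ohd(19.8, 226.5, 4.3, scheme_from_config(diplotype = "Gc2/Gc2"))
  gc11 <- free_25ohd(19.8, 226.5, 4.3, scheme_from_config(diplotype = "Gc1f/Gc1f"))
  expect_equal(gc22$free_pg_ml, 11.0, tolerance = 0.01)
  expect_equal(gc11$free_pg_ml, 4.2, tolerance = 0.02)
  # free strictly decreases as affinity increases across the six diplotypes
  frees <- vapply(gc_diplotypes(), function(d) {
    free_25ohd(19.8, 226.5, 4.3, scheme_from_config(diplotype = d))$free_pg_ml
  }, numeric(1))
  expect_true(all(diff(frees) > 0))  # ordered tightest -> weakest binder
})

test_that("degenerate and boundary inputs behave", {
  expect_equal(free_25ohd(0, 226.5, 4.3)$free_pg_ml, 0)
  expect_equal(free_25ohd(0, 226.5, 4.3)$bioavailable_ng_ml, 0)
  # no binders: everything is free
  none <- free_25ohd(19.8, 0, 0)
  expect_equal(none$free_pg_ml, 19.8 * 1000)
  expect_equal(none$frac_free, 1)
  expect_error(free_25ohd(-1, 226.5, 4.3), "non-negative")
  expect_error(binding_scheme(k_dbp = -1), "positive")
})

test_that("fractions sum to one and respect physiologic bounds", {
  set.seed(11)
  vdbp <- runif(200, 100, 400)
  alb <- runif(200, 3, 5.5)
  fr <- bound_fractions(vdbp, alb)
  expect_equal(fr$frac_dbp + fr$frac_alb + fr$frac_free,
               rep(1, 200), tolerance = 1e-9)
  expect_true(all(fr$frac_free > 0 & fr$frac_free < 0.001))
  # fractions independent of total under the linear model
  a <- free_25ohd(10, 226.5, 4.3)
  b <- free_25ohd(40, 226.5, 4.3)
  expect_equal(a$frac_dbp, b$frac_dbp)
  # doubling k_dbp raises the VDBP-bound share, lowers the others
  hi <- bound_fractions(226.5, 4.3, binding_scheme(k_dbp = 1.4e9))
  lo <- bound_fractions(226.5, 4.3)
  expect_gt(hi$frac_dbp, lo$frac_dbp)
  expect_lt(hi$frac_alb, lo$frac_alb)
  expect_lt(hi$frac_free, lo$frac_free)
})

test_that("free 25OHD is monotone in its inputs", {
  base <- free_25ohd(19.8, 226.5, 4.3)$free_pg_ml
  expect_gt(free_25ohd(25, 226.5, 4.3)$free_pg_ml, base)
  expect_lt(free_25ohd(19.8, 300, 4.3)$free_pg_ml, base)
  expect_lt(free_25ohd(19.8, 226.5, 5.0)$free_pg_ml, base)
})

test_that("exact mass-action oracle brackets and bounds the linear model", {
  ex <- free_25ohd_exact(19.8, 226.5, 4.3)
  expect_equal(ex$free_pg_ml, 6.4, tolerance = 0.01)
  lin <- free_25ohd(19.8, 226.5, 4.3)
  expect_lt(abs(lin$free_pg_ml - ex$free_pg_ml) / ex$free_pg_ml, 0.02)
  expect_equal(ex$frac_dbp + ex$frac_alb + ex$frac_free, 1, tolerance = 1e-6)
  expect_equal(free_25ohd_exact(0, 226.5, 4.3)$free_pg_ml, 0)
  # mass-balance residual below tolerance
  scheme <- binding_scheme()
  f <- to_molar(ex$free_pg_ml / 1000, "25ohd", scheme)
  pd <- to_molar(226.5, "vdbp", scheme)
  pa <- to_molar(4.3, "albumin", scheme)
  resid <- f * (1 + scheme$k_dbp * pd / (1 + scheme$k_dbp * f) +
                  scheme$k_alb * pa / (1 + scheme$k_alb * f)) -
    to_molar(19.8, "25ohd", scheme)
  expect_lt(abs(resid) / to_molar(19.8, "25ohd", scheme), 1e-6)
})

test_that("linear never exceeds exact, and binders saturate in the limit", {
  set.seed(12)
  grid <- expand.grid(total = c(5, 20, 40, 60), vdbp = c(100, 250, 400),
                      alb = c(3, 4.3, 5.5))
  lin <- free_25ohd(grid$total, grid$vdbp, grid$alb)
  ex <- free_25ohd_exact(grid$total, grid$vdbp, grid$alb)
  expect_true(all(lin$free_pg_ml <= ex$free_pg_ml + 1e-12))
  # the relative gap is governed by binder depletion: it stays below the
  # ligand/binder molar ratio everywhere, and below 2% once the ligand is
  # under 2.5% of the VDBP pool
  ratio <- to_molar(grid$total, "25ohd") / to_molar(grid$vdbp, "vdbp")
  rel <- abs(lin$free_pg_ml - ex$free_pg_ml) / ex$free_pg_ml
  expect_true(all(rel < ratio))
  expect_true(all(rel[ratio < 0.025] < 0.02))
  # ligand 100x the binder with no albumin: nearly all free
  vdbp_tiny <- 2  # ug/mL
  total_sat <- 100 * to_molar(vdbp_tiny, "vdbp") * 400.64 * 1e6  # ng/mL
  sat <- free_25ohd_exact(total_sat, vdbp_tiny, 0)
  expect_gt(sat$frac_free, 0.99)
})
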