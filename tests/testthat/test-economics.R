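make_arm <- function(name = "toy", drug = 0, admin = 0, u_pf = 1, u_pp = 1,
                     frac = 0, pp_cost = 0, eol = 0, ae = list(),
                     os = immortal_curve(), pfs = immortal_curve()) {
  arm_parameters(name, drug_cost_per_cycle = drug, admin_cost_per_cycle = admin,
                 utility_pf = u_pf, utility_pp = u_pp, ae_profile = ae,
                 postprog_treated_fraction = frac,
                 postprog_cost_per_cycle = pp_cost, eol_cost = eol,
                 os_curve = os, pfs_curve = pfs)
}

test_that("a free, perfect-health, immortal strategy accrues (0, 3, 3)", {
  cfg <- model_config(discount_rate_annual = 0)
  arm <- make_arm()
  tr <- build_trace(arm$os_curve, arm$pfs_curve, zero_life_table(), cfg)
  acc <- accrue(tr, arm, cfg)
  expect_equal(acc$total_cost, 0)
  expect_equal(acc$life_years, 3, tolerance = 1e-9)
  expect_equal(acc$qalys, 3, tolerance = 1e-9)
})

test_that("treatment cost stops at the 35-cycle cap", {
  cfg <- model_config(discount_rate_annual = 0)
  arm <- make_arm(drug = 6915, admin = 150)
  tr <- build_trace(arm$os_curve, arm$pfs_curve, zero_life_table(), cfg)
  acc <- accrue(tr, arm, cfg)
  expect_equal(acc$total_cost, 35 * (6915 + 150), tolerance = 1e-6)
})

test_that("6-weekly dosing charges double doses on alternate cycles", {
  cfg <- model_config(discount_rate_annual = 0, dose_schedule = "q6w")
  arm <- make_arm(drug = 6915, admin = 150)
  tr <- build_trace(arm$os_curve, arm$pfs_curve, zero_life_table(), cfg)
  acc <- accrue(tr, arm, cfg)
  # dosing cycles 0, 2, ..., 34: 18 administrations of a double dose
  expect_equal(acc$total_cost, 18 * (2 * 6915 + 150), tolerance = 1e-6)
})

test_that("QALYs never exceed life-years and equal them at utility one", {
  ctx <- base_case_context()
  for (arm in ctx$arms) {
    tr <- build_trace(arm$os_curve, arm$pfs_curve, ctx$life_table, ctx$config)
    acc <- accrue(tr, arm, ctx$config)
    expect_lte(acc$qalys, acc$life_years)
    arm1 <- arm
    arm1$utility_pf <- 1; arm1$utility_pp <- 1; arm1$ae_profile <- list()
    acc1 <- accrue(tr, arm1, ctx$config)
    expect_equal(acc1$qalys, acc1$life_years, tolerance = 1e-12)
  }
})

test_that("adverse-event profiles add one-time costs and decrements", {
  cfg <- model_config(discount_rate_annual = 0)
  ae <- list(list(probability = 0.5, cost = 1000, utility_decrement = 0.1))
  plain <- make_arm()
  hit <- make_arm(ae = ae)
  tr <- build_trace(plain$os_curve, plain$pfs_curve, zero_life_table(), cfg)
  a0 <- accrue(tr, plain, cfg)
  a1 <- accrue(tr, hit, cfg)
  expect_equal(a1$total_cost - a0$total_cost, 500)
  expect_equal(a0$qalys - a1$qalys, 0.05, tolerance = 1e-12)
  expect_equal(a1$life_years, a0$life_years)
})

test_that("end-of-life costs accrue once per death", {
  cfg <- model_config(discount_rate_annual = 0)
  dying <- param_surv("exponential", list(rate = 0.5))
  arm0 <- make_arm(os = dying, pfs = dying)
  arm1 <- make_arm(os = dying, pfs = dying, eol = 1000)
  tr <- build_trace(dying, dying, zero_life_table(), cfg)
  a0 <- accrue(tr, arm0, cfg)
  a1 <- accrue(tr, arm1, cfg)
  expect_equal(a1$total_cost - a0$total_cost, 1000 * tr$dead[nrow(tr)],
               tolerance = 1e-9)
})

test_that("pairwise comparison computes incrementals, ICERs and dominance", {
  a <- list(name = "a", total_cost = 207589, life_years = 1.171, qalys = 0.816)
  b <- list(name = "b", total_cost = 254646, life_years = 1.324, qalys = 0.954)
  res <- compare(a, b)
  expect_equal(res$d_cost, 47057)
  expect_equal(res$icer_per_qaly, 47057 / (0.954 - 0.816), tolerance = 1e-12)
  expect_equal(res$icer_per_ly, 47057 / (1.324 - 1.171), tolerance = 1e-12)
  expect_true(is.na(res$dominance))

  expect_identical(compare(a, a)$dominance, "equivalent")
  cheaper_better <- list(name = "c", total_cost = 100, life_years = 2, qalys = 2)
  expect_identical(compare(a, cheaper_better)$dominance, "b dominant")
  worse <- list(name = "d", total_cost = 3e5, life_years = 1, qalys = 0.7)
  expect_identical(compare(a, worse)$dominance, "b dominated")
})

test_that("net monetary benefit follows its identities", {
  a <- list(name = "a", total_cost = 0, life_years = 1.171, qalys = 0.816)
  b <- list(name = "b", total_cost = 47057, life_years = 1.324, qalys = 0.954)
  res <- compare(a, b)
  expect_equal(net_monetary_benefit(res, 150000),
               150000 * 0.138 - 47057, tolerance = 1e-9)
  expect_equal(net_monetary_benefit(res, 0), -47057)
  expect_equal(net_monetary_benefit(res, res$icer_per_qaly), 0, tolerance = 1e-6)
  expect_error(net_monetary_benefit(res, -1), ">= 0")
})

test_that("raising the drug price strictly increases the ICER", {
  ctx <- base_case_context()
  base <- run_cea(ctx)
  up <- run_cea(set_param(ctx, "arms.pembrolizumab.drug_cost_per_cycle", 8000))
  expect_gt(up$icer_per_qaly, base$icer_per_qaly)
  down <- run_cea(set_param(ctx, "arms.pembrolizumab.drug_cost_per_cycle", 5000))
  expect_lt(down$icer_per_qaly, base$icer_per_qaly)
})

test_that("arm parameters are validated", {
  expect_error(make_arm(u_pf = 1.2), "utilities")
  expect_error(make_arm(drug = -1), "costs")
  expect_error(make_arm(frac = 1.5), "fraction")
  expect_error(arm_parameters("x", drug_cost_per_cycle = 0, utility_pf = 0.8,
                              ae_profile = list(list(probability = 2)),
                              postprog_treated_fraction = 0.5,
                              postprog_cost_per_cycle = 100),
               "ae_profile")
})
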