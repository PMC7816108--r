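test_that("per-cycle probabilities follow the conditional survival ratio", {
  # exponential memorylessness: identical probability at every start time
  e <- param_surv("exponential", list(rate = 0.05))
  expected <- 1 - exp(-0.05 * 0.69)
  for (t in c(0, 3, 11.7, 30)) {
    expect_equal(cycle_probability(e, t, 0.69), expected, tolerance = 1e-12)
  }
  # closed-form Weibull ratio
  w <- param_surv("weibull", list(shape = 0.9, scale = 20))
  p <- cycle_probability(w, 5, 0.69)
  expect_equal(p, 1 - exp(-(5.69 / 20)^0.9 + (5 / 20)^0.9), tolerance = 1e-12)
  # decreasing-hazard Weibull: per-cycle probability decreases in t
  grid <- seq(0.5, 30, 0.5)
  expect_true(all(diff(cycle_probability(w, grid, 0.69)) < 0))
})

test_that("background mortality converts annual probabilities and clamps ages", {
  lt <- life_table(60:70, seq(0.01, 0.06, 0.005))
  expect_equal(background_mortality(life_table(60:70, rep(0, 11)), 65, 0.69), 0)
  cyc <- 21 / (365.25 / 12)
  expect_equal(background_mortality(life_table(60:61, c(0.012, 0.012)), 60, cyc),
               1 - 0.988^(cyc / 12), tolerance = 1e-12)
  expect_equal(background_mortality(lt, 120, 1),
               background_mortality(lt, 70, 1))
  expect_equal(background_mortality(lt, 20, 1),
               background_mortality(lt, 60, 1))
})

test_that("occupancies are conserved and death occupancy is monotone", {
  ctx <- base_case_context()
  for (arm in ctx$arms) {
    tr <- build_trace(arm$os_curve, arm$pfs_curve, ctx$life_table, ctx$config)
    expect_lt(max(abs(tr$pf + tr$pp + tr$dead - 1)), 1e-9)
    expect_true(all(tr$pf >= 0 & tr$pp >= 0 & tr$dead >= 0))
    expect_true(all(diff(tr$dead) >= -1e-12))
    expect_true(all(diff(tr$discount) <= 0))
    expect_equal(tr$discount[1], 1)
  }
})

test_that("degenerate cohorts behave as expected", {
  cfg <- model_config(discount_rate_annual = 0)
  lt0 <- zero_life_table()
  # immortal cohort: everyone stays progression-free; 3 undiscounted life-years
  tr <- build_trace(immortal_curve(), immortal_curve(), lt0, cfg)
  expect_equal(tr$pf[nrow(tr)], 1, tolerance = 1e-9)
  expect_equal(max(tr$dead), 0, tolerance = 1e-9)
  expect_equal(life_years(tr, discounted = FALSE), 3, tolerance = 1e-9)
  expect_equal(nrow(tr) - 1L,
               ceiling(cfg$horizon_years * 12 / cycle_length_months(cfg)))
  # certain death in the first cycle
  tr2 <- build_trace(instant_death_curve(), instant_death_curve(), lt0, cfg)
  expect_equal(tr2$dead[2], 1, tolerance = 1e-9)
  expect_equal(life_years(tr2, discounted = FALSE), 0,
               tolerance = cycle_length_months(cfg) / 12)
})

test_that("discounted life-years of an immortal cohort match the annuity integral", {
  cfg <- model_config(horizon_years = 1, discount_rate_annual = 0.03)
  tr <- build_trace(immortal_curve(), immortal_curve(), zero_life_table(), cfg)
  analytic <- (1 - 1.03^(-1)) / log(1.03)
  expect_lt(abs(life_years(tr, discounted = TRUE) - analytic) / analytic, 0.01)
})

test_that("the trace reproduces the OS law: life-years match RMST by quadrature", {
  ctx <- base_case_context()
  arm <- ctx$arms$pembrolizumab
  tr <- build_trace(arm$os_curve, arm$pfs_curve, zero_life_table(), ctx$config)
  undisc <- life_years(tr, discounted = FALSE)
  expect_lt(abs(undisc - rmst(arm$os_curve, 36) / 12) / undisc, 0.02)

  # exponential limit with discounting, against the closed-form integrand
  os <- param_surv("exponential", list(rate = 0.06))
  pfs <- param_surv("exponential", list(rate = 0.2))
  tr2 <- build_trace(os, pfs, zero_life_table(), model_config())
  quad <- stats::integrate(function(t) exp(-0.06 * t) * 1.03^(-t / 12),
                           0, 36, rel.tol = 1e-10)$value / 12
  expect_lt(abs(life_years(tr2, discounted = TRUE) - quad) / quad, 0.01)
})

test_that("uniformly raising mortality never increases life-years", {
  ctx <- base_case_context()
  arm <- ctx$arms$pembrolizumab
  base <- build_trace(arm$os_curve, arm$pfs_curve, ctx$life_table, ctx$config)
  worse <- build_trace(apply_hazard_ratio(arm$os_curve, 1.3), arm$pfs_curve,
                       ctx$life_table, ctx$config)
  expect_lt(life_years(worse), life_years(base))
})

test_that("the cure scenario switches to pure background mortality after the landmark", {
  ctx <- base_case_context()
  cfg <- model_config(cure_scenario = TRUE, cure_time_months = 30)
  arm <- ctx$arms$pembrolizumab
  tr <- build_trace(arm$os_curve, arm$pfs_curve, ctx$life_table, cfg)
  cyc <- cycle_length_months(cfg)
  rows <- which(tr$time_months >= 30 & !is.na(tr$p_death))
  expected <- background_mortality(
    ctx$life_table, cfg$start_age_years + tr$time_months[rows] / 12,
    diff(tr$time_months)[rows])
  expect_equal(tr$p_death[rows], expected, tolerance = 1e-15)
  # before the landmark the disease hazard dominates
  expect_gt(tr$p_death[1], expected[1])
})

test_that("half-cycle correction changes life-years by at most half a cycle of occupancy", {
  ctx <- base_case_context()
  arm <- ctx$arms$placebo
  on <- build_trace(arm$os_curve, arm$pfs_curve, ctx$life_table, ctx$config)
  cfg_off <- model_config(half_cycle_correction = FALSE)
  off <- build_trace(arm$os_curve, arm$pfs_curve, ctx$life_table, cfg_off)
  delta <- abs(life_years(on, FALSE) - life_years(off, FALSE))
  expect_lt(delta, cycle_length_months(ctx$config) / 12 / 2)
})

test_that("partitioned-survival mode agrees with the markov mode on the alive total", {
  ctx <- base_case_context()
  arm <- ctx$arms$pembrolizumab
  mk <- build_trace(arm$os_curve, arm$pfs_curve, zero_life_table(), ctx$config)
  ps <- build_trace(arm$os_curve, arm$pfs_curve, zero_life_table(),
                    model_config(structure = "partitioned"))
  expect_equal(mk$pf + mk$pp, ps$pf + ps$pp, tolerance = 1e-9)
  expect_equal(life_years(mk), life_years(ps), tolerance = 1e-9)
  # partitioned PF occupancy reads the PFS curve directly
  expect_equal(ps$pf, pmin(surv_prob(arm$pfs_curve, ps$time_months),
                           surv_prob(arm$os_curve, ps$time_months)))
})

test_that("model configuration is validated", {
  expect_error(model_config(horizon_years = 0), "horizon_years")
  expect_error(model_config(discount_rate_annual = 1), "discount_rate")
  expect_error(model_config(max_treatment_cycles = -1), "max_treatment_cycles")
  expect_error(model_config(background_mode = "multiply"), "'arg'")
})
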