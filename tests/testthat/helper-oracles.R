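# Independent oracles and small fixtures shared across test files.

# Brute-force product-limit estimator, written directly from the risk-set
# definition (independent of survival::survfit).
brute_force_km <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s <- cumprod(vapply(et, function(t) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    1 - d / n
  }, numeric(1)))
  data.frame(time = et, surv = s)
}

# Right-continuous step lookup on a digitized curve.
km_at <- function(curve, t) {
  idx <- findInterval(t + 1e-9, curve$time_months)
  curve$survival[pmax(idx, 1)]
}

# Median read off a KM curve: first time survival drops to <= 0.5.
km_median <- function(curve) {
  i <- which(curve$survival <= 0.5)[1]
  curve$time_months[i]
}

# Survival laws used as degenerate fixtures.
immortal_curve <- function() param_surv("exponential", list(rate = 1e-12))
instant_death_curve <- function() param_surv("exponential", list(rate = 1e6))

zero_life_table <- function() life_table(60:100, rep(0, 41))

# Base-case OS calibration constants, recomputed from first principles.
base_weibull_shape <- function() log(log(0.25) / log(0.5)) / log(30 / 13.9)
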