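#' Kaplan-Meier estimate of pseudo individual-patient data
#'
#' Product-limit estimate via [survival::survfit()], returned as a
#' [digitized_curve()] with the anchor point (0, 1) followed by steps at
#' event times only.
#'
#' @param ipd a [pseudo_ipd()].
#' @return a [digitized_curve()].
#' @export
km_estimate <- function(ipd) {
  ipd <- as_pseudo_ipd(ipd)
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1, data = ipd)
  keep <- fit$n.event > 0
  digitized_curve(c(0, fit$time[keep]), c(1, fit$surv[keep]))
}

#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' Inverts the published Kaplan-Meier figure: given digitized curve
#' coordinates and the number-at-risk table printed beneath the figure,
#' solves, within each inter-risk-time interval, for integer numbers of
#' events (placed at the curve's reading times) and censorings such that
#'
#' 1. the KM curve of the output tracks the input coordinates, and
#' 2. the at-risk counts match the risk table at every interval boundary.
#'
#' The scheme follows the iterative reconstruction used for published
#' oncology KM figures: a first pass assumes no censoring and derives
#' real-valued event counts from successive survival ratios
#' (d = n (1 - S_j / S_{j-1})); the censoring count per interval is then
#' the at-risk drop not explained by events, and the interval is re-solved
#' with those censorings interleaved. Censoring times start from an even
#' layout across the interval, but their split around each reading is
#' adjusted when the even layout cannot reproduce the reading's drop
#' factor (late in follow-up, where risk sets are small, the size of the
#' risk set at an event visibly changes the step height). A reading
#' lying exactly on a risk-table time carries the survival drop
#' accumulated over the interval that ends there, so its events belong to
#' that interval. All placement rules are deterministic, so
#' reconstruction is reproducible. Patients still at risk after the last
#' interval are administratively censored at the end of follow-up.
#'
#' Noisy digitizations are first repaired to be non-increasing with an
#' isotonic (pool-adjacent-violators) pass.
#'
#' @param curve a [digitized_curve()] (or data frame with `time_months`,
#'   `survival`; values are clipped to \[0,1\] and monotonized).
#' @param risk a [risk_table()]. The first entry is the sample size.
#' @param total_events optional total event count; interval event counts
#'   are rescaled proportionally (largest-remainder rounding) to match it.
#' @return a [pseudo_ipd()] with exactly `risk$n_risk[1]` records.
#' @export
reconstruct_ipd <- function(curve, risk, total_events = NULL) {
  if (!inherits(curve, "digitized_curve")) {
    stopifnot(is.data.frame(curve),
              all(c("time_months", "survival") %in% names(curve)))
    s <- pava_nonincreasing(pmin(pmax(curve$survival, 0), 1))
    curve <- digitized_curve(curve$time_months, pmin(pmax(s, 0), 1))
  }
  if (!inherits(risk, "risk_table")) risk <- risk_table(risk$time_months, risk$n_risk)
  if (risk$n_risk[1] <= 0) stop("first risk-table entry must be > 0", call. = FALSE)
  if (min(curve$time_months) > min(risk$time_months) + 1e-9) {
    stop("risk table starts before the digitized curve; no common span",
         call. = FALSE)
  }
  # anchor the curve at time 0
  if (curve$time_months[1] > 0) {
    curve <- digitized_curve(c(0, curve$time_months), c(1, curve$survival))
  }
  t_end <- max(max(curve$time_months), max(risk$time_months))

  bounds <- c(risk$time_months, Inf)
  n_int <- nrow(risk)
  # reading points: strictly positive times where the curve value can drop
  steps <- curve[curve$time_months > 0, , drop = FALSE]

  all_events_t <- numeric(0); all_events_d <- integer(0)
  all_cens <- numeric(0)
  n_cur <- risk$n_risk[1]; s_cur <- 1

  for (i in seq_len(n_int)) {
    lo <- bounds[i]; hi <- bounds[i + 1]
    in_i <- steps$time_months > lo & steps$time_months <= hi
    pts <- steps[in_i, , drop = FALSE]
    target <- if (i < n_int) risk$n_risk[i + 1] else NA_integer_
    hi_fin <- if (is.finite(hi)) hi else t_end

    # pass A: no censoring
    solA <- solve_km_interval(n_cur, s_cur, pts, 0L, lo, hi_fin)
    if (i < n_int) {
      cens_n <- max(0L, n_cur - target - sum(solA$d_int))
      sol <- solve_km_interval(n_cur, s_cur, pts, cens_n, lo, hi_fin)
      for (it in 1:10) {
        mis <- (n_cur - cens_n - sum(sol$d_int)) - target
        if (mis == 0L) break
        if (mis < 0L && cens_n < -mis) break
        cens_n <- cens_n + mis
        sol <- solve_km_interval(n_cur, s_cur, pts, cens_n, lo, hi_fin)
      }
      mis <- (n_cur - cens_n - sum(sol$d_int)) - target
      if (mis > 0L) {
        # residual patients: censor at the very end of the interval
        sol$cens_times <- c(sol$cens_times, rep(hi_fin - 1e-7, mis))
        cens_n <- cens_n + mis
      } else if (mis < 0L) {
        # events overshoot the allowed at-risk drop even with no
        # censoring: trim from the last readings and replay the KM product
        need <- -mis
        for (j in rev(seq_along(sol$d_int))) {
          if (need <= 0) break
          cut <- min(sol$d_int[j], need)
          sol$d_int[j] <- sol$d_int[j] - cut
          need <- need - cut
        }
        if (need > 0) {
          stop(sprintf(
            "inconsistent inputs in interval (%g, %g]: curve implies more exits than the risk table allows",
            lo, hi_fin), call. = FALSE)
        }
        nn <- n_cur; sf <- s_cur; ci <- 1L
        for (j in seq_along(sol$d_int)) {
          while (ci <= length(sol$cens_times) &&
                 sol$cens_times[ci] < pts$time_months[j]) {
            nn <- max(nn - 1L, 0L); ci <- ci + 1L
          }
          d <- sol$d_int[j]
          if (nn > 0 && d > 0) sf <- sf * (1 - d / nn)
          nn <- nn - d
        }
        sol$s_fit <- sf
      }
      n_next <- target
    } else {
      sol <- solA
      n_next <- n_cur - sum(sol$d_int)
    }
    all_events_t <- c(all_events_t, pmin(pts$time_months, hi_fin - 1e-6))
    all_events_d <- c(all_events_d, sol$d_int)
    all_cens <- c(all_cens, sol$cens_times)
    s_cur <- sol$s_fit
    n_cur <- n_next
  }

  if (!is.null(total_events)) {
    d <- rescale_counts(all_events_d, total_events)
    # re-derive per-interval censor counts against the risk table
    all_cens <- numeric(0)
    n_cur <- risk$n_risk[1]
    for (i in seq_len(n_int - 1)) {
      lo <- bounds[i]; hi <- bounds[i + 1]
      in_i <- all_events_t > lo & all_events_t <= hi
      ev_i <- sum(d[in_i])
      target <- risk$n_risk[i + 1]
      # when the imposed total makes the risk drop unexplainable, censoring
      # is clamped at zero and the at-risk match becomes approximate
      cens_n <- max(0L, n_cur - target - ev_i)
      if (cens_n > 0L) {
        all_cens <- c(all_cens,
                      lo + seq_len(cens_n) / (cens_n + 1) * (min(hi, t_end) - lo))
      }
      n_cur <- n_cur - ev_i - cens_n
    }
    n_cur <- n_cur - sum(d[all_events_t > bounds[n_int]])
    all_events_d <- d
  }

  times <- c(rep(pmax(all_events_t, .Machine$double.eps), all_events_d),
             all_cens,
             rep(max(t_end, .Machine$double.eps), n_cur))
  event <- c(rep(1L, sum(all_events_d)),
             rep(0L, length(all_cens)),
             rep(0L, n_cur))
  o <- order(times, -event)
  pseudo_ipd(times[o], event[o])
}

# Solve one inter-risk-time interval: integer events per reading and
# censoring times for cens_n censored patients. Censors default to an even
# layout across the interval; the number consumed before each reading is
# adjusted (ties toward the even layout) when that improves how closely
# the KM update can match the reading's survival value.
solve_km_interval <- function(n_start, s_start, pts, cens_n, lo, hi) {
  J <- nrow(pts)
  span <- hi - lo
  if (J == 0L) {
    cts <- if (cens_n > 0) lo + seq_len(cens_n) / (cens_n + 1) * span else numeric(0)
    return(list(d_int = integer(0), cens_times = cts, s_fit = s_start))
  }
  n <- n_start; s_fit <- s_start
  d_int <- integer(J); c_int <- integer(J)
  rem <- cens_n
  t_prev <- lo
  cum_nominal <- 0L
  for (j in seq_len(J)) {
    t_j <- pts$time_months[j]
    nominal_here <- if (span > 0) {
      min(rem, max(0L, as.integer(round(cens_n * (t_j - lo) / span)) - cum_nominal))
    } else 0L
    if (n <= 0L || s_fit <= 0) { t_prev <- t_j; next }
    s_target <- pts$survival[j]
    f <- s_target / s_fit
    pick <- function(c) {
      nc <- n - c
      if (nc <= 0L) return(c(0, Inf))
      dr <- nc * (1 - f)
      cand <- unique(pmin(pmax(c(floor(dr), ceiling(dr)), 0), nc))
      err <- abs(s_fit * (1 - cand / nc) - s_target)
      k <- which.min(err)
      c(cand[k], err[k])
    }
    best <- pick(nominal_here); c_use <- nominal_here
    if (best[2] > 1e-9 && rem > 0L) {
      for (c in order(abs(0:rem - nominal_here))) {
        cc <- (0:rem)[c]
        if (cc == nominal_here) next
        p <- pick(cc)
        if (p[2] < best[2] - 1e-12) { best <- p; c_use <- cc }
      }
    }
    d <- as.integer(best[1])
    c_int[j] <- c_use
    n <- n - c_use
    if (d > 0L && n > 0L) s_fit <- s_fit * (1 - d / n)
    n <- n - d
    d_int[j] <- d
    rem <- rem - c_use
    cum_nominal <- cum_nominal + nominal_here
    t_prev <- t_j
  }
  # censor times: the c_int[j] censors spread in the gap before reading j,
  # any remainder spread after the last reading
  cts <- numeric(0)
  t_prev <- lo
  for (j in seq_len(J)) {
    if (c_int[j] > 0L) {
      gap <- pts$time_months[j] - t_prev
      cts <- c(cts, t_prev + seq_len(c_int[j]) / (c_int[j] + 1) * gap)
    }
    t_prev <- pts$time_months[j]
  }
  if (rem > 0L) {
    gap <- hi - t_prev
    if (gap <= 0) gap <- max(span, 1e-6)  # degenerate: reading at boundary
    cts <- c(cts, pmin(t_prev + seq_len(rem) / (rem + 1) * gap, hi - 1e-7))
  }
  list(d_int = d_int, cens_times = sort(cts), s_fit = s_fit)
}

# Proportional rescaling with largest-remainder rounding to an exact total.
rescale_counts <- function(counts, total) {
  if (total < 0) stop("total_events must be >= 0", call. = FALSE)
  s <- sum(counts)
  if (s == 0) {
    if (total == 0) return(counts)
    stop("cannot rescale zero events to a positive total", call. = FALSE)
  }
  x <- counts * total / s
  f <- floor(x)
  rem <- as.integer(round(total - sum(f)))
  if (rem > 0) {
    o <- order(x - f, decreasing = TRUE)
    f[o[seq_len(rem)]] <- f[o[seq_len(rem)]] + 1
  }
  as.integer(f)
}
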