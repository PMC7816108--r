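#' Pseudo individual-patient data
#'
#' A data frame of (possibly reconstructed) patient-level records with
#' columns `time_months` (> 0) and `event` (1 = event, 0 = censored),
#' carrying optional `arm` and `endpoint` labels as attributes.
#'
#' @param time_months positive event/censoring times (months).
#' @param event 0/1 event indicators.
#' @param arm,endpoint optional labels.
#' @return a data frame of class `pseudo_ipd`.
#' @export
pseudo_ipd <- function(time_months, event, arm = NA_character_,
                       endpoint = NA_character_) {
  if (length(time_months) == 0) stop("IPD must have at least one record", call. = FALSE)
  if (length(time_months) != length(event)) {
    stop("time_months and event lengths differ", call. = FALSE)
  }
  if (any(!is.finite(time_months)) || any(time_months <= 0)) {
    stop("all times must be positive and finite", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1", call. = FALSE)
  structure(
    data.frame(time_months = as.numeric(time_months),
               event = as.integer(event)),
    arm = arm, endpoint = endpoint,
    class = c("pseudo_ipd", "data.frame"))
}

as_pseudo_ipd <- function(x) {
  if (inherits(x, "pseudo_ipd")) return(x)
  if (is.data.frame(x) && all(c("time_months", "event") %in% names(x))) {
    return(pseudo_ipd(x$time_months, x$event))
  }
  stop("expected a pseudo_ipd or a data frame with time_months and event",
       call. = FALSE)
}

#' Digitized survival curve
#'
#' Ordered (time, survival) coordinates as produced by a graph digitizer
#' applied to a published Kaplan-Meier figure: times strictly increasing,
#' survival non-increasing, starting at or below 1.
#'
#' @param time_months non-negative, strictly increasing times.
#' @param survival survival probabilities, non-increasing.
#' @return a data frame of class `digitized_curve`.
#' @export
digitized_curve <- function(time_months, survival) {
  if (length(time_months) != length(survival) || length(time_months) == 0) {
    stop("curve needs equal-length, nonempty time and survival vectors",
         call. = FALSE)
  }
  if (any(diff(time_months) <= 0)) {
    stop("curve times must be strictly increasing", call. = FALSE)
  }
  if (any(time_months < 0)) stop("curve times must be >= 0", call. = FALSE)
  if (any(survival < 0 | survival > 1)) {
    stop("survival must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(survival) > 1e-12)) {
    i <- which(diff(survival) > 1e-12)[1]
    stop(sprintf("survival increases between t = %g and t = %g",
                 time_months[i], time_months[i + 1]), call. = FALSE)
  }
  structure(data.frame(time_months = as.numeric(time_months),
                       survival = as.numeric(survival)),
            class = c("digitized_curve", "data.frame"))
}

#' Number-at-risk table
#'
#' @param time_months strictly increasing interval-start times.
#' @param n_risk non-increasing, non-negative at-risk counts.
#' @return a data frame of class `risk_table`.
#' @export
risk_table <- function(time_months, n_risk) {
  if (length(time_months) != length(n_risk) || length(time_months) == 0) {
    stop("risk table needs equal-length, nonempty vectors", call. = FALSE)
  }
  if (any(diff(time_months) <= 0)) {
    stop("risk-table times must be strictly increasing", call. = FALSE)
  }
  if (any(n_risk < 0) || any(n_risk != round(n_risk))) {
    stop("n_risk must be non-negative integers", call. = FALSE)
  }
  if (any(diff(n_risk) > 0)) {
    i <- which(diff(n_risk) > 0)[1]
    stop(sprintf("at-risk count increases between t = %g and t = %g",
                 time_months[i], time_months[i + 1]), call. = FALSE)
  }
  structure(data.frame(time_months = as.numeric(time_months),
                       n_risk = as.integer(n_risk)),
            class = c("risk_table", "data.frame"))
}

#' Life table
#'
#' Annual all-cause death probabilities by (contiguous, increasing) integer
#' age, used for background mortality.
#'
#' @param age integer ages, strictly increasing and contiguous.
#' @param annual_death_prob probabilities in \[0, 1\].
#' @return a data frame of class `life_table`.
#' @export
life_table <- function(age, annual_death_prob) {
  if (length(age) != length(annual_death_prob) || length(age) == 0) {
    stop("life table needs equal-length, nonempty vectors", call. = FALSE)
  }
  if (any(diff(age) != 1)) {
    stop("ages must be strictly increasing and contiguous", call. = FALSE)
  }
  if (any(annual_death_prob < 0 | annual_death_prob > 1)) {
    stop("annual death probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(data.frame(age = as.integer(age),
                       annual_death_prob = as.numeric(annual_death_prob)),
            class = c("life_table", "data.frame"))
}

# ---- CSV dialects ----------------------------------------------------------

#' Read/write the package's CSV interchange formats
#'
#' IPD: `time_months,event`; curve: `time_months,survival`;
#' risk table: `time_months,n_risk`; life table: `age,annual_death_prob`.
#'
#' @param path CSV file path.
#' @param x object to write.
#' @name cea_csv
NULL

#' @rdname cea_csv
#' @export
read_ipd <- function(path) {
  d <- utils::read.csv(path)
  pseudo_ipd(d$time_months, d$event)
}

#' @rdname cea_csv
#' @export
write_ipd <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname cea_csv
#' @export
read_curve <- function(path) {
  d <- utils::read.csv(path)
  digitized_curve(d$time_months, d$survival)
}

#' @rdname cea_csv
#' @export
write_curve <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname cea_csv
#' @export
read_risk_table <- function(path) {
  d <- utils::read.csv(path)
  risk_table(d$time_months, d$n_risk)
}

#' @rdname cea_csv
#' @export
write_risk_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname cea_csv
#' @export
read_life_table <- function(path) {
  d <- utils::read.csv(path)
  life_table(d$age, d$annual_death_prob)
}

#' @rdname cea_csv
#' @export
write_life_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
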