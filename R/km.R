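#' Kaplan-Meier estimate from pseudo individual patient data
#'
#' Product-limit estimator of the survivor function, computed with
#' [survival::survfit()]. Input is a pseudo-IPD data frame with columns
#' `time_months` (positive) and `event` (1 = event, 0 = administratively
#' censored).
#'
#' @param ipd Data frame with columns `time_months`, `event`.
#' @return A `km_curve`: data frame of steps (`time`, `survival`, `n_risk`)
#'   starting implicitly at `S(0) = 1`, with steps at event times only.
#' @examples
#' ipd <- data.frame(time_months = c(1, 2, 3), event = c(1, 1, 0))
#' km_estimate(ipd)
#' @export
km_estimate <- function(ipd) {
  validate_ipd(ipd)
  if (sum(ipd$event) < 1) {
    warning("no events: Kaplan-Meier curve is flat at 1", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1, data = ipd)
  steps <- data.frame(time = fit$time, survival = fit$surv,
                      n_risk = fit$n.risk)
  structure(list(steps = steps, n = nrow(ipd)), class = "km_curve")
}

validate_ipd <- function(ipd) {
  if (!is.data.frame(ipd) || !all(c("time_months", "event") %in% names(ipd))) {
    stop("ipd must be a data frame with columns time_months and event",
         call. = FALSE)
  }
  if (any(ipd$time_months <= 0)) stop("all times must be > 0", call. = FALSE)
  if (!all(ipd$event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  invisible(ipd)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d subjects, %d steps, final S = %.4f\n",
              x$n, nrow(x$steps), min(c(1, x$steps$survival))))
  invisible(x)
}

#' @export
surv_prob.km_curve <- function(x, t) {
  stopifnot(all(t >= 0))
  s <- c(1, x$steps$survival)
  idx <- findInterval(t, x$steps$time) + 1L  # right-continuous step function
  s[idx]
}

#' @export
median_surv.km_curve <- function(x) {
  below <- x$steps$time[x$steps$survival <= 0.5]
  if (length(below) == 0) return(NA_real_)
  min(below)
}

#' Read / write pseudo-IPD CSV
#'
#' The interchange format for simulated patient-level data: a header line and
#' columns `time_months,event`.
#'
#' @param path File path.
#' @param ipd Data frame with columns `time_months`, `event`.
#' @return `read_ipd` returns the validated data frame; `write_ipd` its path,
#'   invisibly.
#' @export
read_ipd <- function(path) {
  ipd <- utils::read.csv(path)
  validate_ipd(ipd)
  ipd
}

#' @rdname read_ipd
#' @export
write_ipd <- function(ipd, path) {
  validate_ipd(ipd)
  utils::write.csv(ipd[c("time_months", "event")], path, row.names = FALSE)
  invisible(path)
}

#' Export a Kaplan-Meier curve as CSV
#'
#' @param km A `km_curve`.
#' @param path File path; columns `time,survival,n_risk`.
#' @export
write_km_curve <- function(km, path) {
  stopifnot(inherits(km, "km_curve"))
  utils::write.csv(km$steps, path, row.names = FALSE)
  invisible(path)
}

#' Hybrid Kaplan-Meier + parametric-tail survival curve
#'
#' Within-trial survival follows the Kaplan-Meier estimate up to
#' `switch_time`; beyond it the parametric tail is rescaled by
#' `KM(switch_time) / S_tail(switch_time)` so the two pieces meet
#' continuously and the combined curve stays non-increasing. This is the
#' usual construction for extrapolating trial survival with a parametric
#' model fit.
#'
#' @param km A `km_curve`.
#' @param tail A `surv_dist` used beyond `switch_time`.
#' @param switch_time Splice point in months, `>= 0` and within KM support.
#' @return A `hybrid_surv` object evaluable via [surv_prob()].
#' @export
build_hybrid <- function(km, tail, switch_time) {
  stopifnot(inherits(km, "km_curve"), inherits(tail, "surv_dist"),
            length(switch_time) == 1, switch_time >= 0)
  if (nrow(km$steps) > 0 && switch_time > max(km$steps$time)) {
    stop("switch_time lies beyond the Kaplan-Meier support", call. = FALSE)
  }
  s_tail <- surv_prob(tail, switch_time)
  if (s_tail <= 0) stop("parametric tail is 0 at switch_time", call. = FALSE)
  rescale <- surv_prob(km, switch_time) / s_tail
  structure(list(km = km, tail = tail, switch_time = switch_time,
                 rescale = rescale), class = "hybrid_surv")
}

#' @export
surv_prob.hybrid_surv <- function(x, t) {
  stopifnot(all(t >= 0))
  out <- numeric(length(t))
  pre <- t <= x$switch_time
  out[pre] <- surv_prob(x$km, t[pre])
  out[!pre] <- x$rescale * surv_prob(x$tail, t[!pre])
  pmin(out, 1)
}

#' @export
print.hybrid_surv <- function(x, ...) {
  cat(sprintf("<hybrid_surv> KM to %.3g months, then %s tail (rescale %.4f)\n",
              x$switch_time, x$tail$family, x$rescale))
  invisible(x)
}

#' @export
median_surv.hybrid_surv <- function(x) {
  if (surv_prob(x, x$switch_time) <= 0.5) return(median_surv(x$km))
  stats::uniroot(function(t) surv_prob(x, t) - 0.5,
                 lower = x$switch_time, upper = 2400, tol = 1e-10)$root
}
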