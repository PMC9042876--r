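#' @importFrom survival Surv survdiff survfit
#' @importFrom stats p.adjust pchisq median setNames
NULL

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function, starting at
#' \eqn{S(0) = 1}, right-continuous and nonincreasing, dropping only at
#' event times.
#'
#' @param time non-negative follow-up times in days.
#' @param event 1 = event observed, 0 = censored.
#' @return data.frame of class \code{km_curve} with columns \code{time},
#'   \code{survival}, \code{n_risk}, \code{n_event}, first row at time 0.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) > 0L, length(time) == length(event),
            all(time >= 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = c(0, fit$time),
                    survival = c(1, fit$surv),
                    n_risk = c(length(time), fit$n.risk),
                    n_event = c(0, fit$n.event))
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier curve up to \code{horizon}; finite under
#' censoring and therefore usable to compare which of two classes survives
#' better over a common follow-up window.
#'
#' @param time,event survival data as in \code{\link{km_estimate}}.
#' @param horizon upper limit of integration (days).
#' @return a single number (days).
#' @export
rmst <- function(time, event, horizon = max(time)) {
  km <- km_estimate(time, event)
  tt <- c(km$time[km$time < horizon], horizon)
  ss <- km$survival[km$time < horizon]
  sum(diff(tt) * ss)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank test: at each distinct event time the
#' observed minus hypergeometric-expected event count in the first group is
#' accumulated and the statistic \eqn{(\sum O - E)^2 / \sum V} is referred
#' to a chi-square distribution with 1 df. Censored subjects remain at risk
#' for events at the same time.
#'
#' With zero events in both groups the statistic is undefined; the result
#' is flagged (\code{zero_events = TRUE}) and returned with p = 1.
#'
#' @param time,event survival data over both groups.
#' @param group vector with exactly two distinct values; the first level
#'   (alphabetical, or factor level order) is "group A".
#' @return list of class \code{logrank_result}: \code{statistic},
#'   \code{p_value}, \code{n_a}, \code{n_b}, \code{observed_a},
#'   \code{expected_a}, \code{zero_events}.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  g <- factor(group)
  if (nlevels(g) != 2L)
    stop("log-rank test requires exactly two nonempty groups", call. = FALSE)
  n <- table(g)
  if (sum(event) == 0) {
    res <- list(statistic = NA_real_, p_value = 1, n_a = unname(n[1L]),
                n_b = unname(n[2L]), observed_a = 0, expected_a = 0,
                zero_events = TRUE)
    class(res) <- "logrank_result"
    return(res)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  res <- list(statistic = unname(sd$chisq),
              p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
              n_a = unname(n[1L]), n_b = unname(n[2L]),
              observed_a = unname(sd$obs[1L]),
              expected_a = unname(sd$exp[1L]),
              zero_events = FALSE)
  class(res) <- "logrank_result"
  res
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank chi-square = %.4g (1 df), p = %.4g [n = %d vs %d]\n",
              x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} n / j}, capped at 1 and returned in
#' the original order.
#'
#' @param p numeric vector of p-values in [0, 1] (NA passed through).
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Which expression class survives better
#'
#' Compares the two classes by restricted mean survival over the common
#' follow-up window (up to the shorter class's last observed time), which
#' stays well-defined under censoring. Ties resolve to \code{"low"}.
#'
#' @param time,event survival data.
#' @param class character vector of \code{"low"}/\code{"high"}.
#' @return \code{"high"} or \code{"low"}.
#' @export
better_survival_class <- function(time, event, class) {
  stopifnot(all(class %in% c("low", "high")))
  horizon <- min(tapply(time, class, max))
  hi <- rmst(time[class == "high"], event[class == "high"], horizon)
  lo <- rmst(time[class == "low"], event[class == "low"], horizon)
  if (hi > lo) "high" else "low"
}

#' Export a Kaplan-Meier curve per class as a plain table
#' @param time,event survival data.
#' @param class class labels (any number of levels).
#' @return data.frame with columns \code{class}, \code{time},
#'   \code{survival}, \code{n_risk}, \code{n_event}.
#' @export
km_by_class <- function(time, event, class) {
  do.call(rbind, lapply(sort(unique(class)), function(cl) {
    km <- km_estimate(time[class == cl], event[class == cl])
    cbind(class = cl, as.data.frame(km))
  }))
}
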