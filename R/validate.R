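#' Median split of an expression vector
#'
#' External validation cohorts come from other platforms, so the step
#' thresholds learned on the discovery cohort's scale do not transfer;
#' patients are instead divided at the within-cohort median of each
#' feature. Values strictly above the median are \code{"high"}, at or
#' below are \code{"low"}; missing values stay unlabeled.
#'
#' @param values named numeric vector over the cohort's samples.
#' @return named character vector of \code{"low"}/\code{"high"}/\code{NA}.
#' @export
median_split <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 2L || min(x) == max(x))
    stop(errorCondition("no valid median split: fewer than 2 distinct values",
                        class = c("no_valid_threshold", "error", "condition")))
  assign_classes(values, stats::median(x))
}

#' Validate one marker in an external cohort
#'
#' Median-splits the cohort by the marker's expression and runs the
#' log-rank test between the classes; any (time, event) endpoint (overall,
#' disease-free, distant-relapse-free survival) is accepted. Markers absent
#' from the cohort's expression matrix, or with a degenerate expression
#' vector, are reported without a test.
#'
#' @param feature_id the marker to test.
#' @param expression feature-by-sample matrix of the validation cohort.
#' @param time,event survival endpoint, aligned with the expression
#'   columns.
#' @param endpoint_label free-text endpoint tag (e.g. "OS"), metadata only.
#' @return one-row data.frame: \code{feature_id}, \code{status}
#'   (\code{"ok"}, \code{"unavailable"} or \code{"degenerate"}),
#'   \code{n_low}, \code{n_high}, \code{logrank_stat}, \code{p_value},
#'   \code{better_survival_class}, \code{endpoint}.
#' @export
validate_marker <- function(feature_id, expression, time, event,
                            endpoint_label = "OS") {
  base <- data.frame(feature_id = feature_id, status = "unavailable",
                     n_low = NA_integer_, n_high = NA_integer_,
                     logrank_stat = NA_real_, p_value = NA_real_,
                     better_survival_class = NA_character_,
                     endpoint = endpoint_label, stringsAsFactors = FALSE)
  if (!feature_id %in% rownames(expression)) return(base)
  vals <- expression[feature_id, ]
  cls <- tryCatch(median_split(vals), no_valid_threshold = function(e) NULL)
  if (is.null(cls)) {
    base$status <- "degenerate"
    return(base)
  }
  ok <- !is.na(cls)
  base$status <- "ok"
  base$n_low <- sum(cls[ok] == "low")
  base$n_high <- sum(cls[ok] == "high")
  lr <- logrank_test(time[ok], event[ok], cls[ok])
  base$logrank_stat <- lr$statistic
  base$p_value <- lr$p_value
  base$better_survival_class <- better_survival_class(time[ok], event[ok], cls[ok])
  base
}

#' Validate a set of markers in an external cohort
#' @param feature_ids markers to test.
#' @inheritParams validate_marker
#' @return row-bound \code{\link{validate_marker}} results.
#' @export
validate_markers <- function(feature_ids, expression, time, event,
                             endpoint_label = "OS") {
  out <- do.call(rbind, lapply(feature_ids, validate_marker,
                               expression = expression, time = time,
                               event = event,
                               endpoint_label = endpoint_label))
  rownames(out) <- NULL
  out
}
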