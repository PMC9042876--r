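#' Fit a least-squares step function to one feature's expression
#'
#' Sorts the non-missing values ascending and, for every breakpoint
#' \code{b} in \code{1..n-1}, fits the two-level step whose segments are the
#' means of the first \code{b} and last \code{n-b} values. The breakpoint
#' minimizing the total sum of squared errors is chosen (ties broken toward
#' the smallest \code{b}) and the binarization threshold is placed at the
#' midpoint of the two segment means. Because the fit pools all samples
#' across all cancer types, the threshold defines high/low expression
#' globally rather than per cohort subset.
#'
#' The search is done in O(n) with prefix sums over mean-centered values,
#' SSE(b) = sum(xc^2) - S1(b)^2/b - (S - S1(b))^2/(n - b); centering keeps
#' the cancellation error negligible. Breakpoints whose SSE ties the
#' minimum within a relative tolerance of 1e-8 count as ties (exact ties
#' arise from duplicated values) and resolve to the smallest b.
#'
#' @param values numeric vector (log-scale expression); missing allowed.
#' @param feature_id optional id stored in the result.
#' @return an object of class \code{step_threshold}: a list with
#'   \code{feature_id}, \code{threshold}, \code{breakpoint_index} (size of
#'   the low segment), \code{sse}, \code{n_used}.
#' @export
fit_step_threshold <- function(values, feature_id = NA_character_) {
  x <- sort(unname(values[!is.na(values)]))
  n <- length(x)
  if (n < 2L || x[1L] == x[n])
    stop(errorCondition(
      paste0("no valid step threshold for feature ", feature_id,
             ": fewer than 2 distinct non-missing values"),
      class = c("no_valid_threshold", "error", "condition")))
  mu <- mean(x)
  xc <- x - mu
  cs <- cumsum(xc)
  tot <- cs[n]
  ss <- sum(xc^2)
  b <- seq_len(n - 1L)
  s1 <- cs[b]
  sse <- ss - s1^2 / b - (tot - s1)^2 / (n - b)
  bi <- which(sse <= min(sse) + 1e-8 * ss)[1L]  # near-ties -> smallest b
  m1 <- mu + s1[bi] / bi
  m2 <- mu + (tot - s1[bi]) / (n - bi)
  structure(list(feature_id = feature_id,
                 threshold = (m1 + m2) / 2,
                 breakpoint_index = bi,
                 sse = max(sse[bi], 0),
                 n_used = n),
            class = "step_threshold")
}

#' Fit step thresholds for every row of an expression matrix
#'
#' Features with fewer than two distinct non-missing values admit no step
#' and are excluded (listed in the \code{"excluded"} attribute).
#'
#' @param m numeric matrix, features in rows, samples in columns.
#' @return data.frame with one row per fitted feature: \code{feature_id},
#'   \code{threshold}, \code{breakpoint_index}, \code{sse}, \code{n_used}.
#' @export
fit_step_thresholds <- function(m) {
  fits <- lapply(rownames(m), function(f) {
    tryCatch(fit_step_threshold(m[f, ], f),
             no_valid_threshold = function(e) NULL)
  })
  keep <- !vapply(fits, is.null, logical(1))
  out <- do.call(rbind, lapply(fits[keep], function(t)
    data.frame(feature_id = t$feature_id, threshold = t$threshold,
               breakpoint_index = t$breakpoint_index, sse = t$sse,
               n_used = t$n_used, stringsAsFactors = FALSE)))
  if (is.null(out))
    out <- data.frame(feature_id = character(), threshold = numeric(),
                      breakpoint_index = integer(), sse = numeric(),
                      n_used = integer(), stringsAsFactors = FALSE)
  attr(out, "excluded") <- rownames(m)[!keep]
  out
}

#' Assign high/low expression classes under a fixed threshold
#'
#' Values strictly above the threshold are \code{"high"}, values at or
#' below are \code{"low"} (ties go to low for determinism); missing values
#' stay unlabeled (\code{NA}).
#'
#' @param values named numeric vector (names are sample ids).
#' @param threshold a \code{step_threshold} object or a plain number.
#' @return named character vector of \code{"low"}/\code{"high"}/\code{NA}.
#' @export
assign_classes <- function(values, threshold) {
  if (inherits(threshold, "step_threshold")) threshold <- threshold$threshold
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  out <- ifelse(is.na(values), NA_character_,
                ifelse(values > threshold, "high", "low"))
  names(out) <- names(values)
  out
}

#' @export
print.step_threshold <- function(x, ...) {
  cat(sprintf("step threshold for %s: %.4g (low segment %d of %d, SSE %.4g)\n",
              x$feature_id, x$threshold, x$breakpoint_index, x$n_used, x$sse))
  invisible(x)
}
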