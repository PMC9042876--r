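#' Build cancer-drug groups
#'
#' Assigns every eligible patient to one group per (cancer type, drug)
#' combination they belong to; a patient exposed to several drugs is a
#' member of several groups. Eligibility requires a clinical record (cancer
#' type plus survival outcome), a standardized drug record (records mapped
#' to \code{UNMAPPED} are excluded), and an expression profile. Groups
#' smaller than \code{min_group_size} are dropped.
#'
#' Duplicate treatment records of the same drug count once (set semantics).
#'
#' @param clinical data.frame from \code{\link{read_clinical}}.
#' @param drugs data.frame from \code{\link{standardize_drugs}} (or any
#'   table with \code{patient_id} and \code{standardized_name}).
#' @param expression expression matrix whose columns define which patients
#'   have expression data.
#' @param min_group_size minimum eligible patients per group (default 15).
#' @return data.frame with columns \code{cancer_type}, \code{drug},
#'   \code{n} and a list column \code{patient_ids}, ordered by cancer then
#'   drug.
#' @export
build_groups <- function(clinical, drugs, expression, min_group_size = 15L) {
  if (!"standardized_name" %in% names(drugs))
    stop("drug records must be standardized first (standardize_drugs)", call. = FALSE)
  d <- drugs[drugs$standardized_name != UNMAPPED,
             c("patient_id", "standardized_name")]
  d <- unique(d)
  d <- d[d$patient_id %in% clinical$patient_id &
           d$patient_id %in% colnames(expression), , drop = FALSE]
  d$cancer_type <- clinical$cancer_type[match(d$patient_id, clinical$patient_id)]
  if (nrow(d) == 0L)
    return(data.frame(cancer_type = character(), drug = character(),
                      n = integer(), patient_ids = I(list())))
  key <- paste(d$cancer_type, d$standardized_name, sep = "\r")
  members <- lapply(split(d$patient_id, key), sort)
  members <- members[order(names(members))]
  parts <- do.call(rbind, strsplit(names(members), "\r", fixed = TRUE))
  out <- data.frame(cancer_type = parts[, 1L], drug = parts[, 2L],
                    n = lengths(members), stringsAsFactors = FALSE)
  out$patient_ids <- I(unname(members))
  out <- out[out$n >= min_group_size, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate feature-by-group combinations
#'
#' The Cartesian product of selected cancer-drug groups and features, i.e.
#' every (feature, group) pair the screen will consider before the
#' class-size gate is applied.
#'
#' @param groups data.frame from \code{\link{build_groups}} (only
#'   \code{cancer_type} and \code{drug} are used).
#' @param feature_ids character vector of feature ids.
#' @return data.frame with columns \code{cancer_type}, \code{drug},
#'   \code{feature_id}; its row count is the number of combinations.
#' @export
enumerate_combinations <- function(groups, feature_ids) {
  if (nrow(groups) == 0L || length(feature_ids) == 0L)
    return(data.frame(cancer_type = character(), drug = character(),
                      feature_id = character(), stringsAsFactors = FALSE))
  idx <- rep(seq_len(nrow(groups)), times = length(feature_ids))
  data.frame(cancer_type = groups$cancer_type[idx],
             drug = groups$drug[idx],
             feature_id = rep(feature_ids, each = nrow(groups)),
             stringsAsFactors = FALSE)
}

# Screen a fixed patient set for survival association of each feature.
# Shared by the group screen, the cancer-wide contrast and the gene screen.
screen_patient_set <- function(patient_ids, features, expression, thresholds,
                               clinical, min_class_size = 5L) {
  thr <- stats::setNames(thresholds$threshold, thresholds$feature_id)
  surv <- clinical[match(patient_ids, clinical$patient_id), ]
  rows <- lapply(features, function(f) {
    base <- data.frame(feature_id = f, n_low = NA_integer_,
                       n_high = NA_integer_, tested = FALSE,
                       logrank_stat = NA_real_, p_value = NA_real_,
                       better_survival_class = NA_character_,
                       gate_reason = NA_character_, stringsAsFactors = FALSE)
    if (!f %in% names(thr) || !f %in% rownames(expression)) {
      base$gate_reason <- "no_threshold"
      return(base)
    }
    cls <- assign_classes(expression[f, patient_ids], thr[[f]])
    ok <- !is.na(cls)
    base$n_low <- sum(cls[ok] == "low")
    base$n_high <- sum(cls[ok] == "high")
    if (base$n_low < min_class_size || base$n_high < min_class_size) {
      base$gate_reason <- "class_size"
      return(base)
    }
    lr <- logrank_test(surv$survival_time[ok], surv$event[ok], cls[ok])
    base$tested <- TRUE
    base$logrank_stat <- lr$statistic
    base$p_value <- lr$p_value
    base$better_survival_class <-
      better_survival_class(surv$survival_time[ok], surv$event[ok], cls[ok])
    base
  })
  do.call(rbind, rows)
}

#' Screen one cancer-drug group
#'
#' For each feature, assigns high/low classes within the group using the
#' globally fitted step threshold, skips features with fewer than
#' \code{min_class_size} patients in either class (recorded as gated), runs
#' the log-rank test between classes, and finally applies Benjamini-Hochberg
#' adjustment over the p-values of the features actually tested in this
#' group. The better-surviving class is determined by restricted mean
#' survival over the common follow-up window.
#'
#' @param group one-row slice of the \code{\link{build_groups}} result (or
#'   a list with \code{cancer_type}, \code{drug}, \code{patient_ids}).
#' @param expression feature-by-sample matrix.
#' @param thresholds threshold table from \code{\link{fit_step_thresholds}}.
#' @param clinical clinical table.
#' @param features features to test (default: all fitted thresholds).
#' @param min_class_size class-size gate (default 5).
#' @return data.frame with one row per feature: class sizes, gate status,
#'   log-rank statistic and p-value, group-wise \code{fdr}, and the
#'   better-surviving class.
#' @export
screen_group <- function(group, expression, thresholds, clinical,
                         features = thresholds$feature_id,
                         min_class_size = 5L) {
  pid <- if (is.data.frame(group)) group$patient_ids[[1L]] else group$patient_ids
  out <- screen_patient_set(pid, features, expression, thresholds, clinical,
                            min_class_size)
  ct <- if (is.data.frame(group)) group$cancer_type[1L] else group$cancer_type
  dr <- if (is.data.frame(group)) group$drug[1L] else group$drug
  out <- cbind(cancer_type = ct, drug = dr, out, stringsAsFactors = FALSE)
  out$fdr <- NA_real_
  out$fdr[out$tested] <- bh_adjust(out$p_value[out$tested])
  out
}

#' Screen every cancer-drug group
#'
#' Runs \code{\link{screen_group}} for each group. With
#' \code{fdr_scope = "per_group"} (the default) the BH adjustment is applied
#' within each group across its tested features; with \code{"global"} a
#' single adjustment is applied across all tested (feature, group) pairs.
#'
#' @inheritParams screen_group
#' @param groups data.frame from \code{\link{build_groups}}.
#' @param fdr_scope \code{"per_group"} or \code{"global"}.
#' @return row-bound screen table over all groups.
#' @export
screen_cohort <- function(groups, expression, thresholds, clinical,
                          features = thresholds$feature_id,
                          min_class_size = 5L,
                          fdr_scope = c("per_group", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  res <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i)
    screen_group(groups[i, ], expression, thresholds, clinical,
                 features, min_class_size)))
  if (is.null(res))
    return(data.frame())
  if (fdr_scope == "global") {
    res$fdr <- NA_real_
    res$fdr[res$tested] <- bh_adjust(res$p_value[res$tested])
  }
  rownames(res) <- NULL
  res
}

#' Flag drug-specific markers by the cancer-wide contrast
#'
#' A feature significant within a cancer-drug group is only a
#' \emph{drug-specific} marker if the same test run on all patients of that
#' cancer type is not significant. For each cancer type the identical
#' screen (same global thresholds, same class-size gate) is run over all
#' patients of the cancer with expression data, BH-adjusted across all
#' features tested cancer-wide; a group-significant feature is flagged
#' drug-specific when its cancer-level adjusted value is at or above
#' \code{fdr_threshold} (mode \code{"adjusted"}) or its raw cancer-level
#' p-value is at or above \code{cancer_alpha} (mode \code{"raw"}). A
#' feature gated cancer-wide counts as not significant cancer-wide.
#'
#' @param group_results output of \code{\link{screen_cohort}}.
#' @param clinical,expression,thresholds as in \code{\link{screen_group}}.
#' @param fdr_threshold group-level significance threshold (default 0.1).
#' @param mode cancer-level comparison on \code{"adjusted"} (default) or
#'   \code{"raw"} p-values.
#' @param cancer_alpha raw-p threshold used when \code{mode = "raw"}.
#' @param min_class_size class-size gate, as in the group screen.
#' @return \code{group_results} with added columns \code{cancer_level_p}
#'   (adjusted or raw, per mode; NA when gated cancer-wide) and
#'   \code{drug_specific}.
#' @export
drug_specific_filter <- function(group_results, clinical, expression,
                                 thresholds, fdr_threshold = 0.1,
                                 mode = c("adjusted", "raw"),
                                 cancer_alpha = 0.1,
                                 min_class_size = 5L) {
  mode <- match.arg(mode)
  group_results$group_significant <-
    !is.na(group_results$fdr) & group_results$fdr < fdr_threshold
  group_results$cancer_level_p <- NA_real_
  group_results$drug_specific <- FALSE
  for (ct in unique(group_results$cancer_type)) {
    pats <- clinical$patient_id[clinical$cancer_type == ct]
    pats <- intersect(pats, colnames(expression))
    cw <- screen_patient_set(pats, thresholds$feature_id, expression,
                             thresholds, clinical, min_class_size)
    cw$fdr <- NA_real_
    cw$fdr[cw$tested] <- bh_adjust(cw$p_value[cw$tested])
    val <- if (mode == "adjusted") cw$fdr else cw$p_value
    thr <- if (mode == "adjusted") fdr_threshold else cancer_alpha
    sel <- group_results$cancer_type == ct
    m <- match(group_results$feature_id[sel], cw$feature_id)
    group_results$cancer_level_p[sel] <- val[m]
    cw_sig <- !is.na(val[m]) & val[m] < thr
    group_results$drug_specific[sel] <- group_results$group_significant[sel] & !cw_sig
  }
  group_results
}
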