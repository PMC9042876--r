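#' @importFrom stats lm coef complete.cases var
NULL

#' Screen target genes of drug-specific miRNA markers
#'
#' For each cancer-drug group holding at least one drug-specific miRNA
#' marker, tests every known target gene of that group's marker miRNAs for
#' survival association, with the same machinery as the miRNA screen:
#' classes from the globally fitted gene step thresholds, the class-size
#' gate, log-rank, and Benjamini-Hochberg adjustment across the genes
#' tested within the group. Genes with adjusted values below
#' \code{gene_fdr} are flagged significant.
#'
#' @param markers data.frame of drug-specific miRNA markers (rows of the
#'   screen table with \code{drug_specific = TRUE}); needs columns
#'   \code{cancer_type}, \code{drug}, \code{feature_id}.
#' @param pairs miRNA-target pair table (\code{\link{read_target_pairs}}).
#' @param gene_expression gene-by-sample matrix.
#' @param gene_thresholds gene threshold table.
#' @param clinical clinical table.
#' @param groups group table from \code{\link{build_groups}}.
#' @param gene_fdr gene-level FDR threshold (default 0.01).
#' @param min_class_size class-size gate (default 5).
#' @return data.frame with one row per (group, target gene): screen columns
#'   plus \code{significant}; attribute \code{"no_target_mirnas"} lists
#'   marker miRNAs without any known target.
#' @export
screen_targets <- function(markers, pairs, gene_expression, gene_thresholds,
                           clinical, groups, gene_fdr = 0.01,
                           min_class_size = 5L) {
  empty <- data.frame(cancer_type = character(), drug = character(),
                      feature_id = character(), n_low = integer(),
                      n_high = integer(), tested = logical(),
                      logrank_stat = numeric(), p_value = numeric(),
                      better_survival_class = character(),
                      gate_reason = character(), fdr = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (nrow(markers) == 0L) return(empty)
  no_targets <- setdiff(unique(markers$feature_id), unique(pairs$mirna_id))
  gkey <- paste(markers$cancer_type, markers$drug, sep = "\r")
  out <- lapply(unique(gkey), function(k) {
    mk <- markers[gkey == k, , drop = FALSE]
    gi <- which(groups$cancer_type == mk$cancer_type[1L] &
                  groups$drug == mk$drug[1L])
    if (!length(gi)) return(NULL)
    genes <- unique(pairs$gene_id[pairs$mirna_id %in% mk$feature_id])
    genes <- intersect(genes, gene_thresholds$feature_id)
    if (!length(genes)) return(NULL)
    res <- screen_group(groups[gi, ], gene_expression, gene_thresholds,
                        clinical, features = genes,
                        min_class_size = min_class_size)
    res$significant <- !is.na(res$fdr) & res$fdr < gene_fdr
    res
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  attr(out, "no_target_mirnas") <- no_targets
  out
}

#' Form miRNA-mediated gene-cancer-drug combinations
#'
#' One combination per (drug-specific miRNA marker, significant target gene
#' of that miRNA) within the same cancer-drug group. A gene significant for
#' two marker miRNAs of one group yields two combinations.
#'
#' @param mirna_markers drug-specific miRNA marker rows (with \code{fdr}).
#' @param gene_results output of \code{\link{screen_targets}}.
#' @param pairs miRNA-target pair table.
#' @return data.frame with columns \code{cancer_type}, \code{drug},
#'   \code{mirna_id}, \code{mirna_fdr}, \code{mirna_direction},
#'   \code{gene_id}, \code{gene_fdr}, \code{gene_direction},
#'   \code{regulation}.
#' @export
mediated_combinations <- function(mirna_markers, gene_results, pairs) {
  empty <- data.frame(cancer_type = character(), drug = character(),
                      mirna_id = character(), mirna_fdr = numeric(),
                      mirna_direction = character(), gene_id = character(),
                      gene_fdr = numeric(), gene_direction = character(),
                      regulation = character(), stringsAsFactors = FALSE)
  if (nrow(mirna_markers) == 0L || nrow(gene_results) == 0L) return(empty)
  sig_genes <- gene_results[gene_results$significant, , drop = FALSE]
  if (nrow(sig_genes) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(mirna_markers)), function(i) {
    m <- mirna_markers[i, ]
    tg <- pairs[pairs$mirna_id == m$feature_id, , drop = FALSE]
    g <- sig_genes[sig_genes$cancer_type == m$cancer_type &
                     sig_genes$drug == m$drug &
                     sig_genes$feature_id %in% tg$gene_id, , drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    data.frame(cancer_type = m$cancer_type, drug = m$drug,
               mirna_id = m$feature_id, mirna_fdr = m$fdr,
               mirna_direction = paste0(m$better_survival_class, "_better"),
               gene_id = g$feature_id, gene_fdr = g$fdr,
               gene_direction = paste0(g$better_survival_class, "_better"),
               regulation = tg$regulation[match(g$feature_id, tg$gene_id)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Simple linear association between miRNA and target-gene expression
#'
#' Ordinary least-squares fit of gene expression on miRNA expression over
#' paired samples, returning the slope and the two-sided t-test p-value for
#' zero slope.
#'
#' @param mirna_values,gene_values paired numeric vectors.
#' @return list with \code{slope}, \code{p_value}, \code{n}.
#' @export
expression_correlation <- function(mirna_values, gene_values) {
  ok <- stats::complete.cases(mirna_values, gene_values)
  x <- mirna_values[ok]; y <- gene_values[ok]
  if (length(x) < 3L)
    stop("expression correlation needs at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0)
    stop("zero variance in miRNA expression", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["x", "Estimate"]),
       p_value = unname(sm["x", "Pr(>|t|)"]),
       n = length(x))
}

#' Classify miRNA-target survival-direction consistency
#'
#' For an inhibitory miRNA-target pair the survival associations are
#' consistent when the directions are opposite: high miRNA with low gene
#' (or low miRNA with high gene) giving better survival. For an activating
#' pair they are consistent when the directions agree. With unknown
#' regulation the verdict is unknown.
#'
#' @param regulation \code{"inhibit"}, \code{"activate"} or
#'   \code{"unknown"} (vectorized).
#' @param mirna_direction,gene_direction \code{"high_better"} or
#'   \code{"low_better"}.
#' @return character vector of \code{"consistent"}, \code{"inconsistent"},
#'   \code{"unknown"}.
#' @export
classify_consistency <- function(regulation, mirna_direction, gene_direction) {
  stopifnot(all(regulation %in% c("inhibit", "activate", "unknown")),
            all(is.na(mirna_direction) |
                  mirna_direction %in% c("high_better", "low_better")),
            all(is.na(gene_direction) |
                  gene_direction %in% c("high_better", "low_better")))
  known <- regulation != "unknown" &
    !is.na(mirna_direction) & !is.na(gene_direction)
  agree <- mirna_direction == gene_direction
  out <- ifelse(!known, "unknown",
                ifelse(regulation == "inhibit",
                       ifelse(agree, "inconsistent", "consistent"),
                       ifelse(agree, "consistent", "inconsistent")))
  as.character(out)
}

#' Expression correlation and consistency verdict for each combination
#'
#' For every miRNA-mediated combination, fits the miRNA-gene expression
#' association on the patients of that combination's cancer-drug group,
#' flags non-significant correlations (retained, not dropped), and
#' classifies survival-direction consistency against the pair's regulatory
#' direction.
#'
#' @param combos output of \code{\link{mediated_combinations}}.
#' @param mirna_expression,gene_expression expression matrices.
#' @param groups group table from \code{\link{build_groups}}.
#' @param corr_alpha significance level for the correlation flag
#'   (default 0.05).
#' @return \code{combos} with added columns \code{corr_slope},
#'   \code{corr_p}, \code{corr_n}, \code{corr_significant}, \code{verdict}.
#' @export
concordance_table <- function(combos, mirna_expression, gene_expression,
                              groups, corr_alpha = 0.05) {
  combos$corr_slope <- rep(NA_real_, nrow(combos))
  combos$corr_p <- rep(NA_real_, nrow(combos))
  combos$corr_n <- rep(NA_integer_, nrow(combos))
  for (i in seq_len(nrow(combos))) {
    gi <- which(groups$cancer_type == combos$cancer_type[i] &
                  groups$drug == combos$drug[i])
    pid <- groups$patient_ids[[gi[1L]]]
    cc <- expression_correlation(mirna_expression[combos$mirna_id[i], pid],
                                 gene_expression[combos$gene_id[i], pid])
    combos$corr_slope[i] <- cc$slope
    combos$corr_p[i] <- cc$p_value
    combos$corr_n[i] <- cc$n
  }
  combos$corr_significant <- !is.na(combos$corr_p) & combos$corr_p < corr_alpha
  combos$verdict <- classify_consistency(combos$regulation,
                                         combos$mirna_direction,
                                         combos$gene_direction)
  combos
}
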