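#' @importFrom grDevices png dev.off
#' @importFrom graphics legend lines plot
NULL

#' Pipeline configuration
#'
#' Collects input paths, column maps and the screening constants: minimum
#' group size 15, minimum class size 5 per expression class, miRNA marker
#' FDR threshold 0.1, target-gene FDR threshold 0.01, and correlation
#' significance level 0.05.
#'
#' @param clinical,drugs,mirna paths to the clinical table, raw drug
#'   records and miRNA expression matrix (required).
#' @param genes,pairs paths to gene expression and miRNA-target pairs;
#'   when either is NULL the target-gene stage is skipped.
#' @param drug_map path to a raw-to-canonical drug-name table with columns
#'   \code{raw}, \code{canonical}; NULL means names are already canonical
#'   (an identity mapping is built from the observed names).
#' @param out_dir output directory.
#' @param clinical_columns column map passed to \code{\link{read_clinical}}.
#' @param min_group_size,min_class_size,mirna_fdr,gene_fdr,corr_alpha
#'   screening constants (see above).
#' @param fdr_scope \code{"per_group"} or \code{"global"}.
#' @param cancer_specificity_mode \code{"adjusted"} or \code{"raw"}.
#' @param cancer_alpha raw-p threshold for mode \code{"raw"}.
#' @param make_plots also write PNG Kaplan-Meier plots for each
#'   drug-specific marker.
#' @param seed integer seed (recorded in the manifest; the pipeline itself
#'   is deterministic given its inputs).
#' @return validated list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(clinical, drugs, mirna, genes = NULL,
                            pairs = NULL, drug_map = NULL, out_dir,
                            clinical_columns = list(patient = "patient_id",
                                                    cancer = "cancer_type",
                                                    time = "survival_time",
                                                    event = "event"),
                            min_group_size = 15L, min_class_size = 5L,
                            mirna_fdr = 0.1, gene_fdr = 0.01,
                            corr_alpha = 0.05,
                            fdr_scope = c("per_group", "global"),
                            cancer_specificity_mode = c("adjusted", "raw"),
                            cancer_alpha = 0.1, make_plots = FALSE,
                            seed = 1L) {
  stopifnot(min_group_size >= 1, min_class_size >= 1,
            mirna_fdr >= 0, mirna_fdr <= 1, gene_fdr >= 0, gene_fdr <= 1,
            corr_alpha > 0, corr_alpha < 1, cancer_alpha > 0, cancer_alpha <= 1)
  structure(list(clinical = clinical, drugs = drugs, mirna = mirna,
                 genes = genes, pairs = pairs, drug_map = drug_map,
                 out_dir = out_dir, clinical_columns = clinical_columns,
                 min_group_size = as.integer(min_group_size),
                 min_class_size = as.integer(min_class_size),
                 mirna_fdr = mirna_fdr, gene_fdr = gene_fdr,
                 corr_alpha = corr_alpha,
                 fdr_scope = match.arg(fdr_scope),
                 cancer_specificity_mode = match.arg(cancer_specificity_mode),
                 cancer_alpha = cancer_alpha, make_plots = make_plots,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

log_line <- function(con, stage, level, msg) {
  writeLines(sprintf("[%s] %s: %s", stage, level, msg), con)
}

#' Run the full drug-specific marker discovery pipeline
#'
#' Executes binarization, group building, the per-group miRNA screen, the
#' cancer-wide drug-specificity contrast, the target-gene screen,
#' combination building and concordance classification, writing every
#' output table plus a run manifest and a line-oriented log to
#' \code{config$out_dir}. Identical config and inputs produce identical
#' outputs. On error, files written by the failed run are removed.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return the manifest: a list of output paths and summary counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$clinical, config$drugs, config$mirna,
              config$genes, config$pairs, config$drug_map))
    if (!is.null(p) && !file.exists(p))
      stop("input path does not exist: ", p, call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  out <- function(name) {
    p <- file.path(config$out_dir, name)
    written <<- c(written, p)
    p
  }
  log_path <- file.path(config$out_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  ok <- FALSE
  on.exit({
    if (!ok) unlink(c(written, log_path))
  }, add = TRUE)

  log_line(con, "load", "INFO", paste("run started", format(Sys.time())))
  clinical <- read_clinical(config$clinical, config$clinical_columns)
  log_line(con, "load", "INFO",
           sprintf("clinical: %d patients, %d rows dropped", nrow(clinical),
                   attr(clinical, "drop_report")$n_dropped))
  drugs_raw <- read_tsv_checked(config$drugs)
  if (!all(c("patient_id", "raw_name") %in% names(drugs_raw)))
    stop("drug records need columns patient_id, raw_name", call. = FALSE)
  mapping <- if (!is.null(config$drug_map)) {
    read_tsv_checked(config$drug_map)
  } else {
    nm <- unique(drugs_raw$raw_name)
    data.frame(raw = nm, canonical = normalize_drug_name(nm),
               stringsAsFactors = FALSE)
  }
  drugs <- standardize_drugs(drugs_raw, mapping)
  log_line(con, "load", "INFO",
           sprintf("drugs: %d records, %d unmapped", nrow(drugs),
                   attr(drugs, "n_unmapped")))
  mirna <- read_expression(config$mirna)

  thresholds <- fit_step_thresholds(mirna)
  log_line(con, "binarize", "INFO",
           sprintf("miRNA thresholds: %d fitted, %d excluded",
                   nrow(thresholds), length(attr(thresholds, "excluded"))))
  write_tsv(thresholds, out("mirna_thresholds.tsv"))

  groups <- build_groups(clinical, drugs, mirna, config$min_group_size)
  census <- groups[, c("cancer_type", "drug", "n")]
  write_tsv(census, out("group_census.tsv"))
  log_line(con, "groups", "INFO", sprintf("%d cancer-drug groups", nrow(groups)))

  combos_all <- enumerate_combinations(groups, thresholds$feature_id)
  screen <- screen_cohort(groups, mirna, thresholds, clinical,
                          min_class_size = config$min_class_size,
                          fdr_scope = config$fdr_scope)
  screen <- drug_specific_filter(screen, clinical, mirna, thresholds,
                                 fdr_threshold = config$mirna_fdr,
                                 mode = config$cancer_specificity_mode,
                                 cancer_alpha = config$cancer_alpha,
                                 min_class_size = config$min_class_size)
  marker_tbl <- screen[, c("cancer_type", "drug", "feature_id", "n_low",
                           "n_high", "logrank_stat", "p_value", "fdr",
                           "cancer_level_p", "drug_specific")]
  write_tsv(marker_tbl, out("markers.tsv"))
  ds <- screen[screen$drug_specific, , drop = FALSE]
  write_tsv(ds[, names(marker_tbl)], out("drug_specific_markers.tsv"))
  for (g in unique(paste(screen$cancer_type, screen$drug, sep = "\r")))
    log_line(con, "screen", "INFO",
             sprintf("group %s: %d tested, %d gated",
                     gsub("\r", "/", g),
                     sum(screen$tested[paste(screen$cancer_type,
                                             screen$drug, sep = "\r") == g]),
                     sum(!screen$tested[paste(screen$cancer_type,
                                              screen$drug, sep = "\r") == g])))

  km_dir <- file.path(config$out_dir, "km")
  dir.create(km_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(ds))) {
    gi <- which(groups$cancer_type == ds$cancer_type[i] &
                  groups$drug == ds$drug[i])
    pid <- groups$patient_ids[[gi]]
    cls <- assign_classes(mirna[ds$feature_id[i], pid],
                          thresholds$threshold[thresholds$feature_id ==
                                                 ds$feature_id[i]])
    okc <- !is.na(cls)
    surv <- clinical[match(pid[okc], clinical$patient_id), ]
    km <- km_by_class(surv$survival_time, surv$event, cls[okc])
    stem <- sprintf("%s_%s_%s", ds$cancer_type[i], ds$drug[i], ds$feature_id[i])
    p <- file.path(km_dir, paste0(stem, ".tsv"))
    written <- c(written, p)
    write_tsv(km, p)
    if (isTRUE(config$make_plots)) {
      pf <- file.path(km_dir, paste0(stem, ".png"))
      written <- c(written, pf)
      grDevices::png(pf, width = 600, height = 480)
      plot_km(surv$survival_time, surv$event, cls[okc], main = stem)
      grDevices::dev.off()
    }
  }

  gene_results <- NULL
  combos <- NULL
  concord <- NULL
  if (!is.null(config$genes) && !is.null(config$pairs)) {
    gene <- read_expression(config$genes)
    pairs <- read_target_pairs(config$pairs)
    gene_thresholds <- fit_step_thresholds(gene)
    write_tsv(gene_thresholds, out("gene_thresholds.tsv"))
    gene_results <- screen_targets(ds, pairs, gene, gene_thresholds,
                                   clinical, groups,
                                   gene_fdr = config$gene_fdr,
                                   min_class_size = config$min_class_size)
    write_tsv(gene_results, out("gene_screen.tsv"))
    combos <- mediated_combinations(ds, gene_results, pairs)
    if (nrow(combos))
      combos <- concordance_table(combos, mirna, gene, groups,
                                  corr_alpha = config$corr_alpha)
    else
      combos <- cbind(combos, corr_slope = numeric(), corr_p = numeric(),
                      corr_n = integer(), corr_significant = logical(),
                      verdict = character())
    write_tsv(combos, out("combinations.tsv"))
    concord <- data.frame(verdict = c("consistent", "inconsistent", "unknown"),
                          n = c(sum(combos$verdict == "consistent"),
                                sum(combos$verdict == "inconsistent"),
                                sum(combos$verdict == "unknown")))
    write_tsv(concord, out("consistency_summary.tsv"))
    log_line(con, "targets", "INFO",
             sprintf("%d genes screened, %d significant, %d combinations",
                     nrow(gene_results), sum(gene_results$significant),
                     nrow(combos)))
  }

  manifest <- list(
    out_dir = config$out_dir,
    n_patients = nrow(clinical),
    n_groups = nrow(groups),
    n_features = nrow(thresholds),
    combinations_enumerated = nrow(combos_all),
    combinations_tested = sum(screen$tested),
    combinations_gated = sum(!screen$tested),
    n_group_significant = sum(screen$group_significant),
    n_drug_specific = sum(screen$drug_specific),
    n_genes_tested = if (is.null(gene_results)) NA_integer_
                     else sum(gene_results$tested),
    n_gene_significant = if (is.null(gene_results)) NA_integer_
                         else sum(gene_results$significant),
    n_combinations = if (is.null(combos)) NA_integer_ else nrow(combos),
    n_consistent = if (is.null(concord)) NA_integer_
                   else concord$n[concord$verdict == "consistent"],
    n_inconsistent = if (is.null(concord)) NA_integer_
                     else concord$n[concord$verdict == "inconsistent"],
    n_unknown = if (is.null(concord)) NA_integer_
                else concord$n[concord$verdict == "unknown"],
    seed = config$seed)
  persist <- setdiff(names(manifest), "out_dir")  # paths vary run to run
  mdf <- data.frame(key = persist,
                    value = vapply(manifest[persist], function(v)
                      paste(as.character(v), collapse = ";"), character(1)))
  write_tsv(mdf, out("manifest.tsv"))
  log_line(con, "done", "INFO", "pipeline finished")
  ok <- TRUE
  manifest
}

#' Kaplan-Meier plot for a two-class split
#'
#' @param time,event survival data.
#' @param class class labels.
#' @param main plot title.
#' @return invisibly NULL; draws on the current device.
#' @export
plot_km <- function(time, event, class, main = "") {
  cls <- sort(unique(class))
  cols <- c("#1b7837", "#762a83")[seq_along(cls)]
  plot(NULL, xlim = c(0, max(time)), ylim = c(0, 1),
       xlab = "days", ylab = "survival probability", main = main)
  for (i in seq_along(cls)) {
    km <- km_estimate(time[class == cls[i]], event[class == cls[i]])
    lines(c(km$time, max(time)), c(km$survival, km$survival[nrow(km)]),
          type = "s", col = cols[i], lwd = 2)
  }
  legend("bottomleft", legend = cls, col = cols, lwd = 2, bty = "n")
  invisible(NULL)
}
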