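#' @importFrom stats rnorm rexp rbinom
NULL

#' Configuration for the synthetic TCGA-like cohort generator
#'
#' The generator emulates the statistical structure the screening pipeline
#' assumes: a pan-cancer cohort in which patients carry cancer-type labels,
#' per-patient drug exposures, log-scale miRNA and gene expression, and
#' right-censored survival. Planted marker miRNAs are bimodal mixtures whose
#' high/low class shifts the death hazard only inside one (cancer, drug)
#' group; all other miRNAs are unimodal null features. Planted target genes
#' are decreasing affine functions of their miRNA plus noise and are emitted
#' as \code{inhibit}-regulation target pairs.
#'
#' @param n_cancer_types number of cancer-type labels.
#' @param patients_per_cancer patients per cancer type.
#' @param drugs_per_cancer size of the drug pool (shared across cancers,
#'   as chemotherapy agents are in practice).
#' @param drug_exposure_prob per-drug exposure fraction; each (cancer, drug)
#'   pair exposes exactly \code{round(patients_per_cancer *
#'   drug_exposure_prob)} randomly chosen patients, so a patient can belong
#'   to several cancer-drug groups.
#' @param n_mirnas,n_genes numbers of miRNA and gene features.
#' @param planted_markers data.frame with columns \code{cancer_type},
#'   \code{drug}, \code{mirna_id}, \code{hazard_ratio} and a comma-separated
#'   \code{target_gene_ids} column (may be empty strings).
#' @param bimodal_params list with \code{low_mean}, \code{high_mean},
#'   \code{sd}, \code{high_fraction} for planted-marker expression.
#' @param baseline_hazard death hazard per day for unaffected patients.
#' @param censoring_rate independent exponential censoring hazard per day.
#' @param max_follow_up administrative study-end cap in days: patients
#'   still at risk at this time are censored there, as in a real cohort
#'   with a fixed follow-up window. Default \code{Inf} (no cap).
#' @param seed integer seed; all randomness flows from it.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_cancer_types = 2L,
                       patients_per_cancer = 150L,
                       drugs_per_cancer = 3L,
                       drug_exposure_prob = 0.25,
                       n_mirnas = 50L,
                       n_genes = 60L,
                       planted_markers = NULL,
                       bimodal_params = list(low_mean = 2, high_mean = 6,
                                             sd = 1, high_fraction = 0.5),
                       baseline_hazard = 1e-3,
                       censoring_rate = 2.5e-4,
                       max_follow_up = Inf,
                       seed = 1L) {
  if (is.null(planted_markers))
    planted_markers <- data.frame(cancer_type = character(),
                                  drug = character(),
                                  mirna_id = character(),
                                  hazard_ratio = numeric(),
                                  target_gene_ids = character(),
                                  stringsAsFactors = FALSE)
  bp <- bimodal_params
  stopifnot(n_cancer_types >= 1, patients_per_cancer >= 1,
            drugs_per_cancer >= 1, drug_exposure_prob > 0,
            drug_exposure_prob <= 1, n_mirnas >= 1, n_genes >= 0,
            all(planted_markers$hazard_ratio > 0),
            bp$high_fraction > 0, bp$high_fraction < 1,
            bp$low_mean < bp$high_mean, bp$sd > 0,
            baseline_hazard > 0, censoring_rate > 0, max_follow_up > 0)
  structure(list(n_cancer_types = as.integer(n_cancer_types),
                 patients_per_cancer = as.integer(patients_per_cancer),
                 drugs_per_cancer = as.integer(drugs_per_cancer),
                 drug_exposure_prob = drug_exposure_prob,
                 n_mirnas = as.integer(n_mirnas),
                 n_genes = as.integer(n_genes),
                 planted_markers = planted_markers,
                 bimodal_params = bp,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 max_follow_up = max_follow_up,
                 seed = as.integer(seed)),
            class = "sim_config")
}

split_gene_ids <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, ",")[[1L]]
}

#' Generate a synthetic cohort with planted drug-specific markers
#'
#' Survival times are exponential with hazard
#' \code{baseline_hazard * hazard_ratio^z} where \code{z} is the patient's
#' high-class indicator for a planted miRNA, applied only to patients in
#' that marker's (cancer, drug) exposure group; censoring is independent
#' exponential, the recorded time is the minimum and the event indicator
#' marks whether death came first. A patient covered by several planted
#' markers multiplies their hazard ratios.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{clinical}, \code{drugs} (raw records),
#'   \code{mirna} and \code{gene} expression matrices, \code{pairs}
#'   (miRNA-target table), \code{truth} (the planted-marker table) and
#'   \code{latent_classes} (patients x planted miRNAs high-class matrix).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(config$seed)

  n_pat <- config$n_cancer_types * config$patients_per_cancer
  cancer_types <- sprintf("CT%02d", seq_len(config$n_cancer_types))
  patients <- sprintf("P%05d", seq_len(n_pat))
  cancer_of <- rep(cancer_types, each = config$patients_per_cancer)
  drug_pool <- sprintf("drug%02d", seq_len(config$drugs_per_cancer))
  mirna_ids <- sprintf("mir-%04d", seq_len(config$n_mirnas))
  gene_ids <- if (config$n_genes > 0)
    sprintf("gene-%04d", seq_len(config$n_genes)) else character()

  pm <- config$planted_markers
  if (nrow(pm)) {
    bad <- !(pm$cancer_type %in% cancer_types) | !(pm$drug %in% drug_pool)
    if (any(bad))
      stop("planted marker references a nonexistent cancer/drug: ",
           paste(pm$cancer_type[bad], pm$drug[bad], sep = "/", collapse = ", "),
           call. = FALSE)
    if (!all(pm$mirna_id %in% mirna_ids))
      stop("planted marker references a nonexistent miRNA id", call. = FALSE)
    tg <- unlist(lapply(pm$target_gene_ids, split_gene_ids))
    if (!all(tg %in% gene_ids))
      stop("planted marker references a nonexistent target gene id", call. = FALSE)
  }

  # drug exposure: fixed-count random subset per (cancer, drug)
  n_exp <- max(1L, round(config$patients_per_cancer * config$drug_exposure_prob))
  exposure <- do.call(rbind, lapply(cancer_types, function(ct) {
    idx <- which(cancer_of == ct)
    do.call(rbind, lapply(drug_pool, function(d)
      data.frame(patient_id = patients[sort(sample(idx, n_exp))],
                 raw_name = d, stringsAsFactors = FALSE)))
  }))

  bp <- config$bimodal_params
  mid <- (bp$low_mean + bp$high_mean) / 2
  planted_mirnas <- unique(pm$mirna_id)
  z <- matrix(0L, n_pat, length(planted_mirnas),
              dimnames = list(patients, planted_mirnas))
  mirna <- matrix(NA_real_, config$n_mirnas, n_pat,
                  dimnames = list(mirna_ids, patients))
  for (f in mirna_ids) {
    if (f %in% planted_mirnas) {
      zz <- stats::rbinom(n_pat, 1L, bp$high_fraction)
      z[, f] <- zz
      mirna[f, ] <- stats::rnorm(n_pat,
                                 ifelse(zz == 1L, bp$high_mean, bp$low_mean),
                                 bp$sd)
    } else {
      mirna[f, ] <- stats::rnorm(n_pat, mid, bp$sd)
    }
  }

  planted_genes <- character()
  gene <- matrix(NA_real_, config$n_genes, n_pat,
                 dimnames = list(gene_ids, patients))
  if (config$n_genes > 0) {
    for (i in seq_len(nrow(pm))) {
      for (g in split_gene_ids(pm$target_gene_ids[i])) {
        gene[g, ] <- (bp$low_mean + bp$high_mean) - mirna[pm$mirna_id[i], ] +
          stats::rnorm(n_pat, 0, bp$sd / 2)
        planted_genes <- c(planted_genes, g)
      }
    }
    for (g in setdiff(gene_ids, planted_genes))
      gene[g, ] <- stats::rnorm(n_pat, mid, bp$sd)
  }

  hazard <- rep(config$baseline_hazard, n_pat)
  for (i in seq_len(nrow(pm))) {
    members <- exposure$patient_id[exposure$raw_name == pm$drug[i]]
    members <- members[cancer_of[match(members, patients)] == pm$cancer_type[i]]
    affected <- members[z[members, pm$mirna_id[i]] == 1L]
    hazard[match(affected, patients)] <-
      hazard[match(affected, patients)] * pm$hazard_ratio[i]
  }
  t_death <- stats::rexp(n_pat, hazard)
  t_cens <- pmin(stats::rexp(n_pat, config$censoring_rate),
                 config$max_follow_up)
  clinical <- data.frame(patient_id = patients,
                         cancer_type = cancer_of,
                         survival_time = pmin(t_death, t_cens),
                         event = as.integer(t_death <= t_cens),
                         stringsAsFactors = FALSE)

  # target-pair table: planted inhibitory pairs plus unknown-regulation decoys
  pairs <- data.frame(mirna_id = character(), gene_id = character(),
                      regulation = character(), source = character(),
                      stringsAsFactors = FALSE)
  if (nrow(pm) && config$n_genes > 0) {
    pairs <- do.call(rbind, lapply(seq_len(nrow(pm)), function(i) {
      tg <- split_gene_ids(pm$target_gene_ids[i])
      if (!length(tg)) return(NULL)
      data.frame(mirna_id = pm$mirna_id[i], gene_id = tg,
                 regulation = "inhibit", source = "planted",
                 stringsAsFactors = FALSE)
    }))
    if (is.null(pairs)) pairs <- data.frame(mirna_id = character(),
                                            gene_id = character(),
                                            regulation = character(),
                                            source = character(),
                                            stringsAsFactors = FALSE)
  }
  decoy_genes <- setdiff(gene_ids, planted_genes)
  if (length(decoy_genes)) {
    decoy <- data.frame(mirna_id = sample(mirna_ids, length(decoy_genes),
                                          replace = TRUE),
                        gene_id = decoy_genes,
                        regulation = "unknown", source = "decoy",
                        stringsAsFactors = FALSE)
    pairs <- unique(rbind(pairs, decoy))
  }

  list(clinical = clinical,
       drugs = exposure,
       mirna = mirna,
       gene = gene,
       pairs = pairs,
       truth = pm,
       latent_classes = z)
}

#' Write a generated cohort in the tab-separated dialects the loaders read
#' @param cohort result of \code{\link{generate_cohort}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(clinical = file.path(dir, "clinical.tsv"),
             drugs = file.path(dir, "drugs.tsv"),
             mirna = file.path(dir, "mirna_expression.tsv"),
             gene = file.path(dir, "gene_expression.tsv"),
             pairs = file.path(dir, "target_pairs.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_tsv(cohort$clinical, paths["clinical"])
  write_tsv(cohort$drugs, paths["drugs"])
  write_expression(cohort$mirna, paths["mirna"])
  if (nrow(cohort$gene)) write_expression(cohort$gene, paths["gene"])
  write_tsv(cohort$pairs, paths["pairs"])
  write_tsv(cohort$truth, paths["truth"])
  invisible(paths)
}
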