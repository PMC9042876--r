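# Independent oracles, kept deliberately naive and separate from the
# implementations they check.

# exhaustive step fit: try every breakpoint, compute SSE from segment means
naive_step_fit <- function(v) {
  x <- sort(v[!is.na(v)])
  n <- length(x)
  sse <- vapply(seq_len(n - 1L), function(b) {
    lo <- x[seq_len(b)]; hi <- x[(b + 1L):n]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, numeric(1))
  # same documented tie rule as the implementation: SSE ties (to within a
  # relative tolerance, as produced by duplicated values) go to smallest b
  b <- which(sse <= min(sse) + 1e-8 * sum((x - mean(x))^2))[1L]
  list(breakpoint_index = b, sse = sse[b],
       threshold = (mean(x[seq_len(b)]) + mean(x[(b + 1L):n])) / 2)
}

# direct step-up BH formula
naive_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# hand log-rank: hypergeometric observed-minus-expected sums over event times
naive_logrank <- function(time, event, group) {
  g <- factor(group)
  stopifnot(nlevels(g) == 2L)
  a <- levels(g)[1L]
  oe <- 0; vv <- 0; obs <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & g == a)
    d <- sum(event == 1 & time == t)
    d_a <- sum(event == 1 & time == t & g == a)
    e_a <- d * n_a / n
    v <- if (n > 1) d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1) else 0
    oe <- oe + (d_a - e_a); vv <- vv + v; obs <- obs + d_a
  }
  stat <- if (vv > 0) oe^2 / vv else NA_real_
  list(statistic = stat,
       p_value = if (is.na(stat)) 1 else pchisq(stat, 1, lower.tail = FALSE),
       observed_a = obs)
}

# closed-form simple OLS slope and two-sided t-test p
naive_ols <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  s2 <- sum((y - a - b * x)^2) / (n - 2)
  se <- sqrt(s2 / sum((x - mean(x))^2))
  list(slope = b, p_value = 2 * pt(abs(b / se), n - 2, lower.tail = FALSE))
}

# one-cancer cohort with a single planted marker diluted in a large cancer
# population so the cancer-wide contrast stays quiet
marker_cohort_config <- function(seed, hazard_ratio = 4,
                                 patients = 3200L, exposure = 0.0125,
                                 n_mirnas = 4L, n_genes = 0L,
                                 target_gene_ids = "") {
  pm <- data.frame(cancer_type = "CT01", drug = "drug01",
                   mirna_id = "mir-0001", hazard_ratio = hazard_ratio,
                   target_gene_ids = target_gene_ids,
                   stringsAsFactors = FALSE)
  sim_config(n_cancer_types = 1L, patients_per_cancer = patients,
             drugs_per_cancer = 1L, drug_exposure_prob = exposure,
             n_mirnas = n_mirnas, n_genes = n_genes, planted_markers = pm,
             bimodal_params = list(low_mean = 2, high_mean = 8, sd = 1,
                                   high_fraction = 0.5),
             baseline_hazard = 1e-3, censoring_rate = 2e-5, seed = seed)
}

# run binarize -> groups -> screen -> specificity filter on a cohort
screen_cohort_end_to_end <- function(cohort, min_group_size = 15L,
                                     min_class_size = 5L) {
  thr <- fit_step_thresholds(cohort$mirna)
  drugs <- cohort$drugs
  drugs$standardized_name <- drugs$raw_name
  groups <- build_groups(cohort$clinical, drugs, cohort$mirna, min_group_size)
  res <- screen_cohort(groups, cohort$mirna, thr, cohort$clinical,
                       min_class_size = min_class_size)
  drug_specific_filter(res, cohort$clinical, cohort$mirna, thr,
                       min_class_size = min_class_size)
}
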