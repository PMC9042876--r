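concordant_cohort <- function(seed = 42) {
  # protective planted miRNA (high class survives longer) with two
  # inhibitory target genes, diluted in a large single-cancer cohort
  pm <- data.frame(cancer_type = "CT01", drug = "drug01",
                   mirna_id = "mir-0001", hazard_ratio = 0.25,
                   target_gene_ids = "gene-0001,gene-0002",
                   stringsAsFactors = FALSE)
  sim_config(n_cancer_types = 1L, patients_per_cancer = 4000L,
             drugs_per_cancer = 1L, drug_exposure_prob = 0.015,
             n_mirnas = 6L, n_genes = 8L, planted_markers = pm,
             bimodal_params = list(low_mean = 2, high_mean = 6, sd = 1,
                                   high_fraction = 0.5),
             baseline_hazard = 1e-3, censoring_rate = 2.5e-4, seed = seed)
}

test_that("the consistency truth table matches the stated rule exactly", {
  dirs <- c("high_better", "low_better")
  grid <- expand.grid(reg = c("inhibit", "activate"), m = dirs, g = dirs,
                      stringsAsFactors = FALSE)
  verdicts <- classify_consistency(grid$reg, grid$m, grid$g)
  expected <- ifelse(grid$reg == "inhibit",
                     ifelse(grid$m != grid$g, "consistent", "inconsistent"),
                     ifelse(grid$m == grid$g, "consistent", "inconsistent"))
  expect_equal(verdicts, expected)
  expect_equal(classify_consistency("inhibit", "high_better", "low_better"),
               "consistent")
  expect_equal(classify_consistency("activate", "high_better", "high_better"),
               "consistent")
  expect_equal(classify_consistency("inhibit", "high_better", "high_better"),
               "inconsistent")
  expect_equal(classify_consistency("unknown", "high_better", "low_better"),
               "unknown")
  expect_equal(classify_consistency("inhibit", NA, "low_better"), "unknown")
})

test_that("consistency is invariant under flipping both survival directions", {
  flip <- function(d) ifelse(d == "high_better", "low_better", "high_better")
  for (reg in c("inhibit", "activate"))
    for (m in c("high_better", "low_better"))
      for (g in c("high_better", "low_better"))
        expect_equal(classify_consistency(reg, m, g),
                     classify_consistency(reg, flip(m), flip(g)))
})

test_that("expression correlation matches the closed-form OLS oracle", {
  set.seed(51)
  x <- rnorm(30, 5)
  y <- -2 * x + rnorm(30, 0, 0.1)
  cc <- expression_correlation(x, y)
  ref <- naive_ols(x, y)
  expect_equal(cc$slope, ref$slope, tolerance = 1e-10)
  expect_equal(cc$p_value, ref$p_value, tolerance = 1e-10)
  expect_lt(cc$slope, 0)
  expect_lt(cc$p_value, 0.05)
})

test_that("correlation rejects degenerate inputs and ignores missing pairs", {
  expect_error(expression_correlation(c(1, 2), c(3, 4)), "3 complete pairs")
  expect_error(expression_correlation(rep(2, 10), rnorm(10)), "zero variance")
  set.seed(52)
  x <- rnorm(20); y <- x + rnorm(20, 0, 0.1)
  x[3] <- NA; y[7] <- NA
  expect_equal(expression_correlation(x, y)$n, 18L)
})

test_that("null correlation p-values are roughly uniform over a seed batch", {
  set.seed(53)
  p <- replicate(200, expression_correlation(rnorm(30), rnorm(30))$p_value)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("planted inhibitory targets are recovered and classified consistent", {
  co <- generate_cohort(concordant_cohort())
  thr <- fit_step_thresholds(co$mirna)
  gthr <- fit_step_thresholds(co$gene)
  drugs <- co$drugs; drugs$standardized_name <- drugs$raw_name
  groups <- build_groups(co$clinical, drugs, co$mirna, 15)
  res <- screen_cohort(groups, co$mirna, thr, co$clinical)
  res <- drug_specific_filter(res, co$clinical, co$mirna, thr)
  ds <- res[res$drug_specific, ]
  expect_true("mir-0001" %in% ds$feature_id)

  gr <- screen_targets(ds, co$pairs, co$gene, gthr, co$clinical, groups)
  sig <- gr$feature_id[gr$significant]
  expect_gte(sum(c("gene-0001", "gene-0002") %in% sig), 1L)

  combos <- mediated_combinations(ds, gr, co$pairs)
  cc <- concordance_table(combos, co$mirna, co$gene, groups)
  planted <- cc[cc$mirna_id == "mir-0001" &
                  cc$gene_id %in% c("gene-0001", "gene-0002"), ]
  expect_gte(nrow(planted), 1L)
  expect_true(all(planted$corr_slope < 0))
  expect_true(all(planted$corr_significant))
  expect_true(all(planted$verdict == "consistent"))
  # verdict counts partition the combinations
  expect_equal(sum(cc$verdict %in% c("consistent", "inconsistent", "unknown")),
               nrow(cc))
})

test_that("combination building follows Table-2-style multiplicity", {
  markers <- data.frame(cancer_type = c("CT01", "CT01"), drug = "drugX",
                        feature_id = c("mir-1", "mir-2"), fdr = c(0.01, 0.02),
                        better_survival_class = c("high", "low"),
                        stringsAsFactors = FALSE)
  genes <- data.frame(cancer_type = "CT01", drug = "drugX",
                      feature_id = c("GENE1", "GENE2"), fdr = c(0.001, 0.002),
                      better_survival_class = c("low", "low"),
                      significant = TRUE, stringsAsFactors = FALSE)
  pairs <- data.frame(mirna_id = c("mir-1", "mir-1", "mir-2"),
                      gene_id = c("GENE1", "GENE2", "GENE1"),
                      regulation = c("inhibit", "inhibit", "activate"),
                      stringsAsFactors = FALSE)
  combos <- mediated_combinations(markers, genes, pairs)
  # mir-1 pairs with both genes; GENE1 shared by both miRNAs -> two rows
  expect_equal(nrow(combos), 3L)
  expect_equal(sum(combos$gene_id == "GENE1"), 2L)
  expect_equal(nrow(mediated_combinations(markers, genes[0, ], pairs)), 0L)
})

test_that("marker miRNAs without known targets are reported, not fatal", {
  markers <- data.frame(cancer_type = "CT01", drug = "drugX",
                        feature_id = "mir-orphan", fdr = 0.01,
                        better_survival_class = "high",
                        stringsAsFactors = FALSE)
  pairs <- data.frame(mirna_id = "mir-1", gene_id = "GENE1",
                      regulation = "inhibit", stringsAsFactors = FALSE)
  groups <- data.frame(cancer_type = "CT01", drug = "drugX", n = 20L)
  groups$patient_ids <- I(list(sprintf("P%02d", 1:20)))
  expr <- matrix(rnorm(20), 1, 20,
                 dimnames = list("GENE1", sprintf("P%02d", 1:20)))
  thr <- fit_step_thresholds(expr)
  clinical <- data.frame(patient_id = sprintf("P%02d", 1:20),
                         cancer_type = "CT01",
                         survival_time = 1:20 * 10, event = 1)
  out <- screen_targets(markers, pairs, expr, thr, clinical, groups)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "no_target_mirnas"), "mir-orphan")
})
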