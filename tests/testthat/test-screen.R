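make_toy_inputs <- function(n_per_drug = 20) {
  # 40 BRCA-like patients; drugX for the first block, drugY overlapping
  n <- 2 * n_per_drug
  pid <- sprintf("P%03d", seq_len(n))
  clinical <- data.frame(patient_id = pid, cancer_type = "CT01",
                         survival_time = seq(100, by = 10, length.out = n),
                         event = rep(1, n), stringsAsFactors = FALSE)
  drugs <- data.frame(patient_id = c(pid[1:n_per_drug], pid[(n_per_drug - 4):n]),
                      raw_name = c(rep("drugX", n_per_drug),
                                   rep("drugY", n - n_per_drug + 5)),
                      stringsAsFactors = FALSE)
  drugs$standardized_name <- drugs$raw_name
  expr <- matrix(rnorm(2 * n, 5), 2, n,
                 dimnames = list(c("mir-a", "mir-b"), pid))
  list(clinical = clinical, drugs = drugs, expr = expr)
}

test_that("group building applies eligibility, size gate and multi-membership", {
  ti <- make_toy_inputs()
  g <- build_groups(ti$clinical, ti$drugs, ti$expr, min_group_size = 15)
  expect_equal(nrow(g), 2L)
  expect_setequal(g$drug, c("drugX", "drugY"))
  # overlapping patients sit in both groups
  both <- intersect(g$patient_ids[[1]], g$patient_ids[[2]])
  expect_gt(length(both), 0L)
  # 14 eligible patients -> no group
  g14 <- build_groups(ti$clinical[1:14, ], ti$drugs, ti$expr, 15)
  expect_equal(nrow(g14), 0L)
  # exactly 15 passes
  g15 <- build_groups(ti$clinical[1:15, ], ti$drugs, ti$expr, 15)
  expect_equal(g15$n, 15L)
  expect_equal(g15$drug, "drugX")
})

test_that("unmapped drugs, duplicate records and missing expression are excluded", {
  ti <- make_toy_inputs()
  dr <- ti$drugs
  dr$standardized_name[dr$patient_id == "P001"] <- UNMAPPED
  dr <- rbind(dr, dr[2, ])                       # duplicate record, set semantics
  expr <- ti$expr[, colnames(ti$expr) != "P002"] # P002 lacks expression
  g <- build_groups(ti$clinical, dr, expr, min_group_size = 5)
  gx <- g[g$drug == "drugX", ]
  expect_false("P001" %in% gx$patient_ids[[1]])
  expect_false("P002" %in% gx$patient_ids[[1]])
  expect_equal(gx$n, 18L)
})

test_that("group membership is invariant to input row order", {
  ti <- make_toy_inputs()
  g1 <- build_groups(ti$clinical, ti$drugs, ti$expr, 15)
  set.seed(41)
  g2 <- build_groups(ti$clinical[sample(nrow(ti$clinical)), ],
                     ti$drugs[sample(nrow(ti$drugs)), ],
                     ti$expr[, sample(ncol(ti$expr))], 15)
  expect_identical(g1, g2)
})

test_that("combination enumeration is the group-by-feature product", {
  ti <- make_toy_inputs()
  g <- build_groups(ti$clinical, ti$drugs, ti$expr, 15)
  expect_equal(nrow(enumerate_combinations(g, c("f1", "f2", "f3"))), 6L)
  expect_equal(nrow(enumerate_combinations(g[0, ], c("f1"))), 0L)
})

test_that("the class-size gate skips imbalanced features without testing", {
  ti <- make_toy_inputs()
  # mir-a splits 4 low / 16 high within drugX under a global threshold of 0
  ti$expr["mir-a", ] <- 1
  ti$expr["mir-a", c("P001", "P002", "P003", "P004")] <- -1
  thr <- data.frame(feature_id = c("mir-a", "mir-b"), threshold = c(0, 0),
                    breakpoint_index = 1L, sse = 0, n_used = 40L)
  g <- build_groups(ti$clinical, ti$drugs, ti$expr, 15)
  res <- screen_group(g[g$drug == "drugX", ], ti$expr, thr, ti$clinical)
  row <- res[res$feature_id == "mir-a", ]
  expect_false(row$tested)
  expect_equal(row$gate_reason, "class_size")
  expect_equal(row$n_low, 4L)
  expect_true(is.na(row$p_value))
})

test_that("class counts never exceed the group size when values are missing", {
  ti <- make_toy_inputs()
  ti$expr["mir-a", 1:6] <- NA
  thr <- fit_step_thresholds(ti$expr)
  g <- build_groups(ti$clinical, ti$drugs, ti$expr, 15)
  res <- screen_cohort(g, ti$expr, thr, ti$clinical)
  gi <- match(paste(res$cancer_type, res$drug),
              paste(g$cancer_type, g$drug))
  expect_true(all(res$n_low + res$n_high <= g$n[gi]))
})

test_that("a planted marker is recovered as significant and drug-specific", {
  co <- generate_cohort(marker_cohort_config(seed = 101))
  res <- screen_cohort_end_to_end(co)
  row <- res[res$feature_id == "mir-0001", ]
  expect_lt(row$fdr, 0.1)
  expect_true(row$drug_specific)
  expect_equal(row$better_survival_class, "low")   # high class has 4x hazard
})

test_that("the cancer-wide contrast strips markers that are not drug-specific", {
  # plant the marker effect in ALL patients of the cancer via full exposure:
  # the cancer-wide test is then as significant as the group test
  co <- generate_cohort(marker_cohort_config(seed = 102, patients = 120,
                                             exposure = 1))
  res <- screen_cohort_end_to_end(co)
  row <- res[res$feature_id == "mir-0001", ]
  expect_lt(row$fdr, 0.1)
  expect_lt(row$cancer_level_p, 0.1)
  expect_false(row$drug_specific)
})

test_that("raw-p specificity mode uses the unadjusted cancer-level p-value", {
  co <- generate_cohort(marker_cohort_config(seed = 103))
  thr <- fit_step_thresholds(co$mirna)
  drugs <- co$drugs; drugs$standardized_name <- drugs$raw_name
  g <- build_groups(co$clinical, drugs, co$mirna, 15)
  res <- screen_cohort(g, co$mirna, thr, co$clinical)
  adj <- drug_specific_filter(res, co$clinical, co$mirna, thr)
  raw <- drug_specific_filter(res, co$clinical, co$mirna, thr,
                              mode = "raw", cancer_alpha = 0.1)
  i <- which(adj$feature_id == "mir-0001")
  expect_lte(raw$cancer_level_p[i], adj$cancer_level_p[i])
})

test_that("marker recovery power rises with hazard ratio", {
  hits <- vapply(c(1.5, 4), function(hr) {
    sum(vapply(1:6, function(s) {
      co <- generate_cohort(marker_cohort_config(seed = 200 + s,
                                                 hazard_ratio = hr,
                                                 patients = 800,
                                                 exposure = 0.05))
      res <- screen_cohort_end_to_end(co)
      row <- res[res$feature_id == "mir-0001", ]
      isTRUE(row$fdr < 0.1)
    }, logical(1)))
  }, numeric(1))
  expect_gte(hits[2], hits[1])
  expect_gte(hits[2], 5)
})

test_that("null screen p-values are approximately uniform", {
  cfg <- sim_config(n_cancer_types = 1, patients_per_cancer = 100,
                    drugs_per_cancer = 1, drug_exposure_prob = 0.4,
                    n_mirnas = 1000, n_genes = 0, censoring_rate = 2e-5,
                    seed = 104)
  co <- generate_cohort(cfg)
  thr <- fit_step_thresholds(co$mirna)
  drugs <- co$drugs; drugs$standardized_name <- drugs$raw_name
  g <- build_groups(co$clinical, drugs, co$mirna, 15)
  res <- screen_cohort(g, co$mirna, thr, co$clinical)
  p <- res$p_value[res$tested]
  expect_gt(length(p), 800)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.06)
})
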