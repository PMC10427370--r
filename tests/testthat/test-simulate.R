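small_cfg <- function(...) {
  sim_config(n_patients = 10, n_genes = 260, n_markers_per_type = 10,
             seed = 11, ...)
}

test_that("generators are deterministic for a fixed seed", {
  cfg <- small_cfg()
  r1 <- generate_reference_profiles(cfg)
  r2 <- generate_reference_profiles(cfg)
  expect_identical(r1, r2)
  b1 <- generate_bulk_cohort(cfg, r1)
  b2 <- generate_bulk_cohort(cfg, r1)
  expect_identical(b1, b2)
  h1 <- generate_hmc_cohort(cfg)
  h2 <- generate_hmc_cohort(cfg)
  expect_identical(h1, h2)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_genes = 100, n_markers_per_type = 50),
               class = "hmc_size_error")
  expect_error(sim_config(dhmg_fraction_per_dose =
                            c("37.5" = 0.2, "50" = 0.1, "75" = 0.3)),
               class = "hmc_config_error")
  expect_error(sim_config(tissues = "LN"), class = "hmc_config_error")
  expect_error(sim_config(censoring_rate = 1.5), class = "hmc_config_error")
  expect_error(generate_hmc_cohort(small_cfg(days = 0)),
               class = "hmc_config_error")
})

test_that("reference profiles elevate each type's markers by marker_fold", {
  cfg <- small_cfg(marker_fold = 10)
  ref <- generate_reference_profiles(cfg)
  mk <- attr(ref, "markers")
  expect_equal(length(unique(unlist(mk))), 13 * cfg$n_markers_per_type)
  own <- mean(ref[mk[["GMP-like"]], "GMP-like"])
  other <- mean(ref[mk[["GMP-like"]], colnames(ref) != "GMP-like"])
  expect_gt(own / other, 7)
  expect_lt(own / other, 13)
  # non-marker baseline sits near mean 5
  nonmark <- setdiff(rownames(ref), unlist(mk))
  expect_gt(mean(ref[nonmark, ]), 3.5)
  expect_lt(mean(ref[nonmark, ]), 7)
})

test_that("between-type reference correlation is below within-type", {
  ref <- generate_reference_profiles(small_cfg())
  between <- cor(ref[, "GMP-like"], ref[, "NK"])
  # a bootstrap re-draw of the same column (its own noise model) stays
  # near-perfectly correlated; between-type must be clearly lower
  expect_lt(between, 0.9)
})

test_that("bulk cohort fractions are simplex points and labels follow the score", {
  cfg <- small_cfg()
  bulk <- generate_bulk_cohort(cfg, generate_reference_profiles(cfg))
  expect_true(all(abs(rowSums(bulk$truth$sample_fractions) - 1) < 1e-9))
  expect_true(all(bulk$truth$sample_fractions >= 0))
  expect_setequal(names(bulk$truth$labels), unique(bulk$sheet$patient_id))
})

test_that("response_effect = 0 yields a balanced responder rate", {
  cfg <- sim_config(n_patients = 400, n_genes = 130, n_markers_per_type = 10,
                    tissues = "BM", response_effect = 0, seed = 21)
  bulk <- generate_bulk_cohort(cfg, generate_reference_profiles(cfg))
  rate <- mean(bulk$truth$labels)
  expect_gt(rate, 0.42)
  expect_lt(rate, 0.58)
})

test_that("response_effect = 5 makes GMP-HSC strongly predictive", {
  cfg <- sim_config(n_patients = 200, n_genes = 130, n_markers_per_type = 10,
                    tissues = "BM", response_effect = 5, seed = 23)
  bulk <- generate_bulk_cohort(cfg, generate_reference_profiles(cfg))
  x <- bulk$truth$patient_fractions[, "GMP-like"] -
    bulk$truth$patient_fractions[, "HSC-like"]
  expect_gt(roc_auc(x, bulk$truth$labels)$auc, 0.9)
})

test_that("near-zero dispersion pure sample tracks its reference column", {
  cfg <- small_cfg(nb_dispersion = 1e-4)
  ref <- generate_reference_profiles(cfg)
  # single pure-type mixture built through the same mixing rule
  prof <- sweep(ref, 2, colSums(ref), "/")[, "NK"]
  lens <- rep(1, length(prof))
  mu <- 1e6 * prof / sum(prof)
  set.seed(1)
  counts <- rnbinom(length(mu), mu = mu, size = 1e4)
  expect_gt(cor(counts, prof), 0.999)
})

test_that("5hmC cohort plants dose-dependent shifts and survival signal", {
  cfg <- sim_config(n_patients = 100, n_genes = 400, n_markers_per_type = 10,
                    seed = 31)
  hmc <- generate_hmc_cohort(cfg)
  sizes <- hmc$truth$shifted_sizes
  doses <- hmc$truth$dose
  med <- tapply(sizes, doses, median)
  expect_true(all(diff(med[order(as.numeric(names(med)))]) >= 0))
  # survival_hazard_coef > 0: more shifted genes -> longer survival
  os <- hmc$sheet$os_time[match(names(sizes), hmc$sheet$patient_id)]
  expect_gt(cor(sizes, os, method = "spearman"), 0)
})

test_that("null 5hmC settings leave Day5 indistinguishable from Day0", {
  cfg <- sim_config(n_patients = 12, n_genes = 500, n_markers_per_type = 10,
                    dhmg_fraction_per_dose = c("37.5" = 0, "50" = 0, "75" = 0),
                    seed = 41)
  hmc <- generate_hmc_cohort(cfg)
  counts <- vapply(unique(hmc$sheet$patient_id), function(p)
    as.integer(patient_dhmg_count(hmc$counts, hmc$sheet, p)), integer(1))
  # expected count under the null is below the raw-p rate x n_genes since
  # the |lfc| filter removes most false positives
  expect_lt(mean(counts), 0.01 * cfg$n_genes * 2)
  expect_true(all(lengths(hmc$truth$shifted_sets) == 0))
})

test_that("written cohorts re-read identically", {
  cfg <- small_cfg()
  bulk <- generate_bulk_cohort(cfg, generate_reference_profiles(cfg))
  dir <- withr::local_tempdir()
  write_cohort(bulk, dir)
  counts <- read_counts(file.path(dir, "counts.tsv"))
  expect_equal(unclass(counts), bulk$counts * 1, ignore_attr = "hmc_state")
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  expect_equal(sheet$sample_id, bulk$sheet$sample_id)
  expect_true(file.exists(file.path(dir, "gene_lengths.tsv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
})
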