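test_that("composition scores combine fractions as specified", {
  frac <- rbind(P1 = c(0.6, 0.1, 0.05), P2 = c(0.2, 0.2, 0.1))
  colnames(frac) <- c("GMP-like", "HSC-like", "NK")
  expect_equal(unname(composition_score(frac, "gmp_minus_hsc")), c(0.5, 0))
  expect_equal(unname(composition_score(frac, "nk_plus_gmp")), c(0.65, 0.3))
  expect_equal(unname(composition_score(frac, "nk")), c(0.05, 0.1))
  expect_error(composition_score(frac[, 1:2, drop = FALSE], "nk"),
               class = "hmc_validation_error")
})

test_that("AUC equals Mann-Whitney pair counting", {
  perfect <- roc_auc(c(1, 2, 9, 10), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(perfect$auc, 1)

  mixed <- roc_auc(c(0.9, 0.7, 0.8, 0.6), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(mixed$auc, 0.75)

  set.seed(71)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force some ties
    l <- runif(n) < 0.5
    if (length(unique(l)) < 2) next
    expect_equal(roc_auc(s, l)$auc, auc_brute(s, l), tolerance = 1e-12)
  }

  # invariance under strictly monotone transforms
  s <- rnorm(30); l <- runif(30) < 0.5
  if (length(unique(l)) == 2)
    expect_equal(roc_auc(exp(s), l)$auc, roc_auc(s, l)$auc)
  expect_error(roc_auc(s, rep(TRUE, 30)), class = "hmc_validation_error")
})

test_that("grouped folds partition patients with balanced sizes", {
  f <- grouped_kfold(sprintf("P%02d", 1:22), k = 5, seed = 72)
  expect_equal(sort(as.vector(table(f)), decreasing = TRUE),
               c(5, 5, 4, 4, 4))
  expect_setequal(names(f), sprintf("P%02d", 1:22))

  # all samples of a patient inherit one fold
  pats <- rep(c("A", "B", "C", "D", "E"), each = 4)
  ff <- grouped_kfold(pats, k = 5, seed = 73)
  per_sample <- ff[pats]
  expect_true(all(tapply(per_sample, pats,
                         function(v) length(unique(v))) == 1))
  expect_error(grouped_kfold(c("A", "B"), k = 5),
               class = "hmc_validation_error")
})

test_that("a perfectly separating feature yields CV AUC 1", {
  set.seed(74)
  pats <- rep(sprintf("P%02d", 1:10), each = 2)
  labs <- rep(c(TRUE, FALSE), each = 10)
  x <- cbind(sep = as.numeric(labs), noise = rnorm(20))
  rownames(x) <- paste0("s", 1:20)
  folds <- grouped_kfold(pats, k = 5, seed = 75)
  # no column subsampling: only two features, one of them decisive
  m <- train_signature_model(x, labs, pats, folds, colsample_bytree = 1,
                             seed = 76)
  expect_equal(m$cv_auc, 1)
  expect_gt(m$fscore[["sep"]], 0)
})

test_that("signature training, selection and evaluation work end to end", {
  cfg <- sim_config(n_patients = 24, n_genes = 400, n_markers_per_type = 10,
                    n_response_genes = 5, seed = 77)
  hmc <- generate_hmc_cohort(cfg)
  feats <- t(rlog_approx(hmc$counts))
  labs <- is_responder(hmc$sheet$response)
  pats <- hmc$sheet$patient_id
  train_pat <- sprintf("P%03d", 1:16)
  test_pat <- sprintf("P%03d", 17:24)
  tr <- pats %in% train_pat
  folds <- grouped_kfold(pats[tr], k = 5, seed = 78)
  m <- train_signature_model(feats[tr, ], labs[tr], pats[tr], folds,
                             seed = 79)
  sel <- select_top_k_refit(m, k_grid = c(3, 5, 11, 25))
  expect_true(sel$k %in% c(3, 5, 11, 25))
  expect_length(sel$selected_genes, sel$k)

  # determinism given the seed
  m2 <- train_signature_model(feats[tr, ], labs[tr], pats[tr], folds,
                              seed = 79)
  sel2 <- select_top_k_refit(m2, k_grid = c(3, 5, 11, 25))
  expect_identical(sel$selected_genes, sel2$selected_genes)
  expect_equal(sel$cv_auc, sel2$cv_auc)

  ev <- evaluate_test(sel, feats[!tr, ], labs[!tr], pats[!tr],
                      sheet = hmc$sheet)
  expect_true(ev$auc >= 0 && ev$auc <= 1)
  expect_named(ev$subgroup_auc, c("day0", "day5", "BM", "PB"))

  # inverting test labels mirrors the AUC
  ev_inv <- evaluate_test(sel, feats[!tr, ], !labs[!tr], pats[!tr])
  expect_equal(ev_inv$auc, 1 - ev$auc, tolerance = 1e-12)

  # leakage guard trips on any shared patient
  expect_error(evaluate_test(sel, feats, labs, pats),
               class = "hmc_leakage_error")
})

test_that("top-k selection concentrates near the planted signature size", {
  cfg <- sim_config(n_patients = 30, n_genes = 300, n_markers_per_type = 10,
                    n_response_genes = 5, response_log2_shift = 1.5,
                    seed = 80)
  hmc <- generate_hmc_cohort(cfg)
  feats <- t(rlog_approx(hmc$counts))
  labs <- is_responder(hmc$sheet$response)
  pats <- hmc$sheet$patient_id
  folds <- grouped_kfold(pats, k = 5, seed = 81)
  m <- train_signature_model(feats, labs, pats, folds, seed = 82)
  sel <- select_top_k_refit(m, k_grid = c(3, 5, 8, 25, 100))
  expect_lte(sel$k, 25)
  # degenerate grid: all genes returns the base model's performance
  all_k <- select_top_k_refit(m, k_grid = ncol(feats))
  expect_equal(all_k$cv_auc, m$cv_auc, tolerance = 0.1)
})
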