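test_that("Kaplan-Meier estimates match hand-computed product limits", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 2], 1 / 3)
  expect_equal(km$surv[km$time == 3], 1 / 3)  # censoring: no step

  all_cens <- km_estimate(c(1, 5, 9), c(0, 0, 0))
  expect_true(all(all_cens$surv == 1))

  four <- km_estimate(1:4, rep(1, 4))
  expect_equal(four$surv, c(0.75, 0.5, 0.25, 0))

  expect_error(km_estimate(c(-1, 2), c(1, 1)),
               class = "hmc_validation_error")
})

test_that("log-rank test matches the O-E/V definition", {
  same <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                       rep(c("A", "B"), each = 3))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  sep <- logrank_test(c(1, 2, 3, 4), rep(1, 4), c("A", "A", "B", "B"))
  expect_equal(sep$chisq, 2.8824, tolerance = 1e-3)

  set.seed(91)
  for (i in 1:40) {
    n <- sample(10:40, 1)
    time <- round(rexp(n, 0.1), 3)
    event <- rbinom(n, 1, 0.8)
    group <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(group)) < 2 || sum(event) == 0) next
    lr <- logrank_test(time, event, group)
    expect_equal(lr$chisq, logrank_brute(time, event, group),
                 tolerance = 1e-8)
  }

  # invariance under strictly increasing time transforms
  time <- c(2, 5, 7, 11, 13, 17); event <- c(1, 1, 0, 1, 1, 1)
  grp <- c("A", "B", "A", "B", "A", "B")
  expect_equal(logrank_test(time, event, grp)$chisq,
               logrank_test(time^2 + 1, event, grp)$chisq,
               tolerance = 1e-12)
})

test_that("Cox fits reproduce the closed-form small example", {
  fit <- cox_fit(c(1, 2, 3), c(1, 1, 1), data.frame(x = c(1, 0, 1)))
  expect_equal(fit$coefficients$coef, -log(2) / 2, tolerance = 1e-6)

  # doubling a covariate halves its coefficient
  fit2 <- cox_fit(c(1, 2, 3), c(1, 1, 1), data.frame(x = c(2, 0, 2)))
  expect_equal(fit2$coefficients$coef, fit$coefficients$coef / 2,
               tolerance = 1e-8)
})

test_that("Cox coverage holds for an uninformative covariate", {
  set.seed(92)
  covered <- replicate(40, {
    n <- 100
    time <- rexp(n, 0.05)
    event <- rbinom(n, 1, 0.85)
    x <- rnorm(n)
    fit <- cox_fit(time, event, data.frame(x = x))
    abs(fit$coefficients$coef) < 2 * fit$coefficients$se
  })
  expect_gte(mean(covered), 0.9)
})

test_that("median split applies the ties-to-low rule", {
  expect_identical(as.vector(median_split(c(a = 1, b = 2, c = 3, d = 4))),
                   c("low", "low", "high", "high"))
  grp <- median_split(c(1, 2, 2, 9))
  expect_identical(as.vector(grp), c("low", "low", "low", "high"))
  expect_identical(unname(attr(grp, "sizes")), c(3L, 1L))
  expect_identical(as.vector(median_split(c(1, 2, 3))),
                   c("low", "low", "high"))
  expect_error(median_split(rep(3, 5)), class = "hmc_validation_error")
})

test_that("per-patient DhMG counting needs complete designs and finds shifts", {
  cfg <- sim_config(n_patients = 6, n_genes = 500, n_markers_per_type = 10,
                    dhmg_fraction_per_dose = c("37.5" = 0.1, "50" = 0.1,
                                               "75" = 0.1),
                    nb_dispersion = 0.01, seed = 93)
  hmc <- generate_hmc_cohort(cfg)
  p <- "P001"
  n <- patient_dhmg_count(hmc$counts, hmc$sheet, p)
  truth <- hmc$truth$shifted_sizes[[p]]
  expect_gt(as.integer(n), 0.75 * truth)
  expect_lt(as.integer(n), 1.25 * truth + 10)

  bm_only <- hmc$sheet[hmc$sheet$tissue == "BM", ]
  expect_error(patient_dhmg_count(hmc$counts, bm_only, p),
               class = "hmc_validation_error")
})

test_that("day correlation is a Spearman rho with the expected extremes", {
  cfg <- sim_config(n_patients = 4, n_genes = 400, n_markers_per_type = 10,
                    dhmg_fraction_per_dose = c("37.5" = 0, "50" = 0,
                                               "75" = 0),
                    nb_dispersion = 1e-3, seed = 94)
  hmc <- generate_hmc_cohort(cfg)
  r <- day_correlation(hmc$counts, hmc$sheet, "P001")
  expect_gt(r, 0.98)  # no planted shift, tiny noise

  set.seed(95)
  for (i in 1:25) {
    x <- rnorm(40); y <- rnorm(40)
    expect_equal(cor(x, y, method = "spearman"), spearman_brute(x, y),
                 tolerance = 1e-12)
  }
})

test_that("dose trend reports medians and pairwise rank-sum p values", {
  counts <- c(10, 12, 11, 30, 35, 33, 80, 90, 85)
  doses <- rep(c(37.5, 50, 75), each = 3)
  dt <- dose_trend(counts, doses)
  expect_true(all(diff(dt$medians) > 0))
  expect_equal(nrow(dt$pairwise), 3)

  same <- dose_trend(c(5, 5, 5, 5), c(37.5, 37.5, 75, 75))
  expect_equal(same$pairwise$p, 1)
  expect_error(dose_trend(c(1, 2), c(50, 50)),
               class = "hmc_validation_error")
})

test_that("stronger 5hmC alteration confers better survival on generated cohorts", {
  cfg <- sim_config(n_patients = 60, seed = 96)
  hmc <- generate_hmc_cohort(cfg)
  pats <- unique(hmc$sheet$patient_id)
  dhmg <- vapply(pats, function(p)
    as.integer(patient_dhmg_count(hmc$counts, hmc$sheet, p)), integer(1))
  grp <- median_split(dhmg)
  os <- hmc$sheet[match(pats, hmc$sheet$patient_id), ]
  lr <- logrank_test(os$os_time, os$os_event, grp)
  km_hi <- km_estimate(os$os_time[grp == "high"], os$os_event[grp == "high"])
  km_lo <- km_estimate(os$os_time[grp == "low"], os$os_event[grp == "low"])
  expect_lt(lr$p, 0.05)
  expect_gt(median(os$os_time[grp == "high"]), median(os$os_time[grp == "low"]))

  # multivariable Cox with age and sex keeps the direction
  fit <- cox_fit(os$os_time, os$os_event,
                 data.frame(high_dhmg = as.integer(grp == "high"),
                            age = os$age, sex = as.integer(os$sex == "M")))
  expect_lt(fit$coefficients$coef[fit$coefficients$term == "high_dhmg"], 0)
})
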