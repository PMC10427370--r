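# Per-patient 5hmC responsiveness statistics (DhMG counts, Day5-vs-Day0
# Spearman correlation), median split, and survival analysis
# (Kaplan-Meier, log-rank, Cox with Breslow ties) via the survival package.

#' Per-patient differentially hydroxymethylated gene count
#'
#' Runs the NB Wald test Day 5 versus Day 0 on one patient's samples
#' (pooling BM and PB as replicates, the 2-vs-2 design of paired dual-tissue
#' cohorts) and counts genes passing the DhMG rule (raw p < 0.01,
#' |log2FC| >= 0.5).
#'
#' @param counts Raw 5hmC count matrix over the cohort.
#' @param sheet Sample sheet.
#' @param patient Patient id.
#' @param tissues Tissues to pool (default both).
#' @return Integer DhMG count (the gene sets are attached as the `dhmg`
#'   attribute).
#' @export
patient_dhmg_count <- function(counts, sheet, patient,
                               tissues = c("BM", "PB")) {
  rows <- sheet[sheet$patient_id == patient & sheet$tissue %in% tissues, ]
  day0 <- rows$sample_id[rows$day == 0]
  day5 <- rows$sample_id[rows$day == 5]
  if (length(day0) < 2 || length(day5) < 2)
    hmc_stop(sprintf(
      "patient %s lacks Day0/Day5 samples in both tissues (have %d/%d)",
      patient, length(day0), length(day5)),
      "hmc_validation_error")
  res <- nb_wald_test(counts, day0, day5)
  hits <- filter_dhmgs(res)
  out <- length(hits$all)
  attr(out, "dhmg") <- hits
  out
}

#' Day 5 versus Day 0 global 5hmC correlation for one patient
#'
#' Spearman correlation between a patient's size-factor-normalized Day 0
#' and Day 5 gene profiles; lower correlation means stronger global 5hmC
#' alteration. Profiles are averaged across tissues when more than one of
#' the requested tissues is present.
#'
#' @param counts Raw 5hmC count matrix.
#' @param sheet Sample sheet.
#' @param patient Patient id.
#' @param tissues Tissues used (default `"BM"`, matching the paired-BM
#'   analysis design; pass `c("BM", "PB")` to average both).
#' @return Spearman rho.
#' @export
day_correlation <- function(counts, sheet, patient, tissues = "BM") {
  rows <- sheet[sheet$patient_id == patient & sheet$tissue %in% tissues, ]
  day0 <- rows$sample_id[rows$day == 0]
  day5 <- rows$sample_id[rows$day == 5]
  if (!length(day0) || !length(day5))
    hmc_stop(sprintf("patient %s lacks a Day0/Day5 pair in %s",
                     patient, paste(tissues, collapse = "/")),
             "hmc_validation_error")
  sub <- counts[, c(day0, day5), drop = FALSE]
  count_state(sub) <- "raw"
  sf <- size_factors(sub)
  q <- sweep(sub, 2, sf, "/")
  v0 <- rowMeans(q[, day0, drop = FALSE])
  v5 <- rowMeans(q[, day5, drop = FALSE])
  stats::cor(v0, v5, method = "spearman")
}

#' Split patients at the median of a statistic
#'
#' Values above the median go to `"high"`; values at or below the median go
#' to `"low"` (the documented tie rule).
#'
#' @param values Named numeric vector (patient -> statistic).
#' @return Named character vector of `"low"`/`"high"` labels with group
#'   sizes in the `sizes` attribute.
#' @export
median_split <- function(values) {
  if (length(values) < 2)
    hmc_stop("need >= 2 patients", "hmc_validation_error")
  if (max(values) == min(values))
    hmc_stop("constant values cannot be split", "hmc_validation_error")
  med <- stats::median(values)
  grp <- ifelse(values > med, "high", "low")
  attr(grp, "sizes") <- c(low = sum(grp == "low"), high = sum(grp == "high"))
  attr(grp, "median") <- med
  grp
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator (right-continuous steps at event times; censored
#' times shrink the risk set without a step).
#'
#' @param time Non-negative follow-up times.
#' @param event 1 = death observed, 0 = censored.
#' @return An `hmc_km` data.frame of (time, n_risk, n_event, surv).
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0))
    hmc_stop("negative survival time", "hmc_validation_error")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  class(out) <- c("hmc_km", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' summed over event times; p from chi-square with 1 df (two-tailed).
#'
#' @param time,event Survival outcome across both groups.
#' @param group Two-level grouping vector.
#' @return List with `chisq`, `p`, and per-group observed/expected counts.
#' @export
logrank_test <- function(time, event, group) {
  if (length(unique(group)) != 2)
    hmc_stop("log-rank test needs exactly two groups", "hmc_validation_error")
  if (sum(event) == 0)
    hmc_stop("no events observed", "hmc_validation_error")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Breslow tie handling (the
#' hand-checkable convention; `ties = "efron"` available via `ties`).
#' Monotone likelihood (perfect separation) is detected from the fit
#' diagnostics and flagged.
#'
#' @param time,event Survival outcome.
#' @param covariates data.frame of covariates (e.g. group indicator, age,
#'   sex).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return An `hmc_cox` list: coefficient table (`coef`, `hr`, `se`, `z`,
#'   `p`), log-likelihood, and a `diverged` flag.
#' @export
cox_fit <- function(time, event, covariates, ties = "breslow") {
  if (sum(event) == 0)
    hmc_stop("no events observed", "hmc_validation_error")
  covariates <- as.data.frame(covariates)
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  tab <- data.frame(
    term = rownames(s$coefficients),
    coef = s$coefficients[, "coef"],
    hr = s$coefficients[, "exp(coef)"],
    se = s$coefficients[, "se(coef)"],
    z = s$coefficients[, "z"],
    p = s$coefficients[, "Pr(>|z|)"],
    row.names = NULL)
  diverged <- any(abs(tab$coef) > 15)
  out <- list(coefficients = tab, loglik = fit$loglik,
              n = fit$n, n_events = fit$nevent, ties = ties,
              diverged = diverged)
  class(out) <- "hmc_cox"
  if (diverged)
    warning("possible monotone likelihood (coefficient diverged)")
  out
}

#' @export
print.hmc_cox <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties): %d subjects, %d events%s\n",
              x$ties, x$n, x$n_events,
              if (x$diverged) " [DIVERGED]" else ""))
  print(transform(x$coefficients, coef = signif(coef, 4), hr = signif(hr, 4),
                  se = signif(se, 4), z = signif(z, 3), p = signif(p, 3)))
  invisible(x)
}

#' Dose trend of per-patient DhMG counts
#'
#' Pairwise Wilcoxon rank-sum tests between all dose groups plus the
#' per-dose median counts (the monotone-trend summary).
#'
#' @param counts_per_patient Named numeric vector of DhMG counts.
#' @param doses Dose level per patient (same order).
#' @return List with `medians` (per dose, ascending) and `pairwise`
#'   data.frame (dose_a, dose_b, p).
#' @export
dose_trend <- function(counts_per_patient, doses) {
  lev <- sort(unique(doses))
  if (length(lev) < 2)
    hmc_stop("need >= 2 dose groups", "hmc_validation_error")
  for (d in lev)
    if (sum(doses == d) < 2)
      hmc_stop(sprintf("dose group %s has < 2 patients", d),
               "hmc_validation_error")
  medians <- vapply(lev, function(d)
    stats::median(counts_per_patient[doses == d]), numeric(1))
  names(medians) <- lev
  pairs <- utils::combn(lev, 2)
  pw <- data.frame(
    dose_a = pairs[1, ], dose_b = pairs[2, ],
    p = apply(pairs, 2, function(pr)
      basic_tests(counts_per_patient[doses == pr[1]],
                  counts_per_patient[doses == pr[2]],
                  kind = "wilcoxon_ranksum")$p))
  list(medians = medians, pairwise = pw)
}
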