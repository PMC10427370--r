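# Synthetic-cohort generator. Emulates the statistical structure the
# downstream analysis assumes -- bulk counts as NB-noised mixtures of
# cell-type reference profiles, responder labels driven by the malignant
# GMP-like/HSC-like balance and NK abundance, paired Day0/Day5 5hmC
# matrices with dose-dependent per-gene shifts, and survival times whose
# hazard falls with the magnitude of 5hmC alteration -- with full ground
# truth recorded so parameter recovery is testable.

#' Simulation configuration
#'
#' Builds and validates the parameter set for the cohort generators.
#'
#' @param n_patients Number of patients.
#' @param tissues Tissues sampled per patient, subset of `c("BM", "PB")`.
#' @param days Sampling days, subset of `c(0, 5)` (5hmC cohorts need both).
#' @param n_genes Number of genes in the universe.
#' @param cell_types The 13 reference cell types; defaults to the six
#'   malignant AML subsets plus seven immune populations of
#'   [cell_type_compartments()].
#' @param n_markers_per_type Marker genes planted per cell type (disjoint
#'   across types by construction).
#' @param marker_fold Fold-elevation of a marker gene in its own type.
#' @param sequencing_depth Expected total counts per sample.
#' @param nb_dispersion Negative-binomial dispersion of the counts.
#' @param response_effect Log-odds of response per standard deviation of the
#'   composite composition score (GMP-like minus HSC-like, plus NK), i.e.
#'   labels are drawn with probability `plogis(response_effect * z)` where z
#'   is the cohort-standardized composite. 0 gives a 50% response rate with
#'   labels independent of composition.
#' @param dirichlet_concentration Total concentration of the Dirichlet from
#'   which patient cell-type fractions are drawn (means fixed at 0.2 for
#'   GMP-like and HSC-like, the rest sharing 0.6).
#' @param tissue_concentration Concentration tying per-tissue sample
#'   fractions to their patient's fractions (larger = more BM/PB agreement).
#' @param dose_levels Azacitidine dose levels (mg/m2), subset of
#'   `c(37.5, 50, 75)`; patients are assigned doses cyclically.
#' @param dhmg_fraction_per_dose Named vector mapping dose to the fraction
#'   of genes shifted at Day 5; must be non-decreasing in dose.
#' @param dhmg_log2_shift Absolute log2 shift applied to shifted genes at
#'   Day 5 (sign random per gene).
#' @param n_response_genes Number of genes whose 5hmC level differs between
#'   responders and non-responders (ground truth for signature selection).
#' @param response_log2_shift Log2 responder shift of those genes.
#' @param survival_hazard_coef Decrease in log-hazard per shifted gene
#'   (positive values mean stronger 5hmC alteration leads to longer survival).
#' @param base_hazard Baseline hazard per day.
#' @param censoring_rate Probability a patient's survival time is censored.
#' @param seed Integer seed; all generators derive their streams from it.
#' @return A validated `hmc_sim_config` list.
#' @export
sim_config <- function(n_patients = 40,
                       tissues = c("BM", "PB"),
                       days = c(0, 5),
                       n_genes = 2000,
                       cell_types = names(cell_type_compartments()),
                       n_markers_per_type = 50,
                       marker_fold = 10,
                       sequencing_depth = 1e6,
                       nb_dispersion = 0.05,
                       response_effect = 3,
                       dirichlet_concentration = 8,
                       tissue_concentration = 200,
                       dose_levels = c(37.5, 50, 75),
                       dhmg_fraction_per_dose = c("37.5" = 0.02, "50" = 0.05,
                                                  "75" = 0.10),
                       dhmg_log2_shift = 2,
                       n_response_genes = 30,
                       response_log2_shift = 1,
                       survival_hazard_coef = 0.015,
                       base_hazard = 1 / 365,
                       censoring_rate = 0.2,
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), tissues = tissues, days = days,
    n_genes = as.integer(n_genes), cell_types = cell_types,
    n_markers_per_type = as.integer(n_markers_per_type),
    marker_fold = marker_fold, sequencing_depth = sequencing_depth,
    nb_dispersion = nb_dispersion, response_effect = response_effect,
    dirichlet_concentration = dirichlet_concentration,
    tissue_concentration = tissue_concentration,
    dose_levels = dose_levels,
    dhmg_fraction_per_dose = dhmg_fraction_per_dose,
    dhmg_log2_shift = dhmg_log2_shift,
    n_response_genes = as.integer(n_response_genes),
    response_log2_shift = response_log2_shift,
    survival_hazard_coef = survival_hazard_coef,
    base_hazard = base_hazard, censoring_rate = censoring_rate,
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_patients < 1 || n_genes < 1 || n_markers_per_type < 1)
      hmc_stop("counts must be >= 1", "hmc_config_error")
    if (!all(tissues %in% c("BM", "PB")) || !length(tissues))
      hmc_stop("tissues must be a non-empty subset of BM, PB",
               "hmc_config_error")
    if (!all(days %in% c(0, 5)) || !length(days))
      hmc_stop("days must be a non-empty subset of 0, 5", "hmc_config_error")
    if (length(cell_types) != 13)
      hmc_stop("exactly 13 cell types required", "hmc_config_error")
    if (n_markers_per_type * 13 > n_genes)
      hmc_stop(sprintf(
        "n_markers_per_type x 13 (%d) exceeds n_genes (%d)",
        n_markers_per_type * 13, n_genes), "hmc_size_error")
    if (!all(dose_levels %in% c(37.5, 50, 75)) || !length(dose_levels))
      hmc_stop("dose_levels must be a subset of 37.5, 50, 75",
               "hmc_config_error")
    fr <- dhmg_fraction_per_dose[as.character(sort(as.numeric(
      names(dhmg_fraction_per_dose))))]
    if (any(diff(fr) < 0))
      hmc_stop("dhmg_fraction_per_dose must be non-decreasing in dose",
               "hmc_config_error")
    if (any(fr < 0 | fr > 1))
      hmc_stop("dhmg fractions must lie in [0, 1]", "hmc_config_error")
    if (censoring_rate < 0 || censoring_rate > 1)
      hmc_stop("censoring_rate must lie in [0, 1]", "hmc_config_error")
    if (nb_dispersion <= 0 || marker_fold <= 0 || sequencing_depth <= 0)
      hmc_stop("dispersion, marker_fold and depth must be positive",
               "hmc_config_error")
  })
  class(cfg) <- "hmc_sim_config"
  cfg
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Generate cell-type reference expression profiles
#'
#' Draws a gene baseline (log-normal, mean expression 5) shared across the
#' 13 cell types, then elevates each type's disjoint marker block by
#' `marker_fold` in that type's column only. Mild multiplicative noise keeps
#' non-marker rows from being exactly collinear across types.
#'
#' @param config A [sim_config()].
#' @return Genes x 13 matrix of positive mean expressions with a `markers`
#'   attribute (named list of marker genes per type).
#' @export
generate_reference_profiles <- function(config) {
  stopifnot(inherits(config, "hmc_sim_config"))
  set.seed(derive_seed(config$seed, "reference"))
  n <- config$n_genes
  k <- length(config$cell_types)
  ids <- gene_ids(n)
  # meanlog chosen so the baseline mean is 5
  base <- stats::rlnorm(n, meanlog = log(5) - 0.18, sdlog = 0.6)
  ref <- matrix(base, n, k) *
    matrix(stats::rlnorm(n * k, 0, 0.05), n, k)
  dimnames(ref) <- list(ids, config$cell_types)
  markers <- vector("list", k)
  names(markers) <- config$cell_types
  m <- config$n_markers_per_type
  for (t in seq_len(k)) {
    rows <- ((t - 1) * m + 1):(t * m)
    ref[rows, t] <- ref[rows, t] * config$marker_fold
    markers[[t]] <- ids[rows]
  }
  attr(ref, "markers") <- markers
  ref
}

#' Generate a bulk RNA-seq cohort with ground truth
#'
#' Per patient, cell-type fractions are drawn from a Dirichlet (GMP-like and
#' HSC-like mean 0.2 each); per-tissue sample fractions are re-drawn around
#' the patient's fractions so BM and PB agree strongly. The responder label
#' is Bernoulli with probability `plogis(response_effect * z)` where z is
#' the standardized composite (GMP - HSC) + NK. Counts are negative binomial
#' with mean = depth x (column-normalized reference %*% fractions).
#'
#' @param config A [sim_config()].
#' @param reference Output of [generate_reference_profiles()] on the same
#'   gene universe.
#' @return List with `counts` (raw matrix), `sheet` (sample sheet),
#'   `gene_lengths_kb` (named, log-uniform 0.5-10 kb, for TPM) and `truth`
#'   (per-sample and per-patient fractions, labels, composite score).
#' @export
generate_bulk_cohort <- function(config, reference) {
  stopifnot(inherits(config, "hmc_sim_config"))
  if (!identical(rownames(reference), gene_ids(config$n_genes)))
    hmc_stop("reference gene universe does not match config",
             "hmc_config_error")
  set.seed(derive_seed(config$seed, "bulk"))
  ct <- config$cell_types
  k <- length(ct)
  target <- stats::setNames(rep(0.6 / (k - 2), k), ct)
  target[c("GMP-like", "HSC-like")] <- 0.2
  alpha <- target * config$dirichlet_concentration

  pid <- sprintf("P%03d", seq_len(config$n_patients))
  pat_frac <- t(vapply(pid, function(p) rdirichlet1(alpha), numeric(k)))
  colnames(pat_frac) <- ct
  composite <- (pat_frac[, "GMP-like"] - pat_frac[, "HSC-like"]) +
    pat_frac[, "NK"]
  z <- if (stats::sd(composite) > 0)
    (composite - mean(composite)) / stats::sd(composite) else composite * 0
  p_resp <- stats::plogis(config$response_effect * z)
  responder <- stats::runif(config$n_patients) < p_resp
  # responders split CR vs CRi roughly 2:1, as seen clinically
  response <- ifelse(responder,
                     ifelse(stats::runif(config$n_patients) < 2 / 3,
                            "CR", "CRi"),
                     "TF")
  dose <- rep(config$dose_levels, length.out = config$n_patients)
  age <- round(stats::runif(config$n_patients, 55, 75))
  sex <- sample(c("M", "F"), config$n_patients, replace = TRUE)

  lengths_kb <- stats::setNames(
    exp(stats::runif(config$n_genes, log(0.5), log(10))),
    rownames(reference))
  prof <- sweep(reference, 2, colSums(reference), "/")
  rows <- list(); cnt <- list(); samp_frac <- list()
  for (i in seq_along(pid)) {
    for (ts in config$tissues) {
      f <- rdirichlet1(pat_frac[i, ] * config$tissue_concentration + 1e-6)
      sid <- sprintf("%s_%s_D0", pid[i], ts)
      # reads scale with expression x transcript length, so TPM recovers
      # the linear expression mixture the signature is defined on
      rate <- as.vector(prof %*% f) * lengths_kb
      mu <- config$sequencing_depth * rate / sum(rate)
      cnt[[sid]] <- stats::rnbinom(config$n_genes, mu = mu,
                                   size = 1 / config$nb_dispersion)
      samp_frac[[sid]] <- f
      rows[[sid]] <- data.frame(
        sample_id = sid, patient_id = pid[i], tissue = ts, day = 0,
        dose_mg_m2 = dose[i], response = response[i],
        os_time = NA_real_, os_event = NA_integer_,
        age = age[i], sex = sex[i], stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, cnt)
  rownames(counts) <- rownames(reference)
  sheet <- validate_sample_sheet(do.call(rbind, rows))
  true_fractions <- do.call(rbind, samp_frac)
  colnames(true_fractions) <- ct
  truth <- list(
    patient_fractions = pat_frac, sample_fractions = true_fractions,
    labels = stats::setNames(responder, pid),
    composite = stats::setNames(composite, pid),
    response_prob = stats::setNames(p_resp, pid))
  class(truth) <- "hmc_truth"
  list(counts = counts, sheet = sheet, gene_lengths_kb = lengths_kb,
       truth = truth)
}

#' Generate a paired Day0/Day5 5hmC cohort with ground truth
#'
#' Each patient has a private per-gene 5hmC baseline; at Day 5 a
#' dose-dependent random gene subset is shifted by `dhmg_log2_shift`
#' (random sign). A fixed set of response-informative genes is additionally
#' shifted in responders (both days), providing ground truth for signature
#' selection. Survival is exponential with log-hazard decreasing in the
#' number of shifted genes, censored at a uniform fraction of the event
#' time for a random `censoring_rate` share of patients.
#'
#' @param config A [sim_config()] with both days present.
#' @return List with `counts` (Day0 + Day5 raw matrix), `sheet` and `truth`
#'   (shifted gene sets and sizes, responder labels, response genes, true
#'   hazards).
#' @export
generate_hmc_cohort <- function(config) {
  stopifnot(inherits(config, "hmc_sim_config"))
  if (!all(c(0, 5) %in% config$days))
    hmc_stop("5hmC cohort needs both Day 0 and Day 5 in config$days",
             "hmc_config_error")
  set.seed(derive_seed(config$seed, "hmc"))
  n <- config$n_genes
  ids <- gene_ids(n)
  pid <- sprintf("P%03d", seq_len(config$n_patients))
  dose <- rep(config$dose_levels, length.out = config$n_patients)
  responder <- stats::runif(config$n_patients) < 0.5
  response <- ifelse(responder,
                     ifelse(stats::runif(config$n_patients) < 2 / 3,
                            "CR", "CRi"),
                     "TF")
  age <- round(stats::runif(config$n_patients, 55, 75))
  sex <- sample(c("M", "F"), config$n_patients, replace = TRUE)

  # shared cohort 5hmC profile (wide dynamic range across genes) with
  # moderate per-patient multiplicative deviations: patients differ, but
  # per-gene between-patient spread stays commensurate with the planted
  # responder and Day5 effects
  cohort_base <- stats::rlnorm(n, 0, 1)
  # response-informative genes are planted among detectably expressed genes
  eligible <- ids[cohort_base >= stats::quantile(cohort_base, 0.25)]
  response_genes <- sample(eligible, config$n_response_genes)
  resp_sign <- stats::setNames(
    sample(c(-1, 1), config$n_response_genes, replace = TRUE),
    response_genes)
  rows <- list(); cnt <- list()
  shifted_sets <- vector("list", config$n_patients)
  names(shifted_sets) <- pid
  hazards <- numeric(config$n_patients)
  os_time <- numeric(config$n_patients)
  os_event <- integer(config$n_patients)
  for (i in seq_along(pid)) {
    base <- cohort_base * stats::rlnorm(n, 0, 0.35)
    base <- base / sum(base)
    mu0 <- stats::setNames(config$sequencing_depth * base, ids)
    if (responder[i]) {
      mu0[response_genes] <- mu0[response_genes] *
        2^(resp_sign * config$response_log2_shift)
    }
    frac <- config$dhmg_fraction_per_dose[[as.character(dose[i])]]
    n_shift <- floor(frac * n)
    shifted <- if (n_shift > 0) sample(ids, n_shift) else character(0)
    shifted_sets[[i]] <- shifted
    mu5 <- mu0
    if (n_shift > 0) {
      sgn <- sample(c(-1, 1), n_shift, replace = TRUE)
      mu5[shifted] <- mu5[shifted] * 2^(sgn * config$dhmg_log2_shift)
    }
    hazards[i] <- config$base_hazard *
      exp(-config$survival_hazard_coef * n_shift)
    t_event <- stats::rexp(1, rate = hazards[i])
    if (stats::runif(1) < config$censoring_rate) {
      os_time[i] <- stats::runif(1, 0, t_event); os_event[i] <- 0L
    } else {
      os_time[i] <- t_event; os_event[i] <- 1L
    }
    for (ts in config$tissues) {
      for (d in c(0, 5)) {
        sid <- sprintf("%s_%s_D%d", pid[i], ts, d)
        mu <- if (d == 0) mu0 else mu5
        cnt[[sid]] <- stats::rnbinom(n, mu = mu,
                                     size = 1 / config$nb_dispersion)
        rows[[sid]] <- data.frame(
          sample_id = sid, patient_id = pid[i], tissue = ts, day = d,
          dose_mg_m2 = dose[i], response = response[i],
          os_time = os_time[i], os_event = os_event[i],
          age = age[i], sex = sex[i], stringsAsFactors = FALSE)
      }
    }
  }
  counts <- do.call(cbind, cnt)
  rownames(counts) <- ids
  sheet <- validate_sample_sheet(do.call(rbind, rows))
  truth <- list(
    labels = stats::setNames(responder, pid),
    dose = stats::setNames(dose, pid),
    shifted_sets = shifted_sets,
    shifted_sizes = stats::setNames(lengths(shifted_sets), pid),
    response_genes = response_genes,
    hazards = stats::setNames(hazards, pid))
  class(truth) <- "hmc_truth"
  list(counts = counts, sheet = sheet, truth = truth)
}

#' Write a simulated cohort to a directory
#'
#' Emits the counts TSV, sample sheet TSV, gene-length TSV (bulk cohorts)
#' and a truth JSON, the plain-text interchange formats the readers accept.
#'
#' @param cohort Output of [generate_bulk_cohort()] or
#'   [generate_hmc_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(cohort$counts, file.path(dir, "counts.tsv"))
  write_sample_sheet(cohort$sheet, file.path(dir, "sample_sheet.tsv"))
  if (!is.null(cohort$gene_lengths_kb)) {
    utils::write.table(
      data.frame(gene = names(cohort$gene_lengths_kb),
                 length_kb = cohort$gene_lengths_kb),
      file.path(dir, "gene_lengths.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- cohort$truth
  class(truth) <- NULL
  truth$patient_fractions <- if (!is.null(truth$patient_fractions))
    as.data.frame(truth$patient_fractions)
  truth$sample_fractions <- if (!is.null(truth$sample_fractions))
    as.data.frame(truth$sample_fractions)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
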