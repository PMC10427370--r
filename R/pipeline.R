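# End-to-end orchestration: run the stages in dependency order on a
# cohort (synthetic or user-supplied), write per-stage TSV/JSON outputs,
# a provenance manifest and a deterministic summary.

#' Run the full analysis pipeline
#'
#' Executes differential expression, co-expression modules, enrichment,
#' deconvolution, composition classifiers and (when a 5hmC cohort is
#' supplied or simulated) the per-patient DhMG statistics with survival
#' analysis, writing every stage's outputs plus a provenance manifest and
#' summary JSON to `out_dir`. With no input paths the pipeline simulates a
#' cohort from `sim` (a [sim_config()]), making a self-contained smoke run.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `out_dir` (required); optional `counts`, `sheet`, `gene_lengths`,
#'   `hmc_counts`, `hmc_sheet` file paths; `sim` (list of [sim_config()]
#'   overrides used when paths are absent); `stages` (character subset of
#'   `c("diff", "coexpression", "enrichment", "deconvolution",
#'   "classifiers", "survival")`); `seed` (global seed); `gmt` (path to
#'   gene sets for enrichment); `edges` (path to an interaction edge list).
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_full <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) hmc_stop("config$out_dir required", "hmc_config_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% c("diff", "coexpression", "enrichment",
                                 "deconvolution", "classifiers", "survival")
  summary <- list(seed = seed, stages = stages)
  manifest <- list(package_version = as.character(
    utils::packageVersion("hmcresponse")),
    seed = seed, stages = stages, config = config[order(names(config))])

  sim_overrides <- config$sim %||% list()
  sim_overrides$seed <- seed
  cfg <- do.call(sim_config, sim_overrides)

  # ---- inputs: bulk RNA cohort -------------------------------------------
  simulated <- is.null(config$counts)
  reference <- generate_reference_profiles(cfg)
  if (simulated) {
    bulk <- generate_bulk_cohort(cfg, reference)
    counts <- bulk$counts; sheet <- bulk$sheet
    lengths_kb <- bulk$gene_lengths_kb
    write_cohort(bulk, file.path(out_dir, "bulk_cohort"))
  } else {
    counts <- read_counts(config$counts)
    sheet <- read_sample_sheet(config$sheet)
    lt <- utils::read.delim(config$gene_lengths)
    lengths_kb <- stats::setNames(lt[[2]], lt[[1]])
  }
  manifest$simulated_bulk <- simulated
  responder <- is_responder(sheet$response)
  names(responder) <- sheet$sample_id

  tpm <- tpm_normalize(counts, lengths_kb)
  diff_res <- NULL
  run_stage <- function(name, expr) {
    if (!name %in% stages) {
      message(sprintf("stage '%s' disabled; skipping", name))
      return(NULL)
    }
    tryCatch(expr, error = function(e)
      hmc_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               "hmc_stage_error"))
  }

  # ---- differential expression -------------------------------------------
  if ("diff" %in% stages) {
    grp_a <- sheet$sample_id[!responder[sheet$sample_id]]
    grp_b <- sheet$sample_id[responder[sheet$sample_id]]
    diff_res <- run_stage("diff", nb_wald_test(counts, grp_a, grp_b))
    utils::write.table(diff_res, file.path(out_dir, "diff_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    degs <- filter_degs(diff_res)
    summary$n_deg <- length(degs$all)
    summary$n_deg_up <- length(degs$up)
    summary$n_deg_down <- length(degs$down)
  }

  # ---- co-expression modules ---------------------------------------------
  if ("coexpression" %in% stages && !is.null(diff_res)) {
    degs <- filter_degs(diff_res)$all
    if (length(degs) >= 8) {
      vst <- rlog_approx(counts)
      corr <- pairwise_correlation(vst[degs, , drop = FALSE])
      mods <- cluster_modules(corr, k = min(4, nrow(corr)))
      summary$module_sizes <- mods$sizes
      utils::write.table(
        data.frame(gene = names(mods$assignment),
                   module = mods$assignment),
        file.path(out_dir, "modules.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      message("coexpression skipped: fewer than 8 DEGs")
    }
  }

  # ---- enrichment ---------------------------------------------------------
  if ("enrichment" %in% stages && !is.null(diff_res)) {
    sets <- if (!is.null(config$gmt)) read_gmt(config$gmt) else
      list(top_marker_set = attr(reference, "markers")[["GMP-like"]])
    ranking <- stats::setNames(diff_res$stat, diff_res$gene)
    enr <- lapply(sets, function(s)
      tryCatch(preranked_gsea(ranking, s, n_perm = 500, seed = seed),
               error = function(e) NULL))
    summary$enrichment <- lapply(Filter(Negate(is.null), enr), function(e)
      list(es = e$es, nes = e$nes, p = e$p))
  }

  # ---- deconvolution + composition classifiers ---------------------------
  fractions_pat <- NULL
  if ("deconvolution" %in% stages) {
    sig <- build_signature(reference, markers_per_type = 50)
    est <- estimate_fractions(tpm, sig)
    comp <- compartment_normalize(est)
    fractions_pat <- average_tissues(comp, sheet)
    utils::write.table(
      data.frame(patient = rownames(fractions_pat), fractions_pat,
                 check.names = FALSE),
      file.path(out_dir, "fractions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    summary$mean_fractions <- as.list(round(colMeans(fractions_pat), 4))
  }
  if ("classifiers" %in% stages) {
    if (is.null(fractions_pat)) {
      message("composition classifiers skipped: deconvolution disabled")
    } else {
      pat_resp <- is_responder(
        sheet$response[match(rownames(fractions_pat), sheet$patient_id)])
      if (length(unique(pat_resp)) == 2) {
        summary$composition_auc <- lapply(
          c(gmp = "gmp", gmp_minus_hsc = "gmp_minus_hsc", nk = "nk",
            nk_plus_gmp = "nk_plus_gmp"),
          function(m) roc_auc(composition_score(fractions_pat, m),
                              pat_resp)$auc)
      }
    }
  }

  # ---- 5hmC responsiveness + survival ------------------------------------
  if ("survival" %in% stages) {
    if (!is.null(config$hmc_counts)) {
      hmc_counts <- read_counts(config$hmc_counts)
      hmc_sheet <- read_sample_sheet(config$hmc_sheet)
    } else {
      hmc <- generate_hmc_cohort(cfg)
      hmc_counts <- hmc$counts; hmc_sheet <- hmc$sheet
      write_cohort(hmc, file.path(out_dir, "hmc_cohort"))
    }
    pats <- unique(hmc_sheet$patient_id)
    dhmg <- vapply(pats, function(p)
      as.integer(patient_dhmg_count(hmc_counts, hmc_sheet, p)), integer(1))
    doses <- hmc_sheet$dose_mg_m2[match(pats, hmc_sheet$patient_id)]
    utils::write.table(
      data.frame(patient = pats, dose = doses, dhmg_count = dhmg),
      file.path(out_dir, "dhmg_counts.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    summary$dhmg_median_by_dose <- as.list(
      tapply(dhmg, doses, stats::median))
    grp <- median_split(dhmg)
    os <- hmc_sheet[match(pats, hmc_sheet$patient_id),
                    c("os_time", "os_event")]
    lr <- logrank_test(os$os_time, os$os_event, grp)
    summary$survival_logrank_p <- lr$p
    summary$survival_split_sizes <- as.list(attr(grp, "sizes"))
    km <- rbind(
      cbind(group = "low", km_estimate(os$os_time[grp == "low"],
                                       os$os_event[grp == "low"])),
      cbind(group = "high", km_estimate(os$os_time[grp == "high"],
                                        os$os_event[grp == "high"])))
    utils::write.table(km, file.path(out_dir, "km_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Bone-marrow / peripheral-blood concordance
#'
#' Per-patient Pearson correlation between the BM and PB feature vectors
#' (cell-type fractions or any per-sample feature matrix).
#'
#' @param features Samples x features numeric matrix (rownames =
#'   sample_id).
#' @param sheet Sample sheet.
#' @return List with per-patient `correlations` and their `mean`.
#' @export
concordance_check <- function(features, sheet) {
  pats <- unique(sheet$patient_id)
  cors <- c()
  for (p in pats) {
    rows <- sheet[sheet$patient_id == p, ]
    bm <- rows$sample_id[rows$tissue == "BM"]
    pb <- rows$sample_id[rows$tissue == "PB"]
    bm <- intersect(bm, rownames(features))
    pb <- intersect(pb, rownames(features))
    if (!length(bm) || !length(pb)) next
    v_bm <- colMeans(features[bm, , drop = FALSE])
    v_pb <- colMeans(features[pb, , drop = FALSE])
    cors[p] <- stats::cor(v_bm, v_pb)
  }
  if (!length(cors))
    hmc_stop("no patients with both BM and PB samples",
             "hmc_validation_error")
  list(correlations = cors, mean = mean(cors))
}
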