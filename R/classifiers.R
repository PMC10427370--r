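# Response classifiers: composition-based scores with ROC/AUC, and the
# 5hmC gradient-boosting signature -- patient-grouped cross-validation,
# split-count (F score) gene ranking, top-k refit, shuffled-label control,
# and a train/test leakage guard.

#' Composition-based response score
#'
#' Scores patients from their (compartment-normalized, tissue-averaged)
#' cell-type fractions. `gmp_minus_hsc` is the GMP-like minus HSC-like
#' fraction; `nk_plus_gmp` the sum of NK and GMP-like fractions;
#' single-type modes return the fraction itself.
#'
#' @param fractions Patients x cell-types matrix.
#' @param mode One of `"gmp"`, `"hsc"`, `"gmp_minus_hsc"`, `"nk"`,
#'   `"nk_plus_gmp"`.
#' @return Named numeric vector of patient scores.
#' @export
composition_score <- function(fractions,
                              mode = c("gmp_minus_hsc", "gmp", "hsc", "nk",
                                       "nk_plus_gmp")) {
  mode <- match.arg(mode)
  need <- switch(mode,
    gmp = "GMP-like", hsc = "HSC-like", nk = "NK",
    gmp_minus_hsc = c("GMP-like", "HSC-like"),
    nk_plus_gmp = c("NK", "GMP-like"))
  miss <- setdiff(need, colnames(fractions))
  if (length(miss))
    hmc_stop(sprintf("missing cell type(s): %s", paste(miss, collapse = ", ")),
             "hmc_validation_error")
  out <- switch(mode,
    gmp = fractions[, "GMP-like"],
    hsc = fractions[, "HSC-like"],
    nk = fractions[, "NK"],
    gmp_minus_hsc = fractions[, "GMP-like"] - fractions[, "HSC-like"],
    nk_plus_gmp = fractions[, "NK"] + fractions[, "GMP-like"])
  stats::setNames(as.vector(out), rownames(fractions))
}

#' ROC curve and AUC
#'
#' AUC as the Mann-Whitney U statistic scaled by `n_pos * n_neg` (tied
#' scores count one half), with curve points at every observed threshold.
#'
#' @param scores Numeric scores, higher = more likely positive.
#' @param labels Logical (or 0/1) class labels.
#' @return An `hmc_roc` list: `auc` and a `curve` data.frame of
#'   (threshold, fpr, tpr).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels))
    hmc_stop("scores and labels must be complete", "hmc_validation_error")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    hmc_stop("both classes must be present", "hmc_validation_error")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(scores >= t & !labels) / n_neg, 0),
    tpr = vapply(thr, function(t) sum(scores >= t & labels) / n_pos, 0))
  out <- list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg)
  class(out) <- "hmc_roc"
  out
}

#' @export
print.hmc_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Patient-grouped k-fold assignment
#'
#' Partitions patients (not samples) into k folds balanced in patient
#' count (sizes differ by at most 1); every sample of a patient inherits
#' the patient's fold, so no patient can appear on both sides of a split.
#'
#' @param patients Character vector of patient ids (duplicates collapse).
#' @param k Number of folds.
#' @param seed Optional seed for the shuffle.
#' @return Named integer vector: fold per patient.
#' @export
grouped_kfold <- function(patients, k = 5, seed = NULL) {
  pats <- unique(patients)
  if (k > length(pats))
    hmc_stop(sprintf("k = %d exceeds number of patients (%d)",
                     k, length(pats)),
             "hmc_validation_error")
  if (!is.null(seed)) set.seed(seed)
  # assign in shuffled order; fold sizes n%/%k, +1 for the first n%%k folds
  shuffled <- sample(pats)
  fold <- integer(length(pats))
  names(fold) <- shuffled
  sizes <- rep(length(pats) %/% k, k) +
    c(rep(1, length(pats) %% k), rep(0, k - length(pats) %% k))
  fold[] <- rep(seq_len(k), times = sizes)
  fold[pats]
}

count_splits <- function(bst, feature_names) {
  tr <- xgboost::xgb.model.dt.tree(model = bst)
  tab <- table(tr$Feature[tr$Feature != "Leaf"])
  out <- stats::setNames(numeric(length(feature_names)), feature_names)
  out[names(tab)] <- as.numeric(tab)
  out
}

fit_xgb <- function(x, y, params, nrounds) {
  d <- xgboost::xgb.DMatrix(x, label = as.numeric(y))
  xgboost::xgb.train(params = params, data = d, nrounds = nrounds,
                     verbose = 0)
}

#' Train a 5hmC gradient-boosting response signature model
#'
#' Fits a gradient-boosted tree ensemble (binary logistic) on
#' rlog-transformed 5hmC features. Out-of-fold probabilities from the
#' patient-grouped folds are pooled into the cross-validation AUC; gene
#' importance is the F score (number of tree splits using the gene) of a
#' final fit on all training samples. Responders are the positive class.
#'
#' @param features Samples x genes numeric matrix (rlog scale).
#' @param labels Logical responder label per sample.
#' @param patients Patient id per sample.
#' @param folds Fold assignment per patient from [grouped_kfold()].
#' @param max_depth,nrounds,eta Boosting hyperparameters (defaults 3, 100,
#'   0.1).
#' @param colsample_bytree Fraction of genes sampled per tree (default
#'   0.1). With many more genes than samples a greedy booster re-uses a
#'   handful of features; per-tree column subsampling spreads splits across
#'   the informative set, stabilizing the F-score ranking.
#' @param seed Seed recorded and passed to the booster.
#' @return An `hmc_sigmodel` list: the final `model`, `fscore`, pooled
#'   `cv_auc`, `cv_prob` (out-of-fold probabilities), fold map, training
#'   data and hyperparameters (kept for refits and the leakage guard).
#' @export
train_signature_model <- function(features, labels, patients, folds,
                                  max_depth = 3, nrounds = 100, eta = 0.1,
                                  colsample_bytree = 0.1, seed = 1L) {
  if (nrow(features) != length(labels) || length(labels) != length(patients))
    hmc_stop("features, labels and patients must align",
             "hmc_validation_error")
  if (is.null(colnames(features)))
    hmc_stop("features must have gene column names", "hmc_validation_error")
  miss <- setdiff(unique(patients), names(folds))
  if (length(miss))
    hmc_stop(sprintf("patients without fold assignment: %s",
                     paste(utils::head(miss, 5), collapse = ", ")),
             "hmc_validation_error")
  sample_fold <- folds[patients]
  params <- list(objective = "binary:logistic", max_depth = max_depth,
                 eta = eta, colsample_bytree = colsample_bytree,
                 nthread = 1, seed = seed)
  cv_prob <- rep(NA_real_, nrow(features))
  fold_auc <- c()
  for (f in sort(unique(sample_fold))) {
    hold <- sample_fold == f
    # leakage invariant: folds are per patient, so no patient can have
    # samples on both sides of this split
    stopifnot(!any(patients[hold] %in% patients[!hold]))
    if (length(unique(labels[!hold])) < 2) {
      cv_prob[hold] <- mean(labels[!hold])
      next
    }
    bst <- fit_xgb(features[!hold, , drop = FALSE], labels[!hold],
                   params, nrounds)
    cv_prob[hold] <- stats::predict(
      bst, xgboost::xgb.DMatrix(features[hold, , drop = FALSE]))
    if (length(unique(labels[hold])) == 2)
      fold_auc[as.character(f)] <- roc_auc(cv_prob[hold], labels[hold])$auc
  }
  cv_auc <- roc_auc(cv_prob, labels)$auc
  cv_auc_fold_mean <- if (length(fold_auc)) mean(fold_auc) else NA_real_
  final <- fit_xgb(features, labels, params, nrounds)
  fscore <- count_splits(final, colnames(features))
  if (all(fscore == 0))
    warning("no informative splits; model is constant (AUC ~ 0.5)")
  out <- list(model = final, fscore = sort(fscore, decreasing = TRUE),
              cv_auc = cv_auc, cv_auc_fold_mean = cv_auc_fold_mean,
              cv_prob = cv_prob, folds = folds,
              genes = colnames(features),
              train_features = features, train_labels = labels,
              train_patients = patients,
              params = params, nrounds = nrounds, seed = seed)
  class(out) <- "hmc_sigmodel"
  out
}

#' @export
print.hmc_sigmodel <- function(x, ...) {
  cat(sprintf("5hmC signature model: %d genes, %d training samples (%d patients)\n",
              length(x$genes), nrow(x$train_features),
              length(unique(x$train_patients))))
  cat(sprintf("  pooled grouped-CV AUC: %.3f\n", x$cv_auc))
  top <- utils::head(x$fscore[x$fscore > 0], 5)
  cat(sprintf("  top F scores: %s\n",
              paste(sprintf("%s=%d", names(top), top), collapse = ", ")))
  invisible(x)
}

#' Select the best top-k gene signature by cross-validated refit
#'
#' For each k in the grid, the top-k genes by F score are used to refit the
#' model under the same patient-grouped folds; the k maximizing the pooled
#' CV AUC wins (ties go to the smaller k). The returned model is refit on
#' the full training set restricted to the chosen genes.
#'
#' @param model An [train_signature_model()] result.
#' @param k_grid Integer vector of candidate signature sizes.
#' @return An `hmc_sigmodel` for the chosen gene subset, with `k`,
#'   `selected_genes` and `cv_auc_by_k` recorded.
#' @export
select_top_k_refit <- function(model, k_grid = c(5, 11, 25, 50)) {
  stopifnot(inherits(model, "hmc_sigmodel"))
  ranked <- names(model$fscore)
  n_avail <- sum(model$fscore > 0)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid > length(ranked))) {
    warning("k grid truncated to the number of features")
    k_grid <- k_grid[k_grid <= length(ranked)]
  }
  if (!length(k_grid))
    hmc_stop("empty k grid", "hmc_validation_error")
  refit_with <- function(genes) {
    train_signature_model(
      model$train_features[, genes, drop = FALSE], model$train_labels,
      model$train_patients, model$folds,
      max_depth = model$params$max_depth, nrounds = model$nrounds,
      eta = model$params$eta,
      colsample_bytree = model$params$colsample_bytree, seed = model$seed)
  }
  aucs <- vapply(k_grid, function(k) refit_with(ranked[seq_len(k)])$cv_auc,
                 numeric(1))
  best_k <- k_grid[which.max(aucs)]  # which.max takes the first (smallest k)
  genes <- ranked[seq_len(best_k)]
  refit <- refit_with(genes)
  refit$k <- best_k
  refit$selected_genes <- genes
  refit$cv_auc_by_k <- stats::setNames(aucs, k_grid)
  refit$n_contributing <- n_avail
  refit
}

#' Shuffled-label control for the signature model
#'
#' Re-trains the model with patient response labels randomly permuted
#' across patients (each patient's samples keep a common, shuffled label)
#' and records the fold-averaged CV AUC per shuffle. A sound pipeline
#' yields control AUCs centered on 0.5. The fold-averaged statistic is used
#' because pooled out-of-fold probabilities are biased below 0.5 under a
#' label-permutation null (fold models' probability scales anti-correlate
#' with held-out class balance), which would make the control misleadingly
#' "anti-predictive" even for a leak-free pipeline.
#'
#' @param model An [train_signature_model()] result.
#' @param n_shuffles Number of label permutations.
#' @param seed Seed for the shuffle stream.
#' @return Numeric vector of control CV AUCs.
#' @export
shuffled_label_control <- function(model, n_shuffles = 20, seed = 1L) {
  stopifnot(inherits(model, "hmc_sigmodel"))
  set.seed(seed)
  pats <- unique(model$train_patients)
  pat_label <- vapply(pats, function(p)
    model$train_labels[match(p, model$train_patients)], logical(1))
  vapply(seq_len(n_shuffles), function(i) {
    shuf <- stats::setNames(sample(pat_label), pats)
    lab <- shuf[model$train_patients]
    m <- train_signature_model(
      model$train_features, lab, model$train_patients, model$folds,
      max_depth = model$params$max_depth, nrounds = model$nrounds,
      eta = model$params$eta,
      colsample_bytree = model$params$colsample_bytree, seed = model$seed)
    m$cv_auc_fold_mean
  }, numeric(1))
}

#' Evaluate a signature model on a held-out test set
#'
#' Hard leakage guard: any patient present in both the training and test
#' sets is an error. Reports the overall test AUC plus within-day and
#' within-tissue AUCs when a sample sheet is supplied.
#'
#' @param model An `hmc_sigmodel` (typically from [select_top_k_refit()]).
#' @param features Test samples x genes matrix.
#' @param labels Logical test labels per sample.
#' @param patients Test patient ids per sample.
#' @param sheet Optional sample sheet (rows matched by rownames of
#'   `features` against `sample_id`) for subgroup AUCs.
#' @return List with `auc`, `prob`, and `subgroup_auc` (named vector, NA
#'   where a subgroup lacks both classes).
#' @export
evaluate_test <- function(model, features, labels, patients, sheet = NULL) {
  overlap <- intersect(unique(patients), unique(model$train_patients))
  if (length(overlap))
    hmc_stop(sprintf("train/test patient overlap: %s",
                     paste(overlap, collapse = ", ")),
             "hmc_leakage_error")
  genes <- model$selected_genes %||% model$genes
  miss <- setdiff(genes, colnames(features))
  if (length(miss))
    hmc_stop(sprintf("test features missing %d model gene(s)", length(miss)),
             "hmc_validation_error")
  prob <- stats::predict(
    model$model, xgboost::xgb.DMatrix(features[, genes, drop = FALSE]))
  names(prob) <- rownames(features)
  auc <- roc_auc(prob, labels)$auc
  sub <- c()
  if (!is.null(sheet)) {
    meta <- sheet[match(rownames(features), sheet$sample_id), ]
    groups <- list(day0 = meta$day == 0, day5 = meta$day == 5,
                   BM = meta$tissue == "BM", PB = meta$tissue == "PB")
    sub <- vapply(groups, function(g) {
      g <- which(g)
      if (length(unique(labels[g])) < 2) return(NA_real_)
      roc_auc(prob[g], labels[g])$auc
    }, numeric(1))
  }
  list(auc = auc, prob = prob, subgroup_auc = sub)
}
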