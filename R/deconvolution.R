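# Digital cytometry: build a signature matrix from cell-type reference
# profiles and estimate malignant/immune fractions in bulk samples by
# non-negative least squares in linear (TPM) space.

#' Build a deconvolution signature matrix
#'
#' For each cell type, genes are ranked by their fold over the maximum of
#' all other types, and the top `markers_per_type` discriminating genes are
#' taken; the union of selections forms the signature rows. A deliberate,
#' transparent replacement for condition-number-swept signature builders:
#' selection is deterministic and the resulting condition number is
#' reported rather than optimized.
#'
#' @param reference Genes x cell-types matrix of positive mean expressions.
#' @param markers_per_type Number of genes selected per type (default 50).
#' @param compartments Named vector mapping cell type to `"malignant"` or
#'   `"immune"`; defaults to [cell_type_compartments()] when the reference
#'   columns match the 13 canonical types.
#' @return An `hmc_signature` matrix (signature genes x types) with
#'   `compartments` and `condition_number` attributes.
#' @export
build_signature <- function(reference, markers_per_type = 50,
                            compartments = NULL) {
  if (is.null(compartments)) {
    if (!all(colnames(reference) %in% names(cell_type_compartments())))
      hmc_stop("supply a compartments map for non-canonical cell types",
               "hmc_validation_error")
    compartments <- cell_type_compartments()[colnames(reference)]
  }
  k <- ncol(reference)
  sel <- character(0)
  for (t in seq_len(k)) {
    other_max <- apply(reference[, -t, drop = FALSE], 1, max)
    fold <- reference[, t] / pmax(other_max, .Machine$double.eps)
    disc <- fold > 1
    if (!any(disc))
      hmc_stop(sprintf("cell type '%s' has no discriminating genes",
                       colnames(reference)[t]),
               "hmc_validation_error")
    take <- order(fold, decreasing = TRUE)[seq_len(min(markers_per_type,
                                                       sum(disc)))]
    sel <- union(sel, rownames(reference)[take])
  }
  sig <- reference[sel, , drop = FALSE]
  attr(sig, "compartments") <- compartments
  attr(sig, "condition_number") <- kappa(sig, exact = TRUE)
  class(sig) <- c("hmc_signature", class(sig))
  sig
}

#' Estimate cell-type fractions by non-negative least squares
#'
#' Solves, per sample, `min || S f - b ||` subject to `f >= 0` over the
#' signature genes, in linear TPM space (no log transform: mixing is
#' assumed linear in expression), then rescales the weights to proportions.
#' Scale-invariant in the bulk column.
#'
#' @param bulk Gene x sample matrix (TPM or comparable linear scale).
#' @param signature An [build_signature()] matrix.
#' @param min_overlap Minimum fraction of signature genes that must be
#'   present in the bulk matrix (default 0.5).
#' @return An `hmc_fractions` object: `fractions` (samples x types summing
#'   to 1), `raw_weights`, `residual_norm`, plus the compartment map.
#' @export
estimate_fractions <- function(bulk, signature, min_overlap = 0.5) {
  genes <- intersect(rownames(signature), rownames(bulk))
  if (length(genes) < min_overlap * nrow(signature))
    hmc_stop(sprintf(
      "only %d/%d signature genes present in bulk (need >= %.0f%%)",
      length(genes), nrow(signature), 100 * min_overlap),
      "hmc_validation_error")
  S <- unclass(signature)[genes, , drop = FALSE]
  B <- bulk[genes, , drop = FALSE]
  k <- ncol(S)
  n <- ncol(B)
  w <- matrix(0, n, k, dimnames = list(colnames(B), colnames(S)))
  rn <- numeric(n)
  for (j in seq_len(n)) {
    b <- B[, j]
    scale <- sum(b)
    if (scale <= 0) next  # empty sample: all-zero weights
    # solve on the unit-sum column: NNLS is scale-equivariant, and a fixed
    # problem scale keeps the active-set iteration well-conditioned
    fit <- pracma::lsqnonneg(S, b / scale)
    w[j, ] <- fit$x
    rn[j] <- sqrt(fit$resid.norm) * scale
  }
  tot <- rowSums(w)
  frac <- w / ifelse(tot > 0, tot, 1)
  out <- list(fractions = frac, raw_weights = w, residual_norm = rn,
              compartments = attr(signature, "compartments"))
  class(out) <- "hmc_fractions"
  out
}

#' @export
print.hmc_fractions <- function(x, ...) {
  cat(sprintf("Cell-type fraction estimates: %d samples x %d types\n",
              nrow(x$fractions), ncol(x$fractions)))
  cat("Mean fractions:\n")
  print(round(colMeans(x$fractions), 3))
  invisible(x)
}

#' Renormalize fractions within compartments
#'
#' Rescales the malignant subset vector and the immune population vector so
#' each sums to 1 within its compartment. A compartment with zero mass in a
#' sample yields NA for that compartment with a warning. Idempotent.
#'
#' @param est An [estimate_fractions()] result (or a plain samples x types
#'   matrix plus `compartments`).
#' @param compartments Optional compartment map overriding the stored one.
#' @return Matrix of compartment-normalized fractions (same shape), with
#'   each compartment block summing to 1 per sample.
#' @export
compartment_normalize <- function(est, compartments = NULL) {
  frac <- if (inherits(est, "hmc_fractions")) est$fractions else est
  compartments <- compartments %||%
    (if (inherits(est, "hmc_fractions")) est$compartments) %||%
    cell_type_compartments()[colnames(frac)]
  out <- frac
  for (comp in unique(compartments)) {
    cols <- names(compartments)[compartments == comp]
    cols <- intersect(cols, colnames(frac))
    s <- rowSums(frac[, cols, drop = FALSE])
    zero <- s <= 0
    if (any(zero)) {
      warning(sprintf("%d sample(s) have zero %s mass; returning NA",
                      sum(zero), comp))
      s[zero] <- NA_real_
    }
    out[, cols] <- frac[, cols, drop = FALSE] / s
  }
  out
}

#' Average fractions across tissues per patient
#'
#' Arithmetic mean of the per-sample fraction vectors across the tissues
#' available for each patient. Means of points on a simplex stay on the
#' simplex, so no renormalization is applied.
#'
#' @param est An [estimate_fractions()] result or samples x types matrix.
#' @param sheet Sample sheet mapping `sample_id` to `patient_id`.
#' @return Patients x types matrix.
#' @export
average_tissues <- function(est, sheet) {
  frac <- if (inherits(est, "hmc_fractions")) est$fractions else est
  common <- intersect(rownames(frac), sheet$sample_id)
  if (!length(common))
    hmc_stop("no estimated samples found in sample sheet",
             "hmc_validation_error")
  dropped <- setdiff(sheet$sample_id, rownames(frac))
  if (length(dropped))
    warning(sprintf("%d sheet sample(s) without estimates excluded",
                    length(dropped)))
  pat <- sheet$patient_id[match(common, sheet$sample_id)]
  sums <- rowsum(frac[common, , drop = FALSE], pat)
  counts <- table(pat)
  sums / as.vector(counts[rownames(sums)])
}
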