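# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed error
#'
#' All user-facing errors in the package carry a condition class so callers
#' can distinguish format errors from validation errors programmatically.
#' @noRd
hmc_stop <- function(msg, class = "hmc_error", call. = FALSE) {
  stop(structure(
    class = c(class, "hmc_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' The 13 reference cell types
#'
#' Six malignant AML subsets (named for the normal hematopoietic state they
#' resemble) and seven non-leukemic immune populations.
#'
#' @return Named character vector mapping cell type to compartment
#'   (`"malignant"` or `"immune"`).
#' @export
cell_type_compartments <- function() {
  c(
    "HSC-like" = "malignant", "Prog-like" = "malignant",
    "GMP-like" = "malignant", "ProMono-like" = "malignant",
    "Mono-like" = "malignant", "cDC-like" = "malignant",
    "B" = "immune", "cDC" = "immune", "CTL" = "immune",
    "Monocyte" = "immune", "Plasma" = "immune", "T" = "immune",
    "NK" = "immune"
  )
}

# Normalization state of a count matrix ("raw", "normalized", "tpm",
# "rlog-approx"). Stored as an attribute so matrices stay plain matrices.
count_state <- function(x) attr(x, "hmc_state") %||% "raw"

`count_state<-` <- function(x, value) {
  attr(x, "hmc_state") <- value
  x
}

assert_count_matrix <- function(x, require_raw = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    hmc_stop("count matrix must be a numeric matrix", "hmc_validation_error")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    hmc_stop("count matrix must have gene rownames and sample colnames",
             "hmc_validation_error")
  if (anyNA(x) || any(x < 0))
    hmc_stop("count matrix must be non-negative and complete",
             "hmc_validation_error")
  if (require_raw) {
    if (count_state(x) != "raw")
      hmc_stop(sprintf("raw counts required, got state '%s'", count_state(x)),
               "hmc_validation_error")
    if (any(x != round(x)))
      hmc_stop("raw counts must be integers", "hmc_validation_error")
  }
  invisible(x)
}

# Round half-up to whole percent (0.6087 -> 61), matching clinical reporting.
percent_round <- function(p) floor(p * 100 + 0.5)

# Deterministic sub-seed derivation: one RNG stream per cohort, children for
# per-sample draws, kept below 2^31.
derive_seed <- function(seed, salt) {
  (as.integer(seed) * 69069 + sum(utf8ToInt(as.character(salt)))) %% 2147483647L
}

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}
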