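# Readers and writers for the on-disk artifacts: count matrices (TSV),
# sample sheets (TSV), gene sets (GMT). TSV throughout; gene ids are opaque
# strings.

#' Read a gene x sample count matrix from TSV
#'
#' Expects a header line; the first column holds gene identifiers, remaining
#' columns one sample each. Entries must be non-negative; for `state = "raw"`
#' they must additionally be integers.
#'
#' @param path Path to a tab-separated file.
#' @param state Normalization state tag to attach (`"raw"`, `"normalized"`,
#'   `"tpm"` or `"rlog-approx"`). Non-raw states permit fractional values.
#' @return Numeric matrix with gene rownames, sample colnames and the state
#'   recorded as an attribute.
#' @export
read_counts <- function(path, state = "raw") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    hmc_stop("count TSV needs a gene id column plus at least one sample",
             "hmc_format_error")
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    hmc_stop(sprintf("duplicate gene id(s): %s",
                     paste(unique(dup), collapse = ", ")),
             "hmc_format_error")
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      hmc_stop(sprintf("non-numeric entry at row %d, column '%s'",
                       bad, colnames(vals)[j]),
               "hmc_format_error")
    }
  }
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (any(m < 0))
    hmc_stop("negative counts are not allowed", "hmc_format_error")
  if (state == "raw" && any(m != round(m)))
    hmc_stop("raw counts must be integers", "hmc_format_error")
  count_state(m) <- state
  m
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_counts()]: first column `gene`, one column per sample.
#' @param x Count matrix.
#' @param path Output path.
#' @export
write_counts <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, `name<TAB>description<TAB>member...`.
#' Members of the form `gene=weight` are parsed into per-gene numeric weights
#' (used for coefficient-weighted signature scores such as LSC17-style
#' scores); plain members carry no weights.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (order-preserving). Sets with
#'   weighted members carry a named numeric `weights` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      hmc_stop(sprintf("GMT line %d has fewer than 3 fields", i),
               "hmc_format_error")
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members))
      hmc_stop(sprintf("GMT set '%s' has no members", f[1]),
               "hmc_format_error")
    if (all(grepl("=", members, fixed = TRUE))) {
      parts <- strsplit(members, "=", fixed = TRUE)
      genes <- vapply(parts, `[`, "", 1)
      w <- as.numeric(vapply(parts, `[`, "", 2))
      if (anyNA(w))
        hmc_stop(sprintf("GMT set '%s': malformed weight", f[1]),
                 "hmc_format_error")
      names(w) <- genes
      members <- genes
      attr(members, "weights") <- w
    }
    if (anyDuplicated(members))
      hmc_stop(sprintf("GMT set '%s' has duplicate members", f[1]),
               "hmc_format_error")
    out[[f[1]]] <- members
  }
  out
}

#' Write gene sets to GMT
#' @param sets Named list of character vectors, optionally with a `weights`
#'   attribute as produced by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    members <- sets[[nm]]
    w <- attr(members, "weights")
    if (!is.null(w)) members <- paste0(members, "=", w[members])
    paste(c(nm, "na", members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

.sheet_required <- c("sample_id", "patient_id", "tissue", "day")
.sheet_optional <- c("dose_mg_m2", "response", "os_time", "os_event",
                     "age", "sex")

#' Validate a sample sheet
#'
#' Checks the metadata table that binds samples to patients: unique sample
#' ids, unique (patient, tissue, day) triples, categorical fields restricted
#' to their allowed values (tissue BM/PB; day 0/5; dose 37.5/50/75 mg/m2;
#' response CR/CRi/TF; event 0/1), and survival time present whenever an
#' event is recorded. Optional fields may be missing entirely or NA per row.
#'
#' @param sheet A data.frame.
#' @return The validated data.frame, invisibly classed `hmc_sheet`.
#' @export
validate_sample_sheet <- function(sheet) {
  miss <- setdiff(.sheet_required, names(sheet))
  if (length(miss))
    hmc_stop(sprintf("sample sheet missing column(s): %s",
                     paste(miss, collapse = ", ")),
             "hmc_validation_error")
  if (anyDuplicated(sheet$sample_id))
    hmc_stop("duplicate sample_id in sample sheet", "hmc_validation_error")
  key <- paste(sheet$patient_id, sheet$tissue, sheet$day)
  if (anyDuplicated(key))
    hmc_stop("duplicate (patient_id, tissue, day) in sample sheet",
             "hmc_validation_error")
  check_levels <- function(col, allowed) {
    if (!col %in% names(sheet)) return()
    v <- sheet[[col]]
    bad <- setdiff(unique(v[!is.na(v)]), allowed)
    if (length(bad))
      hmc_stop(sprintf("unknown %s value(s): %s", col,
                       paste(bad, collapse = ", ")),
               "hmc_validation_error")
  }
  check_levels("tissue", c("BM", "PB"))
  check_levels("day", c(0, 5))
  check_levels("dose_mg_m2", c(37.5, 50, 75))
  check_levels("response", c("CR", "CRi", "TF"))
  check_levels("os_event", c(0, 1))
  check_levels("sex", c("M", "F"))
  if (all(c("os_time", "os_event") %in% names(sheet))) {
    ev <- !is.na(sheet$os_event) & sheet$os_event == 1
    if (any(ev & is.na(sheet$os_time)))
      hmc_stop("os_event = 1 requires os_time", "hmc_validation_error")
    if (any(!is.na(sheet$os_time) & sheet$os_time < 0))
      hmc_stop("os_time must be non-negative", "hmc_validation_error")
  }
  class(sheet) <- unique(c("hmc_sheet", class(sheet)))
  invisible(sheet)
}

#' Read and validate a sample sheet TSV
#' @param path Path to a tab-separated sample sheet.
#' @return Validated data.frame (see [validate_sample_sheet()]).
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' Write a sample sheet TSV
#' @param sheet Sample sheet data.frame.
#' @param path Output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Responder status from clinical response category
#'
#' Responders are patients achieving complete remission with or without
#' count recovery (CR or CRi); treatment failure (TF) is non-response.
#'
#' @param response Character vector of CR / CRi / TF (NA allowed).
#' @return Logical vector (NA where response missing).
#' @export
is_responder <- function(response) {
  out <- rep(NA, length(response))
  out[response %in% c("CR", "CRi")] <- TRUE
  out[response %in% "TF"] <- FALSE
  out
}

#' Overall response rate of a cohort
#'
#' Counts each patient once; the overall response rate is
#' (CR + CRi) / total, reported both as a proportion and as a whole percent
#' (rounded half-up).
#'
#' @param sheet Sample sheet with `patient_id` and `response` columns.
#' @return List with `n_responders`, `n_total`, `rate` and `pct`.
#' @export
responder_rate <- function(sheet) {
  per_patient <- !duplicated(sheet$patient_id)
  resp <- sheet$response[per_patient]
  resp <- resp[!is.na(resp)]
  if (!length(resp))
    hmc_stop("no patients with recorded response", "hmc_validation_error")
  n_resp <- sum(is_responder(resp))
  n_tot <- length(resp)
  list(n_responders = n_resp, n_total = n_tot,
       rate = n_resp / n_tot, pct = percent_round(n_resp / n_tot))
}
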