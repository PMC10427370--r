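# Normalization and differential testing: median-of-ratios size factors,
# TPM, an rlog approximation, a negative-binomial Wald test with trended
# dispersion shrinkage, BH adjustment and the threshold filters for
# differentially expressed genes (DEGs) and differentially
# hydroxymethylated genes (DhMGs).

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: each sample's factor is the median, over genes
#' expressed in every sample, of that sample's count divided by the gene's
#' geometric mean across samples.
#'
#' @param counts Raw count matrix (genes x samples).
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  assert_count_matrix(counts)
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep))
    hmc_stop(paste0("no gene is expressed in all samples; supply a filtered ",
                    "matrix or use a pseudo-reference"),
             "hmc_validation_error")
  sub <- counts[keep, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  sf <- apply(sub / geo, 2, stats::median)
  stats::setNames(sf, colnames(counts))
}

#' Transcripts-per-million normalization
#'
#' Counts are divided by gene length (kb) to per-kilobase rates, then each
#' sample is scaled so its rates sum to one million.
#'
#' @param counts Raw count matrix.
#' @param lengths_kb Named numeric vector of gene lengths in kilobases.
#' @return Matrix in TPM state; every column sums to 1e6.
#' @export
tpm_normalize <- function(counts, lengths_kb) {
  assert_count_matrix(counts)
  missing <- setdiff(rownames(counts), names(lengths_kb))
  if (length(missing))
    hmc_stop(sprintf("missing gene length(s): %s",
                     paste(utils::head(missing, 5), collapse = ", ")),
             "hmc_validation_error")
  len <- lengths_kb[rownames(counts)]
  if (any(len <= 0))
    hmc_stop("gene lengths must be positive", "hmc_validation_error")
  rate <- counts / len
  out <- sweep(rate, 2, colSums(rate), "/") * 1e6
  count_state(out) <- "tpm"
  out
}

#' Approximate regularized-log transform
#'
#' `log2(count / size_factor + 1)` per entry: a documented approximation to
#' the regularized log that shares its scale (log2 of normalized counts) and
#' its behavior at high counts, without the per-gene shrinkage fit.
#'
#' @param counts Raw count matrix.
#' @param sf Size factors; computed with [size_factors()] when omitted.
#' @return Matrix in rlog-approx state.
#' @export
rlog_approx <- function(counts, sf = NULL) {
  assert_count_matrix(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  out <- log2(sweep(counts, 2, sf, "/") + 1)
  count_state(out) <- "rlog-approx"
  out
}

# Trended dispersion: median method-of-moments dispersion within mean bins,
# fit as a0 + a1/mean (asymptotic dispersion plus a Poisson-dominated term).
fit_dispersion_trend <- function(mean_expr, disp_raw) {
  ok <- disp_raw > 0 & mean_expr > 0
  if (sum(ok) < 10) return(function(m) rep(max(mean(disp_raw[ok]), 0.01),
                                           length(m)))
  mq <- mean_expr[ok]; dq <- disp_raw[ok]
  bins <- cut(rank(mq, ties.method = "first"),
              breaks = min(20, max(2, floor(sum(ok) / 25))))
  bm <- tapply(mq, bins, stats::median)
  bd <- tapply(dq, bins, stats::median)
  keep <- !is.na(bm) & !is.na(bd) & bd > 0
  if (sum(keep) < 2) return(function(m) rep(stats::median(dq), length(m)))
  fit <- stats::lm(bd[keep] ~ I(1 / bm[keep]))
  a0 <- max(stats::coef(fit)[1], 1e-8)
  a1 <- max(stats::coef(fit)[2], 0)
  function(m) pmin(pmax(a0 + a1 / pmax(m, 1e-8), 1e-8), 20)
}

#' Negative-binomial Wald test between two sample groups
#'
#' Tests each gene for a difference between groups B and A on
#' size-factor-normalized counts. Gene-wise dispersions are estimated by
#' method of moments from the pooled within-group variance and shrunk 50/50
#' (in log space) toward a mean-dispersion trend fitted across genes; the
#' Wald statistic is the log2 fold change over its delta-method standard
#' error, referred to a Student t with moderated degrees of freedom (three
#' times the residual df, reflecting the information the trend shrinkage
#' contributes).
#'
#' @param counts Raw count matrix containing both groups.
#' @param group_a,group_b Character vectors of sample ids; the reported
#'   `log2_fc` is B versus A. Groups must be disjoint with >= 2 samples each.
#' @param shrink Weight of the trend in the log-space dispersion blend.
#' @param pseudocount Added to group means before forming the fold change.
#' @return An `hmc_diff` data.frame with columns `gene`, `base_mean`,
#'   `log2_fc`, `se`, `stat`, `p`, `padj`, `passes_deg`, `passes_dhmg`.
#'   Genes with zero counts in all tested samples are dropped (count
#'   recorded in the `n_dropped` attribute).
#' @export
nb_wald_test <- function(counts, group_a, group_b, shrink = 0.5,
                         pseudocount = 0.5) {
  assert_count_matrix(counts)
  if (length(intersect(group_a, group_b)))
    hmc_stop("groups overlap", "hmc_validation_error")
  miss <- setdiff(c(group_a, group_b), colnames(counts))
  if (length(miss))
    hmc_stop(sprintf("samples not in matrix: %s", paste(miss, collapse = ", ")),
             "hmc_validation_error")
  if (length(group_a) < 2 || length(group_b) < 2)
    hmc_stop("each group needs at least 2 samples", "hmc_validation_error")
  sub <- counts[, c(group_a, group_b), drop = FALSE]
  nonzero <- rowSums(sub) > 0
  n_dropped <- sum(!nonzero)
  sub <- sub[nonzero, , drop = FALSE]
  count_state(sub) <- "raw"
  sf <- size_factors(sub)
  q <- sweep(sub, 2, sf, "/")
  qa <- q[, group_a, drop = FALSE]
  qb <- q[, group_b, drop = FALSE]
  na <- length(group_a); nb <- length(group_b)
  ma <- rowMeans(qa); mb <- rowMeans(qb)
  m <- rowMeans(q)
  # pooled within-group variance -> method-of-moments dispersion
  var_w <- ((na - 1) * row_vars(qa) + (nb - 1) * row_vars(qb)) / (na + nb - 2)
  s_inv <- mean(1 / sf)
  disp_raw <- (var_w - m * s_inv) / m^2
  trend <- fit_dispersion_trend(m, disp_raw)
  disp_tr <- trend(m)
  disp <- disp_tr
  pos <- which(disp_raw > 0)
  disp[pos] <- exp((1 - shrink) * log(disp_raw[pos]) +
                     shrink * log(disp_tr[pos]))
  disp <- pmin(pmax(disp, 1e-8), 20)
  lfc <- log2((mb + pseudocount) / (ma + pseudocount))
  var_ma <- ma * sum(1 / sf[group_a]) / na^2 + disp * ma^2 / na
  var_mb <- mb * sum(1 / sf[group_b]) / nb^2 + disp * mb^2 / nb
  se <- sqrt(var_ma / (ma + pseudocount)^2 + var_mb / (mb + pseudocount)^2) /
    log(2)
  se <- pmax(se, 1e-12)
  stat <- lfc / se
  # Moderated reference: the 50/50 trend shrinkage roughly triples the
  # effective information in the dispersion estimate, so the statistic is
  # referred to t with 3x the residual degrees of freedom rather than the
  # normal (which is anti-conservative for the 2-3 replicate designs here).
  df <- 3 * (na + nb - 2)
  p <- 2 * stats::pt(-abs(stat), df = df)
  padj <- bh_adjust(p)
  res <- data.frame(gene = rownames(sub), base_mean = m, log2_fc = lfc,
                    se = se, stat = stat, p = p, padj = padj,
                    row.names = NULL, stringsAsFactors = FALSE)
  res$passes_deg <- res$padj <= 0.1 & abs(res$log2_fc) >= 0.5
  res$passes_dhmg <- res$p < 0.01 & abs(res$log2_fc) >= 0.5
  attr(res, "n_dropped") <- n_dropped
  attr(res, "groups") <- list(a = group_a, b = group_b)
  class(res) <- c("hmc_diff", "data.frame")
  res
}

#' @export
print.hmc_diff <- function(x, ...) {
  cat(sprintf("NB Wald test: %d genes (%d all-zero dropped), %d vs %d samples\n",
              nrow(x), attr(x, "n_dropped") %||% 0,
              length(attr(x, "groups")$a), length(attr(x, "groups")$b)))
  cat(sprintf("  DEG rule (padj <= 0.1, |lfc| >= 0.5): %d genes\n",
              sum(x$passes_deg)))
  cat(sprintf("  DhMG rule (p < 0.01, |lfc| >= 0.5): %d genes\n",
              sum(x$passes_dhmg)))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' capped at 1 (delegates to [stats::p.adjust()] after validation).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    hmc_stop("p-values must lie in [0, 1]", "hmc_validation_error")
  stats::p.adjust(p, method = "BH")
}

#' Filter differentially expressed genes
#'
#' DEG rule: `padj <= 0.1` and `|log2_fc| >= 0.5`, both thresholds
#' inclusive.
#'
#' @param result An `hmc_diff` result with `padj` computed.
#' @return List with `up`, `down` and `all` gene id vectors.
#' @export
filter_degs <- function(result) {
  hit <- result$padj <= 0.1 & abs(result$log2_fc) >= 0.5
  list(up = result$gene[hit & result$log2_fc > 0],
       down = result$gene[hit & result$log2_fc < 0],
       all = result$gene[hit])
}

#' Filter differentially hydroxymethylated genes
#'
#' DhMG rule: raw `p < 0.01` (strict) and `|log2_fc| >= 0.5`. Distinct from
#' the DEG rule: raw rather than adjusted p, and strict inequality.
#'
#' @param result An `hmc_diff` result.
#' @return List with `up`, `down` and `all` gene id vectors.
#' @export
filter_dhmgs <- function(result) {
  hit <- result$p < 0.01 & abs(result$log2_fc) >= 0.5
  list(up = result$gene[hit & result$log2_fc > 0],
       down = result$gene[hit & result$log2_fc < 0],
       all = result$gene[hit])
}

#' Basic two-sample and paired tests
#'
#' The elementary comparisons used throughout the analysis: two-tailed
#' unpaired t, paired t, and the Wilcoxon rank-sum test (exact for small
#' tie-free samples, normal approximation with tie correction otherwise).
#'
#' @param x,y Numeric vectors (matched and equal length for the paired
#'   kind).
#' @param kind One of `"t_unpaired"`, `"t_paired"`, `"wilcoxon_ranksum"`.
#' @return List with `statistic` and two-sided `p`.
#' @export
basic_tests <- function(x, y, kind = c("t_unpaired", "t_paired",
                                       "wilcoxon_ranksum")) {
  kind <- match.arg(kind)
  if (kind == "t_paired" && length(x) != length(y))
    hmc_stop("paired test requires equal-length vectors",
             "hmc_validation_error")
  # degenerate inputs first: fully tied data carry no evidence, and a
  # constant paired difference has no within-pair variance to test against
  if (kind == "wilcoxon_ranksum" && length(unique(c(x, y))) == 1)
    return(list(statistic = length(x) * length(y) / 2, p = 1))
  if (kind == "t_paired" && stats::sd(x - y) == 0) {
    d <- mean(x - y)
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                p = if (d == 0) 1 else 0))
  }
  ht <- switch(kind,
    t_unpaired = stats::t.test(x, y, var.equal = FALSE),
    t_paired = stats::t.test(x, y, paired = TRUE),
    wilcoxon_ranksum = suppressWarnings(stats::wilcox.test(
      x, y, exact = length(x) <= 25 && length(y) <= 25, correct = TRUE))
  )
  list(statistic = unname(ht$statistic), p = ht$p.value)
}
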