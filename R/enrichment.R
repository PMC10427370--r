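# Gene-set enrichment: preranked GSEA (weighted Kolmogorov-Smirnov running
# sum with a gene-label permutation null), single-sample rank-based set
# scores, and coefficient-weighted signature scores (LSC17-style).

# ES of a hit set given the ranked |stat|^w weights. The running sum gains
# hit_weight/total at each hit and loses 1/(N - Nh) per miss; extremes can
# only occur immediately at (after) a hit or immediately before one, so the
# walk is evaluated at hit positions only -- O(Nh) per permutation.
es_from_positions <- function(pos, hitw_ranked, N) {
  h <- length(pos)
  o <- order(pos)
  pos <- pos[o]
  w <- hitw_ranked[o]
  tot <- sum(w)
  cumhit <- if (tot > 0) cumsum(w) / tot else seq_len(h) / h
  miss_step <- 1 / (N - h)
  idx <- seq_len(h)
  up <- cumhit - (pos - idx) * miss_step
  down <- c(0, cumhit[-h]) - (pos - 1 - (idx - 1)) * miss_step
  max_up <- max(up)
  min_down <- min(down, 0)
  if (max_up >= -min_down) max_up else min_down
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic on a ranked gene list:
#' hits increment proportionally to `|stat|^weight_exponent`, misses
#' decrement `1/(N - Nh)`; the enrichment score (ES) is the maximum signed
#' deviation of the walk. The null distribution comes from gene-label
#' permutations; NES is ES divided by the mean |null ES| of the same sign,
#' and the two-sided p-value is the sign-matched tail proportion (resolution
#' `1/(n_perm + 1)`).
#'
#' @param stats Named numeric vector of ranking statistics (one per gene).
#'   Ties are broken deterministically by gene id.
#' @param set Character vector of member genes (>= 2 must intersect).
#' @param n_perm Number of permutations.
#' @param weight_exponent 1 for classic weighted GSEA; 0 gives the
#'   unweighted KS walk.
#' @param seed Optional integer seed for the permutation stream.
#' @return An `hmc_gsea` list: `es`, `nes`, `p`, `n_hits`,
#'   `core_enrichment` (leading-edge genes), `null_es`.
#' @export
preranked_gsea <- function(stats, set, n_perm = 1000, weight_exponent = 1,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  o <- order(-stats, names(stats))
  s <- stats[o]
  genes <- names(s)
  N <- length(s)
  hit <- genes %in% set
  Nh <- sum(hit)
  if (Nh < 2)
    hmc_stop("fewer than 2 set genes present in the ranking",
             "hmc_validation_error")
  if (Nh >= N)
    hmc_stop("set covers the whole ranking", "hmc_validation_error")
  absw <- abs(s)^weight_exponent
  pos <- which(hit)
  es <- es_from_positions(pos, absw[pos], N)
  null_es <- vapply(seq_len(n_perm), function(i) {
    rpos <- sample.int(N, Nh)
    es_from_positions(rpos, absw[rpos], N)
  }, numeric(1))
  same <- null_es[sign(null_es) == sign(es)]
  if (length(same)) {
    nes <- es / mean(abs(same))
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  } else {
    nes <- NA_real_
    p <- 1 / (n_perm + 1)
  }
  # leading edge: hits at or before (after, for negative ES) the extremum
  core <- if (es >= 0) {
    miss_step <- 1 / (N - Nh)
    cumhit <- cumsum(absw[pos]) / max(sum(absw[pos]), .Machine$double.eps)
    walk <- cumhit - (pos - seq_along(pos)) * miss_step
    genes[pos[seq_len(which.max(walk))]]
  } else {
    cumhit <- cumsum(absw[pos]) / max(sum(absw[pos]), .Machine$double.eps)
    miss_step <- 1 / (N - Nh)
    walk <- c(0, cumhit[-Nh]) - (pos - seq_along(pos)) * miss_step
    genes[pos[which.min(walk):Nh]]
  }
  out <- list(es = es, nes = nes, p = p, n_hits = Nh,
              core_enrichment = core, null_es = null_es)
  class(out) <- "hmc_gsea"
  out
}

#' @export
print.hmc_gsea <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.3f, NES = %.3f, p = %.4g (%d hits, %d leading-edge)\n",
              x$es, x$nes, x$p, x$n_hits, length(x$core_enrichment)))
  invisible(x)
}

#' Per-sample gene-set score
#'
#' Rank-based single-sample enrichment: within each sample, genes are
#' ranked by expression and the score is
#' `(mean rank of set genes - mean rank of non-set genes) / N`. Invariant
#' to any monotone transform of a sample's expression values; higher means
#' more enriched.
#'
#' @param expr Gene x sample expression matrix (log scale recommended).
#' @param set Character vector of member genes (>= 2 present, and a
#'   non-empty complement).
#' @return Named numeric vector, one score per sample.
#' @export
sample_set_score <- function(expr, set) {
  inset <- rownames(expr) %in% set
  if (sum(inset) < 2)
    hmc_stop("fewer than 2 set genes present in expression matrix",
             "hmc_validation_error")
  if (all(inset))
    hmc_stop("set covers all genes; score undefined without a complement",
             "hmc_validation_error")
  N <- nrow(expr)
  apply(expr, 2, function(v) {
    r <- rank(v)
    (mean(r[inset]) - mean(r[!inset])) / N
  })
}

#' Coefficient-weighted signature score
#'
#' `score_s = sum_g w_g * log2(TPM_gs + 1)` over the weighted genes, the
#' form of regression-coefficient signature scores such as LSC17. Genes
#' absent from the matrix contribute 0 (with a warning); at least 80% of
#' weighted genes must be present.
#'
#' @param tpm Gene x sample TPM matrix.
#' @param weights Named numeric vector of per-gene coefficients.
#' @return Named numeric vector, one score per sample.
#' @export
weighted_signature_score <- function(tpm, weights) {
  present <- intersect(names(weights), rownames(tpm))
  if (!length(present))
    hmc_stop("none of the weighted genes are present", "hmc_validation_error")
  if (length(present) < 0.8 * length(weights))
    hmc_stop(sprintf("only %d/%d weighted genes present (need >= 80%%)",
                     length(present), length(weights)),
             "hmc_validation_error")
  if (length(present) < length(weights))
    warning(sprintf("%d weighted gene(s) absent; contributing 0",
                    length(weights) - length(present)))
  as.vector(weights[present] %*% log2(tpm[present, , drop = FALSE] + 1)) |>
    stats::setNames(colnames(tpm))
}

#' Paired Day 5 versus Day 0 comparison of per-sample scores
#'
#' Matches scores by patient and applies a two-sided paired t-test to the
#' per-patient Day5 - Day0 differences. Unpaired extra samples are ignored
#' (count messaged).
#'
#' @param scores_day0,scores_day5 Numeric vectors named by patient id.
#' @return List with `statistic`, `p`, `n_pairs`, `mean_difference`.
#' @export
paired_day_comparison <- function(scores_day0, scores_day5) {
  pats <- intersect(names(scores_day0), names(scores_day5))
  n_un <- length(scores_day0) + length(scores_day5) - 2 * length(pats)
  if (n_un > 0)
    message(sprintf("%d unpaired score(s) ignored", n_un))
  if (length(pats) < 3)
    hmc_stop("need >= 3 complete Day0/Day5 pairs", "hmc_validation_error")
  d <- scores_day5[pats] - scores_day0[pats]
  if (stats::sd(d) == 0) {
    # degenerate: identical differences; t undefined for exactly-zero sd
    return(list(statistic = if (all(d == 0)) 0 else sign(d[1]) * Inf,
                p = if (all(d == 0)) 1 else 0,
                n_pairs = length(pats), mean_difference = mean(d)))
  }
  ht <- stats::t.test(scores_day5[pats], scores_day0[pats], paired = TRUE)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       n_pairs = length(pats), mean_difference = mean(d))
}
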