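# Co-expression modules among differentially expressed genes: pairwise
# Pearson correlation on variance-stabilized expression, hierarchical
# clustering of correlation profiles, and module extension with a
# user-supplied gene-gene interaction edge list.

#' Pairwise gene-gene Pearson correlation
#'
#' Correlations between rows (genes) of a variance-stabilized (log-scale)
#' expression matrix. Genes with zero variance have undefined correlation
#' and are dropped with a warning.
#'
#' @param expr Gene x sample matrix, >= 3 samples.
#' @return Symmetric correlation matrix, unit diagonal.
#' @export
pairwise_correlation <- function(expr) {
  if (ncol(expr) < 3)
    hmc_stop("need >= 3 samples for correlations", "hmc_validation_error")
  if (nrow(expr) < 2)
    hmc_stop("need >= 2 genes", "hmc_validation_error")
  v <- row_vars(expr)
  if (any(v == 0)) {
    warning(sprintf("%d zero-variance gene(s) dropped", sum(v == 0)))
    expr <- expr[v > 0, , drop = FALSE]
  }
  stats::cor(t(expr))
}

#' Cluster genes into co-expression modules
#'
#' Agglomerative clustering (average linkage) of the Euclidean distances
#' between rows of the gene-gene correlation matrix, cut at `k` modules.
#' Deterministic, and invariant to gene input order up to module
#' relabelling.
#'
#' @param corr Correlation matrix from [pairwise_correlation()].
#' @param k Number of modules (default 4).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return An `hmc_modules` list: `assignment` (named integer vector),
#'   `sizes`, `mean_intra_correlation` per module, and the linkage used.
#' @export
cluster_modules <- function(corr, k = 4, linkage = "average") {
  n <- nrow(corr)
  if (k > n)
    hmc_stop(sprintf("k = %d exceeds number of genes (%d)", k, n),
             "hmc_validation_error")
  hc <- stats::hclust(stats::dist(corr), method = linkage)
  assignment <- stats::cutree(hc, k = k)
  intra <- vapply(seq_len(k), function(m) {
    g <- names(assignment)[assignment == m]
    if (length(g) < 2) return(NA_real_)
    sub <- corr[g, g]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  out <- list(assignment = assignment,
              sizes = as.vector(table(assignment)),
              mean_intra_correlation = intra,
              linkage = linkage, k = k)
  class(out) <- "hmc_modules"
  out
}

#' @export
print.hmc_modules <- function(x, ...) {
  cat(sprintf("%d co-expression modules (%s linkage)\n", x$k, x$linkage))
  for (m in seq_len(x$k))
    cat(sprintf("  module %d: %d genes, mean intra-r %.3f\n",
                m, x$sizes[m], x$mean_intra_correlation[m]))
  invisible(x)
}

#' Read a gene-gene interaction edge list
#'
#' TSV with two gene-id columns (header optional third score column is
#' ignored).
#'
#' @param path Path to the edge list.
#' @return Two-column character data.frame (`gene1`, `gene2`).
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    hmc_stop("edge list needs two gene-id columns", "hmc_format_error")
  data.frame(gene1 = as.character(df[[1]]), gene2 = as.character(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Extend a module with first-order interaction neighbors
#'
#' Adds every direct neighbor (from the edge list) of a module gene whose
#' mean expression exceeds `tpm_floor` TPM (strictly). Monotone in the edge
#' list: adding edges never removes genes.
#'
#' @param module Character vector of module gene ids.
#' @param edges Edge data.frame from [read_edge_list()] (or NULL, in which
#'   case the module is returned unchanged with a warning).
#' @param tpm Gene x sample TPM matrix used for the expression floor.
#' @param tpm_floor Minimum mean TPM for an added neighbor (default 3,
#'   strict inequality).
#' @return List with `genes` (module plus additions), `added` (the new
#'   genes) and `source` (per-gene `"module"`/`"extended"` provenance).
#' @export
extend_module <- function(module, edges, tpm, tpm_floor = 3) {
  if (is.null(edges) || !nrow(edges)) {
    warning("no edges supplied; module returned unchanged")
    return(list(genes = module, added = character(0),
                source = stats::setNames(rep("module", length(module)),
                                         module)))
  }
  touch <- edges$gene1 %in% module | edges$gene2 %in% module
  nbr <- setdiff(unique(c(edges$gene1[touch], edges$gene2[touch])), module)
  nbr <- nbr[nbr %in% rownames(tpm)]
  if (length(nbr)) {
    keep <- rowMeans(tpm[nbr, , drop = FALSE]) > tpm_floor
    nbr <- nbr[keep]
  }
  genes <- c(module, nbr)
  list(genes = genes, added = nbr,
       source = stats::setNames(
         c(rep("module", length(module)), rep("extended", length(nbr))),
         genes))
}
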