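# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (direct transcriptions of definitions) so they can
# arbitrate the package's vectorized implementations.

bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[o[i]] <- min(1, min(m * p[o[seq(i, m)]] / seq(i, m)))
  }
  adj
}

size_factors_brute <- function(counts) {
  keep <- apply(counts, 1, function(r) all(r > 0))
  geo <- apply(counts[keep, , drop = FALSE], 1,
               function(r) exp(mean(log(r))))
  apply(counts[keep, , drop = FALSE], 2,
        function(col) median(col / geo))
}

pearson_brute <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

spearman_brute <- function(x, y) pearson_brute(rank(x), rank(y))

auc_brute <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

logrank_brute <- function(time, event, group) {
  g <- unique(group)
  stopifnot(length(g) == 2)
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g[1])
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n - d) / (n - 1) * n1 * (n - n1) / n^2
  }
  o_minus_e^2 / v
}

# full O(N) running-sum walk for GSEA ES (signed extreme)
es_brute <- function(stats_sorted, hit, weight) {
  N <- length(stats_sorted)
  nh <- sum(hit)
  w <- abs(stats_sorted)^weight
  tot <- sum(w[hit])
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) w[i] / tot else -1 / (N - nh)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# small named NB count matrix
toy_counts <- function(n_genes, n_samples, mu = 100, size = 20,
                       seed = NULL, prefix = "s") {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = size),
              n_genes, n_samples,
              dimnames = list(sprintf("g%05d", seq_len(n_genes)),
                              paste0(prefix, seq_len(n_samples))))
  m
}
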