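## Independent brute-force oracles and small fixture builders. Each
## oracle is coded directly from the defining formula, separately from
## the package implementation it checks.

rand_em <- function(n_genes, n_cells, seed, max_count = 20L,
                    zero_frac = 0.3) {
  set.seed(seed)
  x <- matrix(sample(0:max_count, n_genes * n_cells, replace = TRUE),
              n_genes, n_cells)
  x[matrix(runif(n_genes * n_cells) < zero_frac, n_genes, n_cells)] <- 0
  expression_matrix(x, sprintf("g%03d", seq_len(n_genes)),
                    sprintf("c%03d", seq_len(n_cells)), "counts")
}

## U-score: sort, average ranks, truncate, apply the formula
uscore_brute <- function(x, gene_ids, set, r_max) {
  apply(x, 2, function(col) {
    ord <- rank(-col, ties.method = "average")
    ord[ord > r_max] <- r_max + 1
    r <- ord[match(set, gene_ids)]
    n <- length(set)
    u <- sum(r) - n * (n + 1) / 2
    max(0, 1 - u / (n * r_max))
  })
}

## recovery-curve activity by explicit loop over the top-T positions
aucell_brute <- function(x, gene_ids, targets, threshold_frac) {
  N <- length(gene_ids)
  T_ <- ceiling(threshold_frac * N)
  n_t <- length(targets)
  denom <- sum(pmin(seq_len(T_), n_t))
  apply(x, 2, function(col) {
    ord <- order(-col, gene_ids)
    top <- gene_ids[ord[seq_len(T_)]]
    y <- vapply(seq_len(T_), function(k) sum(top[seq_len(k)] %in% targets),
                numeric(1))
    sum(y) / denom
  })
}

## running-sum enrichment score by explicit loop
ssgsea_brute <- function(x, gene_ids, set, alpha) {
  N <- length(gene_ids)
  n_s <- length(set)
  apply(x, 2, function(col) {
    ord <- order(-col, gene_ids)
    es <- 0; cin <- 0; cout <- 0
    vsum <- sum(vapply(seq_len(N), function(i) {
      if (gene_ids[ord[i]] %in% set) (N - i + 1)^alpha else 0
    }, numeric(1)))
    for (i in seq_len(N)) {
      if (gene_ids[ord[i]] %in% set) cin <- cin + (N - i + 1)^alpha / vsum
      else cout <- cout + 1 / (N - n_s)
      es <- es + (cin - cout)
    }
    es
  })
}

## Jensen-Shannon divergence from the entropy formula, base-2 logs
jsd_brute <- function(p, q) {
  h <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  m <- (p + q) / 2
  h(m) - (h(p) + h(q)) / 2
}

## squared energy distance by a double loop over all pairs
energy_brute <- function(a, b) {
  ed <- function(u, v) sqrt(sum((u - v)^2))
  s_ab <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    s_ab <- s_ab + ed(a[i, ], b[j, ])
  s_aa <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(a)))
    s_aa <- s_aa + ed(a[i, ], a[j, ])
  s_bb <- 0
  for (i in seq_len(nrow(b))) for (j in seq_len(nrow(b)))
    s_bb <- s_bb + ed(b[i, ], b[j, ])
  2 * s_ab / (nrow(a) * nrow(b)) - s_aa / nrow(a)^2 - s_bb / nrow(b)^2
}

## all-pairs concordance AUC, low score predicts the positive class
auc_brute <- function(score, positive) {
  s1 <- score[positive]; s0 <- score[!positive]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + (a < b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

## upper-tail hypergeometric p by enumerating the pmf
hyper_brute <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## penalized-cosine marker score by a per-gene loop
cosg_brute <- function(x, clusters, mu) {
  ks <- sort(unique(clusters))
  out <- matrix(0, nrow(x), length(ks), dimnames = list(rownames(x), ks))
  for (g in seq_len(nrow(x))) {
    cs <- vapply(ks, function(k) {
      ind <- as.numeric(clusters == k)
      den <- sqrt(sum(x[g, ]^2)) * sqrt(sum(ind^2))
      if (den == 0) 0 else sum(x[g, ] * ind) / den
    }, numeric(1))
    for (j in seq_along(ks)) {
      den <- cs[j]^2 + mu * sum(cs[-j]^2)
      out[g, j] <- if (den == 0) 0 else cs[j]^2 / den
    }
  }
  out
}

## Cox partial log-likelihood (Breslow ties) for a grid-search oracle
cox_pll <- function(beta, times, events, x) {
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    d <- which(times == t & events == 1)
    risk <- which(times >= t)
    ll <- ll + sum(x[d] * beta) -
      length(d) * log(sum(exp(x[risk] * beta)))
  }
  ll
}

## log-rank O/E/V sums coded directly from the definition (2 groups)
logrank_brute <- function(times, events, grp1) {
  o <- e <- v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & grp1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & grp1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

## small deterministic synthetic dataset shared by integration tests
small_sim <- function(seed = 7L) {
  sim_config(seed = seed, n_genes = 600L, n_bulk_samples = 60L,
             n_sc_samples = 4L, cells_per_sample = 150L,
             program_size_up = 60L, program_size_down = 60L,
             regulon_size = 30L)
}
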