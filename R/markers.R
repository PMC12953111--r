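## Cluster marker scoring by penalized cosine similarity and pathway
## enrichment by hypergeometric test.

#' Penalized-cosine marker scores per cluster
#'
#' For gene g and cluster k, c_{g,k} is the cosine similarity between
#' the gene's expression vector across cells and the binary indicator of
#' cluster membership; the marker score is
#' c^2 / (c^2 + mu * sum of the squared cosines for the other clusters),
#' with 0/0 defined as 0. High scores mark genes expressed specifically
#' in one cluster.
#'
#' @param em an \code{expression_matrix} over cells, non-negative values.
#' @param clusters per-cell cluster labels (>= 2 clusters, each with at
#'   least 2 cells).
#' @param mu penalty weight on off-cluster similarity (default 1).
#' @param top_n genes reported per cluster (default 50), ranked by score
#'   descending then gene id ascending.
#' @return list with \code{scores} (gene x cluster matrix of penalized
#'   scores), \code{cosine} (gene x cluster cosines) and \code{top}
#'   (named list of top_n marker genes per cluster).
#' @export
marker_scores <- function(em, clusters, mu = 1.0, top_n = 50L) {
  stopifnot(inherits(em, "expression_matrix"))
  clusters <- as.character(clusters)
  .assert(length(clusters) == length(em$column_ids),
          "clusters length must match cell count")
  x <- .dense(em$values)
  .assert(all(x >= 0), "marker scoring requires non-negative expression")
  ks <- sort(unique(clusters))
  .assert(length(ks) >= 2, "need at least 2 clusters")
  sizes <- table(clusters)
  .assert(all(sizes >= 2), "cluster with < 2 cells: %s",
          paste(names(sizes)[sizes < 2], collapse = ","))
  gene_norm <- sqrt(rowSums(x^2))
  cosine <- vapply(ks, function(k) {
    ind <- clusters == k
    num <- rowSums(x[, ind, drop = FALSE])
    den <- gene_norm * sqrt(sum(ind))
    ifelse(den > 0, num / den, 0)
  }, numeric(nrow(x)))
  rownames(cosine) <- em$gene_ids
  c2 <- cosine^2
  tot <- rowSums(c2)
  scores <- vapply(seq_along(ks), function(j) {
    denom <- c2[, j] + mu * (tot - c2[, j])
    ifelse(denom > 0, c2[, j] / denom, 0)
  }, numeric(nrow(x)))
  colnames(scores) <- ks
  rownames(scores) <- em$gene_ids
  top <- lapply(setNames(ks, ks), function(k) {
    ord <- order(-scores[, k], em$gene_ids)
    em$gene_ids[head(ord, top_n)]
  })
  list(scores = scores, cosine = cosine, top = top)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail (at least k overlapping genes) hypergeometric test of a
#' query gene set against each set of a collection over a finite gene
#' universe, with BH adjustment across sets.
#'
#' @param query character vector of query genes.
#' @param collection named list of gene sets.
#' @param universe character vector defining the gene universe.
#' @return data.frame per set: k (overlap), K (set size in universe),
#'   n (query size in universe), N (universe size), p, p_adj.
#' @export
hypergeom_enrichment <- function(query, collection, universe) {
  universe <- unique(universe)
  N <- length(universe)
  q <- intersect(unique(query), universe)
  .assert(length(q) > 0, "query has no genes in the universe")
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(unique(collection[[nm]]), universe)
    k <- length(intersect(q, s))
    K <- length(s); n <- length(q)
    p <- if (k == 0) 1.0 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_pvalues(out$p, "BH")
  rownames(out) <- NULL
  out
}
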