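## Regulon construction (correlation-surrogate target ranking), activity
## scoring (area under the recovery curve), specificity scoring
## (Jensen-Shannon) and top-regulon / top-target selection.

#' Construct a regulon object
#'
#' @param tf transcription factor gene id.
#' @param targets character vector of target gene ids (TF excluded).
#' @param importance non-negative finite importance weights.
#' @return a \code{regulon}.
#' @export
regulon <- function(tf, targets, importance) {
  .assert(length(targets) == length(importance),
          "targets and importance differ in length")
  .assert(!tf %in% targets, "TF must not appear among its own targets")
  .assert(all(is.finite(importance)), "importances must be finite")
  ord <- order(-importance, targets)
  structure(list(tf = tf, targets = targets[ord],
                 importance = importance[ord]),
            class = "regulon")
}

#' @exportS3Method base::print
print.regulon <- function(x, ...) {
  cat(sprintf("<regulon> %s with %d targets (top: %s)\n", x$tf,
              length(x$targets),
              paste(head(x$targets, 5), collapse = ", ")))
  invisible(x)
}

#' Rank candidate targets of a TF by correlation importance
#'
#' A declared surrogate for tree-ensemble network inference: the
#' importance of a candidate gene is the absolute Spearman correlation
#' of its expression with the TF's across cells, sorted descending with
#' gene-id ties ascending.
#'
#' @param em an \code{expression_matrix} over cells.
#' @param tf TF gene id, present in the matrix with nonzero variance.
#' @param candidates candidate gene ids (default: all other genes).
#' @return a \code{regulon}.
#' @export
rank_targets <- function(em, tf, candidates = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  .assert(tf %in% em$gene_ids, "TF %s not in matrix", tf)
  if (is.null(candidates)) candidates <- setdiff(em$gene_ids, tf)
  candidates <- setdiff(intersect(candidates, em$gene_ids), tf)
  x <- .dense(em$values)
  tf_expr <- x[match(tf, em$gene_ids), ]
  .assert(sd(tf_expr) > 0, "TF %s has zero variance", tf)
  rt <- rank(tf_expr)
  cand_idx <- match(candidates, em$gene_ids)
  imp <- vapply(cand_idx, function(i) {
    xi <- x[i, ]
    if (sd(xi) == 0) return(0)
    abs(cor(rt, rank(xi)))
  }, numeric(1))
  regulon(tf, candidates, imp)
}

#' AUCell-style regulon activity per cell
#'
#' Per cell, genes are ordered by expression descending (ties broken by
#' gene id ascending for determinism); with T = ceiling(threshold_frac
#' * N), the recovery curve y(k) counts regulon targets among the top k
#' genes, and the activity is sum_{k=1..T} y(k) divided by the
#' best-possible packing sum_{k=1..T} min(k, n_targets), so a regulon
#' whose targets fill the top ranks scores 1 and one with no target in
#' the top T scores 0.
#'
#' @param em an \code{expression_matrix} over cells.
#' @param reg a \code{regulon} (>= 5 targets present in the matrix).
#' @param threshold_frac fraction of top-ranked genes scanned
#'   (default 0.05).
#' @return named per-cell activity vector in [0,1].
#' @export
aucell <- function(em, reg, threshold_frac = 0.05) {
  stopifnot(inherits(em, "expression_matrix"), inherits(reg, "regulon"))
  targets <- intersect(reg$targets, em$gene_ids)
  .assert(length(targets) >= 5,
          "regulon %s retains %d targets (< 5)", reg$tf, length(targets))
  N <- length(em$gene_ids)
  T_ <- ceiling(threshold_frac * N)
  .assert(T_ >= 1, "degenerate matrix: top-rank window is empty")
  x <- .dense(em$values)
  n_t <- length(targets)
  is_target <- em$gene_ids %in% targets
  denom <- sum(pmin(seq_len(T_), n_t))
  id_order <- order(em$gene_ids)   # tiebreak: gene id ascending
  act <- vapply(seq_len(ncol(x)), function(j) {
    ord <- order(-x[, j], em$gene_ids)
    hits <- is_target[ord[seq_len(T_)]]
    sum(cumsum(hits)) / denom
  }, numeric(1))
  names(act) <- em$column_ids
  act
}

## Jensen-Shannon divergence with base-2 logs (range [0,1])
.jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Regulon specificity score per cell class
#'
#' The activity vector is normalized to a distribution p over cells; for
#' each class the indicator distribution q (uniform over the class's
#' cells) is compared to p by Jensen-Shannon divergence (base-2 logs, in
#' [0,1]); the specificity score is 1 - sqrt(JSD). A regulon active
#' uniformly in exactly one class scores 1 for it; activity disjoint
#' from the class scores 0.
#'
#' @param activity per-cell activity, non-negative, not all zero.
#' @param classes per-cell class labels (>= 2 classes).
#' @return named numeric vector of per-class specificity scores.
#' @export
regulon_specificity <- function(activity, classes) {
  .assert(all(activity >= 0), "activity must be non-negative")
  .assert(sum(activity) > 0, "activity is all zero")
  classes <- as.character(classes)
  .assert(length(classes) == length(activity), "classes length mismatch")
  ks <- sort(unique(classes))
  .assert(length(ks) >= 2, "need at least 2 classes")
  p <- activity / sum(activity)
  vapply(setNames(ks, ks), function(k) {
    ind <- classes == k
    q <- ind / sum(ind)
    1 - sqrt(.jsd(p, q))
  }, numeric(1))
}

#' Select the most specific regulons per class
#'
#' @param rss matrix of specificity scores (regulon x class).
#' @param per_class regulons kept per class (default 10).
#' @return named list per class of regulon names sorted by specificity
#'   descending (ties broken by name ascending).
#' @export
select_top_regulons <- function(rss, per_class = 10L) {
  .assert(is.matrix(rss) && !is.null(rownames(rss)) &&
            !is.null(colnames(rss)), "rss must be a named matrix")
  lapply(setNames(colnames(rss), colnames(rss)), function(k) {
    ord <- order(-rss[, k], rownames(rss))
    head(rownames(rss)[ord], per_class)
  })
}

#' Extract the top-k targets of a regulon by importance
#'
#' @param reg a \code{regulon}.
#' @param k number of targets (default 50); all if fewer are available.
#' @return character vector of target gene ids.
#' @export
top_targets <- function(reg, k = 50L) {
  stopifnot(inherits(reg, "regulon"))
  head(reg$targets, k)    # targets already sorted by importance desc
}
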