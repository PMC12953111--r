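## Per-cell rank-based gene-set scoring (normalized Mann-Whitney U with
## max-rank truncation) and top-decile phenotype labeling.

#' Per-cell U-score of a gene set
#'
#' For each cell, all genes are ranked by expression descending with
#' average ranks for ties (zeros share the bottom rank block); ranks
#' beyond \code{r_max} are truncated to \code{r_max + 1}. With r_i the
#' (truncated) ranks of the n retained set genes,
#' U' = sum(r_i) - n(n+1)/2 and the score is 1 - U'/(n * r_max), clipped
#' below at 0. The score lies in [0,1] and is invariant to any strictly
#' monotone per-cell transform of expression.
#'
#' @param em an \code{expression_matrix} over cells (any per-cell
#'   monotone scale).
#' @param set character vector of gene ids; genes absent from the matrix
#'   are dropped with a warning.
#' @param r_max rank cutoff (default 1500).
#' @param min_set_size minimum retained set size (default 3).
#' @return named numeric vector of per-cell scores in [0,1].
#' @export
uscore <- function(em, set, r_max = 1500L, min_set_size = 3L) {
  stopifnot(inherits(em, "expression_matrix"))
  .assert(r_max >= 2, "r_max must be >= 2")
  set <- unique(set)
  keep <- set %in% em$gene_ids
  if (!all(keep)) {
    warning(sprintf("%d of %d set genes absent from matrix; dropped",
                    sum(!keep), length(set)), call. = FALSE)
  }
  set <- set[keep]
  n <- length(set)
  .assert(n >= min_set_size,
          "gene set retains %d genes (< min_set_size %d)", n, min_set_size)
  .assert(n <= r_max, "set size %d exceeds r_max %d", n, r_max)
  x <- .dense(em$values)
  idx <- match(set, em$gene_ids)
  scores <- vapply(seq_len(ncol(x)), function(j) {
    r <- rank(-x[, j], ties.method = "average")
    r[r > r_max] <- r_max + 1
    u <- sum(r[idx]) - n * (n + 1) / 2
    max(0, 1 - u / (n * r_max))
  }, numeric(1))
  names(scores) <- em$column_ids
  scores
}

#' Label cells by top-decile signature scores
#'
#' Cells in the top \code{q} fraction of the up-signature score are
#' labeled LNM, cells in the top \code{q} fraction of the down-signature
#' score non-LNM; cells exceeding both thresholds are abstentions (NS,
#' counted and logged as conflicts), as are all remaining cells.
#' Thresholds are linear-interpolation quantiles at 1 - q over all cells
#' passed in.
#'
#' @param up_score,down_score per-cell scores of equal length.
#' @param q top fraction defining each phenotype (default 0.10).
#' @param cell_ids optional cell identifiers.
#' @return a \code{cell_label_table} data.frame with columns cell_id,
#'   up_score, down_score, label; attribute \code{conflicts} holds the
#'   double-threshold count.
#' @export
label_cells <- function(up_score, down_score, q = 0.10, cell_ids = NULL) {
  .assert(length(up_score) == length(down_score),
          "score vectors differ in length")
  .assert(q > 0 && q < 0.5, "q must lie in (0, 0.5)")
  .assert(sd(up_score) > 0 && sd(down_score) > 0,
          "constant score vector: thresholding undefined")
  thr_up <- quantile(up_score, 1 - q, type = 7, names = FALSE)
  thr_dn <- quantile(down_score, 1 - q, type = 7, names = FALSE)
  hi_up <- up_score >= thr_up
  hi_dn <- down_score >= thr_dn
  label <- rep("NS", length(up_score))
  label[hi_up & !hi_dn] <- "LNM"
  label[hi_dn & !hi_up] <- "non-LNM"
  conflicts <- sum(hi_up & hi_dn)
  if (conflicts > 0) .log_msg("%d cells above both thresholds -> NS",
                              conflicts)
  if (is.null(cell_ids)) {
    cell_ids <- names(up_score)
    if (is.null(cell_ids)) cell_ids <- sprintf("cell%05d",
                                               seq_along(up_score))
  }
  out <- data.frame(cell_id = cell_ids, up_score = up_score,
                    down_score = down_score, label = label,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "conflicts") <- conflicts
  attr(out, "thr_up") <- thr_up
  attr(out, "thr_dn") <- thr_dn
  class(out) <- c("cell_label_table", "data.frame")
  out
}

#' @exportS3Method base::print
print.cell_label_table <- function(x, ...) {
  tab <- table(factor(x$label, levels = c("LNM", "non-LNM", "NS")))
  cat(sprintf("<cell_label_table> %d cells: %d LNM, %d non-LNM, %d NS (%d conflicts)\n",
              nrow(x), tab[["LNM"]], tab[["non-LNM"]], tab[["NS"]],
              attr(x, "conflicts")))
  invisible(x)
}
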