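## Reference-based bulk deconvolution: per-type mean reference profiles
## from annotated single cells, non-negative least squares mixture
## estimation with simplex normalization, and group comparisons of the
## resulting infiltration scores.

#' Build a cell-type reference profile from single cells
#'
#' Per type, the mean linear-scale expression over its cells, restricted
#' to a marker gene union (typically the per-type top markers from
#' \code{marker_scores}).
#'
#' @param em an \code{expression_matrix} over cells on a linear scale
#'   (counts).
#' @param types per-cell type labels; every type needs >= 10 cells.
#' @param genes marker gene union the profile is restricted to
#'   (default: all genes).
#' @return genes x types numeric matrix (a reference profile).
#' @export
build_reference <- function(em, types, genes = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  types <- as.character(types)
  .assert(length(types) == length(em$column_ids), "types length mismatch")
  sizes <- table(types)
  .assert(all(sizes >= 10), "cell type below 10 cells: %s",
          paste(names(sizes)[sizes < 10], collapse = ","))
  if (is.null(genes)) genes <- em$gene_ids
  genes <- intersect(genes, em$gene_ids)
  .assert(length(genes) > 0, "no marker genes present in the matrix")
  x <- .dense(em$values)[match(genes, em$gene_ids), , drop = FALSE]
  ref <- vapply(sort(unique(types)), function(t) {
    rowMeans(x[, types == t, drop = FALSE])
  }, numeric(length(genes)))
  rownames(ref) <- genes
  .assert(all(colSums(ref) > 0), "reference has an all-zero column")
  ref
}

#' Estimate per-sample cell-type fractions by non-negative least squares
#'
#' Bulk log2(TPM+1) values are back-transformed to the linear scale and,
#' per sample, the mixture weights minimizing ||b - R f|| subject to
#' f >= 0 are found by NNLS over the genes shared with the reference,
#' then normalized to the probability simplex. Both raw and normalized
#' weights are returned.
#'
#' @param bulk an \code{expression_matrix}; log2-scale values are
#'   back-transformed as 2^x - 1, linear values used as-is.
#' @param ref genes x types reference matrix from
#'   \code{build_reference}.
#' @return list with \code{fractions} (samples x types, rows on the
#'   simplex) and \code{raw} (unnormalized NNLS weights).
#' @export
estimate_fractions <- function(bulk, ref) {
  stopifnot(inherits(bulk, "expression_matrix"))
  shared <- intersect(bulk$gene_ids, rownames(ref))
  .assert(length(shared) >= 20,
          "only %d genes shared between bulk and reference (< 20)",
          length(shared))
  b <- .dense(bulk$values)[match(shared, bulk$gene_ids), , drop = FALSE]
  if (bulk$scale_tag %in% c("log2tpm1", "lognorm")) b <- 2^b - 1
  R <- ref[match(shared, rownames(ref)), , drop = FALSE]
  if (qr(R)$rank < ncol(R)) {
    warning("reference matrix is rank-deficient; least-norm NNLS solution returned",
            call. = FALSE)
  }
  raw <- t(vapply(seq_len(ncol(b)), function(j) {
    pracma::lsqnonneg(R, b[, j])$x
  }, numeric(ncol(R))))
  colnames(raw) <- colnames(R)
  rownames(raw) <- bulk$column_ids
  rs <- rowSums(raw)
  .assert(all(rs > 0), "NNLS returned an all-zero mixture for a sample")
  frac <- raw / rs
  list(fractions = frac, raw = raw)
}

#' Compare infiltration scores across clinical groups
#'
#' Per cell type, a two-sided Wilcoxon rank-sum test (exact for small
#' total n, normal approximation with continuity correction otherwise)
#' between two clinical groups, BH-adjusted across types. Supported
#' groupings: nodal status (N>0 vs N=0) and clinical stage (III vs
#' I-II).
#'
#' @param fractions samples x types matrix (rows aligned with clinical
#'   sample_id).
#' @param clinical clinical data.frame with sample_id plus n_stage or
#'   stage.
#' @param grouping \code{"nodal"} or \code{"stage"}.
#' @return data.frame per type: n_group1, n_group0, median difference,
#'   direction, p, p_adj.
#' @export
compare_infiltration <- function(fractions, clinical,
                                 grouping = c("nodal", "stage")) {
  grouping <- match.arg(grouping)
  idx <- match(rownames(fractions), clinical$sample_id)
  .assert(!anyNA(idx), "fraction rows missing from clinical table")
  clin <- clinical[idx, ]
  g1 <- switch(grouping,
               nodal = !is.na(clin$n_stage) & clin$n_stage != "N0",
               stage = !is.na(clin$stage) & clin$stage == "III")
  g0 <- switch(grouping,
               nodal = !is.na(clin$n_stage) & clin$n_stage == "N0",
               stage = !is.na(clin$stage) & clin$stage %in% c("I", "II"))
  .assert(any(g1) && any(g0), "a comparison group is empty")
  rows <- lapply(colnames(fractions), function(tp) {
    x1 <- fractions[g1, tp]; x0 <- fractions[g0, tp]
    p <- if (length(x1) < 3 || length(x0) < 3) NA_real_
    else if (sd(c(x1, x0)) == 0) 1.0
    else suppressWarnings(
      wilcox.test(x1, x0, exact = (length(x1) + length(x0)) <= 50,
                  correct = TRUE)$p.value)
    data.frame(type = tp, n_group1 = length(x1), n_group0 = length(x0),
               delta_median = median(x1) - median(x0),
               direction = ifelse(median(x1) >= median(x0), "up", "down"),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- adjust_pvalues(out$p[ok], "BH")
  rownames(out) <- NULL
  out
}
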