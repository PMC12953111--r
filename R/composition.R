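## Composition shifts between LNM and non-LNM cells: per-type Fisher
## tests, paired per-sample subpopulation tests, and energy distance of
## embedding point clouds.

#' Cell-type composition shift between LNM and non-LNM cells
#'
#' For each cell type a 2x2 Fisher exact test (this type vs rest, LNM vs
#' non-LNM over labeled cells; NS cells are excluded) with BH adjustment
#' across types. Odds ratios are the sample cross-product ratio with a
#' Haldane 0.5 correction applied when any cell of the table is zero.
#'
#' @param labels a \code{cell_label_table} (or any data.frame with a
#'   \code{label} column).
#' @param types per-cell type labels, same order as \code{labels}.
#' @return data.frame per type: counts, proportions, odds_ratio, p,
#'   p_adj.
#' @export
celltype_shift <- function(labels, types) {
  lab <- labels$label
  .assert(length(types) == length(lab), "types length mismatch")
  keep <- lab %in% c("LNM", "non-LNM")
  lab <- lab[keep]; types <- as.character(types)[keep]
  n_lnm_tot <- sum(lab == "LNM"); n_non_tot <- sum(lab == "non-LNM")
  .assert(n_lnm_tot >= 1 && n_non_tot >= 1,
          "need at least one LNM and one non-LNM cell")
  all_types <- sort(unique(types))
  rows <- lapply(all_types, function(tp) {
    a <- sum(types == tp & lab == "LNM")
    b <- sum(types == tp & lab == "non-LNM")
    if (a + b == 0) {
      warning(sprintf("type %s absent from both groups; dropped", tp),
              call. = FALSE)
      return(NULL)
    }
    c_ <- n_lnm_tot - a; d_ <- n_non_tot - b
    tab <- matrix(c(a, b, c_, d_), 2, byrow = TRUE)
    p <- fisher.test(tab)$p.value
    if (any(tab == 0)) tab <- tab + 0.5
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    data.frame(type = tp, n_LNM = a, n_nonLNM = b,
               prop_LNM = a / n_lnm_tot, prop_nonLNM = b / n_non_tot,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_pvalues(out$p, "BH")
  rownames(out) <- NULL
  out
}

#' Paired per-sample subpopulation shift test
#'
#' Within each sample, the share of every type among that sample's LNM
#' cells is paired with its share among the sample's non-LNM cells; a
#' two-sided Wilcoxon signed-rank test across samples (exact where
#' possible) is computed per type with Holm adjustment across types.
#' Samples lacking cells on one side are dropped for that comparison
#' (logged); a type with fewer than 3 usable samples gets p = NA.
#'
#' @param labels a \code{cell_label_table}.
#' @param types per-cell type labels.
#' @param samples per-cell sample identifiers.
#' @return data.frame per type: n_samples, mean_prop_LNM,
#'   mean_prop_nonLNM, p, p_adj; attribute \code{pairs} holds the
#'   per-sample proportion pairs.
#' @export
per_sample_subpop_test <- function(labels, types, samples) {
  lab <- labels$label
  types <- as.character(types); samples <- as.character(samples)
  keep <- lab %in% c("LNM", "non-LNM")
  lab <- lab[keep]; types <- types[keep]; samples <- samples[keep]
  smp <- sort(unique(samples))
  usable <- vapply(smp, function(s) {
    any(lab[samples == s] == "LNM") && any(lab[samples == s] == "non-LNM")
  }, logical(1))
  if (any(!usable)) .log_msg("%d samples lack one label compartment; dropped",
                             sum(!usable))
  smp <- smp[usable]
  if (length(smp) < 3)
    .log_msg("only %d samples with cells in both label groups; p set to NA",
             length(smp))
  all_types <- sort(unique(types))
  pairs <- lapply(setNames(all_types, all_types), function(tp) {
    t(vapply(smp, function(s) {
      in_s <- samples == s
      c(lnm = mean(types[in_s & lab == "LNM"] == tp),
        non = mean(types[in_s & lab == "non-LNM"] == tp))
    }, numeric(2)))
  })
  rows <- lapply(all_types, function(tp) {
    pr <- pairs[[tp]]
    dif <- pr[, "lnm"] - pr[, "non"]
    p <- if (length(dif) < 3) NA_real_
    else if (all(dif == 0)) 1.0
    else suppressWarnings(
      wilcox.test(pr[, "lnm"], pr[, "non"], paired = TRUE)$p.value)
    data.frame(type = tp, n_samples = nrow(pr),
               mean_prop_LNM = mean(pr[, "lnm"]),
               mean_prop_nonLNM = mean(pr[, "non"]),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- adjust_pvalues(out$p[ok], "Holm")
  rownames(out) <- NULL
  attr(out, "pairs") <- pairs
  out
}

## exact squared energy distance between two 2-D point clouds
## (V-statistic form: all ordered pairs, so identical multisets give 0)
.energy_dist_sq <- function(a, b) {
  da <- as.matrix(stats::dist(a)); db <- as.matrix(stats::dist(b))
  dab <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  2 * mean(dab) - mean(da) - mean(db)
}

#' Embedding distribution distance between LNM and non-LNM cells
#'
#' Squared energy distance (based on expected pairwise Euclidean
#' distances, V-statistic convention) between the 2-D embedding point
#' clouds of LNM and non-LNM cells, computed exactly per cell type, with
#' a within-group bootstrap giving replicate distributions. Types with
#' fewer than 5 cells in either group are skipped with a warning.
#'
#' @param emb two-column matrix/data.frame of embedding coordinates.
#' @param labels a \code{cell_label_table}.
#' @param types per-cell type labels.
#' @param n_boot bootstrap replicates (default 200).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame per retained type with \code{energy_distance};
#'   attribute \code{replicates} is a named list of bootstrap vectors.
#' @export
embedding_distance <- function(emb, labels, types, n_boot = 200L, seed = 1L) {
  emb <- as.matrix(emb)
  .assert(ncol(emb) == 2, "embedding must be 2-D")
  lab <- labels$label
  types <- as.character(types)
  set.seed(seed)
  all_types <- sort(unique(types))
  reps <- list()
  rows <- lapply(all_types, function(tp) {
    a <- emb[types == tp & lab == "LNM", , drop = FALSE]
    b <- emb[types == tp & lab == "non-LNM", , drop = FALSE]
    if (nrow(a) < 5 || nrow(b) < 5) {
      warning(sprintf("type %s below 5 cells in a group; skipped", tp),
              call. = FALSE)
      return(NULL)
    }
    d2 <- .energy_dist_sq(a, b)
    reps[[tp]] <<- vapply(seq_len(n_boot), function(i) {
      .energy_dist_sq(a[sample(nrow(a), replace = TRUE), , drop = FALSE],
                      b[sample(nrow(b), replace = TRUE), , drop = FALSE])
    }, numeric(1))
    data.frame(type = tp, energy_distance = d2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  rownames(out) <- NULL
  attr(out, "replicates") <- reps
  out
}
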