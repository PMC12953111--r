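## Two-group differential expression with empirical-Bayes variance
## moderation (the two-sample special case of the moderated t), ranking,
## and construction of the directional top-k gene sets.

## Invert the trigamma function by Newton iteration (monotone decreasing,
## convex on (0, Inf)); used to solve trigamma(d0/2) = excess variance.
.trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits a scaled-F prior to per-gene residual variances by matching the
#' mean and variance of z = log(s2): the excess of var(z) over
#' trigamma(d/2) identifies the prior degrees of freedom d0 through
#' trigamma(d0/2); the mean equation then yields the prior variance s0^2.
#' When var(z) does not exceed trigamma(d/2), the prior is degenerate
#' (d0 = Inf) and s0^2 is the common variance implied by the mean of z.
#'
#' @param s2 per-gene residual variances (at least 20 positive values).
#' @param d common residual degrees of freedom.
#' @return list with \code{d0} (possibly \code{Inf}) and \code{s0_sq}.
#' @export
estimate_prior <- function(s2, d) {
  .assert(d > 0, "residual degrees of freedom must be positive")
  s2 <- s2[is.finite(s2)]
  .assert(any(s2 > 0), "all residual variances are zero: degenerate data")
  pos <- s2[s2 > 0]
  .assert(length(pos) >= 20, "need at least 20 genes with positive variance")
  z <- log(pos)
  excess <- var(z) - trigamma(d / 2)
  if (excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(z) - digamma(d / 2) + log(d / 2))
  } else {
    d0 <- 2 * .trigamma_inverse(excess)
    s0_sq <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-test between two bulk groups
#'
#' For each gene: beta = mean(treatment) - mean(control) on the log2
#' scale, pooled residual variance s2 with d = n1 + n2 - 2 df, posterior
#' variance s2_post = (d0*s0^2 + d*s2) / (d0 + d), moderated
#' t = beta / sqrt(s2_post * (1/n1 + 1/n2)) referred to a t distribution
#' with d0 + d degrees of freedom (standard normal when d0 = Inf), and
#' Benjamini-Hochberg adjusted p-values across all tested genes. Genes
#' with zero variance in both groups and zero beta get p = 1.
#'
#' @param bulk an \code{expression_matrix} on the log2 scale.
#' @param groups factor/character per column with values
#'   \code{control} / \code{treatment} (other values are dropped).
#' @param prior optionally a precomputed prior from
#'   \code{estimate_prior}; by default estimated from the data.
#' @param drop_zero_variance drop genes with zero variance across all
#'   retained samples before testing (default TRUE, logged).
#' @return a \code{de_result} data.frame with columns gene, logFC, t,
#'   P.Value, adj.P.Val, s2, s2_post, plus attributes d, d0, s0_sq.
#' @export
moderated_t_test <- function(bulk, groups, prior = NULL,
                             drop_zero_variance = TRUE) {
  stopifnot(inherits(bulk, "expression_matrix"))
  groups <- as.character(groups)
  keep <- groups %in% c("control", "treatment")
  .assert(sum(groups == "control") >= 2 && sum(groups == "treatment") >= 2,
          "need at least 2 samples per group")
  x <- .dense(bulk$values)[, keep, drop = FALSE]
  g <- groups[keep]
  n1 <- sum(g == "treatment"); n2 <- sum(g == "control")
  d <- n1 + n2 - 2

  if (drop_zero_variance) {
    v_all <- apply(x, 1, var)
    zv <- v_all == 0
    if (any(zv)) .log_msg("dropping %d zero-variance genes of %d before DE",
                          sum(zv), length(zv))
    x <- x[!zv, , drop = FALSE]
  }
  .assert(nrow(x) > 0, "no genes left to test")

  mt <- rowMeans(x[, g == "treatment", drop = FALSE])
  mc <- rowMeans(x[, g == "control", drop = FALSE])
  beta <- mt - mc
  ss <- (rowSums((x[, g == "treatment", drop = FALSE] - mt)^2) +
         rowSums((x[, g == "control", drop = FALSE] - mc)^2))
  s2 <- ss / d

  if (is.null(prior)) prior <- estimate_prior(s2, d)
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tmod <- ifelse(se > 0, beta / se, 0)
  df_total <- d0 + d
  p <- 2 * pt(-abs(tmod), df = df_total)
  p[se == 0 & beta == 0] <- 1
  res <- data.frame(gene = rownames(x), logFC = beta, t = tmod,
                    P.Value = p, adj.P.Val = adjust_pvalues(p, "BH"),
                    s2 = s2, s2_post = s2_post,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "d") <- d
  attr(res, "d0") <- d0
  attr(res, "s0_sq") <- s0_sq
  attr(res, "n1") <- n1
  attr(res, "n2") <- n2
  class(res) <- c("de_result", "data.frame")
  res
}

#' @exportS3Method base::print
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> %d genes; d = %s, d0 = %.4g, s0^2 = %.4g\n",
              nrow(x), attr(x, "d"), attr(x, "d0"), attr(x, "s0_sq")))
  cat(sprintf("  %d genes at adj.P < 0.05 (%d up, %d down)\n",
              sum(x$adj.P.Val < 0.05),
              sum(x$adj.P.Val < 0.05 & x$logFC > 0),
              sum(x$adj.P.Val < 0.05 & x$logFC < 0)))
  print(utils::head(x[order(x$adj.P.Val, -abs(x$logFC)), 1:5], 6), ...)
  invisible(x)
}

#' Build directional top-k gene sets from a DE result
#'
#' Genes are ranked by adjusted p ascending, then |logFC| descending,
#' then gene id ascending; the up set takes the first k with positive
#' logFC, the down set the first k with negative logFC. If fewer than k
#' genes are available in a direction, all are returned and a message
#' logged.
#'
#' @param de a \code{de_result}.
#' @param k set size per direction (default 100).
#' @return list with \code{up} and \code{down} character vectors.
#' @export
build_direction_genesets <- function(de, k = 100L) {
  .assert(k > 0, "k must be positive")
  .assert(nrow(de) > 0, "empty DE result")
  ord <- order(de$adj.P.Val, -abs(de$logFC), de$gene)
  ranked <- de[ord, ]
  up <- ranked$gene[ranked$logFC > 0]
  dn <- ranked$gene[ranked$logFC < 0]
  if (length(up) < k) .log_msg("only %d upregulated genes available (< %d)",
                               length(up), k)
  if (length(dn) < k) .log_msg("only %d downregulated genes available (< %d)",
                               length(dn), k)
  list(up = head(up, k), down = head(dn, k))
}

#' Multiple-testing adjustment (Benjamini-Hochberg or Holm)
#'
#' @param p p-values in [0,1].
#' @param method "BH" (step-up FDR) or "Holm" (step-down FWER).
#' @return adjusted p-values, clipped to [0,1].
#' @export
adjust_pvalues <- function(p, method = c("BH", "Holm")) {
  method <- match.arg(method)
  .assert(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0,1]")
  out <- p.adjust(p, method = if (method == "BH") "BH" else "holm")
  pmin(pmax(out, 0), 1)
}
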