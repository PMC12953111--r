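## Signature scoring on bulk samples and the clinical readouts:
## single-sample enrichment, Kaplan-Meier / log-rank / Cox survival,
## maximally selected cutpoint, score-by-TMB strata, response ROC, and
## drug-sensitivity correlation.

#' Single-sample gene-set enrichment score (running-sum)
#'
#' Per sample, genes are ordered by expression descending (gene-id
#' ascending tiebreak); the i-th ranked gene carries value
#' v = N - i + 1. The in-set empirical CDF steps by v^alpha normalized
#' over the set's values, the out-set CDF by 1/(N - n_S); the raw
#' enrichment score is the sum over all ranks of the CDF difference.
#' Scores may optionally be min-max normalized across samples.
#'
#' @param bulk an \code{expression_matrix} over samples.
#' @param set character vector of gene ids (>= 5 present in the matrix).
#' @param alpha rank weighting exponent (default 0.25).
#' @param normalize \code{"minmax"} to rescale scores across samples to
#'   [0,1], \code{"none"} for raw running-sum scores.
#' @return named per-sample score vector.
#' @export
ssgsea_score <- function(bulk, set, alpha = 0.25,
                         normalize = c("minmax", "none")) {
  stopifnot(inherits(bulk, "expression_matrix"))
  normalize <- match.arg(normalize)
  .assert(alpha >= 0, "alpha must be >= 0")
  set <- unique(set)
  set <- intersect(set, bulk$gene_ids)
  n_s <- length(set)
  .assert(n_s >= 5, "gene set retains %d genes in the matrix (< 5)", n_s)
  N <- length(bulk$gene_ids)
  .assert(N - n_s >= 1, "set must not cover the whole gene universe")
  x <- .dense(bulk$values)
  in_set <- bulk$gene_ids %in% set
  es <- vapply(seq_len(ncol(x)), function(j) {
    ord <- order(-x[, j], bulk$gene_ids)
    hit <- in_set[ord]
    v <- (N - seq_len(N) + 1)^alpha
    w_in <- ifelse(hit, v, 0)
    cdf_in <- cumsum(w_in) / sum(v[hit])
    cdf_out <- cumsum(!hit) / (N - n_s)
    sum(cdf_in - cdf_out)
  }, numeric(1))
  names(es) <- bulk$column_ids
  if (normalize == "minmax" && length(es) > 1) {
    rng <- range(es)
    if (diff(rng) > 0) es <- (es - rng[1]) / diff(rng)
  }
  es
}

#' Kaplan-Meier product-limit estimate per group
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators.
#' @param groups per-subject group labels.
#' @return data.frame with group, time, n_risk, n_event, survival.
#' @export
km_estimate <- function(times, events, groups) {
  .assert(all(times >= 0), "times must be non-negative")
  .assert(all(events %in% c(0, 1)), "events must be 0/1")
  groups <- as.character(groups)
  .assert(all(table(groups) > 0) && length(unique(groups)) >= 1,
          "empty group")
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  if (is.null(fit$strata)) {
    grp <- rep(unique(groups), length(fit$time))
  } else {
    grp <- rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, survival = fit$surv,
             stringsAsFactors = FALSE)
}

#' Log-rank test
#'
#' Observed-minus-expected statistic with hypergeometric variance at
#' each distinct event time; chi-square with (groups - 1) degrees of
#' freedom.
#'
#' @inheritParams km_estimate
#' @return list with chisq, df, p (p is NA when there are no events).
#' @export
logrank <- function(times, events, groups) {
  groups <- as.character(groups)
  .assert(length(unique(groups)) >= 2, "need at least 2 groups")
  if (sum(events) == 0) return(list(chisq = 0, df = length(unique(groups)) - 1,
                                    p = NA_real_))
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd_$n) - 1
  list(chisq = unname(sd_$chisq), df = df,
       p = pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards fit for a single covariate
#'
#' Partial-likelihood Newton maximization (Breslow tie convention) via
#' the survival package; monotone-likelihood (perfect separation) fits
#' are flagged and the coefficient capped.
#'
#' @param times,events follow-up and 0/1 event indicator.
#' @param x binary or real covariate, non-constant.
#' @param cap absolute bound on the reported log-HR under separation.
#' @return list with log_hr, se, p (Wald), hr, ci_lower, ci_upper,
#'   separated flag.
#' @export
cox_hr <- function(times, events, x, cap = 15) {
  .assert(sum(events) >= 1, "need at least one event")
  .assert(sd(as.numeric(x)) > 0, "covariate is constant")
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(times, events) ~ x, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)))
  beta <- unname(coef(fit))
  se <- sqrt(unname(diag(vcov(fit))))
  separated <- !is.finite(beta) || abs(beta) > cap
  if (separated) {
    warning("monotone partial likelihood (separation); log-HR capped",
            call. = FALSE)
    beta <- sign(beta) * cap
  }
  p <- 2 * pnorm(-abs(beta / se))
  list(log_hr = beta, se = se, p = p, hr = exp(beta),
       ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
       separated = separated)
}

#' Maximally selected log-rank cutpoint
#'
#' Evaluates the two-group log-rank chi-square at every distinct score
#' value whose low/high split keeps both groups within the given
#' quantile bounds and returns the maximizing cut (ties: lower cut).
#' The p-value at the chosen cut is the naive log-rank p and is flagged
#' as an uncorrected minimum-p.
#'
#' @param score per-sample score, non-constant.
#' @param times,events survival columns.
#' @param bounds lower/upper quantile bounds for the split (default
#'   0.10, 0.90).
#' @return list with cutpoint, chisq, p_at_cut, uncorrected_minimum_p
#'   flag, and the candidate table.
#' @export
optimal_cutpoint <- function(score, times, events, bounds = c(0.10, 0.90)) {
  .assert(sd(score) > 0, "score is constant")
  .assert(bounds[1] > 0 && bounds[2] < 1 && bounds[1] < bounds[2],
          "bounds must lie inside (0,1)")
  n <- length(score)
  cand <- sort(unique(score))
  ok <- vapply(cand, function(cc) {
    pl <- mean(score <= cc)
    pl >= bounds[1] && pl <= bounds[2]
  }, logical(1))
  cand <- cand[ok]
  .assert(length(cand) > 0, "no admissible cut inside the quantile bounds")
  stats <- vapply(cand, function(cc) {
    logrank(times, events, ifelse(score <= cc, "low", "high"))$chisq
  }, numeric(1))
  best <- which(stats == max(stats))[1]   # ties -> lower cut
  cut <- cand[best]
  lr <- logrank(times, events, ifelse(score <= cut, "low", "high"))
  list(cutpoint = cut, chisq = lr$chisq, p_at_cut = lr$p,
       uncorrected_minimum_p = TRUE,
       candidates = data.frame(cut = cand, chisq = stats))
}

#' Stratify by score and TMB median splits
#'
#' Median splits on both axes (ties to the low group) define four
#' strata; empty strata are dropped with a warning and the global
#' log-rank degrees of freedom reduced accordingly.
#'
#' @param score,tmb per-sample vectors, non-constant.
#' @param times,events survival columns.
#' @return list with labels (per-sample stratum), km table, and global
#'   log-rank chisq/df/p.
#' @export
combo_stratify <- function(score, tmb, times, events) {
  .assert(sd(score) > 0 && sd(tmb) > 0, "score and tmb must be non-constant")
  hi_s <- score > median(score)
  hi_t <- tmb > median(tmb)
  lab <- paste0(ifelse(hi_s, "highScore", "lowScore"), "/",
                ifelse(hi_t, "highTMB", "lowTMB"))
  present <- table(lab)
  if (length(present) < 4)
    warning(sprintf("%d of 4 strata empty; df reduced", 4 - length(present)),
            call. = FALSE)
  lr <- logrank(times, events, lab)
  list(labels = lab, km = km_estimate(times, events, lab),
       chisq = lr$chisq, df = lr$df, p = lr$p)
}

#' ROC of a score for predicting response (low score = responder)
#'
#' AUC is the Mann-Whitney concordance of the negated score against
#' responder status (ties count one half), so scores lower in
#' responders give AUC > 0.5. Also reports the two-sided Wilcoxon
#' rank-sum comparison of scores between responders and non-responders
#' and the ROC points for the low-score-positive decision rule.
#'
#' @param score per-sample score.
#' @param response character/logical responder status ("responder" /
#'   "non_responder", or TRUE for responder).
#' @return list with auc, wilcox_p, and a roc data.frame (threshold,
#'   tpr, fpr).
#' @export
response_roc <- function(score, response) {
  if (is.logical(response)) {
    resp <- response
  } else {
    resp <- as.character(response) == "responder"
  }
  keep <- !is.na(resp) & !is.na(score)
  score <- score[keep]; resp <- resp[keep]
  n1 <- sum(resp); n0 <- sum(!resp)
  .assert(n1 > 0 && n0 > 0, "both response classes must be present")
  r <- rank(score)
  ## U counts pairs where responder score exceeds non-responder score
  u_gt <- sum(r[resp]) - n1 * (n1 + 1) / 2
  auc <- 1 - u_gt / (n1 * n0)
  wp <- suppressWarnings(wilcox.test(score[resp], score[!resp])$p.value)
  thr <- c(sort(unique(score)), Inf)
  roc <- data.frame(threshold = thr,
                    tpr = vapply(thr, function(t) mean(score[resp] <= t),
                                 numeric(1)),
                    fpr = vapply(thr, function(t) mean(score[!resp] <= t),
                                 numeric(1)))
  list(auc = auc, wilcox_p = wp, roc = roc)
}

#' Correlate a score with drug IC50 values
#'
#' Spearman correlation (average-rank ties) of the score against each
#' IC50 column, BH-adjusted, with the most negatively and most
#' positively correlated drugs listed.
#'
#' @param score per-sample score.
#' @param ic50_table data.frame/matrix of per-sample IC50 columns.
#' @param top_k list size per sign (default 20).
#' @param min_n minimum complete pairs per drug (default 10).
#' @return list with table (drug, n, rho, p, p_adj), top_negative,
#'   top_positive.
#' @export
drug_correlation <- function(score, ic50_table, top_k = 20L, min_n = 10L) {
  ic50_table <- as.data.frame(ic50_table)
  rows <- lapply(colnames(ic50_table), function(dr) {
    y <- as.numeric(ic50_table[[dr]])
    ok <- !is.na(y) & !is.na(score)
    if (sum(ok) < min_n || sd(y[ok]) == 0) {
      return(data.frame(drug = dr, n = sum(ok), rho = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(cor.test(score[ok], y[ok], method = "spearman",
                                    exact = FALSE))
    data.frame(drug = dr, n = sum(ok), rho = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- NA_real_
  ok <- !is.na(tab$p)
  tab$p_adj[ok] <- adjust_pvalues(tab$p[ok], "BH")
  rownames(tab) <- NULL
  ranked <- tab[!is.na(tab$rho), ]
  list(table = tab,
       top_negative = head(ranked$drug[order(ranked$rho)], top_k),
       top_positive = head(ranked$drug[order(-ranked$rho)], top_k))
}
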