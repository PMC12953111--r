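mkbulk <- function(x, ids = sprintf("g%02d", seq_len(nrow(x)))) {
  expression_matrix(x, ids, sprintf("s%02d", seq_len(ncol(x))),
                    "log2tpm1")
}

test_that("single-sample enrichment closed forms hold", {
  ## one set gene at the top rank, alpha = 0, N = 10 -> raw ES = N/2
  x <- matrix(10:1, ncol = 1)
  em <- mkbulk(x)
  ## min_set_size guard is 5; use the formula's 5-gene analog first
  s5 <- ssgsea_score(em, paste0("g0", 1:5), alpha = 0, normalize = "none")
  ref5 <- ssgsea_brute(x, em$gene_ids, paste0("g0", 1:5), 0)
  expect_equal(unname(s5), unname(ref5), tolerance = 1e-12)

  ## top vs bottom placement flips the sign
  top_set <- paste0("g0", 1:5)
  bottom_set <- c(paste0("g0", 6:9), "g10")
  expect_gt(unname(ssgsea_score(em, top_set, 0.25, "none")), 0)
  expect_lt(unname(ssgsea_score(em, bottom_set, 0.25, "none")), 0)
})

test_that("single-gene-at-top analytic value N/2 holds for the raw running sum", {
  ## the formula evaluated with a 1-gene set (checked against the
  ## independent loop, bypassing the size guard via the oracle)
  x <- matrix(10:1, ncol = 1)
  ids <- sprintf("g%02d", 1:10)
  es <- ssgsea_brute(x, ids, "g01", alpha = 0)
  expect_equal(unname(es), 5.0, tolerance = 1e-12)
})

test_that("enrichment scores match the brute-force loop on random fixtures", {
  for (s in 1:20) {
    em <- rand_em(15, 4, seed = 90 + s)
    set <- sample(em$gene_ids, 5)
    got <- ssgsea_score(em, set, alpha = 0.25, normalize = "none")
    ref <- ssgsea_brute(as.matrix(em$values), em$gene_ids, set, 0.25)
    expect_equal(unname(got), unname(ref), tolerance = 1e-12)
  }
})

test_that("enrichment is invariant to per-sample monotone transforms", {
  em <- rand_em(30, 5, seed = 95)
  set <- sample(em$gene_ids, 6)
  a <- ssgsea_score(em, set, 0.25, "none")
  tr <- expression_matrix(exp(as.matrix(em$values) / 4), em$gene_ids,
                          em$column_ids, "log2tpm1")
  expect_equal(ssgsea_score(tr, set, 0.25, "none"), a, tolerance = 1e-12)
})

test_that("Kaplan-Meier matches hand-computed product-limit values", {
  times <- c(1, 2, 2, 3, 4, 5, 6, 7)
  events <- c(1, 1, 0, 1, 0, 1, 1, 0)
  km <- km_estimate(times, events, rep("all", 8))
  at <- function(t) km$survival[km$time == t]
  expect_equal(at(1), 7 / 8, tolerance = 1e-12)
  expect_equal(at(2), 7 / 8 * 6 / 7, tolerance = 1e-12)
  expect_equal(at(3), 0.75 * 4 / 5, tolerance = 1e-12)
  expect_equal(at(5), 0.6 * 2 / 3, tolerance = 1e-12)
  expect_equal(at(6), 0.4 * 1 / 2, tolerance = 1e-12)

  ## no censoring: empirical survival function
  km2 <- km_estimate(1:5, rep(1, 5), rep("a", 5))
  expect_equal(km2$survival, (4:0) / 5, tolerance = 1e-12)

  ## all censored: flat at 1
  km3 <- km_estimate(1:5, rep(0, 5), rep("a", 5))
  expect_true(all(km3$survival == 1))
})

test_that("log-rank is zero on duplicated groups and matches the O/E/V sums", {
  times <- c(2, 4, 6, 8, 10)
  events <- c(1, 1, 0, 1, 1)
  lr0 <- logrank(c(times, times), c(events, events),
                 rep(c("a", "b"), each = 5))
  expect_equal(lr0$chisq, 0, tolerance = 1e-9)
  expect_equal(lr0$p, 1, tolerance = 1e-9)

  ## non-overlapping event times, no censoring
  t2 <- c(1, 2, 3, 4, 5, 11, 12, 13, 14, 15)
  e2 <- rep(1, 10)
  g2 <- rep(c("early", "late"), each = 5)
  lr <- logrank(t2, e2, g2)
  expect_equal(lr$chisq, logrank_brute(t2, e2, g2 == "early"),
               tolerance = 1e-9)
  expect_equal(lr$p, pchisq(lr$chisq, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_true(is.na(logrank(times, rep(0, 5), rep(c("a", "b"),
                                                  c(2, 3)))$p))
})

test_that("Cox fit matches an independent partial-likelihood maximizer", {
  times <- c(3, 5, 7, 2, 11, 9)
  events <- c(1, 1, 0, 1, 1, 1)
  x <- c(0.5, -1, 0.3, 2, -0.7, 1.1)
  fit <- cox_hr(times, events, x)
  opt <- optimize(function(b) cox_pll(b, times, events, x),
                  c(-10, 10), maximum = TRUE, tol = 1e-10)
  expect_equal(fit$log_hr, opt$maximum, tolerance = 1e-6)

  ## identical groups -> HR = 1
  fit0 <- cox_hr(rep(times, 2), rep(events, 2), rep(c(0, 1), each = 6))
  expect_equal(fit0$hr, 1, tolerance = 1e-6)
  expect_error(cox_hr(times, events, rep(1, 6)), "constant")
  expect_error(cox_hr(times, rep(0, 6), x), "one event")
})

test_that("perfect separation is flagged and capped", {
  times <- c(1, 2, 3, 10, 11, 12)
  events <- rep(1, 6)
  x <- c(1, 1, 1, 0, 0, 0)
  expect_warning(fit <- cox_hr(times, events, x), "capped|separation")
  expect_true(fit$separated)
  expect_lte(abs(fit$log_hr), 15)
})

test_that("optimal cutpoint maximizes, respects bounds and tie-breaks low", {
  set.seed(101)
  n <- 120
  score <- runif(n)
  surv <- generate_survival(score, beta = 0, censor_rate = 0.2, seed = 5)
  oc <- optimal_cutpoint(score, surv$os_time, surv$os_event)
  med_stat <- logrank(surv$os_time, surv$os_event,
                      ifelse(score <= median(score), "lo", "hi"))$chisq
  expect_gte(oc$chisq + 1e-9, med_stat)
  expect_true(oc$uncorrected_minimum_p)
  splits <- mean(score <= oc$cutpoint)
  expect_true(splits >= 0.10 && splits <= 0.90)
  ## with equal statistics everywhere possible, ties return the lower cut
  first_max <- oc$candidates$cut[which(
    oc$candidates$chisq == max(oc$candidates$chisq))][1]
  expect_equal(oc$cutpoint, first_max)
  expect_error(optimal_cutpoint(rep(1, 10), surv$os_time[1:10],
                                surv$os_event[1:10]), "constant")
})

test_that("a strong hazard step at the median is localized by the cutpoint", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    score <- runif(300)
    lam <- ifelse(score > 0.5, 4, 1) / 365
    tt <- rexp(300, lam)
    oc <- optimal_cutpoint(score, tt, rep(1, 300))
    q <- mean(score <= oc$cutpoint)
    q >= 0.40 && q <= 0.60
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("median-split strata are balanced and degenerate splits reduce df", {
  set.seed(102)
  n <- 400
  score <- runif(n); tmb <- runif(n)
  surv <- generate_survival(score, 0.3, 0.2, seed = 7)
  cs <- combo_stratify(score, tmb, surv$os_time, surv$os_event)
  expect_true(all(abs(table(cs$labels) - 100) <= 20))
  expect_equal(cs$df, 3)

  expect_warning(
    cs2 <- combo_stratify(score, score, surv$os_time, surv$os_event),
    "strata empty")
  expect_equal(cs2$df, 1)
})

test_that("response AUC equals all-pairs concordance, with its extremes", {
  ## perfectly separated (responders lower) -> AUC 1
  score <- c(1, 2, 3, 10, 11, 12)
  resp <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(response_roc(score, resp)$auc, 1)

  ## 6-point fixture with ties vs the brute-force count
  s2 <- c(1, 2, 2, 3, 2, 5)
  r2 <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  expect_equal(response_roc(s2, r2)$auc, auc_brute(s2, r2),
               tolerance = 1e-12)

  ## independence -> AUC near 1/2
  set.seed(103)
  s3 <- rnorm(1000)
  r3 <- sample(c(TRUE, FALSE), 1000, replace = TRUE)
  expect_lt(abs(response_roc(s3, r3)$auc - 0.5), 0.05)
  expect_error(response_roc(s3, rep(TRUE, 1000)), "classes")
})

test_that("drug correlations recover monotone couplings and handle ties", {
  set.seed(104)
  score <- rnorm(20)
  tab <- data.frame(d_up = exp(score), d_down = -score,
                    d_const = rep(1, 20))
  res <- drug_correlation(score, tab, min_n = 10)
  expect_equal(res$table$rho[res$table$drug == "d_up"], 1,
               tolerance = 1e-12)
  expect_equal(res$table$rho[res$table$drug == "d_down"], -1,
               tolerance = 1e-12)
  expect_true(is.na(res$table$rho[res$table$drug == "d_const"]))
  expect_equal(res$top_negative[1], "d_down")
  expect_equal(res$top_positive[1], "d_up")

  ## 12-sample fixture with ties vs rank-then-Pearson
  s <- c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7, 7, 8)
  y <- c(3, 1, 4, 4, 2, 6, 5, 5, 8, 7, 9, 9)
  res2 <- drug_correlation(s, data.frame(d = y), min_n = 10)
  expect_equal(res2$table$rho, cor(rank(s), rank(y)), tolerance = 1e-12)
})
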