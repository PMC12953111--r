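test_that("identical config gives identical outputs", {
  cfg <- small_sim(seed = 21)
  a <- generate_paired_dataset(cfg)
  b <- generate_paired_dataset(cfg)
  expect_identical(a, b)
})

test_that("planted bulk effect is realized at the configured size", {
  cfg <- small_sim(seed = 22)
  cfg$n_bulk_samples <- 120L
  ds <- generate_paired_dataset(cfg)
  b <- as.matrix(ds$bulk$matrix$values)
  lnm <- ds$truth$is_lnm
  lfc <- rowMeans(b[ds$truth$up_genes, lnm, drop = FALSE]) -
    rowMeans(b[ds$truth$up_genes, !lnm, drop = FALSE])
  expect_gt(mean(lfc), 1.0 - 0.15)
  expect_lt(mean(lfc), 1.0 + 0.15)

  ## null case: zero effect mean and spread
  cfg0 <- cfg
  cfg0$bulk_effect_log2fc <- 0
  cfg0$bulk_effect_sd <- 0
  ds0 <- generate_paired_dataset(cfg0)
  b0 <- as.matrix(ds0$bulk$matrix$values)
  lfc0 <- rowMeans(b0[ds0$truth$up_genes, ds0$truth$is_lnm, drop = FALSE]) -
    rowMeans(b0[ds0$truth$up_genes, !ds0$truth$is_lnm, drop = FALSE])
  expect_lt(abs(mean(lfc0)), 0.1)
})

test_that("infeasible program sizes are rejected", {
  expect_error(sim_config(n_genes = 400L, program_size_up = 150L),
               "infeasible")
})

test_that("negative binomial moments match the configured dispersion", {
  cfg <- sim_config(seed = 23, n_genes = 800L, n_sc_samples = 2L,
                    cells_per_sample = 300L, program_size_up = 60L,
                    program_size_down = 60L, regulon_size = 30L)
  ds <- generate_paired_dataset(cfg)
  x <- as.matrix(ds$sc$matrix$values)
  tcell <- ds$sc$cells$major_type == "Tcell"
  ## background genes only: no type effects, program or regulon loading
  special <- c(ds$truth$up_genes, ds$truth$down_genes,
               unlist(ds$truth$markers), ds$truth$regulon$tf,
               ds$truth$regulon$targets)
  bg <- setdiff(ds$sc$matrix$gene_ids, special)
  xs <- x[bg, tcell]
  m <- rowMeans(xs)
  v <- apply(xs, 1, var)
  keep <- m > 0.5
  ratio <- v[keep] / (m[keep] + m[keep]^2 * cfg$nb_dispersion)
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("survival generator recovers the planted hazard coefficient", {
  ## beta = 0.8, n = 500: Cox estimate close to truth averaged over seeds
  est <- vapply(1:15, function(s) {
    set.seed(s * 100)
    z <- rnorm(500)
    surv <- generate_survival(z, beta = 0.8, censor_rate = 0.3, seed = s)
    cox_hr(surv$os_time, surv$os_event, z)$log_hr
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.8), 0.15)
})

test_that("null hazard gives unit HR coverage and censoring hits its target", {
  cover <- vapply(1:60, function(s) {
    set.seed(s)
    z <- rnorm(120)
    surv <- generate_survival(z, beta = 0, censor_rate = 0.3, seed = s + 1)
    fit <- cox_hr(surv$os_time, surv$os_event, z)
    fit$ci_lower <= 1 && fit$ci_upper >= 1
  }, logical(1))
  expect_gte(mean(cover), 0.90)

  surv <- generate_survival(rnorm(4000), beta = 0.5, censor_rate = 0.4,
                            seed = 9)
  expect_lt(abs(mean(surv$os_event == 0) - 0.4), 0.05)
  expect_error(generate_survival(rnorm(10), 0.5, censor_rate = 1.2),
               "censor_rate")
})

test_that("embedding clusters are recoverable and empty input passes through", {
  cells <- data.frame(subpop = rep(c("A", "B", "C"), each = 200))
  emb <- generate_embedding(cells, seed = 5)
  centers <- aggregate(cbind(emb_x, emb_y) ~ subpop, emb, mean)
  d <- as.matrix(dist(centers[, c("emb_x", "emb_y")]))
  expect_true(all(d[upper.tri(d)] >= 6))   # >= 6 sd apart (unit sd)
  assign_near <- apply(cbind(emb$emb_x, emb$emb_y), 1, function(p) {
    centers$subpop[which.min((centers$emb_x - p[1])^2 +
                               (centers$emb_y - p[2])^2)]
  })
  expect_gte(mean(assign_near == emb$subpop), 0.99)

  empty <- generate_embedding(data.frame(subpop = character(0)))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("emb_x", "emb_y") %in% colnames(empty)))
})

test_that("dataset bundle writes every on-disk artifact the readers consume", {
  ds <- generate_paired_dataset(small_sim(seed = 24))
  d <- withr::local_tempdir()
  write_dataset_bundle(ds, d)
  expect_true(all(file.exists(file.path(d, c(
    "matrix.mtx", "genes.tsv", "barcodes.tsv", "cells.tsv",
    "bulk_expr.tsv", "clinical.tsv", "lnm_true_sets.gmt",
    "true_regulon.tsv", "truth.json")))))
  back <- read_expression_mtx(file.path(d, "matrix.mtx"),
                              file.path(d, "genes.tsv"),
                              file.path(d, "barcodes.tsv"))
  expect_equal(dim(back), dim(ds$sc$matrix))
  clin <- read_clinical(file.path(d, "clinical.tsv"))
  expect_equal(as.character(clin$group),
               as.character(ds$bulk$clinical$group))
  bulk <- read_bulk_tsv(file.path(d, "bulk_expr.tsv"))
  expect_equal(as.matrix(bulk$values), as.matrix(ds$bulk$matrix$values),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("TMB coupling and response direction follow the configuration", {
  ds <- generate_paired_dataset(sim_config(seed = 25,
                                           n_bulk_samples = 400L,
                                           n_sc_samples = 2L,
                                           cells_per_sample = 100L,
                                           n_genes = 600L,
                                           program_size_up = 50L,
                                           program_size_down = 50L,
                                           regulon_size = 20L))
  clin <- ds$bulk$clinical
  rho <- cor(ds$truth$true_signature, clin$tmb, method = "spearman")
  expect_lt(abs(rho - (-0.4)), 0.12)
  ## responders sit at lower true signature
  expect_lt(mean(ds$truth$true_signature[clin$response == "responder"]),
            mean(ds$truth$true_signature[clin$response == "non_responder"]))
})
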