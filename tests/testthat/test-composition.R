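mklab <- function(labels) {
  structure(data.frame(cell_id = seq_along(labels), label = labels,
                       stringsAsFactors = FALSE),
            class = c("cell_label_table", "data.frame"))
}

test_that("equal composition gives unit odds ratios and p = 1", {
  lab <- mklab(rep(c("LNM", "non-LNM"), each = 40))
  types <- rep(rep(c("A", "B"), each = 20), 2)
  sh <- celltype_shift(lab, types)
  expect_true(all(abs(sh$odds_ratio - 1) < 1e-12))
  expect_true(all(sh$p == 1))
  expect_equal(sum(sh$prop_LNM), 1, tolerance = 1e-9)
})

test_that("types absent on one side get finite Haldane odds ratios", {
  lab <- mklab(rep(c("LNM", "non-LNM"), each = 10))
  types <- c(rep("A", 5), rep("B", 5), rep("B", 10))  # A only in LNM
  sh <- celltype_shift(lab, types)
  orA <- sh$odds_ratio[sh$type == "A"]
  expect_true(is.finite(orA) && orA > 1)
})

test_that("Fisher p equals full hypergeometric enumeration on small tables", {
  two_sided_fisher <- function(a, b, c_, d_) {
    m <- a + c_; n_ <- b + d_; k <- a + b
    support <- max(0, k - n_):min(k, m)
    dens <- dhyper(support, m, n_, k)
    sum(dens[dens <= dhyper(a, m, n_, k) * (1 + 1e-7)])
  }
  set.seed(51)
  for (i in 1:30) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    p_pkg <- fisher.test(tab)$p.value
    p_ref <- two_sided_fisher(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(p_pkg, p_ref, tolerance = 1e-9)
  }
})

test_that("paired per-sample test reproduces the exact signed-rank null", {
  ## one type shifted +0.2 in every sample's LNM compartment, 8 samples:
  ## all signs positive -> two-sided exact p = 2 / 2^8
  n_s <- 8
  m <- 200   # compartment size fine enough for distinct paired differences
  cells <- do.call(rbind, lapply(seq_len(n_s), function(s) {
    lnm_a <- round(m * (0.3 + 0.2 + 0.005 * s))
    non_a <- round(m * 0.3)
    data.frame(
      sample = sprintf("s%d", s),
      label = c(rep("LNM", m), rep("non-LNM", m)),
      type = c(rep("A", lnm_a), rep("B", m - lnm_a),
               rep("A", non_a), rep("B", m - non_a)))
  }))
  res <- per_sample_subpop_test(mklab(cells$label), cells$type,
                                cells$sample)
  expect_equal(res$p[res$type == "A"], 2 / 2^8, tolerance = 1e-12)
  expect_equal(res$p_adj[res$type == "A"], min(1, 2 * 2 / 2^8),
               tolerance = 1e-12)
})

test_that("identical compartment proportions give p = 1 everywhere", {
  cells <- do.call(rbind, lapply(1:4, function(s) {
    data.frame(sample = sprintf("s%d", s),
               label = rep(c("LNM", "non-LNM"), each = 10),
               type = rep(c(rep("A", 4), rep("B", 6)), 2))
  }))
  res <- per_sample_subpop_test(mklab(cells$label), cells$type,
                                cells$sample)
  expect_true(all(res$p == 1))
})

test_that("too few usable samples reports NA p-values", {
  cells <- data.frame(sample = rep(c("s1", "s2"), each = 10),
                      label = rep(c("LNM", "non-LNM"), 10),
                      type = "A")
  res <- suppressMessages(
    per_sample_subpop_test(mklab(cells$label), cells$type, cells$sample))
  expect_true(all(is.na(res$p)))
  expect_true(all(is.na(res$p_adj)))
})

test_that("squared energy distance matches the brute-force double loop", {
  set.seed(52)
  a <- matrix(rnorm(12), 6, 2)
  b <- matrix(rnorm(12, mean = 1), 6, 2)
  lab <- mklab(rep(c("LNM", "non-LNM"), each = 6))
  res <- embedding_distance(rbind(a, b), lab, rep("T", 12), n_boot = 5)
  expect_equal(res$energy_distance, energy_brute(a, b), tolerance = 1e-12)

  ## identical multisets -> 0
  res0 <- embedding_distance(rbind(a, a), lab, rep("T", 12), n_boot = 5)
  expect_equal(res0$energy_distance, 0, tolerance = 1e-12)
})

test_that("energy distance is rigid-motion invariant and grows with shift", {
  set.seed(53)
  a <- matrix(rnorm(20), 10, 2)
  b <- matrix(rnorm(20), 10, 2)
  d0 <- energy_brute(a, b)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(energy_brute(a %*% R + 3, b %*% R + 3), d0,
               tolerance = 1e-12)
  shifts <- c(0, 1, 2, 4)
  ds <- vapply(shifts, function(s) energy_brute(a, sweep(b, 2, c(s, 0),
                                                          "+")),
               numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("small embedding groups are skipped with a warning", {
  lab <- mklab(c(rep("LNM", 3), rep("non-LNM", 8)))
  emb <- matrix(rnorm(22), 11, 2)
  expect_warning(res <- embedding_distance(emb, lab, rep("T", 11),
                                           n_boot = 3), "skipped")
  expect_null(res)
})

test_that("within-sample label shuffling destroys the planted shift", {
  ds <- generate_paired_dataset(small_sim(seed = 32))
  up <- uscore(ds$sc$matrix, ds$truth$up_genes, r_max = 500)
  dn <- uscore(ds$sc$matrix, ds$truth$down_genes, r_max = 500)
  lab <- suppressMessages(label_cells(up, dn, q = 0.10))
  myelo <- ds$sc$cells$major_type == "Myeloid"
  set.seed(99)
  p_perm <- vapply(1:40, function(i) {
    shuffled <- lab
    for (s in unique(ds$sc$cells$sample)) {
      idx <- which(ds$sc$cells$sample == s)
      shuffled$label[idx] <- sample(lab$label[idx])
    }
    res <- suppressMessages(
      per_sample_subpop_test(shuffled[myelo, ],
                             ds$sc$cells$subpop[myelo],
                             ds$sc$cells$sample[myelo]))
    res$p[res$type == ds$truth$planted_subpop]
  }, numeric(1))
  ## permuted p-values should not pile up near zero
  expect_gt(mean(p_perm > 0.05), 0.8)
})
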