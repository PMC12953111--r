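## Synthetic paired bulk + single-cell generator with planted ground truth.
##
## The generator plants three linked signals:
##   * an LNM transcriptional program (up/down gene sets) shifted in the
##     metastatic bulk group and, at the single-cell level, in one myeloid
##     subpopulation ("planted" neutrophil-like state);
##   * a TF regulon whose targets load on a per-cell latent activity that
##     is hotter in the planted subpopulation;
##   * bulk samples mixed from the realized per-type mean profiles, with
##     survival, TMB, response and drug IC50 channels tied to the true
##     per-sample signature (the planted subpopulation's abundance).

.MAJOR_TYPES <- c("Epithelial", "Tcell", "Bcell", "NKcell",
                  "Fibroblast", "Myeloid")
.MYELOID_SUBPOPS <- c("Mac_C1Q", "Mono_CD14", "DC_cDC2", "Neu_ELANE")
.PLANTED_SUBPOP <- "Neu_ELANE"
.MYELOID_SPLIT <- c(Mac_C1Q = 0.35, Mono_CD14 = 0.25,
                    DC_cDC2 = 0.15, Neu_ELANE = 0.25)

#' Configuration for the synthetic paired dataset
#'
#' Defaults define the study conditions used throughout the package's
#' recovery tests: 2000 genes, 120 bulk samples (half with nodal
#' metastasis), 8 single-cell samples of 300 cells, a planted 150+150
#' gene program with mean log2 fold change 1.0, and a 60-target planted
#' regulon.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes.
#' @param n_bulk_samples number of bulk samples.
#' @param lnm_fraction proportion of bulk samples in the metastatic group.
#' @param n_sc_samples number of single-cell samples.
#' @param cells_per_sample cells per single-cell sample.
#' @param cell_type_props named simplex over the six major cell types;
#'   the Myeloid entry is split over four subpopulations, one of which
#'   (\code{Neu_ELANE}) carries the planted program.
#' @param program_size_up,program_size_down planted program sizes.
#' @param bulk_effect_log2fc mean of the per-gene planted bulk effect
#'   (log2 fold change).
#' @param bulk_effect_sd standard deviation of the per-gene effect.
#' @param sc_program_shift natural-log shift applied to program genes in
#'   the planted subpopulation.
#' @param regulon_size number of planted regulon targets.
#' @param regulon_loading linear loading of targets on latent activity.
#' @param nb_dispersion negative binomial dispersion (var = m + m^2*phi).
#' @param surv_beta log-hazard coefficient on the standardized true
#'   signature.
#' @param censor_rate target censoring proportion.
#' @param tmb_corr target Spearman correlation of TMB with the score
#'   (negative couples high score to low TMB).
#' @return a \code{sim_config} list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_bulk_samples = 120L,
                       lnm_fraction = 0.5,
                       n_sc_samples = 8L,
                       cells_per_sample = 300L,
                       cell_type_props = c(Epithelial = 0.30, Tcell = 0.25,
                                           Bcell = 0.08, NKcell = 0.05,
                                           Fibroblast = 0.08, Myeloid = 0.24),
                       program_size_up = 150L,
                       program_size_down = 150L,
                       bulk_effect_log2fc = 1.0,
                       bulk_effect_sd = 0.25,
                       sc_program_shift = 1.0,
                       regulon_size = 60L,
                       regulon_loading = 1.2,
                       nb_dispersion = 0.5,
                       surv_beta = 0.8,
                       censor_rate = 0.3,
                       tmb_corr = -0.4) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_bulk_samples = as.integer(n_bulk_samples),
              lnm_fraction = lnm_fraction,
              n_sc_samples = as.integer(n_sc_samples),
              cells_per_sample = as.integer(cells_per_sample),
              cell_type_props = cell_type_props,
              program_size_up = as.integer(program_size_up),
              program_size_down = as.integer(program_size_down),
              bulk_effect_log2fc = bulk_effect_log2fc,
              bulk_effect_sd = bulk_effect_sd,
              sc_program_shift = sc_program_shift,
              regulon_size = as.integer(regulon_size),
              regulon_loading = regulon_loading,
              nb_dispersion = nb_dispersion,
              surv_beta = surv_beta,
              censor_rate = censor_rate,
              tmb_corr = tmb_corr)
  .assert(all(sort(names(cfg$cell_type_props)) == sort(.MAJOR_TYPES)),
          "cell_type_props must be named over the six major types")
  .assert(abs(sum(cfg$cell_type_props) - 1) < 1e-12,
          "cell_type_props must sum to 1")
  .assert(all(cfg$cell_type_props > 0 & cfg$cell_type_props < 1),
          "cell_type_props must lie in (0,1)")
  for (p in c("lnm_fraction", "censor_rate"))
    .assert(cfg[[p]] >= 0 && cfg[[p]] < 1, "%s must lie in [0,1)", p)
  .assert(cfg$nb_dispersion > 0 && cfg$regulon_loading > 0,
          "dispersion and loading must be positive")
  .assert(cfg$program_size_up <= cfg$n_genes / 4 &&
          cfg$program_size_down <= cfg$n_genes / 4,
          "program sizes above n_genes/4 signal an infeasible config")
  class(cfg) <- "sim_config"
  cfg
}

## leaf-level type proportions (9 types: 5 non-myeloid majors + 4 subpops)
.leaf_props <- function(cell_type_props) {
  majors <- cell_type_props[setdiff(.MAJOR_TYPES, "Myeloid")]
  myelo <- cell_type_props[["Myeloid"]] * .MYELOID_SPLIT
  c(majors, myelo)
}

#' Generate the paired synthetic bulk + single-cell dataset
#'
#' Single-cell counts are negative binomial with a per-gene log-normal
#' baseline, per-type marker effects, the planted program shift in the
#' planted subpopulation, and a linear loading of regulon targets on a
#' per-cell Gamma latent activity (hotter in the planted subpopulation).
#' Bulk samples are TPM-normalized linear mixtures of the realized
#' per-type mean profiles weighted by Dirichlet true fractions (the
#' planted subpopulation is 50% more abundant in metastatic samples),
#' log2(x+1)-transformed, with the planted program shifted by the
#' per-gene bulk effect in metastatic samples and Gaussian noise
#' (sd 0.25) added on the log scale. Survival, TMB, response and 30 drug
#' IC50 channels are tied to the standardized true signature (log planted
#' fraction). Deterministic given the config seed.
#'
#' @param cfg a \code{sim_config}.
#' @return a list with elements \code{sc} (expression_matrix + cell
#'   table), \code{bulk} (expression_matrix + clinical table) and
#'   \code{truth} (planted ground truth).
#' @export
generate_paired_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes
  gene_ids <- sprintf("G%04d", seq_len(G))
  leaf_props <- .leaf_props(cfg$cell_type_props)
  leaf_types <- names(leaf_props)
  K <- length(leaf_types)

  ## ---- gene roles (disjoint by construction) ----
  pool <- sample(gene_ids)
  take <- function(n) { out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; out }
  up_genes <- sort(take(cfg$program_size_up))
  down_genes <- sort(take(cfg$program_size_down))
  markers <- lapply(setNames(leaf_types, leaf_types), function(t) take(40L))
  tf_gene <- take(1L)
  target_genes <- sort(take(cfg$regulon_size))

  ## ---- single-cell counts ----
  n_cells <- cfg$n_sc_samples * cfg$cells_per_sample
  sample_id <- rep(sprintf("SC%02d", seq_len(cfg$n_sc_samples)),
                   each = cfg$cells_per_sample)
  leaf <- sample(leaf_types, n_cells, replace = TRUE, prob = leaf_props)
  major <- ifelse(leaf %in% .MYELOID_SUBPOPS, "Myeloid", leaf)
  planted <- leaf == .PLANTED_SUBPOP

  base_log <- rnorm(G, mean = -0.5, sd = 1)        # ln NB mean
  type_eff <- matrix(0, G, K, dimnames = list(gene_ids, leaf_types))
  for (t in leaf_types) type_eff[markers[[t]], t] <- 1.5

  activity <- rgamma(n_cells, shape = 2, scale = 0.5 * (1 + planted))

  idx_up <- match(up_genes, gene_ids)
  idx_dn <- match(down_genes, gene_ids)
  idx_tg <- match(c(tf_gene, target_genes), gene_ids)

  logmu <- matrix(base_log, G, n_cells) + type_eff[, match(leaf, leaf_types)]
  logmu[idx_up, planted] <- logmu[idx_up, planted] + cfg$sc_program_shift
  logmu[idx_dn, planted] <- logmu[idx_dn, planted] - cfg$sc_program_shift
  logmu[idx_tg, ] <- logmu[idx_tg, ] +
    cfg$regulon_loading * rep(activity, each = length(idx_tg))

  counts <- matrix(rnbinom(G * n_cells, mu = exp(logmu),
                           size = 1 / cfg$nb_dispersion), G, n_cells)
  rownames(counts) <- gene_ids
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  sc_mat <- expression_matrix(as(Matrix::Matrix(counts, sparse = TRUE),
                                 "CsparseMatrix"),
                              gene_ids, cell_ids, "counts")

  cells <- data.frame(cell_id = cell_ids, sample = sample_id,
                      major_type = major, subpop = leaf,
                      stringsAsFactors = FALSE)
  cells <- generate_embedding(cells, seed = cfg$seed + 1L)

  ## ---- realized per-type mean profiles (linear counts scale) ----
  profiles <- vapply(leaf_types, function(t) {
    rowMeans(counts[, leaf == t, drop = FALSE])
  }, numeric(G))

  ## ---- bulk mixtures ----
  nB <- cfg$n_bulk_samples
  n_lnm <- round(nB * cfg$lnm_fraction)
  is_lnm <- c(rep(TRUE, n_lnm), rep(FALSE, nB - n_lnm))
  base_f <- matrix(leaf_props, nB, K, byrow = TRUE,
                   dimnames = list(NULL, leaf_types))
  base_f[is_lnm, .PLANTED_SUBPOP] <- base_f[is_lnm, .PLANTED_SUBPOP] * 1.5
  conc <- 100
  gam <- matrix(rgamma(nB * K, shape = base_f * conc, scale = 1), nB, K)
  true_f <- gam / rowSums(gam)
  colnames(true_f) <- leaf_types

  true_sig <- as.numeric(scale(log(true_f[, .PLANTED_SUBPOP])))

  lin <- profiles %*% t(true_f)                    # genes x samples
  tpm <- sweep(lin, 2, colSums(lin), "/") * 1e6
  bulk_log <- log2(tpm + 1)
  eff_up <- rnorm(length(idx_up), cfg$bulk_effect_log2fc, cfg$bulk_effect_sd)
  eff_dn <- rnorm(length(idx_dn), cfg$bulk_effect_log2fc, cfg$bulk_effect_sd)
  bulk_log[idx_up, is_lnm] <- bulk_log[idx_up, is_lnm] + eff_up
  bulk_log[idx_dn, is_lnm] <- bulk_log[idx_dn, is_lnm] - eff_dn
  bulk_log <- bulk_log + matrix(rnorm(G * nB, sd = 0.25), G, nB)
  bulk_log <- pmax(bulk_log, 0)
  bulk_ids <- sprintf("BULK%03d", seq_len(nB))
  bulk_mat <- expression_matrix(bulk_log, gene_ids, bulk_ids, "log2tpm1")

  ## ---- clinical channels ----
  surv <- generate_survival(true_sig, beta = cfg$surv_beta,
                            censor_rate = cfg$censor_rate,
                            seed = cfg$seed + 2L)
  set.seed(cfg$seed + 3L)
  z <- qnorm((rank(true_sig) - 0.5) / nB)
  rho_p <- 2 * sin(pi * cfg$tmb_corr / 6)          # Spearman -> Pearson copula
  z2 <- rho_p * z + sqrt(1 - rho_p^2) * rnorm(nB)
  tmb <- qgamma(pnorm(z2), shape = 2, rate = 0.2)
  response <- ifelse(rbinom(nB, 1, plogis(-1.0 * true_sig)) == 1,
                     "responder", "non_responder")
  n_stage <- ifelse(is_lnm, sample(c("N1", "N2", "N3"), nB, TRUE,
                                   prob = c(0.5, 0.35, 0.15)), "N0")
  stage <- ifelse(is_lnm, sample(c("II", "III"), nB, TRUE),
                  sample(c("I", "II"), nB, TRUE, prob = c(0.7, 0.3)))
  n_drugs <- 30L
  slope <- seq(-1, 1, length.out = n_drugs)
  ic50 <- vapply(seq_len(n_drugs), function(j) {
    slope[j] * true_sig + rnorm(nB)
  }, numeric(nB))
  colnames(ic50) <- sprintf("ic50_drug%02d", seq_len(n_drugs))

  clinical <- data.frame(sample_id = bulk_ids,
                         n_stage = n_stage, m_stage = "M0", stage = stage,
                         os_time = surv$os_time, os_event = surv$os_event,
                         tmb = tmb, response = response,
                         stringsAsFactors = FALSE)
  clinical <- cbind(clinical, as.data.frame(ic50))
  clinical$group <- derive_groups(clinical$n_stage, clinical$m_stage)

  truth <- list(up_genes = up_genes, down_genes = down_genes,
                regulon = regulon(tf_gene, target_genes,
                                  rep(1, length(target_genes))),
                planted_subpop = .PLANTED_SUBPOP,
                markers = markers,
                type_profiles = profiles,
                true_fractions = true_f,
                true_signature = true_sig,
                is_lnm = is_lnm)
  .assert(all(abs(rowSums(true_f) - 1) < 1e-9), "fractions must be simplex")

  list(sc = list(matrix = sc_mat, cells = cells),
       bulk = list(matrix = bulk_mat, clinical = clinical),
       truth = truth, config = cfg)
}

#' Generate exponential survival tied to a score
#'
#' Event times are exponential with rate \code{r0 * exp(beta * z)} where
#' \code{z} is the standardized score; censoring is independent uniform
#' on (0, c_max) with c_max solved so the expected censored proportion
#' matches \code{censor_rate}.
#'
#' @param scores per-sample real scores.
#' @param beta log-hazard coefficient per standard deviation of score.
#' @param censor_rate target censoring proportion in [0, 1).
#' @param seed RNG seed.
#' @param r0 baseline hazard (per day; default log(2)/730, two-year
#'   median survival at score zero).
#' @return data.frame with \code{os_time} and \code{os_event} columns.
#' @export
generate_survival <- function(scores, beta, censor_rate, seed = 1L,
                              r0 = log(2) / 730) {
  .assert(all(is.finite(scores)), "scores must be finite")
  .assert(censor_rate >= 0 && censor_rate < 1,
          "censor_rate must lie in [0,1)")
  set.seed(seed)
  z <- if (sd(scores) > 0) as.numeric(scale(scores)) else rep(0, length(scores))
  tt <- rexp(length(z), rate = r0 * exp(beta * z))
  if (censor_rate == 0) {
    return(data.frame(os_time = tt, os_event = 1L))
  }
  ## expected censored share for uniform(0, cmax): mean(min(T/cmax, 1))
  f <- function(cmax) mean(pmin(tt / cmax, 1)) - censor_rate
  cmax <- uniroot(f, lower = min(tt) * 1e-6, upper = max(tt) / censor_rate * 10,
                  tol = 1e-8)$root
  cens <- runif(length(tt), 0, cmax)
  data.frame(os_time = pmin(tt, cens), os_event = as.integer(tt <= cens))
}

#' Generate a 2-D embedding from subpopulation labels
#'
#' Places each subpopulation on an isotropic Gaussian cluster (unit sd)
#' around centers spaced on a circle far enough apart that
#' nearest-center assignment recovers the labels.
#'
#' @param cell_table data.frame with a \code{subpop} column.
#' @param seed RNG seed.
#' @param radius circle radius for cluster centers.
#' @return the cell table with \code{emb_x}, \code{emb_y} columns added.
#' @export
generate_embedding <- function(cell_table, seed = 1L, radius = 20) {
  .assert("subpop" %in% colnames(cell_table),
          "cell table needs a subpop column")
  n <- nrow(cell_table)
  if (n == 0L) {
    cell_table$emb_x <- numeric(0)
    cell_table$emb_y <- numeric(0)
    return(cell_table)
  }
  set.seed(seed)
  pops <- sort(unique(cell_table$subpop))
  theta <- 2 * pi * (seq_along(pops) - 1) / length(pops)
  cx <- setNames(radius * cos(theta), pops)
  cy <- setNames(radius * sin(theta), pops)
  cell_table$emb_x <- cx[cell_table$subpop] + rnorm(n)
  cell_table$emb_y <- cy[cell_table$subpop] + rnorm(n)
  rownames(cell_table) <- NULL
  cell_table
}

#' Write a generated dataset bundle to disk
#'
#' Emits the on-disk forms the pipeline readers consume: sparse MTX plus
#' gene/cell sidecars and a cell metadata TSV for the single-cell data,
#' a bulk expression TSV, a clinical TSV, GMT files with the planted
#' program, a regulon TSV, and a truth JSON.
#'
#' @param ds output of \code{generate_paired_dataset}.
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
write_dataset_bundle <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_expression_mtx(ds$sc$matrix, p("matrix.mtx"), p("genes.tsv"),
                       p("barcodes.tsv"))
  write.table(ds$sc$cells, p("cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_bulk_tsv(ds$bulk$matrix, p("bulk_expr.tsv"))
  clin <- ds$bulk$clinical
  clin$group <- NULL                      # derived column, not stored
  write.table(clin, p("clinical.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_gmt(list(LNM_UP = ds$truth$up_genes, LNM_DOWN = ds$truth$down_genes),
            p("lnm_true_sets.gmt"))
  write_regulon_tsv(ds$truth$regulon, p("true_regulon.tsv"))
  truth_json <- list(up_genes = ds$truth$up_genes,
                     down_genes = ds$truth$down_genes,
                     tf = ds$truth$regulon$tf,
                     targets = ds$truth$regulon$targets,
                     planted_subpop = ds$truth$planted_subpop,
                     true_signature = ds$truth$true_signature)
  jsonlite::write_json(truth_json, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
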