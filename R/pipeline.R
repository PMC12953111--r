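## End-to-end orchestration: simulate -> bulk DE -> phenotype projection
## -> composition -> markers -> regulon -> deconvolution -> clinical
## signature, writing a run directory with per-stage outputs and a
## content-hashed summary.

#' Pipeline configuration
#'
#' Bundles the generator configuration with the downstream parameters,
#' each defaulting to the module's own default.
#'
#' @param sim a \code{sim_config} for the synthetic stage.
#' @param top_k directional DE gene-set size.
#' @param quantile top fraction for phenotype labeling.
#' @param r_max U-score rank cutoff.
#' @param threshold_frac top-rank fraction for regulon activity.
#' @param top_targets regulon targets kept for the signature.
#' @param per_class_regulons regulons retained per class by specificity.
#' @param alpha single-sample enrichment weighting exponent.
#' @param n_tf_candidates marker genes per myeloid subpopulation used as
#'   candidate regulator hubs when no TF is supplied.
#' @param tf optional TF gene id(s); when NULL the stage builds a
#'   regulon for the top markers of every myeloid subpopulation and
#'   selects the one most specific to the metastasis-enriched
#'   subpopulation.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(sim = sim_config(), top_k = 100L,
                            quantile = 0.10, r_max = 1500L,
                            threshold_frac = 0.05, top_targets = 50L,
                            per_class_regulons = 10L, alpha = 0.25,
                            n_tf_candidates = 3L, tf = NULL) {
  structure(list(sim = sim, top_k = top_k, quantile = quantile,
                 r_max = r_max, threshold_frac = threshold_frac,
                 top_targets = top_targets,
                 per_class_regulons = per_class_regulons, alpha = alpha,
                 n_tf_candidates = n_tf_candidates, tf = tf),
            class = "pipeline_config")
}

.hash_files <- function(paths) {
  h <- tools::md5sum(paths)
  as.list(setNames(unname(h), basename(paths)))
}

#' Run the full analysis pipeline
#'
#' Executes the eight stages in dependency order on a synthetic dataset
#' generated from the configuration, writes every stage's outputs into
#' \code{out_dir} (write-once) and a \code{summary.json} with content
#' hashes of all outputs. Reruns with the same configuration produce
#' identical hashes.
#'
#' @param config a \code{pipeline_config}.
#' @param out_dir run directory (created; pre-existing stage outputs are
#'   an error).
#' @return an \code{lnm_pipeline} object (invisible components: the
#'   dataset, per-stage results and the summary list).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(stages = list())
  done <- function(name, paths, info = NULL) {
    summary$stages[[name]] <<- c(list(outputs = .hash_files(paths)), info)
  }

  ## 1. simulate -------------------------------------------------------
  ds <- generate_paired_dataset(config$sim)
  data_dir <- file.path(out_dir, "data")
  write_dataset_bundle(ds, data_dir)
  done("simulate", list.files(data_dir, full.names = TRUE),
       list(seed = config$sim$seed))

  ## 2. bulk differential expression -----------------------------------
  de <- moderated_t_test(ds$bulk$matrix, ds$bulk$clinical$group)
  sets <- build_direction_genesets(de, config$top_k)
  de_path <- file.path(out_dir, "de.tsv")
  write.table(de, de_path, sep = "\t", quote = FALSE, row.names = FALSE)
  gmt_path <- file.path(out_dir, "lnm_sets.gmt")
  write_gmt(list(LNM_UP = sets$up, LNM_DOWN = sets$down), gmt_path)
  done("de", c(de_path, gmt_path),
       list(n_up = length(sets$up), n_down = length(sets$down)))

  ## 3. phenotype projection -------------------------------------------
  up_sc <- uscore(ds$sc$matrix, sets$up, r_max = config$r_max)
  dn_sc <- uscore(ds$sc$matrix, sets$down, r_max = config$r_max)
  labels <- label_cells(up_sc, dn_sc, q = config$quantile,
                        cell_ids = ds$sc$cells$cell_id)
  lab_path <- file.path(out_dir, "labels.tsv")
  write.table(labels, lab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  done("project", lab_path,
       list(n_lnm = sum(labels$label == "LNM"),
            n_nonlnm = sum(labels$label == "non-LNM"),
            conflicts = attr(labels, "conflicts")))

  ## 4. composition ----------------------------------------------------
  cells <- ds$sc$cells
  shift_major <- celltype_shift(labels, cells$major_type)
  shift_sub <- celltype_shift(labels, cells$subpop)
  myelo <- cells$major_type == "Myeloid"
  sub_lab <- labels[myelo, ]
  per_sample <- per_sample_subpop_test(sub_lab, cells$subpop[myelo],
                                       cells$sample[myelo])
  dist_res <- embedding_distance(cells[, c("emb_x", "emb_y")], labels,
                                 cells$major_type,
                                 seed = config$sim$seed + 4L)
  comp_paths <- file.path(out_dir, c("shift_major.tsv", "shift_subpop.tsv",
                                     "per_sample_subpop.tsv", "dist.tsv"))
  write.table(shift_major, comp_paths[1], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(shift_sub, comp_paths[2], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(per_sample, comp_paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dist_res, comp_paths[4], sep = "\t", quote = FALSE,
              row.names = FALSE)
  myelo_sub <- shift_sub[shift_sub$type %in% unique(cells$subpop[myelo]), ]
  enriched <- myelo_sub$type[which.max(myelo_sub$odds_ratio)]
  done("composition", comp_paths, list(enriched_subpop = enriched))

  ## 5. markers --------------------------------------------------------
  mk_sub <- marker_scores(.subset_cells(ds$sc$matrix, myelo),
                          cells$subpop[myelo], top_n = 50L)
  mk_all <- marker_scores(ds$sc$matrix, cells$subpop, top_n = 50L)
  mk_path <- file.path(out_dir, "markers.tsv")
  mk_tab <- do.call(rbind, lapply(names(mk_sub$top), function(k) {
    data.frame(cluster = k, gene = mk_sub$top[[k]],
               score = mk_sub$scores[mk_sub$top[[k]], k],
               stringsAsFactors = FALSE)
  }))
  write.table(mk_tab, mk_path, sep = "\t", quote = FALSE, row.names = FALSE)
  done("markers", mk_path, list(clusters = names(mk_sub$top)))

  ## 6. regulon --------------------------------------------------------
  ## candidate regulator pool: the top markers of every myeloid
  ## subpopulation, so specificity ranking works over a shared pool
  cand_tfs <- config$tf
  if (is.null(cand_tfs))
    cand_tfs <- unique(unlist(lapply(mk_sub$top, head,
                                     config$n_tf_candidates)))
  regulons <- lapply(cand_tfs, function(tf) rank_targets(ds$sc$matrix, tf))
  names(regulons) <- cand_tfs
  acts <- vapply(regulons, function(r) {
    aucell(ds$sc$matrix, regulon(r$tf, head(r$targets, config$top_targets),
                                 head(r$importance, config$top_targets)),
           config$threshold_frac)
  }, numeric(length(ds$sc$cells$cell_id)))
  rss <- t(vapply(cand_tfs, function(tf) {
    regulon_specificity(acts[, tf], cells$subpop)
  }, numeric(length(unique(cells$subpop)))))
  rownames(rss) <- cand_tfs
  top_reg <- select_top_regulons(rss, config$per_class_regulons)
  ## among the retained most-specific regulons, the governing regulon is
  ## the one whose activity is highest in the enriched subpopulation's
  ## cells (sparse low-activity regulons can reach high specificity by
  ## chance; the activity contrast disambiguates them)
  shortlist <- top_reg[[enriched]]
  in_sub <- cells$subpop == enriched
  mean_act <- vapply(shortlist, function(tf) mean(acts[in_sub, tf]),
                     numeric(1))
  chosen_tf <- shortlist[order(-mean_act, shortlist)][1]
  targets <- top_targets(regulons[[chosen_tf]], config$top_targets)
  reg_paths <- file.path(out_dir, c("activity.tsv", "rss.tsv",
                                    "targets.gmt"))
  write.table(data.frame(cell_id = cells$cell_id, acts,
                         check.names = FALSE),
              reg_paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(regulon = rownames(rss), rss,
                         check.names = FALSE),
              reg_paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(setNames(list(targets), paste0(chosen_tf, "_targets")),
            reg_paths[3])
  done("regulon", reg_paths, list(chosen_tf = chosen_tf))

  ## 7. deconvolution --------------------------------------------------
  marker_union <- unique(unlist(mk_all$top))
  ref <- build_reference(ds$sc$matrix, cells$subpop, marker_union)
  fr <- estimate_fractions(ds$bulk$matrix, ref)
  inf_nodal <- compare_infiltration(fr$fractions, ds$bulk$clinical, "nodal")
  inf_stage <- compare_infiltration(fr$fractions, ds$bulk$clinical, "stage")
  dec_paths <- file.path(out_dir, c("fractions.tsv",
                                    "infiltration_tests.tsv"))
  write.table(data.frame(sample_id = rownames(fr$fractions), fr$fractions,
                         check.names = FALSE),
              dec_paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  inf <- rbind(cbind(contrast = "nodal", inf_nodal),
               cbind(contrast = "stage", inf_stage))
  write.table(inf, dec_paths[2], sep = "\t", quote = FALSE,
              row.names = FALSE)
  done("deconv", dec_paths, list(types = colnames(fr$fractions)))

  ## 8. clinical signature ---------------------------------------------
  clin <- ds$bulk$clinical
  score <- ssgsea_score(ds$bulk$matrix, targets, alpha = config$alpha)
  grp <- ifelse(score > median(score), "high", "low")
  lr <- logrank(clin$os_time, clin$os_event, grp)
  cox <- cox_hr(clin$os_time, clin$os_event, as.numeric(scale(score)))
  oc <- optimal_cutpoint(score, clin$os_time, clin$os_event)
  tmb_p <- suppressWarnings(
    wilcox.test(clin$tmb[grp == "high"], clin$tmb[grp == "low"],
                alternative = "less")$p.value)
  combo <- combo_stratify(score, clin$tmb, clin$os_time, clin$os_event)
  roc <- response_roc(score, clin$response)
  drugs <- drug_correlation(score, clin[, grep("^ic50_", colnames(clin)),
                                        drop = FALSE])
  sig_paths <- file.path(out_dir, c("scores.tsv", "survival.json",
                                    "roc.tsv", "drugs.tsv"))
  write.table(data.frame(sample_id = names(score), score = score,
                         group = grp),
              sig_paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(median_split_logrank = lr, cox = cox[c("log_hr", "se", "p", "hr")],
         optimal_cut = oc[c("cutpoint", "chisq", "p_at_cut")],
         tmb_high_lower_p = tmb_p,
         combo_logrank = combo[c("chisq", "df", "p")],
         response_auc = roc$auc),
    sig_paths[2], auto_unbox = TRUE, digits = NA)
  write.table(roc$roc, sig_paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(drugs$table, sig_paths[4], sep = "\t", quote = FALSE,
              row.names = FALSE)
  done("signature", sig_paths,
       list(cox_p = cox$p, logrank_p = lr$p, auc = roc$auc))

  ## summary -----------------------------------------------------------
  sum_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, digits = NA)
  res <- structure(list(dataset = ds, de = de, sets = sets,
                        labels = labels, shift_major = shift_major,
                        shift_subpop = shift_sub,
                        per_sample = per_sample, distances = dist_res,
                        markers = mk_sub, rss = rss,
                        enriched_subpop = enriched, chosen_tf = chosen_tf,
                        regulons = regulons, targets = targets,
                        fractions = fr, infiltration = inf,
                        score = score, logrank = lr, cox = cox,
                        optimal_cut = oc, tmb_p = tmb_p, combo = combo,
                        roc = roc, drugs = drugs, summary = summary,
                        out_dir = out_dir),
                   class = "lnm_pipeline")
  invisible(res)
}

## column subset of an expression matrix
.subset_cells <- function(em, keep) {
  expression_matrix(em$values[, keep, drop = FALSE], em$gene_ids,
                    em$column_ids[keep], em$scale_tag)
}

#' @exportS3Method base::print
print.lnm_pipeline <- function(x, ...) {
  cat("<lnm_pipeline> run directory:", x$out_dir, "\n")
  cat(sprintf("  stages completed: %d\n", length(x$summary$stages)))
  cat(sprintf("  enriched subpopulation: %s; regulator: %s\n",
              x$enriched_subpop, x$chosen_tf))
  cat(sprintf("  signature: Cox log-HR %.3f (p = %.2g), median-split log-rank p = %.2g, response AUC %.3f\n",
              x$cox$log_hr, x$cox$p, x$logrank$p, x$roc$auc))
  invisible(x)
}
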