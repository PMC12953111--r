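# lnmsig

Linking lymph-node metastasis in a bulk transcriptomic cohort to cell
states in single-cell RNA-seq data, and deriving a regulon-based
clinical signature.

## The problem

In cohorts like TCGA lung adenocarcinoma, pathological N stage is known
per patient, but only at the bulk level. `lnmsig` implements the full
analytic chain that projects that phenotype down to single cells and
back up to the clinic:

1. **Bulk DE** between nodal-metastatic (N1–N3/M0) and non-metastatic
   (N0/M0) samples using an empirical-Bayes **moderated t**
   ($\tilde t_g = \hat\beta_g / \sqrt{s^2_{post,g}(1/n_1+1/n_2)}$ with
   $s^2_{post} = (d_0 s_0^2 + d s_g^2)/(d_0+d)$), yielding the top-100
   up/down gene sets.
2. **Phenotype projection**: a per-cell rank-based **U-score**
   ($1 - U'/(n\,r_{max})$, ranks truncated at $r_{max}=1500$) for each
   set; cells in the top decile become LNM / non-LNM, the rest NS.
3. **Composition**: Fisher tests of cell-type shifts, paired per-sample
   Wilcoxon tests of myeloid subpopulation shares (Holm-adjusted), and
   energy distances between label groups on the embedding.
4. **Markers and regulons**: penalized-cosine marker scores; regulons
   as |Spearman|-ranked target modules around candidate hubs; per-cell
   activity as the normalized **area under the target-recovery curve**
   (top 5% of each cell's ranking); per-class **regulon specificity**
   $1-\sqrt{\mathrm{JSD}(p, q)}$. The most specific regulon for the
   metastasis-enriched subpopulation contributes its top-50 targets.
5. **Deconvolution**: marker-restricted NNLS with simplex
   normalization gives per-sample infiltration scores, compared across
   nodal status and stage.
6. **Clinical readouts**: a single-sample enrichment (running-sum)
   score of the target set drives Kaplan–Meier / log-rank / Cox
   survival analysis, a maximally selected cutpoint, TMB contrasts,
   a response ROC (low score predicts response) and drug-IC50
   Spearman rankings.

A synthetic-data generator with a planted transcriptional program,
planted regulon and score-linked outcomes (survival, TMB, response,
drug sensitivity) makes every stage testable by parameter recovery; see
`vignettes/methods.Rmd` for the model and its limits.

## Worked example

```r
library(lnmsig)
res <- run_pipeline(pipeline_config(sim = sim_config(seed = 1)), "runs/demo")
print(res)
#> <lnm_pipeline> run directory: runs/demo
#>   stages completed: 8
#>   enriched subpopulation: Neu_ELANE; regulator: G0763
#>   signature: Cox log-HR 0.790 (p = 3.6e-09), median-split log-rank p = 4.7e-07, response AUC 0.733

print(res$labels)
#> <cell_label_table> 2400 cells: 235 LNM, 235 non-LNM, 1930 NS (5 conflicts)

head(res$shift_subpop[order(-res$shift_subpop$odds_ratio),
                      c("type", "n_LNM", "n_nonLNM", "odds_ratio", "p_adj")], 3)
#>        type n_LNM n_nonLNM   odds_ratio        p_adj
#> 7 Neu_ELANE   162        0 1041.3265306 1.524321e-67
#> 8    NKcell     7       12    0.5705409 3.492545e-01
#> 5   Mac_C1Q    10       17    0.5699346 2.630497e-01
```

Reading the output: the neutrophil-like subpopulation carrying the
planted metastasis program dominates the LNM-labeled compartment (odds
ratio 1041 vs the other myeloid subpopulations' ≤1), the signature
derived from the recovered regulon's targets carries the planted
prognostic signal (hazard ratio `exp(0.790) ≈ 2.2` per SD of score),
and a low signature score predicts treatment response (AUC 0.733). The
run directory contains every stage's TSV/GMT/JSON outputs and a
`summary.json` with content hashes; reruns under the same seed are
hash-identical.

Individual stages are plain functions operating on ordinary containers
(`expression_matrix`, data.frames, named lists): `moderated_t_test()`,
`uscore()`, `label_cells()`, `celltype_shift()`, `marker_scores()`,
`rank_targets()`, `aucell()`, `regulon_specificity()`,
`build_reference()`, `estimate_fractions()`, `ssgsea_score()`,
`cox_hr()`, `optimal_cutpoint()`, `response_roc()`,
`drug_correlation()`, plus readers/writers for MTX, GMT, regulon and
clinical TSVs.

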