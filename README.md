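# igem

Geneset-embedded joint non-negative matrix factorization for integrating
gene expression and DNA methylation, with the full surrounding analysis
pipeline: differential feature selection, recursive geneset merging,
gene–CpG interaction-graph construction, topic–phenotype association
statistics, genotype quality control and cis-QTL scans, and a synthetic
multi-omic cohort generator with planted ground truth.

The package is aimed at researchers integrating two omic views measured on
the same subjects — the motivating setting is antidepressant treatment
response in depression cohorts (expression + methylation + genotypes +
MADRS questionnaires) — who want latent "meta-phenotypes" that are directly
interpretable in terms of known genesets.

## The model

Given non-negative matrices `X1` (subjects × genes) and `X2` (subjects ×
CpGs), a fixed row-normalized geneset design `ρ` (genesets × genes) and a
sparse non-negative gene–CpG interaction graph `B`, the model factorizes
both views over a shared subject loading matrix `W` (subjects × K topics):

    X1 ≈ W H1,   H1 = α ρ        (gene basis constrained through genesets)
    X2 ≈ W H2                    (free methylation basis)

by minimizing

    L = ‖X1 − Wαρ‖²_F + ‖X2 − W H2‖²_F
        + λ_net Σ_{g,c} B[g,c] Σ_k (H1[k,g] − H2[k,c])²
        + λ_W ΣW + λ_α Σα + λ_H ΣH2,        all factors ≥ 0

with multiplicative updates (order `W → α → H2`, `H1 = αρ` recomputed after
the `α` step, an ε guard on denominators). The graph term pulls the basis
scores of correlated proximal gene–CpG pairs together; the L1 terms
encourage sparse loadings. With all penalties zero and `ρ = I` one update
step reduces exactly to the standard two-view Lee–Seung rules. `α` (topics ×
genesets) is what makes topics interpretable: each topic is a non-negative
combination of genesets, and `H1 = αρ` never leaves their span.

Downstream, subject topic scores `W` are associated with responder status
(Spearman, BH over the K topics), with per-item MADRS change ratios
`(week0 − week8)/week0` (Pearson, BH over all pairs), and with genotypes
(OLS with age and sex, additive and major-allele-presence codings); cis-QTL
scans test SNPs within 500 kb with BH control per feature at FDR 0.1.

## Worked example

```r
library(igem)
cohort <- generate_cohort(sim_config(n_subjects = 90, n_topics = 4,
                                     n_genes = 90, n_cpgs = 120,
                                     n_snps = 200, n_genesets = 12,
                                     diff_frac = 0.3), seed = 7)
merged <- merge_genesets(cohort$genesets)
de  <- differential_expression(log(cohort$expression),
                               cohort$truth$labels, merged$genesets)
dm  <- differential_methylation(cohort$methylation, cohort$truth$labels,
                                de$feature_id[de$pass], cohort$layout)
rho <- build_rho(merged$genesets, de$feature_id[de$pass])
graph  <- build_interaction_graph(log(cohort$expression)[de$pass, ],
                                  cohort$methylation[dm$pass, ],
                                  cohort$layout)
inputs <- normalize_inputs(log(cohort$expression)[de$pass, ],
                           cohort$methylation[dm$pass, ],
                           cohort$truth$covariates)
fit <- igem(inputs$X1, inputs$X2, rho$rho[, colnames(inputs$X1)],
            as.matrix(graph$B)[colnames(inputs$X1), colnames(inputs$X2)],
            K = 4, lambda_net = 0.5, lambda_W = 0.1, lambda_alpha = 0.1,
            lambda_H = 0.1, n_restarts = 2, seed = 1)
fit
#> Geneset-embedded joint NMF fit
#>   90 subjects, 34 genes, 54 CpGs, 12 genesets, K = 4 topics
#>   objective 867.078 after 353 iterations (converged; best of 2 restarts)

topic_response_association(fit$W, cohort$truth$labels)
#>    topic     rho  p_value p_adjusted significant
#> 1 topic1 -0.6515 3.55e-12   4.73e-12        TRUE
#> 2 topic2 -0.7561 6.94e-18   1.39e-17        TRUE
#> 3 topic3  0.8642 5.57e-28   2.23e-27        TRUE
#> 4 topic4 -0.0669 5.31e-01   5.31e-01       FALSE

head(top_features(fit$H1, n = 3), 6)
#>    topic rank feature_id score relative_score
#> 1 topic1    1   gene0086 0.656          1.000
#> 2 topic1    2   gene0090 0.616          0.938
#> 3 topic1    3   gene0050 0.614          0.935
#> 4 topic2    1   gene0003 0.760          1.000
#> 5 topic2    2   gene0057 0.760          1.000
#> 6 topic2    3   gene0055 0.552          0.726
```

The Spearman table says topics 1–3 separate responders from non-responders
(the generator planted label effects across 30 % of features, so several
recovered topics absorb them); the relative scores in the top-feature table
are each topic's factor scores as a proportion of its top feature, the
layout used for reporting topic content.

The same flow runs from a shell via the staged pipeline:

```sh
Rscript inst/cli/igem.R all --config inst/extdata/config-small.yaml --out /tmp/run
```

which writes every intermediate product (selected features, `rho.tsv`, edge
list, `W/alpha/H1/H2`, association tables, QC and QTL tables, a newick
patient tree) plus a `manifest.json` of output checksums.

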