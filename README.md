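# lncRisk

Risk lncRNA prioritization and prognostic signature discovery from
miRNA-mediated ceRNA networks, for analysts working with paired
tumor/normal RNA-seq cohorts and survival follow-up.

Long non-coding RNAs can act as competing endogenous RNAs (ceRNAs):
lncRNAs and protein-coding genes (PCGs) that share many targeting miRNAs
compete for them and become co-regulated. `lncRisk` implements the full
analysis built on that idea:

1. **Differential expression** — low-FPKM filtering and a paired
   empirical-Bayes moderated t-test on `log2(x + 1)` tumor−normal
   differences (variance prior fitted by moment matching on log variances;
   selection at `p < 0.05` and `|log2FC| > 1`).
2. **Dysregulated ceRNA network** — the intersection of (a) lncRNA–PCG
   pairs sharing significantly many miRNAs under the upper-tail
   hypergeometric test `P(X ≥ r) = Σ_{i≥r} C(t,i)C(m−t,n−i)/C(m,n)`
   (`p < 0.01`) and (b) positively co-expressed DE pairs
   (Pearson `pcc > 0.5`, `p < 0.01`).
3. **Risk lncRNAs** — random walk with restart
   `p_{t+1} = (1−r)·W·p_t + r·p_0` from known disease PCG seeds on the
   column-normalized network (convergence `1e-10`), with an empirical
   p-value per lncRNA from resampled pseudo-seed sets
   (`p = m/n_perm`, risk call at `p < 0.05`) and a Wilcoxon rank-sum
   comparison of risk vs non-risk scores.
4. **Topology & function** — degree/betweenness/closeness with hub
   reporting, log-log OLS fit of the degree distribution,
   over-representation analysis on user-supplied GMT sets, neighborhood
   and Jaccard summaries, and tumor/normal separability of the risk
   lncRNAs by bidirectional hierarchical clustering (adjusted Rand index).
5. **Prognostic signature** — per-lncRNA maximally selected log-rank
   cutpoint screen, then an exhaustive search over **all** `2^k − 1`
   subsets of the screened candidates: joint Cox fit (Efron ties), risk
   score `Σ x_i e_i`, median split, log-rank; the minimum-p subset wins.
   Evaluation by Kaplan–Meier medians, IPCW time-dependent AUC at
   1/3/5/10 years, and univariate/multivariable Cox independence analysis
   against age and stage.

A configurable synthetic-data generator (`simulate_all()`) emits every
pipeline input — expression, interaction tables, disease seeds, survival —
with planted ground truth, so the whole analysis is testable end to end
without any download. See the methods vignette
(`vignettes/methods.Rmd`) for the model, parameter defaults and design
rationale.

## Worked example

```r
library(lncRisk)

cfg <- simulation_config(n_patients = 100, n_lncRNA = 200, n_PCG = 600,
                         n_miRNA = 400, n_de_lnc = 60, n_de_pcg = 200,
                         n_true_cerna = 40, n_cerna_modules = 12,
                         targets_per_gene = 20, overlap_boost = 10,
                         n_seed_genes = 50,
                         signature_coefs = c(-0.8, -0.7, -0.6, -0.5),
                         censor_rate = 0.6, rng_seed = 1)
sim <- simulate_all(cfg)

es   <- filter_low_expression(sim$es)
de   <- paired_moderated_t(es)
sel  <- select_de(de)
cand <- build_cerna_candidates(sim$mirna_pcg, sim$mirna_lnc, p_cut = 0.01,
                               lnc_ids = sel$lncRNA, pcg_ids = sel$PCG)
coex <- coexpression_pairs(es, sel$lncRNA, sel$PCG)
net  <- intersect_networks(cand, coex, node_attrs = de)
net
#> cerna_network: 32 lncRNAs, 34 PCGs, 163 edges

rw <- permutation_significance(net, sim$seeds, restart = 0.7,
                               n_perm = 2000, rng_seed = 2)
rw
#> rwr_result: 32 lncRNAs scored from 7 seeds (r = 0.7, 2000 permutations);
#>   6 risk lncRNAs at p < 0.05
head(rw$table, 5)
#>      node      score empirical_p risk
#> 1 lnc0021 0.03296703           0 TRUE
#> 2 lnc0068 0.03296703           0 TRUE
#> 3 lnc0103 0.03296703           0 TRUE
#> 4 lnc0188 0.03296703           0 TRUE
#> 5 lnc0070 0.01648352           0 TRUE
compare_score_distributions(rw)$p
#> [1] 4.600747e-05

risk <- rw$table$node[rw$table$risk]
scr  <- screen_survival_lncRNAs(risk, sim$es, sim$survival)
res  <- exhaustive_signature_search(scr$lncRNA[scr$selected],
                                    sim$es, sim$survival)
res$best
#> signature_model: 3 lncRNAs (lnc0021, lnc0103, lnc0188),
#>   log-rank p = 1.66e-11
#>   groups: 50 high / 50 low at median cutoff -4.304;
#>   median survival 1.331 vs NA
time_dependent_auc(res$best$scores, sim$survival, horizons = c(1, 3, 5))
#>   horizon       auc n_cases n_controls
#> 1       1 0.8416406      20         69
#> 2       3 0.9063890      34         39
#> 3       5 0.9438110      39         22
```

Reading the output: the walk flags 6 of 32 network lncRNAs as risk
lncRNAs — the four top scorers are exactly the planted signature
(`sim$truth$signature` names `lnc0021`, `lnc0068`, `lnc0103`, `lnc0188`) —
and their scores separate cleanly from the non-risk lncRNAs (Wilcoxon
p ≈ 5e-5). The subset search settles on a three-lncRNA signature whose
median-split groups differ strongly in survival (log-rank p ≈ 2e-11; the
low-risk median is never reached within follow-up, printed as `NA`), with
time-dependent AUCs of 0.84–0.94 — high because the planted hazards are
strong relative to a real cohort.

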