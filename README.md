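# degbias

Degradation-aware differential expression for 3′-biased RNA-seq.

## The problem

Poly(A)-primed RNA-seq libraries made from degraded RNA lose read
coverage far from the 3′ end, while coverage within ~500 bp of the 3′
terminus stays largely intact. When compared samples differ in RNA
integrity (RIN), the lost fraction grows with transcript length, so
short transcripts look spuriously overexpressed in the degraded group —
a confound that library-size or global TMM normalization cannot remove.
`degbias` is for analysts whose groups differ in integrity (aged tissue,
frozen batches, archival material) and who still need calibrated
differential expression.

## The method

1. **3′-truncated gene models** — each gene is reduced to its most
   abundant (dominant) isoform, truncated to the 500 bp of spliced
   sequence nearest the 3′ end (strand-aware), and reads are counted in
   that window.
2. **Binned TMM** — after a CPM > 2 in ≥ 3 samples pre-filter, genes are
   split into 10 transcript-length bins; within each bin, TMM factors
   are computed (reference = sample whose 75th-percentile CPM is closest
   to the mean; M-values `M_g = log2[(y_gk/N_k)/(y_gr/N_r)]` doubly
   trimmed 30 %/5 % with precision weights
   `w_g = 1/[(N_k−y_gk)/(N_k y_gk) + (N_r−y_gr)/(N_r y_gr)]`); bins are
   merged into pseudo-counts `ŷ_gs = y_gs · Ñ/(N_s f_{s,b(g)})` on the
   common effective library `Ñ` (geometric mean of library sizes). An
   optional second pass re-bins by average CPM.
3. **NB exact test** — common dispersion φ (variance `μ + φμ²`) by
   conditional maximum likelihood, then the conditional exact test on
   the rounded pseudo-counts' group sums, with Benjamini–Hochberg FDR.
4. **Downstream** — 2-fold / 4-fold + p < 0.05 DE thresholds, Venn
   intersections across contrasts, Fisher (hypergeometric upper-tail)
   over-representation on top-50/100/200/500/1000 up/down lists with
   minimum-p merging against the pre-filtered background, and qPCR
   validation by 2^−ΔΔCt with two reference genes.

A synthetic-data module generates the whole causal chain — gene models
with one dominant isoform, exponential 3′ coverage decay
(`density ∝ exp(−d/λ)`, `λ` = per-sample decay scale standing in for
RIN), NB counts, spiked DE — with known ground truth, so every stage is
tested without external data.

## Worked example

A null experiment (no true DE) in which the second group is strongly
degraded (decay scale 800 bp vs 4000 bp):

```r
library(degbias)
cfg <- pipeline_config(
  sim = simulation_config(
    n_genes = 2000,
    design = two_group_design(3, decay_group1 = 4000, decay_group2 = 800),
    de_fraction = 0, seed = 1
  )
)
compare_modes(cfg)
#>                 branch n_null_genes logfc_length_rho fpr_p05 bin_median_logfc_range
#> 1  full_length_libsize         2000       -0.9131066  0.6140              1.4711858
#> 2 truncated_binned_tmm         2000       -0.0246107  0.0580              0.0906051
```

Reading the numbers: with full-length counting and library-size-only
normalization, log2 fold change is almost a deterministic function of
transcript length (Spearman ρ = −0.91 on genes with no true effect) and
61 % of null genes are "significant" at p < 0.05. Counting in the 500 bp
3′ window and normalizing with length-binned TMM brings the correlation
to −0.02 and the false-positive rate to 5.8 % — the confound is gone.

`run_pipeline(cfg, "outdir")` runs the same machinery end to end
(simulate → GTF → truncate → count → normalize → test → enrich) and
writes TSV outputs plus a `manifest.json` with parameters, seed and MD5
checksums; identical configuration and seed reproduce the manifest
exactly.

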