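# oncofunnel

Tumours that gain copies of a gene often over-express it, and genes whose
copy-number gain (CNG) and over-expression recur together across many tumour
samples are strong candidates for prognostic biomarkers. `oncofunnel`
implements the prioritization funnel that turns that observation into a gene
list, for researchers integrating literature annotations with pan-cancer
copy-number and expression data:

1. **Literature curation** — screen GeneRIF-style annotation records for the
   boolean keyword pattern
   `(prognosis OR prognostic) AND (cancer OR tumour OR carcinoma)`
   (case-insensitive, whole words) and tabulate distinct supporting PubMed
   IDs per gene.
2. **CNV profiling** — count, per gene, the tumour samples with GAIN and
   LOSS calls; classify a gene CNG when `n_gain / n_loss > 2` (CNL
   symmetrically); keep "frequent CNG" genes with `n_gain > 30`.
3. **Expression concordance** — compute per-sample Z-scores against a
   reference sample population,

   $$Z = \frac{x - \mu}{\sigma},$$

   where $\mu$ and $\sigma$ are the reference mean and standard deviation of
   the gene's expression; call a sample over-expressed when $Z > 2$; count
   the matched samples that are simultaneously gained and over-expressed and
   keep **key genes** with more than 20 such concordant samples.
4. **Downstream summaries** on the key genes: hypergeometric gene-set
   enrichment with Benjamini–Hochberg correction, OncoPrint-style per-cohort
   alteration frequencies with top-k amplified rankings and their
   cross-cohort intersection, Kaplan–Meier / log-rank comparison of altered
   versus unaltered samples, and seed-neighborhood summaries of an
   interaction network (linker genes ranked by seed connections, degree
   tables).

Because the public databases behind such analyses are version-dependent
snapshots, the package ships a deterministic **synthetic cohort generator**
(`synth_config()` / `generate_bundle()`) that emits every input the pipeline
consumes — literature TSV, CNV call matrix with cohort labels, expression
matrix with designated reference samples, clinical endpoints, GMT gene sets,
network edge list — with planted driver genes, a planted enriched set and a
planted hazard difference, plus the ground truth to validate recovery.

## Worked example

```r
library(oncofunnel)

bundle <- generate_bundle(synth_config(seed = 42))
fit <- run_pipeline(bundle)
fit
#> <prognosis_pipeline>
#>   curated 397 -> cnv_overlap 397 -> cng 27 -> cnl 10 -> frequent_cng 12 -> key_genes 12
```

The funnel starts from 397 literature-curated genes (80% of the 500-gene
universe carries prognosis literature by construction), classifies 27 genes
as CNG by the gain/loss ratio rule, keeps 12 with more than 30 gained
samples, and all 12 pass the concordance gate — exactly the 12 planted
drivers, no false positives:

```r
fit$key_genes[1:3, ]
#>   gene  n_gain n_gain_over n_loss n_loss_under passes_key_gene
#> 1 DRV02     60          59     15            0 TRUE
#> 2 DRV03     60          56     15            0 TRUE
#> 3 DRV04     60          53     11            1 TRUE
```

`n_gain_over` is the number of matched samples where the gene is both
gained and over-expressed (Z > 2): 59 of DRV02's 60 gained samples show the
dosage effect. The planted gene set tops the enrichment table
(`fit$enrichment`: overlap k = 10 of K = 30, adjusted p = 1.87e-10), and
samples altered in a key gene die markedly faster:

```r
glance(fit$survival)
#>   statistic    df  p.value
#> 1      98.0     1 4.11e-23
tidy(fit$survival)
#>   group         n events median
#> 1 ALTERED     462    455   14.9
#> 2 UNALTERED   138    121   50.4
```

(median overall survival in months; the generator plants a hazard ratio
of 3 for altered samples). Each result has `tidy()`/`glance()` methods and
plots: `autoplot()` on Kaplan–Meier curves, `plot_funnel()`,
`plot_enrichment()`, `plot_alteration_landscape()`.

Real data enter through the same surface: `run_pipeline("run.yaml")` with a
`files:` block pointing at the TSV/GMT inputs (see
`?run_pipeline`, and `inst/scripts/run_pipeline.R` for a shell entry
point).

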