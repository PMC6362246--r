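# larvaseq

Reference-free analysis of larval developmental transcriptomes: from a
redundant de novo contig pool to stage-wise differential expression, GO
enrichment and polymorphism summaries — with a ground-truth simulator so
every step is testable without the original sequencing libraries.

The package is aimed at groups assembling transcriptomes for non-model
marine invertebrates (the design mirrors a four-stage sea-cucumber larval
study: blastula → gastrula → auricularia → pentactula, one RNA-seq
library per stage, reads pooled from several wild populations), where
three problems dominate:

1. **Assembly redundancy.** Polymorphism between populations and variable
   UTRs fragment the assembly into many near-identical contigs.
   `larvaseq` extracts stop-codon-to-stop-codon coding regions (no `ATG`
   anchoring, so 5'-truncated contigs still yield CDSs, minimum 30
   residues) and reduces redundancy with a declining-identity schedule of
   greedy clustering plus end-overlap consensus merging
   (0.95/0.90 → 0.90/0.80 → 0.80/0.80, merge identity 99% then 80%),
   followed by isoform grouping at 0.95 identity over half the shorter
   sequence.
2. **Unreplicated differential expression.** With one library per stage,
   dispersion cannot be estimated.  Genes passing the expression filters
   (more than 20 mapped read pairs in total, and at least 10-fold
   nucleotide coverage) are tested per stage against the blastula with a
   two-sided negative-binomial exact test at fixed dispersion
   φ = 0.1 (variance μ + φμ²); calls require |log₂FC| ≥ 1 and
   Benjamini–Hochberg adjusted p < 0.05.
3. **Annotation-level summaries.** Hypergeometric GO enrichment on direct
   annotations only (no ancestor propagation), filtered at ≥ 5 sequences
   and ratio ≥ 1.5; expression-profile clustering at an 80% matching
   threshold with TF/GO retention rules; transition/transversion and
   per-kilobase summaries of VCF polymorphisms filtered at DP ≥ 20 and
   MQ ≥ 40.

## Worked example

Simulate a 300-gene four-stage study with the default conditions (a
quarter of genes perturbed 8-fold at one stage), call DEGs, and check the
calls against the planted truth:

```r
library(larvaseq)

cfg <- sim_config(seed = 42, n_genes = 300)
sim <- simulate_stage_counts(cfg)
res <- call_degs(sim$cm, de_params())
deg <- subset(res, is_deg)
cat("genes tested:", length(unique(res$gene)),
    " DEG calls:", nrow(deg), "\n")
#> genes tested: 300  DEG calls: 71
head(deg[order(deg$p_adjusted), ], 3)
#>          gene       stage log2_fold_change  p_value p_adjusted is_deg
#> 317 gene00017 auricularia            -4.68 3.33e-09   4.99e-07   TRUE
#> 493 gene00193 auricularia             4.53 2.64e-09   4.99e-07   TRUE
#> 382 gene00082 auricularia             4.05 4.89e-08   4.89e-06   TRUE

truth_key  <- paste(sim$truth$gene, sim$truth$stage)
called_key <- paste(deg$gene, deg$stage)
cat("planted changes recovered:",
    sum(truth_key %in% called_key), "of", length(truth_key), "\n")
#> planted changes recovered: 67 of 75
```

The three strongest calls are planted genes recovered with fold-changes
near the true log₂ 8 = 3 (overshoot is expected for the winners at
dispersion 0.1), and 67/75 planted gene-stage changes are recalled at an
adjusted-p threshold of 0.05.

Variant arithmetic works directly on published count tables too:

```r
s <- variant_summary_from_counts("all", 689365, 455283, 58932)
round(s$tstv, 3)
#> [1] 1.514
```

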