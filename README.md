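# globinmatch

Benchmarking tools for globin-blocked whole-blood mRNA-Seq.

Whole-blood RNA-seq libraries are dominated by hemoglobin (Hb)
transcripts from ten globin genes (*HBA1*, *HBA2*, *HBB*, *HBD*,
*HBE1*, *HBG1*, *HBG2*, *HBM*, *HBQ1*, *HBZ*): an unblocked library
spends roughly half of its reads on them. Globin blocking (GB)
suppresses amplification of globin cDNA during library preparation and
frees that depth for the rest of the transcriptome. The benchmark
question this package serves: does a blocked library still carry
enough of its donor's biological signal to be matched back to its
unblocked (noGB) sibling from the same RNA isolate — and how do
technical batch layers (sequencing run, machine model) interfere?

The package is aimed at bioinformaticians evaluating depletion
protocols or auditing sample identity in paired RNA-seq designs. It
provides:

* a **paired-cohort simulator** (`simulate_paired_cohort()`):
  log-normal baseline expression, per-isolate biological signal shared
  by both libraries, globin-mass rescaling to calibrated depletion
  levels (noGB ≈ Normal(0.43, 0.14), GB ≈ Normal(0.080, 0.043)),
  gene-wise run- and machine-level batch perturbations, multinomial
  counting — fully reproducible from one seed;
* **quantification** (`compute_tpm()`, `globin_fraction()`,
  `count_detected()`, `non_globin_gain()`, `phred_to_error()`,
  `compare_groups()`);
* the **scaled Spearman matching score**. With `r_S[i,j]` the
  Spearman correlation of raw counts (genes with mean TPM > 0.5 in
  both panels) between noGB sample `i` and GB sample `j`, and `r̄_j`
  the mean of column `j`:

  ```
  r_mod[i,j] = (r_S[i,j] / r̄_j) / max_j (r_S[i,j] / r̄_j)
  ```

  Exactly one entry per row equals 1 — the assigned partner. Robust
  outlier exclusion and iterative re-matching are layered on top
  (`detect_outliers()`, `iterative_matching()`);
* **PCA on scaled TPM** with mean-and-median ≥ 1 gene filtering and
  absolute-loading gene ranking (`run_pca()`, `top_loading_genes()`),
  plus an exact upper-tail **hypergeometric overlap test**
  (`shared_term_hypergeom()`);
* a **pipeline driver** (`run_pipeline()`) writing TSV/JSON artifacts
  and a checksummed run manifest.

## Worked example

Simulate eight isolates sequenced on one shared lane (no batch layer
separates the protocols), then match blocked to unblocked libraries:

```r
library(globinmatch)

cfg <- simulation_config(n_individuals = 8, n_genes = 1000,
                         libsize_noGB_mean = 5e4, libsize_noGB_sd = 5e3,
                         libsize_GB_mean = 4e4, libsize_GB_sd = 5e3,
                         seed = 2024)
cohort <- simulate_paired_cohort(cfg, scenario = "dataset2")
cohort
#> gb_cohort: 1000 genes x 16 samples (8 isolates, scenario dataset2, seed 2024)

gf <- globin_fraction(cohort$counts, cohort$genes)
proto <- cohort$samples$protocol[match(names(gf), cohort$samples$sample_id)]
round(tapply(gf, proto, mean), 3)
#>    GB  noGB
#> 0.072 0.440

gb   <- cohort$counts[, cohort$samples$protocol == "GB"]
nogb <- cohort$counts[, cohort$samples$protocol == "noGB"]
iterative_matching(nogb, gb, cohort$genes, cohort$truth, max_rounds = 1)
#> match_report: 8 assignments over 8 pairs, 1 round(s)
#>   accuracy 1.000 (8/8); post-exclusion 1.000
```

The realized globin fractions sit at the calibrated depletion levels
(44.0% unblocked, 7.2% blocked here), and every blocked library is
assigned back to its own isolate. Two closed-form quantities used
throughout:

```r
round(non_globin_gain(0.43, 0.08), 4)   # non-globin reads gained per mapped read
#> [1] 0.614
signif(shared_term_hypergeom(6784, 345, 34, 14), 3)
#> [1] 3.29e-10
```

The first says a drop of the globin fraction from 43% to 8% yields
61.4% more non-globin reads at equal depth; the second is the
probability of two enrichment-term lists sharing 14 or more terms by
chance, given a universe of 6,784 terms, 345 background hits and 34
query terms.

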