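# regmap

Integrative mapping of tissue regulatory regions from histone-mark
cistromes, with enhancer–gene association, TF colocalization, signature
activity scoring, and CRISPRa Perturb-seq calling.

## The problem

Smooth-muscle tissues such as the pregnant human myometrium coordinate
their transcriptome through distal regulatory elements. Given
per-specimen peak sets for the enhancer marks H3K27ac and H3K4me1, an
expression table, a TF occupancy cistrome (e.g. progesterone-receptor
ChIP-seq), Hi-C loops, and a Perturb-seq screen, an analyst wants to
know:

* which regions are **putative enhancers** (double-positive for both
  marks) and which of them are shared across specimens;
* which H3K27ac clusters form **super enhancers** — stitched at gap
  ≤ 12.5 kb, called at span > 15 kb (the geometric rule, not
  ROSE-style signal ranking);
* which genes each enhancer plausibly regulates (TSS within a 100-kb
  window, or in the opposite anchor of a chromatin loop), stratified by
  expression bin (inactive < 1 ≤ low < 5 ≤ mid < 15 ≤ high, in FPKM);
* how strongly each catalog **colocalizes** with a TF cistrome
  (fraction of regions with ≥ 1 bp overlap), with a 2×2 odds-ratio /
  Fisher contrast between catalogs;
* a per-specimen **TF activity T-score** from an up/down gene
  signature — here the Welch t-statistic on per-gene z-scores, up
  versus down genes — and its Pearson correlation with a candidate
  target gene;
* which gRNAs in a CRISPRa Perturb-seq screen **activate** their
  targets: singlet cells only, fold change > 1.5 versus non-targeting
  controls, and for screen-wide calls a Wilcoxon rank-sum test with
  Benjamini–Hochberg adjusted p < 0.05.

`regmap` implements all of this on a strict 0-based half-open (BED)
coordinate model with bedtools-compatible merge semantics, plus seeded
synthetic-data generators that plant ground truth for every stage, so
the whole pipeline is testable offline.

## Worked example

```r
library(regmap)

# three specimens, 120 shared double-positive loci planted
pk  <- simulate_peaksets(n_samples = 3, n_shared = 120,
                         n_private_per_sample = 60, seed = 1)
enh <- mapply(call_putative_enhancers, pk$h3k27ac, pk$h3k4me1,
              SIMPLIFY = FALSE)
build_catalog(enh)
#> EnhancerCatalog: 3 sample(s), 120 common enhancer(s)
#>  sample n_enhancers n_common_overlap fraction_common
#>      S1         120              120               1
#>      S2         120              120               1
#>      S3         120              120               1

se  <- simulate_super_enhancer_landscape(k_clusters = 8, seed = 1)
ses <- call_super_enhancers(se$peaks)   # gap <= 12500, span > 15000
head(as.data.frame(ses), 3)
#>   chrom  start    end length n_constituents constituent_bp
#> 1 chrS1  35347  59203  23856              2          12356
#> 2 chrS1  79743 104289  24546              3          14046
#> 3 chrS1 128394 151982  23588              2          12088

occ <- simulate_occupancy(super_enhancer_regions(ses), fraction = 0.76,
                          seed = 2)
colocalize(super_enhancer_regions(ses), occ$occupancy,
           category = "super_enhancer")
#> Colocalization [super_enhancer]: 6 / 8 regions (75.0%)

# 43 specimens with a planted activity axis at rho = 0.47
act    <- simulate_activity_correlation(n_samples = 43, rho = 0.47,
                                        seed = 4)
scores <- compute_tscores(act$fpkm, act$signature)
correlate_activity(scores, setNames(act$fpkm[act$target_gene, ],
                                    colnames(act$fpkm)))
#> Pearson r = 0.447 (n = 43, p = 0.00266)
```

The catalog reports every specimen's enhancer count and the fraction
overlapping the common (all-sample consensus) set; the colocalization
line is the planted 76% rounded to the nearest achievable 6/8; the
final correlation recovers the planted ρ = 0.47 up to sampling noise at
n = 43.

## End-to-end pipeline

```sh
Rscript -e 'regmap::regmap_cli()' simulate --dir fixture --seed 1
Rscript -e 'regmap::regmap_cli()' run --config fixture/config.json
```

writes BED/TSV artifacts and a deterministic `report.json` (reruns are
byte-identical). Per-stage subcommands (`merge`, `intersect`,
`consensus`, `call-enhancers`, `call-superenhancers`, `associate`,
`colocalize`, `tf-activity`, `perturb-call`) mirror the R API; see
`vignettes/regulatory-mapping.Rmd` for the models, conventions and
design decisions.

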