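# esetools

Concordance, positional and selection analysis of exonic splice enhancer
(ESE) hexamer catalogues.

## The problem

Exonic splice enhancers are short exonic motifs — conventionally 6-mers
over the 4,096-hexamer universe — that promote recognition of adjacent
splice sites, largely through SR-protein binding. Several systematic
screens have nominated ESE hexamer catalogues using very different
definitions, and the catalogues only partially agree. `esetools` is for
molecular evolutionists and splicing researchers who want to ask, for any
family of motif catalogues:

- how concordant are the catalogues, against a uniform null, a
  nominated-motif pool null, or a hypothesised true-ESE pool — and how
  large a single true-ESE pool would explain the observed sharing;
- do the catalogues behave like true enhancers: purine-rich, enriched at
  exon ends over cores and introns, predictive of synonymous codon-usage
  gradients near junctions, slow-evolving at four-fold degenerate sites,
  SNP-poor, and denser next to weak splice sites and long introns?

## The statistics at the core

* **Concordance.** For catalogues of sizes *n₁, n₂* drawn uniformly
  without replacement from *N* motifs the overlap is hypergeometric with
  mean *n₁n₂/N*; for *k* catalogues the expected *k*-way intersection is
  *N·∏(nᵢ/N)*. `simulate_overlap()` adds Monte-Carlo sd, Z and empirical
  one-tailed P; `estimate_pool_size()` inverts the model (analytic seed
  *(∏nᵢ/T)^{1/(k-1)}*, simulation bisection) to estimate the true-pool
  size from an observed intersection *T*.
* **HPI** (hexamer preference index): per-codon Z score of frame-codon
  usage in a catalogue against catalogues of codon-usage-weighted random
  hexamers, and its concordance with per-codon usage-vs-distance
  regression slopes over all 87 synonymous codon pairs (exact binomial +
  Spearman, combined by Fisher's method).
* **Selection tests**: divergence at four-fold degenerate third
  positions and SNP-bearing-site proportions, in versus out of ESEs,
  paired by distance from the exon junction, with composition-matched
  pseudoESE catalogues as mutability controls.
* **Positional profiling**: motif coverage across a merged
  intron | exon-ends (+core) | intron layout, flank-vs-core paired tests,
  purine content in and out of ESEs.
* **Association tests**: Spearman (and partial Spearman) correlations of
  flank ESE density with splice-site strength, intron length, exon class
  and expression covariates.
* **Synthetic data**: generators for catalogues drawn from a known pool,
  exons with boundary-decaying motif embedding, ortholog pairs with an
  in-ESE rate deficit, SNPs with an in-ESE deficit, and copula-coupled
  splice scores — all with recorded ground truth, so every estimator has
  a parameter-recovery test.

## Worked example

Four catalogues of the classic sizes (238, 238, 285, 400) drawn from a
shared pool of 850 true motifs, analysed exactly as real catalogues
would be:

```r
library(esetools)

cats <- gen_hexamer_catalogues(pool_size = 850,
                               set_sizes = c(238, 238, 285, 400), seed = 7)
overlap_table(cats$sets, reps = 2000, seed = 8)
#>   set1 set2  n1  n2   O    E    F    Z P P_label significant
#> 1 sim1 sim2 238 238  74 13.8 5.35 17.4 0 <0.0005        TRUE
#> 2 sim1 sim3 238 285  71 16.6 4.29 14.1 0 <0.0005        TRUE
#> 3 sim1 sim4 238 400 106 23.2 4.56 18.9 0 <0.0005        TRUE
#> 4 sim2 sim3 238 285  79 16.6 4.77 16.3 0 <0.0005        TRUE
#> 5 sim2 sim4 238 400 111 23.2 4.78 19.3 0 <0.0005        TRUE
#> 6 sim3 sim4 285 400 124 27.8 4.46 19.1 0 <0.0005        TRUE
```

Every pair overlaps far beyond the uniform expectation E = n₁n₂/4096
(fold enrichments F of 4–5, Z of 14–19), exactly what shared sampling
from one pool produces. Inverting the four-way intersection recovers the
pool:

```r
obs4 <- length(intersect_at_least(cats$sets, 4))   # 11 motifs in all four
estimate_pool_size(c(238, 238, 285, 400), obs4, reps = 5000, seed = 9)
#> [1] 840
```

Embedding these motifs in synthetic coding exons with a 15% in-ESE rate
deficit at four-fold sites (d = 0.35, r = 0.85) and re-estimating:

```r
g    <- gen_genome(n_exons = 1000, pool = cats$pool, seed = 10, coding = TRUE)
op   <- gen_ortholog_pairs(g, d = 0.35, r = 0.85, seed = 11)
prof <- divergence_by_distance(op$pairs, cats$pool)
tst  <- paired_distance_test(prof, prof, cols = c("prop_ese", "prop_non"))
percent_difference(tst$median_a, tst$median_b)
#> [1] -12.3      # median ESE 0.292 vs non-ESE 0.333, paired P = 1.5e-04
```

ESE sites evolve measurably slower than equidistant non-ESE sites, on
the order of the imposed deficit. The vignette
(`vignettes/ese-concordance.Rmd`) documents the models, parameter
defaults and the design decisions behind every module.

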