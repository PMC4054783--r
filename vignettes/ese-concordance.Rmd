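---
title: "Comparing exonic splice enhancer catalogues: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing exonic splice enhancer catalogues: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esetools)
```

## The scientific problem

Exonic splice enhancers (ESEs) are short exonic motifs — conventionally
hexamers — that promote recognition of nearby splice sites, typically by
recruiting SR proteins. Several systematic screens have nominated hexamer
catalogues of putative ESEs, using quite different definitions (enrichment
in exons versus introns and near weak splice sites; enrichment in
non-coding exons versus pseudoexons; conservation at wobble positions;
direct mini-gene mutagenesis). The catalogues only partially agree, which
raises two linked questions this package is built to answer:

1. **Concordance.** How much do the catalogues overlap, relative to
   sensible nulls, and how large would a single underlying pool of true
   ESEs have to be to explain the observed sharing?
2. **Diagnostics of function.** Do the catalogues — and consensus
   intersection sets built from them — behave the way true enhancers
   should: purine-rich, enriched near exon ends, predictive of synonymous
   codon-usage gradients, slow-evolving at four-fold degenerate sites,
   SNP-poor, denser next to weak splice sites and long introns?

Every analysis is also exercisable on synthetic data generated in-package
with recorded ground truth, so each pipeline stage has a download-free
parameter-recovery test.

## Concordance statistics

For two catalogues of sizes $n_1, n_2$ drawn uniformly without replacement
from a universe of $N$ hexamers ($N = 4096$), the intersection is
hypergeometric with mean $n_1 n_2 / N$ and variance
$\frac{n_1 n_2}{N}\frac{N-n_1}{N}\frac{N-n_2}{N-1}$. For $k$ catalogues
the expected $k$-way intersection is exactly $N \prod_i (n_i/N)$, by
linearity of expectation (each motif is in sample $i$ with probability
$n_i/N$, independently across samples). `simulate_overlap()` draws
replicate catalogue families to obtain the null sd, a $Z$ score and an
empirical one-tailed $P$ (the fraction of replicates with an intersection
at least as large as observed, reported as `<1/reps` at zero
exceedances); the closed forms above serve as its analytic oracles in the
tests. Three nulls are supported: the uniform 4,096-hexamer universe, a
nominated-hexamer pool (every motif any screen proposed), and a
hypothesised true-ESE pool.

`estimate_pool_size()` inverts the sampling model: given catalogue sizes
and a target $k$-way intersection $T$, the analytic solution is
$N = (\prod_i n_i / T)^{1/(k-1)}$; the search then refines by bisection on
integer $N$ with the expected intersection estimated by simulation, and
reports the estimate to the nearest 10, matching the "around 850"
resolution at which such estimates are meaningful. The estimate is
strongly sensitive to $T$ (it scales as $T^{-1/(k-1)}$), which is why the
reporting is deliberately coarse.

## Positional density profiling

Following the merged-sequence construction of the pseudoexon-based screen,
each exon longer than 50 nt contributes a composite: the last 100 nt of
the upstream intron, the exon's first and last 50 nt (plus its central
100 nt when longer than 200 nt), and the first 100 nt of the downstream
intron. Density is implemented as **coverage fraction** — the fraction of
nucleotide positions covered by at least one motif occurrence — rather
than a match-count rate; this is the scale on which published region
medians sit (under randomness coverage is roughly
$1-(1-|S|/4096)^6$ for a catalogue $S$, e.g. about 7% for a 50-motif
set). Two per-hexamer normalisations are emitted (median density divided
by catalogue size, and the median of per-exon per-hexamer densities),
since the published per-hexamer columns are not always consistent with a
single rule.

Exons of 51–100 nt have overlapping 50-nt flank windows; overlapping
positions are emitted once (the whole exon is used), avoiding double
counting. Matches are looked up on the composite, so a match can span an
artificial junction; each covered position is assigned to its own region.
The paired flank-versus-core test (exons > 200 nt: the two 50-nt flanks
pooled against the central 100 nt of the same exon) instead masks the
intact exon sequence — the within-exon pairing is the point of that test
and needs no intron context. Wilcoxon machinery uses exact distributions
below 25 informative pairs and the normal approximation with continuity
correction above.

## HPI and codon-usage gradients

The hexamer preference index treats each hexamer $n_1 \dots n_6$ as
contributing its four fully specified frame codons
($n_1n_2n_3, \dots, n_4n_5n_6$), pools them over the catalogue, drops
stops and renormalises. The null rebuilds same-size catalogues whose
hexamers are concatenations of two sense codons drawn in proportion to a
codon-usage table (bundled human reference values by default), parsed
identically. HPI is the per-codon $Z$ score of the observed proportion
against this null. The null stream is drawn as exactly two vectorised
usage-weighted `sample()` calls (first codons, then second codons), which
makes the computation reproducible and lets an independently coded
counting path verify it to machine precision.

Usage-versus-distance slopes are fit per codon by ordinary least squares
of the within-synonymous-family proportion on distance, indexed in
**codons** from the nearest exon boundary within the exon half, capped at
35 codons (about 100 nt, where enhancer constraint concentrates). The
concordance test orients every synonymous pair so the HPI difference is
positive, tallies the sign of the slope difference (exact one-tailed
binomial against 0.5; zero differences dropped; HPI ties cannot be
oriented and are dropped with a log message), adds a one-tailed Spearman
correlation of slope difference on HPI difference, and combines the two
$P$ values by Fisher's method. The combined statistic is referred to
$\chi^2$ at df = 4 by default — the standard reference for two combined
tests — with a df = 2 compatibility switch, because published overall
$P$ thresholds for these statistics are consistent with a df = 2
reference; the package defaults to the orthodox choice and documents the
discrepancy rather than silently matching it.

## Divergence, SNPs and pseudoESE controls

Selection tests use four-fold degenerate third positions only, and only
where the aligned codons share the same four-fold family in both species,
so any difference is synonymous in both. Substitution is any base
mismatch at such a site (raw proportions; no multiple-hit correction, as
the quantities compared are equidistant proportions, not rates).
Classification as ESE/non-ESE uses the human mask only. Distances are nt
from the nearest junction within the exon half, truncated at 100 nt;
per-distance cells with fewer than 50 classified sites are dropped from
the paired tests as a stability guard. The ESE-versus-non-ESE contrast is
a Wilcoxon test paired by distance; the headline summary is
$100(\mathrm{med}_{ESE} - \mathrm{med}_{non})/\mathrm{med}_{non}$ over
the shared distance support.

Because ESEs differ in base composition from bulk exonic sequence,
composition alone could mimic a rate difference. The pseudoESE control
generates 100 replicate catalogues whose hexamers have bases drawn
i.i.d. from the real catalogue's average composition (uniqueness enforced
within a set; real members not excluded — the contamination by true
motifs is acknowledged and attenuates the contrast), and compares the
real profile against the per-distance median across replicates.

The net-selection estimate is deliberately coarse arithmetic: local
reduction = rate deficit × ESE density near ends, then net = local ×
fraction of sequence near ends, each stage rounded half-up to a whole
percent (round-half-up is required to reproduce the published two-stage
15% × 30% → 5% → ×80% → 4% chain; banker's rounding would break it).

## Association tests

Splice-score correlations use the terminal 50 nt of each exon end
omitting the terminal 3 nt (to keep the splice site itself out of the
density window); class and intron-length analyses use the final 100 nt
with no terminal exclusion, mirroring the analyses they reproduce.
Intron-length correlations pair each exon end with its own flanking
intron and pool both ends (per-end results are also returned), default
Spearman with a Pearson switch, optionally restricted to introns under
1,501 nt. The partial Spearman correlation rank-transforms everything and
correlates residuals of least-squares fits on the covariate ranks, with a
$t$ reference at $n - 2 - k$ df. Expression summaries apply the
negative-control mask (values below the per-tissue control mean set to
zero), drop all-zero genes, normalise tissues by total signal, and report
breadth, tau ($\sum_i (1 - x_i/x_{max})/(n-1)$, the standard specificity
index; the source analyses name no formula), mean and median.

## The synthetic-data generator

`gen_genome()` and its companions emulate the statistical structure the
analyses assume, not human genomic realism. Defaults, chosen once:

- exon lengths lognormal, median 130 nt (sdlog 0.35, minimum 60): the
  typical internal human exon is about 130 bp;
- flanking introns lognormal, median 1,500 nt (sdlog 1), with 100-nt
  flank sequence stored — enough for the composite construction;
- uniform background base composition;
- motif stamping probabilities follow a logistic decay from the boundary
  (plateau 0.06, floor 0.005, midpoint 50 nt, scale 8), giving roughly
  30% nucleotide coverage at exon ends and a few percent in cores —
  matching the reported 30–40% flank ESE density and its decay over the
  first 50–100 nt.

Stamps overwrite background (collisions allowed); the truth mask is
**re-derived from the final sequence** against the pool, so truth equals
what `mask_ese_positions()` finds — including chance matches, which occur
at roughly $1-(1-|pool|/4096)^6$ coverage and are genuinely ESE by
construction. Tests that need a near-empty exon core therefore use small
pools. Splice scores (and optionally intron lengths) are coupled to
realized flank densities through a Gaussian copula with the Spearman
target mapped by $\rho_P = 2\sin(\pi\rho_S/6)$. Coding exons are built
from usage-drawn codons; an imposed synonymous-pair trend is linear in
the within-pair probability, so the slope estimator's target is the
imposed coefficient itself. Ortholog pairs substitute four-fold third
positions at rate $d$ outside the truth mask and $d\,r$ inside; SNPs
likewise at $s$ and $s\,q$.

What the generator does **not** emulate: isochore/GC structure, CpG
hypermutability, indels, alignment error, splice-site consensus
sequences, linked selection. Passing recovery tests therefore shows the
estimators are correct under the assumed sampling structure, not that
real data meet those assumptions.

Determinism: identical parameters and seed give byte-identical output;
every generator returns a `truth` record and recovery tests read truth
only from it.

## Problem sizes and numerical choices

The test suite runs at deliberately modest problem sizes — the package's
own choice of scale for routine verification: 10,000-replicate nulls for
the headline concordance numbers, 2,000 ortholog pairs (with 200
bootstrap resamples) for divergence recovery, 10,000 exons for copula
recovery, 100 seeded runs for test-size calibration. Monte Carlo
tolerances are stated in the tests as multiples of the relevant standard
errors, never as free constants.

Other fixed choices: coordinates are 0-based half-open internally and
1-based inclusive in reports, with the first exonic base at distance 1;
sequences are sense-strand throughout (minus-strand input must be
reverse-complemented upstream); ambiguous bases break motif matches and
are excluded from composition denominators; motif list input is
deduplicated with a warning rather than an error; the 5% ortholog exon
length rule uses the first species' length as denominator and removes the
offending gene, matching the gene-level filter described for the source
data; duplicate gene entries resolve to the longest first-species
transcript, ties broken by the second species.

## Known limitations

- The pool-size estimator assumes all catalogues are uniform samples from
  one pool; heterogeneous detection probabilities would bias it, and no
  richness estimator beyond the matching procedure is provided.
- The published composition table's unexplained significance row is not
  reproduced (the test behind it is unidentified); composition output is
  descriptive, with an optional chi-square against a user-supplied
  background.
- Raw published catalogues are optional external inputs, not bundled;
  analyses depending on them run only when the user supplies the lists.
- The divergence model scores substitutions without correcting for
  multiple hits, which is adequate for equidistant-proportion contrasts
  but not for absolute rate estimation.
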