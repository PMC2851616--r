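---
title: "Integrated copy-number and expression analysis for amplicon driver discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated copy-number and expression analysis for amplicon driver discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnadriver)
```

## The problem

Epithelial ovarian carcinomas carry complex somatic copy-number landscapes:
broad and focal gains and losses cover a substantial fraction of the genome
in every tumour, and recurrently amplified regions contain tens to hundreds
of genes each. Only a few of those genes are *drivers* — genes whose
increased dosage is selected for — while the rest are co-amplified
passengers. The single most useful discriminating signal at this scale is
the **dosage effect**: a driver's expression should track its DNA copy
number across tumours, while a passenger's need not.

`cnadriver` implements a complete desk-scale pipeline around that idea:

1. **Segmentation.** Marker-level absolute copy-number profiles (diploid =
   2) are segmented per sample and chromosome by circular binary
   segmentation (CBS) with permutation inference.
2. **Recurrence.** Segments are state-called (gain above 2.5 copies, loss
   below 1.5), a per-base gain-frequency track is built across the cohort,
   and maximal intervals gained in at least 40% of samples are extracted
   and collapsed by cytoband.
3. **Germline filtering.** Copy-number polymorphisms (CNPs) are called
   from the matched normals — any locus gained *or* lost in more than 5% of
   normals — and subtracted from the candidate regions, splitting or
   trimming them as needed.
4. **Integration.** For each surviving region, samples split into a gain
   group G (region copy number above 3) and a neutral group N (1.5–2.5
   copies); each region gene is tested for differential expression with an
   empirical-Bayes moderated t-statistic (histotype covariate,
   Benjamini–Hochberg correction within region) and correlated with its
   own ±10 kb copy number.
5. **High-amplitude amplicons.** Separately, loci at copy number ≥ 5 in
   ≥ 5 samples are collected, since rare but dramatic amplifications also
   mark drivers even below the 40% recurrence bar.
6. **Prioritisation.** Branch A keeps differentially expressed genes
   (adjusted p < 0.05) in frequent regions with log~2~ fold change > 0.7 or
   copy-number/expression correlation r > 0.7, then applies per-chromosome
   gain-frequency cuts; branch B keeps high-amplitude genes with r > 0.6 or
   logFC > 0.6. The final candidate list is their union, and every gene
   carries per-criterion flags that a rule-replay audit re-checks.

A synthetic-cohort generator with planted amplicons, dosage slopes,
passenger noise and germline CNPs provides ground truth for every stage.

## Coordinate and scale conventions

All intervals are held internally as **0-based half-open** `[start, end)`;
SEG files are written 1-based inclusive and converted at the I/O boundary,
and cytoband files follow the UCSC 0-based convention. Copy number is kept
on the **absolute scale** (diploid = 2) throughout: the state thresholds
(2.5, 1.5), the G-group cutoff (3) and the high-amplitude bar (5) only make
sense on that scale, so ratio-scale inputs must be converted before entry.

A sample's segments **tile** its marker span: each segment starts at its
first marker's position and ends where the next segment begins (the last
ends at the final marker). The usual first-to-last-marker bounds would
leave gaps between adjacent segments, which breaks per-base frequency
algebra; placing the boundary at the change point's marker keeps the
interval arithmetic exact at marker resolution. The corollary — true of
any marker-based pipeline — is that all reported boundaries are quantised
to the marker spacing.

## The segmentation statistic

For a series \(x_1, \dots, x_n\), CBS considers every arc
\(x_{i+1..j}\) and its complement and computes

\[ T_{ij} \;=\; \frac{\bar{x}_{\mathrm{arc}} - \bar{x}_{\mathrm{comp}}}
   {\sqrt{1/k + 1/(n-k)}}, \qquad k = j - i , \]

maximising \(|T|\) over all arcs with both sides at least `min_width`
markers (default 2). Whether the split is kept is decided by permutation:
the markers are shuffled and the maximal \(|T|\) recomputed; the split is
accepted iff the permutation p-value is below `alpha` (default 0.01). The
scale of the data cancels under permutation, so \(T\) is left unscaled.
Accepted splits recurse into the resulting sub-segments. Ties in
\(|T|\) resolve to the leftmost, then shortest, arc, which makes the
procedure deterministic; note that a boundary arc and its complement carry
equal \(|T|\), so the same breakpoint can be reported through either
representation.

Two numerical choices matter in practice:

* **Sequential stopping.** Permutations stop early once the decision at
  `alpha` is settled: rejection as soon as the exceedance count exceeds
  `alpha * n_perm`, acceptance once at least `2/alpha` permutations have
  produced an upper p estimate \((e+1)/(m+1)\) of at most `alpha/2`. The
  reported p is `(e+1)/(m+1)`. This keeps the reference behaviour of a
  plain permutation test (and exact reproducibility under `set.seed`)
  while making deep recursions affordable.
* **Degenerate series.** Constant series (or series shorter than
  `2 * min_width`) return a single segment without testing.

The test suite checks the recursion against an independent, exhaustive
max-\(|T|\) search oracle written in plain R: on random series of up to 60
markers with up to two planted change points (shift at least 1 copy, marker
sd 0.1), detected boundaries must match the oracle in at least 95% of
series.

## The moderated t-statistic

Within a region, each gene g is fitted by least squares with

\[ \mathrm{expr}_{gs} = \mu_g + \beta_g\,\mathbb{1}[s \in G] +
   \gamma_{g,h(s)} + \varepsilon_{gs}, \]

where \(h(s)\) is the histotype of sample s (levels with fewer than two
usable samples collapse into `"other"`). The group coefficient is the
log~2~ fold change. Residual variances \(s_g^2\) (d residual df) are
shrunk by empirical Bayes towards a prior \((d_0, s_0^2)\) estimated by
moment matching on \(\log s_g^2\): with
\(e_g = \log s_g^2 - \psi(d/2) + \log(d/2)\), the model implies
\(\mathrm{Var}(e) = \psi'(d_0/2) + \psi'(d/2)\) and the mean fixes
\(s_0^2\); \(\psi'^{-1}\) is solved by Newton iteration. The posterior
variance is \(\tilde{s}_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)\) and

\[ \tilde{t}_g = \frac{\widehat{\mathrm{logFC}}_g}{\tilde{s}_g \sqrt{v}} \]

has \(d_0 + d\) degrees of freedom (capped at the pooled residual df of
the gene set; when the moment equation shows no excess dispersion,
\(d_0 = \infty\) and the prior scale is the pooled mean variance). Setting
\(d_0 = 0\) recovers the ordinary covariate-adjusted t exactly, which the
tests assert to 1e-10, and the full pipeline is cross-checked against an
independent established implementation of the same empirical-Bayes model.

Moment matching is unstable on tiny gene sets, so regions with fewer than
10 probesets borrow a global prior estimated from all regions' residual
variances pooled; larger regions use their own.

Benjamini–Hochberg adjustment is applied **within each region**, matching
a per-region analysis design in which each region's gene set is its own
family; p-values are adjusted by the step-up rule
\(p_{(i)}^{adj} = \min_{j \ge i} m\,p_{(j)}/j\) with `NA` values excluded
from m.

## Region algebra

The frequency track is a breakpoint sweep: the union of all segment
boundaries cuts each chromosome into intervals on which the number of
covering gained (or lost) samples is constant; the tests require exact
agreement with brute-force per-base counting. Frequent-gain extraction
keeps intervals at or above the threshold (the comparison is inclusive:
40.3% of samples passes a 40% bar) and merges adjacent qualifying
intervals.

Cytoband collapsing groups frequent intervals by the band they fall in;
each group's region spans its members' minimum start to maximum end, and
an interval straddling a band boundary forms a separate group tagged with
the joined band names rather than being absorbed into either band. Region
ids are `<chrom>_<ordinal>` in genomic order. Because fragments and
regions are re-bounded from their members, collapsed regions do not cover
whole cytobands and resolution is not lost.

CNP subtraction is plain interval difference, applied CNP by CNP: an
interior CNP splits a region in two (so there can be more regions after
elimination than before), an edge CNP trims, a covering CNP deletes. The
result is order-independent and is tested against a per-base difference
oracle. No minimum fragment size is imposed — real candidate regions can
be tens of kb. After subtraction each fragment's gain frequency is
re-checked against the 40% bar and recorded (`passes_freq_post_split`);
only passing fragments are integrated, but all fragments stay in the
regions table for audit.

## Choices where the design was genuinely open

* **G-group cutoff.** Two readings circulate for "gain" at a region:
  strictly more than 3 copies, or 3 copies and above. The pipeline
  defaults to the strict reading (`gain_group_cutoff = 3.0`, exclusive)
  and exposes the cutoff, so the laxer convention is one argument away.
  Samples between 2.5 and the cutoff are excluded from both groups, as are
  samples with a loss (below 1.5) — a loss is not neutral evidence.
* **CNP counting.** Germline CNPs often show gain in some individuals and
  loss in others at the same locus, so carriers are pooled across both
  states by default (`mode = "pooled"`); a separate-state mode exists.
  The >5% threshold is strict: 3 of 57 normals qualifies, 2 of 57 does
  not.
* **Gene-level gain frequency** (used by the per-chromosome cuts) is the
  fraction of the copy-number cohort whose flanked gene copy number
  exceeds the state gain cutoff (2.5). This is the most local reading —
  frequency of the gene itself rather than of its host region — and the
  denominator is configurable.
* **Per-chromosome frequency cuts** are defined for chr8 (≥ 60%), chr3
  (≥ 50%) and chr20 (≥ 42%); chromosomes without a configured cut fall
  back to the baseline 40% with a logged warning rather than failing.
* **Probeset-to-gene collapse.** A gene satisfies a cut if any of its
  probesets does: gene-level p is the minimum adjusted p, logFC and r the
  maxima. With the default one-probeset-per-gene simulation this is the
  identity.
* **Strictness of cuts** follows the printed operators everywhere: logFC
  and r cuts are strict (`> 0.7`, `> 0.6`), frequency cuts inclusive
  (`>= 40%`, `>= 60%`), the high-amplitude definition inclusive on both
  axes (CN ≥ 5, support ≥ 5 samples).

## What the synthetic cohort emulates — and what it does not

`demo_cohort_config()` fixes the reference study conditions used by the
acceptance checks: 60 tumours and 20 matched normals over two chromosomes
(60 and 80 Mb, markers every 100 kb), five histotypes in the proportions
of a typical ovarian-carcinoma series, three frequent driver amplicons
(carrier frequencies 0.55/0.60/0.60, attained copy number 3 or 4, dosage
slope β = 0.5 log~2~ units per copy), one 1 Mb high-amplitude amplicon
(copy number 6 in 10% of tumours), a Poisson(6) background of passenger
segments per tumour (lengths log-uniform on 50 kb–10 Mb, copy number 1 or
3, overlaps resolved by the max-CN rule), two germline CNPs (population
frequencies 0.25 and 0.15 — common CNPs; at 20 normals the strict >5%
rule needs at least two carriers, so rare CNPs are below the design's
detection floor), marker noise sd 0.3 and expression noise sd 0.3 with
histotype offsets (sd 0.5) on a random 10% of genes. One CNP sits inside
a driver amplicon, the situation that motivates the splitting rules.
Genes are placed uniformly (500 in the demo); genes wholly inside a driver
amplicon carry its dosage slope, except genes overlapping a planted CNP,
which remain passengers — a germline-variable locus cannot serve as a
somatic dosage reporter and the analysis excises such loci by
construction.

Synthetic CNP and amplicon sizes are expressed in *markers*, not bp:
detectability is driven by marker count, so at 100 kb spacing the planted
1 Mb CNP (10 markers) plays the role that a 10–30 kb CNP plays on a
modern SNP array with one marker per kb.

The generator deliberately does **not** model probe-level intensities,
allele-specific copy number, tumour purity or ploidy shifts, GC waves, or
correlated noise. Passing tests therefore demonstrate the correctness of
the statistical machinery and interval algebra under honest noise — not
robustness to array artefacts, impure samples or mis-centred baselines,
which real data add on top.

## Problem sizes and runtime

The packaged demonstration cohort (80 profiles of 1,400 markers, 500
genes) runs end to end in well under a minute; the oracle-equivalence
check segments 200 series of up to 60 markers, and the region-algebra
check runs 100 random instances of up to 50 kb × 20 samples against
per-base oracles. The moderated-t calibration uses 2,000 null genes with
15 + 15 samples and three histotype levels. These sizes were chosen so
that the whole evidence chain — generator, oracles, pipeline — is
exercised at desk scale.

## Known limitations

* Boundary placement is quantised to the marker spacing (inherent to
  marker-based segmentation); the CNP-absence guarantee after subtraction
  is correspondingly exact only up to one spacing at each edge.
* The permutation test's sequential acceptance rule trades a slight loss
  of p-value resolution (p is never reported below `1/(m+1)`) for speed;
  near-threshold splits (true p within about a factor of two of `alpha`)
  can be decided either way, which is why correctness is asserted against
  the exhaustive oracle in aggregate rather than split by split.
* Only gains feed region discovery; losses are state-called and summarised
  per sample but candidate loss/LOH regions are out of scope.
* The histotype covariate is the only batch-like adjustment; no surrogate
  variables or array-batch terms are fitted.
* With `d0 = Inf` (no excess variance dispersion) the prior scale is the
  pooled mean variance; heavy-tailed variance distributions that defeat
  moment matching would call for a robust estimator, which is not
  implemented.
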