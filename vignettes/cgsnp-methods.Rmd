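---
title: "Methods: cgSNP classification, enrichment testing and methylation differences"
author: "cpgvar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cgSNP classification, enrichment testing and methylation differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgvar)
library(data.table)
```

# The model and its assumptions

`cpgvar` analyses variants whose two alleles differ in whether a CpG
dinucleotide overlaps the variant base. The analysis rests on three
modelling choices.

**Trinucleotide scope.** A single-base substitution can only create or
destroy a CpG that involves the substituted base itself, so the
classifier looks at exactly one base on each side (`left-[a/b]-right`).
Longer flanks are accepted in the input but only the adjacent bases are
used. A CpG is present for allele `x` iff `left+x` or `x+right` spells
`CG`:

```{r}
cpg_present("C", "G", "A"); cpg_present("A", "C", "G"); cpg_present("A", "A", "A")
```

**Shift exclusion.** When *both* alleles yield a CpG — necessarily at
different adjacent dinucleotides, as in `C[C/G]G` where both `CCG` and
`CGG` contain a CpG — the site keeps a CpG under either allele; the CpG
moves by one base rather than appearing or disappearing. Because
methylation of immediately adjacent CpGs is strongly correlated, such
shifts are excluded from cgSNPs (`CG_SHIFT_EXCLUDED`). Implementing the
rule as "both alleles yield CpG presence" reproduces the `C[C/G]G` case
without positional bookkeeping of which dinucleotide moved.

**Ancestral orientation.** The ancestral trinucleotide is the initial
state: a CpG-polymorphic variant whose ancestral allele lacks the CpG is
a gain, one whose ancestral allele carries it is a loss, and a missing
ancestral state leaves the variant `CG_UNORIENTED` — still a cgSNP for
tagging purposes, just not directable. An ancestral base matching
neither allele is treated as a data error at parse time.

Exhaustive enumeration of all 4×4×3×4 = 192 ordered
(left, ancestral, derived, right) cases gives 22 gain and 22 loss
scenarios (44 ordered; 22 after collapsing each scenario with its
reverse complement) and 2 shift scenarios — the `C[C/G]G` pair:

```{r}
attr(enumerate_scenarios(), "scenario_summary")
```

The gain/loss balance is structural: swapping ancestral and derived
alleles is a bijection between the two sets. `enumerate_scenarios()`
emits the full per-scenario list so the enumeration convention behind
any externally quoted scenario count can be checked against it directly;
the package reports its own count rather than assuming one.

Classification is strand-invariant (CpG is its own reverse complement),
which the test suite asserts over all 192 cases. Context bases that are
ambiguity codes (N/IUPAC) classify as `NON_CG` with a machine-readable
`context_warning` flag rather than an error, so genome-scale runs do not
abort; indels and multiallelic records are rejected at parse time with a
counted skip.

# Genomic context

CpG islands are merge-normalised; **shores** are the ±2 kb flanks minus
any island overlap, and **open sea** is everything farther away.
Shore zones of nearby islands merge, island labels always win, and known
chromosome ends truncate shores. Gene context is `GENEBODY` inside any
gene interval, else `PROMOTER` within 2 kb upstream of a gene's
strand-aware 5′ end, else `INTERGENIC`; a promoter overlapping a
neighboring gene's body yields `GENEBODY` there, since a position inside
any gene is a gene-body position. Promoters are anchored at the gene
interval's 5′ end (no transcript-level resolution). Both widths are
parameters (`shore_width`, `promoter_width`, default 2000 bp). The
labels partition every position; tests verify agreement with a per-base
distance-scan oracle on randomized toy genomes.

# LD, tagging and pruning

r² is the standard squared allelic correlation
`D²/(p_A p_a p_B p_b)`. The package consumes a PLINK-style pair table
and stores its symmetric closure; an absent pair means r² = 0, and no LD
is imputed across chromosomes or blocks.

Two conventions are fixed and used everywhere: sharing/tagging uses the
**strict** inequality r² > threshold (default 0.8), and greedy pruning
scans SNPs in genome order (chrom, pos, id), retaining a SNP iff its r²
to every already-retained SNP is ≤ threshold. The greedy scan is chosen
for determinism and testability rather than reproducing any specific
windowed algorithm; the retained set provably contains no internal pair
above the threshold and is maximal under the scan order. A proxy's tag
count excludes the proxy itself, and tag counts are computed on the full
panel while pruning defines the proxy set.

A **cgSNPt** is a proxy that is itself a cgSNP (gain, loss or
unoriented) or tags at least one cgSNP; the status is monotone when the
threshold is lowered.

# Enrichment testing

**Logistic model.** `ln(P/(1−P)) = β₀ + β_cgSNPt·X_cgSNPt + β_MAF·X_MAF
+ β_tags·X_tags`, fitted by maximum likelihood (`stats::glm`), with MAF
and the tag count as confounder adjustments — both are correlated with
cgSNPt status (a SNP tagging many others is more likely to tag a cgSNP)
and with outcome ascertainment. The cgSNPt effect is reported as
`OR = exp(β)` with 95 % Wald limits `exp(β ± 1.96·SE)`, matching the
conventional OR/CI reporting style; profile-likelihood intervals are not
used. Complete separation, non-convergence and constant covariates are
hard errors with diagnostics, not silent results.

**Matched resampling.** Proxies are stratified by MAF bins of width 0.05
over [0, 0.5] crossed with tag-count classes {0}, {1–2}, {3–5}, {6–10},
{>10} (both configurable; the bin edges are a design choice, made
configurable because no canonical set exists). Given an index set (e.g.
the 500 proxies with top outcome signals), `n_draws = 300` matched sets
are drawn by stratified sampling **without replacement** from the
non-index proxies, each draw reproducing the index set's per-stratum
composition exactly — asserted, not assumed. Index SNPs are excluded
from the pool so the null is "a panel SNP that is not one of the index
SNPs". The empirical p-value is the fraction of draws whose cgSNPt count
**meets or exceeds** the observed count: ties count toward p, which is
conservative. Zero exceedances are reported as `< 1/n_draws` rather than
0; an add-one `(b+1)/(n+1)` variant is available via
`correction = "add_one"`. A stratum whose pool cannot supply its draw is
an error naming the stratum — the test's stated precondition.

**Reported-p bins and categories.** Trait-associated SNPs (catalog
convention: reported p ≤ 1e-5) are split on the −log10 scale into eight
bins, by default [5,6), [6,7), [7,8), [8,11), [11,14), [14,17), [17,20),
[20,∞); only the outer anchors of such binning are ever quoted in
catalogs, so the interior edges are configurable. Per-bin and
per-category fits use that bin/category's SNPs as positives against the
same negative set — all proxies associated with no trait — so odds
ratios are comparable across bins; a pooled fit accompanies the
per-category ones.

# Methylation differences at cgMuts

Somatic mutations are classified with the reference allele as the
initial state; `CG_LOSS` calls are **cgMuts**. The destroyed CpG's
cytosine is the mutated base when the C was hit, or one base 5′ when the
G was hit. Differences are `normal − tumor` at that cytosine. Only sites
present in both tracks enter the nearby-site comparison (intersection);
tumor methylation at a lost CpG is used as reported — residual signal
from heterozygosity or tumor purity is real signal, not an artifact to
zero out.

Nearby CpG sites are assigned by their distance in bp to the *nearest*
cgMut cytosine into half-open annuli (0,10], (10,50], (50,100],
(100,500], (500,1000], (1000,2000]; the cgMut site itself is the
separate `SITE` bin and sites beyond 2 kb are excluded. Annuli rather
than nested radii keep the bins disjoint. Summaries report the
10/25/50/75/90th percentiles (linear interpolation between order
statistics, `quantile type = 7`) and the fraction of sites with higher
normal methylation.

# The synthetic-data generator

The generator emulates the study conditions end to end with known ground
truth; its defaults are fixed once and are not tuned to outcomes.

* **Panel** (default n = 50,000 SNPs, one toy chromosome, ~150 bp
  spacing; CpG islands cover 5 % of it in 1 kb runs). Flank composition
  differs by region: immediate context bases are drawn with G+C
  probability 0.6 inside islands vs 0.4 outside, and an ancestral CpG
  overlapping the variant is planted with probability 0.30 inside
  islands vs 0.08 outside — this is what makes CpG *losses* dominate in
  islands, the qualitative pattern the classifier must recover. The
  ancestral allele is missing in 2 % of records (a small unoriented
  fraction, as in real panels). MAF is `0.5·Beta(1.2, 2.5)` with a
  lower-mean shape for cgSNPs, creating the mild MAF–cgSNP correlation
  the confounder adjustment must absorb.
* **LD** is simulated from haplotype pools (blocks of 20 SNPs, 120
  haplotypes copied from 4 founders with 5 % per-site error) rather than
  an arbitrary r² matrix, so every emitted r² is realisable and equals
  `r2_from_haplotype_counts()` applied to the pool by construction.
  Cross-block r² is exactly 0.
* **Outcomes** are Bernoulli draws from the logistic model itself with
  planted coefficients (defaults β₀ = −4, β_cgSNPt = ln 1.5,
  β_MAF = 0.5, β_tags = 0.02; trait categories override β_cgSNPt, e.g. a
  larger cancer effect, to exercise the per-category contrast). Planted
  reported p-values for positives are drawn per bin by design — they
  exist to exercise the binning logic, not as test statistics.
* **Methylation pair** (default 20,000 CpGs on 600 kb — WGBS-like ~30 bp
  spacing so every annulus is populated). Normal levels are
  `Beta(6, 2)` (most CpGs highly methylated); tumor = normal + N(0,
  0.03) noise, except at 53 planted CpG-destroying mutations where the
  tumor level drops by N(0.20, 0.07), truncated to keep levels in
  [0, 1]. Decoy non-CpG mutations are emitted alongside.

What the generator does **not** emulate: coalescent population
structure, recombination maps, mutation-rate heterogeneity,
ascertainment of genotyping arrays, read-level bisulfite noise, or
tumor–normal global methylation differences. Passing tests therefore
demonstrate the correctness and calibration of the *procedures* under
the planted model, not the real-data effect sizes, which depend on
external panels the package deliberately does not download.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; 1-based only at TSV/BED
  boundaries, converted exactly once in the readers/writers.
* MAF stratum edges are computed as `(0:10)/20` rather than an
  accumulating `seq()` so bin boundaries like 0.30 are exact doubles.
* Greedy pruning and the matched draws are deterministic given the input
  order and seed; every stochastic function takes an explicit seed and
  the pipeline is byte-reproducible (asserted on the results JSON).
* Empty inputs: empty summaries return empty tables; an empty difference
  vector, an all-positive/negative outcome, or a constant covariate are
  errors, not NaNs.
* Monomorphic loci have undefined r² and error; the generator instead
  flips one haplotype to keep simulated loci polymorphic.

# Problem sizes used by the test suite

The suite runs the classifier oracle exhaustively (192 cases), the
annotation oracle on 100 random toy tracks, enrichment recovery on 100
replicates of 50,000-SNP panels plus 200 null replicates, resampling
calibration on 200 repetitions of 300 draws × 500-SNP index sets over a
20,000-proxy panel with 50 power repetitions, and the methylation
analysis at the default 20,000-CpG scale — sizes chosen to give stable
Monte-Carlo estimates at desk scale. The calibration band for the null
resampling test (fraction of p ≤ 0.05 within 1.5–8.5 %) is the binomial
band around the nominal 5 % widened slightly toward 0 because ties
counting toward p make the test conservative on discrete counts.

# Known limitations

* Orientation relies on the supplied ancestral allele; no outgroup
  inference is attempted.
* Promoters are defined from gene intervals, not transcript TSSs.
* The pruning order is genome order; other orders give different (also
  valid) maximal sets.
* Per-bin/per-category logistic fits share negatives across fits, so the
  fits are not independent across bins.
* The matched resampling test requires every index stratum to be
  coverable by the pool; tiny strata must be merged by widening the bin
  edges if this precondition fails.
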