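# cpgvar

Classification and enrichment analysis of CpG-site-related variants
(cgSNPs): single-nucleotide substitutions that create or abolish a CpG
dinucleotide, the sequence substrate of DNA methylation.

## The problem

Most methylation QTL work maps variants to the methylation of *other*
CpG sites; a variant can instead act directly, by adding or removing the
CpG itself. `cpgvar` provides a tested pipeline for asking whether such
variants matter genome-wide:

1. **Classify.** In the trinucleotide context `left-[a/b]-right`, a SNP
   is CpG-polymorphic when exactly one allele yields a CpG overlapping
   the variant base. Oriented by the ancestral allele it becomes a
   **cg-gain-SNP** (derived allele creates the CpG) or **cg-loss-SNP**
   (ancestral CpG abolished); with the ancestral state unknown it stays
   unoriented but is still a cgSNP. Substitutions where *both* alleles
   carry a CpG at different adjacent dinucleotides (the `C[C/G]G` case)
   are *shifts*, excluded from cgSNPs. Classification is
   strand-invariant because CpG is its own reverse complement.
2. **Annotate.** CpG-island context (island / shore = ±2 kb flank /
   open sea) and gene context (gene body / promoter = 2 kb upstream of
   the strand-aware 5′ end / intergenic).
3. **Tag.** From pairwise LD, a proxy SNP is a **cgSNPt** when it is a
   cgSNP or tags one at r² > 0.8; greedy LD pruning (r² = 0.8, with 0.5
   and 0.3 as sensitivity thresholds) defines the proxy panel.
4. **Test enrichment.** Logistic model
   `ln(P/(1−P)) = β₀ + β_cgSNPt·X_cgSNPt + β_MAF·X_MAF + β_tags·X_tags`,
   reporting `OR = exp(β_cgSNPt)` with a 95 % Wald CI; and a matched
   resampling test that redraws the top-signal index set 300 times by
   stratified sampling without replacement (MAF × tag-count strata),
   yielding an empirical p-value for the observed cgSNPt count.
5. **Methylation.** At somatic mutations that destroy a CpG (cgMuts),
   normal-minus-tumor methylation differences at the lost site versus
   CpG sites in distance annuli (±10 bp … ±2 kb).

A seeded synthetic-data module generates every input with known ground
truth (planted coefficients, planted methylation drop, LD from simulated
haplotype pools), so the full pipeline is testable without any external
download.

## Worked example

```r
library(cpgvar)

cfg    <- synth_config(seed = 42, n_snps = 20000)
panel  <- generate_snp_panel(cfg)
summarize_classes(panel$snps, "region")
#>      region  n_cg n_gain n_loss n_unoriented pct_gain pct_loss
#> 1: OPEN_SEA  3516   1333   2113           70 37.91240 60.09670
#> 2:    SHORE   963    341    608           14 35.41018 63.13603
#> 3:   ISLAND   448     89    351            8 19.86607 78.34821
#> 4:   Global  4927   1763   3072           92 35.78242 62.35031
```

CpG losses dominate inside islands (78 % vs 60 % in open sea) because
island flanks carry more pre-existing CpGs to destroy — the direction
the generator plants and the classifier must recover.

```r
ld      <- generate_ld_blocks(panel, cfg)
proxies <- annotate_proxies(panel$snps, ld_index(ld))
oc      <- plant_outcomes(proxies, cfg, type = "eqtl")  # planted OR 1.5
fit <- fit_enrichment_model(data.table::data.table(
  y = oc$y, x_cgsnpt = as.integer(proxies$is_cgsnpt),
  x_maf = proxies$maf, x_tags = proxies$n_tagged))
fit
#> Enrichment (logistic): OR[cgSNPt] = 1.419 (95% CI 1.158-1.739), p = 0.000756
#>   n = 20000 (445 positive); beta_maf = -0.180, beta_tags = -0.088

proxies[, stratum := assign_strata(proxies)]
matched_simulation_test(head(oc$outcomes$snp_id, 200), proxies,
                        n_draws = 300, seed = 42)
#> Matched resampling: observed 64 cgSNPts in 200 index SNPs; null mean 52.1 (300 draws); empirical p 0.0533333
```

The fitted odds ratio (1.42, CI covering the planted 1.5) and the excess
of cgSNPts in the outcome-positive index set over its matched null
(64 vs 52.1) are the two enrichment read-outs of the pipeline.

A thin command-line wrapper with subcommands
(`synth`, `classify`, `annotate`, `tag`, `methdiff`, `run`) is installed
at `system.file("cli", "cpgvar.R", package = "cpgvar")`.

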