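small_cfg <- function(seed, ...) {
  synth_config(seed = seed, n_snps = 2000, n_cpg = 3000,
               meth_genome_size = 90000, ...)
}

test_that("generation is a pure function of the config seed", {
  cfg <- small_cfg(31)
  p1 <- generate_snp_panel(cfg)
  p2 <- generate_snp_panel(cfg)
  expect_identical(p1$snps, p2$snps)
  expect_identical(generate_ld_blocks(p1, cfg), generate_ld_blocks(p2, cfg))
  m1 <- generate_methylation_pair(cfg)
  m2 <- generate_methylation_pair(cfg)
  expect_identical(m1$tumor, m2$tumor)
  expect_identical(m1$mutations, m2$mutations)
})

test_that("ancestral missingness controls the unoriented fraction", {
  p <- generate_snp_panel(small_cfg(5, ancestral_missing_rate = 0))
  expect_equal(sum(p$snps$cg_class == "CG_UNORIENTED"), 0L)
  p2 <- generate_snp_panel(small_cfg(5, ancestral_missing_rate = 0.5))
  expect_gt(sum(p2$snps$cg_class == "CG_UNORIENTED"), 0L)
})

test_that("islands carry the planted excess of CpG losses", {
  for (seed in c(2, 12, 22)) {
    p <- generate_snp_panel(synth_config(seed = seed, n_snps = 8000))
    s <- summarize_classes(p$snps, "region")
    isl <- s[s$region == "ISLAND", ]
    sea <- s[s$region == "OPEN_SEA", ]
    expect_gt(isl$pct_loss, sea$pct_loss)
  }
})

test_that("emitted r2 values are realisable and round-trip through the file", {
  cfg <- small_cfg(9)
  p <- generate_snp_panel(cfg)
  ld <- generate_ld_blocks(p, cfg)
  expect_true(all(ld$r2 >= 0 & ld$r2 <= 1))
  # no cross-block pairs: blocks are consecutive runs of block_size SNPs
  blk <- setNames(ceiling(seq_len(nrow(p$snps)) / cfg$block_size),
                  p$snps$snp_id)
  expect_true(all(blk[ld$snp_a] == blk[ld$snp_b]))
  f <- tempfile(fileext = ".tsv")
  write_ld_tsv(ld, f)
  expect_equal(read_ld_tsv(f), ld, tolerance = 1e-12)
})

test_that("a two-haplotype pool gives r2 of exactly 1 within blocks", {
  cfg <- small_cfg(3, n_founders = 1, founder_mutation_rate = 0.5,
                   block_size = 4, haplotype_pool_size = 2)
  # pool of 2 haplotypes: every polymorphic pair of sites is in complete LD
  p <- generate_snp_panel(cfg)
  ld <- generate_ld_blocks(p, cfg)
  expect_true(all(ld$r2 == 1))
})

test_that("planted null and non-null outcome models behave as constructed", {
  px <- simulate_proxy_panel(50000, seed = 44)
  cfg0 <- synth_config(seed = 44, beta_cgsnpt = 0, beta_maf = 0,
                       beta_tags = 0, beta0 = -2)
  oc0 <- plant_outcomes(px, cfg0, type = "eqtl", seed = 45)
  tab <- table(px$is_cgsnpt, oc0$y)
  crude_or <- (tab[2, 2] * tab[1, 1]) / (tab[1, 2] * tab[2, 1])
  expect_lt(abs(crude_or - 1), 0.15)
  # with covariate effects off, the crude 2x2 OR estimates exp(beta) directly
  cfg1 <- synth_config(seed = 44, beta_cgsnpt = log(1.5), beta_maf = 0,
                       beta_tags = 0, beta0 = -2)
  oc1 <- plant_outcomes(px, cfg1, type = "eqtl", seed = 45)
  tab1 <- table(px$is_cgsnpt, oc1$y)
  crude_or1 <- (tab1[2, 2] * tab1[1, 1]) / (tab1[1, 2] * tab1[2, 1])
  expect_lt(abs(crude_or1 - 1.5), 0.2)
  # trait categories are ordered as planted over the same panel
  cfgc <- synth_config(seed = 44, beta0 = -3,
                       category_betas = c(cancer = log(2.5), other = log(1.0)),
                       category_probs = c(cancer = 0.5, other = 0.5))
  occ <- plant_outcomes(px, cfgc, type = "trait", seed = 46)
  res <- category_enrichment(occ$outcomes, px)
  expect_gt(res$cancer$or_cgsnpt, res$other$or_cgsnpt)
})

test_that("methylation pair plants the site effect and nothing else", {
  cfg <- small_cfg(8, meth_delta_mean = 0)
  m <- generate_methylation_pair(cfg)
  cg <- find_cgmuts(m$mutations)
  sd0 <- site_differences(cg, m$normal, m$tumor)
  expect_lt(abs(median(sd0$diff_nt)), 0.05)
  # ground truth round-trips: the planted sites are exactly the cgMut CpGs
  expect_equal(sort(cg$cpg_pos), sort(m$truth$cgmut_pos))
  expect_equal(nrow(cg), cfg$n_cgmuts)
})

test_that("a written synthetic dataset reproduces its stored ground truth", {
  dir <- tempfile("synthds")
  cfg <- small_cfg(17)
  files <- write_synth_dataset(cfg, dir)
  expect_true(all(file.exists(files)))
  truth <- jsonlite::read_json(files[["ground_truth"]], simplifyVector = TRUE)
  snps <- classify_snps(read_snp_tsv(files[["snps"]]))
  expect_identical(truth$cg_class[match(snps$snp_id, truth$snp_id)],
                   snps$cg_class)
  px <- annotate_proxies(snps, ld_index(read_ld_tsv(files[["ld"]])))
  expect_identical(truth$is_cgsnpt[match(px$snp_id, truth$snp_id)],
                   px$is_cgsnpt)
  # byte-identical regeneration under the same seed
  dir2 <- tempfile("synthds")
  files2 <- write_synth_dataset(cfg, dir2)
  for (f in names(files)) {
    expect_identical(readLines(files[[f]]), readLines(files2[[f]]),
                     label = paste("file", f))
  }
})
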