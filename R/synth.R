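#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the generator with defaults sized like the
#' study conditions the package is built for: a common-variant panel
#' with flanking context and partially missing ancestral alleles,
#' haplotype-block LD, outcome labels drawn from the logistic enrichment
#' model with planted coefficients, and a paired tumor/normal
#' whole-genome-bisulfite-like methylation pair with a planted reduction
#' at CpG-destroying mutations.
#'
#' @param seed integer seed; mandatory — every generator draw derives
#'   from it, there is no implicit randomness.
#' @param n_snps panel size (default 50000).
#' @param bp_per_snp mean SNP spacing in bp on the toy genome.
#' @param island_fraction fraction of the toy genome covered by CpG
#'   islands; `island_width` the island length in bp.
#' @param island_width,gene_width,gene_spacing toy-genome geometry, bp.
#' @param p_gc_island,p_gc_open per-base G+C probability of flanking
#'   sequence inside islands / in open sea.
#' @param cpg_prior_island,cpg_prior_open probability that an ancestral
#'   CpG overlapping the variant is planted, by region — elevated inside
#'   islands so CpG losses dominate there.
#' @param flank_len flank length emitted each side, bases.
#' @param ancestral_missing_rate fraction of records with unknown
#'   ancestral state.
#' @param maf_shape1,maf_shape2 Beta shape parameters; MAF is
#'   `0.5 * Beta(shape1, shape2)`. `maf_cg_shape1` replaces `maf_shape1`
#'   for cgSNPs, giving the mild MAF/cgSNP correlation that the
#'   confounder adjustment must absorb.
#' @param block_size,haplotype_pool_size,n_founders,founder_mutation_rate
#'   LD-block simulation: SNPs per block, haplotypes in the pool, founder
#'   haplotypes, per-site copying error.
#' @param beta0,beta_cgsnpt,beta_maf,beta_tags planted coefficients of
#'   the outcome model on the log-odds scale.
#' @param category_betas named vector of per-category cgSNPt log-odds
#'   replacing `beta_cgsnpt` for trait outcomes.
#' @param category_probs sampling weights of the trait categories.
#' @param n_cpg,meth_genome_size,n_cgmuts,n_noncg_muts methylation pair:
#'   CpG count, toy genome length, planted CpG-loss mutations, non-CpG
#'   decoy mutations.
#' @param meth_delta_mean,meth_delta_sd planted normal-minus-tumor
#'   reduction at cgMut sites (truncated to keep levels in \[0, 1\]).
#' @param meth_noise_sd tumor-vs-normal noise at unmutated CpGs.
#' @param normal_beta length-2 Beta parameters of normal-tissue levels.
#' @return a validated list of class `"synth_config"`.
#' @export
synth_config <- function(seed,
                         n_snps = 50000, bp_per_snp = 150,
                         island_fraction = 0.05, island_width = 1000,
                         gene_width = 3000, gene_spacing = 10000,
                         p_gc_island = 0.60, p_gc_open = 0.40,
                         cpg_prior_island = 0.30, cpg_prior_open = 0.08,
                         flank_len = 5,
                         ancestral_missing_rate = 0.02,
                         maf_shape1 = 1.2, maf_shape2 = 2.5,
                         maf_cg_shape1 = 0.9,
                         block_size = 20, haplotype_pool_size = 120,
                         n_founders = 4, founder_mutation_rate = 0.05,
                         beta0 = -4.0, beta_cgsnpt = log(1.5),
                         beta_maf = 0.5, beta_tags = 0.02,
                         category_betas = c(cancer = log(1.5),
                                            obesity = log(1.1),
                                            neurological = log(1.1)),
                         category_probs = c(cancer = 0.3, obesity = 0.3,
                                            neurological = 0.4),
                         n_cpg = 20000, meth_genome_size = 600000,
                         n_cgmuts = 53, n_noncg_muts = 50,
                         meth_delta_mean = 0.20, meth_delta_sd = 0.07,
                         meth_noise_sd = 0.03, normal_beta = c(6, 2)) {
  if (missing(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed is required", call. = FALSE)
  }
  cfg <- as.list(environment())
  probs <- c(cfg$island_fraction, cfg$p_gc_island, cfg$p_gc_open,
             cfg$cpg_prior_island, cfg$cpg_prior_open,
             cfg$ancestral_missing_rate, cfg$founder_mutation_rate,
             cfg$category_probs)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  counts <- c(cfg$n_snps, cfg$block_size, cfg$haplotype_pool_size,
              cfg$n_founders, cfg$n_cpg, cfg$n_cgmuts)
  if (any(counts < 1)) stop("counts must be positive", call. = FALSE)
  if (cfg$n_cgmuts > cfg$n_cpg) {
    stop("n_cgmuts exceeds the number of available CpGs", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

.sample_bases <- function(n, p_gc) {
  if (length(p_gc) > 1L) {        # per-element G+C probability
    gc <- runif(n) < p_gc
    out <- character(n)
    out[gc] <- sample(c("C", "G"), sum(gc), replace = TRUE)
    out[!gc] <- sample(c("A", "T"), sum(!gc), replace = TRUE)
    return(out)
  }
  p <- c((1 - p_gc) / 2, p_gc / 2, p_gc / 2, (1 - p_gc) / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = p)
}

.random_flank <- function(n, len, p_gc) {
  m <- matrix(.sample_bases(n * len, p_gc), nrow = n)
  apply(m, 1, paste, collapse = "")
}

#' Generate a synthetic SNP panel with flanking context
#'
#' Emits a SNP table on a single toy chromosome with flank composition
#' differing inside and outside CpG islands (elevated G+C and a higher
#' prior of an ancestral CpG overlapping the variant inside islands, so
#' CpG losses dominate there), an ancestral allele missing at the
#' configured rate, and MAF mildly correlated with cgSNP status. The
#' island and gene tracks of the toy genome are returned alongside.
#'
#' @param config a [synth_config()].
#' @return a list: `snps` (full SNP-table schema plus truth columns
#'   `cg_class`, `region`), `islands` and `genes` (`GRanges`),
#'   `genome_size`.
#' @export
generate_snp_panel <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_snps
  genome_size <- n * config$bp_per_snp
  n_islands <- max(1L, round(config$island_fraction * genome_size /
                               config$island_width))
  slot <- genome_size %/% n_islands
  island_start <- (seq_len(n_islands) - 1L) * slot +
    sample.int(max(1L, slot - config$island_width - 4000L), n_islands,
               replace = TRUE)
  islands <- GRanges("chr1", IRanges(start = island_start + 1L,
                                     width = config$island_width))
  n_genes <- max(1L, genome_size %/% config$gene_spacing)
  gene_start <- (seq_len(n_genes) - 1L) * (genome_size %/% n_genes) +
    sample.int(max(1L, genome_size %/% n_genes - config$gene_width),
               n_genes, replace = TRUE)
  genes <- GRanges("chr1", IRanges(start = gene_start + 1L,
                                   width = config$gene_width),
                   strand = sample(c("+", "-"), n_genes, replace = TRUE))

  pos <- sort(sample.int(genome_size, n)) - 1L
  in_island <- countOverlaps(.pos_to_gr("chr1", pos), islands) > 0
  p_gc <- ifelse(in_island, config$p_gc_island, config$p_gc_open)
  cpg_prior <- ifelse(in_island, config$cpg_prior_island,
                      config$cpg_prior_open)

  flank5 <- .random_flank(n, config$flank_len, config$p_gc_open)
  flank3 <- .random_flank(n, config$flank_len, config$p_gc_open)
  # region-specific immediate context
  left <- .sample_bases(n, p_gc)
  right <- .sample_bases(n, p_gc)
  anc <- .sample_bases(n, p_gc)
  plant <- runif(n) < cpg_prior
  orient_right <- runif(n) < 0.5
  anc[plant & orient_right] <- "C"
  right[plant & orient_right] <- "G"
  left[plant & !orient_right] <- "C"
  anc[plant & !orient_right] <- "G"
  der <- vapply(anc, function(a) sample(setdiff(DNA_BASES, a), 1L),
                character(1))
  substr(flank5, config$flank_len, config$flank_len) <- left
  substr(flank3, 1L, 1L) <- right

  swap <- runif(n) < 0.5   # allele order is arbitrary in the table
  snps <- data.table(
    snp_id = sprintf("rs%07d", seq_len(n)),
    chrom = "chr1", pos = pos, strand = "+",
    allele_a = ifelse(swap, der, anc),
    allele_b = ifelse(swap, anc, der),
    ancestral = ifelse(runif(n) < config$ancestral_missing_rate,
                       NA_character_, anc))
  snps <- classify_snps(cbind(snps, data.table(flank5 = flank5,
                                               flank3 = flank3)))
  is_cg <- snps$cg_class %in% CGSNP_CLASSES
  maf <- 0.5 * rbeta(n, config$maf_shape1, config$maf_shape2)
  maf[is_cg] <- 0.5 * rbeta(sum(is_cg), config$maf_cg_shape1,
                            config$maf_shape2)
  snps[, maf := maf]
  snps[, region := locate_region(chrom, pos, build_region_index(islands))]
  setcolorder(snps, c("snp_id", "chrom", "pos", "strand", "allele_a",
                      "allele_b", "ancestral", "maf", "flank5", "flank3",
                      "cg_class", "context_warning", "region"))
  list(snps = snps[], islands = islands, genes = genes,
       genome_size = genome_size)
}

#' Simulate LD blocks with exactly realisable r-squared
#'
#' SNPs are grouped into consecutive blocks; within each block a pool of
#' haplotypes is drawn from a handful of founder haplotypes with a small
#' per-site copying error, and every within-block pairwise r-squared is
#' computed from the pool's haplotype counts with
#' [r2_from_haplotype_counts()] — so every emitted value is realisable
#' and self-consistent by construction. Cross-block r-squared is 0 and
#' such pairs are not emitted. Sites monomorphic in the pool are
#' perturbed (one haplotype flipped) to keep both alleles present.
#'
#' @param panel output of [generate_snp_panel()] (or any SNP table sorted
#'   by position).
#' @param config a [synth_config()].
#' @return a `data.table` of LD pairs: `snp_a`, `snp_b`, `r2`.
#' @export
generate_ld_blocks <- function(panel, config) {
  stopifnot(inherits(config, "synth_config"))
  snps <- if (is.list(panel) && !is.data.frame(panel)) panel$snps else panel
  set.seed(config$seed + 1L)
  ids <- as.character(snps$snp_id)
  n <- length(ids)
  block_of <- ceiling(seq_len(n) / config$block_size)
  H <- config$haplotype_pool_size
  out <- vector("list", max(block_of))
  for (b in seq_len(max(block_of))) {
    members <- ids[block_of == b]
    m <- length(members)
    if (m < 2L) next
    founders <- matrix(rbinom(config$n_founders * m, 1L, 0.5),
                       nrow = config$n_founders)
    pick <- sample.int(config$n_founders, H, replace = TRUE)
    X <- founders[pick, , drop = FALSE]
    flip <- matrix(runif(H * m) < config$founder_mutation_rate, nrow = H)
    X[flip] <- 1L - X[flip]
    mono <- which(colSums(X) %in% c(0L, H))
    for (j in mono) X[sample.int(H, 1L), j] <- 1L - X[1L, j]
    pairs <- which(upper.tri(diag(m)), arr.ind = TRUE)
    n11 <- crossprod(X)
    cs <- colSums(X)
    i <- pairs[, 1]; j <- pairs[, 2]
    nAB <- n11[cbind(i, j)]
    nAb <- cs[i] - nAB
    naB <- cs[j] - nAB
    nab <- H - nAB - nAb - naB
    out[[b]] <- data.table(snp_a = members[i], snp_b = members[j],
                           r2 = r2_from_haplotype_counts(nAB, nAb, naB, nab))
  }
  rbindlist(out)
}

#' Simulate a proxy panel at the covariate level
#'
#' A lightweight generator for model-recovery experiments: per-proxy MAF,
#' tag count and cgSNPt status with the mild MAF/cgSNPt correlation of
#' the sequence-level generator, without flanking sequence or LD files.
#'
#' @param n number of proxies.
#' @param seed integer seed.
#' @param tag_rate Poisson mean of the tag count.
#' @param cgsnpt_intercept,cgsnpt_maf_slope logistic coefficients of
#'   cgSNPt status on MAF.
#' @return a `data.table` with `snp_id`, `is_cgsnpt`, `n_tagged`, `maf`.
#' @export
simulate_proxy_panel <- function(n, seed, tag_rate = 3,
                                 cgsnpt_intercept = -0.2,
                                 cgsnpt_maf_slope = 1.2) {
  set.seed(seed)
  maf <- 0.5 * rbeta(n, 1.2, 2.5)
  data.table(
    snp_id = sprintf("px%07d", seq_len(n)),
    is_cgsnpt = runif(n) < plogis(cgsnpt_intercept + cgsnpt_maf_slope * maf),
    n_tagged = rpois(n, tag_rate),
    maf = maf)
}

#' Plant outcome labels from the logistic enrichment model
#'
#' Draws outcome membership `y ~ Bernoulli(logit^-1(b0 + b_cgsnpt X +
#' b_maf MAF + b_tags tags))` over a proxy panel. For trait outcomes each
#' proxy is assigned a candidate category whose planted log-odds replaces
#' `b_cgsnpt` (e.g. a larger cancer effect), and positives receive a
#' synthetic reported p-value drawn per reported-p bin — those p-values
#' exist only to exercise the binning logic, they are not test
#' statistics.
#'
#' @param proxies proxy annotation table (`snp_id`, `is_cgsnpt`,
#'   `n_tagged`, `maf`).
#' @param config a [synth_config()].
#' @param type `"eqtl"` or `"trait"`.
#' @param seed optional integer overriding the config-derived seed.
#' @return a list: `outcomes` (positives only: `snp_id`, `outcome`,
#'   `trait`, `category`, `reported_p`), `y` (full 0/1 vector in proxy
#'   order), `betas` (the planted coefficients used per proxy).
#' @export
plant_outcomes <- function(proxies, config, type = c("eqtl", "trait"),
                           seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  type <- match.arg(type)
  set.seed(if (is.null(seed)) config$seed + 2L else seed)
  px <- as.data.table(proxies)
  n <- nrow(px)
  if (type == "trait") {
    cats <- sample(names(config$category_betas), n, replace = TRUE,
                   prob = config$category_probs[names(config$category_betas)])
    b_cg <- unname(config$category_betas[cats])
  } else {
    cats <- rep(NA_character_, n)
    b_cg <- rep(config$beta_cgsnpt, n)
  }
  lp <- config$beta0 + b_cg * as.integer(px$is_cgsnpt) +
    config$beta_maf * px$maf + config$beta_tags * px$n_tagged
  y <- as.integer(runif(n) < plogis(lp))
  pos <- which(y == 1L)
  edges <- c(5, 6, 7, 8, 11, 14, 17, 20, 25)
  bin <- sample.int(8L, length(pos), replace = TRUE)
  rp <- 10^-runif(length(pos), edges[bin], edges[bin + 1L])
  outcomes <- data.table(
    snp_id = px$snp_id[pos],
    outcome = type,
    trait = if (type == "trait") paste0(cats[pos], "_trait") else "expression",
    category = cats[pos],
    reported_p = rp)
  list(outcomes = outcomes, y = y,
       betas = list(beta0 = config$beta0, beta_cgsnpt_by_snp = b_cg,
                    beta_maf = config$beta_maf, beta_tags = config$beta_tags,
                    category = cats))
}

#' Generate a paired normal/tumor methylation set with planted cgMut effects
#'
#' Places CpG cytosines on a toy chromosome, draws normal-tissue levels
#' from a Beta distribution, and sets tumor levels equal to normal plus
#' small noise — except at `n_cgmuts` randomly chosen CpG-destroying
#' mutation sites, where the tumor level is reduced by a
#' `Normal(meth_delta_mean, meth_delta_sd)` draw (levels truncated to
#' \[0, 1\]). A decoy set of non-CpG mutations is emitted alongside to
#' exercise cgMut filtering.
#'
#' @param config a [synth_config()].
#' @return a list: `normal` and `tumor` tracks (`chrom`, `pos` 0-based,
#'   `level`), `mutations` (`chrom`, `pos`, `ref`, `alt`, `flank5`,
#'   `flank3`), `truth` (`cgmut_pos`, `delta`).
#' @export
generate_methylation_pair <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 3L)
  n <- config$n_cpg
  pos <- sort(sample.int(config$meth_genome_size %/% 2L, n)) * 2L
  normal <- rbeta(n, config$normal_beta[1], config$normal_beta[2])
  tumor <- pmin(1, pmax(0, normal + rnorm(n, 0, config$meth_noise_sd)))

  mut_idx <- sort(sample.int(n, config$n_cgmuts))
  delta <- rnorm(config$n_cgmuts, config$meth_delta_mean,
                 config$meth_delta_sd)
  tumor[mut_idx] <- pmin(1, pmax(0, normal[mut_idx] - delta))

  flank_len <- config$flank_len
  cg_muts <- data.table(
    chrom = "chr1", pos = pos[mut_idx],
    ref = "C",
    alt = sample(c("A", "T"), config$n_cgmuts, replace = TRUE),
    flank5 = .random_flank(config$n_cgmuts, flank_len, 0.4),
    flank3 = paste0("G", .random_flank(config$n_cgmuts, flank_len - 1L, 0.4)))
  # decoys: A>T far from any planted CpG orientation, never CpG-related
  nd <- config$n_noncg_muts
  decoy_pos <- sort(sample.int(config$meth_genome_size %/% 2L, nd)) * 2L - 1L
  decoys <- data.table(
    chrom = "chr1", pos = decoy_pos, ref = "A",
    alt = sample(c("T", "C"), nd, replace = TRUE),
    flank5 = paste0(.random_flank(nd, flank_len - 1L, 0.4), "T"),
    flank3 = paste0("A", .random_flank(nd, flank_len - 1L, 0.4)))
  decoys[alt == "C", alt := "T"]  # keep decoys strictly non-CpG
  mutations <- rbind(cg_muts, decoys)
  setorder(mutations, chrom, pos)
  list(normal = data.table(chrom = "chr1", pos = pos, level = normal),
       tumor = data.table(chrom = "chr1", pos = pos, level = tumor),
       mutations = mutations,
       truth = data.table(cgmut_pos = pos[mut_idx], delta = delta))
}
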