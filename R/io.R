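#' Read and write the tab-separated SNP table
#'
#' The on-disk schema (header required) is: `snp_id`, `chrom`, `pos`
#' (1-based), `strand`, `allele_a`, `allele_b`, `ancestral` (`"."` when
#' missing), `maf`, `flank5`, `flank3`; the writer emits any additional
#' columns (e.g. `cg_class`, `region`) unchanged. Internally positions
#' are 0-based; the 1-based shift happens only at this boundary.
#'
#' Rows violating the biallelic-substitution contract — alleles not
#' single A/C/G/T bases, identical alleles, an ancestral base matching
#' neither allele, or MAF outside \[0, 0.5\] — are rejected with a counted
#' skip naming the first offending line numbers. The record set the
#' analysis sees is therefore always clean.
#'
#' @param path file path.
#' @return `read_snp_tsv()`: a `data.table` with 0-based `pos` and `NA`
#'   ancestral for missing; skip counts in the `n_skipped` attribute.
#' @export
read_snp_tsv <- function(path) {
  required <- c("snp_id", "chrom", "pos", "strand", "allele_a", "allele_b",
                "ancestral", "maf", "flank5", "flank3")
  dt <- fread(path, sep = "\t", colClasses = list(character = "chrom"))
  miss <- setdiff(required, names(dt))
  if (length(miss)) {
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dt[, ancestral := ifelse(ancestral %in% c(".", ""), NA_character_,
                           as.character(ancestral))]
  bad <- !(dt$allele_a %in% DNA_BASES) | !(dt$allele_b %in% DNA_BASES) |
    dt$allele_a == dt$allele_b |
    (!is.na(dt$ancestral) & dt$ancestral != dt$allele_a &
       dt$ancestral != dt$allele_b) |
    !is.finite(dt$maf) | dt$maf < 0 | dt$maf > 0.5
  if (any(bad)) {
    lines <- which(bad) + 1L  # header is line 1
    message("read_snp_tsv: skipped ", sum(bad), " malformed row(s), e.g. ",
            "line(s) ", paste(head(lines, 5), collapse = ", "))
    dt <- dt[!bad]
  }
  dt[, pos := as.integer(pos) - 1L]
  setattr(dt, "n_skipped", sum(bad))
  dt[]
}

#' @rdname read_snp_tsv
#' @param snps SNP table with 0-based `pos`.
#' @export
write_snp_tsv <- function(snps, path) {
  out <- copy(as.data.table(snps))
  out[, pos := as.integer(pos) + 1L]
  out[, ancestral := ifelse(is.na(ancestral), ".", ancestral)]
  fwrite(out, path, sep = "\t", na = "NA")
  invisible(path)
}

#' Read a BED interval track
#'
#' BED is 0-based half-open on disk; the returned `GRanges` follows the
#' usual 1-based closed convention. Zero- or negative-width records are
#' rejected with their record numbers; with `require_strand = TRUE`
#' (gene tracks) every record must carry `+` or `-`.
#'
#' @param path BED file path.
#' @param require_strand logical; demand 6-column BED with strand.
#' @return a `GRanges`.
#' @export
read_bed <- function(path, require_strand = FALSE) {
  raw <- fread(path, header = FALSE, select = 2:3,
               col.names = c("start", "end"))
  if (any(raw$start >= raw$end)) {
    stop("BED record(s) with start >= end at line ",
         paste(head(which(raw$start >= raw$end), 5), collapse = ", "),
         " in ", path, call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "BED")
  if (require_strand && any(as.character(strand(gr)) == "*")) {
    stop("BED track ", path, " must carry strand (6 columns)",
         call. = FALSE)
  }
  gr
}

#' @rdname read_bed
#' @param gr a `GRanges` to write.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a PLINK-style LD pair table
#'
#' Tolerant of the PLINK `--r2` column layout: the columns `SNP_A`,
#' `SNP_B`, `R2` are picked out case-insensitively and any others
#' (CHR_A, BP_A, ...) are ignored. Reversed duplicate pairs collapse to
#' one symmetric entry when the index is built.
#'
#' @param path file path (whitespace- or tab-separated, header required).
#' @return a `data.table` with columns `snp_a`, `snp_b`, `r2`.
#' @export
read_ld_tsv <- function(path) {
  dt <- fread(path)
  nm <- toupper(names(dt))
  pick <- function(col) {
    i <- match(col, nm)
    if (is.na(i)) stop("missing required column '", col, "' in ", path,
                       call. = FALSE)
    dt[[i]]
  }
  data.table(snp_a = as.character(pick("SNP_A")),
             snp_b = as.character(pick("SNP_B")),
             r2 = as.numeric(pick("R2")))
}

#' @rdname read_ld_tsv
#' @param pairs LD pair table.
#' @export
write_ld_tsv <- function(pairs, path) {
  out <- as.data.table(pairs)[, .(SNP_A = snp_a, SNP_B = snp_b, R2 = r2)]
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read and write outcome tables (eQTL / trait-associated labels)
#'
#' Schema: `snp_id`, `outcome` (`eqtl` or `trait`), `trait`, `category`,
#' `reported_p`. Membership in the table marks a SNP outcome-positive.
#'
#' @param path file path.
#' @return a `data.table`.
#' @export
read_outcome_tsv <- function(path) {
  dt <- fread(path, sep = "\t")
  need <- c("snp_id", "outcome", "trait", "category", "reported_p")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(dt$reported_p) &
          (dt$reported_p <= 0 | dt$reported_p > 1))) {
    stop("reported_p outside (0, 1] in ", path, call. = FALSE)
  }
  dt[, snp_id := as.character(snp_id)]
  dt[]
}

#' @rdname read_outcome_tsv
#' @param outcomes outcome table.
#' @export
write_outcome_tsv <- function(outcomes, path) {
  fwrite(as.data.table(outcomes), path, sep = "\t", na = "NA")
  invisible(path)
}

#' Read and write methylation tracks
#'
#' bedGraph-like three-column TSV with header: `chrom`, `pos` (1-based
#' position of the CpG cytosine on disk; 0-based in memory), `level` in
#' \[0, 1\].
#'
#' @param path file path.
#' @return a `data.table` with 0-based `pos`.
#' @export
read_meth_tsv <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = list(character = "chrom"))
  need <- c("chrom", "pos", "level")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(dt$level < 0 | dt$level > 1)) {
    stop("methylation level outside [0, 1] in ", path, call. = FALSE)
  }
  dt[, pos := as.integer(pos) - 1L]
  dt[]
}

#' @rdname read_meth_tsv
#' @param track methylation track with 0-based `pos`.
#' @export
write_meth_tsv <- function(track, path) {
  out <- copy(as.data.table(track))
  out[, pos := as.integer(pos) + 1L]
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read and write mutation tables
#'
#' Schema: `chrom`, `pos` (1-based on disk), `ref`, `alt`, `flank5`,
#' `flank3`.
#'
#' @param path file path.
#' @return a `data.table` with 0-based `pos`.
#' @export
read_mutation_tsv <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = list(character = "chrom"))
  need <- c("chrom", "pos", "ref", "alt", "flank5", "flank3")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dt[, pos := as.integer(pos) - 1L]
  dt[]
}

#' @rdname read_mutation_tsv
#' @param mutations mutation table with 0-based `pos`.
#' @export
write_mutation_tsv <- function(mutations, path) {
  out <- copy(as.data.table(mutations))
  out[, pos := as.integer(pos) + 1L]
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write a full synthetic dataset to disk
#'
#' Runs every generator and emits the SNP table, island and gene BED
#' tracks, LD pair table, eQTL and trait outcome tables, methylation
#' tracks and mutation list, plus a `ground_truth.json` with the planted
#' parameters and per-SNP truth needed to verify any downstream stage.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_synth_dataset <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)

  panel <- generate_snp_panel(config)
  ld <- generate_ld_blocks(panel, config)
  proxies <- annotate_proxies(panel$snps, ld_index(ld))
  eqtl <- plant_outcomes(proxies, config, type = "eqtl",
                         seed = config$seed + 2L)
  trait <- plant_outcomes(proxies, config, type = "trait",
                          seed = config$seed + 4L)
  meth <- generate_methylation_pair(config)

  write_snp_tsv(panel$snps[, .(snp_id, chrom, pos, strand, allele_a,
                               allele_b, ancestral, maf, flank5, flank3)],
                p("snps.tsv"))
  write_bed(panel$islands, p("islands.bed"))
  write_bed(panel$genes, p("genes.bed"))
  write_ld_tsv(ld, p("ld.tsv"))
  write_outcome_tsv(eqtl$outcomes, p("eqtl.tsv"))
  write_outcome_tsv(trait$outcomes, p("trait.tsv"))
  write_meth_tsv(meth$normal, p("meth_normal.tsv"))
  write_meth_tsv(meth$tumor, p("meth_tumor.tsv"))
  write_mutation_tsv(meth$mutations, p("mutations.tsv"))
  truth <- list(
    seed = config$seed,
    planted = list(beta0 = config$beta0, beta_cgsnpt = config$beta_cgsnpt,
                   beta_maf = config$beta_maf, beta_tags = config$beta_tags,
                   category_betas = as.list(config$category_betas),
                   meth_delta_mean = config$meth_delta_mean),
    snp_id = panel$snps$snp_id,
    cg_class = panel$snps$cg_class,
    is_cgsnpt = proxies$is_cgsnpt[match(panel$snps$snp_id, proxies$snp_id)],
    cgmut_pos = meth$truth$cgmut_pos,
    cgmut_delta = meth$truth$delta)
  jsonlite::write_json(truth, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- c(snps = p("snps.tsv"), islands = p("islands.bed"),
             genes = p("genes.bed"), ld = p("ld.tsv"),
             eqtl = p("eqtl.tsv"), trait = p("trait.tsv"),
             meth_normal = p("meth_normal.tsv"),
             meth_tumor = p("meth_tumor.tsv"),
             mutations = p("mutations.tsv"),
             ground_truth = p("ground_truth.json"))
  invisible(files)
}
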