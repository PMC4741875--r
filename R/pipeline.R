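#' Run the cgSNP enrichment pipeline end to end
#'
#' classify -> annotate -> tag -> prune -> enrich (+ optional methdiff),
#' reading every input from disk and writing per-threshold result sets.
#' Each stage logs its row counts (read, skipped, per-class, retained)
#' via `message()`, and the whole run is deterministic given `seed`:
#' rerunning with the same inputs and seed reproduces the results JSON
#' byte for byte.
#'
#' @param snps path to the SNP TSV (schema of [read_snp_tsv()]).
#' @param islands,genes paths to BED tracks (`genes` optional).
#' @param ld path to the LD pair TSV.
#' @param outcomes path to an outcome TSV (eQTL or trait labels).
#' @param normal,tumor,mutations optional paths for the methylation
#'   stage; all three must be given together.
#' @param out_dir output directory.
#' @param tag_r2 tagging / sharing threshold on r-squared.
#' @param prune_r2 one or more pruning thresholds; one result set is
#'   written per value (sensitivity analysis).
#' @param index_size size of the top-signal index set for the matched
#'   resampling test.
#' @param n_draws matched draws.
#' @param seed integer seed (required).
#' @param shore_width,promoter_width annotation widths in bp.
#' @return invisibly, a list with one element per pruning threshold
#'   (`enrichment`, `simulation`, `n_proxies`) plus `methylation` when
#'   the methylation inputs were given. Also written as
#'   `results.json` in `out_dir`.
#' @export
run_pipeline <- function(snps, islands, ld, outcomes,
                         genes = NULL, normal = NULL, tumor = NULL,
                         mutations = NULL, out_dir,
                         tag_r2 = 0.8, prune_r2 = 0.8,
                         index_size = 500, n_draws = 300, seed,
                         shore_width = 2000, promoter_width = 2000) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  snp_dt <- read_snp_tsv(snps)
  message("pipeline: read ", nrow(snp_dt), " SNPs (",
          attr(snp_dt, "n_skipped"), " skipped)")
  snp_dt <- classify_snps(snp_dt)
  tab <- table(snp_dt$cg_class)
  message("pipeline: classified — ",
          paste(names(tab), as.integer(tab), sep = "=", collapse = ", "))

  island_gr <- read_bed(islands)
  gene_gr <- if (!is.null(genes)) read_bed(genes, require_strand = TRUE)
  snp_dt <- annotate_snps(snp_dt, island_gr, gene_gr,
                          shore_width = shore_width,
                          promoter_width = promoter_width)
  write_snp_tsv(snp_dt, file.path(out_dir, "classified.tsv"))

  idx <- ld_index(read_ld_tsv(ld))
  proxies_all <- annotate_proxies(snp_dt, idx, threshold = tag_r2)
  outcome_dt <- read_outcome_tsv(outcomes)

  setorder(snp_dt, chrom, pos, snp_id)
  results <- list()
  for (thr in prune_r2) {
    kept <- ld_prune(snp_dt$snp_id, idx, threshold = thr)
    proxies <- proxies_all[snp_id %in% kept]
    message("pipeline: prune r2=", thr, " retained ", nrow(proxies),
            " of ", nrow(proxies_all), " proxies")
    frame <- .enrichment_frame(proxies)
    frame[, y := as.integer(snp_id %in% outcome_dt$snp_id)]
    enr <- fit_enrichment_model(frame)

    proxies[, stratum := assign_strata(proxies)]
    pos_dt <- outcome_dt[snp_id %in% proxies$snp_id]
    setorder(pos_dt, reported_p, snp_id)
    index_ids <- head(unique(pos_dt$snp_id), index_size)
    sim <- matched_simulation_test(index_ids, proxies, n_draws = n_draws,
                                   seed = seed)
    message("pipeline: strata in use ", length(unique(proxies$stratum)),
            "; index ", length(index_ids), "; observed cgSNPts ",
            sim$observed_count, "; empirical p ", sim$p_label)
    results[[paste0("r2_", thr)]] <- list(
      threshold = thr, n_proxies = nrow(proxies),
      enrichment = unclass(enr),
      simulation = list(observed_count = sim$observed_count,
                        empirical_p = sim$empirical_p,
                        p_label = sim$p_label, n_draws = sim$n_draws,
                        index_size = sim$index_size,
                        null_counts = sim$null_counts))
  }

  if (!is.null(normal) || !is.null(tumor) || !is.null(mutations)) {
    if (is.null(normal) || is.null(tumor) || is.null(mutations)) {
      stop("normal, tumor and mutations must be given together",
           call. = FALSE)
    }
    cgmuts <- find_cgmuts(read_mutation_tsv(mutations))
    nt <- read_meth_tsv(normal)
    tt <- read_meth_tsv(tumor)
    message("pipeline: ", nrow(cgmuts), " cgMuts")
    summary_bins <- bin_nearby(cgmuts, nt, tt)
    fwrite(summary_bins, file.path(out_dir, "methdiff.tsv"), sep = "\t")
    results$methylation <- summary_bins
  }

  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
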