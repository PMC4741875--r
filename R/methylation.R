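#' Identify CpG-abolishing somatic mutations (cgMuts)
#'
#' Classifies each substitution with the reference allele as the initial
#' state and keeps those classified `CG_LOSS` — mutations that destroy a
#' CpG present in the reference (normal) sequence. The position of the
#' destroyed CpG's cytosine is recorded: the mutated base itself when the
#' mutation hits the C of the CpG, or one base to the left when it hits
#' the G. Mutations with unresolvable context are skipped with a warning;
#' an optional interval restriction (e.g. exons) is applied.
#'
#' @param mutations data.frame with columns `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `flank5`, `flank3`.
#' @param restrict_to optional `GRanges`; mutations outside it are dropped.
#' @return a `data.table` of cgMuts with added columns `cg_class`
#'   (all `CG_LOSS`) and `cpg_pos` (0-based position of the CpG cytosine).
#' @export
find_cgmuts <- function(mutations, restrict_to = NULL) {
  dt <- as.data.table(mutations)
  need <- c("chrom", "pos", "ref", "alt", "flank5", "flank3")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(restrict_to)) {
    stopifnot(is(restrict_to, "GRanges"))
    keep <- countOverlaps(.pos_to_gr(dt$chrom, dt$pos), restrict_to) > 0
    dt <- dt[keep]
  }
  if (nrow(dt) == 0L) return(dt[, `:=`(cg_class = character(0),
                                       cpg_pos = integer(0))][])
  cls <- classify_snps(dt[, .(allele_a = ref, allele_b = alt,
                              ancestral = ref, flank5, flank3)])
  if (any(cls$context_warning)) {
    warning(sum(cls$context_warning),
            " mutation(s) with unresolvable context skipped", call. = FALSE)
  }
  dt[, cg_class := cls$cg_class]
  out <- dt[cg_class == "CG_LOSS"]
  if (nrow(out) == 0L) return(out[, cpg_pos := integer(0)][])
  # cytosine of the lost CpG: at the variant when ref C is followed by G,
  # one base 5' when ref G is preceded by C
  right <- toupper(substr(out$flank3, 1L, 1L))
  out[, cpg_pos := ifelse(ref == "C" & right == "G", pos, pos - 1L)]
  out[]
}

.meth_key <- function(track) {
  dt <- as.data.table(track)
  stopifnot(all(c("chrom", "pos", "level") %in% names(dt)))
  if (any(dt$level < 0 | dt$level > 1)) {
    stop("methylation levels must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(dt[, .(chrom, pos)])) {
    stop("duplicate CpG positions in methylation track", call. = FALSE)
  }
  setkey(dt, chrom, pos)
  dt
}

#' Normal-minus-tumor methylation difference at cgMut CpG sites
#'
#' For each cgMut, looks up the methylation level of the destroyed CpG's
#' cytosine in the paired tracks and returns `normal - tumor`. Sites
#' absent from the normal track are skipped with a warning; sites absent
#' from the tumor track are dropped and counted in the `n_dropped_tumor`
#' attribute.
#'
#' @param cgmuts output of [find_cgmuts()].
#' @param normal,tumor methylation tracks: data.frames with `chrom`,
#'   `pos` (0-based CpG cytosine), `level` in \[0, 1\].
#' @return a `data.table` with `chrom`, `cpg_pos`, `normal`, `tumor`,
#'   `diff_nt` (= normal - tumor).
#' @export
site_differences <- function(cgmuts, normal, tumor) {
  mu <- as.data.table(cgmuts)
  nt <- .meth_key(normal)
  tt <- .meth_key(tumor)
  q <- mu[, .(chrom, pos = cpg_pos)]
  n_lev <- nt[q, level]
  if (any(is.na(n_lev))) {
    warning(sum(is.na(n_lev)),
            " cgMut site(s) absent from the normal track skipped",
            call. = FALSE)
  }
  t_lev <- tt[q, level]
  keep <- !is.na(n_lev)
  dropped_tumor <- sum(keep & is.na(t_lev))
  keep <- keep & !is.na(t_lev)
  out <- data.table(chrom = q$chrom[keep], cpg_pos = q$pos[keep],
                    normal = n_lev[keep], tumor = t_lev[keep])
  out[, diff_nt := normal - tumor]
  setattr(out, "n_dropped_tumor", dropped_tumor)
  out[]
}

#' Percentile summary of methylation differences
#'
#' Reports the 10th/25th/50th/75th/90th percentiles (linear interpolation
#' between order statistics) and the fraction of sites with higher
#' methylation in normal than tumor.
#'
#' @param differences numeric vector of normal-minus-tumor differences.
#' @return one-row `data.table`: `n_sites`, `p10`, `p25`, `p50`, `p75`,
#'   `p90`, `frac_normal_higher`.
#' @export
summarize_distribution <- function(differences) {
  if (length(differences) == 0L) {
    stop("empty summary: no differences supplied", call. = FALSE)
  }
  qs <- quantile(differences, c(0.10, 0.25, 0.50, 0.75, 0.90),
                 names = FALSE, type = 7)
  data.table(n_sites = length(differences),
             p10 = qs[1], p25 = qs[2], p50 = qs[3], p75 = qs[4], p90 = qs[5],
             frac_normal_higher = mean(differences > 0))
}

#' Methylation differences at cgMut sites and in distance annuli
#'
#' The cgMut CpG itself forms the `SITE` bin; every other CpG present in
#' both tracks is assigned — by its distance in bp to the nearest cgMut
#' cytosine — to one of the half-open annuli `(0, 10]`, `(10, 50]`,
#' `(50, 100]`, `(100, 500]`, `(500, 1000]`, `(1000, 2000]` (defaults) and
#' summarised per bin. Sites beyond the last edge are excluded.
#'
#' @param cgmuts output of [find_cgmuts()].
#' @param normal,tumor paired methylation tracks.
#' @param edges increasing annulus outer radii in bp.
#' @return a `data.table`, one row per non-empty bin (ordered SITE then
#'   increasing distance), with the columns of [summarize_distribution()]
#'   plus `bin`.
#' @export
bin_nearby <- function(cgmuts, normal, tumor,
                       edges = c(10, 50, 100, 500, 1000, 2000)) {
  if (is.unsorted(edges, strictly = TRUE) || any(edges <= 0)) {
    stop("annulus edges must be positive and strictly increasing",
         call. = FALSE)
  }
  mu <- as.data.table(cgmuts)
  nt <- .meth_key(normal)
  tt <- .meth_key(tumor)
  # intersection of the two tracks
  both <- nt[tt, .(chrom, pos, normal = level, tumor = i.level), nomatch = NULL]
  # distance in bp between CpG cytosine positions (rolling-nearest join;
  # NA on chromosomes without any cgMut)
  mu_pos <- data.table(chrom = mu$chrom, pos = mu$cpg_pos, mpos = mu$cpg_pos)
  setkey(mu_pos, chrom, pos)
  nearest <- mu_pos[both[, .(chrom, pos)], roll = "nearest"]
  both[, dist_bp := abs(pos - nearest$mpos)]
  both[, diff_nt := normal - tumor]

  labels <- c("SITE", paste0("±", edges))
  bins <- rep(NA_character_, nrow(both))
  bins[!is.na(both$dist_bp) & both$dist_bp == 0] <- "SITE"
  ann <- !is.na(both$dist_bp) & both$dist_bp > 0 & both$dist_bp <= max(edges)
  bins[ann] <- labels[-1][findInterval(both$dist_bp[ann], c(0, edges),
                                       left.open = TRUE)]
  both[, bin := factor(bins, levels = labels)]
  out <- both[!is.na(bin), summarize_distribution(diff_nt), by = bin]
  setorder(out, bin)
  out[]
}
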