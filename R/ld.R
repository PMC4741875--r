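#' Squared allelic correlation from two-locus haplotype counts
#'
#' Standard r-squared: with haplotype frequencies `p_AB` etc. and allele
#' frequencies `p_A = p_AB + p_Ab` (and so on), `D = p_AB - p_A p_B` and
#' `r2 = D^2 / (p_A p_a p_B p_b)`.
#'
#' @param n_AB,n_Ab,n_aB,n_ab non-negative haplotype counts (vectorised).
#' @return numeric vector of r-squared values in \[0, 1\].
#' @examples
#' r2_from_haplotype_counts(50, 0, 0, 50)   # 1: perfect coupling
#' r2_from_haplotype_counts(25, 25, 25, 25) # 0: independence
#' @export
r2_from_haplotype_counts <- function(n_AB, n_Ab, n_aB, n_ab) {
  n <- n_AB + n_Ab + n_aB + n_ab
  if (any(n <= 0)) stop("total haplotype count must be positive", call. = FALSE)
  p_AB <- n_AB / n
  p_A <- (n_AB + n_Ab) / n
  p_B <- (n_AB + n_aB) / n
  denom <- p_A * (1 - p_A) * p_B * (1 - p_B)
  if (any(denom == 0)) {
    stop("undefined LD: at least one locus is monomorphic in the counts",
         call. = FALSE)
  }
  D <- p_AB - p_A * p_B
  pmin(1, D^2 / denom)
}

#' Build a symmetric LD index from pairwise r-squared records
#'
#' Stores the symmetric closure of the loaded pairs as an adjacency table;
#' a pair absent from the index has r-squared 0. Reversed duplicate rows
#' (b, a) collapse onto (a, b); conflicting r2 for the same pair keep the
#' maximum.
#'
#' @param pairs a data.frame with columns `snp_a`, `snp_b`, `r2` (the
#'   layout produced by [read_ld_tsv()]).
#' @return an object of class `"ld_index"`.
#' @export
ld_index <- function(pairs) {
  dt <- as.data.table(pairs)[, .(snp_a = as.character(snp_a),
                                 snp_b = as.character(snp_b),
                                 r2 = as.numeric(r2))]
  if (any(is.na(dt$r2)) || any(dt$r2 < 0 | dt$r2 > 1)) {
    stop("r2 values must lie in [0, 1]", call. = FALSE)
  }
  if (any(dt$snp_a == dt$snp_b)) {
    stop("self pairs are not allowed in an LD index", call. = FALSE)
  }
  # canonical orientation, drop duplicates, then mirror
  canon <- dt[, .(snp_a = pmin(snp_a, snp_b), snp_b = pmax(snp_a, snp_b), r2)]
  canon <- canon[, .(r2 = max(r2)), by = .(snp_a, snp_b)]
  adj <- rbind(canon,
               canon[, .(snp_a = snp_b, snp_b = snp_a, r2)])
  setkey(adj, snp_a)
  structure(list(adj = adj, n_pairs = nrow(canon)), class = "ld_index")
}

#' @export
print.ld_index <- function(x, ...) {
  cat("ld_index:", x$n_pairs, "pairs,",
      length(unique(x$adj$snp_a)), "SNPs\n")
  invisible(x)
}

.neighbors <- function(index, ids, threshold) {
  stopifnot(inherits(index, "ld_index"))
  index$adj[.(as.character(ids)), nomatch = NULL][r2 > threshold]
}

#' Number of SNPs tagged by each proxy SNP
#'
#' Counts distinct other SNPs in LD with the query at r-squared strictly
#' greater than `threshold`. The proxy itself is never counted. Unknown
#' ids get 0 with a warning.
#'
#' @param snp_ids character vector of query ids.
#' @param index an [ld_index()].
#' @param threshold tagging threshold on r-squared (strict inequality).
#' @return integer vector of tag counts, one per query.
#' @export
tag_count <- function(snp_ids, index, threshold = 0.8) {
  snp_ids <- as.character(snp_ids)
  known <- unique(index$adj$snp_a)
  if (any(!snp_ids %in% known)) {
    warning(sum(!snp_ids %in% known),
            " id(s) absent from the LD index given tag count 0",
            call. = FALSE)
  }
  nb <- .neighbors(index, snp_ids, threshold)
  counts <- nb[, .(n = uniqueN(snp_b)), by = snp_a]
  out <- integer(length(snp_ids))
  m <- match(snp_ids, counts$snp_a)
  out[!is.na(m)] <- counts$n[m[!is.na(m)]]
  out
}

#' cgSNPt status: cgSNP or tagging at least one cgSNP
#'
#' A proxy SNP is a cgSNPt when it is itself a cgSNP (class `CG_GAIN`,
#' `CG_LOSS` or `CG_UNORIENTED`) or is in LD (r-squared strictly above
#' `threshold`) with at least one cgSNP.
#'
#' @param snp_ids character vector of query ids.
#' @param cg_classes named character vector (or data.frame with `snp_id`,
#'   `cg_class`) giving the cgSNP class of every SNP in the panel.
#' @param index an [ld_index()].
#' @param threshold sharing threshold on r-squared.
#' @return logical vector, one per query.
#' @export
cgsnpt_status <- function(snp_ids, cg_classes, index, threshold = 0.8) {
  snp_ids <- as.character(snp_ids)
  if (is.data.frame(cg_classes)) {
    cg_classes <- setNames(cg_classes$cg_class, cg_classes$snp_id)
  }
  is_cg <- function(ids) {
    cls <- cg_classes[ids]
    !is.na(cls) & cls %in% CGSNP_CLASSES
  }
  out <- is_cg(snp_ids)
  todo <- snp_ids[!out]
  if (length(todo)) {
    nb <- .neighbors(index, todo, threshold)
    if (nrow(nb)) {
      tagged_cg <- nb[is_cg(snp_b), unique(snp_a)]
      out[!out] <- todo %in% tagged_cg
    }
  }
  unname(out)
}

#' Greedy LD pruning
#'
#' Scans SNPs in the supplied order (use genome order: chrom, pos, id for
#' determinism) and retains a SNP iff its r-squared with every
#' already-retained SNP is at most `threshold`. The result is a maximal
#' set under the greedy order: every removed SNP exceeds the threshold
#' with some retained SNP.
#'
#' @param snp_ids character vector in the deterministic scan order.
#' @param index an [ld_index()].
#' @param threshold pruning threshold on r-squared; pairs with r-squared
#'   strictly above it may not co-occur in the output.
#' @return character vector of retained ids (a subsequence of `snp_ids`).
#' @export
ld_prune <- function(snp_ids, index, threshold = 0.8) {
  snp_ids <- as.character(snp_ids)
  nb <- .neighbors(index, snp_ids, threshold)
  adj <- split(nb$snp_b, nb$snp_a)
  retained <- new.env(hash = TRUE, parent = emptyenv())
  keep <- logical(length(snp_ids))
  for (i in seq_along(snp_ids)) {
    id <- snp_ids[i]
    partners <- adj[[id]]
    conflict <- FALSE
    for (p in partners) {
      if (!is.null(retained[[p]])) { conflict <- TRUE; break }
    }
    if (!conflict) {
      keep[i] <- TRUE
      retained[[id]] <- TRUE
    }
  }
  snp_ids[keep]
}

#' Per-SNP proxy annotation: cgSNP status, cgSNPt status, tag count
#'
#' Convenience wrapper combining [tag_count()] and [cgsnpt_status()] over
#' a classified SNP table.
#'
#' @param classified a classified SNP table (needs `snp_id`, `cg_class`,
#'   `maf`).
#' @param index an [ld_index()].
#' @param threshold tagging/sharing threshold on r-squared.
#' @return a `data.table` with columns `snp_id`, `is_cgsnp`, `is_cgsnpt`,
#'   `n_tagged`, `maf`.
#' @export
annotate_proxies <- function(classified, index, threshold = 0.8) {
  dt <- as.data.table(classified)
  out <- dt[, .(snp_id = as.character(snp_id),
                is_cgsnp = cg_class %in% CGSNP_CLASSES,
                maf = maf)]
  out[, n_tagged := suppressWarnings(tag_count(snp_id, index, threshold))]
  out[, is_cgsnpt := cgsnpt_status(snp_id, dt, index, threshold)]
  setcolorder(out, c("snp_id", "is_cgsnp", "is_cgsnpt", "n_tagged", "maf"))
  out[]
}
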