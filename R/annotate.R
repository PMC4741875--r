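#' Build a CpG-island context index
#'
#' Islands are merge-normalised, then shores are the +/- `shore_width`
#' flanks of the merged islands minus any island overlap; everything
#' farther than `shore_width` from an island is open sea. Shore zones of
#' nearby islands merge and never overwrite island labels; known
#' chromosome ends (seqlengths on `islands`) truncate shores.
#'
#' @param islands a `GRanges` of CpG islands.
#' @param shore_width shore width in bp (default 2000).
#' @return a list with `GRanges` elements `islands` (merged) and `shores`,
#'   of class `"region_index"`.
#' @export
build_region_index <- function(islands, shore_width = 2000) {
  stopifnot(is(islands, "GRanges"))
  if (length(shore_width) != 1L || is.na(shore_width) || shore_width < 0) {
    stop("shore_width must be a single non-negative number", call. = FALSE)
  }
  isl <- GenomicRanges::reduce(islands, ignore.strand = TRUE)
  ext <- GenomicRanges::trim(suppressWarnings(isl + shore_width))
  shores <- GenomicRanges::reduce(
    GenomicRanges::setdiff(ext, isl, ignore.strand = TRUE))
  structure(list(islands = isl, shores = shores), class = "region_index")
}

.pos_to_gr <- function(chrom, pos) {
  GRanges(chrom, IRanges(start = pos + 1L, width = 1L))
}

#' Locate positions in CpG-island context
#'
#' @param chrom chromosome names (vectorised with `pos`).
#' @param pos 0-based positions.
#' @param index a region index from [build_region_index()].
#' @return character vector with values `"ISLAND"`, `"SHORE"`, `"OPEN_SEA"`;
#'   precedence ISLAND > SHORE > OPEN_SEA. Positions on chromosomes absent
#'   from the index are `OPEN_SEA` with a warning.
#' @export
locate_region <- function(chrom, pos, index) {
  stopifnot(inherits(index, "region_index"))
  q <- .pos_to_gr(chrom, pos)
  known <- unique(as.character(seqnames(c(index$islands, index$shores))))
  if (any(!chrom %in% known) && length(known)) {
    warning("position(s) on chromosome(s) absent from the island track ",
            "labelled OPEN_SEA", call. = FALSE)
  }
  out <- rep("OPEN_SEA", length(q))
  # suppress seqlevel-mismatch chatter; unknown chromosomes already warned
  out[suppressWarnings(countOverlaps(q, index$shores)) > 0] <- "SHORE"
  out[suppressWarnings(countOverlaps(q, index$islands)) > 0] <- "ISLAND"
  out
}

#' Locate positions in gene context
#'
#' A position inside any gene interval is `GENEBODY`; otherwise, if it
#' lies within `promoter_width` bp upstream of a gene's strand-aware 5'
#' end, it is `PROMOTER`; otherwise `INTERGENIC`. Precedence
#' GENEBODY > PROMOTER, so a promoter overlapping a neighboring gene's
#' body yields GENEBODY at the overlapped positions.
#'
#' @param chrom,pos chromosome names and 0-based positions.
#' @param genes a stranded `GRanges` of gene intervals; every strand must
#'   be `+` or `-`.
#' @param promoter_width promoter extent upstream of the 5' end, bp.
#' @return character vector with values `"GENEBODY"`, `"PROMOTER"`,
#'   `"INTERGENIC"`.
#' @export
gene_context <- function(chrom, pos, genes, promoter_width = 2000) {
  stopifnot(is(genes, "GRanges"))
  if (any(as.character(strand(genes)) == "*")) {
    stop("genes must carry strand (+ or -)", call. = FALSE)
  }
  q <- .pos_to_gr(chrom, pos)
  prom <- GenomicRanges::trim(suppressWarnings(
    promoters(genes, upstream = promoter_width, downstream = 0)))
  out <- rep("INTERGENIC", length(q))
  out[countOverlaps(q, prom, ignore.strand = TRUE) > 0] <- "PROMOTER"
  out[countOverlaps(q, genes, ignore.strand = TRUE) > 0] <- "GENEBODY"
  out
}

#' Annotate classified SNPs with region labels
#'
#' Adds `region` (CpG-island context) and, when `genes` is supplied,
#' `gene_region` columns to a classified SNP table.
#'
#' @param snps a data.frame with `chrom` and `pos` (0-based) columns.
#' @param islands `GRanges` of CpG islands.
#' @param genes optional stranded `GRanges` of genes.
#' @param shore_width,promoter_width widths in bp.
#' @return the table as a `data.table` with label columns added.
#' @export
annotate_snps <- function(snps, islands, genes = NULL,
                          shore_width = 2000, promoter_width = 2000) {
  dt <- as.data.table(snps)
  idx <- build_region_index(islands, shore_width = shore_width)
  dt[, region := locate_region(chrom, pos, idx)]
  if (!is.null(genes)) {
    dt[, gene_region := gene_context(chrom, pos, genes,
                                     promoter_width = promoter_width)]
  }
  dt[]
}
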