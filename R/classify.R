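#' @name cg-classes
#' @title cgSNP class labels
#' @description
#' Substitutions are first classified by whether CpG presence in the
#' trinucleotide context differs between the two alleles
#' (`NON_CG`, `CG_POLYMORPHIC`, `CG_SHIFT`), then oriented with the
#' ancestral allele into the final five-level cgSNP class:
#' `NON_CG`, `CG_GAIN` (derived allele creates a CpG), `CG_LOSS`
#' (derived allele abolishes the ancestral CpG), `CG_UNORIENTED`
#' (CpG-polymorphic but ancestral state unknown), and
#' `CG_SHIFT_EXCLUDED` (both alleles carry a CpG at different adjacent
#' dinucleotides, e.g. C[C/G]G; never counted as a cgSNP).
#' @keywords internal
NULL

SUB_CLASSES <- c("NON_CG", "CG_POLYMORPHIC", "CG_SHIFT")
CG_CLASSES  <- c("NON_CG", "CG_GAIN", "CG_LOSS", "CG_UNORIENTED",
                 "CG_SHIFT_EXCLUDED")
CGSNP_CLASSES <- c("CG_GAIN", "CG_LOSS", "CG_UNORIENTED")

DNA_BASES <- c("A", "C", "G", "T")

.check_bases <- function(..., what = "base") {
  for (x in list(...)) {
    bad <- !(x %in% DNA_BASES)
    if (any(bad)) {
      stop("invalid ", what, ": ", paste(unique(x[bad]), collapse = ", "),
           " (must be one of A, C, G, T)", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Complement and reverse-complement of base strings
#'
#' @param x character vector of A/C/G/T strings (case-insensitive; other
#'   letters pass through unchanged so ambiguity codes survive round trips).
#' @return character vector of the same length.
#' @examples
#' complement_bases("ACGT")
#' reverse_complement("ACGT")
#' @export
complement_bases <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

#' @rdname complement_bases
#' @export
reverse_complement <- function(x) {
  vapply(strsplit(complement_bases(x), ""), function(b)
    paste(rev(b), collapse = ""), character(1))
}

#' Is a CpG dinucleotide present at the variant position?
#'
#' Tests whether the trinucleotide `left`-`center`-`right` carries a CpG
#' overlapping the center base, i.e. whether `left`+`center` or
#' `center`+`right` spells "CG".
#'
#' @param left,center,right single bases (vectorised; all in A/C/G/T).
#' @return logical vector.
#' @examples
#' cpg_present("C", "G", "A")  # TRUE, left dinucleotide is CG
#' cpg_present("A", "C", "G")  # TRUE, right dinucleotide is CG
#' cpg_present("A", "A", "A")  # FALSE
#' @export
cpg_present <- function(left, center, right) {
  .check_bases(left, center, right)
  (left == "C" & center == "G") | (center == "C" & right == "G")
}

#' Classify a substitution by its effect on CpG presence
#'
#' A biallelic substitution is `CG_POLYMORPHIC` when exactly one allele
#' yields a CpG overlapping the variant base, `CG_SHIFT` when both alleles
#' do (necessarily at different dinucleotides, as in C\[C/G\]G where both
#' CCG and CGG contain a CpG), and `NON_CG` when neither does. Shift
#' variants are never treated as cgSNPs downstream: the CpG does not
#' appear or disappear, it moves by one base.
#'
#' @param left,right flanking bases (vectorised).
#' @param allele_a,allele_b the two alleles; must differ elementwise.
#' @return character vector with values in
#'   `c("NON_CG", "CG_POLYMORPHIC", "CG_SHIFT")`.
#' @examples
#' classify_substitution("C", "C", "T", "G")  # CG_POLYMORPHIC (CpG lost on T)
#' classify_substitution("C", "C", "G", "G")  # CG_SHIFT
#' classify_substitution("A", "A", "T", "A")  # NON_CG
#' @export
classify_substitution <- function(left, allele_a, allele_b, right) {
  .check_bases(left, allele_a, allele_b, right)
  if (any(allele_a == allele_b)) {
    stop("degenerate variant: allele_a equals allele_b", call. = FALSE)
  }
  cg_a <- cpg_present(left, allele_a, right)
  cg_b <- cpg_present(left, allele_b, right)
  out <- rep("NON_CG", length(cg_a))
  out[xor(cg_a, cg_b)] <- "CG_POLYMORPHIC"
  out[cg_a & cg_b] <- "CG_SHIFT"
  out
}

#' Orient a CpG-polymorphic substitution with the ancestral allele
#'
#' Taking the ancestral trinucleotide as the initial state, a
#' `CG_POLYMORPHIC` variant is a `CG_GAIN` when the derived allele creates
#' the CpG and a `CG_LOSS` when the ancestral allele carried it; with a
#' missing ancestral state it stays `CG_UNORIENTED`. `NON_CG` and
#' `CG_SHIFT` inputs pass through as `NON_CG` and `CG_SHIFT_EXCLUDED`.
#'
#' @param sub_class output of [classify_substitution()] for the same
#'   alleles and context.
#' @param allele_a,allele_b the two alleles.
#' @param ancestral ancestral base, or `NA` when unknown; when present it
#'   must equal one of the alleles.
#' @param left,right the context bases used for `sub_class`.
#' @return character vector with values in
#'   `c("NON_CG", "CG_GAIN", "CG_LOSS", "CG_UNORIENTED", "CG_SHIFT_EXCLUDED")`.
#' @examples
#' orient_gain_loss("CG_POLYMORPHIC", "C", "T", "C", left = "C", right = "G")
#' orient_gain_loss("CG_POLYMORPHIC", "C", "T", NA,  left = "C", right = "G")
#' @export
orient_gain_loss <- function(sub_class, allele_a, allele_b, ancestral,
                             left, right) {
  n <- length(sub_class)
  stopifnot(sub_class %in% SUB_CLASSES)
  known <- !is.na(ancestral)
  if (any(known & ancestral != allele_a & ancestral != allele_b)) {
    stop("inconsistent ancestral allele: not among the two alleles",
         call. = FALSE)
  }
  out <- rep("NON_CG", n)
  out[sub_class == "CG_SHIFT"] <- "CG_SHIFT_EXCLUDED"
  poly <- sub_class == "CG_POLYMORPHIC"
  out[poly & !known] <- "CG_UNORIENTED"
  idx <- which(poly & known)
  if (length(idx)) {
    anc_cg <- cpg_present(left[idx], ancestral[idx], right[idx])
    out[idx] <- ifelse(anc_cg, "CG_LOSS", "CG_GAIN")
  }
  out
}

# Extract the immediate trinucleotide context from flanks: the base just 5'
# of the variant is the LAST character of flank5, the base just 3' the FIRST
# character of flank3. Longer flanks are accepted but only these are used.
.context_bases <- function(flank5, flank3) {
  list(left  = toupper(substr(flank5, nchar(flank5), nchar(flank5))),
       right = toupper(substr(flank3, 1L, 1L)))
}

#' Classify a table of SNP records into cgSNP classes
#'
#' Takes the base immediately 5' (last character of `flank5`) and 3'
#' (first character of `flank3`) of each variant as the trinucleotide
#' context, classifies the substitution and orients it with the ancestral
#' allele. Classification is strand-invariant: a record given
#' reverse-complemented (alleles, ancestral and flanks complemented and
#' swapped) receives the identical class, because CpG is its own reverse
#' complement.
#'
#' Records whose context bases are ambiguity codes (N or other IUPAC
#' letters) are classified `NON_CG` with `context_warning = TRUE` rather
#' than erroring, so genome-scale runs do not abort on unresolvable
#' context.
#'
#' @param snps a data.frame with columns `allele_a`, `allele_b`,
#'   `ancestral` (`NA` when missing), `flank5`, `flank3` (the SNP-table
#'   schema of [read_snp_tsv()]).
#' @return the input as a `data.table` with added columns `cg_class`
#'   (five-level class) and `context_warning` (logical).
#' @seealso [classify_substitution()], [orient_gain_loss()]
#' @export
classify_snps <- function(snps) {
  dt <- as.data.table(snps)
  required <- c("allele_a", "allele_b", "ancestral", "flank5", "flank3")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(dt) == 0L) {
    dt[, `:=`(cg_class = character(0), context_warning = logical(0))]
    return(dt[])
  }
  ctx <- .context_bases(dt$flank5, dt$flank3)
  ok <- ctx$left %in% DNA_BASES & ctx$right %in% DNA_BASES
  if (any(!ok)) {
    warning(sum(!ok), " record(s) with ambiguous context bases classified ",
            "NON_CG (context_warning = TRUE)", call. = FALSE)
  }
  cls <- rep("NON_CG", nrow(dt))
  if (any(ok)) {
    sub <- classify_substitution(ctx$left[ok], dt$allele_a[ok],
                                 dt$allele_b[ok], ctx$right[ok])
    cls[ok] <- orient_gain_loss(sub, dt$allele_a[ok], dt$allele_b[ok],
                                dt$ancestral[ok], ctx$left[ok], ctx$right[ok])
  }
  dt[, cg_class := cls]
  dt[, context_warning := !ok]
  dt[]
}

#' @rdname classify_snps
#' @param snp a single-row data.frame or named list with the same fields.
#' @return `classify_snp_record()`: a single class string.
#' @export
classify_snp_record <- function(snp) {
  fields <- as.list(snp)[c("allele_a", "allele_b", "ancestral",
                           "flank5", "flank3")]
  classify_snps(as.data.table(fields))$cg_class
}

#' Enumerate all substitution-in-context scenarios
#'
#' Builds the complete table of ordered (left, ancestral, derived, right)
#' single-base substitutions over A/C/G/T — 4 x 4 x 3 x 4 = 192 rows —
#' and classifies each with the package's rules, treating the ancestral
#' base as the initial state. Gains and losses are equinumerous by
#' construction (swapping ancestral and derived maps one onto the other).
#'
#' The attached summary (see `attr(x, "scenario_summary")`) also reports
#' the strand-collapsed count, in which a scenario and its reverse
#' complement count once.
#'
#' @return a `data.table` with columns `left_base`, `ancestral_allele`,
#'   `derived_allele`, `right_base`, `class`, `is_shift`, plus a
#'   `scenario_summary` attribute (named integer vector).
#' @export
enumerate_scenarios <- function() {
  g <- CJ(left_base = DNA_BASES, ancestral_allele = DNA_BASES,
          derived_allele = DNA_BASES, right_base = DNA_BASES)
  g <- g[ancestral_allele != derived_allele]
  sub <- classify_substitution(g$left_base, g$ancestral_allele,
                               g$derived_allele, g$right_base)
  g[, class := orient_gain_loss(sub, ancestral_allele, derived_allele,
                                ancestral_allele, left_base, right_base)]
  g[, is_shift := class == "CG_SHIFT_EXCLUDED"]
  n_gain <- sum(g$class == "CG_GAIN")
  n_loss <- sum(g$class == "CG_LOSS")
  # strand-collapsed: pair each scenario with its reverse complement
  key <- with(g, paste(left_base, ancestral_allele, derived_allele, right_base))
  rc_key <- with(g, paste(complement_bases(right_base),
                          complement_bases(ancestral_allele),
                          complement_bases(derived_allele),
                          complement_bases(left_base)))
  gl <- g$class %in% c("CG_GAIN", "CG_LOSS")
  collapsed <- length(unique(pmin(key[gl], rc_key[gl])))
  attr(g, "scenario_summary") <- c(
    n_total = nrow(g), n_gain = n_gain, n_loss = n_loss,
    n_shift = sum(g$is_shift),
    n_gain_loss_ordered = n_gain + n_loss,
    n_gain_loss_strand_collapsed = collapsed)
  g[]
}

#' Summarise cgSNP classes by region
#'
#' Per group: the total number of cgSNPs (gains + losses + unoriented) and
#' counts and percentages of gains and losses, with percentages computed
#' against the group's total cgSNPs — so a group with unoriented records
#' has gain% + loss% < 100.
#'
#' @param classified output of [classify_snps()] carrying a region label.
#' @param group_by name of the grouping column (e.g. `"region"`).
#' @return a `data.table`, one row per group plus a `"Global"` row, with
#'   columns `n_cg`, `n_gain`, `n_loss`, `n_unoriented`, `pct_gain`,
#'   `pct_loss`.
#' @export
summarize_classes <- function(classified, group_by = "region") {
  dt <- as.data.table(classified)
  if (nrow(dt) == 0L) return(data.table())
  if (!group_by %in% names(dt)) {
    stop("grouping column '", group_by, "' not found", call. = FALSE)
  }
  one <- function(cls) {
    n_gain <- sum(cls == "CG_GAIN")
    n_loss <- sum(cls == "CG_LOSS")
    n_un   <- sum(cls == "CG_UNORIENTED")
    n_cg   <- n_gain + n_loss + n_un
    list(n_cg = n_cg, n_gain = n_gain, n_loss = n_loss, n_unoriented = n_un,
         pct_gain = if (n_cg > 0) 100 * n_gain / n_cg else NA_real_,
         pct_loss = if (n_cg > 0) 100 * n_loss / n_cg else NA_real_)
  }
  out <- dt[, one(cg_class), by = group_by]
  glob <- cbind(data.table(g = "Global"), as.data.table(one(dt$cg_class)))
  setnames(glob, "g", group_by)
  rbind(out, glob)
}
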