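#' Covariate-adjusted logistic enrichment model
#'
#' Fits the logistic model
#' `ln(P/(1-P)) = b0 + b_cgsnpt * X_cgsnpt + b_maf * X_maf + b_tags * X_tags`
#' by maximum likelihood, where `y` marks outcome-positive proxies (eQTL
#' or trait-associated) and `X_cgsnpt` marks cgSNPts; MAF and the tag
#' count enter as confounder adjustments. The cgSNPt effect is reported
#' as an odds ratio with a 95% Wald confidence interval,
#' `exp(b +/- 1.96 SE)`.
#'
#' @param input a data.frame with columns `y` (0/1), `x_cgsnpt` (0/1 or
#'   logical), `x_maf`, `x_tags`.
#' @return an object of class `"enrichment_result"`: a list with the four
#'   coefficients, `or_cgsnpt`, `ci_low`, `ci_high`, `p_wald`, `n`,
#'   `n_positive`, `converged`.
#' @export
fit_enrichment_model <- function(input) {
  dt <- as.data.table(input)
  need <- c("y", "x_cgsnpt", "x_maf", "x_tags")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  y <- as.integer(dt$y)
  x <- as.integer(dt$x_cgsnpt)
  if (!all(y %in% 0:1) || !all(x %in% 0:1)) {
    stop("y and x_cgsnpt must be binary", call. = FALSE)
  }
  if (sum(y) == 0L || sum(y) == length(y)) {
    stop("need at least one positive and one negative outcome", call. = FALSE)
  }
  if (length(unique(x)) < 2L) {
    stop("collinearity: x_cgsnpt is constant", call. = FALSE)
  }
  if (!all(is.finite(dt$x_maf)) || !all(is.finite(dt$x_tags))) {
    stop("covariates must be finite", call. = FALSE)
  }
  df <- data.frame(y = y, x_cgsnpt = x, x_maf = dt$x_maf, x_tags = dt$x_tags)
  fit <- suppressWarnings(glm(y ~ x_cgsnpt + x_maf + x_tags,
                              family = binomial(), data = df))
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  if (!fit$converged || any(!is.finite(se)) || abs(cf[["x_cgsnpt"]]) > 15) {
    stop("separation or non-convergence in the logistic fit (|beta_cgsnpt| = ",
         signif(abs(cf[["x_cgsnpt"]]), 3), ", converged = ", fit$converged,
         ")", call. = FALSE)
  }
  b <- cf[["x_cgsnpt"]]
  s <- se[["x_cgsnpt"]]
  structure(list(
    beta0 = cf[["(Intercept)"]], beta_cgsnpt = b,
    beta_maf = cf[["x_maf"]], beta_tags = cf[["x_tags"]],
    se_cgsnpt = s,
    or_cgsnpt = exp(b), ci_low = exp(b - 1.96 * s), ci_high = exp(b + 1.96 * s),
    p_wald = 2 * pnorm(-abs(b / s)),
    n = length(y), n_positive = sum(y), converged = fit$converged),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Enrichment (logistic): OR[cgSNPt] = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
    x$or_cgsnpt, x$ci_low, x$ci_high, x$p_wald))
  cat(sprintf("  n = %d (%d positive); beta_maf = %.3f, beta_tags = %.3f\n",
              x$n, x$n_positive, x$beta_maf, x$beta_tags))
  invisible(x)
}

#' Assign proxies to MAF x tag-count matching strata
#'
#' Bins are half-open `[e_i, e_{i+1})` with the last bin closed on the
#' right for MAF, and integer classes for tag counts. Defaults: MAF bins
#' of width 0.05 over \[0, 0.5\]; tag-count classes
#' \{0\}, \{1-2\}, \{3-5\}, \{6-10\}, \{>10\}.
#'
#' @param proxies a data.frame with `maf` and `n_tagged` columns.
#' @param maf_edges strictly increasing MAF bin edges covering all values.
#' @param tag_edges strictly increasing lower edges of the tag-count bins
#'   (first edge must be <= the smallest count; the last bin is unbounded).
#' @return factor of stratum labels, one per proxy.
#' @export
assign_strata <- function(proxies,
                          maf_edges = (0:10) / 20,
                          tag_edges = c(0, 1, 3, 6, 11)) {
  dt <- as.data.table(proxies)
  if (is.unsorted(maf_edges, strictly = TRUE) ||
      is.unsorted(tag_edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  if (any(dt$maf < maf_edges[1]) || any(dt$maf > maf_edges[length(maf_edges)])) {
    stop("MAF value outside the stratum edges", call. = FALSE)
  }
  if (any(dt$n_tagged < tag_edges[1])) {
    stop("tag count outside the stratum edges", call. = FALSE)
  }
  mb <- findInterval(dt$maf, maf_edges, rightmost.closed = TRUE)
  tb <- findInterval(dt$n_tagged, tag_edges)
  factor(sprintf("maf%02d.tag%d", mb, tb))
}

#' Stratified matched-resampling enrichment test
#'
#' Compares the number of cgSNPts in an index set (e.g. the 500 proxies
#' with top eQTL signals) with its expectation under matched resampling:
#' `n_draws` sets of the same size are drawn by stratified random sampling
#' without replacement from the non-index proxies, each draw reproducing
#' the index set's per-stratum composition exactly (MAF and tag count as
#' matching factors). The empirical p-value is the proportion of draws
#' whose cgSNPt count meets or exceeds the observed count; ties count
#' toward the p-value. When no draw reaches the observed count the
#' p-value is reported as `< 1/n_draws`; `correction = "add_one"` uses
#' `(b + 1)/(n_draws + 1)` instead of the raw proportion.
#'
#' @param index_ids ids of the index set.
#' @param proxies proxy annotation table with `snp_id`, `is_cgsnpt` and a
#'   `stratum` column (see [assign_strata()]).
#' @param n_draws number of matched draws (default 300).
#' @param seed integer seed; required, every draw is reproducible.
#' @param correction `"raw"` (default) or `"add_one"`.
#' @return an object of class `"simulation_result"`: `observed_count`,
#'   `null_counts` (length `n_draws`), `empirical_p`, `p_label`,
#'   `n_draws`, `index_size`.
#' @export
matched_simulation_test <- function(index_ids, proxies, n_draws = 300, seed,
                                    correction = c("raw", "add_one")) {
  correction <- match.arg(correction)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  dt <- as.data.table(proxies)
  need <- c("snp_id", "is_cgsnpt", "stratum")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  index_ids <- as.character(index_ids)
  in_index <- dt$snp_id %in% index_ids
  if (sum(in_index) != length(unique(index_ids))) {
    stop("index ids must all be present in the proxy table", call. = FALSE)
  }
  idx <- dt[in_index]
  pool <- dt[!in_index]
  need_by_stratum <- idx[, .N, by = stratum]
  pool_by_stratum <- split(pool$is_cgsnpt, pool$stratum)
  observed <- sum(idx$is_cgsnpt)

  set.seed(seed)
  null_counts <- integer(n_draws)
  for (s in seq_len(nrow(need_by_stratum))) {
    st <- as.character(need_by_stratum$stratum[s])
    k <- need_by_stratum$N[s]
    avail <- pool_by_stratum[[st]]
    if (is.null(avail) || length(avail) < k) {
      stop("infeasible matching: stratum '", st, "' needs ", k,
           " but the pool holds ", length(avail), call. = FALSE)
    }
    for (d in seq_len(n_draws)) {
      null_counts[d] <- null_counts[d] +
        sum(avail[sample.int(length(avail), k)])
    }
  }
  b <- sum(null_counts >= observed)
  p <- if (correction == "raw") b / n_draws else (b + 1) / (n_draws + 1)
  label <- if (correction == "raw" && b == 0L) {
    sprintf("< %g", 1 / n_draws)
  } else sprintf("%g", p)
  structure(list(observed_count = observed, null_counts = null_counts,
                 empirical_p = p, p_label = label, n_draws = n_draws,
                 index_size = nrow(idx), correction = correction),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "Matched resampling: observed %d cgSNPts in %d index SNPs; null mean %.1f (%d draws); empirical p %s\n",
    x$observed_count, x$index_size, mean(x$null_counts), x$n_draws, x$p_label))
  invisible(x)
}

#' Bin trait-associated SNPs by reported association p-value
#'
#' Catalog SNPs (reported p <= 1e-5) are placed in bins on the -log10
#' scale. The default eight bins are
#' \[5,6), \[6,7), \[7,8), \[8,11), \[11,14), \[14,17), \[17,20), \[20, Inf).
#'
#' @param reported_p reported association p-values, all in (0, 1e-5\].
#' @param edges increasing -log10(p) bin edges (last bin unbounded).
#' @return factor of bin labels (e.g. `"E-5~"`, ..., `"<E-20"`), one per SNP.
#' @export
bin_by_reported_p <- function(reported_p,
                              edges = c(5, 6, 7, 8, 11, 14, 17, 20)) {
  if (any(!is.finite(reported_p)) || any(reported_p <= 0) ||
      any(reported_p > 1)) {
    stop("reported p-values must lie in (0, 1]", call. = FALSE)
  }
  lp <- -log10(reported_p)
  if (any(lp < edges[1])) {
    stop("reported p-values above the catalog threshold 1e-",
         edges[1], call. = FALSE)
  }
  labels <- c(paste0("E-", edges[-length(edges)], "~"),
              paste0("<E-", edges[length(edges)]))
  factor(labels[findInterval(lp, edges)], levels = labels)
}

#' Per-bin enrichment of cgSNPts among trait-associated SNPs
#'
#' Positives in each reported-p bin are tested against the same negative
#' set — all proxies never associated with any trait — with
#' [fit_enrichment_model()]. Empty bins are skipped with a warning.
#'
#' @param trait_snps data.frame with `snp_id` and `reported_p` for the
#'   associated SNPs.
#' @param proxies proxy annotation table (`snp_id`, `is_cgsnpt`,
#'   `n_tagged`, `maf`).
#' @param edges passed to [bin_by_reported_p()].
#' @return named list of `enrichment_result` objects, one per non-empty bin.
#' @export
enrich_by_pbin <- function(trait_snps, proxies,
                           edges = c(5, 6, 7, 8, 11, 14, 17, 20)) {
  ts <- as.data.table(trait_snps)
  ts[, bin := bin_by_reported_p(reported_p, edges)]
  px <- .enrichment_frame(proxies)
  out <- list()
  for (lv in levels(ts$bin)) {
    ids <- ts[bin == lv, as.character(snp_id)]
    if (!length(ids)) {
      warning("empty p-value bin '", lv, "' skipped", call. = FALSE)
      next
    }
    frame <- px[!(snp_id %in% setdiff(ts$snp_id, ids))]
    frame[, y := as.integer(snp_id %in% ids)]
    out[[lv]] <- fit_enrichment_model(frame)
  }
  out
}

.enrichment_frame <- function(proxies) {
  px <- as.data.table(proxies)
  px[, .(snp_id = as.character(snp_id),
         x_cgsnpt = as.integer(is_cgsnpt), x_maf = maf, x_tags = n_tagged)]
}

#' Per-category enrichment of cgSNPts among trait-associated SNPs
#'
#' One logistic fit per trait category (positives: that category's SNPs;
#' negatives: all proxies associated with no trait), plus a pooled fit
#' over all associated SNPs. Categories with no positives are skipped
#' with a warning.
#'
#' @param trait_snps data.frame with `snp_id` and `category`.
#' @param proxies proxy annotation table.
#' @return named list of `enrichment_result` objects, including
#'   `"pooled"`.
#' @export
category_enrichment <- function(trait_snps, proxies) {
  ts <- as.data.table(trait_snps)
  px <- .enrichment_frame(proxies)
  all_pos <- unique(as.character(ts$snp_id))
  out <- list()
  for (cat_lv in unique(as.character(ts$category))) {
    ids <- ts[category == cat_lv, unique(as.character(snp_id))]
    if (!length(ids)) {
      warning("category '", cat_lv, "' has no positives; skipped",
              call. = FALSE)
      next
    }
    frame <- px[!(snp_id %in% setdiff(all_pos, ids))]
    frame[, y := as.integer(snp_id %in% ids)]
    out[[cat_lv]] <- fit_enrichment_model(frame)
  }
  frame <- copy(px)[, y := as.integer(snp_id %in% all_pos)]
  out[["pooled"]] <- fit_enrichment_model(frame)
  out
}
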