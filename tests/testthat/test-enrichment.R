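make_outcome_frame <- function(n, seed, beta_cgsnpt, config_args = list()) {
  cfg <- do.call(synth_config, c(list(seed = seed,
                                      beta_cgsnpt = beta_cgsnpt),
                                 config_args))
  px <- simulate_proxy_panel(n, seed = seed)
  oc <- plant_outcomes(px, cfg, type = "eqtl", seed = seed + 1L)
  data.table::data.table(y = oc$y, x_cgsnpt = as.integer(px$is_cgsnpt),
                         x_maf = px$maf, x_tags = px$n_tagged)
}

test_that("the logistic fit recovers a planted cgSNPt odds ratio", {
  frame <- make_outcome_frame(50000, seed = 101, beta_cgsnpt = log(1.5),
                              config_args = list(beta0 = -3))
  fit <- fit_enrichment_model(frame)
  expect_true(fit$converged)
  expect_lt(abs(fit$or_cgsnpt - 1.5), 0.3)
  expect_true(fit$ci_low <= 1.5 && 1.5 <= fit$ci_high)
  expect_true(fit$ci_low <= fit$or_cgsnpt && fit$or_cgsnpt <= fit$ci_high)
})

test_that("degenerate enrichment inputs are rejected", {
  base <- data.table::data.table(y = c(0, 0, 1, 1), x_cgsnpt = c(0, 1, 0, 1),
                                 x_maf = 0.1, x_tags = 1)
  expect_error(fit_enrichment_model(base[y == 0]), "at least one positive")
  allsame <- data.table::copy(base)[, x_cgsnpt := 1]
  expect_error(fit_enrichment_model(allsame), "collinearity")
  expect_error(fit_enrichment_model(base[, .(y, x_cgsnpt)]), "missing required")
})

test_that("the glm fit matches a generic-optimizer likelihood maximum", {
  frame <- make_outcome_frame(200, seed = 7, beta_cgsnpt = log(2),
                              config_args = list(beta0 = -1))
  fit <- fit_enrichment_model(frame)
  opt <- optim(c(0, 0, 0, 0), enrichment_loglik, y = frame$y,
               x_cgsnpt = frame$x_cgsnpt, x_maf = frame$x_maf,
               x_tags = frame$x_tags,
               control = list(fnscale = -1, maxit = 5000, reltol = 1e-14),
               method = "BFGS")
  expect_equal(unname(c(fit$beta0, fit$beta_cgsnpt, fit$beta_maf,
                        fit$beta_tags)),
               opt$par, tolerance = 1e-4)
})

test_that("strata are deterministic MAF x tag-count bins", {
  px <- data.table::data.table(maf = c(0.12, 0.12, 0.30), n_tagged = c(0L, 0L, 7L))
  s <- assign_strata(px)
  expect_equal(as.character(s[1]), "maf03.tag1")  # [0.10, 0.15) x {0}
  expect_identical(s[1], s[2])                    # identical covariates, same label
  expect_equal(as.character(s[3]), "maf07.tag4")  # [0.30, 0.35) x {6-10}
  expect_error(assign_strata(data.table::data.table(maf = 0.7, n_tagged = 0L)),
               "outside")
  expect_error(assign_strata(px, maf_edges = c(0.5, 0.1)), "increasing")
})

test_that("matched draws reproduce the index stratum composition exactly", {
  # pool composition encodes the stratum: every pool member of stratum A is a
  # cgSNPt, none of stratum B is — so any draw with the right composition has
  # exactly k_A cgSNPts, and any miscount would be visible immediately.
  px <- data.table::data.table(
    snp_id = sprintf("s%03d", 1:240),
    is_cgsnpt = rep(c(TRUE, FALSE), each = 120),
    stratum = factor(rep(c("A", "B"), each = 120)))
  index_ids <- c(px$snp_id[1:30], px$snp_id[121:140])  # 30 from A, 20 from B
  sim <- matched_simulation_test(index_ids, px, n_draws = 50, seed = 3)
  expect_true(all(sim$null_counts == 30L))
  expect_equal(sim$observed_count, 30L)
  expect_equal(sim$empirical_p, 1)   # ties count toward the p-value
})

test_that("simulation test is seed-reproducible with conservative tie handling", {
  set.seed(99)
  px <- data.table::data.table(
    snp_id = sprintf("s%04d", 1:2000),
    is_cgsnpt = runif(2000) < 0.4,
    stratum = factor(sample(c("A", "B", "C"), 2000, TRUE)))
  idx_ids <- px$snp_id[sample.int(2000, 100)]
  s1 <- matched_simulation_test(idx_ids, px, n_draws = 40, seed = 11)
  s2 <- matched_simulation_test(idx_ids, px, n_draws = 40, seed = 11)
  expect_identical(s1$null_counts, s2$null_counts)
  expect_equal(s1$empirical_p, mean(s1$null_counts >= s1$observed_count))
  # empirical p is non-increasing in the observed count
  p_at <- function(obs) mean(s1$null_counts >= obs)
  obs_grid <- 0:100
  expect_true(all(diff(sapply(obs_grid, p_at)) <= 0))
})

test_that("zero exceedances report p below the resolution of the draws", {
  px <- data.table::data.table(
    snp_id = sprintf("s%03d", 1:120),
    is_cgsnpt = rep(c(TRUE, FALSE), each = 60),
    stratum = factor("A"))
  # index = all the cgSNPts; the pool has 60 non-cgSNPts for draws of 60
  sim <- matched_simulation_test(px$snp_id[1:60], px, n_draws = 25, seed = 1)
  expect_equal(sim$empirical_p, 0)
  expect_equal(sim$p_label, "< 0.04")
  sim2 <- matched_simulation_test(px$snp_id[1:60], px, n_draws = 25, seed = 1,
                                  correction = "add_one")
  expect_equal(sim2$empirical_p, 1 / 26)
})

test_that("infeasible strata are named in the error", {
  px <- data.table::data.table(snp_id = c("a", "b", "c"),
                               is_cgsnpt = c(TRUE, FALSE, FALSE),
                               stratum = factor(c("A", "A", "B")))
  expect_error(matched_simulation_test(c("a", "b"), px, n_draws = 5, seed = 1),
               "stratum 'A'")
})

test_that("reported p-values land in the documented bins", {
  expect_equal(as.character(bin_by_reported_p(3e-6)), "E-5~")
  expect_equal(as.character(bin_by_reported_p(1e-20)), "<E-20")
  expect_equal(as.character(bin_by_reported_p(1e-12)), "E-11~")
  expect_error(bin_by_reported_p(2), "\\(0, 1\\]")
  expect_error(bin_by_reported_p(1e-3), "catalog threshold")
})

test_that("per-bin and per-category enrichment share the negative set", {
  set.seed(5)
  px <- simulate_proxy_panel(20000, seed = 5)
  cfg <- synth_config(seed = 5, beta0 = -3,
                      category_betas = c(cancer = log(3), other = 0),
                      category_probs = c(cancer = 0.5, other = 0.5))
  oc <- plant_outcomes(px, cfg, type = "trait", seed = 6)
  res <- category_enrichment(oc$outcomes, px)
  expect_true(all(c("cancer", "other", "pooled") %in% names(res)))
  # planted contrast: the cancer effect exceeds the null category's
  expect_gt(res$cancer$or_cgsnpt, res$other$or_cgsnpt)
  expect_gt(res$cancer$or_cgsnpt, 1.5)
  # single category equals the pooled fit
  solo <- category_enrichment(oc$outcomes[category == "cancer"], px)
  expect_equal(solo$cancer$beta_cgsnpt, solo$pooled$beta_cgsnpt)
  # p-value bins: every positive lands in one bin and fits run per bin
  bins <- enrich_by_pbin(oc$outcomes, px)
  expect_true(length(bins) >= 1)
  expect_true(all(vapply(bins, function(b) b$converged, logical(1))))
})
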