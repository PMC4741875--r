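test_that("cpg_present detects CpG overlapping the center base", {
  expect_true(cpg_present("C", "G", "A"))
  expect_true(cpg_present("A", "C", "G"))
  expect_false(cpg_present("A", "A", "A"))
  expect_false(cpg_present("G", "C", "A"))   # GC is not CG
  expect_error(cpg_present("N", "A", "A"), "invalid")
})

test_that("substitutions are classified as polymorphic, shift or non-CG", {
  expect_equal(classify_substitution("C", "C", "T", "G"), "CG_POLYMORPHIC")
  expect_equal(classify_substitution("C", "C", "G", "G"), "CG_SHIFT")
  expect_equal(classify_substitution("A", "A", "T", "A"), "NON_CG")
  expect_error(classify_substitution("A", "C", "C", "G"), "degenerate")
})

all_cases <- local({
  b <- c("A", "C", "G", "T")
  g <- expand.grid(left = b, anc = b, der = b, right = b,
                   stringsAsFactors = FALSE)
  g[g$anc != g$der, ]
})

test_that("classifier agrees with the string-search oracle on all 192 cases", {
  got <- classify_substitution(all_cases$left, all_cases$anc,
                               all_cases$der, all_cases$right)
  want <- mapply(oracle_classify, all_cases$left, all_cases$anc,
                 all_cases$der, all_cases$right, USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("classification is invariant under reverse complement, all 192 cases", {
  orig <- classify_substitution(all_cases$left, all_cases$anc,
                                all_cases$der, all_cases$right)
  rc <- classify_substitution(complement_bases(all_cases$right),
                              complement_bases(all_cases$anc),
                              complement_bases(all_cases$der),
                              complement_bases(all_cases$left))
  expect_identical(orig, rc)
  # oriented classes are strand-invariant too
  o1 <- orient_gain_loss(orig, all_cases$anc, all_cases$der, all_cases$anc,
                         all_cases$left, all_cases$right)
  o2 <- orient_gain_loss(rc, complement_bases(all_cases$anc),
                         complement_bases(all_cases$der),
                         complement_bases(all_cases$anc),
                         complement_bases(all_cases$right),
                         complement_bases(all_cases$left))
  expect_identical(o1, o2)
})

test_that("ancestral allele orients gains and losses, with swap symmetry", {
  expect_equal(orient_gain_loss("CG_POLYMORPHIC", "C", "T", "C", "C", "G"),
               "CG_LOSS")
  expect_equal(orient_gain_loss("CG_POLYMORPHIC", "C", "T", "T", "C", "G"),
               "CG_GAIN")
  expect_equal(orient_gain_loss("CG_POLYMORPHIC", "C", "T", NA, "C", "G"),
               "CG_UNORIENTED")
  expect_equal(orient_gain_loss("CG_SHIFT", "C", "G", "C", "C", "G"),
               "CG_SHIFT_EXCLUDED")
  expect_equal(orient_gain_loss("NON_CG", "A", "T", "A", "A", "A"), "NON_CG")
  expect_error(orient_gain_loss("CG_POLYMORPHIC", "C", "T", "G", "C", "G"),
               "inconsistent ancestral")
  # swap property over every polymorphic scenario
  sub <- classify_substitution(all_cases$left, all_cases$anc,
                               all_cases$der, all_cases$right)
  poly <- sub == "CG_POLYMORPHIC"
  with_a <- orient_gain_loss(sub[poly], all_cases$anc[poly],
                             all_cases$der[poly], all_cases$anc[poly],
                             all_cases$left[poly], all_cases$right[poly])
  with_b <- orient_gain_loss(sub[poly], all_cases$anc[poly],
                             all_cases$der[poly], all_cases$der[poly],
                             all_cases$left[poly], all_cases$right[poly])
  expect_true(all((with_a == "CG_GAIN") == (with_b == "CG_LOSS")))
})

test_that("SNP records classify from flanks and are strand-invariant", {
  row <- make_snp_row(flank5 = "TTTAC", allele_a = "C", allele_b = "T",
                      ancestral = "C", flank3 = "GCATT")
  expect_equal(classify_snp_record(row), "CG_LOSS")
  expect_equal(classify_snp_record(rc_snp_row(row)), "CG_LOSS")
  # unoriented and gain mirrors
  row$ancestral <- NA_character_
  expect_equal(classify_snp_record(row), "CG_UNORIENTED")
  row$ancestral <- "T"
  expect_equal(classify_snp_record(row), "CG_GAIN")
  expect_equal(classify_snp_record(rc_snp_row(row)), "CG_GAIN")
})

test_that("ambiguous context bases give NON_CG with a warning flag", {
  row <- make_snp_row(flank3 = "NCATT")
  expect_warning(out <- classify_snps(row), "ambiguous")
  expect_equal(out$cg_class, "NON_CG")
  expect_true(out$context_warning)
})

test_that("scenario enumeration covers 192 cases with equinumerous gains and losses", {
  sc <- enumerate_scenarios()
  expect_equal(nrow(sc), 192L)
  expect_equal(anyDuplicated(sc[, 1:4]), 0L)
  s <- attr(sc, "scenario_summary")
  expect_equal(unname(s["n_gain"]), unname(s["n_loss"]))
  # the only shift scenarios are the C[C/G]G pair
  shift <- sc[sc$is_shift, ]
  expect_equal(nrow(shift), 2L)
  expect_true(all(shift$left_base == "C" & shift$right_base == "G"))
  # counts agree with the independent oracle
  want <- mapply(oracle_classify, sc$left_base, sc$ancestral_allele,
                 sc$derived_allele, sc$right_base, USE.NAMES = FALSE)
  expect_equal(unname(s["n_gain"] + s["n_loss"]),
               sum(want == "CG_POLYMORPHIC"))
  expect_equal(unname(s["n_gain_loss_ordered"]), 44L)
})

test_that("class summaries use total cgSNPs as the denominator", {
  dt <- data.table::data.table(
    cg_class = c(rep("CG_GAIN", 10), rep("CG_LOSS", 10)),
    region = "ISLAND")
  s <- summarize_classes(dt, "region")
  expect_equal(s[s$region == "ISLAND", ]$pct_gain, 50)
  expect_equal(s[s$region == "ISLAND", ]$pct_loss, 50)
  dt2 <- data.table::data.table(
    cg_class = c("CG_GAIN", "CG_GAIN", "CG_LOSS", "CG_LOSS",
                 "CG_UNORIENTED", "NON_CG"),
    region = "OPEN_SEA")
  s2 <- summarize_classes(dt2, "region")
  row <- s2[s2$region == "OPEN_SEA", ]
  expect_equal(row$n_cg, 5L)         # unoriented counts, NON_CG does not
  expect_equal(row$pct_gain, 40)
  expect_equal(row$pct_loss, 40)
  expect_equal(nrow(summarize_classes(data.table::data.table())), 0L)
})
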