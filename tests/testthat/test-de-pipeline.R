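test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10L, 20L, 5L, 10L, 40L, 10L), nrow = 3)
  colnames(m) <- c("s1", "s2")

  # identical columns: all factors 1
  mm <- cbind(s1 = c(3L, 8L, 2L), s2 = c(3L, 8L, 2L))
  expect_equal(unname(size_factors(mm)), c(1, 1))

  # second column = 2x first for every gene: factor ratio 2
  m2 <- cbind(s1 = c(10L, 20L, 5L), s2 = c(20L, 40L, 10L))
  sf2 <- size_factors(m2)
  expect_equal(unname(sf2[2] / sf2[1]), 2, tolerance = 1e-12)

  # single gene (10, 40): ratio of factors is 4
  m1 <- matrix(c(10L, 40L), nrow = 1)
  sf1 <- size_factors(m1)
  expect_equal(unname(sf1[2] / sf1[1]), 4, tolerance = 1e-12)

  # scale equivariance
  panel <- build_panel(n_background = 200)
  cm <- generate_counts(panel, seed = 21)
  sf <- size_factors(cm$counts)
  m3 <- cm$counts
  m3[, 2] <- m3[, 2] * 3L
  sf3 <- size_factors(m3)
  expect_equal(unname(sf3[2] / sf[2]), unname(3 * sf3[1] / sf[1]),
               tolerance = 1e-10)

  # no all-nonzero gene: total-count fallback with a warning
  mz <- cbind(s1 = c(0L, 5L), s2 = c(5L, 0L))
  expect_warning(sfz <- size_factors(mz), "total-count")
  expect_equal(unname(sfz), c(1, 1))
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  panel <- build_panel(n_background = 500)
  cm <- generate_counts(panel, seed = 22)
  ours <- size_factors(cm$counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(cm$counts)
  # both are defined up to a common scale; compare after normalizing
  expect_equal(unname(ours / exp(mean(log(ours)))),
               unname(ref / exp(mean(log(ref)))), tolerance = 1e-10)
})

test_that("dispersion estimation recovers known truth", {
  # Poisson data: raw dispersion near zero
  panel <- build_panel(n_background = 500)
  cm <- generate_counts(panel, n_per_group = 25, depths = rep(1, 50),
                        alpha = 0, seed = 23)
  disp <- estimate_dispersion(cm$counts, cm$samples$group)
  expect_lte(median(disp$alpha_raw, na.rm = TRUE), 0.01)

  # constant counts within groups: raw method-of-moments alpha is 0
  mc <- cbind(a1 = c(5L, 9L), a2 = c(5L, 9L),
              b1 = c(7L, 2L), b2 = c(7L, 2L))
  dc <- estimate_dispersion(mc, groups = c("a", "a", "b", "b"),
                            sf = rep(1, 4))
  expect_equal(dc$alpha_raw, c(0, 0))

  # NB truth alpha = 0.2 at n = 50 per group: shrunken median in [0.1, 0.3]
  cm2 <- generate_counts(panel, n_per_group = 50, depths = rep(1, 100),
                         alpha = 0.2, seed = 24)
  d2 <- estimate_dispersion(cm2$counts, cm2$samples$group)
  med <- median(d2$alpha_shrunk, na.rm = TRUE)
  expect_gte(med, 0.1)
  expect_lte(med, 0.3)

  # all-zero genes are excluded
  mz <- rbind(g1 = c(0L, 0L, 0L, 0L), g2 = c(5L, 6L, 7L, 8L))
  dz <- estimate_dispersion(mz, groups = c("a", "a", "b", "b"),
                            sf = rep(1, 4))
  expect_true(is.na(dz$alpha_raw[1]))
})

test_that("Wald tests behave correctly on degenerate and null inputs", {
  # identical group means: log2FC exactly 0
  m <- cbind(wt1 = c(10L, 50L), wt2 = c(30L, 70L),
             kd1 = c(10L, 50L), kd2 = c(30L, 70L))
  de <- wald_test(m, groups = c("wild_type", "wild_type", "rnai", "rnai"),
                  sf = rep(1, 4), alphas = c(0.05, 0.05))
  expect_equal(de$log2fc, c(0, 0))
  expect_true(all(!de$significant))

  # all-zero gene: NA p-value, never significant
  mz <- rbind(g1 = c(0L, 0L, 0L, 0L), g2 = c(5L, 9L, 50L, 90L))
  dez <- suppressWarnings(
    wald_test(mz, groups = c("wild_type", "wild_type", "rnai", "rnai"),
              sf = rep(1, 4), alphas = c(0.05, 0.05)))
  expect_true(is.na(dez$p_value[1]))
  expect_false(dez$significant[1])
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  # worked example: p = (.01, .02, .03, .04), m = 4 -> all 0.04
  expect_equal(brute_force_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))

  set.seed(601)
  for (j in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, "BH"), brute_force_bh(p),
                 tolerance = 1e-12)
  }

  # padj is never below p and respects the step-up ordering end to end
  panel <- build_panel(n_background = 300)
  cm <- generate_counts(panel, seed = 25)
  de <- run_de(cm)
  ok <- !is.na(de$padj)
  expect_true(all(de$padj[ok] >= de$p_value[ok] - 1e-12))
  expect_equal(de$padj[ok], brute_force_bh(de$p_value[ok]),
               tolerance = 1e-12)
})

test_that("log2 fold changes are invariant to per-sample rescaling", {
  panel <- build_panel(n_background = 300)
  cm <- generate_counts(panel, seed = 26)
  de1 <- run_de(cm$counts, cm$samples$group)
  m2 <- cm$counts
  m2[, 1] <- m2[, 1] * 7L
  m2[, 5] <- m2[, 5] * 3L
  de2 <- run_de(m2, cm$samples$group)
  expect_equal(de2$log2fc, de1$log2fc, tolerance = 1e-10)
})

test_that("RPKM follows its defining formula exactly", {
  # 1000 reads on a 2 kb transcript in a 10^7-read library: RPKM = 50
  m <- matrix(c(1000L, 10L^7 - 1000L), nrow = 2)
  rownames(m) <- c("target", "rest")
  r <- rpkm(m, gene_lengths = c(2000, 1e5))
  expect_equal(unname(r["target", 1]), 50)

  # zero counts give zero RPKM; doubling depth at fixed count halves RPKM
  expect_equal(unname(rpkm(matrix(c(0L, 100L), 2), c(500, 500))[1, 1]), 0)
  m2 <- matrix(c(40L, 60L), nrow = 2)
  m3 <- matrix(c(40L, 160L), nrow = 2)
  expect_equal(rpkm(m3, c(1000, 1000))[1, 1],
               rpkm(m2, c(1000, 1000))[1, 1] / 2)

  expect_error(rpkm(matrix(0L, 2, 1), c(100, 100)), "zero total")

  # exact integer identity on random inputs
  set.seed(602)
  mm <- matrix(rpois(60, 50), 10)
  ll <- sample(500:5000, 10)
  expect_equal(rpkm(mm, ll),
               sweep(mm * 1e9 / ll, 2, colSums(mm), `/`))
})

test_that("pathway summary reports the EBG/LBG dichotomy on planted effects", {
  panel <- build_panel()
  cm <- generate_counts(panel, seed = 27)
  de <- run_de(cm)
  pw <- pathway_summary(de, panel)
  lbg <- pw[pw$role == "LBG", ]
  expect_true(all(lbg$all_copies_down))
  expect_true(all(lbg$dichotomy_call == "LBG-like coordinate-down"))
  ebg <- pw[pw$role == "EBG", ]
  expect_true(all(!ebg$all_copies_down))
  expect_true(all(ebg$dichotomy_call == "EBG-like mixed"))

  # null data: no class looks coordinately down
  p0 <- build_panel(effect_preset_null())
  cm0 <- generate_counts(p0, seed = 28)
  pw0 <- pathway_summary(run_de(cm0), p0)
  expect_true(all(pw0$dichotomy_call == "EBG-like mixed"))
})

test_that("regulator table reports fold-downs and handles null data", {
  p0 <- build_panel(effect_preset_null(), n_background = 500)
  cm0 <- generate_counts(p0, seed = 29)
  rt0 <- regulator_table(run_de(cm0), p0)
  expect_equal(nrow(rt0), 6)
  expect_true(all(abs(log2(rt0$fold_down)) < 1))

  panel <- build_panel()
  cm <- generate_counts(panel, seed = 30)
  rt <- regulator_table(run_de(cm), panel)
  rto <- rt$fold_down[rt$subrole %in% c("RTO1", "RTO2")]
  act <- rt$fold_down[rt$subrole %in% c("MYB5a", "bHLH1", "bHLH2", "WD40a")]
  expect_true(min(rto) > max(act))
})

test_that("exact segregation test matches enumeration and binom.test", {
  # 6 of 8 under 3:1 is the modal outcome: two-sided p = 1
  s <- segregation_binomial(8, 6, ratio = 3)
  expect_equal(s$modal_count, 6)
  expect_equal(s$p_value, 1)
  expect_equal(sum(s$pmf$prob), 1, tolerance = 1e-12)

  # 4 of 4 under 1:1: pmf(4) = (1/2)^4
  s2 <- segregation_binomial(4, 4, ratio = 1)
  expect_equal(s2$pmf$prob[s2$pmf$k == 4], 0.0625)

  # independent cross-check against stats::binom.test
  for (case in list(c(8, 6, 3), c(8, 2, 3), c(20, 10, 3), c(12, 12, 1))) {
    ours <- segregation_binomial(case[1], case[2], case[3])
    ref <- stats::binom.test(case[2], case[1],
                             p = case[3] / (case[3] + 1))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(segregation_binomial(8, 6, ratio = -1), "ratio")
})
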