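test_that("layout construction enforces non-empty zones and positive spacing", {
  lay <- petal_layout(nrow = 12, ncol = 8, h = 0.5)
  expect_equal(sort(unique(as.vector(lay$zone))), c("lobe", "nectar_guide"))
  expect_equal(sum(lay$zone == "nectar_guide"), 4 * 8)
  expect_error(petal_layout(h = 0), "h")
  expect_error(petal_layout(nrow = 3, guide_fraction = 0.01), "non-empty")
})

test_that("the explicit scheme rejects time steps above the stability bound", {
  p <- petal_params()
  lay <- petal_layout(nrow = 12, ncol = 8)
  bound <- lay$h^2 / (4 * max(p$D_a, p$D_i))
  err <- tryCatch(integrate_rd(p, lay, dt = bound * 1.5, t_end = 1, seed = 1),
                  error = function(e) conditionMessage(e))
  expect_match(err, "stability bound")
  expect_match(err, sprintf("%g", bound), fixed = TRUE)
})

test_that("the no-flux diffusion operator conserves mass", {
  set.seed(500)
  M <- matrix(runif(48 * 30), 48, 30)
  lap <- mbwsim:::laplacian_noflux(M, h = 0.5)
  # total mass change from diffusion alone is zero up to rounding
  expect_lt(abs(sum(lap)) / sum(M), 1e-12)
  # constant fields are invariant
  expect_equal(max(abs(mbwsim:::laplacian_noflux(matrix(2, 5, 7), 1))), 0)
})

test_that("noise-free simulation from a stable homogeneous state stays uniform", {
  p <- petal_params(sigma_a = 0.05)  # stable low state, no Turing band
  lay <- petal_layout(nrow = 16, ncol = 12)
  fld <- integrate_rd(p, lay, t_end = 20, noise_amplitude = 0, seed = 3)
  cv <- stats::sd(fld$a) / mean(fld$a)
  expect_lt(cv, 1e-8)
  expect_true(all(fld$a >= 0 & fld$i >= 0))
})

test_that("pattern summaries match brute-force component counting", {
  lay <- petal_layout(nrow = 20, ncol = 20, h = 1, guide_fraction = 0.5)

  # all-zero field
  s0 <- summarize_pattern(matrix(0, 20, 20), lay)
  w0 <- s0[s0$zone == "whole", ]
  expect_equal(w0$classification, "uniform_low")
  expect_equal(w0$spot_count, 0L)
  expect_equal(w0$pigmented_area_fraction, 0)

  # uniform field above the pigmentation cutoff
  s1 <- summarize_pattern(matrix(1.3, 20, 20), lay)
  w1 <- s1[s1$zone == "whole", ]
  expect_equal(w1$classification, "uniform_high")
  expect_equal(w1$pigmented_area_fraction, 1)
  expect_equal(w1$spot_count, 0L)

  # two disjoint 3x3 supra-threshold blocks
  f <- matrix(0, 20, 20)
  f[3:5, 3:5] <- 1
  f[12:14, 9:11] <- 1
  s2 <- summarize_pattern(f, lay, margin_cells = 0)
  w2 <- s2[s2$zone == "whole", ]
  expect_equal(w2$classification, "spotted")
  expect_equal(w2$spot_count, 2L)
  expect_equal(w2$spot_count, flood_fill_components(f >= w2$threshold[1]))
  expect_equal(w2$pigmented_area_fraction, 18 / 400)

  # random masks: igraph-based counting equals flood fill
  set.seed(501)
  for (j in 1:10) {
    mask <- matrix(runif(15 * 15) < 0.35, 15, 15)
    expect_equal(mbwsim:::count_components(mask)$n,
                 flood_fill_components(mask))
  }
})

test_that("empty zones yield no summary row", {
  lay1 <- line_layout(64, 0.5)  # no nectar guide
  s <- summarize_pattern(matrix(0.2, 1, 64), lay1)
  expect_false("nectar_guide" %in% s$zone)
  expect_true(all(c("lobe", "whole") %in% s$zone))
})

test_that("identical seed and configuration reproduce summaries exactly", {
  p <- petal_params()
  lay <- petal_layout(nrow = 24, ncol = 16)
  pre <- genotype_presets("F1")
  f1 <- integrate_rd(p, lay, pre, t_end = 30, seed = 9)
  f2 <- integrate_rd(p, lay, pre, t_end = 30, seed = 9)
  expect_identical(f1$a, f2$a)
  expect_identical(summarize_pattern(f1), summarize_pattern(f2))
  f3 <- integrate_rd(p, lay, pre, t_end = 30, seed = 10)
  expect_false(identical(f1$a, f3$a))
})

test_that("simulated 1D wavelength agrees with the dispersion prediction", {
  p <- turing_fixture()
  rep <- linear_stability(p, seq(0.05, 6, length.out = 400))
  expect_true(rep$turing_unstable)
  lambda_pred <- 2 * pi / rep$k_max

  fld <- integrate_rd(p, line_layout(256, 0.5), t_end = 80, seed = 7)
  lambda_sim <- dominant_wavelength(fld)
  expect_gt(lambda_sim, lambda_pred / 2)
  expect_lt(lambda_sim, lambda_pred * 2)
})

test_that("field export writes readable delimited matrices", {
  p <- petal_params(sigma_a = 0.05)
  lay <- petal_layout(nrow = 10, ncol = 6)
  fld <- integrate_rd(p, lay, t_end = 5, noise_amplitude = 0, seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_grid_field(fld, dir)
  expect_true(all(file.exists(paths)))
  back <- as.matrix(utils::read.table(paths[1], skip = 1))
  expect_equal(unname(back), unname(fld$a), tolerance = 1e-12)
})
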