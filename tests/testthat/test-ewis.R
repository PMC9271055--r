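test_that("interaction fit matches the explicit sandwich matrix formula", {
  # fixed 8-observation fixture
  y <- c(1.2, 0.4, -0.3, 2.1, 1.7, -0.9, 0.2, 1.1)
  g <- c(0, 1, 2, 0, 1, 2, 1, 0)
  e <- c(0.5, -1.2, 0.3, 1.8, -0.4, -0.9, 1.1, 0.0)
  fit <- gei_test(y, g, e, min_n = 8)
  oracle <- oracle_sandwich_gxe(y, g, e)
  expect_equal(fit$beta_interaction, oracle$beta, tolerance = 1e-10)
  expect_equal(fit$se_interaction, oracle$se, tolerance = 1e-10)
  expect_equal(fit$p_value, 2 * pnorm(-abs(fit$z)), tolerance = 1e-10)
})

test_that("robust SEs match the matrix oracle on random designs", {
  set.seed(61)
  for (i in 1:200) {
    n <- sample(20:60, 1)
    g <- rbinom(n, 2, runif(1, 0.2, 0.5))
    if (length(unique(g)) < 2) next
    e <- rnorm(n)
    y <- 0.2 * g + 0.1 * e + rnorm(n) * (1 + 0.3 * g)  # heteroskedastic
    fit <- gei_test(y, g, e)
    oracle <- oracle_sandwich_gxe(y, g, e)
    expect_equal(fit$beta_interaction, oracle$beta, tolerance = 1e-10)
    expect_equal(fit$se_interaction, oracle$se, tolerance = 1e-10)
  }
})

test_that("degenerate interaction designs raise collinearity errors", {
  g <- rbinom(50, 2, 0.4); y <- rnorm(50)
  expect_error(gei_test(y, g, rep(1, 50)), "collinear",
               class = "vqtlewis_degenerate_error")
  expect_error(gei_test(y, g, rnorm(50), covariates = cbind(g2 = g)),
               "collinear", class = "vqtlewis_degenerate_error")
  expect_error(gei_test(y[1:5], g[1:5], rnorm(5)),
               class = "vqtlewis_input_error")
})

test_that("an exact interaction fit is flagged with a floored p", {
  set.seed(62)
  g <- rbinom(200, 2, 0.4); e <- rnorm(200)
  fit <- gei_test(g * e, g, e)
  expect_true(fit$exact_fit)
  expect_equal(fit$beta_interaction, 1, tolerance = 1e-8)
  expect_lte(fit$p_value, 1e-300)
})

test_that("Bonferroni threshold arithmetic over pairs and effective exposures", {
  expect_equal(bonferroni_threshold(0.05, 184, 1156.2), 2.3503e-7,
               tolerance = 1e-4)
  expect_equal(bonferroni_threshold(0.05, 1, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 11.1 * 1e6), 4.50e-9,
               tolerance = 1e-3)
  expect_error(bonferroni_threshold(0.05, 0), class = "vqtlewis_input_error")
})

test_that("ewis_scan emits the full grid and meta-analyzes across strata", {
  set.seed(63)
  cfg <- sim_config(n_samples = c(EUR = 800, AFR = 300), n_variants = 4,
                    seed = 63)
  st <- make_study(cfg)
  pairs <- tibble::tibble(variant = c("v1", "v2"), biomarker = "trait")
  exps <- c("body_mass_1", "body_fat_1", "lifestyle_1")
  out <- ewis_scan(st, pairs, exps)
  expect_identical(nrow(out), 6L)
  expect_true(all(out$n_strata == 2))
  expect_true(all(nchar(out$dir_string) == 2))
  # stratum missing an exposure: drop it from AFR -> '?' in direction string
  st2 <- st
  st2$strata$AFR$exposures$body_mass_1 <- NULL
  out2 <- ewis_scan(st2, pairs[1, ], "body_mass_1")
  expect_identical(substr(out2$dir_string, 2, 2), "?")
  expect_identical(out2$n_strata, 1L)
  expect_error(ewis_scan(st, tibble::tibble(v = "v1")),
               class = "vqtlewis_input_error")
})

test_that("conditional scan: single signal, duplicated exposure, chain length", {
  set.seed(64)
  n <- 2000
  g <- rbinom(n, 2, 0.3)
  e1 <- rnorm(n)
  y <- 0.2 * g + 0.2 * e1 + 0.25 * g * e1 + rnorm(n)
  exps <- tibble::tibble(e1 = e1, null1 = rnorm(n), null2 = rnorm(n))
  ch <- conditional_scan(y, g, exps, entry_threshold = 1e-3,
                         secondary_threshold = 0.05 / 3)
  expect_identical(ch$n_independent, 1L)
  expect_identical(ch$chain$exposure[1], "e1")
  # a duplicated column is skipped as collinear, not double counted
  exps_dup <- dplyr::mutate(exps, e1_copy = e1)
  ch2 <- conditional_scan(y, g, exps_dup, entry_threshold = 1e-3,
                          secondary_threshold = 0.05 / 4)
  expect_identical(ch2$n_independent, 1L)
  expect_true("e1_copy" %in% ch2$skipped)
})

test_that("two orthogonal planted interactions give a chain of length 2", {
  set.seed(65)
  n <- 6000
  g <- rbinom(n, 2, 0.3)
  e1 <- rnorm(n); e2 <- rnorm(n)
  y <- 0.1 * g + 0.2 * e1 + 0.1 * e2 + 0.25 * g * e1 + 0.2 * g * e2 + rnorm(n)
  exps <- tibble::tibble(e1 = e1, e2 = e2, null1 = rnorm(n))
  ch <- conditional_scan(y, g, exps, entry_threshold = 1e-4,
                         secondary_threshold = 1e-3)
  expect_identical(ch$n_independent, 2L)
  expect_setequal(ch$chain$exposure, c("e1", "e2"))
})

test_that("enrichment chi-square reproduces printed-scale contingency results", {
  r <- enrichment_chisq(49, 135, 145, 4268)
  expect_equal(signif(r$p_value, 2), 1.8e-52)
  big <- enrichment_chisq(847, 437073, 1590, 10501350)
  expect_lt(big$log10_p, -300)
  expect_identical(big$p_value, 0)
  # agreement with stats::chisq.test where p is representable
  ct <- suppressWarnings(chisq.test(rbind(c(49, 135), c(145, 4268))))
  expect_equal(r$statistic, unname(ct$statistic), tolerance = 1e-10)
  expect_equal(r$p_value, ct$p.value, tolerance = 1e-10)
})

test_that("chi-square edge behavior: independence, Yates monotonicity, errors", {
  even <- enrichment_chisq(10, 90, 20, 180)
  expect_lt(even$statistic, 0.1)
  expect_gt(even$p_value, 0.7)
  set.seed(66)
  for (i in 1:50) {
    cells <- rpois(4, 30) + 1
    corrected <- enrichment_chisq(cells[1], cells[2], cells[3], cells[4])
    plain <- enrichment_chisq(cells[1], cells[2], cells[3], cells[4],
                              continuity_correction = FALSE)
    expect_gte(plain$statistic, corrected$statistic)
  }
  expect_error(enrichment_chisq(0, 0, 5, 5), class = "vqtlewis_input_error")
  expect_error(enrichment_chisq(-1, 2, 3, 4), class = "vqtlewis_input_error")
})

test_that("exposure PCA separates planted latent factors", {
  set.seed(67)
  n <- 2000
  mass <- rnorm(n); fat <- rnorm(n)
  panel <- tibble::tibble(
    bmi = mass + 0.2 * rnorm(n), weight = mass + 0.2 * rnorm(n),
    waist = mass + 0.3 * rnorm(n),
    fat_pct = fat + 0.2 * rnorm(n), impedance = fat + 0.2 * rnorm(n)
  )
  pca <- exposure_pca(panel)
  # loadings orthonormal
  expect_equal(max(abs(crossprod(pca$loadings) - diag(5))), 0,
               tolerance = 1e-10)
  # component variances non-increasing
  expect_true(all(diff(pca$sdev) <= 1e-12))
  # first two components split the mass block from the fat block
  l1 <- abs(pca$loadings[, 1]); l2 <- abs(pca$loadings[, 2])
  mass_cols <- 1:3; fat_cols <- 4:5
  pc_mass <- if (mean(l1[mass_cols]) > mean(l1[fat_cols])) 1 else 2
  pc_fat <- 3 - pc_mass
  expect_gt(mean(abs(pca$loadings[mass_cols, pc_mass])),
            mean(abs(pca$loadings[fat_cols, pc_mass])))
  expect_gt(mean(abs(pca$loadings[fat_cols, pc_fat])),
            mean(abs(pca$loadings[mass_cols, pc_fat])))
  expect_error(exposure_pca(panel[1:3, ]), class = "vqtlewis_input_error")
})

test_that("stratified means cut exposures into balanced quantile bins", {
  set.seed(68)
  y <- rnorm(999); g <- rbinom(999, 2, 0.5); e <- sample(seq_len(999))
  cells <- stratified_means(y, g, as.numeric(e))
  bins <- cells |> dplyr::group_by(bin) |> dplyr::summarise(n = sum(n))
  expect_identical(bins$n, rep(333L, 3))
  expect_equal(sum(cells$mean * cells$n, na.rm = TRUE) / sum(cells$n),
               mean(y), tolerance = 1e-10)
})

test_that("a planted crossing interaction shows a trend only where it exists", {
  set.seed(69)
  n <- 30000
  g <- rbinom(n, 2, 0.5)
  e <- rnorm(n)
  slope <- c(0.5, 0.25, 0)[g + 1]  # positive slope in g=0, none in g=2
  y <- slope * e + rnorm(n, sd = 0.3)
  cells <- stratified_means(y, g, e)
  m0 <- cells$mean[cells$genotype == 0]
  m2 <- cells$mean[cells$genotype == 2]
  expect_true(all(diff(m0) > 0))
  expect_lt(max(abs(diff(m2))), 0.05)
})
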