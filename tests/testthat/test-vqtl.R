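test_that("the Levene statistic equals a one-way ANOVA on |y - class median|", {
  y <- c(0, 2, 1, 0, 4, 1, 0, 8, 3)
  g <- c(0, 0, 0, 1, 1, 1, 2, 2, 2)
  fit <- levene_median_test(y, g)
  oracle <- oracle_levene(y, g)
  expect_equal(fit$statistic, oracle$statistic)
  expect_equal(fit$p_value, oracle$p_value)
  expect_identical(fit$df1, 2L)
  expect_identical(fit$df2, 6L)
  expect_equal(sum(fit$n_i), fit$n)
})

test_that("two-per-class spreads make the deviation ANOVA diverge", {
  # with two observations per class the absolute deviations from the class
  # median are constant within class, so the within term vanishes: F -> Inf
  y <- c(0, 2, 0, 4, 0, 8)
  g <- c(0, 0, 1, 1, 2, 2)
  fit <- levene_median_test(y, g)
  expect_identical(fit$statistic, Inf)
  expect_identical(fit$p_value, 0)
  expect_equal(as.numeric(fit$z_i_bar), c(1, 2, 4))  # |y - class median|
})

test_that("Levene matches the brute-force oracle on random datasets", {
  set.seed(31)
  for (i in 1:200) {
    d <- random_levene_dataset()
    fit <- levene_median_test(d$y, d$g)
    oracle <- oracle_levene(d$y, d$g)
    expect_equal(fit$statistic, oracle$statistic, tolerance = 1e-10)
    expect_equal(fit$p_value, oracle$p_value, tolerance = 1e-10)
  }
})

test_that("Levene agrees with the Brown-Forsythe test in car", {
  skip_if_not_installed("car")
  set.seed(32)
  d <- random_levene_dataset(150)
  fit <- levene_median_test(d$y, d$g)
  ref <- car::leveneTest(d$y, factor(d$g), center = median)
  expect_equal(fit$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(fit$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("degenerate and monomorphic inputs raise typed errors", {
  expect_error(levene_median_test(c(1, 1, 2, 2), c(0, 0, 1, 1)),
               class = "vqtlewis_degenerate_error")  # constant within class
  expect_error(levene_median_test(rnorm(10), rep(0, 10)),
               "monomorphic", class = "vqtlewis_degenerate_error")
  # classes below min_class_count are dropped before k is counted
  expect_error(levene_median_test(rnorm(10), c(rep(0, 9), 1)),
               "monomorphic", class = "vqtlewis_degenerate_error")
  fit <- levene_median_test(rnorm(10), c(rep(0, 5), rep(1, 4), 2),
                            min_class_count = 2)
  expect_identical(fit$k, 2L)
})

test_that("two classes with identical value multisets give F = 0, p = 1", {
  y <- c(1, 3, 7, 1, 3, 7)
  g <- c(0, 0, 0, 1, 1, 1)
  fit <- levene_median_test(y, g)
  expect_equal(fit$statistic, 0)
  expect_equal(fit$p_value, 1)
})

test_that("back-transformation: beta/se is the signed z and p = 1 gives beta 0", {
  fit <- structure(list(p_value = 1, n = 98, z = c(0, 1), g = c(0, 1)),
                   class = "levene_fit")
  eff <- vqtl_direction_and_effect(fit, maf = 0.5)
  expect_equal(eff$beta, 0)
  expect_equal(eff$se, 1 / 7)  # 1/sqrt(2 * 0.25 * 98)
  set.seed(33)
  for (i in 1:50) {
    dir_sign <- sample(c(-1, 1), 1)
    fake <- structure(list(p_value = runif(1), n = sample(50:5000, 1),
                           z = c(0, dir_sign), g = c(0, 1)),
                      class = "levene_fit")
    eff <- vqtl_direction_and_effect(fake, maf = runif(1, 0.01, 0.5))
    expect_equal(eff$beta / eff$se, eff$z, tolerance = 1e-12)
    expect_identical(eff$direction, as.integer(dir_sign))
  }
  expect_error(vqtl_direction_and_effect(fit, maf = 0),
               class = "vqtlewis_input_error")
})

test_that("mirroring class spreads flips the vQTL direction, not its magnitude", {
  set.seed(34)
  n <- 600
  g <- rbinom(n, 2, 0.4)
  y_up <- rnorm(n, sd = 1 + 0.4 * g)      # spread grows with genotype
  y_down <- rnorm(n, sd = 1 + 0.4 * (2 - g))
  f_up <- levene_median_test(y_up, g)
  f_down <- levene_median_test(y_down, g)
  e_up <- vqtl_direction_and_effect(f_up, maf = 0.4)
  e_down <- vqtl_direction_and_effect(f_down, maf = 0.4)
  expect_identical(e_up$direction, 1L)
  expect_identical(e_down$direction, -1L)
})

test_that("ols_scan recovers the closed-form slope and is shift invariant", {
  fit <- ols_scan(c(0, 1, 1), c(0, 1, 2))
  expect_equal(fit$beta, 0.5)
  set.seed(35)
  g <- rbinom(100, 2, 0.3); y <- 0.2 * g + rnorm(100)
  a <- ols_scan(y, g); b <- ols_scan(y + 42, g)
  expect_equal(a$beta, b$beta)
  expect_equal(a$se, b$se)
  expect_equal(a$p_value, b$p_value)
  # classical lm oracle
  s <- summary(lm(y ~ g))$coefficients
  expect_equal(a$beta, s[2, 1], tolerance = 1e-12)
  expect_equal(a$se, s[2, 2], tolerance = 1e-12)
  expect_equal(a$p_value, s[2, 4], tolerance = 1e-12)
  expect_error(ols_scan(rnorm(10), rep(1, 10)),
               class = "vqtlewis_degenerate_error")
})

test_that("run_scan emits the schema, skips bad variants, and is deterministic", {
  set.seed(36)
  gm <- simulate_genotypes(300, 10, c(0.1, 0.45))
  gm$calls[, 4] <- 0L  # monomorphic
  y <- rnorm(300)
  out <- run_scan(gm, y, "vqtl", stratum = "EUR")
  expect_identical(nrow(out), 9L)
  expect_true(all(c("chrom", "pos", "id", "a1", "a2", "af", "n", "stat",
                    "beta", "se", "dir", "p", "kind", "stratum") %in% names(out)))
  expect_identical(attr(out, "skipped")$id, "v4")
  expect_true(all(out$kind == "vqtl"))
  # determinism: identical reruns byte-identical on disk
  d <- withr::local_tempdir()
  write_summary_stats(out, file.path(d, "a.tsv"))
  write_summary_stats(run_scan(gm, y, "vqtl", stratum = "EUR"),
                      file.path(d, "b.tsv"))
  expect_identical(readLines(file.path(d, "a.tsv")),
                   readLines(file.path(d, "b.tsv")))
  # me scan on same fixture
  me <- run_scan(gm, y, "me", stratum = "EUR")
  expect_identical(nrow(me), 9L)
  expect_true(all(me$dir == sign(me$beta)))
  expect_error(run_scan(gm, rep(NA_real_, 300), "vqtl"),
               class = "vqtlewis_input_error")
})

test_that("tidy and glance summarize Levene fits", {
  set.seed(37)
  d <- random_levene_dataset(100)
  fit <- levene_median_test(d$y, d$g)
  td <- tidy(fit)
  expect_identical(nrow(td), as.integer(fit$k))
  expect_equal(sum(td$n), fit$n)
  gl <- glance(fit)
  expect_identical(gl$p_value, fit$p_value)
})
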