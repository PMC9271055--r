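test_that("statin adjustment divides users' values by the factor", {
  expect_equal(adjust_for_statins(5.0, TRUE, 0.749), 6.67557, tolerance = 1e-5)
  expect_equal(adjust_for_statins(5.0, FALSE, 0.749), 5.0)
  expect_equal(adjust_for_statins(3.0, TRUE, 0.684), 4.38596, tolerance = 1e-5)
  expect_equal(adjust_for_statins(c(NA, 2), c(TRUE, TRUE), 0.719),
               c(NA, 2 / 0.719))
  expect_error(adjust_for_statins(1, TRUE, 0), class = "vqtlewis_input_error")
})

test_that("pre-processed biomarkers are standardized residuals", {
  set.seed(21)
  raw <- exp(rnorm(400, sd = 0.4))
  pb <- preprocess_biomarker(raw)
  expect_equal(mean(pb$values, na.rm = TRUE), 0, tolerance = 1e-8)
  expect_equal(var(pb$values, na.rm = TRUE), 1, tolerance = 1e-8)
  expect_identical(pb$steps, c("log", "residualize", "outlier_mask", "zscore"))
})

test_that("residuals are orthogonal to covariates with a planted effect", {
  set.seed(22)
  x <- rnorm(500)
  raw <- exp(2 * x + rnorm(500, sd = 0.5))
  pb <- preprocess_biomarker(raw, covariates = cbind(x))
  expect_lt(abs(cor(pb$values, x, use = "complete.obs")), 1e-10)
})

test_that("a residual planted beyond the outlier threshold is masked", {
  set.seed(23)
  raw <- exp(rnorm(500, sd = 0.3))
  r0 <- preprocess_biomarker(raw)  # baseline residual spread
  raw[7] <- exp(log(raw[7]) + 12 * sd(log(raw)))  # far beyond 5 SD
  pb <- preprocess_biomarker(raw, outlier_sd = 5)
  expect_true(is.na(pb$values[7]))
  expect_gte(pb$n_masked, 1)
  expect_equal(r0$n_masked, 0)
})

test_that("pre-processing is invariant to covariate scaling and rejects bad input", {
  set.seed(24)
  x <- rnorm(300)
  raw <- exp(0.5 * x + rnorm(300, sd = 0.3))
  a <- preprocess_biomarker(raw, covariates = cbind(x))
  b <- preprocess_biomarker(raw, covariates = cbind(1000 * x))
  expect_equal(a$values, b$values, tolerance = 1e-10)
  bad <- raw; bad[5] <- -1
  expect_error(preprocess_biomarker(bad), "sample 5",
               class = "vqtlewis_input_error")
  expect_error(preprocess_biomarker(raw, covariates = cbind(x, x)),
               "rank", class = "vqtlewis_input_error")
})

test_that("statin adjustment feeds through the full pre-processing", {
  set.seed(25)
  user <- rep(c(TRUE, FALSE), 150)
  raw <- exp(rnorm(300, sd = 0.3)) * ifelse(user, 0.749, 1)
  pb <- preprocess_biomarker(raw, statin = list(user = user, factor = 0.749))
  expect_identical(pb$steps[1:2], c("statin_adjust", "log"))
  # dividing users by the factor removes the planted group difference
  expect_gt(t.test(pb$values ~ user)$p.value, 1e-4)
})

test_that("inverse normal transform follows the Blom formula", {
  # middle of 3 distinct values maps to 0
  expect_equal(inverse_normal_transform(c(10, 2, 5))[3], 0)
  # smallest of 5: rank 1 -> qnorm((1 - 3/8) / (5 - 3/4 + 1))
  v <- inverse_normal_transform(c(3, 9, 27, 81, 243))
  expect_equal(v[1], qnorm(0.625 / 5.25))
  expect_equal(v[1], qnorm(0.119048), tolerance = 1e-5)
  # monotone order preserved, missing propagates
  x <- c(rnorm(50), NA)
  out <- inverse_normal_transform(x)
  expect_true(is.na(out[51]))
  expect_identical(order(out[1:50]), order(x[1:50]))
  expect_error(inverse_normal_transform(rep(1, 10)),
               class = "vqtlewis_degenerate_error")
})

test_that("INT output is close to normal at large n", {
  set.seed(26)
  x <- rexp(10000)  # strongly skewed input
  z <- inverse_normal_transform(x)
  probs <- seq(0.01, 0.99, by = 0.01)
  expect_lt(max(abs(quantile(z, probs) - qnorm(probs))), 0.02)
})

test_that("exposure preparation codes types and drops degenerate columns", {
  set.seed(27)
  n <- 200
  raw <- tibble::tibble(
    bmi = rnorm(n, 27, 4),
    cups_tea = rpois(n, 3),
    smoker = sample(c("never", "ever"), n, TRUE),
    activity = factor(sample(c("low", "mid", "high"), n, TRUE),
                      levels = c("low", "mid", "high")),
    meds = sample(c("aspirin", "statin;aspirin", "statin", ""), n, TRUE),
    all_yes = rep("yes", n),
    sparse = c(rnorm(5), rep(NA, n - 5))
  )
  es <- prepare_exposures(raw, types = c(
    bmi = "continuous", cups_tea = "integer", smoker = "categorical-single",
    activity = "categorical-single", meds = "categorical-multiple",
    all_yes = "categorical-single", sparse = "continuous"
  ), min_minor_count = 5)
  expect_equal(var(es$data$bmi, na.rm = TRUE), 1, tolerance = 0.05)
  expect_identical(
    es$coding$coding[es$coding$exposure == "bmi"], "continuous-INT")
  expect_identical(sort(unique(es$data$activity)), c(0, 1, 2))
  expect_true(all(c("meds__aspirin", "meds__statin") %in% names(es$data)))
  expect_true("all_yes" %in% es$dropped$exposure)
  expect_true("sparse" %in% es$dropped$exposure)
  expect_setequal(unique(es$data$smoker), c(0, 1))
  expect_error(prepare_exposures(raw["bmi"], types = c(x = "continuous")),
               "no input type", class = "vqtlewis_input_error")
})

test_that("ordinal coding enumerates ordered levels as 0..k-1", {
  f <- factor(c("low", "high", "mid", "low"), levels = c("low", "mid", "high"))
  es <- prepare_exposures(tibble::tibble(x = f),
                          types = c(x = "categorical-single"),
                          min_nonmissing = 1, min_minor_count = 1)
  expect_identical(es$data$x, c(0, 2, 1, 0))
})

test_that("effective test count has the exact 2-variable closed form", {
  # construct exact sample correlation 0.5: y = r x + sqrt(1-r^2) z, x _|_ z
  x <- c(1, 1, -1, -1); z <- c(1, -1, 1, -1)
  y <- 0.5 * x + sqrt(0.75) * z
  et <- effective_tests(cbind(x, y))
  expect_equal(sort(et$eigenvalues), c(0.5, 1.5))
  expect_equal(et$n_effective, 1.6)
})

test_that("effective test count hits its bounds and is permutation invariant", {
  set.seed(28)
  m <- matrix(rnorm(5000 * 5), ncol = 5)
  et <- effective_tests(m)
  expect_gt(et$n_effective, 4.9)   # independent variables -> ~p
  expect_lte(et$n_effective, 5)
  dup <- m[, c(1, 1, 1)]
  expect_equal(effective_tests(dup)$n_effective, 1)
  perm <- effective_tests(m[, c(3, 1, 5, 2, 4)])
  expect_equal(perm$n_effective, et$n_effective, tolerance = 1e-12)
  expect_error(effective_tests(m[, 1, drop = FALSE]),
               class = "vqtlewis_input_error")
  expect_error(effective_tests(cbind(m[, 1], 1)), "zero variance",
               class = "vqtlewis_input_error")
})
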