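#' Median-based Levene (Brown-Forsythe) test for variance heterogeneity
#'
#' Tests whether a phenotype's variance differs across genotype classes.
#' Each observation is replaced by its absolute deviation from the median of
#' its genotype class, `z_ij = |y_ij - median_i|`, and a one-way ANOVA is
#' run on the `z` values:
#' `F = [(n-k)/(k-1)] * sum_i n_i (zbar_i - zbar)^2 / sum_ij (z_ij - zbar_i)^2`
#' with `F(k-1, n-k)` under the null of equal variances. Median centering
#' makes the test robust to non-normal phenotypes, which matters for
#' log-scale biomarkers.
#'
#' Incomplete cases are excluded; genotype classes with fewer than
#' `min_class_count` observations are dropped before `k` is counted.
#'
#' @param y Numeric phenotype vector (or a `prepared_biomarker`).
#' @param g Genotype vector (additively coded 0/1/2; any discrete coding
#'   works).
#' @param min_class_count Minimum observations for a genotype class to enter
#'   the test (default 2).
#' @return A `levene_fit`: list with `statistic`, `df1`, `df2`, `p_value`,
#'   `k`, `n`, `n_i`, `z_i_bar`, `z_bar`, and the per-sample deviations `z`
#'   with their genotype codes `g` (complete cases, surviving classes).
#' @examples
#' set.seed(1)
#' g <- rbinom(500, 2, 0.4)
#' y <- rnorm(500, sd = 1 + 0.3 * g)
#' levene_median_test(y, g)
#' @export
levene_median_test <- function(y, g, min_class_count = 2) {
  y <- as_phenotype_vector(y)
  if (length(y) != length(g)) stop_input("`y` and `g` must have equal length")
  obs <- !is.na(y) & !is.na(g)
  y <- y[obs]; g <- g[obs]
  counts <- table(g)
  keep_classes <- names(counts)[counts >= min_class_count]
  in_class <- as.character(g) %in% keep_classes
  y <- y[in_class]; g <- g[in_class]
  f <- factor(g)
  k <- nlevels(f)
  if (k < 2) {
    stop_degenerate("fewer than 2 genotype classes with >= %d observations (monomorphic)",
                    min_class_count)
  }
  n <- length(y)
  med <- tapply(y, f, median)
  z <- abs(y - med[f])
  z_i_bar <- tapply(z, f, mean)
  n_i <- as.integer(table(f))
  z_bar <- mean(z)
  between <- sum(n_i * (z_i_bar - z_bar)^2)
  within <- sum((z - z_i_bar[f])^2)
  if (within <= 0 && between <= 0) {
    stop_degenerate("all absolute deviations are constant; variance test is degenerate")
  }
  # within-class-constant deviations with real between-class spread: the
  # F ratio diverges; report Inf with p = 0 rather than erroring
  F_stat <- if (within <= 0) Inf else (n - k) / (k - 1) * between / within
  structure(list(
    statistic = F_stat, df1 = k - 1L, df2 = n - k,
    p_value = pf(F_stat, k - 1, n - k, lower.tail = FALSE),
    k = k, n = n, n_i = stats::setNames(n_i, levels(f)),
    z_i_bar = z_i_bar, z_bar = z_bar,
    z = as.numeric(z), g = as.numeric(g)
  ), class = "levene_fit")
}

#' @export
print.levene_fit <- function(x, ...) {
  cat(sprintf("Median-based Levene test: F(%d, %d) = %.4g, p = %.4g (k = %d, n = %d)\n",
              x$df1, x$df2, x$statistic, x$p_value, x$k, x$n))
  invisible(x)
}

#' Direction and back-transformed effect size for a variance-QTL test
#'
#' The Levene test is direction-free; a sign is recovered by regressing the
#' absolute deviations from the class medians on the additively coded
#' genotype. The signed z-statistic `z = dir * qnorm(1 - p/2)` is then
#' back-transformed to an effect size and standard error on the
#' per-allele scale:
#' `b = z / sqrt(2 p (1-p) (n + z^2))`, `SE = 1 / sqrt(2 p (1-p) (n + z^2))`
#' where `p` is the minor allele frequency, so `b / SE = z` by construction.
#'
#' @param fit A `levene_fit` from [levene_median_test()].
#' @param maf Minor allele frequency in `(0, 1)`.
#' @param n Sample size used in the back-transformation (defaults to the
#'   fit's `n`).
#' @return List with `direction` (-1, 0, +1), `z`, `beta`, `se`.
#' @export
vqtl_direction_and_effect <- function(fit, maf, n = fit$n) {
  stopifnot(inherits(fit, "levene_fit"))
  if (!is_scalar_number(maf) || maf <= 0 || maf >= 1) {
    stop_input("`maf` must lie strictly between 0 and 1")
  }
  slope <- ols_slope(fit$g, fit$z)
  direction <- sign(slope)
  z <- direction * p_to_z(fit$p_value)
  denom <- sqrt(2 * maf * (1 - maf) * (n + z^2))
  list(direction = as.integer(direction), z = z,
       beta = z / denom, se = 1 / denom)
}

# closed-form simple-regression slope; returns 0 for constant x
ols_slope <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(0)
  sum((x - mean(x)) * (y - mean(y))) / sxx
}

#' Single-variant test of a genetic effect on the phenotype mean
#'
#' Ordinary least squares of the (pre-residualized) phenotype on the
#' additively coded genotype, with classical standard error and two-sided
#' t-test. No covariates are included; the phenotype is assumed already
#' residualized.
#'
#' @param y Numeric phenotype vector (or `prepared_biomarker`).
#' @param g Genotype vector.
#' @return List with `beta`, `se`, `statistic` (t), `p_value`, `n`.
#' @export
ols_scan <- function(y, g) {
  y <- as_phenotype_vector(y)
  if (length(y) != length(g)) stop_input("`y` and `g` must have equal length")
  obs <- !is.na(y) & !is.na(g)
  y <- y[obs]; g <- as.numeric(g[obs])
  n <- length(y)
  if (n < 3) stop_input("need at least 3 complete cases")
  sxx <- sum((g - mean(g))^2)
  if (sxx == 0) stop_degenerate("genotype is constant")
  beta <- sum((g - mean(g)) * (y - mean(y))) / sxx
  r <- y - mean(y) - beta * (g - mean(g))
  sigma2 <- sum(r^2) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  t_stat <- if (se > 0) beta / se else sign(beta) * Inf
  list(beta = beta, se = se, statistic = t_stat,
       p_value = 2 * pt(abs(t_stat), n - 2, lower.tail = FALSE), n = n)
}

#' Genome-wide single-stratum scan
#'
#' Runs the variance-heterogeneity test (`kind = "vqtl"`) or the mean-effect
#' test (`kind = "me"`) for every variant in a genotype matrix against one
#' prepared phenotype, with per-test complete-case handling. Variants
#' failing the per-stratum MAF or genotype-class rules are omitted from the
#' results and listed with a reason in the `skipped` attribute.
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotype A `prepared_biomarker` or numeric vector aligned with
#'   the genotype samples.
#' @param kind `"vqtl"` or `"me"`.
#' @param biomarker Label recorded in the output (default `"trait"`).
#' @param stratum Stratum (ancestry) label recorded in the output.
#' @param min_class_count Per-class minimum for the Levene test (default 2).
#' @param min_maf Per-stratum MAF filter applied on observed calls
#'   (default 0: polymorphic only).
#' @return Summary-statistic tibble (one row per tested variant) with
#'   columns `chrom, pos, id, a1, a2, af, n, stat, beta, se, dir, p, kind,
#'   stratum`; skipped variants in `attr(, "skipped")`.
#' @export
run_scan <- function(genotypes, phenotype, kind = c("vqtl", "me"),
                     biomarker = "trait", stratum = "ALL",
                     min_class_count = 2, min_maf = 0) {
  kind <- match.arg(kind)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  y_full <- as_phenotype_vector(phenotype)
  if (length(y_full) != length(genotypes$samples)) {
    stop_input("phenotype length %d does not match %d genotype samples",
               length(y_full), length(genotypes$samples))
  }
  if (all(is.na(y_full))) stop_input("phenotype and genotype samples do not overlap")

  rows <- vector("list", nrow(genotypes$variants))
  skipped <- list()
  for (j in seq_len(nrow(genotypes$variants))) {
    v <- genotypes$variants[j, ]
    g <- genotypes$calls[, j]
    obs <- !is.na(y_full) & !is.na(g)
    af_obs <- mean(g[obs]) / 2
    maf <- min(af_obs, 1 - af_obs)
    if (!sum(obs) || is.na(maf) || maf <= min_maf || maf == 0) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(id = v$id, reason = "maf")
      next
    }
    res <- tryCatch({
      if (kind == "vqtl") {
        fit <- levene_median_test(y_full[obs], g[obs], min_class_count)
        eff <- vqtl_direction_and_effect(fit, maf = maf, n = fit$n)
        list(n = fit$n, stat = fit$statistic, p = fit$p_value,
             dir = eff$direction, beta = eff$beta, se = eff$se)
      } else {
        fit <- ols_scan(y_full[obs], g[obs])
        list(n = fit$n, stat = fit$statistic, p = fit$p_value,
             dir = as.integer(sign(fit$beta)), beta = fit$beta, se = fit$se)
      }
    }, vqtlewis_degenerate_error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(id = v$id, reason = res)
      next
    }
    rows[[j]] <- tibble::tibble(
      chrom = v$chrom, pos = v$pos, id = v$id, a1 = v$alt, a2 = v$ref,
      af = af_obs, n = res$n, stat = res$stat, beta = res$beta, se = res$se,
      dir = res$dir, p = res$p, kind = kind, stratum = stratum,
      biomarker = biomarker
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- if (length(skipped)) dplyr::bind_rows(skipped) else
    tibble::tibble(id = character(), reason = character())
  out
}
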