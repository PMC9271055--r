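#' Gene-environment interaction test with robust standard errors
#'
#' Fits `y ~ g + e + g:e` (plus optional extra covariates) by ordinary
#' least squares and tests the interaction coefficient using a
#' heteroskedasticity-consistent sandwich standard error
#' (`sandwich::vcovHC`, default HC0), with a two-sided normal p-value.
#' Robust errors matter here because a true interaction (or any unmodeled
#' variance heterogeneity) makes the residual variance genotype-dependent,
#' which classical OLS standard errors ignore.
#'
#' @param y Phenotype (`prepared_biomarker` or numeric vector).
#' @param g Genotype vector (dosage or hard calls).
#' @param e Exposure vector.
#' @param covariates Optional numeric matrix/data frame of extra
#'   covariates.
#' @param se_type Sandwich flavor: `"HC0"` (default), `"HC1"`, `"HC3"`.
#' @param min_n Minimum complete cases (default 10).
#' @return A `gei_fit`: list with `coefficients` (tibble: term, estimate,
#'   robust se, z, p), `beta_interaction`, `se_interaction`, `z`,
#'   `p_value`, `n`, `exact_fit` flag.
#' @export
gei_test <- function(y, g, e, covariates = NULL,
                     se_type = c("HC0", "HC1", "HC3"), min_n = 10) {
  se_type <- match.arg(se_type)
  y <- as_phenotype_vector(y)
  g <- as.numeric(g); e <- as.numeric(e)
  if (length(y) != length(g) || length(y) != length(e)) {
    stop_input("`y`, `g`, `e` must have equal length")
  }
  X_extra <- NULL
  if (!is.null(covariates)) {
    X_extra <- as.matrix(covariates)
    if (is.null(colnames(X_extra))) {
      colnames(X_extra) <- paste0("cov", seq_len(ncol(X_extra)))
    }
  }
  obs <- !is.na(y) & !is.na(g) & !is.na(e)
  if (!is.null(X_extra)) obs <- obs & complete.cases(X_extra)
  if (sum(obs) < min_n) stop_input("fewer than %d complete cases", min_n)
  d <- data.frame(y = y[obs], g = g[obs], e = e[obs])
  X <- cbind(`(Intercept)` = 1, g = d$g, e = d$e, `g:e` = d$g * d$e)
  if (!is.null(X_extra)) X <- cbind(X, X_extra[obs, , drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_degenerate("design matrix is rank deficient (collinear column: %s)",
                    dropped[1])
  }
  fit <- lm(d$y ~ X - 1)
  est <- coef(fit)
  names(est) <- colnames(X)
  exact_fit <- sum(resid(fit)^2) < 1e-12 * max(1, sum(d$y^2))
  vc <- if (exact_fit) {
    suppressWarnings(sandwich::vcovHC(fit, type = se_type))
  } else {
    sandwich::vcovHC(fit, type = se_type)
  }
  rse <- sqrt(diag(vc))
  names(rse) <- colnames(X)
  if (exact_fit || any(rse[c("g", "e", "g:e")] == 0)) {
    # perfect fit: SEs degenerate; report a floored p rather than NaN
    z <- ifelse(est == 0, 0, sign(est) * Inf)
    p <- ifelse(est == 0, 1, P_FLOOR)
  } else {
    z <- est / rse
    p <- 2 * pnorm(-abs(z))
  }
  coefs <- tibble::tibble(term = colnames(X), estimate = unname(est),
                          se_robust = unname(rse), z = unname(z),
                          p_value = unname(p))
  structure(list(
    coefficients = coefs,
    beta_g = est[["g"]], beta_e = est[["e"]],
    beta_interaction = est[["g:e"]],
    se_interaction = rse[["g:e"]],
    z = unname(z[match("g:e", colnames(X))]),
    p_value = unname(p[match("g:e", colnames(X))]),
    n = nrow(d), se_type = se_type, exact_fit = exact_fit
  ), class = "gei_fit")
}

#' @export
print.gei_fit <- function(x, ...) {
  cat(sprintf("GEI test (robust %s SE, n = %d): beta_gxe = %.4g (SE %.4g), p = %.4g%s\n",
              x$se_type, x$n, x$beta_interaction, x$se_interaction, x$p_value,
              if (x$exact_fit) " [exact fit]" else ""))
  invisible(x)
}

#' Exposome-wide interaction scan over prioritized variant-biomarker pairs
#'
#' For every (variant, biomarker) pair and every exposure, runs
#' [gei_test()] within each stratum and combines interaction estimates
#' across strata by inverse-variance-weighted fixed-effect meta-analysis.
#' The full pairs-by-exposures grid is emitted; triplets whose fits fail in
#' every stratum appear as `NA` rows.
#'
#' @param study A list of strata; each stratum is a list with elements
#'   `genotypes` (a [genotype_matrix()]), `biomarkers` (named list of
#'   phenotype vectors), `exposures` (tibble of numeric exposures).
#'   A `synthetic_study` from [make_study()] works directly.
#' @param pairs Tibble with columns `variant`, `biomarker`.
#' @param exposures Character vector of exposure names (default: all
#'   exposures present in the first stratum).
#' @param se_type Sandwich flavor passed to [gei_test()].
#' @return Tibble with one row per (variant, biomarker, exposure): `n`,
#'   `beta`, `se`, `z`, `p`, `dir_string`, `n_strata`.
#' @export
ewis_scan <- function(study, pairs, exposures = NULL, se_type = "HC0") {
  strata <- study_strata(study)
  if (is.null(exposures)) exposures <- names(strata[[1]]$exposures)
  if (!all(c("variant", "biomarker") %in% names(pairs))) {
    stop_input("`pairs` needs columns `variant` and `biomarker`")
  }
  known_variants <- unique(unlist(lapply(strata, function(s) s$genotypes$variants$id)))
  known_biomarkers <- unique(unlist(lapply(strata, function(s) names(s$biomarkers))))
  known_exposures <- unique(unlist(lapply(strata, function(s) names(s$exposures))))
  if (length(setdiff(pairs$variant, known_variants))) {
    stop_input("unknown variant '%s'", setdiff(pairs$variant, known_variants)[1])
  }
  if (length(setdiff(pairs$biomarker, known_biomarkers))) {
    stop_input("unknown biomarker '%s'", setdiff(pairs$biomarker, known_biomarkers)[1])
  }
  if (length(setdiff(exposures, known_exposures))) {
    stop_input("unknown exposure '%s'", setdiff(exposures, known_exposures)[1])
  }
  grid <- tidyr::expand_grid(pairs, exposure = exposures)
  rows <- purrr::pmap(grid, function(variant, biomarker, exposure, ...) {
    per_stratum <- purrr::map(strata, function(s) {
      if (!variant %in% s$genotypes$variants$id) return(NULL)
      if (!biomarker %in% names(s$biomarkers)) return(NULL)
      if (!exposure %in% names(s$exposures)) return(NULL)
      g <- s$genotypes$calls[, variant]
      y <- as_phenotype_vector(s$biomarkers[[biomarker]])
      e <- s$exposures[[exposure]]
      tryCatch({
        f <- gei_test(y, g, e, se_type = se_type)
        list(beta = f$beta_interaction, se = f$se_interaction, n = f$n)
      }, vqtlewis_error = function(cond) NULL)
    })
    ok <- !vapply(per_stratum, is.null, logical(1))
    dir_chr <- ifelse(ok, "", "?")
    if (!any(ok)) {
      return(tibble::tibble(variant = variant, biomarker = biomarker,
                            exposure = exposure, n = NA_integer_,
                            beta = NA_real_, se = NA_real_, z = NA_real_,
                            p = NA_real_,
                            dir_string = paste(rep("?", length(strata)), collapse = ""),
                            n_strata = 0L))
    }
    betas <- vapply(per_stratum[ok], `[[`, numeric(1), "beta")
    ses <- vapply(per_stratum[ok], `[[`, numeric(1), "se")
    ns <- vapply(per_stratum[ok], `[[`, numeric(1), "n")
    m <- ivw_meta(betas, ses)
    dir_chr[ok] <- c("0", "+", "-")[match(sign(betas), c(0, 1, -1))]
    tibble::tibble(variant = variant, biomarker = biomarker,
                   exposure = exposure, n = as.integer(sum(ns)),
                   beta = m$beta_meta, se = m$se_meta, z = m$z_meta,
                   p = m$p_meta,
                   dir_string = paste(dir_chr, collapse = ""),
                   n_strata = sum(ok))
  })
  dplyr::bind_rows(rows)
}

# normalize study input: either a bare list of strata or a synthetic_study
study_strata <- function(study) {
  if (inherits(study, "synthetic_study")) return(study$strata)
  if (!is.list(study) || !length(study)) stop_input("`study` must be a list of strata")
  study
}

#' Bonferroni significance threshold over pairs and effective exposures
#'
#' `alpha / n_pairs / n_effective_exposures`. Using the effective (rather
#' than nominal) number of exposures avoids over-correcting for the dense
#' correlation of an exposome panel.
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_pairs Number of variant-biomarker pairs tested.
#' @param n_effective_exposures Effective exposure count (see
#'   [effective_tests()]); default 1.
#' @return The per-test threshold.
#' @examples
#' bonferroni_threshold(0.05, 184, 1156.2)
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_pairs, n_effective_exposures = 1) {
  if (alpha <= 0 || n_pairs <= 0 || n_effective_exposures <= 0) {
    stop_input("all inputs must be positive")
  }
  alpha / n_pairs / n_effective_exposures
}

#' Conditional interaction scan to count independent signals
#'
#' Exposome panels are densely correlated, so the raw count of significant
#' interactions overstates the number of distinct signals. Starting from
#' the most significant exposure for a variant-biomarker pair, remaining
#' exposures are iteratively re-tested while conditioning on every
#' previously selected exposure `s` (both `s` and `g:s` enter the model, so
#' the conditional null is not misspecified); selection stops when no
#' remaining exposure passes `secondary_threshold`. Candidates correlated
#' above `collinearity_r` with a selected exposure are skipped.
#'
#' @param y Phenotype vector or `prepared_biomarker`.
#' @param g Genotype vector.
#' @param exposures Tibble/data frame of numeric exposure columns.
#' @param entry_threshold P-value needed for the first (unconditional)
#'   selection.
#' @param secondary_threshold P-value for subsequent selections; e.g. the
#'   same Bonferroni threshold, or 0.05 for a nominal rule.
#' @param collinearity_r Absolute-correlation cutoff for skipping
#'   near-duplicate candidates (default 0.99).
#' @param se_type Sandwich flavor passed to [gei_test()].
#' @return A `conditional_chain`: list with `chain` (tibble of `step`,
#'   `exposure`, `p_value`), `n_independent`, `skipped` (collinear
#'   candidates), `secondary_threshold`.
#' @export
conditional_scan <- function(y, g, exposures, entry_threshold,
                             secondary_threshold = entry_threshold,
                             collinearity_r = 0.99, se_type = "HC0") {
  y <- as_phenotype_vector(y)
  exposures <- tibble::as_tibble(exposures)
  scan_p <- function(candidates, selected) {
    vapply(candidates, function(nm) {
      if (length(selected)) {
        sel <- as.matrix(exposures[selected])
        cors <- suppressWarnings(
          cor(exposures[[nm]], sel, use = "pairwise.complete.obs"))
        if (any(!is.na(cors) & abs(cors) > collinearity_r)) return(NA_real_)
        gx <- sel * g
        colnames(gx) <- paste0("g:", selected)
        covs <- cbind(sel, gx)
      } else covs <- NULL
      tryCatch(gei_test(y, g, exposures[[nm]], covariates = covs,
                        se_type = se_type)$p_value,
               vqtlewis_error = function(cond) NA_real_)
    }, numeric(1))
  }
  selected <- character()
  chain <- list()
  skipped <- character()
  remaining <- names(exposures)
  threshold <- entry_threshold
  repeat {
    if (!length(remaining)) break
    p <- scan_p(remaining, selected)
    skipped <- union(skipped, remaining[is.na(p) & length(selected) > 0])
    if (all(is.na(p)) || min(p, na.rm = TRUE) >= threshold) break
    best <- remaining[which.min(p)]
    chain[[length(chain) + 1]] <- tibble::tibble(
      step = length(chain) + 1L, exposure = best, p_value = min(p, na.rm = TRUE))
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    threshold <- secondary_threshold
  }
  structure(list(
    chain = if (length(chain)) dplyr::bind_rows(chain) else
      tibble::tibble(step = integer(), exposure = character(), p_value = numeric()),
    n_independent = length(chain),
    skipped = skipped,
    secondary_threshold = secondary_threshold
  ), class = "conditional_chain")
}

#' @export
print.conditional_chain <- function(x, ...) {
  cat(sprintf("<conditional_chain> %d independent signal(s)\n", x$n_independent))
  print(x$chain)
  invisible(x)
}

#' Chi-square test of independence on a 2x2 enrichment table
#'
#' Tests whether the fraction of "hits" differs between two groups (e.g.
#' significant-interaction fractions among vQTL- versus ME-prioritized
#' pairs) with the df = 1 chi-square test, Yates continuity correction by
#' default. The p-value is computed in log space, so values far below
#' double underflow (p < 1e-300) remain representable via `log10_p`.
#'
#' @param a,b,c,d Cell counts, row-wise: the table is
#'   `rbind(c(a, b), c(c, d))`.
#' @param continuity_correction Apply the Yates correction (default
#'   `TRUE`).
#' @return List with `statistic`, `p_value` (0 when below double range),
#'   `log10_p`.
#' @examples
#' enrichment_chisq(49, 135, 145, 4268)
#' @export
enrichment_chisq <- function(a, b, c, d, continuity_correction = TRUE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_input("cell counts must be nonnegative integers")
  }
  n <- sum(counts)
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) stop_input("a zero marginal makes the test undefined")
  num <- abs(a * d - b * c)
  if (continuity_correction) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(marg)
  log_p <- pchisq(stat, df = 1, lower.tail = FALSE, log.p = TRUE)
  list(statistic = stat, p_value = exp(log_p), log10_p = log_p / log(10))
}

#' Principal components of a standardized exposure panel
#'
#' PCA on the correlation scale over complete rows of a (sub)set of
#' exposures; used to summarize dense blocks such as anthropometry into a
#' few interpretable axes (e.g. body-mass-like and body-fat-like
#' components) whose scores can themselves enter interaction tests.
#'
#' @param exposures Tibble/data frame of numeric exposures, or an
#'   `exposure_set`.
#' @param columns Optional character vector selecting exposures.
#' @return An `exposure_pca`: list with `scores` (tibble, rows =
#'   complete-case samples), `loadings` (matrix), `sdev`, `complete_rows`
#'   (logical index into the input rows).
#' @export
exposure_pca <- function(exposures, columns = NULL) {
  if (inherits(exposures, "exposure_set")) exposures <- exposures$data
  exposures <- tibble::as_tibble(exposures)
  if (!is.null(columns)) exposures <- exposures[columns]
  if (ncol(exposures) < 2) stop_input("need at least 2 exposures")
  m <- as.matrix(exposures)
  cc <- complete.cases(m)
  if (sum(cc) < ncol(m)) stop_input("fewer complete rows than exposures")
  pc <- prcomp(m[cc, , drop = FALSE], center = TRUE, scale. = TRUE)
  structure(list(
    scores = tibble::as_tibble(pc$x),
    loadings = pc$rotation,
    sdev = pc$sdev,
    complete_rows = cc
  ), class = "exposure_pca")
}

#' @export
print.exposure_pca <- function(x, ...) {
  cat(sprintf("<exposure_pca> %d components over %d samples; var explained: %s\n",
              length(x$sdev), nrow(x$scores),
              paste(sprintf("%.1f%%", 100 * x$sdev[seq_len(min(3, length(x$sdev)))]^2 /
                              sum(x$sdev^2)), collapse = ", ")))
  invisible(x)
}

#' Phenotype means by genotype and exposure bin
#'
#' Cuts a numeric exposure at empirical quantile boundaries into `n_bins`
#' (tertiles by default) and tabulates the phenotype mean, standard error
#' of the mean, and count for each (genotype, bin) cell — the standard
#' display for a qualitative interaction (e.g. alcohol intake strata by
#' genotype).
#'
#' @param y Phenotype vector or `prepared_biomarker`.
#' @param g Genotype vector.
#' @param e Numeric exposure.
#' @param n_bins Number of quantile bins (default 3).
#' @return Tibble with `genotype`, `bin`, `mean`, `se`, `n`; empty cells
#'   appear with `NA` mean/se and `n = 0`.
#' @export
stratified_means <- function(y, g, e, n_bins = 3) {
  y <- as_phenotype_vector(y)
  if (!is.numeric(e)) stop_input("`e` must be numeric")
  obs <- !is.na(y) & !is.na(g) & !is.na(e)
  y <- y[obs]; g <- g[obs]; e <- e[obs]
  if (!length(y)) stop_input("no complete cases")
  qs <- quantile(e, probs = seq(0, 1, length.out = n_bins + 1))
  qs[1] <- -Inf; qs[n_bins + 1] <- Inf
  bin <- cut(e, breaks = unique(qs), include.lowest = TRUE,
             labels = FALSE)
  grid <- tidyr::expand_grid(genotype = sort(unique(g)),
                             bin = seq_len(max(bin)))
  cells <- tibble::tibble(genotype = g, bin = bin, y = y) |>
    dplyr::group_by(.data$genotype, .data$bin) |>
    dplyr::summarise(mean = mean(.data$y),
                     se = sd(.data$y) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  dplyr::left_join(grid, cells, by = c("genotype", "bin")) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
}
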