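#' Adjust biomarker values for statin use
#'
#' Lipid biomarkers measured under statin treatment understate the untreated
#' value; dividing users' measurements by an empirically estimated
#' adjustment factor (e.g. 0.749 for total cholesterol, 0.684 for LDL-C,
#' 0.719 for ApoB) approximately restores the untreated scale. Non-users are
#' unchanged; missing values propagate.
#'
#' @param values Numeric biomarker vector (raw scale).
#' @param statin_user Logical vector, same length; `NA` is treated as
#'   non-user.
#' @param factor Adjustment factor in `(0, 1]`.
#' @return Numeric vector with users' values divided by `factor`.
#' @examples
#' adjust_for_statins(c(5, 5), c(TRUE, FALSE), 0.749)
#' @export
adjust_for_statins <- function(values, statin_user, factor) {
  if (!is_scalar_number(factor) || factor <= 0 || factor > 1) {
    stop_input("`factor` must be a single number in (0, 1]")
  }
  if (length(values) != length(statin_user)) {
    stop_input("`values` and `statin_user` must have equal length")
  }
  user <- !is.na(statin_user) & statin_user
  values[user] <- values[user] / factor
  values
}

#' Pre-process a raw biomarker into an analysis-ready phenotype
#'
#' Applies, in order: statin adjustment of users' raw values (optional),
#' natural-log transformation, ordinary-least-squares residualization on the
#' covariate matrix (intercept added), masking of residuals more than
#' `outlier_sd` standard deviations from the residual mean, and z-score
#' re-standardization of the surviving values to mean 0 and variance 1.
#' Missingness in `raw` or any covariate propagates.
#'
#' @param raw Numeric vector of strictly positive raw biomarker values.
#' @param covariates Optional numeric matrix/data frame of covariates
#'   (samples in rows). `NULL` means intercept-only residualization
#'   (centering).
#' @param statin Optional list `list(user = <logical>, factor = <number>)`
#'   applied before the log step.
#' @param outlier_sd Outlier masking threshold in residual standard
#'   deviations (default 5).
#' @param log_transform Apply the log step (default `TRUE`).
#' @return A `prepared_biomarker`: list with `values` (z-scored residuals,
#'   `NA` where input was missing or masked), `steps` (provenance), and
#'   `n_masked`.
#' @export
preprocess_biomarker <- function(raw, covariates = NULL, statin = NULL,
                                 outlier_sd = 5, log_transform = TRUE) {
  steps <- character()
  x <- as.numeric(raw)
  if (!is.null(statin)) {
    x <- adjust_for_statins(x, statin$user, statin$factor)
    steps <- c(steps, "statin_adjust")
  }
  if (log_transform) {
    bad <- !is.na(x) & x <= 0
    if (any(bad)) {
      stop_input("non-positive biomarker value at sample %d; cannot log-transform",
                 which(bad)[1])
    }
    x <- log(x)
    steps <- c(steps, "log")
  }
  if (is.null(covariates)) {
    X <- matrix(1, nrow = length(x), ncol = 1)
  } else {
    X <- cbind(1, as.matrix(covariates))
  }
  obs <- !is.na(x) & complete.cases(X)
  if (sum(obs) <= ncol(X)) stop_input("too few complete cases to residualize")
  if (qr(X[obs, , drop = FALSE])$rank < ncol(X)) {
    stop_input("covariate matrix is rank-deficient after adding an intercept")
  }
  r <- rep(NA_real_, length(x))
  fit <- lm.fit(X[obs, , drop = FALSE], x[obs])
  r[obs] <- fit$residuals
  steps <- c(steps, "residualize")
  mu <- mean(r[obs]); s <- sd(r[obs])
  outlier <- obs & abs(r - mu) > outlier_sd * s
  r[outlier] <- NA_real_
  steps <- c(steps, "outlier_mask")
  keep <- !is.na(r)
  if (sum(keep) < 2) stop_degenerate("fewer than 2 values survive outlier masking")
  r[keep] <- (r[keep] - mean(r[keep])) / sd(r[keep])
  steps <- c(steps, "zscore")
  structure(list(values = r, steps = steps, n_masked = sum(outlier)),
            class = "prepared_biomarker")
}

#' @export
print.prepared_biomarker <- function(x, ...) {
  cat(sprintf("<prepared_biomarker> n = %d (%d missing, %d masked); steps: %s\n",
              length(x$values), sum(is.na(x$values)), x$n_masked,
              paste(x$steps, collapse = " -> ")))
  invisible(x)
}

as_phenotype_vector <- function(y) {
  if (inherits(y, "prepared_biomarker")) y$values else as.numeric(y)
}

#' Rank-based inverse normal transformation
#'
#' Maps value `i` to `qnorm((rank_i - offset) / (n - 2*offset + 1))` over
#' the non-missing values; the default offset 3/8 gives Blom scores, the
#' usual GWAS convention. Ties receive average ranks; missing values
#' propagate.
#'
#' @param values Numeric vector.
#' @param offset Rank offset in `[0, 0.5]`; default `3/8`.
#' @return Numeric vector of normal scores.
#' @export
inverse_normal_transform <- function(values, offset = 3 / 8) {
  obs <- !is.na(values)
  n <- sum(obs)
  if (n < 2) stop_input("need at least 2 non-missing values")
  if (length(unique(values[obs])) == 1) {
    stop_degenerate("all non-missing values identical; ranks are degenerate")
  }
  out <- rep(NA_real_, length(values))
  r <- rank(values[obs], ties.method = "average")
  out[obs] <- qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Prepare raw exposure columns for interaction testing
#'
#' Emulates automated exposure pre-processing: continuous and integer
#' columns get the rank-based inverse normal transformation; two-level
#' categorical columns become 0/1 indicators; ordered categorical columns
#' with more than two levels become ordinal integer codes 0..k-1;
#' multiple-choice columns (semicolon-separated selections) expand to one
#' binary indicator per observed level. Columns with too few non-missing
#' observations, a single observed level, or a rarest binary level below
#' `min_minor_count` are dropped.
#'
#' @param data Tibble/data frame of raw exposure columns (no id column), or
#'   a `sample_table` (its exposure-kind columns are used).
#' @param types Named character vector giving each column's input type:
#'   `"continuous"`, `"integer"`, `"categorical-single"`,
#'   `"categorical-multiple"`.
#' @param min_nonmissing Minimum non-missing count to retain a column;
#'   default one tenth of the sample count.
#' @param min_minor_count Minimum count of the rarest level of a binary
#'   exposure (default 10).
#' @param categories Optional named character vector of free-text group
#'   labels per column (e.g. `"anthropometry"`).
#' @return An `exposure_set`: list with `data` (tibble of numeric
#'   exposures), `coding` (tibble of `exposure`, `coding`, `category`,
#'   `source`) and `dropped` (tibble of `exposure`, `reason`).
#' @export
prepare_exposures <- function(data, types, min_nonmissing = NULL,
                              min_minor_count = 10, categories = NULL) {
  if (inherits(data, "sample_table")) {
    keep <- data$kinds$column[!is.na(data$kinds$kind) & data$kinds$kind == "exposure"]
    data <- data$data[keep]
  }
  data <- tibble::as_tibble(data)
  untagged <- setdiff(names(data), names(types))
  if (length(untagged)) stop_input("exposure column '%s' has no input type", untagged[1])
  bad <- setdiff(types[names(data)],
                 c("continuous", "integer", "categorical-single", "categorical-multiple"))
  if (length(bad)) stop_input("unknown exposure input type '%s'", bad[1])
  n <- nrow(data)
  min_nonmissing <- min_nonmissing %||% ceiling(0.1 * n)

  out <- list(); coding <- list(); dropped <- list()
  drop <- function(name, reason) {
    dropped[[length(dropped) + 1]] <<- tibble::tibble(exposure = name, reason = reason)
  }
  add <- function(name, values, code, source) {
    out[[name]] <<- values
    coding[[length(coding) + 1]] <<- tibble::tibble(
      exposure = name, coding = code,
      category = unname((categories %||% character())[source]) %||% NA_character_,
      source = source
    )
  }
  keep_binary <- function(name, values, source) {
    tab <- table(values)
    if (length(tab) < 2) { drop(name, "single observed level"); return() }
    if (min(tab) < min_minor_count) { drop(name, "rare minor level"); return() }
    lev <- names(sort(tab, decreasing = TRUE))  # most frequent level -> 0
    add(name, as.numeric(values == lev[2]), "binary", source)
  }

  for (nm in names(data)) {
    x <- data[[nm]]
    nobs <- sum(!is.na(x) & (!is.character(x) | nzchar(trimws(as.character(x)))))
    if (nobs < min_nonmissing) { drop(nm, "excessive missingness"); next }
    type <- types[[nm]]
    if (type %in% c("continuous", "integer")) {
      x <- as.numeric(x)
      if (length(unique(x[!is.na(x)])) < 2) { drop(nm, "single observed level"); next }
      add(nm, inverse_normal_transform(x), "continuous-INT", nm)
    } else if (type == "categorical-single") {
      f <- if (is.factor(x)) x else factor(x)
      f <- droplevels(f)
      k <- nlevels(f)
      if (k < 2) { drop(nm, "single observed level"); next }
      if (k == 2) {
        keep_binary(nm, f, nm)
      } else {
        add(nm, as.numeric(f) - 1, "ordinal", nm)
      }
    } else {  # categorical-multiple: semicolon-separated selections
      x <- as.character(x)
      sel <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
      levels_seen <- sort(unique(trimws(unlist(sel))))
      levels_seen <- levels_seen[nzchar(levels_seen)]
      for (lev in levels_seen) {
        ind <- vapply(sel, function(s) lev %in% trimws(s), logical(1))
        ind[is.na(x)] <- NA
        keep_binary(paste0(nm, "__", lev), factor(ind, levels = c(FALSE, TRUE)), nm)
      }
    }
  }
  structure(list(
    data = tibble::as_tibble(out),
    coding = if (length(coding)) dplyr::bind_rows(coding) else
      tibble::tibble(exposure = character(), coding = character(),
                     category = character(), source = character()),
    dropped = if (length(dropped)) dplyr::bind_rows(dropped) else
      tibble::tibble(exposure = character(), reason = character())
  ), class = "exposure_set")
}

#' @export
print.exposure_set <- function(x, ...) {
  cat(sprintf("<exposure_set> %d exposures (%d dropped)\n",
              ncol(x$data), nrow(x$dropped)))
  print(dplyr::count(x$coding, .data$coding))
  invisible(x)
}

#' Effective number of independent tests
#'
#' Computes the effective number of independent variables among `p`
#' correlated ones as `(sum(lambda))^2 / sum(lambda^2)` over the eigenvalues
#' `lambda` of their correlation matrix (complete rows only). Used as the
#' Bonferroni denominator for correlated biomarkers or exposures.
#'
#' @param data Numeric matrix or data frame, samples in rows.
#' @param standardize Use the correlation matrix (default `TRUE`); otherwise
#'   the covariance matrix.
#' @return An `effective_tests` object: list with `eigenvalues` and
#'   `n_effective`.
#' @export
effective_tests <- function(data, standardize = TRUE) {
  m <- as.matrix(data)
  if (ncol(m) < 2) stop_input("need at least 2 variables")
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2) stop_input("fewer than 2 complete rows")
  v <- apply(m, 2, var)
  if (any(v == 0)) stop_input("variable %d has zero variance", which(v == 0)[1])
  S <- if (standardize) cor(m) else cov(m)
  lambda <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  structure(list(eigenvalues = lambda,
                 n_effective = sum(lambda)^2 / sum(lambda^2)),
            class = "effective_tests")
}

#' @export
print.effective_tests <- function(x, ...) {
  cat(sprintf("<effective_tests> %.4g effective among %d variables\n",
              x$n_effective, length(x$eigenvalues)))
  invisible(x)
}
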