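#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a median-based Levene fit
#'
#' One row per genotype class: class label, count, and mean absolute
#' deviation from the class median.
#'
#' @param x A `levene_fit`.
#' @param ... Unused.
#' @return A tibble with `genotype`, `n`, `mean_abs_dev`.
#' @export
tidy.levene_fit <- function(x, ...) {
  tibble::tibble(
    genotype = names(x$n_i),
    n = as.integer(x$n_i),
    mean_abs_dev = as.numeric(x$z_i_bar)
  )
}

#' One-row summary of a median-based Levene fit
#'
#' @param x A `levene_fit`.
#' @param ... Unused.
#' @return A tibble with `statistic`, `df1`, `df2`, `p_value`, `k`, `n`.
#' @export
glance.levene_fit <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2,
                 p_value = x$p_value, k = x$k, n = x$n)
}

#' Tidy a robust interaction fit
#'
#' @param x A `gei_fit`.
#' @param ... Unused.
#' @return Coefficient tibble: `term`, `estimate`, `se_robust`, `z`,
#'   `p_value`.
#' @export
tidy.gei_fit <- function(x, ...) x$coefficients

#' One-row summary of a robust interaction fit
#'
#' @param x A `gei_fit`.
#' @param ... Unused.
#' @return A tibble with `beta_interaction`, `se_interaction`, `z`,
#'   `p_value`, `n`, `se_type`, `exact_fit`.
#' @export
glance.gei_fit <- function(x, ...) {
  tibble::tibble(beta_interaction = x$beta_interaction,
                 se_interaction = x$se_interaction, z = x$z,
                 p_value = x$p_value, n = x$n, se_type = x$se_type,
                 exact_fit = x$exact_fit)
}

#' Tidy a conditional interaction chain
#'
#' @param x A `conditional_chain`.
#' @param ... Unused.
#' @return The chain tibble (`step`, `exposure`, `p_value`).
#' @export
tidy.conditional_chain <- function(x, ...) x$chain

#' Tidy an effective-test decomposition
#'
#' @param x An `effective_tests` object.
#' @param ... Unused.
#' @return Tibble of `component`, `eigenvalue`.
#' @export
tidy.effective_tests <- function(x, ...) {
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues)
}
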