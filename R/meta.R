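#' Align per-stratum summary statistics to a common effect allele
#'
#' Before meta-analysis every stratum must report effects on the same
#' allele. The first stratum carrying a variant defines the reference
#' orientation; other strata are kept as-is when alleles match, flipped
#' (beta and direction negated, allele frequency complemented) when their
#' a1/a2 are swapped, and dropped when the allele pairs are irreconcilable.
#'
#' @param stats_list List of summary-stat tibbles (one per stratum), as
#'   produced by [run_scan()].
#' @return List of aligned tibbles in the same order; dropped rows are
#'   recorded in `attr(, "dropped")` (`id`, `stratum`, `reason`).
#' @export
align_alleles <- function(stats_list) {
  stopifnot(is.list(stats_list), length(stats_list) >= 1)
  ref <- list()  # id -> c(a1, a2)
  dropped <- list()
  out <- vector("list", length(stats_list))
  for (s in seq_along(stats_list)) {
    st <- stats_list[[s]]
    keep <- rep(TRUE, nrow(st))
    for (i in seq_len(nrow(st))) {
      key <- st$id[i]
      if (is.null(ref[[key]])) {
        ref[[key]] <- c(st$a1[i], st$a2[i])
        next
      }
      r <- ref[[key]]
      if (st$a1[i] == r[1] && st$a2[i] == r[2]) next
      if (st$a1[i] == r[2] && st$a2[i] == r[1]) {
        st$beta[i] <- -st$beta[i]
        st$dir[i] <- -st$dir[i]
        st$af[i] <- 1 - st$af[i]
        st$a1[i] <- r[1]; st$a2[i] <- r[2]
      } else {
        keep[i] <- FALSE
        dropped[[length(dropped) + 1]] <- tibble::tibble(
          id = key, stratum = st$stratum[i], reason = "irreconcilable alleles")
      }
    }
    out[[s]] <- st[keep, ]
  }
  attr(out, "dropped") <- if (length(dropped)) dplyr::bind_rows(dropped) else
    tibble::tibble(id = character(), stratum = character(), reason = character())
  out
}

#' Stouffer (sample-size-weighted) z-score meta-analysis
#'
#' Combines per-stratum signed z-statistics with weights proportional to the
#' square root of the stratum sample size:
#' `z_meta = sum(sqrt(n_i) z_i) / sqrt(sum(n_i))`, with a two-sided normal
#' p-value. This is the mode used for variance-QTL results, whose Levene
#' p-values carry no native effect size.
#'
#' @param z Numeric vector of signed per-stratum z-statistics.
#' @param n Positive per-stratum sample sizes.
#' @return List with `z_meta`, `p_meta`, `n_total`.
#' @export
stouffer_meta <- function(z, n) {
  if (!length(z)) stop_input("empty input")
  if (length(z) != length(n)) stop_input("`z` and `n` must have equal length")
  if (any(!is.finite(z))) stop_input("non-finite z-statistic")
  if (any(n <= 0)) stop_input("sample sizes must be positive")
  z_meta <- sum(sqrt(n) * z) / sqrt(sum(n))
  list(z_meta = z_meta, p_meta = 2 * pnorm(-abs(z_meta)), n_total = sum(n))
}

#' Inverse-variance-weighted fixed-effect meta-analysis
#'
#' `w_i = 1/se_i^2`; `beta_meta = sum(w_i beta_i)/sum(w_i)`;
#' `se_meta = 1/sqrt(sum(w_i))`. Used for mean-effect and interaction
#' estimates. Cochran's Q heterogeneity statistic is reported but never
#' used for filtering.
#'
#' @param beta Per-stratum effect estimates.
#' @param se Per-stratum standard errors (all positive).
#' @return List with `beta_meta`, `se_meta`, `z_meta`, `p_meta`, `q`,
#'   `q_df`, `q_p`.
#' @export
ivw_meta <- function(beta, se) {
  if (!length(beta)) stop_input("empty input")
  if (length(beta) != length(se)) stop_input("`beta` and `se` must have equal length")
  if (any(se <= 0)) stop_input("standard errors must be positive")
  w <- 1 / se^2
  beta_meta <- sum(w * beta) / sum(w)
  se_meta <- 1 / sqrt(sum(w))
  z_meta <- beta_meta / se_meta
  q <- sum(w * (beta - beta_meta)^2)
  q_df <- length(beta) - 1L
  list(beta_meta = beta_meta, se_meta = se_meta, z_meta = z_meta,
       p_meta = 2 * pnorm(-abs(z_meta)), q = q, q_df = q_df,
       q_p = if (q_df > 0) pchisq(q, q_df, lower.tail = FALSE) else NA_real_)
}

#' Meta-analyze per-stratum summary statistics across ancestry groups
#'
#' Aligns alleles with [align_alleles()], then combines each variant across
#' the strata that carry it: in `"samplesize"` mode per-stratum z-scores are
#' reconstructed from p-value and direction and combined by
#' [stouffer_meta()]; in `"ivw"` mode effect sizes are combined by
#' [ivw_meta()]. Variants present in a single stratum are retained. The
#' direction string carries one character per input stratum: `+`, `-`, `0`
#' or `?` when the stratum lacks the variant.
#'
#' @param stats_list List of per-stratum summary-stat tibbles.
#' @param mode `"samplesize"` (Stouffer) or `"ivw"`.
#' @return Tibble with one row per variant: `chrom, pos, id, a1, a2, af, n,
#'   stat` (meta z), `beta, se, dir, p, kind, stratum` (direction string in
#'   `dir_string`, `stratum = "META"`), plus `q`, `q_p` in IVW mode.
#' @export
meta_analyze <- function(stats_list, mode = c("samplesize", "ivw")) {
  mode <- match.arg(mode)
  aligned <- align_alleles(stats_list)
  strata <- vapply(seq_along(aligned), function(s) {
    st <- aligned[[s]]
    if (nrow(st)) st$stratum[1] else paste0("S", s)
  }, character(1))
  all_stats <- dplyr::bind_rows(
    lapply(seq_along(aligned), function(s) dplyr::mutate(aligned[[s]], .stratum_idx = s))
  )
  if (!nrow(all_stats)) return(all_stats)

  combine_variant <- function(d) {
    first <- d[1, ]
    dir_chr <- rep("?", length(strata))
    dir_chr[d$.stratum_idx] <- c("0", "+", "-")[match(sign(d$dir), c(0, 1, -1))]
    n_total <- sum(d$n)
    if (mode == "samplesize") {
      z_i <- d$dir * p_to_z(d$p)
      m <- stouffer_meta(z_i, d$n)
      beta <- NA_real_; se <- NA_real_; q <- NA_real_; q_p <- NA_real_
      z <- m$z_meta; p <- m$p_meta
    } else {
      m <- ivw_meta(d$beta, d$se)
      beta <- m$beta_meta; se <- m$se_meta; q <- m$q; q_p <- m$q_p
      z <- m$z_meta; p <- m$p_meta
    }
    tibble::tibble(
      chrom = first$chrom, pos = first$pos, id = first$id,
      a1 = first$a1, a2 = first$a2,
      af = sum(d$af * d$n) / n_total, n = n_total,
      stat = z, beta = beta, se = se, dir = as.integer(sign(z)), p = p,
      kind = first$kind, stratum = "META",
      dir_string = paste(dir_chr, collapse = ""),
      q = q, q_p = q_p,
      biomarker = if ("biomarker" %in% names(first)) first$biomarker else NA_character_
    )
  }
  groups <- split(all_stats, factor(all_stats$id, levels = unique(all_stats$id)))
  out <- purrr::map_dfr(groups, combine_variant)
  attr(out, "dropped") <- attr(aligned, "dropped")
  out
}
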