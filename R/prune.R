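#' Distance-based pruning of genome-wide summary statistics
#'
#' Collapses a genome-wide scan to index variants by the standard greedy
#' clumping rule: repeatedly take the most significant remaining variant at
#' or below the significance threshold as an index, then remove every
#' variant within `window_bp` of it on the same chromosome (center-to-point
#' distance, boundary inclusive). Ties in p are broken by (chromosome,
#' position, id), making the result deterministic and invariant to input
#' row order. No linkage-disequilibrium information is used.
#'
#' @param stats Summary-stat tibble with at least `chrom`, `pos`, `id`, `p`.
#' @param significance Only variants with `p <= significance` seed or join
#'   loci (default 1: prune everything).
#' @param window_bp Pruning half-window in basepairs (default 500000).
#' @return Tibble of index-variant rows (all input columns) plus a
#'   list-column `members` of the variant ids absorbed into each locus
#'   (including the index) and `window_bp`.
#' @export
distance_prune <- function(stats, significance = 1, window_bp = 500000) {
  need <- setdiff(c("chrom", "pos", "id", "p"), names(stats))
  if (length(need)) stop_input("stats lack column(s): %s", paste(need, collapse = ", "))
  sig <- stats[!is.na(stats$p) & stats$p <= significance, ]
  if (!nrow(sig)) {
    out <- sig
    out$members <- list()
    out$window_bp <- integer()
    return(out)
  }
  ord <- order(sig$p, sig$chrom, sig$pos, sig$id)
  sig <- sig[ord, ]
  taken <- rep(FALSE, nrow(sig))
  loci <- list()
  for (i in seq_len(nrow(sig))) {
    if (taken[i]) next
    idx <- sig[i, ]
    member_rows <- !taken & sig$chrom == idx$chrom &
      abs(sig$pos - idx$pos) <= window_bp
    taken[member_rows] <- TRUE
    row <- idx
    row$members <- list(sort(sig$id[member_rows]))
    row$window_bp <- as.integer(window_bp)
    loci[[length(loci) + 1]] <- row
  }
  out <- dplyr::bind_rows(loci)
  out[order(out$chrom, out$pos, out$id), ]
}

#' Clump index variants across biomarkers, strata or analysis kinds
#'
#' Stacks several pruned index-variant sets and applies the same greedy
#' distance-based rule at a wider window (default 1 Mb) to group loci that
#' co-locate across analyses. Each group records which sources (biomarker /
#' analysis kind combinations) contributed.
#'
#' @param pruned_sets List of tibbles from [distance_prune()] (each should
#'   carry `biomarker` and/or `kind` columns for attribution).
#' @param window_bp Clumping half-window in basepairs (default 1000000).
#' @return Tibble of locus groups: the lead (smallest-p) entry's `chrom`,
#'   `pos`, `id`, `p`, a `group` integer, and list-columns `constituents`
#'   (tibble of contributing rows) and `sources`.
#' @export
cross_clump <- function(pruned_sets, window_bp = 1000000) {
  stacked <- dplyr::bind_rows(pruned_sets)
  if (!nrow(stacked)) return(stacked)
  src <- paste(
    if ("biomarker" %in% names(stacked)) stacked$biomarker else "",
    if ("kind" %in% names(stacked)) stacked$kind else "",
    sep = "/"
  )
  stacked$.source <- src
  ord <- order(stacked$p, stacked$chrom, stacked$pos, stacked$id)
  stacked <- stacked[ord, ]
  taken <- rep(FALSE, nrow(stacked))
  groups <- list()
  gid <- 0L
  for (i in seq_len(nrow(stacked))) {
    if (taken[i]) next
    lead <- stacked[i, ]
    member_rows <- !taken & stacked$chrom == lead$chrom &
      abs(stacked$pos - lead$pos) <= window_bp
    taken[member_rows] <- TRUE
    gid <- gid + 1L
    groups[[gid]] <- tibble::tibble(
      group = gid, chrom = lead$chrom, pos = lead$pos, id = lead$id,
      p = lead$p,
      constituents = list(stacked[member_rows, setdiff(names(stacked), ".source")]),
      sources = list(sort(unique(stacked$.source[member_rows])))
    )
  }
  dplyr::bind_rows(groups)
}

#' Classify variance-QTL loci against mean-effect loci
#'
#' Labels each vQTL locus group `shared` when any mean-effect (ME) index
#' variant lies within `window_bp` on the same chromosome, else
#' `vqtl_only`; ME groups with no vQTL within the window are `me_only`.
#' Reproduces the overlap summary between variance and mean architectures
#' (e.g. the fraction of vQTLs falling in ME loci).
#'
#' @param vqtl_groups,me_groups Tibbles of index variants or locus groups
#'   with `chrom`, `pos` (and optionally `biomarker`).
#' @param window_bp Overlap half-window (default 1000000).
#' @return List with `counts` (tibble of `classification`, `n`),
#'   `fraction_vqtl_shared`, and `by_biomarker` (per-biomarker breakdown
#'   when a `biomarker` column is present).
#' @export
classify_loci <- function(vqtl_groups, me_groups, window_bp = 1000000) {
  near_any <- function(chrom, pos, other) {
    any(other$chrom == chrom & abs(other$pos - pos) <= window_bp)
  }
  v_shared <- if (nrow(vqtl_groups)) {
    vapply(seq_len(nrow(vqtl_groups)), function(i) {
      near_any(vqtl_groups$chrom[i], vqtl_groups$pos[i], me_groups)
    }, logical(1))
  } else logical()
  m_shared <- if (nrow(me_groups)) {
    vapply(seq_len(nrow(me_groups)), function(i) {
      near_any(me_groups$chrom[i], me_groups$pos[i], vqtl_groups)
    }, logical(1))
  } else logical()
  counts <- tibble::tibble(
    classification = c("vqtl_only", "shared", "me_only"),
    n = c(sum(!v_shared), sum(v_shared), sum(!m_shared))
  )
  by_biomarker <- NULL
  if ("biomarker" %in% names(vqtl_groups) && nrow(vqtl_groups)) {
    by_biomarker <- vqtl_groups |>
      dplyr::mutate(shared = v_shared) |>
      dplyr::count(.data$biomarker, .data$shared)
  }
  list(
    counts = counts,
    fraction_vqtl_shared = if (length(v_shared)) mean(v_shared) else NA_real_,
    by_biomarker = by_biomarker
  )
}
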