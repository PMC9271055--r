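# one replicate of a two-stage screening study: 60 variants (8 with a main
# effect plus a true interaction, 40 main-effect-only, 12 null), one
# interacting exposure among a 10-exposure panel; both screening arms use
# the same stage-1 threshold and the same EWIS Bonferroni threshold
two_stage_study <- function(n = 5000, stage1_alpha = 1e-4) {
  m_gei <- 8; m_me <- 40; m_null <- 12
  m <- m_gei + m_me + m_null
  gm <- simulate_genotypes(n, m, c(0.1, 0.4))
  exposures <- tibble::as_tibble(
    stats::setNames(as.data.frame(matrix(rnorm(n * 10), ncol = 10)),
                    paste0("e", 1:10)))
  gei_ids <- paste0("v", seq_len(m_gei))
  me_ids <- paste0("v", m_gei + seq_len(m_me))
  y <- simulate_phenotype(
    gm, exposures,
    beta_g = stats::setNames(rep(0.15, m_gei + m_me), c(gei_ids, me_ids)),
    beta_e = c(e1 = 0.3),
    beta_ge = tibble::tibble(variant = gei_ids, exposure = "e1", beta = 0.3)
  )
  vqtl <- run_scan(gm, y, "vqtl")
  me <- run_scan(gm, y, "me")
  v_hits <- vqtl$id[vqtl$p < stage1_alpha]
  m_hits <- me$id[me$p < stage1_alpha]
  ewis_threshold <- bonferroni_threshold(0.05, max(1, length(m_hits)), 10)
  has_sig_gei <- function(variant) {
    p <- vapply(names(exposures), function(ex) {
      gei_test(y, gm$calls[, variant], exposures[[ex]])$p_value
    }, numeric(1))
    any(p < ewis_threshold)
  }
  frac <- function(ids) {
    if (!length(ids)) return(NA_real_)
    mean(vapply(ids, has_sig_gei, logical(1)))
  }
  list(frac_vqtl = frac(v_hits), frac_me = frac(m_hits),
       n_vqtl = length(v_hits), n_me = length(m_hits))
}
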