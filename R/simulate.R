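#' Configuration for a synthetic two-stage study
#'
#' Collects the generating parameters for a synthetic genotype/exposure/
#' biomarker study with known ground truth. Defaults describe a desk-scale
#' study: one large and one small ancestry stratum, Hardy-Weinberg
#' genotypes, two densely correlated exposure blocks ("body-mass-like" and
#' "body-fat-like", within-block correlation 0.8) plus independent
#' lifestyle exposures, and sparse effect tables planting additive main
#' effects, exposure main effects, and gene-environment interactions (which
#' induce genotype-dependent phenotypic variance).
#'
#' @param n_samples Named integer vector of samples per stratum.
#' @param n_variants Number of independent variants.
#' @param maf_range Length-2 range the per-variant MAF is drawn from
#'   uniformly (per stratum unless `shared_maf = TRUE`).
#' @param shared_maf Draw one MAF per variant shared by all strata
#'   (default `TRUE`).
#' @param exposure_blocks List of blocks, each
#'   `list(name, size, rho, binary = 0)`; `binary` columns are dichotomized
#'   at the median.
#' @param beta_g Named numeric vector of additive main effects, names are
#'   variant ids (`"v1"`, ...).
#' @param beta_e Named numeric vector of exposure main effects, names are
#'   exposure names.
#' @param beta_ge Tibble with columns `variant`, `exposure`, `beta`:
#'   interaction effects.
#' @param noise_sd Residual standard deviation (default 1).
#' @param skew Exponentiate the linear predictor to produce a skewed,
#'   strictly positive raw-scale phenotype (default `FALSE`), exercising
#'   the log/INT pre-processing path.
#' @param seed Integer seed fixing the whole generated study.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = c(EUR = 5000, AFR = 1000),
                       n_variants = 20,
                       maf_range = c(0.05, 0.45),
                       shared_maf = TRUE,
                       exposure_blocks = list(
                         list(name = "body_mass", size = 5, rho = 0.8),
                         list(name = "body_fat", size = 5, rho = 0.8),
                         list(name = "lifestyle", size = 10, rho = 0, binary = 3)
                       ),
                       beta_g = c(v1 = 0.15, v2 = 0.15),
                       beta_e = c(body_mass_1 = 0.3),
                       beta_ge = tibble::tibble(variant = "v1",
                                                exposure = "body_mass_1",
                                                beta = 0.2),
                       noise_sd = 1, skew = FALSE, seed = 1) {
  if (maf_range[1] <= 0 || maf_range[2] >= 0.5 || maf_range[1] > maf_range[2]) {
    stop_input("maf_range must satisfy 0 < low <= high < 0.5")
  }
  if (noise_sd <= 0) stop_input("noise_sd must be positive")
  structure(list(
    n_samples = n_samples, n_variants = n_variants, maf_range = maf_range,
    shared_maf = shared_maf, exposure_blocks = exposure_blocks,
    beta_g = beta_g, beta_e = beta_e, beta_ge = beta_ge,
    noise_sd = noise_sd, skew = skew, seed = seed
  ), class = "sim_config")
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Each variant gets a MAF drawn uniformly from `maf_range` (unless `mafs`
#' is supplied) and calls drawn as Binomial(2, p), i.e. genotype
#' probabilities `(1-p)^2, 2p(1-p), p^2`. Variants are independent (no
#' linkage disequilibrium) and placed 2 Mb apart on chromosome 1 so that
#' each forms its own locus under default pruning windows.
#'
#' @param n Number of samples.
#' @param m Number of variants.
#' @param maf_range Length-2 MAF range, `0 < low <= high < 0.5`.
#' @param seed Optional seed (sets the RNG state).
#' @param mafs Optional explicit per-variant alternate-allele frequencies.
#' @param sample_prefix,variant_prefix Identifier prefixes.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.45), seed = NULL,
                               mafs = NULL, sample_prefix = "s",
                               variant_prefix = "v") {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mafs)) {
    if (maf_range[1] <= 0 || maf_range[2] >= 0.5 || maf_range[1] > maf_range[2]) {
      stop_input("maf_range must satisfy 0 < low <= high < 0.5")
    }
    mafs <- runif(m, maf_range[1], maf_range[2])
  }
  if (length(mafs) != m) stop_input("need %d allele frequencies", m)
  calls <- vapply(mafs, function(p) rbinom(n, 2, p), integer(n))
  variants <- tibble::tibble(
    id = paste0(variant_prefix, seq_len(m)),
    chrom = "1", pos = as.integer(seq_len(m) * 2e6),
    ref = "A", alt = "G", af = mafs
  )
  genotype_matrix(calls, variants, paste0(sample_prefix, seq_len(n)))
}

#' Simulate a correlated mixed-type exposure panel
#'
#' Exposures come in blocks: multivariate normal with exchangeable
#' within-block correlation `rho`, independent across blocks. The last
#' `binary` columns of a block are dichotomized at the median, giving
#' imbalanced-free binary exposures while preserving the latent
#' correlation.
#'
#' @param n Number of samples.
#' @param blocks List of `list(name, size, rho, binary = 0)`.
#' @param seed Optional seed.
#' @return Tibble of exposures named `<block>_<i>`, with an attribute
#'   `coding` tibble (`exposure`, `coding`, `category`).
#' @export
simulate_exposures <- function(n, blocks = list(list(name = "exp", size = 5, rho = 0)),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cols <- list(); coding <- list()
  for (b in blocks) {
    size <- b$size; rho <- b$rho %||% 0; nb <- b$binary %||% 0
    if (rho < 0 || rho >= 1) stop_input("block '%s': rho must be in [0, 1)", b$name)
    # exchangeable correlation via shared factor: x = sqrt(rho) f + sqrt(1-rho) u
    f <- rnorm(n)
    raw <- vapply(seq_len(size), function(i) {
      sqrt(rho) * f + sqrt(1 - rho) * rnorm(n)
    }, numeric(n))
    for (i in seq_len(size)) {
      nm <- paste0(b$name, "_", i)
      x <- raw[, i]
      if (i > size - nb) {
        x <- as.numeric(x > median(x))
        coding[[length(coding) + 1]] <- tibble::tibble(
          exposure = nm, coding = "binary", category = b$name)
      } else {
        coding[[length(coding) + 1]] <- tibble::tibble(
          exposure = nm, coding = "continuous", category = b$name)
      }
      cols[[nm]] <- x
    }
  }
  out <- tibble::as_tibble(cols)
  attr(out, "coding") <- dplyr::bind_rows(coding)
  out
}

#' Simulate a phenotype with planted main and interaction effects
#'
#' `y = sum_v beta_g[v] g_v + sum_e beta_e[e] x_e +
#'      sum_(v,e) beta_ge[v,e] g_v x_e + eps`, `eps ~ N(0, noise_sd^2)`.
#' A nonzero `beta_ge` makes `Var(y | g_v)` depend on the genotype:
#' with a single interacting exposure of variance `s_e^2`,
#' `Var(y | g = k) = (beta_e + beta_ge k)^2 s_e^2 + noise_sd^2`.
#' With `skew = TRUE` the linear predictor is exponentiated, producing a
#' log-normal-style raw phenotype for testing the log/INT path.
#'
#' @param genotypes A [genotype_matrix()] (or bare calls matrix with
#'   variant-id column names).
#' @param exposures Tibble of numeric exposures.
#' @param beta_g Named vector of additive effects (names = variant ids).
#' @param beta_e Named vector of exposure main effects.
#' @param beta_ge Tibble `variant`, `exposure`, `beta`.
#' @param noise_sd Residual SD.
#' @param skew Exponentiate to a positive raw scale.
#' @param seed Optional seed.
#' @return Numeric phenotype vector.
#' @export
simulate_phenotype <- function(genotypes, exposures,
                               beta_g = numeric(), beta_e = numeric(),
                               beta_ge = NULL, noise_sd = 1, skew = FALSE,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  calls <- if (inherits(genotypes, "genotype_matrix")) genotypes$calls else as.matrix(genotypes)
  exposures <- tibble::as_tibble(exposures)
  n <- nrow(calls)
  if (nrow(exposures) && nrow(exposures) != n) {
    stop_input("exposures have %d rows but genotypes %d samples", nrow(exposures), n)
  }
  eta <- rnorm(n, 0, noise_sd)
  for (v in names(beta_g)) {
    if (!v %in% colnames(calls)) stop_input("beta_g names unknown variant '%s'", v)
    eta <- eta + beta_g[[v]] * calls[, v]
  }
  for (e in names(beta_e)) {
    if (!e %in% names(exposures)) stop_input("beta_e names unknown exposure '%s'", e)
    eta <- eta + beta_e[[e]] * exposures[[e]]
  }
  if (!is.null(beta_ge) && nrow(beta_ge)) {
    for (i in seq_len(nrow(beta_ge))) {
      v <- beta_ge$variant[i]; e <- beta_ge$exposure[i]
      if (!v %in% colnames(calls)) stop_input("beta_ge names unknown variant '%s'", v)
      if (!e %in% names(exposures)) stop_input("beta_ge names unknown exposure '%s'", e)
      eta <- eta + beta_ge$beta[i] * calls[, v] * exposures[[e]]
    }
  }
  if (skew) exp(eta) else eta
}

#' Generate a full synthetic study, optionally writing it to disk
#'
#' Draws genotypes, exposures and a biomarker phenotype for every stratum
#' of a [sim_config()], retaining the generating effect tables as ground
#' truth. With `dir` given, writes a PLINK BED/BIM/FAM fileset, exposure
#' and biomarker TSVs per stratum, and a `truth.json`, so the whole
#' pipeline can run end-to-end from files.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @return A `synthetic_study`: list with `strata` (each having
#'   `genotypes`, `exposures`, `biomarkers`), `truth` (the effect tables
#'   and config), and `files` when written.
#' @export
make_study <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_variants
  shared_mafs <- if (config$shared_maf) {
    runif(m, config$maf_range[1], config$maf_range[2])
  } else NULL
  strata <- list()
  for (s in names(config$n_samples)) {
    n <- config$n_samples[[s]]
    gm <- simulate_genotypes(
      n, m, config$maf_range,
      mafs = shared_mafs %||% runif(m, config$maf_range[1], config$maf_range[2]),
      sample_prefix = paste0(s, "_")
    )
    ex <- simulate_exposures(n, config$exposure_blocks)
    y <- simulate_phenotype(gm, ex, config$beta_g, config$beta_e,
                            config$beta_ge, config$noise_sd, config$skew)
    strata[[s]] <- list(genotypes = gm, exposures = ex,
                        biomarkers = list(trait = y))
  }
  study <- structure(list(
    strata = strata,
    truth = list(beta_g = as.list(config$beta_g),
                 beta_e = as.list(config$beta_e),
                 beta_ge = config$beta_ge, noise_sd = config$noise_sd,
                 seed = config$seed),
    config = config
  ), class = "synthetic_study")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list()
    for (s in names(strata)) {
      prefix <- file.path(dir, paste0("geno_", s))
      write_plink(strata[[s]]$genotypes, prefix)
      ex_path <- file.path(dir, paste0("exposures_", s, ".tsv"))
      readr::write_tsv(dplyr::bind_cols(
        tibble::tibble(sample_id = strata[[s]]$genotypes$samples),
        strata[[s]]$exposures), ex_path, progress = FALSE)
      bm_path <- file.path(dir, paste0("biomarkers_", s, ".tsv"))
      readr::write_tsv(tibble::tibble(
        sample_id = strata[[s]]$genotypes$samples,
        trait = strata[[s]]$biomarkers$trait), bm_path, progress = FALSE)
      files[[s]] <- list(plink = prefix, exposures = ex_path, biomarkers = bm_path)
    }
    truth_path <- file.path(dir, "truth.json")
    jsonlite::write_json(study$truth, truth_path, auto_unbox = TRUE, digits = NA)
    files$truth <- truth_path
    study$files <- files
  }
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d strata (%s); %d variants; %d planted GEI(s)\n",
              length(x$strata), paste(names(x$strata), collapse = ", "),
              nrow(x$strata[[1]]$genotypes$variants),
              if (is.null(x$truth$beta_ge)) 0L else nrow(x$truth$beta_ge)))
  invisible(x)
}
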