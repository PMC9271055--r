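#' Convert an imputed dosage to a hard-call genotype
#'
#' Imputed genotype dosages in `[0, 2]` are converted to hard calls in
#' `{0, 1, 2}` when they lie within `tolerance` of an integer; all other
#' dosages become missing (`NA`). This mirrors the conversion applied to
#' biobank-scale imputed data before variance-QTL testing, where fractional
#' dosages would blur the genotype classes the Levene test compares.
#'
#' @param dosage Numeric vector of dosages in `[0, 2]`. `NA` propagates.
#' @param tolerance Maximum distance from an integer for a call to be made;
#'   must lie in `(0, 0.5)`. Default `0.1`.
#' @return Integer vector of the same length with values in `{0L, 1L, 2L, NA}`.
#' @examples
#' hard_call(c(0.95, 1.15, 2.0))
#' @export
hard_call <- function(dosage, tolerance = 0.1) {
  if (!is.numeric(dosage)) stop_input("`dosage` must be numeric")
  if (!is_scalar_number(tolerance) || tolerance <= 0 || tolerance >= 0.5) {
    stop_input("`tolerance` must be a single number in (0, 0.5)")
  }
  bad <- !is.na(dosage) & (dosage < 0 | dosage > 2)
  if (any(bad)) {
    stop_input("dosage outside [0, 2] at position %d (value %g)",
               which(bad)[1], dosage[which(bad)[1]])
  }
  nearest <- round(dosage)
  # epsilon guards the boundary case (e.g. |1.9 - 2| evaluates to 0.1 + 1e-16)
  out <- ifelse(abs(dosage - nearest) <= tolerance + 1e-12, nearest, NA_real_)
  as.integer(out)
}

#' Construct a genotype matrix container
#'
#' Bundles a samples-by-variants hard-call matrix with per-variant metadata.
#' Alternate (counted) allele frequencies are recomputed from the calls when
#' not supplied.
#'
#' @param calls Integer matrix, samples in rows, variants in columns; values
#'   in `{0, 1, 2, NA}` counting the alternate allele.
#' @param variants Data frame with columns `id`, `chrom`, `pos`, `ref`, `alt`
#'   and optionally `af` (alternate-allele frequency).
#' @param samples Character vector of unique sample identifiers.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `variants` (tibble), `samples`.
#' @export
genotype_matrix <- function(calls, variants, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  variants <- tibble::as_tibble(variants)
  required <- c("id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    stop_input("`variants` lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(variants) != ncol(calls)) {
    stop_input("variant table has %d rows but calls has %d columns",
               nrow(variants), ncol(calls))
  }
  if (length(samples) != nrow(calls)) {
    stop_input("%d sample ids but calls has %d rows", length(samples), nrow(calls))
  }
  if (anyDuplicated(samples)) stop_input("duplicate sample identifiers")
  if (anyDuplicated(variants$id)) stop_input("duplicate variant identifiers")
  ok <- calls %in% c(0L, 1L, 2L, NA)
  if (!all(ok)) stop_input("calls contain values outside {0, 1, 2, NA}")
  bad_allele <- variants$ref == variants$alt | !nzchar(variants$ref) | !nzchar(variants$alt)
  if (any(bad_allele)) stop_input("alleles must be non-empty and distinct (variant %s)",
                                  variants$id[which(bad_allele)[1]])
  if (any(variants$pos < 1)) stop_input("positions are 1-based; found pos < 1")
  if (!"af" %in% names(variants)) {
    variants$af <- colMeans(calls, na.rm = TRUE) / 2
  }
  if (any(!is.na(variants$af) & (variants$af < 0 | variants$af > 1))) {
    stop_input("allele frequencies must lie in [0, 1]")
  }
  dimnames(calls) <- list(as.character(samples), variants$id)
  structure(
    list(calls = calls, variants = variants, samples = as.character(samples)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants\n",
              length(x$samples), nrow(x$variants)))
  print(head(x$variants, 5))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Filter a genotype matrix on minor allele frequency
#'
#' Variants whose minor allele frequency (`min(af, 1 - af)`) is less than or
#' equal to `min_maf` are removed. The filter is symmetric in allele
#' labelling.
#'
#' @param gm A [genotype_matrix()].
#' @param min_maf MAF threshold; variants are kept when MAF > `min_maf`.
#' @return A `genotype_matrix` with the surviving variants, order preserved.
#' @export
filter_maf <- function(gm, min_maf = 0.005) {
  stopifnot(inherits(gm, "genotype_matrix"))
  maf <- pmin(gm$variants$af, 1 - gm$variants$af)
  keep <- !is.na(maf) & maf > min_maf
  genotype_matrix(gm$calls[, keep, drop = FALSE], gm$variants[keep, ], gm$samples)
}

#' Read genotypes from PLINK1 or VCF files
#'
#' Reads hard-called genotypes from a PLINK1 BED/BIM/FAM fileset or a VCF.
#' VCF dosages use the `DS` FORMAT field when present, otherwise the
#' alternate-allele count from `GT`; dosages are hard-called with
#' [hard_call()] at `hard_call_tol`. Variants failing the MAF filter are
#' removed; file order is preserved. Multi-allelic VCF records are rejected.
#'
#' @param path Path to the `.bed` file (or fileset prefix) or the VCF.
#' @param format One of `"auto"`, `"plink-bed"`, `"vcf"`. `"auto"` keys off
#'   the file extension.
#' @param min_maf Variants with minor allele frequency `<= min_maf` are
#'   dropped (default 0.005). Use 0 to keep all polymorphic variants,
#'   negative to disable entirely.
#' @param hard_call_tol Dosage-to-hard-call tolerance (default 0.1).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "plink-bed", "vcf"),
                           min_maf = 0.005, hard_call_tol = 0.1) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "plink-bed"
  }
  gm <- switch(format,
    "vcf" = read_vcf_genotypes(path, hard_call_tol),
    "plink-bed" = read_plink_genotypes(path)
  )
  filter_maf(gm, min_maf)
}

read_vcf_genotypes <- function(path, hard_call_tol = 0.1) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop_input("multi-allelic variant at %s:%s; split or remove it first",
               fix$CHROM[grepl(",", fix$ALT)][1],
               fix$POS[grepl(",", fix$ALT)][1])
  }
  fmt_fields <- unique(unlist(strsplit(vcf@gt[, 1], ":", fixed = TRUE)))
  if ("DS" %in% fmt_fields) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    count_alt <- function(x) {
      ifelse(is.na(x) | grepl("\\.", x), NA_real_,
             vapply(strsplit(x, "[/|]"), function(a) sum(a == "1"), numeric(1)))
    }
    ds <- apply(gt, 2, count_alt)
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(vcf@fix))
  }
  # extract.gt returns variants x samples
  calls <- apply(ds, 2, hard_call, tolerance = hard_call_tol)
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = nrow(fix))
  calls <- t(calls)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  variants <- tibble::tibble(
    id = ids, chrom = as.character(fix$CHROM), pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )
  genotype_matrix(calls, variants, colnames(vcf@gt)[-1])
}

# ---- PLINK1 BED/BIM/FAM ----
# 2-bit SNP-major codec: per variant, samples packed 4 per byte, low bits
# first; 00 = 2 copies of allele A1, 01 = missing, 10 = het, 11 = 0 copies.
# A1 is taken as the counted (alternate) allele, A2 as reference.

plink_prefix <- function(path) sub("\\.(bed|bim|fam)$", "", path)

read_plink_genotypes <- function(path) {
  prefix <- plink_prefix(path)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop_input("file not found: %s", f)

  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam_df); m <- nrow(bim_df)
  samples <- as.character(fam_df[[2]])

  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop_input("%s: not a PLINK1 BED file (bad magic bytes)", bed)
  }
  if (raw[3] != as.raw(0x01)) stop_input("%s: only SNP-major BED is supported", bed)
  bytes_per_variant <- ceiling(n / 4)
  if (length(raw) - 3L != bytes_per_variant * m) {
    stop_input("%s: size inconsistent with %d samples x %d variants", bed, n, m)
  }
  body <- raw[-(1:3)]
  # decode all two-bit fields at once
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8)
  two_bit <- bits[seq(1, 7, by = 2), , drop = FALSE] +
    2L * bits[seq(2, 8, by = 2), , drop = FALSE]
  codes <- matrix(as.vector(two_bit), nrow = 4 * bytes_per_variant)[1:n, , drop = FALSE]
  lookup <- c(2L, NA_integer_, 1L, 0L)  # 00, 01, 10, 11
  calls <- matrix(lookup[codes + 1L], nrow = n, ncol = m)
  variants <- tibble::tibble(
    id = as.character(bim_df$id), chrom = as.character(bim_df$chrom),
    pos = as.integer(bim_df$pos), ref = bim_df$a2, alt = bim_df$a1
  )
  genotype_matrix(calls, variants, samples)
}

#' Write a genotype matrix as a PLINK1 BED/BIM/FAM fileset
#'
#' The alternate allele is written as PLINK A1 (the counted allele).
#'
#' @param gm A [genotype_matrix()].
#' @param prefix Output path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(gm, prefix) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- length(gm$samples); m <- nrow(gm$variants)
  bim <- data.frame(gm$variants$chrom, gm$variants$id, 0L, gm$variants$pos,
                    gm$variants$alt, gm$variants$ref)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(gm$samples, gm$samples, 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  encode <- c(`2` = 0L, `1` = 2L, `0` = 3L)  # genotype -> two-bit code
  bytes_per_variant <- ceiling(n / 4)
  pad <- 4 * bytes_per_variant - n
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(m)) {
    g <- gm$calls[, j]
    code <- ifelse(is.na(g), 1L, encode[as.character(g)])
    code <- c(code, rep(0L, pad))
    quads <- matrix(code, nrow = 4)
    byte_vals <- quads[1, ] + 4L * quads[2, ] + 16L * quads[3, ] + 64L * quads[4, ]
    writeBin(as.raw(byte_vals), con)
  }
  invisible(prefix)
}

#' Write a genotype matrix as an uncompressed VCF with GT fields
#'
#' @param gm A [genotype_matrix()].
#' @param path Output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(gm$variants)), function(j) {
    v <- gm$variants[j, ]
    g <- gm$calls[, j]
    cells <- ifelse(is.na(g), "./.", gt_str[as.character(g)])
    paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT", cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}
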