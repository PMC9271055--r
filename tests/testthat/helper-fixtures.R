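# fixtures built in code; no binary files shipped

# brute-force oracle for the median-based Levene test: one-way ANOVA on
# |y - class median|, via stats::anova -- independent of the package path
oracle_levene <- function(y, g) {
  f <- factor(g)
  med <- tapply(y, f, median)
  z <- abs(y - med[f])
  a <- stats::anova(stats::lm(z ~ f))
  list(statistic = a$`F value`[1], p_value = a$`Pr(>F)`[1])
}

# brute-force HC0 sandwich for the interaction model, straight from the
# matrix formula (X'X)^-1 X' diag(r^2) X (X'X)^-1
oracle_sandwich_gxe <- function(y, g, e) {
  X <- cbind(1, g, e, g * e)
  bread <- solve(crossprod(X))
  beta <- bread %*% crossprod(X, y)
  r <- as.numeric(y - X %*% beta)
  meat <- t(X) %*% (X * r^2)
  V <- bread %*% meat %*% bread
  list(beta = beta[4], se = sqrt(V[4, 4]))
}

# random small genotype/phenotype pair with 2-3 classes, each holding at
# least two observations (the condition under which the decomposition and a
# plain one-way ANOVA on the deviations coincide)
random_levene_dataset <- function(n = NULL) {
  n <- n %||% sample(30:300, 1)
  maf <- runif(1, 0.2, 0.5)
  repeat {
    g <- rbinom(n, 2, maf)
    keep <- g %in% as.integer(names(which(table(g) >= 2)))
    g <- g[keep]
    if (length(unique(g)) >= 2) break
  }
  y <- rnorm(length(g), sd = 1 + 0.2 * g)
  list(y = y, g = g, n = length(g))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# a 4-sample, 2-variant PLINK BED fileset written byte-by-byte by hand
# (SNP-major, 2-bit codes low-pair first: 00=hom A1, 01=missing, 10=het,
# 11=hom A2), with the genotype matrix it encodes
hand_decoded_plink <- function(dir) {
  prefix <- file.path(dir, "hand")
  writeLines(c("1\trsA\t0\t1000\tG\tA", "2\trsB\t0\t2000\tT\tC"),
             paste0(prefix, ".bim"))
  writeLines(sprintf("s%d\ts%d\t0\t0\t0\t-9", 1:4, 1:4), paste0(prefix, ".fam"))
  # variant rsA: s1=hom A1(00), s2=het(10), s3=hom A2(11), s4=missing(01)
  #   byte bits low->high: 00 10 11 01 -> value 0b01111000 = 0x78
  # variant rsB: s1=het(10), s2=het(10), s3=hom A1(00), s4=hom A2(11)
  #   byte: 10 10 00 11 -> 0b11001010 = 0xCA
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x78, 0xCA)), paste0(prefix, ".bed"))
  calls <- matrix(c(2L, 1L, 0L, NA, 1L, 1L, 2L, 0L), nrow = 4,
                  dimnames = list(paste0("s", 1:4), c("rsA", "rsB")))
  list(prefix = prefix, calls = calls)
}

# tiny VCF text fixture: 3 samples, 2 variants, GT only
write_gt_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\tva\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tvb\tC\tT\t.\tPASS\t.\tGT\t0|1\t./.\t0/0"
  ), path)
  matrix(c(0L, 1L, 2L, 1L, NA, 0L), nrow = 3,
         dimnames = list(c("s1", "s2", "s3"), c("va", "vb")))
}

# random summary-stat tibble matching the interchange schema
random_summary_stats <- function(n_rows = 100) {
  out <- tibble::tibble(
    chrom = as.character(sample(1:22, n_rows, TRUE)),
    pos = sample.int(1e8, n_rows),
    id = paste0("rs", seq_len(n_rows)),
    a1 = sample(c("A", "C", "G", "T"), n_rows, TRUE),
    a2 = sample(c("A", "C", "G", "T"), n_rows, TRUE),
    af = runif(n_rows), n = sample(100:1000, n_rows, TRUE),
    stat = rnorm(n_rows), beta = rnorm(n_rows), se = runif(n_rows, 0.01, 1),
    dir = sample(c(-1L, 0L, 1L), n_rows, TRUE),
    p = 10^-runif(n_rows, 0, 300),
    kind = sample(c("vqtl", "me"), n_rows, TRUE),
    stratum = "EUR"
  )
  out$a2 <- ifelse(out$a2 == out$a1, "N", out$a2)
  out
}
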