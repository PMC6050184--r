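## Builders for small in-code fixtures and independent oracles.

toy_genotypes <- function(dosage, pops = NULL, chrom = NULL, pos = NULL,
                          locus_ids = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); m <- ncol(dosage)
  ids <- sprintf("ind%02d", seq_len(n))
  snps <- sprintf("snp%03d", seq_len(m))
  g <- genotypes(dosage, ids, snps,
                 chrom = chrom %||% rep("chr1", m),
                 pos = pos %||% seq_len(m),
                 ref = rep("A", m), alt = rep("G", m),
                 locus_ids = locus_ids %||% snps)
  if (is.null(pops)) return(g)
  list(g = g, pm = data.frame(individual_id = ids, lake_code = pops,
                              stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_panel <- function(n_ind, n_snp, n_pop = 2, miss = 0.1, seed = 1) {
  set.seed(seed)
  d <- matrix(sample(0:2, n_ind * n_snp, replace = TRUE), n_ind, n_snp)
  d[runif(n_ind * n_snp) < miss] <- NA
  toy_genotypes(d, pops = paste0("P", rep_len(seq_len(n_pop), n_ind)))
}

## Independent WC84 oracle: literal scalar transcription of the per-locus
## variance components, loops only.
wc84_oracle_theta <- function(dosage, pop) {
  pops <- unique(pop)
  r <- length(pops)
  sum_a <- sum_t <- 0
  for (l in seq_len(ncol(dosage))) {
    n <- p <- h <- numeric(r)
    for (k in seq_len(r)) {
      dk <- dosage[pop == pops[k], l]
      dk <- dk[!is.na(dk)]
      n[k] <- length(dk)
      if (n[k] > 0) {
        p[k] <- sum(dk) / (2 * n[k])
        h[k] <- mean(dk == 1)
      }
    }
    if (any(n < 1)) next
    nbar <- mean(n)
    if (nbar <= 1) next
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                          (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (!is.finite(a + b + cc)) next
    sum_a <- sum_a + a
    sum_t <- sum_t + a + b + cc
  }
  sum_a / sum_t
}

## minimal VCF writer for hand-built records
write_toy_vcf <- function(path, records, samples) {
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"),
             records)
  writeLines(lines, path)
  path
}
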