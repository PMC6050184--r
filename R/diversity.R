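#' Per-population alternate-allele frequencies
#'
#' @param g a [genotypes()] object.
#' @param pm population map data frame.
#' @return A list with matrices (populations x SNPs) `freq` (alternate-allele
#'   frequency; `NA` where a population has no calls), `n` (number of
#'   genotyped individuals) and `het` (observed heterozygote fraction).
#' @export
allele_frequencies <- function(g, pm) {
  pop <- popmap_factor(g, pm)
  called <- !is.na(g$dosage)
  n <- rowsum(called + 0, pop)
  d0 <- g$dosage
  d0[is.na(d0)] <- 0L
  alt <- rowsum(d0 + 0, pop)
  het <- rowsum((g$dosage == 1L & called) + 0, pop)
  freq <- alt / (2 * n)
  freq[n == 0] <- NA_real_
  hetf <- het / n
  hetf[n == 0] <- NA_real_
  list(freq = freq, n = n, het = hetf, populations = rownames(n))
}

## unbiased expected heterozygosity per the package contract:
## 2 p (1-p) * n/(n-1), n = genotyped diploid individuals
unbiased_he <- function(p, n) {
  he <- 2 * p * (1 - p) * n / (n - 1)
  he[n < 2] <- NA_real_
  he
}

#' Per-population diversity summary
#'
#' For every population: fraction of genotype calls made (`genotype_ratio`),
#' observed heterozygosity `Ho` (mean heterozygote fraction over SNPs with at
#' least one call), unbiased expected heterozygosity `He` (mean over the same
#' SNPs of `2p(1-p) n/(n-1)`), nucleotide diversity `pi` (mean unbiased
#' heterozygosity over locally polymorphic SNPs, divided by
#' `sites_per_locus`), and the count/proportion of locally polymorphic SNPs.
#' SNPs monomorphic within a population contribute 0 to the Ho/He means but
#' stay in the denominator.
#'
#' @param g a [genotypes()] object.
#' @param pm population map data frame.
#' @param sites_per_locus scaling divisor for `pi`, the number of sequenced
#'   sites each variant site represents (default 1 = per-variant-site pi; 80
#'   emulates 80-bp read loci).
#' @return A data frame, one row per population.
#' @export
diversity_summary <- function(g, pm, sites_per_locus = 1) {
  stopifnot(sites_per_locus >= 1)
  af <- allele_frequencies(g, pm)
  pop_sizes <- table(popmap_factor(g, pm))
  n_snp <- ncol(g$dosage)
  out <- lapply(seq_along(af$populations), function(i) {
    p <- af$freq[i, ]
    n <- af$n[i, ]
    has <- n > 0
    if (!any(has)) stop("population ", af$populations[i], " has no genotyped SNPs")
    he <- unbiased_he(p, n)
    poly <- has & !is.na(p) & p > 0 & p < 1
    data.frame(
      lake_code = af$populations[i],
      genotype_ratio = sum(n) / (n_snp * pop_sizes[[af$populations[i]]]),
      Ho = mean(af$het[i, has]),
      He = mean(ifelse(poly[has], he[has], 0), na.rm = TRUE),
      pi = if (any(poly)) mean(he[poly], na.rm = TRUE) / sites_per_locus else 0,
      n_polymorphic = sum(poly),
      prop_polymorphic = sum(poly) / n_snp,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
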