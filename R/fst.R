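## Weir & Cockerham (1984) per-locus variance components for one pair (or
## more) of populations. Vectorised over loci. Inputs are per-population
## matrices (pops x loci) of sample sizes n, alternate-allele frequencies p
## and observed heterozygote fractions h. Returns per-locus a (among-pop),
## b (among individuals within pops) and c (within individuals) components.
wc84_components <- function(n, p, h) {
  r <- nrow(n)
  usable <- colSums(n >= 1) == r
  nbar <- colMeans(n)
  sum_n <- colSums(n)
  nc <- (sum_n - colSums(n^2) / sum_n) / (r - 1)
  pbar <- colSums(n * p) / sum_n
  s2 <- colSums(n * sweep(p, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / sum_n
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- !usable | nbar <= 1 | !is.finite(a + b + cc)
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  list(a = a, b = b, c = cc)
}

theta_from_components <- function(comp, loci = NULL) {
  a <- comp$a; tot <- comp$a + comp$b + comp$c
  if (!is.null(loci)) { a <- a[loci]; tot <- tot[loci] }
  sa <- sum(a, na.rm = TRUE); st <- sum(tot, na.rm = TRUE)
  if (st == 0) return(NA_real_)
  max(-1, min(1, sa / st))
}

#' Pairwise Weir-Cockerham FST with locus bootstrap
#'
#' Multi-locus theta per population pair is the ratio of summed
#' among-population variance components to summed total components
#' (ratio-of-sums). Significance and percentile confidence intervals come
#' from resampling loci with replacement: the p-value is the proportion of
#' bootstrap replicates with theta <= 0.
#'
#' @param g a [genotypes()] object.
#' @param pm population map data frame.
#' @param n_boot number of locus bootstrap replicates (default 1000; 0 skips).
#' @param seed integer seed making the bootstrap reproducible.
#' @return A list of class `stockload_fst`: `theta` (symmetric matrix,
#'   zero diagonal), `p_value`, `ci_lower`, `ci_upper` (same shape),
#'   `mean_theta` (per-population mean pairwise theta) and `pairs`
#'   (long-format data frame).
#' @export
pairwise_fst <- function(g, pm, n_boot = 1000, seed = 1) {
  af <- allele_frequencies(g, pm)
  ## canonical locus order so bootstrap draws do not depend on input order
  ord <- order(g$snp_ids)
  af$freq <- af$freq[, ord, drop = FALSE]
  af$n <- af$n[, ord, drop = FALSE]
  af$het <- af$het[, ord, drop = FALSE]
  pops <- af$populations
  r <- length(pops)
  if (r < 2) stop("need at least two populations")
  for (i in seq_len(r)) {
    if (max(af$n[i, ]) < 2) {
      stop("population ", pops[i],
           " has fewer than 2 genotyped individuals at every locus")
    }
  }
  theta <- pmat <- lo <- hi <- matrix(NA_real_, r, r, dimnames = list(pops, pops))
  diag(theta) <- 0
  rows <- list()
  set.seed(seed)
  n_loci <- ncol(af$freq)
  boot_idx <- if (n_boot > 0) {
    matrix(sample.int(n_loci, n_loci * n_boot, replace = TRUE), ncol = n_boot)
  }
  for (i in seq_len(r - 1)) for (j in (i + 1):r) {
    sel <- c(i, j)
    comp <- wc84_components(af$n[sel, , drop = FALSE],
                            af$freq[sel, , drop = FALSE],
                            af$het[sel, , drop = FALSE])
    th <- theta_from_components(comp)
    theta[i, j] <- theta[j, i] <- th
    p <- ci_l <- ci_u <- NA_real_
    if (n_boot > 0) {
      bt <- vapply(seq_len(n_boot),
                   function(b) theta_from_components(comp, boot_idx[, b]),
                   numeric(1))
      p <- mean(bt <= 0, na.rm = TRUE)
      qs <- stats::quantile(bt, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
      ci_l <- qs[1]; ci_u <- qs[2]
    }
    pmat[i, j] <- pmat[j, i] <- p
    lo[i, j] <- lo[j, i] <- ci_l
    hi[i, j] <- hi[j, i] <- ci_u
    rows[[length(rows) + 1L]] <- data.frame(
      pop1 = pops[i], pop2 = pops[j], theta = th, p_value = p,
      ci_lower = ci_l, ci_upper = ci_u, stringsAsFactors = FALSE)
  }
  structure(list(
    theta = theta, p_value = pmat, ci_lower = lo, ci_upper = hi,
    mean_theta = rowMeans(theta, na.rm = TRUE),
    pairs = do.call(rbind, rows)), class = "stockload_fst")
}

#' Turn a pairwise FST result into a distance matrix
#'
#' Negative estimates are truncated at zero so the result is a valid
#' dissimilarity for ordination.
#'
#' @param fst a [pairwise_fst()] result.
#' @return A `dist` object over populations.
#' @export
fst_dist <- function(fst) {
  m <- pmax(fst$theta, 0)
  stats::as.dist(m)
}
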