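test_that("allele frequencies equal a brute-force per-cell recount", {
  tg <- rand_panel(20, 30, n_pop = 3, miss = 0.2, seed = 3)
  af <- allele_frequencies(tg$g, tg$pm)
  for (p in af$populations) {
    for (j in sample(30, 10)) {
      dj <- tg$g$dosage[tg$pm$lake_code == p, j]
      dj <- dj[!is.na(dj)]
      i <- match(p, af$populations)
      if (length(dj) == 0) {
        expect_true(is.na(af$freq[i, j]))
      } else {
        expect_equal(af$freq[i, j], sum(dj) / (2 * length(dj)))
        expect_equal(af$het[i, j], mean(dj == 1))
      }
    }
  }
  ## single pop, genotypes (0,1,2) -> 0.5
  t1 <- toy_genotypes(matrix(c(0L, 1L, 2L), 3, 1), pops = rep("A", 3))
  expect_equal(unname(allele_frequencies(t1$g, t1$pm)$freq[1, 1]), 0.5)
})

test_that("diversity summary matches closed forms and a brute-force loop", {
  ## single locus, genotypes (0,1,1,2): p = 0.5, n = 4
  t1 <- toy_genotypes(matrix(c(0L, 1L, 1L, 2L), 4, 1), pops = rep("A", 4))
  d1 <- diversity_summary(t1$g, t1$pm)
  expect_equal(d1$Ho, 0.5)
  expect_equal(d1$He, 2 * 0.25 * (4 / 3), tolerance = 1e-12)
  ## population fixed at all loci
  t0 <- toy_genotypes(matrix(2L, 5, 4), pops = rep("A", 5))
  d0 <- diversity_summary(t0$g, t0$pm)
  expect_equal(d0$Ho, 0)
  expect_equal(d0$He, 0)
  expect_equal(d0$n_polymorphic, 0L)
  ## random panel against an independent per-locus loop
  tg <- rand_panel(24, 40, n_pop = 2, miss = 0.15, seed = 9)
  ds <- diversity_summary(tg$g, tg$pm)
  for (p in unique(tg$pm$lake_code)) {
    sub <- tg$g$dosage[tg$pm$lake_code == p, ]
    ho <- he <- numeric(0); npoly <- 0
    pis <- numeric(0)
    for (j in seq_len(ncol(sub))) {
      dj <- sub[!is.na(sub[, j]), j]
      if (!length(dj)) next
      pj <- sum(dj) / (2 * length(dj))
      hej <- 2 * pj * (1 - pj) * length(dj) / (length(dj) - 1)
      ho <- c(ho, mean(dj == 1))
      if (pj > 0 && pj < 1) {
        npoly <- npoly + 1
        he <- c(he, hej)
        pis <- c(pis, hej)
      } else he <- c(he, 0)
    }
    row <- ds[ds$lake_code == p, ]
    expect_equal(row$Ho, mean(ho))
    expect_equal(row$He, mean(he))
    expect_equal(row$pi, mean(pis))
    expect_equal(row$n_polymorphic, npoly)
    expect_equal(row$prop_polymorphic, npoly / 40)
  }
})

test_that("expected heterozygosity is invariant to allele-label swap", {
  tg <- rand_panel(16, 20, n_pop = 2, miss = 0.1, seed = 5)
  d1 <- diversity_summary(tg$g, tg$pm)
  swapped <- toy_genotypes(2L - tg$g$dosage, pops = tg$pm$lake_code)
  d2 <- diversity_summary(swapped$g, swapped$pm)
  expect_equal(d1$He, d2$He)
  expect_equal(d1$n_polymorphic, d2$n_polymorphic)
})

test_that("pairwise theta reproduces limit cases", {
  set.seed(21)
  ## same frequencies, large n -> theta near 0
  d <- matrix(rbinom(2 * 200 * 50, 2, rep(runif(50, 0.2, 0.8), each = 400)),
              400, 50)
  tg <- toy_genotypes(d, pops = rep(c("A", "B"), 200))
  f <- pairwise_fst(tg$g, tg$pm, n_boot = 0)
  expect_lt(abs(f$theta["A", "B"]), 0.02)
  ## fixed for alternative alleles -> theta = 1
  d2 <- rbind(matrix(0L, 10, 5), matrix(2L, 10, 5))
  tg2 <- toy_genotypes(d2, pops = rep(c("A", "B"), each = 10))
  f2 <- pairwise_fst(tg2$g, tg2$pm, n_boot = 0)
  expect_equal(unname(f2$theta["A", "B"]), 1)
})

test_that("theta equals an independently coded component-wise oracle", {
  set.seed(13)
  for (rep in 1:5) {
    d <- matrix(sample(0:2, 14 * 5, replace = TRUE), 14, 5)
    d[runif(70) < 0.15] <- NA
    pops <- rep(c("A", "B"), each = 7)
    tg <- toy_genotypes(d, pops = pops)
    f <- pairwise_fst(tg$g, tg$pm, n_boot = 0)
    expect_equal(unname(f$theta["A", "B"]),
                 wc84_oracle_theta(d, pops), tolerance = 1e-12)
  }
  ## three populations, pairwise against the oracle on the pair subset
  d <- matrix(sample(0:2, 18 * 8, replace = TRUE), 18, 8)
  pops <- rep(c("A", "B", "C"), each = 6)
  tg <- toy_genotypes(d, pops = pops)
  f <- pairwise_fst(tg$g, tg$pm, n_boot = 0)
  sel <- pops %in% c("A", "C")
  expect_equal(unname(f$theta["A", "C"]),
               wc84_oracle_theta(d[sel, ], pops[sel]), tolerance = 1e-12)
})

test_that("single-locus ratio-of-sums degenerates to the per-locus theta", {
  set.seed(31)
  d <- matrix(sample(0:2, 12, replace = TRUE), 12, 1)
  tg <- toy_genotypes(d, pops = rep(c("A", "B"), each = 6))
  f <- pairwise_fst(tg$g, tg$pm, n_boot = 0)
  expect_equal(unname(f$theta["A", "B"]),
               wc84_oracle_theta(d, rep(c("A", "B"), each = 6)))
})

test_that("bootstrap p-values are seed-reproducible and locus-order invariant", {
  tg <- rand_panel(20, 40, n_pop = 2, miss = 0.05, seed = 17)
  f1 <- pairwise_fst(tg$g, tg$pm, n_boot = 200, seed = 99)
  f2 <- pairwise_fst(tg$g, tg$pm, n_boot = 200, seed = 99)
  expect_identical(f1$p_value, f2$p_value)
  expect_identical(f1$ci_lower, f2$ci_lower)
  ## permute locus order (keeping SNP identities): loci are canonicalized
  ## by id internally, so theta AND bootstrap p are exactly invariant
  perm <- sample(40)
  g3 <- genotypes(tg$g$dosage[, perm], tg$g$individual_ids,
                  tg$g$snp_ids[perm], tg$g$chrom[perm], tg$g$pos[perm],
                  tg$g$ref[perm], tg$g$alt[perm], tg$g$locus_ids[perm])
  f3 <- pairwise_fst(g3, tg$pm, n_boot = 200, seed = 99)
  expect_equal(f3$theta, f1$theta)
  expect_identical(f3$p_value, f1$p_value)
})

test_that("degenerate populations are rejected", {
  d <- matrix(c(1L, NA, NA, 1L, 1L, 1L), 3, 2)  # pop B: 1 genotyped ind max
  tg <- toy_genotypes(rbind(d, d), pops = c("A", "A", "A", "B", "B", "B"))
  tg$g$dosage[4:6, ] <- NA
  tg$g$dosage[4, 1] <- 1L
  expect_error(pairwise_fst(tg$g, tg$pm, n_boot = 0), "fewer than 2")
})

test_that("mean theta grows with divergence time under pure drift", {
  thetas <- vapply(c(20, 60, 160), function(G) {
    cfg <- simulation_config(n_lakes = 2, n_unstocked = 2, ne = 60,
                             scale_ne_with_area = FALSE, generations = G,
                             n_loci = 400, s = 0, sample_n = 30,
                             missing_rate = 0, seed = 101)
    ds <- simulate_dataset(cfg)
    pairwise_fst(ds$genotypes, ds$popmap, n_boot = 0)$theta[1, 2]
  }, numeric(1))
  expect_true(all(diff(thetas) > 0))
})
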