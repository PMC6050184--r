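test_that("PCoA reconstructs Euclidean configurations exactly", {
  set.seed(18)
  pts <- cbind(runif(5), runif(5))
  d <- as.matrix(dist(pts))
  p <- pcoa(d)
  tolv <- 1e-9 * max(abs(p$values))
  expect_equal(sum(p$values > tolv), 2L)
  drec <- as.matrix(dist(p$scores[, 1:2]))
  expect_lt(sqrt(mean((drec - d)^2)), 1e-8)
  ## zero matrix: nothing retained
  z <- pcoa(matrix(0, 4, 4))
  expect_equal(ncol(z$scores), 0L)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PCoA of Euclidean distances equals PCA scores up to sign", {
  set.seed(19)
  x <- matrix(rnorm(8 * 3), 8, 3)
  p <- pcoa(as.matrix(dist(x)))
  pc <- prcomp(x, center = TRUE)$x
  for (k in 1:3) {
    expect_equal(abs(cor(p$scores[, k], pc[, k])), 1, tolerance = 1e-8)
  }
})

test_that("Hellinger transform of stocking rows matches hand values", {
  lakes <- data.frame(lake_code = c("A", "B", "C"), area_ha = c(1, 1, 1))
  s <- rbind(A = c(4, 0, 0), B = c(1, 1, 2), C = c(0, 0, 0))
  colnames(s) <- c("s1", "s2", "s3")
  h <- hellinger_stocking(s, lakes)
  expect_equal(unname(h["A", ]), c(1, 0, 0))
  expect_equal(unname(h["B", ]), c(0.5, 0.5, sqrt(0.5)), tolerance = 1e-12)
  expect_equal(unname(h["C", ]), c(0, 0, 0))
  expect_false(anyNA(h))
  ## area scaling is absorbed by the row-relative transform
  lakes2 <- data.frame(lake_code = c("A", "B", "C"), area_ha = c(10, 70, 3))
  expect_equal(hellinger_stocking(s, lakes2), h)
  expect_error(hellinger_stocking(-s, lakes), "non-negative")
})

test_that("broken-stick proportions match the analytic form and sum to one", {
  expect_equal(broken_stick(3), c(11 / 18, 5 / 18, 2 / 18), tolerance = 1e-12)
  expect_equal(round(broken_stick(3), 4), c(0.6111, 0.2778, 0.1111))
  expect_equal(broken_stick(1), 1)
  for (p in 2:10) expect_equal(sum(broken_stick(p)), 1, tolerance = 1e-12)
})

test_that("broken-stick retention finds a planted two-factor structure", {
  hits <- vapply(1:20, function(sd) {
    set.seed(sd)
    n <- 60
    f1 <- rnorm(n); f2 <- rnorm(n)
    x <- cbind(f1, f1, f1, f2, f2, f2) * rep(c(3, 2.5), each = 3) +
      matrix(rnorm(n * 6, sd = 0.3), n, 6)
    sum(pca_broken_stick(x)$retained)
  }, numeric(1))
  expect_gte(mean(hits == 2), 0.9)
  ## single positive-variance column
  one <- pca_broken_stick(cbind(rnorm(10), rnorm(10)))
  expect_true(is.logical(one$retained))
})

test_that("RDA R-squared equals OLS on univariate responses", {
  set.seed(22)
  n <- 40
  x <- matrix(rnorm(n * 3), n, 3)
  y <- x %*% c(1, -2, 0.5) + rnorm(n)
  fit <- rda_fit(y, x, n_perm = 0)
  ols <- summary(lm(y ~ x))
  expect_lt(abs(fit$r_squared - ols$r.squared), 1e-10)
  expect_lt(abs(fit$adj_r_squared - ols$adj.r.squared), 1e-10)
  ## y = x exactly
  expect_equal(rda_fit(x[, 1], x[, 1, drop = FALSE], n_perm = 0)$r_squared, 1,
               tolerance = 1e-12)
  ## orthogonal predictor
  xo <- residuals(lm(rnorm(n) ~ y))
  expect_lt(rda_fit(y, cbind(xo), n_perm = 0)$r_squared, 1e-10)
})

test_that("variance partitioning closes on orthogonalized designs", {
  set.seed(23)
  n <- 50
  x <- scale(rnorm(n), scale = FALSE)
  z <- residuals(lm(rnorm(n) ~ x))  # orthogonal to x by construction
  y <- cbind(x + 0.5 * z + rnorm(n, sd = 0.4),
             -x + z + rnorm(n, sd = 0.4))
  r_x <- rda_fit(y, cbind(x), n_perm = 0)$r_squared
  r_z <- rda_fit(y, cbind(z), n_perm = 0)$r_squared
  r_xz <- rda_fit(y, cbind(x, z), n_perm = 0)$r_squared
  expect_lt(abs(r_x + r_z - r_xz), 1e-8)
  ## semipartial fraction after conditioning equals the marginal share here
  r_part <- partial_rda(y, cbind(x), cbind(z), n_perm = 0)$r_squared
  expect_lt(abs(r_part - r_x), 1e-8)
})

test_that("partial RDA reduces and degenerates as specified", {
  set.seed(24)
  n <- 30
  x <- matrix(rnorm(n * 2), n, 2)
  y <- cbind(x %*% c(1, 1) + rnorm(n))
  full <- rda_fit(y, x, n_perm = 99, seed = 4)
  red <- partial_rda(y, x, NULL, n_perm = 99, seed = 4)
  expect_equal(red$r_squared, full$r_squared)
  expect_equal(red$p_value, full$p_value)
  expect_warning(same <- partial_rda(y, x, x, n_perm = 99, seed = 4),
                 "zero partial variance")
  expect_equal(same$r_squared, 0)
})

test_that("permutation p attains its minimum on perfect fits and is relabeling-invariant", {
  set.seed(25)
  n <- 25
  x <- rnorm(n)
  fit <- rda_fit(cbind(x), cbind(x), n_perm = 199, seed = 7)
  expect_equal(fit$p_value, 1 / 200, tolerance = 1e-12)
  ## joint row relabeling: a strong signal stays at the attainable minimum,
  ## a moderate one agrees within Monte Carlo resolution
  y_strong <- cbind(x + rnorm(n, sd = 0.05))
  ord <- sample(n)
  expect_equal(rda_fit(y_strong, cbind(x), n_perm = 199, seed = 7)$p_value,
               rda_fit(y_strong[ord, , drop = FALSE], cbind(x[ord]),
                       n_perm = 199, seed = 7)$p_value)
  y <- cbind(x + rnorm(n, sd = 2))
  p1 <- rda_fit(y, cbind(x), n_perm = 999, seed = 7)$p_value
  p2 <- rda_fit(y[ord, , drop = FALSE], cbind(x[ord]), n_perm = 999,
                seed = 7)$p_value
  expect_lt(abs(p1 - p2), 0.03)
})

test_that("forward selection recovers a planted informative predictor", {
  n <- 50
  hits <- vapply(1:50, function(sd) {
    set.seed(sd)
    x_true <- rnorm(n)
    y <- sqrt(0.5) * scale(x_true)[, 1] + sqrt(0.5) * rnorm(n)
    cand <- cbind(informative = x_true,
                  matrix(rnorm(n * 5), n, 5,
                         dimnames = list(NULL, paste0("noise", 1:5))))
    sel <- forward_select(y, cand, alpha = 0.05, n_perm = 499, seed = sd)
    identical(sel$selected, "informative")
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("forward selection is conservative on pure noise and exhaustive at alpha 1", {
  n <- 40
  nsel <- vapply(1:40, function(sd) {
    set.seed(sd)
    y <- rnorm(n)
    cand <- matrix(rnorm(n * 4), n, 4,
                   dimnames = list(NULL, paste0("v", 1:4)))
    length(forward_select(y, cand, alpha = 0.05, n_perm = 199,
                          seed = sd)$selected)
  }, numeric(1))
  ## per-step false-selection rate is held near alpha by the Sidak adjustment
  expect_lte(mean(nsel >= 1), 0.15)
  set.seed(60)
  y <- rnorm(20)
  cand <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  all_in <- forward_select(y, cand, alpha = 1, n_perm = 99, seed = 1)
  expect_setequal(all_in$selected, c("a", "b", "c"))
})

test_that("VIF matches its closed form", {
  set.seed(26)
  n <- 200
  x1 <- scale(rnorm(n))[, 1]
  e <- scale(residuals(lm(rnorm(n) ~ x1)))[, 1]
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * e     # empirical correlation exactly 0.9
  v <- vif(cbind(a = x1, b = x2))
  expect_equal(unname(v["a"]), 1 / (1 - 0.81), tolerance = 1e-8)
  expect_equal(unname(v["b"]), 5.263, tolerance = 1e-3)
  ## orthogonal columns
  vo <- vif(cbind(x1, e))
  expect_equal(unname(vo), c(1, 1), tolerance = 1e-8)
  ## duplicated column
  expect_true(is.infinite(max(vif(cbind(x1, x1, e)))))
})

test_that("population-mode imputation restores the majority dosage", {
  tg <- rand_panel(12, 15, n_pop = 2, miss = 0, seed = 27)
  expect_identical(impute_by_population(tg$g, tg$pm)$dosage, tg$g$dosage)
  ## hand case: mode with tie goes to the lower dosage
  d <- matrix(c(0L, 0L, 2L, NA), 4, 1)
  t2 <- toy_genotypes(d, pops = rep("A", 4))
  expect_equal(unname(impute_by_population(t2$g, t2$pm)$dosage[4, 1]), 0L)
  d3 <- matrix(c(0L, 2L, NA), 3, 1)
  t3 <- toy_genotypes(d3, pops = rep("A", 3))
  expect_equal(unname(impute_by_population(t3$g, t3$pm)$dosage[3, 1]), 0L)
  ## random masking: imputed values equal the per-cell modal recount
  set.seed(28)
  base <- rand_panel(30, 20, n_pop = 3, miss = 0, seed = 29)
  d <- base$g$dosage
  mask <- matrix(runif(length(d)) < 0.1, nrow(d), ncol(d))
  dm <- d; dm[mask] <- NA
  gm <- toy_genotypes(dm, pops = base$pm$lake_code)
  imp <- impute_by_population(gm$g, gm$pm)$dosage
  for (cell in which(mask)) {
    i <- (cell - 1) %% nrow(d) + 1
    j <- (cell - 1) %/% nrow(d) + 1
    pop <- base$pm$lake_code[i]
    obs <- dm[base$pm$lake_code == pop, j]
    obs <- obs[!is.na(obs)]
    expected <- if (length(obs)) {
      tab <- tabulate(obs + 1, 3)
      which.max(tab) - 1L       # ties to lower dosage
    } else {
      tabg <- tabulate(dm[!is.na(dm[, j]), j] + 1, 3)
      which.max(tabg) - 1L
    }
    expect_equal(unname(imp[i, j]), expected)
  }
})

test_that("DAPC separates well-separated clusters and yields a proper Q matrix", {
  set.seed(30)
  n <- 60
  d <- rbind(matrix(rbinom(30 * 40, 2, 0.05), 30, 40),
             matrix(rbinom(30 * 40, 2, 0.9), 30, 40))
  g <- toy_genotypes(d)
  q <- dapc(g, k_max = 6, seed = 1)
  expect_equal(q$K, 2L)
  truth <- rep(1:2, each = 30)
  agree <- max(mean(q$clusters == truth), mean(q$clusters == 3 - truth))
  expect_gt(agree, 0.95)
  expect_equal(unname(rowSums(q$Q)), rep(1, n), tolerance = 1e-9)
  ## K = 1 degenerate: single column of ones
  g1 <- toy_genotypes(matrix(rbinom(20 * 10, 2, 0.5), 20, 10))
  q1 <- dapc(g1, k_max = 1, seed = 1)
  expect_equal(unname(q1$Q), matrix(1, 20, 1))
})
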