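#' Principal coordinates analysis
#'
#' Gower double-centering and eigen-decomposition of a symmetric distance
#' matrix. Axis variance proportions are computed over the positive
#' eigenvalues only; axes whose proportion is at least `min_axis_var` are
#' flagged as retained.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param min_axis_var minimum variance fraction for a meaningful axis
#'   (default 0.05).
#' @return A list of class `stockload_pcoa`: `scores` (sites x positive
#'   axes), `values` (all eigenvalues, decreasing), `proportion` (per
#'   positive axis), `retained` (logical mask), `negative_values`.
#' @export
pcoa <- function(d, min_axis_var = 0.05) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  n <- nrow(m)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = n - 1, eig = TRUE))
  ev <- fit$eig
  tol <- 1e-9 * max(abs(ev), 1e-300)
  pos <- which(ev > tol)
  if (!length(pos)) {
    return(structure(list(scores = matrix(0, n, 0, dimnames = list(rownames(m), NULL)),
                          values = ev, proportion = numeric(0),
                          retained = logical(0), negative_values = ev[ev < -tol]),
                     class = "stockload_pcoa"))
  }
  scores <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(scores) <- paste0("PCo", seq_along(pos))
  prop <- ev[pos] / sum(ev[pos])
  structure(list(scores = scores, values = ev, proportion = prop,
                 retained = prop >= min_axis_var,
                 negative_values = ev[ev < -tol]),
            class = "stockload_pcoa")
}

#' Area-normalized Hellinger transform of a stocking matrix
#'
#' Each sink row is divided by the lake's surface area in hectares (stocking
#' density), then Hellinger-transformed (square root of the row-relative
#' value), which keeps shared absences of stocking from drawing lakes
#' together. All-zero rows (never-stocked lakes) stay all-zero.
#'
#' @param s sink x source matrix of stocked mass in kg.
#' @param lakes lake table with `lake_code` and `area_ha` covering the rows
#'   of `s`.
#' @return Transformed matrix, same shape as `s`.
#' @export
hellinger_stocking <- function(s, lakes) {
  s <- as.matrix(s)
  if (any(s < 0)) stop("stocking masses must be non-negative")
  area <- lakes$area_ha[match(rownames(s), lakes$lake_code)]
  if (anyNA(area)) stop("stocking rows missing from the lake table")
  if (any(area <= 0)) stop("lake areas must be positive")
  dens <- s / area
  rs <- rowSums(dens)
  out <- sqrt(sweep(dens, 1, ifelse(rs > 0, rs, 1), "/"))
  dimnames(out) <- dimnames(s)
  out
}

#' Broken-stick expected proportions
#'
#' @param p number of components.
#' @return `b_k = (1/p) * sum_{i=k..p} 1/i`, summing to 1.
#' @export
broken_stick <- function(p) {
  stopifnot(p >= 1)
  rev(cumsum(1 / rev(seq_len(p)))) / p
}

#' PCA with broken-stick axis retention
#'
#' Covariance-based PCA (centered, not scaled); the retained axes are the
#' longest prefix whose observed variance proportion exceeds the broken-stick
#' expectation.
#'
#' @param x numeric matrix (observations x variables).
#' @return A list of class `stockload_pca`: `scores`, `loadings`,
#'   `proportion`, `broken_stick`, `retained` (prefix mask).
#' @export
pca_broken_stick <- function(x) {
  x <- as.matrix(x)
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- fit$sdev^2
  if (sum(v) <= 0) {
    warning("constant matrix: no axes retained")
    return(structure(list(scores = fit$x, loadings = fit$rotation,
                          proportion = rep(0, length(v)),
                          broken_stick = broken_stick(length(v)),
                          retained = rep(FALSE, length(v))),
                     class = "stockload_pca"))
  }
  prop <- v / sum(v)
  bs <- broken_stick(length(v))
  above <- prop > bs
  retained <- above & cumsum(!above) == 0  # longest prefix
  structure(list(scores = fit$x, loadings = fit$rotation, proportion = prop,
                 broken_stick = bs, retained = retained),
            class = "stockload_pca")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing predictor `j` on all others.
#' Perfectly collinear columns get `Inf`.
#'
#' @param x numeric predictor matrix with >= 2 columns and more rows than
#'   columns.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need >= 2 predictor columns")
  if (nrow(x) <= ncol(x)) stop("need more observations than predictors")
  vapply(seq_len(ncol(x)), function(j) {
    r2 <- suppressWarnings(
      summary(stats::lm(x[, j] ~ x[, -j, drop = FALSE]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(x))
}

check_rank <- function(x, label) {
  qx <- qr(scale(x, scale = FALSE))
  if (qx$rank < ncol(x)) {
    warning(sprintf("%s is rank deficient (rank %d < %d columns); ",
                    label, qx$rank, ncol(x)),
            "collinear directions are dropped in the fit")
  }
  qx$rank
}

#' (Partial) redundancy analysis with permutation inference
#'
#' Fits `y ~ x` (conditioning on `z` when supplied) by multivariate least
#' squares through [vegan::rda()]. The reported `r_squared` is the fraction
#' of total variance captured by the constrained axes — for partial models,
#' the semipartial fraction attributable to `x` after removing `z`. Global
#' significance comes from a permutation ANOVA: simple models permute
#' response rows, partial models permute reduced-model residuals, and
#' `p = (exceedances + 1) / (n_perm + 1)`.
#'
#' @param y response matrix (sites x variables).
#' @param x predictor matrix.
#' @param z optional conditioning matrix (partial RDA).
#' @param n_perm number of permutations (default 999; 0 skips the test).
#' @param seed integer seed for the permutations.
#' @return A list of class `stockload_rda`: `r_squared`, `adj_r_squared`,
#'   `pseudo_f`, `p_value`, `site_scores`, `rank`, `conditioned_fraction`,
#'   `max_vif`, and the underlying vegan `model`.
#' @export
rda_fit <- function(y, x, z = NULL, n_perm = 999, seed = 1) {
  y <- as.matrix(y); x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(nrow(y) == nrow(x))
  check_rank(x, "predictor matrix")
  if (!is.null(z)) {
    z <- as.matrix(z)
    stopifnot(nrow(z) == nrow(y))
    resid_rank <- qr(cbind(1, z, x))$rank - qr(cbind(1, z))$rank
    if (resid_rank == 0) {
      warning("conditioning matrix spans the predictors: ",
              "zero partial variance")
      return(structure(list(r_squared = 0, adj_r_squared = 0,
                            pseudo_f = NA_real_, p_value = NA_real_,
                            site_scores = NULL, rank = 0,
                            conditioned_fraction = NA_real_,
                            max_vif = NA_real_, model = NULL),
                       class = "stockload_rda"))
    }
    mod <- vegan::rda(y, x, z)
  } else {
    mod <- vegan::rda(y, x)
  }
  r2 <- vegan::RsquareAdj(mod)
  pf <- p <- NA_real_
  overfit <- is.null(mod$CA) || mod$CA$tot.chi < 1e-12 * mod$tot.chi
  if (n_perm > 0 && overfit) {
    ## no residual component: the observed fit dominates every permutation
    pf <- Inf
    p <- 1 / (n_perm + 1)
  } else if (n_perm > 0) {
    set.seed(seed)
    av <- vegan::anova.cca(mod, permutations = n_perm)
    pf <- av$F[1]
    p <- av$`Pr(>F)`[1]
  }
  sc <- tryCatch(vegan::scores(mod, display = "sites",
                               choices = seq_len(max(1, mod$CCA$rank))),
                 error = function(e) NULL)
  cond_frac <- if (!is.null(z)) mod$pCCA$tot.chi / mod$tot.chi else 0
  mv <- if (ncol(x) >= 2 && nrow(x) > ncol(x)) max(vif(x)) else NA_real_
  structure(list(r_squared = r2$r.squared, adj_r_squared = r2$adj.r.squared,
                 pseudo_f = pf, p_value = p, site_scores = sc,
                 rank = mod$CCA$rank, conditioned_fraction = cond_frac,
                 max_vif = mv, model = mod),
            class = "stockload_rda")
}

#' @rdname rda_fit
#' @export
partial_rda <- function(y, x, z, n_perm = 999, seed = 1) {
  if (is.null(z) || NCOL(z) == 0) return(rda_fit(y, x, NULL, n_perm, seed))
  rda_fit(y, x, z, n_perm, seed)
}

#' Permutation ANOVA for an RDA design
#'
#' Convenience wrapper fitting `y ~ x | z` and returning the global
#' permutation test.
#'
#' @inheritParams rda_fit
#' @return A list with `pseudo_f` and `p_value`.
#' @export
permutation_anova <- function(y, x, z = NULL, n_perm = 999, seed = 1) {
  stopifnot(n_perm >= 99)
  fit <- rda_fit(y, x, z, n_perm = n_perm, seed = seed)
  list(pseudo_f = fit$pseudo_f, p_value = fit$p_value)
}

#' Greedy forward selection of predictor blocks
#'
#' At each step every remaining candidate block is tested by permutation,
#' conditioning on everything already selected; the block with the smallest
#' p-value is added when its Sidak-adjusted value (`1 - (1 - p)^k` over the
#' `k` candidates examined, keeping the per-step false-selection rate at
#' `alpha` under the null) is at most `alpha`. Selection stops when the best
#' adjusted p-value exceeds `alpha`, candidates are exhausted, or no
#' candidate adds rank.
#'
#' @param y response matrix.
#' @param candidates named list of predictor matrices/vectors, or a matrix
#'   whose columns are individual candidates.
#' @param alpha stopping threshold on the permutation p-value (default 0.05).
#' @param n_perm permutations per test (default 999).
#' @param seed integer seed.
#' @return A list: `selected` (names, in selection order) and `log` (data
#'   frame of step, candidate, p, selected flag).
#' @export
forward_select <- function(y, candidates, alpha = 0.05, n_perm = 999, seed = 1) {
  if (is.matrix(candidates) || is.data.frame(candidates)) {
    candidates <- as.matrix(candidates)
    cn <- colnames(candidates)
    if (is.null(cn)) cn <- paste0("x", seq_len(ncol(candidates)))
    candidates <- stats::setNames(
      lapply(seq_len(ncol(candidates)), function(j) candidates[, j, drop = FALSE]),
      cn)
  }
  stopifnot(length(candidates) >= 1)
  y <- as.matrix(y)
  remaining <- names(candidates)
  selected <- character(0)
  log_rows <- list()
  step <- 0L
  repeat {
    if (!length(remaining)) break
    step <- step + 1L
    zmat <- if (length(selected))
      do.call(cbind, unname(candidates[selected])) else NULL
    ps <- vapply(remaining, function(nm) {
      xc <- as.matrix(candidates[[nm]])
      added_rank <- qr(cbind(1, zmat, xc))$rank - qr(cbind(1, zmat))$rank
      if (added_rank == 0) return(NA_real_)
      rda_fit(y, xc, zmat, n_perm = n_perm,
              seed = seed + step)$p_value
    }, numeric(1))
    if (all(is.na(ps))) break
    best <- which.min(ps)
    p_adj <- 1 - (1 - ps[best])^sum(!is.na(ps))
    log_rows[[step]] <- data.frame(step = step, candidate = remaining[best],
                                   p = ps[best], p_adjusted = p_adj,
                                   selected = p_adj <= alpha,
                                   stringsAsFactors = FALSE)
    if (p_adj > alpha) break
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
  }
  list(selected = selected,
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(step = integer(0), candidate = character(0),
                    p = numeric(0), p_adjusted = numeric(0),
                    selected = logical(0)))
}

#' Impute missing dosages by within-population mode
#'
#' Missing genotype calls are replaced by the modal dosage of the
#' individual's population at that SNP (ties broken toward the lower
#' dosage); when a population has no calls at a SNP, the global modal dosage
#' is used.
#'
#' @param g a [genotypes()] object.
#' @param pm population map data frame.
#' @return A complete [genotypes()] object.
#' @export
impute_by_population <- function(g, pm) {
  if (!anyNA(g$dosage)) return(g)
  pop <- popmap_factor(g, pm)
  counts <- lapply(0:2, function(v) rowsum((g$dosage == v) + 0, pop, na.rm = TRUE))
  npop <- nrow(counts[[1]])
  nl <- ncol(g$dosage)
  mode_pop <- matrix(0L, npop, nl, dimnames = list(rownames(counts[[1]]), NULL))
  stacked <- cbind(as.vector(counts[[1]]), as.vector(counts[[2]]),
                   as.vector(counts[[3]]))
  mode_pop[] <- max.col(stacked, ties.method = "first") - 1L
  no_calls <- counts[[1]] + counts[[2]] + counts[[3]] == 0
  gcounts <- matrix(vapply(0:2, function(v) colSums(g$dosage == v, na.rm = TRUE),
                           numeric(nl)), nrow = nl)
  gmode <- max.col(gcounts, ties.method = "first") - 1L
  mode_pop[no_calls] <- matrix(gmode, npop, nl, byrow = TRUE)[no_calls]
  d <- g$dosage
  miss <- which(is.na(d), arr.ind = TRUE)
  d[miss] <- mode_pop[cbind(as.integer(pop)[miss[, 1]], miss[, 2])]
  genotypes(d, g$individual_ids, g$snp_ids, g$chrom, g$pos, g$ref, g$alt,
            g$locus_ids)
}

#' DAPC-style cluster membership matrix
#'
#' PCA of the centered dosage matrix, then cluster-number choice by BIC
#' under a spherical equal-variance Gaussian mixture over the retained
#' components (the probabilistic counterpart of k-means, fitted with
#' [mclust::Mclust()]; a raw k-means `n log(WSS/n) + K log(n)` score
#' decreases monotonically in K on multivariate data and cannot select
#' K on its own), then linear discriminant analysis on the retained
#' components to obtain posterior membership probabilities (the Q matrix).
#'
#' @param g a complete (imputed) [genotypes()] object.
#' @param k_max maximum number of clusters considered (default 30, capped at
#'   n - 1).
#' @param n_pc number of principal components to keep, or `"auto"`
#'   (Kaiser-Guttman: components with above-average eigenvalue, capped at
#'   n/3 — a 90%-of-variance rule drowns the cluster structure of
#'   genotype matrices in hundreds of noise dimensions and makes the BIC
#'   collapse to K = 1).
#' @param seed integer seed for the mixture fit initialisation.
#' @return A list of class `stockload_dapc`: `Q` (individuals x K, rows sum
#'   to 1), `K`, `bic` (per candidate K; lower is better, `NA` where the
#'   mixture fit failed), `clusters`, `n_pc`.
#' @importFrom mclust Mclust mclustBIC
#' @export
dapc <- function(g, k_max = 30, n_pc = "auto", seed = 1) {
  if (k_max < 1) stop("k_max must be >= 1")
  if (anyNA(g$dosage)) stop("dosage matrix has missing values; impute first")
  n <- nrow(g$dosage)
  pc <- stats::prcomp(g$dosage, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (identical(n_pc, "auto")) {
    n_pc <- min(max(1L, sum(v > mean(v))), max(1L, floor(n / 3)))
  }
  n_pc <- max(1L, min(n_pc, sum(v > 1e-12)))
  sc <- pc$x[, seq_len(n_pc), drop = FALSE]
  k_max <- min(k_max, n - 1L)
  set.seed(seed)
  fit <- mclust::Mclust(sc, G = seq_len(k_max),
                        modelNames = if (n_pc == 1L) "E" else "EII",
                        verbose = FALSE)
  if (is.null(fit)) stop("mixture model fit failed for every candidate K")
  ## mclust reports BIC on a larger-is-better scale; flip to the usual
  ## smaller-is-better convention
  bic <- -as.numeric(fit$BIC[, 1])
  K <- fit$G
  clusters <- as.integer(fit$classification)
  if (K == 1) {
    Q <- matrix(1, n, 1, dimnames = list(g$individual_ids, "cluster1"))
  } else {
    Q <- tryCatch({
      ld <- MASS::lda(sc, grouping = factor(clusters))
      post <- stats::predict(ld, sc)$posterior
      colnames(post) <- paste0("cluster", colnames(post))
      rownames(post) <- g$individual_ids
      post
    }, error = function(e) {
      ## degenerate clusters (singletons / zero within-group variance):
      ## fall back to hard assignment
      q <- matrix(0, n, K, dimnames = list(g$individual_ids,
                                           paste0("cluster", seq_len(K))))
      q[cbind(seq_len(n), clusters)] <- 1
      q
    })
  }
  structure(list(Q = Q, K = K, bic = bic, clusters = clusters, n_pc = n_pc),
            class = "stockload_dapc")
}
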