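#' Welch two-sample t test
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value; the sign of `t` follows `mean(x) - mean(y)`.
#'
#' @param x,y numeric vectors (each with >= 2 values).
#' @param var_equal use the classical pooled-variance t instead (default
#'   FALSE).
#' @return A list with `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
welch_t_test <- function(x, y, var_equal = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = length(x) + length(y) - 2,
                                        p = 1, mean_x = mean(x), mean_y = mean(y)))
    stop("zero variance in both groups")
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' One-way ANOVA
#'
#' Classical fixed-effects F test of a numeric response across groups.
#' Groups with a single member are retained (they contribute no within-group
#' degrees of freedom).
#'
#' @param value numeric response vector.
#' @param group group labels (coerced to factor).
#' @return A list with `F`, `df1`, `df2`, `p`, `group_means`.
#' @export
one_way_anova <- function(value, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  if (any(table(group) == 0)) stop("empty group")
  fit <- stats::lm(value ~ group)
  av <- stats::anova(fit)
  if (av$Df[2] < 1) stop("no residual degrees of freedom")
  list(F = av$F[1], df1 = av$Df[1], df2 = av$Df[2], p = av$`Pr(>F)`[1],
       group_means = tapply(value, group, mean))
}

#' One-way MANOVA on a population factor
#'
#' Pillai-trace test of a population effect on one or more response columns,
#' in long layout: every row is one observation (here, one locus measured in
#' one population) and `population` is the grouping factor. With a single
#' response column the test reduces to [one_way_anova()] (Pillai equals the
#' model R-squared).
#'
#' @param responses numeric matrix (observations x responses) or vector.
#' @param population factor of population labels, one per observation.
#' @return A list with `pillai`, `F`, `df_effect`, `df_error`, `p`.
#' @export
population_effect_manova <- function(responses, population) {
  responses <- as.matrix(responses)
  population <- factor(population)
  if (nrow(responses) < nlevels(population) + 1) {
    stop("fewer observations than populations")
  }
  if (ncol(responses) == 1L) {
    a <- one_way_anova(responses[, 1], population)
    ss_tot <- sum((responses[, 1] - mean(responses[, 1]))^2)
    fit <- stats::lm(responses[, 1] ~ population)
    pillai <- 1 - sum(stats::resid(fit)^2) / ss_tot
    return(list(pillai = pillai, F = a$F, df_effect = a$df1,
                df_error = a$df2, p = a$p))
  }
  fit <- stats::manova(responses ~ population)
  s <- summary(fit, test = "Pillai")$stats
  list(pillai = s[1, "Pillai"], F = s[1, "approx F"],
       df_effect = unname(s[1, "Df"]), df_error = unname(s[2, "Df"]),
       p = s[1, "Pr(>F)"])
}
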