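#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness test and the Anscombe-Glynn kurtosis
#' test into the K-squared omnibus statistic, referred to a chi-squared
#' distribution with 2 degrees of freedom. Requires n >= 8 for the kurtosis
#' component's normal approximation.
#'
#' @param x numeric sample, n >= 8.
#' @return List with `statistic` (K-squared), `p_value`, `z_skew`,
#'   `z_kurt`, `n`.
#' @references D'Agostino, Belanger & D'Agostino Jr (1990), Am Stat 44:316.
#' @export
dagostinoTest <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  if (m2 == 0) stop("sample is constant; normality test undefined")
  b1 <- m3 / m2^1.5   # sample skewness g1
  b2 <- m4 / m2^2     # sample kurtosis b2 (normal ~ 3)

  # skewness: D'Agostino (1970) transformation to normality
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * asinh(y / alpha)

  # kurtosis: Anscombe & Glynn (1983) transformation
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  denom <- 1 + xk * sqrt(2 / (a - 4))
  term2 <- sign(denom) * abs((1 - 2 / a) / denom)^(1 / 3)
  z2 <- ((1 - 2 / (9 * a)) - term2) / sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Select a group-comparison test plan
#'
#' Mirrors the test-selection logic used for the behavioral comparisons:
#' each group is checked for normality with the D'Agostino-Pearson test at
#' alpha = 0.05. If every group is consistent with normality, two groups are
#' compared by Welch's t-test and more than two by one-way ANOVA with
#' Dunnett's multiple-comparison test against a reference group. If any
#' group departs from normality (a conservative pooling of the per-group
#' outcomes), two groups fall to the Mann-Whitney test and more than two to
#' Kruskal-Wallis with Dunn's test against the reference. Groups too small
#' for the normality test (n < 8) force the nonparametric branch with a
#' warning.
#'
#' @param values numeric response values.
#' @param group group labels, same length as `values`.
#' @param reference reference group for multi-group comparisons; defaults
#'   to the first group level.
#' @param alpha normality-test level.
#' @return List of class `"testPlan"`: `test` (one of `"welch_t"`,
#'   `"anova_dunnett"`, `"mann_whitney"`, `"kruskal_dunn"`), `normal`
#'   (per-group logical), `normality_p` (per-group p-values, NA when
#'   untestable), `reference`, `groups`.
#' @export
selectTest <- function(values, group, reference = NULL, alpha = 0.05) {
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]
  group <- as.character(group)[keep]
  groups <- unique(group)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (is.null(reference)) reference <- groups[1L]
  if (!reference %in% groups) {
    stop("reference group '", reference, "' not present")
  }
  norm_p <- vapply(groups, function(g) {
    v <- values[group == g]
    if (length(v) < 8L) return(NA_real_)
    # constant samples are degenerate; treat as untestable
    if (length(unique(v)) < 3L) return(NA_real_)
    dagostinoTest(v)$p_value
  }, numeric(1L))
  small <- is.na(norm_p)
  if (any(small)) {
    warning("group(s) too small or degenerate for the normality test (",
            paste(groups[small], collapse = ", "),
            "); falling back to nonparametric tests")
  }
  all_normal <- !any(small) && all(norm_p >= alpha)
  test <- if (length(groups) == 2L) {
    if (all_normal) "welch_t" else "mann_whitney"
  } else {
    if (all_normal) "anova_dunnett" else "kruskal_dunn"
  }
  structure(
    list(test = test, normal = !small & norm_p >= alpha,
         normality_p = norm_p, reference = reference, groups = groups,
         alpha = alpha),
    class = "testPlan"
  )
}

# Dunn's rank-sum z-tests of each group versus the reference, with tie
# correction; p-values Bonferroni-adjusted over the number of comparisons
# (the family Dunn's procedure controls).
.dunnVsReference <- function(values, group, reference) {
  r <- rank(values)
  n <- length(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  groups <- setdiff(unique(group), reference)
  rbar <- tapply(r, group, mean)
  ng <- tapply(r, group, length)
  m <- length(groups)
  do.call(rbind, lapply(groups, function(g) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / ng[[g]] + 1 / ng[[reference]]))
    z <- (rbar[[g]] - rbar[[reference]]) / se
    p <- min(1, 2 * pnorm(-abs(z)) * m)
    data.frame(group = g, statistic = z, p_value = p,
               stringsAsFactors = FALSE)
  }))
}

#' Run group comparisons under a test plan
#'
#' Executes the plan from [selectTest()]. Multi-group procedures compare
#' each group against the reference only (the "versus wild-type"
#' convention); Dunnett adjustment comes from a joint multivariate-t
#' reference distribution ([multcomp::glht()]), Dunn's from Bonferroni
#' over the reference comparisons.
#'
#' @inheritParams selectTest
#' @param plan a plan from [selectTest()]; computed from the data when
#'   omitted.
#' @param metric label carried into the result rows.
#' @return data.frame with one row per comparison: `metric`, `group`,
#'   `reference`, `test`, `statistic`, `p_value`, `adjustment`.
#' @examples
#' set.seed(1)
#' v <- c(rnorm(20), rnorm(20, 2))
#' g <- rep(c("wt", "mut"), each = 20)
#' compareGroups(v, g, reference = "wt")
#' @export
compareGroups <- function(values, group, reference = NULL, plan = NULL,
                          metric = "metric") {
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]
  group <- as.character(group)[keep]
  if (any(table(group) == 0L) || length(values) == 0L) {
    stop("empty group in comparison")
  }
  if (is.null(plan)) plan <- selectTest(values, group, reference = reference)
  reference <- plan$reference
  others <- setdiff(plan$groups, reference)
  row <- function(g, test, stat, p, adj = "none") {
    data.frame(metric = metric, group = g, reference = reference,
               test = test, statistic = as.numeric(stat),
               p_value = as.numeric(p), adjustment = adj,
               stringsAsFactors = FALSE)
  }
  out <- switch(plan$test,
    welch_t = {
      ht <- t.test(values[group == others], values[group == reference])
      row(others, "welch_t", ht$statistic, ht$p.value)
    },
    mann_whitney = {
      ht <- wilcox.test(values[group == others], values[group == reference],
                        exact = FALSE)
      row(others, "mann_whitney", ht$statistic, ht$p.value)
    },
    anova_dunnett = {
      dat <- data.frame(y = values,
                        g = factor(group, levels = c(reference, others)))
      fit <- aov(y ~ g, data = dat)
      gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
      sm <- summary(gl)
      do.call(rbind, lapply(seq_along(others), function(i) {
        row(others[i], "anova_dunnett", sm$test$tstat[i],
            sm$test$pvalues[i], adj = "dunnett")
      }))
    },
    kruskal_dunn = {
      dn <- .dunnVsReference(values, group, reference)
      do.call(rbind, lapply(seq_len(nrow(dn)), function(i) {
        row(dn$group[i], "kruskal_dunn", dn$statistic[i], dn$p_value[i],
            adj = "dunn_bonferroni")
      }))
    },
    stop("unknown test '", plan$test, "'")
  )
  rownames(out) <- NULL
  out
}
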