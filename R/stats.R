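# Statistical primitives shared by the pipeline. Standard tests delegate
# to base R (t.test, oneway.test, fisher.test, p.adjust, cor); each
# function fixes the exact variant the pipeline relies on (two-sided,
# unequal variances, average ranks, cross-product odds ratio).

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return rho, or \code{NA} when either vector is constant.
#' @export
spearmanRho <- function(x, y) {
  .assert(length(x) == length(y) && length(x) >= 2,
          "x and y must have equal length >= 2")
  suppressWarnings(cor(x, y, method = "spearman"))
}

#' Two-tailed Welch's t-test
#'
#' Unequal-variance two-sample t-test with Welch--Satterthwaite degrees
#' of freedom.
#'
#' @param a,b numeric samples.
#' @return list: statistic, df, p.value, method.
#' @examples
#' welchT(1:3, 4:6)  # t = -3.674, df = 4, p ~ 0.0213
#' @export
welchT <- function(a, b) {
  if (stats::var(a) + stats::var(b) == 0) {
    # degenerate: both samples constant
    eq <- mean(a) == mean(b)
    return(list(statistic = if (eq) 0 else -Inf * sign(mean(b) - mean(a)),
                df = length(a) + length(b) - 2,
                p.value = if (eq) 1 else 0,
                method = "Welch two-sample t"))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, method = "Welch two-sample t")
}

#' One-sample t-test
#'
#' @param x numeric sample.
#' @param mu0 hypothesized mean.
#' @return list: statistic, df, p.value, method.
#' @export
oneSampleT <- function(x, mu0 = 0) {
  if (stats::var(x) == 0) {
    eq <- mean(x) == mu0
    return(list(statistic = if (eq) 0 else Inf * sign(mean(x) - mu0),
                df = length(x) - 1, p.value = if (eq) 1 else 0,
                method = "one-sample t"))
  }
  ht <- t.test(x, mu = mu0)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, method = "one-sample t")
}

#' One-way ANOVA
#'
#' Classical equal-variance one-way analysis of variance across groups.
#'
#' @param groups list of numeric vectors.
#' @return list: statistic (F), df1, df2, p.value, method.
#' @export
oneWayAnova <- function(groups) {
  .assert(length(groups) >= 2, "need at least 2 groups")
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ht <- oneway.test(v ~ g, var.equal = TRUE)
  list(statistic = unname(ht$statistic), df1 = unname(ht$parameter[1]),
       df2 = unname(ht$parameter[2]), p.value = ht$p.value,
       method = "one-way ANOVA")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value from the conditional hypergeometric distribution
#' (summing all tables with point probability at most that observed). The
#' reported odds ratio is the sample cross-product ratio, with a Haldane
#' 0.5 correction to every cell when any cell is zero (not the conditional
#' MLE).
#'
#' @param tab 2x2 integer matrix or a length-4 vector (a, b, c, d by row).
#' @return list: oddsRatio, p.value, table.
#' @examples
#' fisherExact2x2(matrix(c(10, 5, 20, 40), 2, byrow = TRUE))$oddsRatio # 4
#' @export
fisherExact2x2 <- function(tab) {
  m <- matrix(as.numeric(tab), 2, 2, byrow = is.null(dim(tab)))
  .assert(all(m >= 0) && all(m == round(m)), "table entries must be counts")
  p <- fisher.test(m)$p.value
  mm <- if (any(m == 0)) m + 0.5 else m
  or <- (mm[1, 1] * mm[2, 2]) / (mm[1, 2] * mm[2, 1])
  list(oddsRatio = or, p.value = p, table = m)
}

#' Bonferroni adjustment
#'
#' @param p numeric p-values.
#' @param m family size (default \code{length(p)}).
#' @return adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, p * m)

#' Benjamini--Hochberg q-values
#'
#' @param p numeric p-values.
#' @return step-up adjusted q-values.
#' @export
bhFdr <- function(p) p.adjust(p, method = "BH")

#' Random-intercept ANOVA via the balanced two-stage estimator
#'
#' Tests a treatment effect shared across groups while treating the group
#' (e.g. cell line) as a random intercept. For balanced small designs this
#' is equivalent to aggregating to per-group treatment-effect means and
#' testing their mean against zero with a one-sample t-test
#' (df = groups - 1).
#'
#' @param values numeric responses (or, when \code{treatment} is NULL,
#'   pre-computed per-group effects).
#' @param treatment two-level factor, first level = control; NULL when
#'   \code{values} are already per-group effects.
#' @param grouping factor of group labels (NULL when values are effects).
#' @return list: statistic, df, p.value, effects, method.
#' @examples
#' randomInterceptAnova(c(10, 20, 30, 40))$statistic  # ~3.873
#' @export
randomInterceptAnova <- function(values, treatment = NULL, grouping = NULL) {
  if (is.null(treatment)) {
    effects <- values
  } else {
    .assert(!is.null(grouping), "grouping required with a treatment factor")
    treatment <- factor(treatment)
    .assert(nlevels(treatment) == 2, "treatment must have exactly 2 levels")
    effects <- vapply(split(seq_along(values), grouping), function(i) {
      tr <- treatment[i]
      mean(values[i][tr == levels(treatment)[2]]) -
        mean(values[i][tr == levels(treatment)[1]])
    }, numeric(1))
  }
  .assert(length(effects) >= 2, "need at least 2 groups")
  if (sd(effects) == 0) {
    pv <- if (mean(effects) == 0) 1 else 0
    return(list(statistic = if (mean(effects) == 0) 0 else Inf,
                df = length(effects) - 1, p.value = pv, effects = effects,
                method = "two-stage random-intercept ANOVA"))
  }
  tt <- oneSampleT(effects, 0)
  list(statistic = tt$statistic, df = tt$df, p.value = tt$p.value,
       effects = effects, method = "two-stage random-intercept ANOVA")
}
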