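#' Chi-square test with Cramer's V
#'
#' Pearson chi-square test of independence (no continuity correction, so
#' the statistic matches the textbook effect-size formula) with
#' `V = sqrt(chi2 / (n * (min(r, c) - 1)))`.
#'
#' @param table A contingency table (matrix of counts).
#' @return List with `chi2`, `df`, `p`, `cramers_v`, `n`.
#' @export
chisq_cramers_v <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("chisq_cramers_v: negative counts", call. = FALSE)
  n <- sum(table)
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (any(ct$expected == 0)) {
    stop("chisq_cramers_v: expected cell count of zero", call. = FALSE)
  }
  v <- sqrt(unname(ct$statistic) / (n * (min(dim(table)) - 1)))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, cramers_v = v, n = n)
}

#' One-way ANOVA with Cohen's f
#'
#' Classical one-way ANOVA F test across groups, with effect size
#' `f = sqrt(eta2 / (1 - eta2))`, `eta2` the between-group share of the
#' total sum of squares.
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor).
#' @return List with `f_stat`, `df1`, `df2`, `p`, `eta2`, `cohens_f`.
#' @export
anova_cohens_f <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("anova_cohens_f: need at least 2 groups",
                                 call. = FALSE)
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  ss <- tab[["Sum Sq"]]
  eta2 <- ss[1] / sum(ss)
  list(f_stat = tab[["F value"]][1], df1 = tab[["Df"]][1],
       df2 = tab[["Df"]][2], p = tab[["Pr(>F)"]][1], eta2 = eta2,
       cohens_f = sqrt(eta2 / (1 - eta2)))
}

#' Two-sample t test with Hedges' g
#'
#' Pooled-variance t test with the small-sample-corrected standardized
#' mean difference `g = J * (mean(x) - mean(y)) / s_pooled`,
#' `J = 1 - 3 / (4 (n1 + n2) - 9)`.
#'
#' @param x,y Numeric samples.
#' @return List with `t`, `df`, `p`, `hedges_g`.
#' @export
hedges_g <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("hedges_g: need at least 2 per group",
                               call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = TRUE)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  j <- 1 - 3 / (4 * (n1 + n2) - 9)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       hedges_g = j * (mean(x) - mean(y)) / sp)
}

#' Between-set difference test with effect size
#'
#' Dispatcher used for sample-description tables: a contingency table
#' gives a chi-square test with Cramer's V; a numeric response with
#' group labels gives a one-way ANOVA with Cohen's f (or, for exactly
#' two groups, also Hedges' g).
#'
#' @param x Either a contingency table (matrix) or a numeric response.
#' @param groups Group labels, required when `x` is numeric.
#' @return The corresponding test result list, with an added `method`
#'   element.
#' @export
group_difference_tests <- function(x, groups = NULL) {
  if (is.matrix(x) || is.table(x)) {
    out <- chisq_cramers_v(x)
    out$method <- "chisq"
    return(out)
  }
  if (is.null(groups)) stop("group_difference_tests: groups required",
                            call. = FALSE)
  out <- anova_cohens_f(x, groups)
  out$method <- "anova"
  if (nlevels(factor(groups)) == 2L) {
    sp <- split(x, groups)
    out$hedges_g <- hedges_g(sp[[1]], sp[[2]])$hedges_g
  }
  out
}
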