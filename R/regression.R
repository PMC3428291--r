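#' Design specification for the net-affect regression
#'
#' The demographic model of baseline net affect: three qualitative
#' predictors (education, completed primary school or more = 1; setting,
#' urban = 1; household income, top three quintiles = 1) with sex
#' (male = 1) and age as covariates.  The initial model adds all
#' pairwise interactions among the four categorical predictors; the
#' reduced model has none.  Age enters linearly and is never
#' interacted.
#'
#' @param response Response column name (default `"net"`, baseline net
#'   affect).
#' @param interactions Character vector of interaction terms in
#'   `"a:b"` notation, or `"all"` for every pairwise interaction among
#'   the categorical predictors.  Use `character(0)` for the reduced
#'   (main-effects) model.
#' @return Object of class `design_spec`.
#' @export
drm_design <- function(response = "net", interactions = "all") {
  main <- c("sex", "age", "education01", "setting01", "income01")
  categorical <- c("sex", "education01", "setting01", "income01")
  if (identical(interactions, "all")) {
    interactions <- utils::combn(categorical, 2,
                                 FUN = paste, collapse = ":")
  } else if (length(interactions)) {
    # canonicalize component order to match R's term labels
    interactions <- vapply(strsplit(interactions, ":", fixed = TRUE),
                           function(v) paste(intersect(main, v),
                                             collapse = ":"),
                           character(1))
  }
  structure(
    list(response = response, main = main, categorical = categorical,
         interactions = interactions),
    class = "design_spec"
  )
}

design_formula <- function(design) {
  stats::reformulate(c(design$main, design$interactions),
                     response = design$response)
}

#' Fit the net-affect regression model
#'
#' Ordinary least squares fit of a [drm_design()] on respondent-level
#' data, with two-sided coefficient t tests, the overall F test, and
#' adjusted R-squared.
#'
#' @param data Data frame holding the response and predictor columns
#'   (see [regression_data()]).
#' @param design A `design_spec`; default is the initial
#'   all-interactions model.
#' @return Object of class `model_fit`: the underlying `lm` in `$fit`,
#'   plus `coefficients` (term, estimate, se, t, p), `f_stat`, `df1`,
#'   `df2`, `f_p`, `r_squared`, `adj_r_squared`, `sigma2`, `rss`, `n`,
#'   and the `design`.
#' @export
fit_linear_model <- function(data, design = drm_design()) {
  fml <- design_formula(design)
  vars <- all.vars(fml)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("fit_linear_model: data lacks column(s) ",
                         paste(miss, collapse = ", "), call. = FALSE)
  data <- data[stats::complete.cases(data[vars]), , drop = FALSE]
  p <- length(attr(stats::terms(fml), "term.labels")) + 1L
  if (nrow(data) <= p) stop("fit_linear_model: fewer observations than parameters",
                            call. = FALSE)
  fit <- stats::lm(fml, data = data)
  if (anyNA(stats::coef(fit))) {
    stop("fit_linear_model: rank-deficient design; aliased term(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)
  ct <- as.data.frame(sm$coefficients)
  names(ct) <- c("estimate", "se", "t", "p")
  ct <- cbind(term = rownames(ct), ct)
  rownames(ct) <- NULL
  structure(
    list(fit = fit, coefficients = ct,
         f_stat = unname(sm$fstatistic[1]),
         df1 = unname(sm$fstatistic[2]), df2 = unname(sm$fstatistic[3]),
         f_p = stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                         lower.tail = FALSE),
         r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
         sigma2 = sm$sigma^2, rss = sum(stats::residuals(fit)^2),
         n = stats::nobs(fit), design = design),
    class = "model_fit"
  )
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("OLS fit of %s: F(%d, %d) = %.2f, p = %.3g, adjusted R2 = %.3f\n",
              x$design$response, x$df1, x$df2, x$f_stat, x$f_p,
              x$adj_r_squared))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Nested-model F test
#'
#' Compares a full model against a reduced model fitted to the same
#' data: `F = [(RSS_r - RSS_f) / df1] / [RSS_f / df2]`, computed through
#' the standard ANOVA model comparison.
#'
#' @param full,reduced `model_fit` objects; the reduced model's terms
#'   must be a subset of the full model's and both must be fitted to the
#'   same observations.
#' @return List with `f`, `df1`, `df2`, `p`.
#' @export
nested_f_test <- function(full, reduced) {
  tf <- attr(stats::terms(full$fit), "term.labels")
  tr <- attr(stats::terms(reduced$fit), "term.labels")
  if (!all(tr %in% tf) || full$n != reduced$n) {
    stop("nested_f_test: models are not nested on the same data",
         call. = FALSE)
  }
  if (setequal(tf, tr)) {
    return(list(f = 0, df1 = 0L, df2 = full$df2, p = 1))
  }
  an <- stats::anova(reduced$fit, full$fit)
  list(f = an$F[2], df1 = an$Df[2], df2 = stats::df.residual(full$fit),
       p = an$`Pr(>F)`[2])
}

#' Prune the initial model to the final design
#'
#' Keeps every main effect and covariate, drops - in a single pass - all
#' interaction terms not significant at `alpha` in the fitted initial
#' model, and returns the resulting design (refit it with
#' [fit_linear_model()]).
#'
#' @param fit A `model_fit` of the initial (interaction) model.
#' @param alpha Significance level for retaining interactions.
#' @return A `design_spec` with only the retained interactions.
#' @export
prune_to_final_model <- function(fit, alpha = 0.05) {
  ct <- fit$coefficients
  keep <- character(0)
  for (term in fit$design$interactions) {
    row <- match(term, ct$term)
    if (!is.na(row) && ct$p[row] < alpha) keep <- c(keep, term)
  }
  design <- fit$design
  design$interactions <- keep
  design
}

#' Respondent-level data for the net-affect regression
#'
#' Merges demographics with baseline (test-wave) affect summaries.
#'
#' @param study A `drm_study`.
#' @return Data frame with one row per respondent scored at baseline:
#'   demographics plus `pa`, `na`, `net`, `u_index`.
#' @export
regression_data <- function(study) {
  sc <- score_study(study)
  sc <- sc[sc$wave == "test", c("respondent_id", "pa", "na", "net", "u_index")]
  merge(study$respondents, sc, by = "respondent_id")
}
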