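measure_cols <- function() c(net = "net", pa = "pa", na = "na", u = "u")

# Table-1 analogue: demographics by set with between-set tests.
build_sample_table <- function(study, alpha = 0.05) {
  rs <- merge(study$respondents, respondent_sets(study), by = "respondent_id")
  tests <- list()
  cat_var <- function(name, values) {
    tab <- table(values, rs$set)
    res <- chisq_cramers_v(tab)
    data.frame(variable = name, test = "chisq", statistic = res$chi2,
               df = res$df, p = res$p,
               effect_size = if (res$p < alpha) res$cramers_v else NA_real_,
               effect_type = "cramers_v", stringsAsFactors = FALSE)
  }
  tests$sex <- cat_var("female", rs$sex == 0)
  tests$education <- cat_var("education_level", rs$education_raw)
  tests$marital <- cat_var("married", rs$marital)
  tests$setting <- cat_var("rural", rs$setting01 == 0)
  tests$income <- cat_var("income_quintile", rs$income_quintile)
  age <- anova_cohens_f(rs$age, rs$set)
  tests$age <- data.frame(variable = "age", test = "anova",
                          statistic = age$f_stat, df = age$df1, p = age$p,
                          effect_size = if (age$p < alpha) age$cohens_f else NA_real_,
                          effect_type = "cohens_f", stringsAsFactors = FALSE)
  list(
    counts = as.data.frame(table(set = rs$set), responseName = "n"),
    tests = do.call(rbind, c(tests, list(make.row.names = FALSE)))
  )
}

test_retest_row <- function(set, measure, x, y, alpha) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  tt <- paired_t_dunlap(x, y, alpha = alpha)
  icc <- icc_oneway(x, y, alpha = alpha)
  data.frame(set = set, measure = measure, n = length(x),
             mean_test = mean(x), sd_test = stats::sd(x),
             mean_retest = mean(y), sd_retest = stats::sd(y),
             t = tt$t, df = tt$df, p = tt$p, d = tt$d,
             significant = tt$significant,
             icc = icc$icc, icc_low = icc$ci_low, icc_high = icc$ci_high,
             band = icc$band, stringsAsFactors = FALSE)
}

# Table-2 analogue: per-set and pooled test-retest reliability, each
# short set paired with the period-matched part of the full retest.
build_reliability_table <- function(matched, alpha = 0.05) {
  rows <- list()
  for (s in c("A", "B", "C", "D")) {
    d <- matched[matched$set == s, , drop = FALSE]
    if (nrow(d) < 3) next
    for (m in names(measure_cols())) {
      if (m == "u" && s == "D") next
      x <- d[[paste0(m, "_test")]]
      y <- d[[paste0(m, "_retest")]]
      rows[[paste(s, m)]] <- test_retest_row(s, m, x, y, alpha)
    }
  }
  for (m in names(measure_cols())) {
    d <- if (m == "u") matched[matched$set != "D", ] else matched
    rows[[paste("pooled", m)]] <-
      test_retest_row("pooled", m, d[[paste0(m, "_test")]],
                      d[[paste0(m, "_retest")]], alpha)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

# Table-S1 analogue: pooled ICC within demographic subgroups.
build_subgroup_icc <- function(study, matched, alpha = 0.05) {
  rs <- study$respondents
  matched <- merge(matched, rs[c("respondent_id", "education01", "income01",
                                 "setting01")], by = "respondent_id")
  rows <- list()
  for (g in c("education01", "income01", "setting01")) {
    for (lv in 0:1) {
      d <- matched[matched[[g]] == lv, , drop = FALSE]
      for (m in names(measure_cols())) {
        dd <- if (m == "u") d[d$set != "D", ] else d
        x <- dd[[paste0(m, "_test")]]; y <- dd[[paste0(m, "_retest")]]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 3) next
        icc <- icc_oneway(x[ok], y[ok], alpha = alpha)
        rows[[paste(g, lv, m)]] <- data.frame(
          group = g, level = lv, measure = m, n = icc$n, icc = icc$icc,
          icc_low = icc$ci_low, icc_high = icc$ci_high, band = icc$band,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

auc_row <- function(label, measure, gold, test) {
  ok <- !is.na(gold) & !is.na(test)
  res <- obuchowski_auc(gold[ok], test[ok])
  data.frame(comparison = label, measure = measure, auc = res$auc,
             se = res$se, n = res$n, n_pairs_used = res$n_pairs_used,
             stringsAsFactors = FALSE)
}

# Criterion-validity AUC tables: short-version baseline scores against
# the full retest as gold standard, and - within the retest - each
# period slice against the full day.
build_auc_tables <- function(study, matched) {
  rows <- list()
  abc <- matched[matched$set %in% c("A", "B", "C"), ]
  for (m in names(measure_cols())) {
    rows[[paste("abc", m)]] <- auc_row("sets_ABC_vs_full", m,
                                       abc[[paste0(m, "_full")]],
                                       abc[[paste0(m, "_test")]])
  }
  dd <- matched[matched$set == "D", ]
  if (nrow(dd) >= 3) {
    for (m in c("net", "pa", "na")) {
      rows[[paste("d", m)]] <- auc_row("set_D_vs_full", m,
                                       dd[[paste0(m, "_full")]],
                                       dd[[paste0(m, "_test")]])
    }
  }
  pooled <- list()
  retest_ep <- study$episodes[study$episodes$wave == "retest", , drop = FALSE]
  scores <- score_study(study)
  full <- scores[scores$wave == "retest", ]
  slice_tab <- list()
  for (p in drm_periods()) {
    sl <- slice_full_wave(retest_ep, p)
    if (!nrow(sl)) next
    ag <- aggregate_episode_scores(sl, weighted = TRUE)
    names(ag)[names(ag) %in% c("pa", "na", "net", "u_index")] <-
      c("pa_slice", "na_slice", "net_slice", "u_slice")
    d <- merge(full, ag, by = "respondent_id")
    slice_tab[[p]] <- d
    for (m in names(measure_cols())) {
      gold <- d[[c(net = "net", pa = "pa", na = "na", u = "u_index")[[m]]]]
      test <- d[[paste0(m, "_slice")]]
      rows[[paste("slice", p, m)]] <- auc_row(paste0("retest_", p, "_vs_full"),
                                              m, gold, test)
    }
  }
  if (length(slice_tab)) {
    allp <- do.call(rbind, slice_tab)
    for (m in names(measure_cols())) {
      gold <- allp[[c(net = "net", pa = "pa", na = "na", u = "u_index")[[m]]]]
      test <- allp[[paste0(m, "_slice")]]
      rows[[paste("slice global", m)]] <- auc_row("retest_global_vs_full", m,
                                                  gold, test)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Table-S3 analogue: agreement battery for the supplementary questions.
build_agreement_table <- function(study, kappa_scheme = "linear") {
  sp <- study$supplementary
  if (is.null(sp) || !nrow(sp)) return(NULL)
  rows <- list()
  for (it in unique(sp$item)) {
    d <- sp[sp$item == it & !is.na(sp$test) & !is.na(sp$retest), ]
    if (nrow(d) < 2) next
    type <- d$type[1]
    if (type == "binary") {
      tab <- table(factor(d$test, 0:1), factor(d$retest, 0:1))
      delta <- delta_2x2(tab)
      kap <- tryCatch(cohen_kappa(tab)$kappa, error = function(e) NA_real_)
      rows[[it]] <- data.frame(
        item = it, type = type, n = nrow(d), delta = delta$delta,
        gof_chi2 = delta$gof_chi2, gof_p = delta$gof_p, kappa = kap,
        weighted_kappa = NA_real_, scheme = NA_character_,
        stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(d$test, 1:3), factor(d$retest, 1:3))
      wk <- weighted_kappa(tab, scheme = kappa_scheme)
      kap <- tryCatch(cohen_kappa(tab)$kappa, error = function(e) NA_real_)
      rows[[it]] <- data.frame(
        item = it, type = type, n = nrow(d), delta = NA_real_,
        gof_chi2 = NA_real_, gof_p = NA_real_, kappa = kap,
        weighted_kappa = wk$kappa, scheme = wk$weight_scheme,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

build_regression <- function(study, alpha = 0.05) {
  data <- regression_data(study)
  initial <- fit_linear_model(data, drm_design(interactions = "all"))
  reduced <- fit_linear_model(data, drm_design(interactions = character(0)))
  comparison <- nested_f_test(initial, reduced)
  final_design <- prune_to_final_model(initial, alpha = alpha)
  final <- fit_linear_model(data, final_design)
  list(initial = initial, reduced = reduced,
       interaction_f_test = comparison, final = final)
}

#' Run the full abbreviated-DRM validation analysis
#'
#' Orchestrates the complete battery on a study: sample description
#' with between-set tests; per-set and pooled test-retest reliability
#' (means, Dunlap-corrected paired t, one-way ICC with CIs), the full
#' retest sliced to each short set's time period; subgroup ICCs by
#' education, income, and setting; criterion-validity AUC tables
#' (pooled short sets vs. the full instrument, and within-retest period
#' slices vs. the full day); the per-activity affect profile with
#' ranking stability; the net-affect regression with interaction
#' pruning and nested-model F test; and the supplementary-question
#' agreement battery (Delta and kappa).  The pipeline only assembles
#' module-level results; every number it reports is recomputable by
#' calling the underlying functions directly.
#'
#' When the study lacks a retest wave the reliability, concordance,
#' activity-stability, and agreement sections are omitted and the
#' result is flagged `partial`.
#'
#' @param study A `drm_study`.
#' @param alpha Significance level used throughout (default 0.05).
#' @param min_pct Baseline reporting filter for the activity ranking,
#'   in percent (default 5).
#' @param kappa_scheme Weighting scheme for the 3-point items
#'   (`"linear"` or `"quadratic"`).
#' @param out_dir Optional directory: writes one CSV per table plus a
#'   `summary.json` with every statistic keyed.
#' @return Object of class `drm_validation`.
#' @export
run_validation <- function(study, alpha = 0.05, min_pct = 5,
                           kappa_scheme = "linear", out_dir = NULL) {
  has_retest <- any(study$episodes$wave == "retest")
  report <- list(alpha = alpha, partial = !has_retest)
  report$sample <- build_sample_table(study, alpha = alpha)
  report$scores <- score_study(study)
  report$regression <- build_regression(study, alpha = alpha)

  if (has_retest) {
    matched <- matched_scores(study)
    n_test <- length(unique(c(
      study$episodes$respondent_id[study$episodes$wave == "test"],
      study$segments$respondent_id[study$segments$wave == "test"])))
    n_excluded <- n_test - nrow(matched)
    if (n_excluded > 0) {
      message(sprintf("run_validation: %d baseline respondent(s) without a usable retest excluded from paired analyses",
                      n_excluded))
    }
    report$matched <- matched
    report$reliability <- build_reliability_table(matched, alpha = alpha)
    report$subgroup_icc <- build_subgroup_icc(study, matched, alpha = alpha)
    report$auc <- build_auc_tables(study, matched)
    report$activity <- activity_table(study, alpha = alpha)
    report$activity_stability <- tryCatch(
      rank_and_correlate(report$activity, min_pct = min_pct, alpha = alpha),
      error = function(e) {
        message("run_validation: activity ranking skipped: ",
                conditionMessage(e))
        NULL
      })
    report$agreement <- build_agreement_table(study,
                                              kappa_scheme = kappa_scheme)
  }

  report <- structure(report, class = "drm_validation")
  if (!is.null(out_dir)) write_validation(report, out_dir)
  report
}

validation_summary_list <- function(report) {
  reg_sum <- function(fit) {
    list(f = fit$f_stat, df1 = fit$df1, df2 = fit$df2, p = fit$f_p,
         adj_r_squared = fit$adj_r_squared,
         coefficients = fit$coefficients)
  }
  out <- list(
    alpha = report$alpha,
    partial = report$partial,
    set_counts = report$sample$counts,
    sample_tests = report$sample$tests,
    regression = list(
      initial = reg_sum(report$regression$initial),
      reduced = reg_sum(report$regression$reduced),
      interaction_f_test = report$regression$interaction_f_test,
      final = reg_sum(report$regression$final)
    )
  )
  if (!report$partial) {
    out$reliability <- report$reliability
    out$subgroup_icc <- report$subgroup_icc
    out$auc <- report$auc
    out$activity <- report$activity
    if (!is.null(report$activity_stability)) {
      st <- report$activity_stability
      out$activity_stability <- list(
        n_activities = st$n_activities,
        spearman = st$spearman$r,
        pearson = st$pearson_of_means$r,
        pearson_ci = c(st$pearson_of_means$ci_low,
                       st$pearson_of_means$ci_high),
        rankings = st$rankings
      )
    }
    out$agreement <- report$agreement
  }
  out
}

#' Write a validation report to disk
#'
#' One CSV per table plus `summary.json` keying every statistic.
#' Identical reports produce byte-identical output.
#'
#' @param report A `drm_validation`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_validation <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
  }
  wr(report$sample$tests, "sample_tests.csv")
  wr(report$scores, "scores.csv")
  wr(report$reliability, "reliability.csv")
  wr(report$subgroup_icc, "subgroup_icc.csv")
  wr(report$auc, "auc.csv")
  wr(report$activity, "activity.csv")
  wr(report$agreement, "agreement.csv")
  wr(report$regression$final$coefficients, "regression_final.csv")
  jsonlite::write_json(validation_summary_list(report),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(out_dir)
}

#' @export
print.drm_validation <- function(x, ...) {
  cat("Abbreviated-DRM validation report\n")
  cat(sprintf("  set allocation: %s\n",
              paste(sprintf("%s=%d", x$sample$counts$set,
                            x$sample$counts$n), collapse = ", ")))
  if (!is.null(x$reliability)) {
    pooled <- x$reliability[x$reliability$set == "pooled", ]
    cat("  pooled test-retest ICC:\n")
    for (i in seq_len(nrow(pooled))) {
      cat(sprintf("    %-4s %.2f (%.2f, %.2f) [%s]\n", pooled$measure[i],
                  pooled$icc[i], pooled$icc_low[i], pooled$icc_high[i],
                  pooled$band[i]))
    }
  }
  if (!is.null(x$auc)) {
    abc <- x$auc[x$auc$comparison == "sets_ABC_vs_full", ]
    cat("  AUC, pooled sets A+B+C vs full instrument:\n")
    for (i in seq_len(nrow(abc))) {
      cat(sprintf("    %-4s %.2f (s.e. = %.2f)\n", abc$measure[i],
                  abc$auc[i], abc$se[i]))
    }
  }
  fin <- x$regression$final
  cat(sprintf("  final regression: F(%d, %d) = %.2f, p = %.3g, adj R2 = %.3f\n",
              fin$df1, fin$df2, fin$f_stat, fin$f_p, fin$adj_r_squared))
  if (x$partial) cat("  (partial run: no retest wave)\n")
  invisible(x)
}
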