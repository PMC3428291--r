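# Pairwise concordance kernel matrix: K[i, j] = 1 if test orders the
# (i, j) pair the same way as gold, 0.5 on a test tie, 0 if discordant,
# NA on a gold tie (those pairs are excluded) and on the diagonal.
concordance_kernel <- function(gold, test) {
  gd <- sign(outer(gold, gold, "-"))
  td <- sign(outer(test, test, "-"))
  k <- (gd * td + 1) / 2          # 1 concordant, 0.5 test tie, 0 discordant
  k[gd == 0] <- NA                # gold ties excluded
  diag(k) <- NA
  k
}

#' Nonparametric ROC-type AUC against a continuous gold standard
#'
#' Accuracy of a test measure when the gold standard is itself
#' continuous: over all subject pairs with distinct gold values, the
#' pair scores 1 when the test orders the subjects concordantly with the
#' gold standard, 0.5 when the test values tie, and 0 when discordant;
#' the AUC is the mean pair score.  With a binary gold standard this
#' reduces to the familiar Mann-Whitney AUC.  Pairs tied on the gold
#' standard are excluded from the denominator and reported via
#' `n_pairs_used`.
#'
#' The standard error is a delete-one jackknife over subjects, which
#' matches the U-statistic asymptotics of the estimator; `se = 0` when
#' the estimator is constant over jackknife replicates (e.g. perfect
#' concordance).
#'
#' @param gold Numeric gold-standard values (e.g. full-day DRM scores).
#' @param test Numeric test values (e.g. short-version scores), aligned
#'   with `gold`.
#' @param se Compute the jackknife standard error (default `TRUE`;
#'   requires at least 3 subjects).
#' @return Object of class `auc_result`: `auc`, `se`, `n`,
#'   `n_pairs_used`.
#' @export
#' @examples
#' set.seed(1)
#' g <- rnorm(100)
#' obuchowski_auc(g, g + rnorm(100))
obuchowski_auc <- function(gold, test, se = TRUE) {
  ok <- !is.na(gold) & !is.na(test)
  gold <- gold[ok]; test <- test[ok]
  n <- length(gold)
  if (n < 2L) stop("obuchowski_auc: need at least 2 subjects", call. = FALSE)
  if (length(unique(gold)) < 2L) {
    stop("obuchowski_auc: gold standard degenerate (all values tied)",
         call. = FALSE)
  }
  k <- concordance_kernel(gold, test)
  valid <- !is.na(k)
  total <- sum(k[valid]) / 2      # each unordered pair counted once
  npairs <- sum(valid) / 2
  auc <- total / npairs
  se_hat <- NA_real_
  if (se) {
    if (n < 3L) stop("obuchowski_auc: need at least 3 subjects for a standard error",
                     call. = FALSE)
    row_sum <- rowSums(k, na.rm = TRUE)
    row_cnt <- rowSums(valid)
    keep <- (npairs - row_cnt) > 0
    loo <- (total - row_sum[keep]) / (npairs - row_cnt[keep])
    m <- length(loo)
    se_hat <- sqrt((m - 1) / m * sum((loo - mean(loo))^2))
  }
  structure(
    list(auc = auc, se = se_hat, n = n, n_pairs_used = npairs),
    class = "auc_result"
  )
}

#' Jackknife standard error of the concordance AUC
#'
#' Convenience wrapper returning only the delete-one jackknife standard
#' error of [obuchowski_auc()].
#'
#' @inheritParams obuchowski_auc
#' @return Numeric standard error.
#' @export
auc_standard_error <- function(gold, test) {
  obuchowski_auc(gold, test, se = TRUE)$se
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (s.e. = %.3f), n = %d, pairs used = %d\n",
              x$auc, x$se, x$n, x$n_pairs_used))
  invisible(x)
}
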