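as_agreement_table <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) != ncol(m)) stop("agreement table must be square", call. = FALSE)
  if (any(m < 0) || any(m != round(m))) {
    stop("agreement table must hold non-negative integer counts", call. = FALSE)
  }
  if (sum(m) < 1) stop("agreement table is empty", call. = FALSE)
  m
}

#' Cohen's kappa
#'
#' Chance-corrected agreement for a K x K cross-classification of test
#' vs retest answers: `kappa = (p_o - p_e) / (1 - p_e)` with expected
#' agreement `p_e` from the marginal products.
#'
#' @param table Square matrix of counts (rows = test answer, columns =
#'   retest answer).
#' @return Object of class `kappa_result`: `kappa`, `p_o`, `p_e`, `n`,
#'   `weighted = FALSE`.
#' @export
#' @examples
#' cohen_kappa(matrix(c(45, 15, 5, 35), 2))
cohen_kappa <- function(table) {
  m <- as_agreement_table(table)
  n <- sum(m)
  p_o <- sum(diag(m)) / n
  p_e <- sum(rowSums(m) * colSums(m)) / n^2
  if (p_e >= 1) stop("cohen_kappa: chance agreement is 1, kappa undefined",
                     call. = FALSE)
  structure(
    list(kappa = (p_o - p_e) / (1 - p_e), p_o = p_o, p_e = p_e, n = n,
         weighted = FALSE, weight_scheme = NA_character_),
    class = "kappa_result"
  )
}

#' Weighted kappa for ordinal categories
#'
#' Kappa with partial credit for near-misses, intended for the 3-point
#' ordinal items (e.g. "better / same / worse mood than others").
#' Disagreement weights are `|i - j| / (K - 1)` (linear, the default:
#' the 3-point categories look equidistant) or its square (quadratic);
#' `kappa_w = 1 - sum(w * observed) / sum(w * expected)`.
#'
#' @inheritParams cohen_kappa
#' @param scheme `"linear"` or `"quadratic"` disagreement weights.
#' @return Object of class `kappa_result` with `weighted = TRUE` and the
#'   `weight_scheme` recorded.
#' @export
weighted_kappa <- function(table, scheme = c("linear", "quadratic")) {
  scheme <- match.arg(scheme)
  m <- as_agreement_table(table)
  k <- nrow(m)
  if (k < 2L) stop("weighted_kappa: need at least 2 categories", call. = FALSE)
  n <- sum(m)
  w <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  if (scheme == "quadratic") w <- w^2
  expected <- outer(rowSums(m), colSums(m)) / n
  denom <- sum(w * expected)
  if (denom == 0) stop("weighted_kappa: chance disagreement is 0, kappa undefined",
                       call. = FALSE)
  structure(
    list(kappa = 1 - sum(w * m) / denom, p_o = sum(diag(m)) / n,
         p_e = sum(diag(expected)) / n, n = n, weighted = TRUE,
         weight_scheme = scheme),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  if (x$weighted) {
    cat(sprintf("weighted kappa (%s weights) = %.3f, n = %d\n",
                x$weight_scheme, x$kappa, x$n))
  } else {
    cat(sprintf("Cohen's kappa = %.3f, n = %d\n", x$kappa, x$n))
  }
  invisible(x)
}

# Multinomial log-likelihood of a 2x2 agreement table under the Delta
# model, parameterized by the genuine-agreement probabilities d1, d2;
# the guessing mass 1 - d1 - d2 spreads uniformly over the four cells.
delta_loglik <- function(d1, d2, m) {
  g <- (1 - d1 - d2) / 4
  p <- c(d1 + g, g, g, d2 + g)
  x <- c(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
  if (any(p < 0) || any(p == 0 & x > 0)) return(-Inf)
  sum(x[x > 0] * log(p[x > 0]))
}

#' Delta coefficient of chance-corrected agreement for 2x2 tables
#'
#' The Delta model assumes that each (test, retest) answer pair either
#' reflects genuine recognition of category i - both answers agree on i,
#' with probability `delta_i` - or consists of random guesses spread
#' evenly over the table.  The overall Delta is the total proportion of
#' answers concordant beyond chance, `delta_1 + delta_2`.  Unlike kappa
#' it does not collapse when the marginal totals are strongly
#' imbalanced.  Estimates below zero indicate worse-than-chance
#' agreement; there the guessing-model interpretation no longer applies.
#'
#' The maximum-likelihood fit has a closed form for 2x2 tables
#' (`delta_i = x_ii / n - (x_12 + x_21) / (2n)`); model adequacy is
#' assessed by a chi-square goodness-of-fit test of the observed cells
#' against the fitted ones (1 degree of freedom: the model forces the
#' two discordant cells to be equal).
#'
#' @param table 2x2 matrix of counts (rows = test, columns = retest).
#' @return Object of class `delta_result`: `delta`,
#'   `per_category_deltas`, `fitted`, `gof_chi2`, `gof_df`, `gof_p`,
#'   `n`, `loglik`.
#' @export
#' @examples
#' delta_2x2(matrix(c(40, 5, 10, 45), 2))
delta_2x2 <- function(table) {
  m <- as_agreement_table(table)
  if (nrow(m) != 2L) stop("delta_2x2: table must be 2x2", call. = FALSE)
  n <- sum(m)
  off <- m[1, 2] + m[2, 1]
  guess <- off / (2 * n)
  d <- c(m[1, 1] / n - guess, m[2, 2] / n - guess)
  fitted <- matrix(c(m[1, 1], off / 2, off / 2, m[2, 2]), 2, byrow = TRUE)
  if (off > 0) {
    gof_chi2 <- (m[1, 2] - m[2, 1])^2 / off
    gof_p <- stats::pchisq(gof_chi2, df = 1, lower.tail = FALSE)
  } else {
    gof_chi2 <- 0
    gof_p <- 1
  }
  structure(
    list(delta = sum(d), per_category_deltas = d, fitted = fitted,
         gof_chi2 = gof_chi2, gof_df = 1L, gof_p = gof_p, n = n,
         loglik = delta_loglik(d[1], d[2], m)),
    class = "delta_result"
  )
}

#' @export
print.delta_result <- function(x, ...) {
  cat(sprintf("Delta = %.3f (per category: %.3f, %.3f), GOF chi2(%d) = %.2f, p = %.3g, n = %d\n",
              x$delta, x$per_category_deltas[1], x$per_category_deltas[2],
              x$gof_df, x$gof_chi2, x$gof_p, x$n))
  invisible(x)
}
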