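#' Association test for an arm-by-category contingency table
#'
#' Implements the trial's test-selection rule: expected counts are computed
#' under independence; if the table is 2x2 and any expected count is below 5
#' the chi-squared approximation is considered violated and a two-sided
#' Fisher exact test is used; otherwise a Pearson chi-squared test, with
#' Yates continuity correction if (and only if) the table is 2x2.
#'
#' @param counts Integer matrix, rows = arms, columns = ordered categories;
#'   at least 2x2, no all-zero row or column.
#' @return A `contingency_result`: list with `test_used` (one of
#'   `"chi_squared"`, `"chi_squared_yates"`, `"fisher_exact"`), `statistic`
#'   (NA for Fisher), `df`, `p_value`, `expected_counts`, `min_expected`.
#' @examples
#' association_test(rbind(FMD = c(23, 10, 10), control = c(3, 13, 23)))
#' @export
association_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("table must be at least 2x2", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("degenerate table: empty row or column margin", call. = FALSE)
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  min_exp <- min(expected)
  is2x2 <- nrow(counts) == 2 && ncol(counts) == 2

  if (is2x2 && min_exp < 5) {
    p <- fisher_exact_2x2(counts)
    res <- list(test_used = "fisher_exact", statistic = NA_real_,
                df = NA_integer_, p_value = p)
  } else {
    ct <- suppressWarnings(stats::chisq.test(counts, correct = is2x2))
    res <- list(test_used = if (is2x2) "chi_squared_yates" else "chi_squared",
                statistic = unname(ct$statistic), df = unname(ct$parameter),
                p_value = ct$p.value)
  }
  res$expected_counts <- expected
  res$min_expected <- min_exp
  class(res) <- "contingency_result"
  res
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("<contingency_result> ", x$test_used, sep = "")
  if (!is.na(x$statistic)) cat(sprintf(", X2 = %.3f, df = %d", x$statistic, x$df))
  cat(sprintf(", p = %.4g (min expected %.2f)\n", x$p_value, x$min_expected))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value by full hypergeometric enumeration: with margins fixed, the
#' table is indexed by its top-left cell k; the two-sided p-value is the sum
#' of P(k) over all k whose point probability does not exceed that of the
#' observed table (with a 1e-7 relative slack against floating-point ties,
#' the convention used by most statistical software). Degenerate margins
#' (an empty row or column) give p = 1 by convention.
#'
#' @param counts 2x2 matrix of non-negative integers.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(rbind(c(7, 36), c(2, 37)))  # ~0.16
#' @export
fisher_exact_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 2, ncol(counts) == 2)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  r1 <- sum(counts[1, ]); c1 <- sum(counts[, 1]); n <- sum(counts)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  klo <- max(0, r1 + c1 - n); khi <- min(r1, c1)
  ks <- klo:khi
  # log point probability of each table with these margins
  logp <- lchoose(c1, ks) + lchoose(n - c1, r1 - ks) - lchoose(n, r1)
  obs <- counts[1, 1] - klo + 1
  min(1, sum(exp(logp)[exp(logp) <= exp(logp[obs]) * (1 + 1e-7)]))
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Standard step-up procedure over m p-values: sort ascending, adjusted
#' p_(i) = min over j >= i of (m/j) p_(j), capped at 1; reject those with
#' adjusted p <= q. Rejection sets are monotone (non-shrinking) in q.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param q Target false discovery rate (default 0.05).
#' @return List with `adjusted` (same order as input) and `rejected`
#'   (logical, same order).
#' @export
benjamini_hochberg <- function(p, q = 0.05) {
  if (length(p) == 0) return(list(adjusted = numeric(0), rejected = logical(0)))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  list(adjusted = adjusted, rejected = adjusted <= q)
}

#' Independent two-sample Student's t test
#'
#' Two-sided, pooled-variance ("Student") t test as used for baseline
#' responder/non-responder comparisons. Zero variance in both groups makes
#' the statistic undefined and is flagged.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `statistic`, `df`, `p_value`, `undefined` flag.
#' @export
two_sample_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(list(statistic = NA_real_, df = length(a) + length(b) - 2,
                p_value = if (mean(a) == mean(b)) 1 else NA_real_,
                undefined = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, undefined = FALSE)
}
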