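#' Bland-Altman limits of agreement
#'
#' Paired-method differences `d_i = a_i - b_i`; limits of agreement are
#' `mean(d) +/- 1.96 * sd(d)` with the sample SD (n - 1 denominator). The
#' 95% CI of the mean difference is `mean +/- 1.96 * sd / sqrt(n)` and of
#' each limit `limit +/- 1.96 * sd * sqrt(3 / n)`.
#'
#' @param a,b Paired measurements of the same quantity by two methods
#'   (e.g. SRF in percent), equal length `>= 2`, finite.
#' @param ids Optional identifiers.
#' @return A `bland_altman` object; see [bland_altman_limits()] for the
#'   fields.
#' @export
bland_altman <- function(a, b, ids = NULL) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("paired values must be finite")
  d <- a - b
  out <- bland_altman_limits(mean(d), stats::sd(d), length(d))
  out$differences <- d
  out$means <- (a + b) / 2
  out$ids <- ids
  out
}

#' Bland-Altman summary from a printed mean and SD
#'
#' Reconstructs the limits of agreement and their confidence intervals
#' from summary statistics alone, as needed when only a published
#' mean/SD table is available.
#'
#' @param mean_diff Mean of the paired differences.
#' @param sd_diff Sample SD of the differences.
#' @param n Number of pairs.
#' @return An object of class `bland_altman` with `mean_diff`, `sd_diff`,
#'   `loa_upper`, `loa_lower`, `ci_mean`, `ci_upper_limit`,
#'   `ci_lower_limit` (each a length-2 interval), and `n`.
#' @export
bland_altman_limits <- function(mean_diff, sd_diff, n) {
  if (n < 2) stop("need at least 2 pairs")
  if (sd_diff < 0) stop("sd_diff must be >= 0")
  upper <- mean_diff + 1.96 * sd_diff
  lower <- mean_diff - 1.96 * sd_diff
  se_mean <- sd_diff / sqrt(n)
  se_limit <- sd_diff * sqrt(3 / n)
  structure(
    list(mean_diff = mean_diff, sd_diff = sd_diff, n = as.integer(n),
         loa_upper = upper, loa_lower = lower,
         ci_mean = mean_diff + c(-1, 1) * 1.96 * se_mean,
         ci_upper_limit = upper + c(-1, 1) * 1.96 * se_limit,
         ci_lower_limit = lower + c(-1, 1) * 1.96 * se_limit),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d, mean diff %.2f (SD %.2f), limits [%.2f, %.2f]\n",
    x$n, x$mean_diff, x$sd_diff, x$loa_lower, x$loa_upper))
  invisible(x)
}

validate_contingency <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != ncol(table))
    stop("contingency table must be square")
  if (any(table < 0) || any(table != round(table)))
    stop("contingency table must hold non-negative integer counts")
  if (sum(table) <= 0) stop("empty contingency table")
  table
}

kappa_label <- function(k) {
  if (k < 0.01) "null"
  else if (k <= 0.20) "slight"
  else if (k <= 0.40) "fair"
  else if (k <= 0.60) "moderate"
  else if (k <= 0.80) "substantial"
  else "almost perfect"
}

#' Cohen's kappa for a square contingency table
#'
#' Observed agreement `Po = trace / N`, chance agreement
#' `Pe = sum(row_i * col_i) / N^2`, `kappa = (Po - Pe) / (1 - Pe)`. The
#' 95% CI uses the large-sample standard error
#' `sqrt(Po (1 - Po) / (N (1 - Pe)^2))`. An optional linear weighting is
#' available for ordinal categories; the default is the unweighted
#' (nominal) statistic.
#'
#' @param table Square matrix of counts, rows = reference (e.g. DRS)
#'   categories, columns = test (e.g. fMRU) categories.
#' @param weights `"unweighted"` or `"linear"`.
#' @return An object of class `kappa_result`: `observed_agreement`,
#'   `expected_agreement`, `kappa`, `se`, `ci95`, `interpretation`.
#' @export
cohens_kappa <- function(table, weights = c("unweighted", "linear")) {
  weights <- match.arg(weights)
  table <- validate_contingency(table)
  k <- nrow(table)
  n <- sum(table)
  if (sum(rowSums(table) > 0) < 2L && sum(colSums(table) > 0) < 2L)
    stop("need at least two non-empty categories")
  w <- if (weights == "unweighted") diag(k)
  else 1 - abs(outer(seq_len(k), seq_len(k), `-`)) / (k - 1)
  p <- table / n
  pe_mat <- outer(rowSums(p), colSums(p))
  po <- sum(w * p)
  pe <- sum(w * pe_mat)
  if (abs(1 - pe) < 1e-12)
    stop("degenerate table: chance agreement equals 1, kappa undefined")
  kap <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  structure(
    list(observed_agreement = po, expected_agreement = pe, kappa = kap,
         se = se, ci95 = kap + c(-1, 1) * 1.96 * se,
         interpretation = kappa_label(kap), weights = weights,
         n = as.integer(n)),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf(
    "<kappa_result> Po = %.3f, Pe = %.3f, kappa = %.3f (95%% CI %.3f-%.3f), %s\n",
    x$observed_agreement, x$expected_agreement, x$kappa, x$ci95[1],
    x$ci95[2], x$interpretation))
  invisible(x)
}

#' Diagnostic effectiveness and misclassification rate
#'
#' Effectiveness is the proportion of cases on the diagonal of the
#' reference-vs-test contingency table (correctly categorized);
#' misclassification is its complement.
#'
#' @param table Square matrix of counts.
#' @return Named numeric `c(effectiveness =, misclassification =)`,
#'   proportions summing to 1.
#' @export
diagnostic_effectiveness <- function(table) {
  table <- validate_contingency(table)
  eff <- sum(diag(table)) / sum(table)
  c(effectiveness = eff, misclassification = 1 - eff)
}

#' Spearman correlation and its square
#'
#' Rank-based correlation with average ranks for ties.
#'
#' @param x,y Numeric vectors, equal length `>= 3`, neither constant.
#' @return A list with `rho` and `r_squared = rho^2`.
#' @export
spearman_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  rho <- stats::cor(x, y, method = "spearman")
  list(rho = rho, r_squared = rho^2)
}

#' Read a labelled contingency table from CSV
#'
#' Expects a header row and a first column of category labels.
#'
#' @param path CSV file path.
#' @return Integer matrix with dimnames.
#' @export
read_contingency_table <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  validate_contingency(as.matrix(d))
}
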