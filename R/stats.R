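# Statistical layer: normality-gated two-sample comparison, correlation,
# chi-square, and ROC analysis with DeLong variance and paired AUC
# comparison.

#' Kolmogorov-Smirnov normality test with Lilliefors correction
#'
#' One-sample KS test against a normal distribution with estimated mean and
#' SD. Because the parameters are estimated from the sample, the plain KS
#' p-value is anti-conservative; the Lilliefors-corrected p-value
#' (via [nortest::lillie.test()]) is used instead.
#'
#' @param x numeric sample (n >= 5, non-constant).
#' @return The p-value.
#' @export
ks_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5L) stop("normality test needs at least 5 observations")
  if (stats::sd(x) == 0) stop("sample is constant; normality is undefined")
  nortest::lillie.test(x)$p.value
}

#' Normality-gated two-group comparison
#'
#' Compares two independent samples with the unpaired t-test (two-sided,
#' equal-variance by default) when both pass the KS normality screen at
#' `alpha_normality`, and with the two-sided Mann-Whitney U test otherwise
#' (exact for small untied samples, normal approximation with tie correction
#' otherwise, the convention of the usual desktop statistics packages).
#'
#' @param x,y numeric samples (each n >= 5 so the normality screen is
#'   defined).
#' @param alpha_normality significance level of the normality screen.
#' @param welch use the Welch (unequal-variance) t-test instead of the
#'   classic equal-variance form.
#' @return List of class `group_comparison`: `test` (`"t"` or `"MWU"`),
#'   `statistic` (t, or the Mann-Whitney U for x vs y), `p`, `mean`, `sd`
#'   (length-2, x then y), `normality_p` (length-2).
#' @export
compare_groups <- function(x, y, alpha_normality = 0.05, welch = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  np <- c(x = ks_normality(x), y = ks_normality(y))
  if (all(np > alpha_normality)) {
    ht <- stats::t.test(x, y, var.equal = !welch)
    test <- "t"; statistic <- unname(ht$statistic)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y))
    test <- "MWU"; statistic <- unname(ht$statistic)
  }
  structure(list(test = test, statistic = statistic, p = ht$p.value,
                 mean = c(mean(x), mean(y)),
                 sd = c(stats::sd(x), stats::sd(y)),
                 normality_p = np),
            class = "group_comparison")
}

#' Pearson correlation with two-sided t-based p-value
#'
#' @param x,y numeric vectors (n >= 3, non-constant).
#' @return List: `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("correlation needs at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input; correlation is undefined")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction by default (the correction is available via
#' `correct = TRUE`).
#'
#' @param table 2x2 matrix of nonnegative counts.
#' @param correct apply the Yates continuity correction.
#' @return List: `chisq`, `p`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal; chi-square is undefined")
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(chisq = unname(ht$statistic), p = ht$p.value)
}

# Mann-Whitney kernel values of each positive against all negatives (V10)
# and of each negative against all positives (V01); AUC = mean of either.
.delong <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp))
}

#' ROC curve summary with DeLong variance
#'
#' AUC via the Mann-Whitney identity (`AUC = U / (n1 * n2)` exactly, ties
#' counted half), standard error via DeLong's structural components, Wald
#' 95% confidence interval clipped to `[0, 1]`, and the z test of
#' `AUC = 0.5`. The `"patient"` group is the positive class. With
#' `direction = "auto"` the orientation (whether larger or smaller values
#' indicate disease) is chosen so the reported AUC is at least 0.5, and the
#' choice is recorded.
#'
#' @param values numeric marker values.
#' @param labels group labels; `positive` marks the positive class.
#' @param positive positive-class label (default `"patient"`).
#' @param direction `"auto"`, `">"` (larger = positive) or `"<"`.
#' @return List of class `roc_result`: `auc`, `se`, `ci` (length-2), `z`,
#'   `p`, `direction`, `n` (named: positive, negative), plus the oriented
#'   `values`/`labels` used (for paired comparison).
#' @export
roc_auc_delong <- function(values, labels, positive = "patient",
                           direction = c("auto", ">", "<")) {
  direction <- match.arg(direction)
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos))
    stop("both classes must be present for ROC analysis")
  orient <- function(v) .delong(v[is_pos], v[!is_pos])
  d <- orient(values)
  used <- ">"
  if (direction == "<" || (direction == "auto" && d$auc < 0.5)) {
    values <- -values
    d <- orient(values)
    used <- "<"
  }
  m <- sum(is_pos); n <- sum(!is_pos)
  se <- sqrt(stats::var(d$v10) / m + stats::var(d$v01) / n)
  ci <- pmin(pmax(d$auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  z <- if (se > 0) (d$auc - 0.5) / se else 0
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(auc = d$auc, se = se, ci = ci, z = z, p = p,
                 direction = used,
                 n = c(positive = m, negative = n),
                 values = values, labels = labels, positive = positive),
            class = "roc_result")
}

#' Paired DeLong comparison of two AUCs
#'
#' Compares the AUCs of two markers measured on the same subjects using the
#' paired DeLong covariance of the structural components; returns the AUC
#' difference, its standard error, and the two-sided z test. Both ROC
#' results must have been computed on identical subject sets (same labels in
#' the same order).
#'
#' @param roc_a,roc_b [roc_auc_delong()] results on the same subjects.
#' @return List: `delta_auc`, `se`, `ci`, `z`, `p`.
#' @export
delong_paired_compare <- function(roc_a, roc_b) {
  stopifnot(inherits(roc_a, "roc_result"), inherits(roc_b, "roc_result"))
  if (!identical(roc_a$labels, roc_b$labels))
    stop("paired AUC comparison requires identical subject sets")
  is_pos <- roc_a$labels == roc_a$positive
  da <- .delong(roc_a$values[is_pos], roc_a$values[!is_pos])
  db <- .delong(roc_b$values[is_pos], roc_b$values[!is_pos])
  m <- sum(is_pos); n <- sum(!is_pos)
  v <- (stats::var(da$v10) + stats::var(db$v10) -
          2 * stats::cov(da$v10, db$v10)) / m +
    (stats::var(da$v01) + stats::var(db$v01) -
       2 * stats::cov(da$v01, db$v01)) / n
  v <- max(v, 0)
  se <- sqrt(v)
  delta <- da$auc - db$auc
  z <- if (se > 0) delta / se else 0
  p <- if (se > 0) 2 * stats::pnorm(-abs(z)) else as.numeric(delta == 0)
  if (se == 0 && delta != 0) p <- 0
  ci <- delta + c(-1, 1) * stats::qnorm(0.975) * se
  list(delta_auc = delta, se = se, ci = ci, z = z, p = p)
}
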