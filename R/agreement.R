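#' Method-agreement statistics
#'
#' The statistical battery for comparing two infarct delineation methods:
#' 2x2 contingency tables over pooled binary segment scores, Cohen's kappa,
#' diagnostic metrics against a gold standard, Bland-Altman bias and limits
#' of agreement, two-way random-effects absolute-agreement single-measure
#' ICC (ICC(2,1)), and the exact Wilcoxon signed-rank test with an optional
#' Bonferroni-lowered significance limit.
#'
#' @name agreement
NULL

#' Cross-tabulate two binary segment scorings
#'
#' Pools all segments (across subjects) into one 2x2 table: `a` counts
#' test+/gold+, `b` test+/gold-, `c` test-/gold+, `d` test-/gold-.
#'
#' @param test,gold binary vectors, [segment_score()]s, or lists thereof.
#' @return A `contingency_2x2` with fields `a`, `b`, `c`, `d`, `n`.
#' @export
contingency <- function(test, gold) {
  flat <- function(x) {
    if (inherits(x, "segment_score")) return(as.integer(x))
    if (is.list(x)) return(unlist(lapply(x, flat)))
    as.integer(x)
  }
  t <- flat(test); g <- flat(gold)
  if (length(t) != length(g)) stop_dwcmr("score vectors differ in length")
  if (!length(t)) stop_dwcmr("no segments to tabulate")
  if (!all(t %in% 0:1) || !all(g %in% 0:1)) stop_dwcmr("scores must be binary")
  structure(list(a = sum(t == 1 & g == 1), b = sum(t == 1 & g == 0),
                 c = sum(t == 0 & g == 1), d = sum(t == 0 & g == 0),
                 n = length(t)),
            class = "contingency_2x2")
}

#' Build a contingency table from counts
#' @param a,b,c,d cell counts (test+/gold+, test+/gold-, test-/gold+,
#'   test-/gold-).
#' @return A `contingency_2x2`.
#' @export
contingency_from_counts <- function(a, b, c, d) {
  if (min(a, b, c, d) < 0 || a + b + c + d <= 0) {
    stop_dwcmr("counts must be non-negative with a positive total")
  }
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(test = c("+", "-"), gold = c("+", "-")))
  print(m)
  invisible(x)
}

#' Cohen's kappa of a 2x2 table
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_o = (a + d)/n` and `p_e` the marginal-product expectation. With
#' degenerate marginals (`p_e = 1`) kappa is 1 for perfect agreement and an
#' error otherwise. Kappa is symmetric in the two raters, so the table
#' orientation does not matter.
#'
#' @param t a `contingency_2x2`.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(t) {
  n <- t$n
  po <- (t$a + t$d) / n
  pe <- ((t$a + t$b) * (t$a + t$c) + (t$c + t$d) * (t$b + t$d)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    if (abs(po - 1) < .Machine$double.eps * 4) return(1)
    stop_dwcmr("degenerate marginals: kappa undefined")
  }
  (po - pe) / (1 - pe)
}

#' Diagnostic metrics against a gold standard
#'
#' Standard definitions with the gold standard on the columns:
#' sensitivity `a/(a+c)`, specificity `d/(b+d)`, PPV `a/(a+b)`,
#' NPV `d/(c+d)`. A metric whose marginal is zero is reported as `NA`
#' (undefined), never as 0.
#'
#' @param t a `contingency_2x2`.
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
diagnostic_metrics <- function(t) {
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(sensitivity = safe(t$a, t$a + t$c),
       specificity = safe(t$d, t$b + t$d),
       ppv = safe(t$a, t$a + t$b),
       npv = safe(t$d, t$c + t$d))
}

#' Percent agreement of a 2x2 table
#' @param t a `contingency_2x2`.
#' @return List with `count` (a + d) and `percent`.
#' @export
percent_agreement <- function(t) {
  list(count = t$a + t$d, percent = 100 * (t$a + t$d) / t$n)
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are taken as `x - y` (state which method is `x` when
#' reporting); the 95% limits of agreement are `bias +/- 1.96 SD` of the
#' differences, symmetric about the bias.
#'
#' @param x,y paired measurements (equal length >= 2).
#' @return List with `bias`, `sd`, `loa` (length-2), `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop_dwcmr("paired vectors differ in length")
  if (length(x) < 2) stop_dwcmr("at least two pairs are required")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s, loa = c(bias - 1.96 * s, bias + 1.96 * s),
       n = length(d))
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation from the paired-measurement matrix `[x y]`, computed from the
#' two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param x,y paired measurements (length >= 3).
#' @return ICC in `[-1, 1]`.
#' @export
icc <- function(x, y) {
  if (length(x) != length(y)) stop_dwcmr("paired vectors differ in length")
  n <- length(x)
  if (n < 3) stop_dwcmr("at least three pairs are required")
  m <- cbind(x, y)
  k <- 2
  grand <- mean(m)
  if (sum((m - grand)^2) < .Machine$double.eps * 4 * max(1, grand^2)) {
    stop_dwcmr("zero total variance: ICC undefined")
  }
  rowm <- rowMeans(m); colm <- colMeans(m)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  sse <- sum((m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (standard convention). With 25 or fewer
#' informative pairs and untied absolute differences the exact signed-rank
#' distribution gives the two-sided p-value; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y paired measurements.
#' @param alpha significance level the returned flag is judged against
#'   (0.05 by default; use the Bonferroni-lowered limit for families of
#'   location comparisons).
#' @return List with `statistic` (V, sum of positive ranks), `p`,
#'   `significant`, `n` (informative pairs), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop_dwcmr("paired vectors differ in length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop_dwcmr("all differences are zero: no test possible")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (n <= 25 && !ties) {
    if (v > n * (n + 1) / 4) {
      p <- 2 * stats::psignrank(v - 1, n, lower.tail = FALSE)
    } else {
      p <- 2 * stats::psignrank(v, n)
    }
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = v, p = p, significant = p < alpha, n = n, method = method)
}

#' Full agreement report for two methods
#'
#' Bundles the battery for one method pair: kappa and percent agreement of
#' the pooled binary segment scores, diagnostic metrics with the second
#' method as gold standard, ICC(2,1), Pearson R^2, Bland-Altman bias and
#' limits of agreement of the paired volumes, and the Wilcoxon signed-rank
#' p with its Bonferroni-adjusted significance flag.
#'
#' @param volumes_test,volumes_gold paired continuous measurements (e.g.
#'   infarct volume percentages).
#' @param scores_test,scores_gold pooled binary segment scores.
#' @param alpha base significance level.
#' @param m number of comparisons in the Bonferroni family (the flag uses
#'   `alpha / m`).
#' @return An `agreement_report` list.
#' @export
agreement_report <- function(volumes_test, volumes_gold,
                             scores_test, scores_gold,
                             alpha = 0.05, m = 1) {
  tab <- contingency(scores_test, scores_gold)
  wil <- tryCatch(
    wilcoxon_signed_rank(volumes_test, volumes_gold, alpha = alpha / m),
    error = function(e) list(statistic = NA_real_, p = NA_real_,
                             significant = FALSE, n = 0, method = "none"))
  or_na <- function(expr) tryCatch(expr, error = function(e) NA_real_,
                                   warning = function(w) NA_real_)
  structure(list(
    table = tab,
    kappa = cohens_kappa(tab),
    agreement = percent_agreement(tab),
    diagnostics = diagnostic_metrics(tab),
    icc = or_na(icc(volumes_test, volumes_gold)),
    r_squared = or_na(stats::cor(volumes_test, volumes_gold)^2),
    bland_altman = tryCatch(bland_altman(volumes_test, volumes_gold),
                            error = function(e) list(bias = NA_real_,
                                                     sd = NA_real_,
                                                     loa = c(NA_real_, NA_real_),
                                                     n = length(volumes_test))),
    wilcoxon = wil,
    alpha = alpha, bonferroni_m = m
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> kappa %.3f, agreement %d/%d (%.1f%%), ICC %.3f, R2 %.3f, bias %.3g\n",
    x$kappa, x$agreement$count, x$table$n, x$agreement$percent,
    x$icc, x$r_squared, x$bland_altman$bias))
  invisible(x)
}
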