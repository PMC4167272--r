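test_that("contingency pooling counts the four cells correctly", {
  t1 <- contingency(c(1, 1, 0, 0, 1), c(1, 1, 0, 0, 1))
  expect_equal(c(t1$a, t1$b, t1$c, t1$d), c(3, 0, 0, 2))
  t2 <- contingency(c(1, 1, 0), c(0, 0, 1))
  expect_equal(c(t2$a, t2$d), c(0, 0))
  expect_error(contingency(c(1, 0), c(1, 0, 0)), "length")
  expect_error(contingency(c(2, 0), c(1, 0)), "binary")
  scores <- list(segment_score(rep(c(1, 0), 8)), segment_score(rep(0, 16)))
  t3 <- contingency(scores, scores)
  expect_equal(t3$n, 32)
  expect_equal(t3$a, 8)
})

test_that("Cohen's kappa matches hand-computed and symmetric values", {
  expect_equal(round(cohens_kappa(contingency_from_counts(51, 1, 4, 120)), 2), 0.93)
  expect_equal(round(cohens_kappa(contingency_from_counts(52, 7, 8, 109)), 2), 0.81)
  expect_equal(cohens_kappa(contingency_from_counts(9, 0, 0, 21)), 1)
  # transposition symmetry on random tables
  set.seed(3)
  for (i in 1:20) {
    cnt <- rmultinom(1, 120, c(0.3, 0.1, 0.15, 0.45))
    t <- contingency_from_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    tt <- contingency_from_counts(cnt[1], cnt[3], cnt[2], cnt[4])
    expect_equal(cohens_kappa(t), cohens_kappa(tt))
  }
  # both raters constant and concordant: kappa defined as 1
  expect_equal(cohens_kappa(contingency_from_counts(7, 0, 0, 0)), 1)
})

test_that("diagnostic metrics follow the standard definitions", {
  d <- diagnostic_metrics(contingency_from_counts(51, 1, 4, 120))
  expect_equal(d$sensitivity, 51 / 55)
  expect_equal(d$specificity, 120 / 121)
  expect_equal(d$ppv, 51 / 52)
  expect_equal(d$npv, 120 / 124)
  perfect <- diagnostic_metrics(contingency_from_counts(10, 0, 0, 20))
  expect_true(all(unlist(perfect) == 1))
  deg <- diagnostic_metrics(contingency_from_counts(0, 0, 3, 7))
  expect_equal(deg$sensitivity, 0)
  expect_true(is.na(deg$ppv))
})

test_that("Bland-Altman bias and limits of agreement", {
  x <- c(1, 2, 3, 4)
  expect_equal(bland_altman(x, x), list(bias = 0, sd = 0, loa = c(0, 0), n = 4))
  ba <- bland_altman(x, x + 0.2)
  expect_equal(ba$bias, -0.2)
  ba2 <- bland_altman(c(0, 2), c(1, 1))   # differences -1, +1
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$loa, c(-1.96, 1.96) * sqrt(2))
  expect_equal(mean(ba2$loa), ba2$bias)   # symmetric about the bias
  expect_error(bland_altman(1, 1), "two pairs")
})

test_that("ICC(2,1) equals the two-way ANOVA brute force", {
  set.seed(12)
  for (i in 1:20) {
    m <- matrix(rnorm(20, 10, 3), ncol = 2)
    m[, 2] <- m[, 2] + rnorm(1, 0, 2)
    v <- data.frame(y = as.vector(m),
                    subj = factor(rep(1:10, 2)),
                    rater = factor(rep(1:2, each = 10)))
    ms <- anova(lm(y ~ subj + rater, data = v))
    msr <- ms["subj", "Mean Sq"]; msc <- ms["rater", "Mean Sq"]
    mse <- ms["Residuals", "Mean Sq"]
    ref <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 10)
    expect_equal(icc(m[, 1], m[, 2]), ref, tolerance = 1e-10)
  }
})

test_that("ICC penalizes offsets that Pearson correlation ignores", {
  x <- c(1, 2, 3, 5, 8, 9)
  y <- x + 10
  expect_lt(icc(x, y), cor(x, y))
  expect_equal(icc(x, x), 1)
  set.seed(5)
  a <- rnorm(200); b <- rnorm(200)
  expect_lt(abs(icc(a, b)), 0.2)
  expect_error(icc(c(2, 2, 2), c(2, 2, 2)), "zero total variance")
})

test_that("exact Wilcoxon p matches full sign enumeration and wilcox.test", {
  set.seed(21)
  for (n in c(5, 7, 9, 10)) {
    for (rep_i in 1:5) {
      x <- round(rnorm(n, 0, 3), 2)
      y <- round(rnorm(n, 0.8, 3), 2)
      d <- x - y
      if (any(d == 0) || any(duplicated(abs(d[d != 0])))) next
      w <- wilcoxon_signed_rank(x, y)
      expect_equal(w$p, enumerate_signed_rank_p(d))
      expect_equal(w$p, wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
    }
  }
})

test_that("Wilcoxon edge cases: symmetric alternation, ties, zero differences", {
  x <- 1:8
  y <- x + c(1, -1, 1, -1, 1, -1, 1, -1)
  expect_equal(wilcoxon_signed_rank(x, y)$p, 1)
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "zero")
  # ties fall back to the normal approximation and stay in [0, 1]
  w <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 7), c(2, 3, 4, 5, 6, 6))
  expect_equal(w$method, "normal approximation")
  expect_true(w$p >= 0 && w$p <= 1)
  # Bonferroni-lowered alpha changes only the flag
  a <- wilcoxon_signed_rank(1:10, (1:10) + 2, alpha = 0.05)
  b <- wilcoxon_signed_rank(1:10, (1:10) + 2, alpha = 0.0045)
  expect_equal(a$p, b$p)
})

test_that("the worked-example agreement counts reproduce the printed table", {
  tabs <- example_location_tables()
  agree <- vapply(tabs, function(t) percent_agreement(t)$count, numeric(1))
  expect_equal(unname(agree), c(171, 161, 172, 161))
  expect_true(all(vapply(tabs, `[[`, numeric(1), "n") == 176))
})

test_that("agreement_report bundles a coherent battery", {
  set.seed(2)
  vol_a <- runif(11, 5, 18)
  vol_b <- vol_a + rnorm(11, 0, 0.8)
  sc_a <- lapply(1:11, function(i) segment_score(rbinom(16, 1, 0.3)))
  sc_b <- sc_a
  rep <- agreement_report(vol_a, vol_b, sc_a, sc_b, m = 11)
  expect_equal(rep$kappa, 1)
  expect_true(rep$icc >= -1 && rep$icc <= 1)
  expect_equal(mean(rep$bland_altman$loa), rep$bland_altman$bias)
  expect_equal(rep$agreement$percent, 100)
})
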