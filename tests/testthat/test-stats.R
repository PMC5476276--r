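test_that("normality screen is calibrated on normal data and powerful on skew", {
  set.seed(101)
  rej <- mean(replicate(1000, ks_normality(rnorm(500)) < 0.05))
  tol <- 3 * sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(rej - 0.05), tol + 0.01)  # Lilliefors approximation slack
  power <- mean(replicate(300, ks_normality(rexp(200)) < 0.05))
  expect_gt(power, 0.95)
  expect_error(ks_normality(rep(3, 10)), "constant")
  expect_error(ks_normality(1:4), "at least 5")
})

test_that("identical samples compare as no effect", {
  x <- c(1, 2, 3, 4, 5, 6, 7)
  cg <- compare_groups(x, x)
  expect_equal(cg$p, 1)
  skewed <- exp(seq(0, 4, length.out = 30))
  cg2 <- compare_groups(skewed, skewed)
  expect_identical(cg2$test, "MWU")
  expect_gt(cg2$p, 0.99)
})

test_that("the normality gate picks the documented test", {
  set.seed(7)
  xn <- rnorm(40); yn <- rnorm(40)
  expect_identical(compare_groups(xn, yn)$test, "t")
  xs <- rexp(40); ys <- rexp(40)
  expect_identical(compare_groups(xs, ys)$test, "MWU")
})

test_that("the U statistic equals the brute-force pair count on random inputs", {
  set.seed(202)
  for (i in 1:1000) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    x <- sample(1:6, n1, replace = TRUE) + sample(c(0, 0.5), n1, replace = TRUE)
    y <- sample(1:6, n2, replace = TRUE) + sample(c(0, 0.5), n2, replace = TRUE)
    u <- suppressWarnings(stats::wilcox.test(x, y))$statistic
    expect_identical(unname(u), brute_force_u(x, y))
  }
})

test_that("two-group comparison holds its type-I error under a seeded null", {
  set.seed(303)
  rej <- mean(replicate(400, compare_groups(rnorm(30), rnorm(30))$p < 0.05))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("group order only flips the sign of the comparison", {
  set.seed(11)
  x <- rnorm(30, 1); y <- rnorm(30)
  a <- compare_groups(x, y); b <- compare_groups(y, x)
  expect_identical(a$test, b$test)
  expect_equal(a$p, b$p)
  expect_equal(a$statistic, -b$statistic)
})

test_that("Pearson wrapper: exact limits, error handling, sampling behaviour", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_error(pearson_r(x, rep(2, 5)), "constant")
  set.seed(404)
  est <- replicate(500, {
    z <- rnorm(38); e <- rnorm(38)
    y <- 0.4 * z + sqrt(1 - 0.4^2) * e
    pearson_r(z, y)$r
  })
  # mean estimate within 2 SE of the generating correlation
  expect_lt(abs(mean(est) - 0.4), 2 * sd(est) / sqrt(500) + 0.01)
})

test_that("chi-square on 2x2 tables: null table, study sex table, permutation oracle", {
  bal <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(bal$chisq, 0)
  expect_equal(bal$p, 1)
  # the study's sex distribution (21/17 vs 19/20) is not significant
  sex <- chi_square_2x2(matrix(c(21, 19, 17, 20), 2))
  expect_gt(sex$p, 0.05)
  # permutation oracle on the same counts
  labels <- rep(c(1, 0), c(38, 39))
  sexvec <- c(rep(1, 21), rep(0, 17), rep(1, 19), rep(0, 20))
  set.seed(505)
  stat_of <- function(v) {
    tab <- table(factor(labels, c(1, 0)), factor(v, c(1, 0)))
    chi_square_2x2(tab)$chisq
  }
  obs <- stat_of(sexvec)
  perm <- replicate(8000, stat_of(sample(sexvec)))
  # mid-p: the permutation law is discrete, so split the atom at the observed
  # statistic when comparing with a continuous chi-square tail
  p_perm <- mean(perm > obs + 1e-9) + 0.5 * mean(abs(perm - obs) < 1e-9)
  expect_lt(abs(p_perm - sex$p), 0.02)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("AUC equals U/(n1 n2) on every input and is 1 under perfect separation", {
  perfect <- roc_auc_delong(c(5, 6, 7, 1, 2, 3),
                            rep(c("patient", "control"), each = 3))
  expect_equal(perfect$auc, 1)
  set.seed(606)
  for (i in 1:200) {
    n1 <- sample(4:12, 1); n2 <- sample(4:12, 1)
    v <- c(sample(1:8, n1, TRUE), sample(1:8, n2, TRUE))
    lab <- rep(c("patient", "control"), c(n1, n2))
    rr <- roc_auc_delong(v, lab, direction = ">")
    expect_equal(rr$auc, brute_force_u(v[1:n1], v[-(1:n1)]) / (n1 * n2),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc_delong(1:5, rep("patient", 5)), "both classes")
})

test_that("DeLong CI covers the null AUC at its nominal rate", {
  set.seed(707)
  cover <- replicate(400, {
    v <- rnorm(77)
    lab <- rep(c("patient", "control"), c(38, 39))
    rr <- roc_auc_delong(v, lab, direction = ">")
    rr$ci[1] <= 0.5 && rr$ci[2] >= 0.5
  })
  expect_gt(mean(cover), 0.91)
  expect_lt(mean(cover), 0.99)
})

test_that("DeLong AUC, SE and paired test agree with an independent implementation", {
  set.seed(808)
  for (i in 1:10) {
    lab <- rep(c("patient", "control"), c(38, 39))
    base <- rnorm(77) + (lab == "patient")
    v1 <- base + rnorm(77, 0, 0.5)
    v2 <- base + rnorm(77, 0, 0.8)
    r1 <- roc_auc_delong(v1, lab, direction = ">")
    r2 <- roc_auc_delong(v2, lab, direction = ">")
    p1 <- pROC::roc(lab, v1, levels = c("control", "patient"),
                    direction = "<", quiet = TRUE)
    expect_equal(r1$auc, as.numeric(pROC::auc(p1)), tolerance = 1e-12)
    expect_equal(r1$se^2, as.numeric(pROC::var(p1, method = "delong")),
                 tolerance = 1e-10)
    p2 <- pROC::roc(lab, v2, levels = c("control", "patient"),
                    direction = "<", quiet = TRUE)
    ours <- delong_paired_compare(r1, r2)
    ref <- pROC::roc.test(p1, p2, method = "delong", paired = TRUE)
    expect_equal(abs(ours$z), abs(as.numeric(ref$statistic)), tolerance = 1e-9)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("paired AUC comparison: self-comparison null, covariance sanity", {
  set.seed(909)
  lab <- rep(c("patient", "control"), c(20, 20))
  v <- rnorm(40) + (lab == "patient")
  r <- roc_auc_delong(v, lab, direction = ">")
  self <- delong_paired_compare(r, r)
  expect_equal(self$delta_auc, 0)
  expect_equal(self$p, 1)
  # noisy copies of one predictor: paired variance below sum of marginals
  for (i in 1:25) {
    a <- v + rnorm(40, 0, 0.4); b <- v + rnorm(40, 0, 0.4)
    ra <- roc_auc_delong(a, lab, direction = ">")
    rb <- roc_auc_delong(b, lab, direction = ">")
    dd <- delong_paired_compare(ra, rb)
    expect_lte(dd$se^2, ra$se^2 + rb$se^2 + 1e-12)
  }
  r_mismatch <- roc_auc_delong(v[c(2:40, 1)], lab[c(2:40, 1)], direction = ">")
  expect_error(delong_paired_compare(r, r_mismatch), "identical subject")
})
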