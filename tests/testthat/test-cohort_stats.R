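# Contingency tests, ANOVA/LSD, rank tests, survival and propensity matching.

test_that("chi-square handles identical proportions and degenerate tables", {
  res <- chi_square_test(matrix(c(10, 10, 20, 20), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_warning(r2 <- chi_square_test(matrix(c(5, 2, 0, 0, 3, 4), 2)),
                 "all-zero")
  expect_equal(r2$df, 1)
  expect_error(chi_square_test(matrix(1:3, 1)), "degenerate")
})

test_that("fisher exact matches hypergeometric enumeration", {
  res <- fisher_exact(matrix(c(5, 0, 0, 5), 2))
  # all mass in the two extreme tables: 2 / choose(10, 5)
  expect_equal(res$p, 2 / choose(10, 5))
  expect_equal(fisher_exact(matrix(1, 2, 2))$p, 1)
  expect_error(fisher_exact(matrix(1:6, 2)), "2x2")
  # asymptotic agreement on a large balanced table
  big <- matrix(c(400, 380, 350, 390), 2)
  expect_lt(abs(fisher_exact(big)$p - chi_square_test(big)$p), 0.02)
})

test_that("ANOVA with equal means is null and LSD reduces to pooled t", {
  set.seed(1)
  v <- stats::rnorm(60)
  g <- rep(letters[1:3], 20)
  res <- anova_lsd(v, g)
  expect_gt(res$p, 0.05)
  # two groups: the LSD p equals the pooled-variance two-sample t p
  v2 <- stats::rnorm(40); g2 <- rep(c("x", "y"), each = 20)
  r2 <- anova_lsd(v2, g2)
  tt <- stats::t.test(v2[g2 == "x"], v2[g2 == "y"], var.equal = TRUE)
  expect_equal(r2$lsd$p, tt$p.value)
  expect_equal(r2$p, tt$p.value)
})

test_that("ANOVA detects 1-sd group offsets with high power", {
  set.seed(2)
  hits <- replicate(60, {
    v <- c(stats::rnorm(30, 0), stats::rnorm(30, 1), stats::rnorm(30, 2))
    anova_lsd(v, rep(1:3, each = 30))$p < 0.01
  })
  expect_gte(mean(hits), 0.95)
})

test_that("wilcoxon exact enumeration matches known values and handles ties", {
  r <- wilcoxon_rank_sum(1:3, 4:6)
  expect_equal(r$method, "exact")
  expect_equal(r$p, 0.1)  # two-sided; one tail is 1/20
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  # exact enumeration and the continuity-corrected normal approximation
  # agree on average at the size boundary
  set.seed(3)
  diffs <- replicate(50, {
    x <- stats::rnorm(6); y <- stats::rnorm(6) + 0.5
    exact <- wilcoxon_rank_sum(x, y)$p
    r12 <- rank(c(x, y)); w <- sum(r12[1:6])
    z <- (abs(w - 39) - 0.5) / sqrt(39)
    abs(exact - 2 * stats::pnorm(-max(z, 0)))
  })
  expect_lt(mean(diffs), 0.02)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "empty")
})

test_that("Kaplan-Meier matches the product-limit hand computation", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$curves$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$curves$n_risk, 4:1)
  # all censored: flat curve at 1, median undefined
  kc <- kaplan_meier(c(2, 3, 9), c(0, 0, 0))
  expect_true(all(kc$curves$surv == 1))
  expect_true(is.na(kc$medians[[1]]))
  expect_equal(attr(kc$medians, "undefined"), "all")
  # duplicating every subject leaves the curve unchanged
  t1 <- c(3, 5, 7, 9); e1 <- c(1, 0, 1, 1)
  a <- kaplan_meier(t1, e1)$curves
  b <- kaplan_meier(rep(t1, 2), rep(e1, 2))$curves
  expect_equal(a$surv, b$surv[match(a$time, b$time)])
})

test_that("log-rank matches the O-E/V hand computation and is scale-invariant", {
  times <- c(1, 2, 3, 4); events <- rep(1, 4); grp <- c("A", "A", "B", "B")
  res <- logrank_test(times, events, grp)
  # direct O-E computation over event times
  oe <- 0; v <- 0
  at_risk <- function(t) c(A = sum(times[grp == "A"] >= t),
                           B = sum(times[grp == "B"] >= t))
  for (t in times) {
    n <- at_risk(t); tot <- sum(n)
    d <- 1
    oe <- oe + (grp[times == t] == "A") - d * n[["A"]] / tot
    if (tot > 1)
      v <- v + d * (n[["A"]] / tot) * (1 - n[["A"]] / tot) * (tot - d) / (tot - 1)
  }
  expect_equal(res$statistic, unname(oe^2 / v))
  expect_equal(res$df, 1)
  # identical data in both groups: chi-square 0
  null <- logrank_test(rep(c(1, 2, 3), 2), rep(1, 6), rep(c("A", "B"), each = 3))
  expect_equal(null$statistic, 0, tolerance = 1e-12)
  expect_equal(null$p, 1)
  # invariance to time rescaling
  r1 <- logrank_test(times, events, grp)
  r2 <- logrank_test(times * 365.25, events, grp)
  expect_equal(r1$p, r2$p)
})

test_that("log-rank has power against a hazard ratio of 2", {
  set.seed(4)
  hits <- replicate(40, {
    t1 <- stats::rexp(200, 1); t2 <- stats::rexp(200, 2)
    cens <- stats::runif(400, 0, 3)
    tt <- pmin(c(t1, t2), cens); ev <- as.integer(c(t1, t2) <= cens)
    logrank_test(tt, ev, rep(c("A", "B"), each = 200))$p < 0.01
  })
  expect_gte(mean(hits), 0.9)
})

test_that("propensity matching balances a planted confounder", {
  set.seed(5)
  n <- 500
  x1 <- stats::rnorm(n)
  x2 <- factor(sample(c("lo", "hi", "Unknown"), n, replace = TRUE))
  lin <- -1.2 + 0.8 * x1 + (x2 == "hi") * 0.7
  tr <- stats::rbinom(n, 1, stats::plogis(lin)) == 1
  cov <- data.frame(x1 = x1, x2 = x2)
  pm <- propensity_match(cov, tr)
  expect_gt(max(abs(pm$smd$smd_before)), 0.5)
  expect_lt(max(abs(pm$smd$smd_after)), 0.1)
  expect_true(all(pm$pairs$treated != pm$pairs$control))
  expect_false(any(duplicated(pm$pairs$control)))
})

test_that("random treatment keeps most subjects and stays balanced", {
  set.seed(6)
  n <- 300
  cov <- data.frame(a = stats::rnorm(n), b = stats::rnorm(n))
  tr <- stats::runif(n) < 0.4
  pm <- propensity_match(cov, tr)
  expect_gte(pm$n_matched / pm$n_treated, 0.8)
  expect_lt(max(abs(pm$smd$smd_after)), 0.1)
})

test_that("identical covariates give constant propensity and zero SMD", {
  cov <- data.frame(a = rep(1, 40), b = rep(2, 40))
  tr <- rep(c(TRUE, FALSE), 20)
  pm <- propensity_match(cov, tr)
  expect_equal(pm$n_matched, 20)
  expect_true(all(pm$smd$smd_after == 0))
})
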