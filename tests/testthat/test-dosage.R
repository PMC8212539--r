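# Frozen expected values below were computed with exact rational
# arithmetic (sums of C(n,k)/2^n), independent of the log-space summation
# under test.

test_that("binomial lower tail matches closed forms and the exact oracle", {
  expect_equal(binomial_lower_p(0, 1), 0.5)
  expect_equal(binomial_lower_p(0, 2), 0.25)
  expect_equal(binomial_lower_p(10, 60), 8.08190728307859e-08,
               tolerance = 1e-12)
  expect_equal(binomial_lower_p(30, 60), 0.551289086504285, tolerance = 1e-12)
  expect_equal(binomial_lower_p(5, 50), 2.10492601127044e-09,
               tolerance = 1e-12)
  expect_equal(binomial_lower_p(100, 200), 0.528174239504628,
               tolerance = 1e-12)
  # worked example: below the Bonferroni threshold for 457 tests
  expect_lt(binomial_lower_p(10, 60), bonferroni_alpha(0.05, 457))
  expect_error(binomial_lower_p(5, 4), "x must satisfy")
  expect_error(binomial_lower_p(1, 0), "n must be")
})

test_that("binomial lower tail agrees with pbinom to 12 significant digits", {
  set.seed(31)
  n <- sample(1:200, 120, replace = TRUE)
  x <- vapply(n, function(ni) sample(0:ni, 1), integer(1))
  mine <- binomial_lower_p(x, n)
  base <- pbinom(x, n, 0.5)
  expect_lt(max(abs(mine - base) / pmax(base, 1e-300)), 1e-12)
  # non-default p0 too
  mine2 <- binomial_lower_p(x, n, p0 = 0.01)
  base2 <- pbinom(x, n, 0.01)
  expect_lt(max(abs(mine2 - base2) / pmax(base2, 1e-300)), 1e-12)
})

test_that("binomial lower tail is monotone in x and totals one at x = n", {
  for (n in c(1, 7, 60, 200, 1000)) {
    p <- binomial_lower_p(0:n, n)
    expect_true(all(diff(p) >= 0))
    # strictly increasing wherever double precision can resolve the step
    resolvable <- p[-1] > 1e-300 & p[-1] < 1 - 1e-12
    expect_true(all(diff(p)[resolvable] > 0))
    expect_equal(p[n + 1], 1)
  }
  # stays finite and accurate deep in the tail at large n
  expect_equal(binomial_lower_p(4000, 10000), pbinom(4000, 10000, 0.5),
               tolerance = 1e-10)
})

test_that("bonferroni threshold is alpha/m and rejects m = 0", {
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
  expect_equal(bonferroni_alpha(0.05, 457), 0.05 / 457)
  expect_error(bonferroni_alpha(0.05, 0), "m must be")
})

test_that("dosage classification: worked example and the n=60 boundary", {
  cfg <- test_config(m = 457)
  # 10 alt / 50 ref at 60x depth is mosaic under the corrected threshold
  out <- classify_dosage(10, 50, 2L, cfg)
  expect_equal(out$label, "mosaic")
  expect_equal(out$dosage, 10 / 60)
  # balanced 30/30 is heterozygous with a large lower-tail p
  bal <- classify_dosage(30, 30, 2L, cfg)
  expect_equal(bal$label, "heterozygous")
  expect_gt(bal$p_lower, 0.5)
  # exact-oracle boundary at n = 60, m = 457: x = 15 mosaic, x = 16 het
  b <- classify_dosage(c(15, 16), c(45, 44), c(2L, 2L), cfg)
  expect_equal(b$label, c("mosaic", "heterozygous"))
})

test_that("homozygous-alt consistency check flags excess reference reads", {
  cfg <- test_config(m = 1)
  out <- classify_dosage(c(58, 40), c(2, 20), c(3L, 3L), cfg)
  expect_equal(out$label, c("homozygous_alt", "inconsistent"))
  expect_warning(z <- classify_dosage(0, 0, 2L, cfg), "zero depth")
  expect_equal(z$label, "inconsistent")
})

test_that("infinite-depth limit: exact 0.5 dosage is never mosaic", {
  for (n in c(100, 1000, 10000)) {
    out <- classify_dosage(n / 2, n / 2, 2L, test_config(m = 1))
    expect_equal(out$label, "heterozygous")
  }
})

test_that("two-proportion z-test reproduces printed pairwise comparisons", {
  # 293 vs 197 of 31,190: the strongest heterozygous contrast
  r <- two_proportion_test(293, 31190, 197, 31190)
  expect_equal(r$p, 1.64e-5, tolerance = 0.05)
  # 16 vs 8 of 31,190: the smallest mosaic contrast
  r2 <- two_proportion_test(16, 31190, 8, 31190)
  expect_equal(r2$p, 0.15, tolerance = 0.05)
  # identical proportions give p = 1
  expect_equal(two_proportion_test(10, 100, 10, 100)$p, 1)
  # degenerate pooled proportions flagged with p = 1
  d <- two_proportion_test(0, 50, 0, 60)
  expect_true(d$degenerate)
  expect_equal(d$p, 1)
})

test_that("two-proportion z-test with continuity matches prop.test", {
  set.seed(19)
  for (i in 1:20) {
    n1 <- sample(100:5000, 1); n2 <- sample(100:5000, 1)
    x1 <- rbinom(1, n1, 0.05); x2 <- rbinom(1, n2, 0.05)
    if (x1 + x2 == 0) next
    mine <- two_proportion_test(x1, n1, x2, n2)$p
    ref <- suppressWarnings(prop.test(c(x1, x2), c(n1, n2))$p.value)
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("large equal-n limit approaches |x1-x2|/sqrt(x1+x2)", {
  n <- 1e7; x1 <- 400; x2 <- 300
  z <- two_proportion_test(x1, n, x2, n, continuity = FALSE)$z
  expect_equal(z, abs(x1 - x2) / sqrt(x1 + x2), tolerance = 0.01)
})

test_that("2xk Fisher test: independence, frozen enumeration, zero margins", {
  # perfectly proportional table
  expect_equal(fisher_exact_2xk(rbind(c(4, 8), c(2, 4))), 1)
  # [[3,0],[0,3]]: enumeration over the 4 admissible tables gives 2/20
  expect_equal(fisher_exact_2xk(rbind(c(3, 0), c(0, 3))), 0.1,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2xk(rbind(c(0, 0), c(3, 5))), 1)
  expect_equal(fisher_exact_2xk(rbind(c(2, 0), c(5, 0))), 1)
  expect_error(fisher_exact_2xk(rbind(c(-1, 2), c(3, 4))), "non-negative")
})

test_that("2xk Fisher matches fisher.test on random 2x2 and 2x3 tables", {
  set.seed(23)
  for (i in 1:60) {
    k <- sample(2:3, 1)
    tab <- matrix(sample(0:12, 2 * k, replace = TRUE), nrow = 2)
    if (sum(tab) == 0 || sum(tab) > 60) next
    mine <- fisher_exact_2xk(tab)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      expect_equal(mine, 1)
    } else {
      expect_equal(mine, fisher.test(tab)$p.value, tolerance = 1e-8)
    }
  }
})

test_that("2x2 Fisher with a zero cell equals the hypergeometric tail", {
  tab <- rbind(c(0, 7), c(5, 9))
  # with a zero in the observed corner the one tail is the point mass sum
  expect_equal(fisher_exact_2xk(tab), fisher.test(tab)$p.value,
               tolerance = 1e-10)
  tab2 <- rbind(c(6, 0), c(4, 11))
  expect_equal(fisher_exact_2xk(tab2), fisher.test(tab2)$p.value,
               tolerance = 1e-10)
})
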