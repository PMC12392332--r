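test_that("pairwise rank statistic matches hand-computed values", {
  s <- steel_dwass_pair_stat(c(1, 2, 3), c(4, 5, 6))
  expect_equal(s$W, 15)
  expect_equal(s$E_W, 10.5)
  expect_equal(s$Var_W, 5.25)
  expect_equal(s$t_stat, 4.5 / sqrt(5.25))
  same <- steel_dwass_pair_stat(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$W, 10.5)
  expect_equal(same$t_stat, 0)
  tied <- steel_dwass_pair_stat(c(5, 5), c(5, 5))
  expect_equal(tied$Var_W, 0)
  expect_equal(tied$t_stat, 0)
  expect_error(steel_dwass_pair_stat(1, c(1, 2)), "at least 2")
})

test_that("swapping the pair negates t and preserves the p-value", {
  set.seed(2)
  a <- rnorm(6); b <- rnorm(8) + 1
  s_ab <- steel_dwass_pair_stat(a, b)
  s_ba <- steel_dwass_pair_stat(b, a)
  expect_equal(s_ab$t_stat, -s_ba$t_stat)
  expect_equal(studentized_range_sf(sqrt(2) * abs(s_ab$t_stat), 3),
               studentized_range_sf(sqrt(2) * abs(s_ba$t_stat), 3))
})

test_that("studentized range tail matches known points and is monotone", {
  expect_equal(studentized_range_sf(0, 2), 1)
  expect_equal(studentized_range_sf(0, 5), 1)
  # k = 2 reduces to the two-sided normal tail at q / sqrt(2)
  for (z in c(0.5, 1.5, 1.96, 3)) {
    expect_equal(studentized_range_sf(sqrt(2) * z, 2), 2 * pnorm(-z),
                 tolerance = 1e-4)
  }
  q <- seq(0.5, 5, by = 0.5)
  sf3 <- studentized_range_sf(q, 3)
  expect_true(all(diff(sf3) < 0))       # decreasing in q
  sf5 <- studentized_range_sf(q, 5)
  expect_true(all(sf5 > sf3))           # increasing in k
  expect_equal(round(studentized_range_sf(3.314, 3), 3), 0.05)
})

test_that("all-pairs test reproduces the k = 2 closed-form cases", {
  res0 <- steel_dwass_test(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(res0$p_value, 1)
  res <- steel_dwass_test(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  z <- 4.5 / sqrt(5.25)
  expect_equal(res$p_value, 2 * pnorm(-z), tolerance = 1e-4)
  expect_equal(round(res$p_value, 4), 0.0495)
  expect_error(steel_dwass_test(list(a = 1:3, b = 2)), "b")
})

test_that("for k = 2 the procedure equals the normal-approximation rank-sum test", {
  set.seed(12)
  for (i in 1:10) {
    a <- rnorm(7); b <- rnorm(9) + runif(1, -1, 1)
    res <- steel_dwass_test(list(a = a, b = b))
    wt <- suppressWarnings(
      wilcox.test(b, a, exact = FALSE, correct = FALSE))
    expect_equal(res$p_value, wt$p.value, tolerance = 1e-8)
  }
})

test_that("the test is invariant to relabeling, shift and positive scaling", {
  set.seed(33)
  g <- list(x = rnorm(5), y = rnorm(6) + 0.5, z = rnorm(4) - 0.5)
  res <- steel_dwass_test(g)
  shifted <- steel_dwass_test(lapply(g, function(v) v + 100))
  scaled <- steel_dwass_test(lapply(g, function(v) v * 3.7))
  expect_equal(res$t_stat, shifted$t_stat)
  expect_equal(res$t_stat, scaled$t_stat)
  perm <- steel_dwass_test(g[c("z", "x", "y")])
  key <- function(d) {
    k <- apply(cbind(d$group_a, d$group_b), 1, function(r)
      paste(sort(r), collapse = "-"))
    setNames(d$p_value, k)[order(k)]
  }
  expect_equal(key(res), key(perm))
})

test_that("asymptotic p-values bracket the exact permutation atoms for small groups", {
  # at n = 4 per group the pairwise statistic is heavily discrete; the
  # continuous studentized-range p should fall inside the atom at the
  # observed value, i.e. between the strict and inclusive exact p
  set.seed(77)
  for (i in 1:2) {
    groups <- list(a = rnorm(4), b = rnorm(4) + 1.2, c = rnorm(4) - 0.4)
    res <- steel_dwass_test(groups)
    oracle <- steel_dwass_exact_oracle(groups)
    expect_true(all(res$p_value >= oracle$strict - 1e-9))
    expect_true(all(res$p_value <= oracle$incl + 1e-9))
  }
})

test_that("signed-rank p-values match exact enumeration and handle zeros", {
  expect_equal(wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1)), 0.25)
  expect_warning(p <- suppressMessages(wilcoxon_signed_rank(1:4, 1:4)),
                 "all differences")
  expect_equal(p, 1)
  set.seed(55)
  # exact path at n = 20 equals the DP enumeration oracle
  for (i in 1:5) {
    x <- rnorm(20); y <- rnorm(20)
    expect_equal(wilcoxon_signed_rank(x, y), signed_rank_exact_p(x - y),
                 tolerance = 1e-12)
  }
  # approximation path (n = 30 > exact cutoff) stays within 0.01 of exact
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    expect_lt(abs(wilcoxon_signed_rank(x, y) - signed_rank_exact_p(x - y)),
              0.01)
  }
})
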