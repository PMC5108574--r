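test_that("odds ratio is the cross-product, with zero-cell handling", {
  expect_equal(round(odds_ratio(two_by_two(25, 145, 697, 8327)), 2), 2.06)
  expect_equal(round(odds_ratio(two_by_two(13, 157, 461, 8563)), 3), 1.538)
  expect_equal(odds_ratio(two_by_two(1, 1, 1, 1)), 1.0)

  or0 <- odds_ratio(two_by_two(5, 0, 3, 7))
  expect_true(is.infinite(or0))
  expect_true(attr(or0, "zero_cell"))
  or_corr <- odds_ratio(two_by_two(5, 0, 3, 7), correction = TRUE)
  expect_true(is.finite(or_corr))

  expect_error(two_by_two(1, -1, 1, 1), "non-negative")
  expect_error(two_by_two(0, 0, 1, 1), "positive")
})

test_that("odds ratios invert under exposure relabelling", {
  set.seed(5)
  for (i in 1:20) {
    x <- sample(1:50, 4)
    t1 <- two_by_two(x[1], x[2], x[3], x[4])
    t2 <- two_by_two(x[2], x[1], x[4], x[3])
    expect_equal(odds_ratio(t1) * odds_ratio(t2), 1.0)
  }
})

test_that("fisher exact follows the point-probability convention", {
  expect_equal(fisher_exact(two_by_two(2, 0, 0, 2)), 1 / 3)
  expect_equal(fisher_exact(two_by_two(5, 5, 5, 5)), 1.0)
  p_big <- fisher_exact(two_by_two(25, 145, 697, 8327))
  expect_lte(p_big, 0.01)
  # normal approximation to the hypergeometric as an order-of-magnitude
  # check on the same table
  m <- 170; n <- 9024; k <- 722; N <- m + n
  mu <- k * m / N
  sd <- sqrt(k * (m / N) * (n / N) * (N - k) / (N - 1))
  p_norm <- 2 * pnorm(25 - 0.5, mu, sd, lower.tail = FALSE)
  expect_lt(abs(log10(p_big) - log10(p_norm)), 1)
})

test_that("fisher exact agrees with stats::fisher.test across random tables", {
  set.seed(6)
  for (i in 1:200) {
    x <- rpois(4, lambda = sample(c(2, 10, 40), 1))
    if (sum(x[1:2]) == 0 || sum(x[3:4]) == 0) next
    ours <- fisher_exact(two_by_two(x[1], x[2], x[3], x[4]))
    base <- stats::fisher.test(matrix(x, 2, byrow = TRUE))$p.value
    expect_equal(ours, min(1, base), tolerance = 1e-10)
  }
})

test_that("woolf interval brackets the odds ratio on the log scale", {
  ci <- woolf_ci(two_by_two(10, 10, 10, 10))
  expect_equal(ci[1] * ci[2], 1.0, tolerance = 1e-12)  # symmetric about 1

  t <- two_by_two(41, 137, 1184, 7840)
  ci2 <- woolf_ci(t)
  or <- odds_ratio(t)
  expect_lt(ci2[1], or)
  expect_gt(ci2[2], or)
  # direct formula evaluation
  se <- sqrt(1 / 41 + 1 / 137 + 1 / 1184 + 1 / 7840)
  expect_equal(ci2, exp(log(or) + c(-1, 1) * qnorm(0.975) * se))

  ci0 <- woolf_ci(t, level = 0)
  expect_equal(ci0[1], ci0[2])
  expect_equal(ci0[1], or)

  expect_error(woolf_ci(two_by_two(0, 5, 5, 5)), "zero cell")
  expect_silent(woolf_ci(two_by_two(0, 5, 5, 5), correction = TRUE))

  # interval shrinks as all cells scale up
  narrow <- woolf_ci(two_by_two(100, 100, 100, 100))
  wide <- woolf_ci(two_by_two(10, 10, 10, 10))
  expect_lt(narrow[2] / narrow[1], wide[2] / wide[1])
})

test_that("binomial TDT doubles the smaller exact tail", {
  expect_equal(tdt_binomial(5, 5)$p_value, 1.0)
  expect_equal(tdt_binomial(10, 0)$p_value, 2 * (1 / 2)^10)
  set.seed(7)
  for (i in 1:20) {
    b <- sample(0:30, 1); c <- sample(0:30, 1)
    if (b + c == 0) next
    expect_equal(tdt_binomial(b, c)$p_value, tdt_binomial(c, b)$p_value)
    expect_lte(tdt_binomial(b, c)$p_value, 1)
  }
  expect_error(tdt_binomial(0, 0), "informative")
})

test_that("haplotype association builds the table from tallies and totals", {
  comp <- published_counts("complete_haplotype_counts")
  case <- setNames(comp$agre, comp$haplotype)
  ctrl <- setNames(comp$control, comp$haplotype)
  res <- haplotype_association_table(case, ctrl, "cB01/tA01",
                                     control_total = 9024)
  expect_equal(res$table$a, 25)
  expect_equal(res$table$b, 145)
  expect_equal(res$table$c, 697)
  expect_equal(res$table$d, 8327)
  expect_equal(round(res$odds_ratio, 2), 2.06)
  res2 <- haplotype_association_table(case, ctrl, "cB02/tB01",
                                      control_total = 9024)
  expect_equal(round(res2$odds_ratio, 3), 0.879)
  expect_error(haplotype_association_table(numeric(0), ctrl, "x"), "empty")
  expect_error(haplotype_association_table(case, ctrl, "cZ99/t!"), "absent")
})

test_that("AFBAC comparison reports OR and percentages", {
  inh <- c("C1k/C1k" = 25, "C1k/C2k" = 15, "C2k/C2k" = 2)
  non <- c("C1k/C1k" = 13, "C1k/C2k" = 20, "C2k/C2k" = 6)
  r1 <- afbac_compare(inh, non, "C1k/C1k")
  expect_equal(round(r1$odds_ratio, 3), 2.941)
  expect_equal(r1$pct_inherited, 59.5)
  expect_equal(r1$pct_noninherited, 33.3)
  r2 <- afbac_compare(inh, non, "C1k/C2k")
  expect_equal(round(r2$odds_ratio, 3), 0.528)
  same <- afbac_compare(inh, inh, "C1k/C1k")
  expect_equal(same$odds_ratio, 1.0)
  expect_error(afbac_compare(inh * 0, non, "C1k/C1k"), "positive")
})

test_that("fisher p is invariant under table transposition", {
  set.seed(8)
  for (i in 1:20) {
    x <- rpois(4, 8) + 1
    p1 <- fisher_exact(two_by_two(x[1], x[2], x[3], x[4]))
    p2 <- fisher_exact(two_by_two(x[1], x[3], x[2], x[4]))
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})
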