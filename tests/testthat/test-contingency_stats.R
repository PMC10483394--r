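# Expected values for the worked AMD example were frozen from an
# independent evaluation of the G2 sum and the hypergeometric closed form:
# G2_case = 21.931715, G2_ctrl = 30.328524, G2_combined = 0.118699,
# C = 52.141541, p = 1.288573e-10; F1 p = C(50,11)/C(146,11) = 3.414142e-06.

test_that("crosstab_pair routes missing genotypes to the fourth class", {
  g <- matrix(c(0L, NA, 0L, 1L), 2, 2)
  ds <- genotype_dataset(rbind(g, c(1L, 1L)), c("case", "case", "control"),
                         data.frame(id = c("x", "y"), chrom = c("1", "2")))
  ct <- crosstab_pair(ds, 1, 2)
  expect_identical(ct$case4x4[1, 1], 1L)       # (0,0)
  expect_identical(ct$case4x4[4, 2], 1L)       # (missing, 1)
  expect_identical(sum(ct$case3x3), 1L)
  expect_identical(sum(ct$case4x4), 2L)
  expect_identical(sum(ct$ctrl4x4), 1L)
  expect_error(crosstab_pair(ds, 1, 1), "differ")
})

test_that("crosstab_pair reproduces the worked-example 3x3 tables", {
  ds <- dataset_from_3x3(amd_case_3x3(), amd_ctrl_3x3())
  ct <- crosstab_pair(ds, 1, 2)
  expect_identical(unname(ct$case3x3), amd_case_3x3())
  expect_identical(unname(ct$ctrl3x3), amd_ctrl_3x3())
  expect_true(all(ct$case4x4[4, ] == 0) && all(ct$case4x4[, 4] == 0))
})

test_that("crosstab conserves individuals when nothing is missing", {
  ds <- random_dataset(21, missing_rate = 0)
  ct <- crosstab_pair(ds, 2, 5)
  expect_identical(sum(ct$case3x3), sum(ds$phenotype == "case"))
  expect_identical(sum(ct$ctrl3x3), sum(ds$phenotype == "control"))
})

test_that("G2 is zero at exact independence and matches frozen values", {
  expect_equal(g2_independence(matrix(4, 3, 3))$g2, 0)
  expect_equal(g2_independence(amd_case_3x3())$g2, 21.931715,
               tolerance = 1e-6)
  expect_equal(g2_independence(amd_ctrl_3x3())$g2, 30.328524,
               tolerance = 1e-6)
  expect_error(g2_independence(matrix(0, 3, 3)), "all-zero")
})

test_that("G2 is invariant to permutation and transposition", {
  set.seed(42)
  for (rep in 1:20) {
    tab <- matrix(rpois(9, 4), 3, 3)
    if (sum(tab) == 0) next
    base <- g2_independence(tab)$g2
    pr <- sample(3); pc <- sample(3)
    expect_equal(g2_independence(tab[pr, pc])$g2, base)
    expect_equal(g2_independence(t(tab))$g2, base)
  }
})

test_that("interaction statistic matches the worked example and Bonferroni", {
  it <- interaction_test(amd_case_3x3(), amd_ctrl_3x3(), min_expected = 1)
  expect_equal(it$C, 52.141541, tolerance = 1e-6)
  expect_equal(it$p, 1.288573e-10, tolerance = 1e-5)
  expect_equal(min(1, it$p * 294643816), 0.0380, tolerance = 0.005)
  expect_true(it$analyzable)
  expect_identical(it$df, 4L)
  expect_equal(it$C, it$g2_case + it$g2_ctrl - it$g2_combined)
})

test_that("identical case/control tables give C = 0 exactly and p = 1", {
  tab <- amd_case_3x3()
  it <- interaction_test(tab, tab)
  expect_identical(it$C, 0)
  expect_identical(it$p, 1)
})

test_that("interaction statistic scales linearly and is symmetric in i/j", {
  set.seed(7)
  for (rep in 1:10) {
    ca <- matrix(rpois(9, 5) + 1, 3, 3)
    ct <- matrix(rpois(9, 5) + 1, 3, 3)
    one <- interaction_test(ca, ct)
    two <- interaction_test(2 * ca, 2 * ct)
    expect_equal(two$g2_case, 2 * one$g2_case)
    expect_equal(two$g2_ctrl, 2 * one$g2_ctrl)
    expect_equal(two$g2_combined, 2 * one$g2_combined)
    expect_equal(two$C, 2 * one$C)
    swapped <- interaction_test(t(ca), t(ct))
    expect_equal(swapped$C, one$C)
  }
})

test_that("expected-count screen flags sparse tables as not analyzable", {
  ca <- matrix(c(0, 0, 0, 1, 2, 1, 1, 1, 2), 3, 3, byrow = TRUE)
  it <- interaction_test(ca, matrix(1, 3, 3), min_expected = 1)
  expect_false(it$analyzable)
  expect_error(interaction_test(matrix(-1, 3, 3), matrix(1, 3, 3)),
               "non-negative")
})

test_that("Haldane odds ratio matches the worked example and its symmetries", {
  h <- haldane_or(two_by_two(0, 96, 11, 39))
  expect_equal(h$OR, 0.0178, tolerance = 0.001)
  expect_equal(h$OR_prime, 56.19, tolerance = 0.001)
  expect_identical(haldane_or(two_by_two(5, 5, 5, 5)),
                   list(OR = 1, OR_prime = 1))
  expect_identical(haldane_or(two_by_two(0, 0, 0, 0))$OR, 1)
  set.seed(3)
  for (rep in 1:10) {
    v <- rpois(4, 6)
    h1 <- haldane_or(two_by_two(v[1], v[2], v[3], v[4]))
    h2 <- haldane_or(two_by_two(v[3], v[4], v[1], v[2]))
    expect_equal(h2$OR, 1 / h1$OR)
    expect_equal(h2$OR_prime, h1$OR_prime)
  }
})

test_that("Pearson chi-square matches closed forms and screens", {
  expect_equal(pearson_chi2(two_by_two(10, 10, 10, 10))$statistic, 0)
  expect_equal(pearson_chi2(two_by_two(10, 10, 10, 10))$p, 1)
  expect_equal(pearson_chi2(two_by_two(20, 0, 0, 20))$statistic, 40)
  t2 <- pearson_chi2(two_by_two(0, 96, 11, 39))
  expect_equal(t2$statistic, 22.84089, tolerance = 1e-6)
  ref <- suppressWarnings(
    chisq.test(matrix(c(0, 96, 11, 39), 2, byrow = TRUE), correct = FALSE))
  expect_equal(t2$statistic, unname(ref$statistic))
  expect_equal(t2$p, ref$p.value)
  expect_false(pearson_chi2(two_by_two(1, 0, 0, 30), min_expected = 1)$analyzable)
  expect_error(pearson_chi2(two_by_two(0, 0, 0, 0)), "empty")
})

test_that("Fisher tests match the closed-form worked example", {
  t <- two_by_two(0, 96, 11, 39)
  expect_equal(fisher_exact(t, "F1"), choose(50, 11) / choose(146, 11))
  expect_identical(fisher_exact(t, "F2"), 1)
  # degenerate margin: single feasible table
  expect_identical(fisher_exact(two_by_two(0, 5, 0, 7), "F1"), 1)
  expect_identical(fisher_exact(two_by_two(0, 5, 0, 7), "F2"), 1)
  expect_identical(fisher_exact(two_by_two(0, 5, 0, 7), "F3"), 1)
})

test_that("Fisher tests agree with the brute-force hypergeometric oracle", {
  # exhaustive over small tables, random sample of larger ones (total <= 60)
  tables <- expand.grid(a = 0:3, b = 0:3, c = 0:3, d = 0:3)
  tables <- tables[rowSums(tables) > 0, ]
  set.seed(99)
  big <- t(replicate(300, {
    n <- sample(4:60, 1)
    as.vector(rmultinom(1, n, prob = runif(4, 0.05, 1)))
  }))
  colnames(big) <- c("a", "b", "c", "d")
  tables <- rbind(tables, as.data.frame(big))
  for (r in seq_len(nrow(tables))) {
    t <- two_by_two(tables$a[r], tables$b[r], tables$c[r], tables$d[r])
    for (side in c("F1", "F2", "F3")) {
      expect_equal(fisher_exact(t, side),
                   fisher_oracle(tables$a[r], tables$b[r], tables$c[r],
                                 tables$d[r], side),
                   tolerance = 1e-10)
    }
  }
})

test_that("Fisher tests agree with the reference implementation", {
  set.seed(5)
  for (rep in 1:40) {
    v <- rpois(4, 5)
    if (sum(v) == 0) next
    t <- two_by_two(v[1], v[2], v[3], v[4])
    m <- matrix(v, 2, 2, byrow = TRUE)
    expect_equal(fisher_exact(t, "F1"),
                 fisher.test(m, alternative = "less")$p.value)
    expect_equal(fisher_exact(t, "F2"),
                 fisher.test(m, alternative = "greater")$p.value)
    expect_equal(fisher_exact(t, "F3"), fisher.test(m)$p.value)
  }
})
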