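test_that("genotype-pair scan finds the worked-example pattern under F1", {
  ds <- dataset_from_3x3(amd_case_3x3(), amd_ctrl_3x3())
  sc <- scan_genotype_pairs(ds, test = "F1", min_support = 10,
                            min_confidence = 0)
  hit <- sc$results[sc$results$g_i == 0 & sc$results$g_j == 1, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(c(hit$a, hit$b, hit$c, hit$d), c(0L, 96L, 11L, 39L))
  expect_equal(hit$p, 3.414142e-06, tolerance = 1e-6)
  expect_equal(hit$p_B, min(1, hit$p * sc$tested_count))
  expect_identical(sc$results$p[1], hit$p)  # best pattern overall
})

test_that("support and confidence filters bound what gets tested", {
  ds <- random_dataset(41, n_case = 30, n_ctrl = 30, n_variants = 6)
  all_pat <- scan_genotype_pairs(ds, test = "F3", min_support = 1)
  expect_lte(all_pat$tested_count, 9 * all_pat$M)
  expect_true(all(all_pat$results$support >= 1))

  none <- scan_genotype_pairs(ds, test = "F3", min_support = 1000)
  expect_identical(none$tested_count, 0L)
  expect_identical(nrow(none$results), 0L)

  conf <- scan_genotype_pairs(ds, test = "F3", min_support = 1,
                              min_confidence = 0.6)
  expect_true(all(conf$results$confidence >= 0.6))
  expect_error(scan_genotype_pairs(ds, test = "F3", min_confidence = 2),
               "min_confidence")
})

test_that("pattern tables use known-genotype totals, not raw group sizes", {
  g <- matrix(c(0L, 1L, 2L, 0L, 1L,
                1L, 1L, 0L, 2L, 0L), ncol = 2)
  g[1, 1] <- NA  # one case missing at variant 1
  ds <- genotype_dataset(g, c("case", "case", "case", "control", "control"),
                         data.frame(id = c("a", "b"), chrom = c("1", "2")))
  sc <- scan_genotype_pairs(ds, test = "F3", min_support = 1)
  expect_true(all(sc$results$a + sc$results$b == 2L))  # 3 cases - 1 missing
  expect_true(all(sc$results$c + sc$results$d == 2L))
})

test_that("with no missing data the nine patterns partition each group", {
  ds <- random_dataset(42, n_case = 25, n_ctrl = 30, n_variants = 5,
                       missing_rate = 0)
  sc <- scan_genotype_pairs(ds, test = "F3", min_support = 0)
  for (id in unique(sc$results$pair_id)) {
    sub <- sc$results[sc$results$pair_id == id, ]
    expect_identical(sum(sub$a), 25L)
    expect_identical(sum(sub$c), 30L)
  }
})

test_that("chi-square runs screen expected counts out of the test count", {
  ds <- random_dataset(43, n_case = 20, n_ctrl = 20, n_variants = 6)
  chi <- scan_genotype_pairs(ds, test = "chi2", min_support = 1,
                             min_expected = 1)
  fis <- scan_genotype_pairs(ds, test = "F3", min_support = 1)
  expect_lte(chi$tested_count, fis$tested_count)
  expect_identical(chi$tested_count, nrow(chi$results))
})

test_that("genotype-pair scan is invariant to worker count", {
  ds <- random_dataset(44, n_case = 30, n_ctrl = 30, n_variants = 7)
  expect_identical(scan_genotype_pairs(ds, test = "F3", workers = 1),
                   scan_genotype_pairs(ds, test = "F3", workers = 3))
})

test_that("rank_patterns ranks by p or OR' with shared ranks on ties", {
  res <- data.frame(pair_id = c(7L, 3L, 5L), i = 1:3, j = 4:6,
                    var_i = "x", var_j = "y",
                    g_i = 0L, g_j = 0L, a = 1L, b = 1L, c = 1L, d = 1L,
                    support = 2L, confidence = 0.5,
                    OR = c(56.2, 1.0, 3.3), OR_prime = c(56.2, 1.0, 3.3),
                    p = c(1e-5, 1e-3, 1e-5), p_B = 1)
  byp <- rank_patterns(res, "p")
  expect_identical(byp$pair_id, c(5L, 7L, 3L))  # tie broken by pair id
  expect_identical(byp$rank, c(1L, 1L, 3L))
  byor <- rank_patterns(res, "OR_prime")
  expect_identical(byor$OR_prime, c(56.2, 3.3, 1.0))
  expect_identical(byor$rank, 1:3)
  single <- rank_patterns(res[1, ], "p")
  expect_identical(single$rank, 1L)
  expect_error(rank_patterns(res, "bogus"))
})

test_that("a pattern planted in controls only attains the best F1 p-value", {
  hits <- 0L
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    n <- 200
    geno <- matrix(sample(0:2, 2 * n * 6, replace = TRUE,
                          prob = c(0.49, 0.42, 0.09)), 2 * n, 6)
    carrier <- runif(n) < 0.3
    geno[n + which(carrier), 1] <- 0L   # controls carrying (0, 0) at (1, 2)
    geno[n + which(carrier), 2] <- 0L
    both0 <- which(geno[seq_len(n), 1] == 0 & geno[seq_len(n), 2] == 0)
    geno[both0, 1] <- 1L                # pattern absent in cases
    geno[both0, 2] <- 1L
    ds <- genotype_dataset(geno, rep(c("case", "control"), each = n),
                           data.frame(id = paste0("v", 1:6),
                                      chrom = as.character(1:6)))
    sc <- scan_genotype_pairs(ds, test = "F1", min_support = 10)
    best <- sc$results[1, ]
    if (best$i == 1 && best$j == 2 && best$g_i == 0 && best$g_j == 0) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 9L)
})
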