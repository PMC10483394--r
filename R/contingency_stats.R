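# Table-level statistics: 4x4/3x3 cross-tabulation per variant pair, the
# likelihood-ratio interaction statistic C, Haldane odds ratios, and the
# Pearson and Fisher tests applied to 2x2 pattern tables.

#' 2x2 phenotype-by-pattern table
#'
#' Counts of individuals by phenotype (case/control) and presence/absence of
#' a genotype pattern, restricted to individuals with known genotypes at both
#' variants: `a` cases with the pattern, `b` cases without, `c` controls
#' with, `d` controls without.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return An object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(v)) || any(v < 0)) {
    stop("two_by_two counts must be non-negative", call. = FALSE)
  }
  structure(as.list(v), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf("2x2 pattern table: a=%d b=%d c=%d d=%d (support %d)\n",
              x$a, x$b, x$c, x$d, x$a + x$c))
  invisible(x)
}

#' Cross-tabulate one variant pair
#'
#' Builds, separately for cases and controls, the 4x4 cross-tabulation of
#' genotypes at variants `i` and `j` where missing is treated as a fourth
#' genotype, together with the known-genotype 3x3 subtables. Every individual
#' falls in exactly one cell of the 4x4 table of their phenotype group; an
#' individual missing either genotype never enters the 3x3 subtable.
#'
#' @param dataset a [genotype_dataset].
#' @param i,j distinct variant column indices.
#' @return An object of class `grouped_pair_table` with elements `case4x4`,
#'   `ctrl4x4`, `case3x3`, `ctrl3x3`, `i`, `j`.
#' @export
crosstab_pair <- function(dataset, i, j) {
  if (i == j) stop("variant indices must differ (got i = j = ", i, ")",
                   call. = FALSE)
  nv <- ncol(dataset$genotypes)
  if (i < 1 || j < 1 || i > nv || j > nv) {
    stop("variant index out of range", call. = FALSE)
  }
  gi <- dataset$genotypes[, i]
  gj <- dataset$genotypes[, j]
  gi[is.na(gi)] <- 3L
  gj[is.na(gj)] <- 3L
  idx <- gi * 4L + gj + 1L
  is_case <- dataset$phenotype == "case"
  case4 <- matrix(tabulate(idx[is_case], nbins = 16L), 4L, 4L, byrow = TRUE)
  ctrl4 <- matrix(tabulate(idx[!is_case], nbins = 16L), 4L, 4L, byrow = TRUE)
  dn <- list(c("0", "1", "2", "miss"), c("0", "1", "2", "miss"))
  dimnames(case4) <- dimnames(ctrl4) <- dn
  structure(
    list(case4x4 = case4, ctrl4x4 = ctrl4,
         case3x3 = case4[1:3, 1:3], ctrl3x3 = ctrl4[1:3, 1:3],
         i = i, j = j),
    class = "grouped_pair_table"
  )
}

#' Likelihood-ratio independence statistic on a 3x3 table
#'
#' Computes the G-statistic `G2 = 2 * sum(n * log(n / e))` over the cells of
#' a 3x3 genotype table, with expected counts from the product of the
#' margins. Cells with zero observed count contribute nothing
#' (`0 * log 0 = 0`). The smallest expected count is reported over cells
#' whose row and column margins are both positive; cells in all-zero rows or
#' columns are structural zeros and are excluded from the screen.
#'
#' @param table 3x3 (or any rectangular) matrix of non-negative counts.
#' @return A list with `g2` and `min_expected`.
#' @export
g2_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- sum(table)
  if (tot == 0) stop("undefined statistic: all-zero table", call. = FALSE)
  rs <- rowSums(table)
  cs <- colSums(table)
  e <- outer(rs, cs) / tot
  nz <- table > 0
  g2 <- 2 * sum(table[nz] * log(table[nz] / e[nz]))
  realizable <- outer(rs > 0, cs > 0)
  list(g2 = g2, min_expected = min(e[realizable]))
}

#' Interaction difference test for one variant pair
#'
#' Tests whether the genotype-genotype interaction structure at a variant
#' pair differs between cases and controls. The statistic is
#' `C = G2_case + G2_ctrl - G2_combined`, where each `G2` is the
#' likelihood-ratio independence statistic of the corresponding 3x3
#' known-genotype table and the combined table is the cellwise sum. Under
#' the null of no interaction difference, `C` is referred to a chi-square
#' distribution with 4 degrees of freedom. A pair is flagged not analyzable
#' when any expected count in any of the three G2 computations falls below
#' `min_expected`; such pairs are excluded from the Bonferroni test count.
#' `C <= 0` can occur for Simpson-type configurations; it is reported as
#' computed with p set to 1.
#'
#' @param case3x3,ctrl3x3 3x3 known-genotype count tables.
#' @param min_expected minimum expected cell count for the pair to count as
#'   analyzable (default 1).
#' @return An object of class `interaction_result`: list with `g2_case`,
#'   `g2_ctrl`, `g2_combined`, `C`, `df` (= 4), `p`, `min_expected`
#'   (smallest expected count seen), `analyzable`.
#' @export
interaction_test <- function(case3x3, ctrl3x3, min_expected = 1) {
  case3x3 <- as.matrix(case3x3)
  ctrl3x3 <- as.matrix(ctrl3x3)
  if (any(case3x3 < 0) || any(ctrl3x3 < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  gc <- g2_independence(case3x3)
  gt <- g2_independence(ctrl3x3)
  gb <- g2_independence(case3x3 + ctrl3x3)
  C <- gc$g2 + gt$g2 - gb$g2
  p <- if (C <= 0) 1 else stats::pchisq(C, df = 4, lower.tail = FALSE)
  min_e <- min(gc$min_expected, gt$min_expected, gb$min_expected)
  structure(
    list(g2_case = gc$g2, g2_ctrl = gt$g2, g2_combined = gb$g2,
         C = C, df = 4L, p = p, min_expected = min_e,
         analyzable = min_e >= min_expected),
    class = "interaction_result"
  )
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf(
    "interaction test: C = %.4f (4 df), p = %.4e%s\n  G2 case %.4f, ctrl %.4f, combined %.4f; min expected %.3f\n",
    x$C, x$p, if (x$analyzable) "" else " [not analyzable]",
    x$g2_case, x$g2_ctrl, x$g2_combined, x$min_expected))
  invisible(x)
}

#' Haldane-corrected odds ratio for a 2x2 pattern table
#'
#' `OR = (a + 1/2)(d + 1/2) / [(b + 1/2)(c + 1/2)]`, finite and positive for
#' any non-negative counts, and the direction-free effect size
#' `OR' = max(OR, 1/OR)`.
#'
#' @param t a [two_by_two].
#' @return A list with `OR` and `OR_prime`.
#' @export
haldane_or <- function(t) {
  OR <- (t$a + 0.5) * (t$d + 0.5) / ((t$b + 0.5) * (t$c + 0.5))
  list(OR = OR, OR_prime = max(OR, 1 / OR))
}

#' Pearson chi-square test on a 2x2 pattern table
#'
#' Standard 1-df Pearson statistic (no continuity correction). The table is
#' flagged not analyzable when any expected count is below `min_expected`;
#' degenerate tables with a zero margin get statistic 0 and p = 1.
#'
#' @param t a [two_by_two].
#' @param min_expected expected-count screen limit (default 1).
#' @return A list with `statistic`, `p` and `analyzable`.
#' @export
pearson_chi2 <- function(t, min_expected = 1) {
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  if (n == 0) stop("undefined statistic: empty table", call. = FALSE)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(list(statistic = 0, p = 1, analyzable = FALSE))
  }
  stat <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  min_e <- min(outer(c(r1, r2), c(c1, c2)) / n)
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       analyzable = min_e >= min_expected)
}

#' Fisher exact test on a 2x2 pattern table
#'
#' Exact hypergeometric test conditioned on both margins. `F2` is one-sided
#' for the pattern being more frequent in cases (sums tables with
#' `a >= a_obs`); `F1` is one-sided toward controls (`a <= a_obs`); `F3` is
#' two-sided by the point-probability rule, summing all tables whose point
#' probability does not exceed the observed one within a relative tolerance
#' of 1e-7.
#'
#' @param t a [two_by_two].
#' @param side one of `"F1"`, `"F2"`, `"F3"`.
#' @return The p-value (in `(0, 1]`).
#' @export
fisher_exact <- function(t, side = c("F3", "F1", "F2")) {
  side <- match.arg(side)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  if (a + b + c + d == 0) stop("undefined test: empty table", call. = FALSE)
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0L, c1 - r2)
  hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, r2, c1)
  obs <- a - lo + 1L
  p <- switch(side,
    F2 = sum(probs[support >= a]),
    F1 = sum(probs[support <= a]),
    F3 = sum(probs[probs <= probs[obs] * (1 + 1e-7)])
  )
  min(1, p)
}
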