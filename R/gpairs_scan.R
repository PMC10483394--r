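# Genotype-pair scan: test every genotype pattern of every admissible
# variant pair against phenotype, with support/confidence filtering and
# exact missing-genotype accounting.

#' Scan all genotype pairs for case-control association
#'
#' For every admissible variant pair, each of its nine genotype pairs is a
#' candidate pattern. The pattern's 2x2 table counts only individuals with
#' known genotypes at both variants (row totals `a + b` and `c + d` are the
#' known-genotype group sizes from the 4x4 cross-tabulation, never the raw
#' group sizes). Patterns with support `a + c >= min_support` and confidence
#' `a/(a + c) >= min_confidence` are tested with the chosen statistic; for
#' the chi-square test only patterns passing the expected-count screen are
#' tested. `tested_count` is the exact number of tests performed and is the
#' Bonferroni multiplier: `p_B = min(1, p * tested_count)`.
#'
#' @param dataset a [genotype_dataset] with at least two variants.
#' @param test `"chi2"` (Pearson) or Fisher `"F1"` (enriched in controls),
#'   `"F2"` (enriched in cases), `"F3"` (two-sided).
#' @param min_support minimum pattern support `a + c` (default 10);
#'   support-0 patterns are never tested (confidence undefined).
#' @param min_confidence minimum confidence in `[0, 1]` (default 0, no
#'   restriction).
#' @param min_expected expected-count screen limit for the chi-square test.
#' @param cross_chrom_only restrict to cross-chromosome variant pairs.
#' @param workers number of worker processes.
#' @param top retain at most this many patterns, best p first.
#' @return A list of class `gpairs_result`: `results` (data frame with
#'   `pair_id`, `i`, `j`, `var_i`, `var_j`, `g_i`, `g_j`, `a`, `b`, `c`,
#'   `d`, `support`, `confidence`, `OR`, `OR_prime`, `p`, `p_B`, sorted
#'   ascending by p, ties by pair id then genotype pair), `tested_count`,
#'   `test`, `M` (admissible variant pairs).
#' @export
scan_genotype_pairs <- function(dataset, test = c("chi2", "F1", "F2", "F3"),
                                min_support = 10, min_confidence = 0,
                                min_expected = 1, cross_chrom_only = FALSE,
                                workers = 1, top = 100000) {
  test <- match.arg(test)
  validate_genotype_dataset(dataset)
  if (min_confidence < 0 || min_confidence > 1) {
    stop("min_confidence must be in [0, 1]", call. = FALSE)
  }
  if (min_support < 0) stop("min_support must be >= 0", call. = FALSE)
  N <- ncol(dataset$genotypes)
  if (N < 2) stop("need at least 2 variants to scan pairs", call. = FALSE)
  M_all <- n_pairs(N)
  pairs <- pair_from_index(seq_len(M_all), N)
  mask <- chromosome_mask(dataset, cross_chrom_only)
  admissible <- mask(pairs[, 1], pairs[, 2])

  gmat <- dataset$genotypes
  gmat[is.na(gmat)] <- 3L
  is_case <- dataset$phenotype == "case"
  gcase <- gmat[is_case, , drop = FALSE]
  gctrl <- gmat[!is_case, , drop = FALSE]
  cell <- expand.grid(gj = 0:2, gi = 0:2)  # row-major over the 3x3

  do_chunk <- function(range) {
    ids <- seq.int(range[1], range[2])
    ids <- ids[admissible[ids]]
    rows <- vector("list", length(ids))
    for (r in seq_along(ids)) {
      i <- unname(pairs[ids[r], 1]); j <- unname(pairs[ids[r], 2])
      tc <- tabulate(gcase[, i] * 4L + gcase[, j] + 1L, nbins = 16L)
      tt <- tabulate(gctrl[, i] * 4L + gctrl[, j] + 1L, nbins = 16L)
      c3 <- matrix(tc, 4L, 4L, byrow = TRUE)[1:3, 1:3]
      t3 <- matrix(tt, 4L, 4L, byrow = TRUE)[1:3, 1:3]
      a <- c3[cbind(cell$gi + 1, cell$gj + 1)]
      cc <- t3[cbind(cell$gi + 1, cell$gj + 1)]
      b <- sum(c3) - a
      d <- sum(t3) - cc
      support <- a + cc
      # support-0 patterns are never tested; confidence is a/(a+c)
      keep <- support >= 1L & support >= min_support &
        a / pmax(support, 1L) >= min_confidence
      if (!any(keep)) { rows[[r]] <- NULL; next }
      w <- which(keep)
      p <- rep(NA_real_, length(w))
      tested <- rep(TRUE, length(w))
      for (q in seq_along(w)) {
        k <- w[q]
        tab <- two_by_two(a[k], b[k], cc[k], d[k])
        if (test == "chi2") {
          ch <- pearson_chi2(tab, min_expected)
          if (!ch$analyzable) { tested[q] <- FALSE; next }
          p[q] <- ch$p
        } else {
          p[q] <- fisher_exact(tab, side = test)
        }
      }
      w <- w[tested]
      p <- p[tested]
      if (!length(w)) { rows[[r]] <- NULL; next }
      ors <- (a[w] + 0.5) * (d[w] + 0.5) / ((b[w] + 0.5) * (cc[w] + 0.5))
      rows[[r]] <- data.frame(
        pair_id = ids[r], i = i, j = j,
        g_i = cell$gi[w], g_j = cell$gj[w],
        a = a[w], b = b[w], c = cc[w], d = d[w],
        support = a[w] + cc[w], confidence = a[w] / (a[w] + cc[w]),
        OR = ors, OR_prime = pmax(ors, 1 / ors), p = p)
    }
    do.call(rbind, rows)
  }
  res <- run_partitioned(M_all, workers, do_chunk)
  if (is.null(res)) {
    res <- data.frame(pair_id = integer(), i = integer(), j = integer(),
                      g_i = integer(), g_j = integer(), a = integer(),
                      b = integer(), c = integer(), d = integer(),
                      support = integer(), confidence = numeric(),
                      OR = numeric(), OR_prime = numeric(), p = numeric())
  }
  tested_count <- nrow(res)
  res$p_B <- pmin(1, res$p * tested_count)
  res$var_i <- if (nrow(res)) dataset$variants$id[res$i] else character()
  res$var_j <- if (nrow(res)) dataset$variants$id[res$j] else character()
  res <- res[, c("pair_id", "i", "j", "var_i", "var_j", "g_i", "g_j",
                 "a", "b", "c", "d", "support", "confidence", "OR",
                 "OR_prime", "p", "p_B")]
  ord <- order(res$p, res$pair_id, res$g_i, res$g_j)
  res <- res[head(ord, top), , drop = FALSE]
  rownames(res) <- NULL
  structure(list(results = res, tested_count = tested_count, test = test,
                 M = sum(admissible)),
            class = "gpairs_result")
}

#' @export
print.gpairs_result <- function(x, ...) {
  cat("genotype-pair scan (", x$test, "): ", format(x$M),
      " admissible variant pairs, ", format(x$tested_count),
      " patterns tested\n", sep = "")
  print(utils::head(x$results, 5))
  invisible(x)
}

#' Rank genotype patterns
#'
#' Orders pattern results ascending by p-value or descending by OR' and
#' attaches a `rank` column equal to 1 plus the number of strictly better
#' patterns, so tied patterns share a rank. Ties in ordering break by pair
#' id then genotype pair.
#'
#' @param results the `results` data frame of a [scan_genotype_pairs()] run
#'   (or the `gpairs_result` itself).
#' @param key `"p"` or `"OR_prime"`.
#' @return The reordered data frame with a `rank` column.
#' @export
rank_patterns <- function(results, key = c("p", "OR_prime")) {
  key <- match.arg(key)
  if (inherits(results, "gpairs_result")) results <- results$results
  score <- if (key == "p") results$p else -results$OR_prime
  ord <- order(score, results$pair_id, results$g_i, results$g_j)
  out <- results[ord, , drop = FALSE]
  out$rank <- rank(score[ord], ties.method = "min")
  rownames(out) <- NULL
  out
}
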