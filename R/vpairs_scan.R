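# Variant-pair interaction scan: evaluate the interaction statistic C over
# every admissible variant pair, count analyzed pairs M_t, Bonferroni-correct
# in a second pass, and rank. Also the per-pair genotype-pattern drill-down.

#' Scan all variant pairs for interaction differences
#'
#' Runs [interaction_test()] on the known-genotype 3x3 tables of every
#' admissible variant pair (all pairs, or cross-chromosome pairs only).
#' `M_t`, the Bonferroni multiplier, is the number of pairs whose expected
#' counts all reach `min_expected`; corrected p-values
#' `p_B = min(1, p * M_t)` are assigned after the full scan, so `M_t` is the
#' exact count of tests performed. Output is identical for any worker count.
#'
#' @param dataset a [genotype_dataset] with at least two variants.
#' @param min_expected expected-count screen limit (default 1).
#' @param cross_chrom_only restrict to pairs of variants on different
#'   chromosomes.
#' @param workers number of worker processes; the pair-id range is split
#'   into contiguous chunks with [partition_pairs()].
#' @param top retain at most this many pairs, best p first (default 1e5).
#' @return A list of class `vpairs_result`: `results` (data frame with
#'   `pair_id`, `i`, `j`, `var_i`, `var_j`, `C`, `p`, `p_B`, `analyzable`,
#'   sorted ascending by p, ties by pair id; non-analyzable pairs carry `NA`
#'   p and sort last), `M` (admissible pairs), `M_t`, `n_pairs_total`.
#' @export
scan_variant_pairs <- function(dataset, min_expected = 1,
                               cross_chrom_only = FALSE, workers = 1,
                               top = 100000) {
  validate_genotype_dataset(dataset)
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

  do_chunk <- function(range) {
    ids <- seq.int(range[1], range[2])
    ids <- ids[admissible[ids]]
    out <- data.frame(pair_id = ids, i = unname(pairs[ids, 1]),
                      j = unname(pairs[ids, 2]),
                      C = rep(NA_real_, length(ids)),
                      p = rep(NA_real_, length(ids)),
                      analyzable = rep(FALSE, length(ids)))
    for (r in seq_along(ids)) {
      i <- out$i[r]; j <- out$j[r]
      t3 <- pair_3x3_tables(gcase, gctrl, i, j)
      if (is.null(t3)) next
      it <- interaction_test(t3$case, t3$ctrl, min_expected)
      out$C[r] <- it$C
      out$p[r] <- it$p
      out$analyzable[r] <- it$analyzable
    }
    out
  }
  res <- run_partitioned(M_all, workers, do_chunk)

  M_t <- sum(res$analyzable)
  res$p[!res$analyzable] <- NA_real_
  res$p_B <- ifelse(res$analyzable, pmin(1, res$p * M_t), NA_real_)
  res$var_i <- dataset$variants$id[res$i]
  res$var_j <- dataset$variants$id[res$j]
  res <- res[, c("pair_id", "i", "j", "var_i", "var_j", "C", "p", "p_B",
                 "analyzable")]
  ord <- order(ifelse(is.na(res$p), Inf, res$p), res$pair_id)
  res <- res[head(ord, top), , drop = FALSE]
  rownames(res) <- NULL
  structure(list(results = res, M = sum(admissible), M_t = M_t,
                 n_pairs_total = M_all),
            class = "vpairs_result")
}

#' @export
print.vpairs_result <- function(x, ...) {
  cat("variant-pair interaction scan:", format(x$n_pairs_total), "pairs,",
      format(x$M), "admissible,", format(x$M_t), "analyzable (M_t)\n")
  print(utils::head(x$results, 5))
  invisible(x)
}

# 3x3 known-genotype tables for a pair, or NULL when a group (or the
# combined table) has no fully-typed individual.
pair_3x3_tables <- function(gcase, gctrl, i, j) {
  tc <- tabulate(gcase[, i] * 4L + gcase[, j] + 1L, nbins = 16L)
  tt <- tabulate(gctrl[, i] * 4L + gctrl[, j] + 1L, nbins = 16L)
  c3 <- matrix(tc, 4L, 4L, byrow = TRUE)[1:3, 1:3]
  t3 <- matrix(tt, 4L, 4L, byrow = TRUE)[1:3, 1:3]
  if (sum(c3) == 0 || sum(t3) == 0) return(NULL)
  list(case = c3, ctrl = t3)
}

# Split the pair-id range, run do_chunk on each, and bind; chunk boundaries
# never change the per-pair statistics, so results are worker-invariant.
run_partitioned <- function(M, workers, do_chunk) {
  ranges <- Filter(function(r) r[1] <= r[2], partition_pairs(M, workers))
  chunks <- if (workers > 1 && .Platform$OS.type != "windows") {
    parallel::mclapply(ranges, do_chunk, mc.cores = workers)
  } else {
    lapply(ranges, do_chunk)
  }
  do.call(rbind, chunks)
}

#' Genotype-pattern drill-down for one variant pair
#'
#' For each of the nine genotype pairs at variants `i` and `j`, builds the
#' 2x2 phenotype-by-presence table from known-genotype totals and reports
#' counts, support, confidence, and Haldane odds ratios, sorted by OR'
#' descending (ties by genotype pair).
#'
#' @param dataset a [genotype_dataset].
#' @param i,j distinct variant indices.
#' @return Data frame with 9 rows: `g_i`, `g_j` (genotype codes 0/1/2),
#'   `a`, `b`, `c`, `d`, `support`, `confidence`, `OR`, `OR_prime`.
#' @export
pairsnps_report <- function(dataset, i, j) {
  ct <- crosstab_pair(dataset, i, j)
  case_known <- sum(ct$case3x3)
  ctrl_known <- sum(ct$ctrl3x3)
  g <- expand.grid(g_j = 0:2, g_i = 0:2)[, c("g_i", "g_j")]
  out <- data.frame(
    g_i = g$g_i, g_j = g$g_j,
    a = ct$case3x3[cbind(g$g_i + 1, g$g_j + 1)],
    c = ct$ctrl3x3[cbind(g$g_i + 1, g$g_j + 1)]
  )
  out$b <- case_known - out$a
  out$d <- ctrl_known - out$c
  out$support <- out$a + out$c
  out$confidence <- ifelse(out$support > 0, out$a / out$support, NA_real_)
  ors <- mapply(function(a, b, c, d) unlist(haldane_or(two_by_two(a, b, c, d))),
                out$a, out$b, out$c, out$d)
  out$OR <- ors["OR", ]
  out$OR_prime <- ors["OR_prime", ]
  out <- out[order(-out$OR_prime, out$g_i, out$g_j),
             c("g_i", "g_j", "a", "b", "c", "d", "support", "confidence",
               "OR", "OR_prime")]
  rownames(out) <- NULL
  out
}
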