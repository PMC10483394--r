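# Sequential numbering of variant pairs, closed-form inversion of pair ids,
# chromosome filtering, and deterministic partitioning across workers.
#
# Pairs are numbered 1..M (M = N(N-1)/2) in nested-loop order:
# (1,2), (1,3), ..., (1,N), (2,3), ..., (N-1,N).

#' Number of variant pairs
#' @param N number of variants.
#' @return `N * (N - 1) / 2`.
#' @export
n_pairs <- function(N) as.double(N) * (N - 1) / 2

#' Pair id of a variant pair
#'
#' @param i,j variant indices with `i < j`.
#' @param N number of variants.
#' @return The sequential pair id in 1..`n_pairs(N)`.
#' @export
index_from_pair <- function(i, j, N) {
  if (any(i >= j) || any(i < 1) || any(j > N)) {
    stop("require 1 <= i < j <= N", call. = FALSE)
  }
  unname((i - 1) * N - i * (i - 1) / 2 + (j - i))
}

#' Variant pair of a pair id
#'
#' Closed-form inversion of the sequential pair numbering via the triangular
#' root, with an integer correction step to absorb floating-point error at
#' block boundaries.
#'
#' @param k pair id(s) in 1..`n_pairs(N)`.
#' @param N number of variants.
#' @return A two-column matrix of `(i, j)` with `i < j`.
#' @export
pair_from_index <- function(k, N) {
  M <- n_pairs(N)
  if (any(k < 1) || any(k > M)) {
    stop("pair id out of range 1..", format(M, scientific = FALSE),
         call. = FALSE)
  }
  k <- as.double(k)
  # count r pairs back from the last: blocks from the end have sizes 1, 2, ...
  r <- M - k
  q <- floor((sqrt(8 * r + 1) - 1) / 2)
  q <- q - (q * (q + 1) / 2 > r)            # floating-point guard
  q <- q + ((q + 1) * (q + 2) / 2 <= r)
  i <- N - 1 - q
  j <- N - (r - q * (q + 1) / 2)
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Partition the pair-id range across workers
#'
#' Splits 1..M into `t` contiguous ranges: the first `t - 1` ranges have
#' size `ceiling(M / t)` and the last takes the remainder (possibly empty).
#'
#' @param M number of pairs.
#' @param t number of workers (>= 1).
#' @return A list of `t` integer vectors `c(from, to)`; an empty range has
#'   `from > to`.
#' @export
partition_pairs <- function(M, t) {
  if (t < 1) stop("worker count must be >= 1", call. = FALSE)
  if (M < 0) stop("M must be >= 0", call. = FALSE)
  chunk <- ceiling(M / t)
  lapply(seq_len(t), function(w) {
    from <- (w - 1) * chunk + 1
    to <- min(w * chunk, M)
    c(from = from, to = to)
  })
}

#' Chromosome admissibility predicate for variant pairs
#'
#' @param dataset a [genotype_dataset].
#' @param cross_chrom_only when `TRUE`, only pairs whose variants lie on
#'   different chromosomes are admissible (string comparison of labels).
#' @return A function `f(i, j)` returning a logical.
#' @export
chromosome_mask <- function(dataset, cross_chrom_only = FALSE) {
  if (!cross_chrom_only) return(function(i, j) rep(TRUE, length(i)))
  chrom <- dataset$variants$chrom
  function(i, j) chrom[i] != chrom[j]
}
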