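# Shared fixtures and independent oracles.

# 3x3 case/control genotype tables of the worked AMD example
# (rows: genotype at the first variant, cols: at the second; codes 0/1/2).
amd_case_3x3 <- function() {
  matrix(c(1L, 0L, 10L, 5L, 26L, 28L, 5L, 16L, 5L), 3, 3, byrow = TRUE)
}
amd_ctrl_3x3 <- function() {
  matrix(c(2L, 11L, 0L, 4L, 10L, 4L, 0L, 4L, 15L), 3, 3, byrow = TRUE)
}

# Expand a pair of 3x3 count tables into a 2-variant dataset whose
# cross-tabulation reproduces them exactly; variants on chromosomes 6 and 9.
dataset_from_3x3 <- function(case3x3, ctrl3x3,
                             ids = c("v1", "v2"), chrom = c("6", "9")) {
  expand <- function(tab) {
    g <- matrix(integer(0), ncol = 2)
    for (gi in 0:2) for (gj in 0:2) {
      k <- tab[gi + 1, gj + 1]
      if (k > 0) g <- rbind(g, matrix(rep(c(gi, gj), k), ncol = 2,
                                      byrow = TRUE))
    }
    g
  }
  gc <- expand(case3x3)
  gt <- expand(ctrl3x3)
  geno <- rbind(gc, gt)
  colnames(geno) <- ids
  genotype_dataset(geno,
                   rep(c("case", "control"), c(nrow(gc), nrow(gt))),
                   data.frame(id = ids, chrom = chrom))
}

# Nested-loop pair enumeration, the oracle for pair_from_index.
loop_pairs <- function(N) {
  out <- matrix(0L, nrow = N * (N - 1) / 2, ncol = 2)
  r <- 0L
  for (i in 1:(N - 1)) for (j in (i + 1):N) {
    r <- r + 1L
    out[r, ] <- c(i, j)
  }
  out
}

# Independent Fisher oracle: hypergeometric pmf by ratio recurrence plus
# normalisation, then brute-force summation over all feasible tables.
fisher_oracle <- function(a, b, c, d, side) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  xs <- lo:hi
  w <- numeric(length(xs))
  w[1] <- 1
  if (length(xs) > 1) {
    for (q in 2:length(xs)) {
      x <- xs[q - 1]
      w[q] <- w[q - 1] * (r1 - x) * (c1 - x) / ((x + 1) * (r2 - c1 + x + 1))
    }
  }
  pr <- w / sum(w)
  obs <- which(xs == a)
  switch(side,
         F2 = sum(pr[xs >= a]),
         F1 = sum(pr[xs <= a]),
         F3 = sum(pr[pr <= pr[obs] * (1 + 1e-7)]))
}

# Independent bit-level decoder of a SNP-major bed file (per the published
# 2-bit encoding), deliberately written byte-by-byte, unlike the package's
# vectorized rawToBits path.
decode_bed_oracle <- function(path, n_ind, n_var) {
  raw <- readBin(path, "raw", n = file.size(path))
  stopifnot(identical(raw[1:3], as.raw(c(0x6c, 0x1b, 0x01))))
  body <- raw[-(1:3)]
  bpv <- ceiling(n_ind / 4)
  map <- c(0L, NA_integer_, 1L, 2L)
  out <- matrix(NA_integer_, n_ind, n_var)
  for (v in seq_len(n_var)) {
    for (s in seq_len(n_ind)) {
      byte <- as.integer(body[(v - 1) * bpv + (s - 1) %/% 4 + 1])
      val <- bitwAnd(bitwShiftR(byte, 2L * ((s - 1) %% 4)), 3L)
      out[s, v] <- map[val + 1]
    }
  }
  out
}

# A small random dataset for round-trip and scan tests.
random_dataset <- function(seed, n_case = 30, n_ctrl = 30, n_variants = 6,
                           missing_rate = 0.05) {
  simulate_genotypes(simulation_config(
    n_case = n_case, n_ctrl = n_ctrl, n_variants = n_variants,
    missing_rate = missing_rate, seed = seed))
}
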