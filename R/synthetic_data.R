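# Case-control genotype simulator: Hardy-Weinberg background variants, an
# optional planted digenic interaction driving disease odds, and MCAR
# missingness. Every scan in the package is testable against data with
# known structure.

#' Simulation configuration
#'
#' @param n_case,n_ctrl exact numbers of cases and controls.
#' @param n_variants number of biallelic variants.
#' @param maf_range lower/upper bounds of the per-variant minor-allele
#'   frequency, drawn uniformly (default 0.05-0.5).
#' @param n_chromosomes chromosomes assigned round-robin to variants
#'   (default 22, autosomes).
#' @param planted_pair optional planted interaction: a list with `i`, `j`
#'   (variant indices), `table` (3x3 positive matrix of disease-odds
#'   multipliers per genotype pair, e.g. from [pure_interaction_table()]),
#'   and optionally `maf` (length-2 MAFs for the two planted variants).
#' @param missing_rate fraction of genotype calls set missing, uniformly at
#'   random, independent of phenotype and genotype (default 0.02, a typical
#'   array-genotyping failure rate).
#' @param seed optional integer seed; the whole dataset is reproducible
#'   from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_case = 500, n_ctrl = 500, n_variants = 50,
                              maf_range = c(0.05, 0.5), n_chromosomes = 22,
                              planted_pair = NULL, missing_rate = 0.02,
                              seed = NULL) {
  if (n_case < 1 || n_ctrl < 1) stop("need cases and controls", call. = FALSE)
  if (any(maf_range <= 0) || any(maf_range > 0.5)) {
    stop("MAF bounds must be in (0, 0.5]", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(planted_pair)) {
    if (planted_pair$i < 1 || planted_pair$j < 1 ||
        planted_pair$i > n_variants || planted_pair$j > n_variants ||
        planted_pair$i == planted_pair$j) {
      stop("planted variant indices out of range", call. = FALSE)
    }
    if (any(planted_pair$table <= 0)) {
      stop("planted odds multipliers must be positive", call. = FALSE)
    }
  }
  structure(list(n_case = n_case, n_ctrl = n_ctrl, n_variants = n_variants,
                 maf_range = maf_range, n_chromosomes = n_chromosomes,
                 planted_pair = planted_pair, missing_rate = missing_rate,
                 seed = seed),
            class = "simulation_config")
}

hwe_probs <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

#' Simulate a case-control genotype dataset
#'
#' Background variants are drawn independently per individual under
#' Hardy-Weinberg proportions with per-variant MAF uniform in `maf_range`.
#' When a pair is planted, disease odds for an individual are a baseline
#' times the table entry for their genotype pair at the planted variants;
#' the baseline is tuned numerically so the expected case fraction matches
#' `n_case / (n_case + n_ctrl)`, and individuals are drawn by rejection
#' until exactly `n_case` cases and `n_ctrl` controls are collected.
#' Missingness is applied after phenotype assignment. Cases occupy the
#' first rows.
#'
#' @param config a [simulation_config()].
#' @return A [genotype_dataset].
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_case + config$n_ctrl
  nv <- config$n_variants
  mafs <- stats::runif(nv, config$maf_range[1], config$maf_range[2])
  pp <- config$planted_pair
  if (!is.null(pp) && !is.null(pp$maf)) {
    mafs[c(pp$i, pp$j)] <- pp$maf
  }

  geno <- matrix(NA_integer_, nrow = n, ncol = nv)
  for (v in seq_len(nv)) {
    geno[, v] <- sample(0:2, n, replace = TRUE, prob = hwe_probs(mafs[v]))
  }

  if (!is.null(pp) && !all(pp$table == 1)) {
    # disease odds per genotype pair; intercept hits the target case fraction
    R <- as.matrix(pp$table)
    w <- outer(hwe_probs(mafs[pp$i]), hwe_probs(mafs[pp$j]))
    target <- config$n_case / n
    f <- function(b) sum(w * stats::plogis(b + log(R))) - target
    b0 <- stats::uniroot(f, c(-30, 30))$root
    g1 <- integer(0); g2 <- integer(0); phen <- character(0)
    need_case <- config$n_case; need_ctrl <- config$n_ctrl
    while (need_case > 0 || need_ctrl > 0) {
      m <- 2L * (need_case + need_ctrl) + 32L
      d1 <- sample(0:2, m, replace = TRUE, prob = hwe_probs(mafs[pp$i]))
      d2 <- sample(0:2, m, replace = TRUE, prob = hwe_probs(mafs[pp$j]))
      pr <- stats::plogis(b0 + log(R[cbind(d1 + 1, d2 + 1)]))
      is_case <- stats::rbinom(m, 1, pr) == 1
      kc <- utils::head(which(is_case), need_case)
      kt <- utils::head(which(!is_case), need_ctrl)
      g1 <- c(g1, d1[kc], d1[kt]); g2 <- c(g2, d2[kc], d2[kt])
      phen <- c(phen, rep("case", length(kc)), rep("control", length(kt)))
      need_case <- need_case - length(kc)
      need_ctrl <- need_ctrl - length(kt)
    }
    ord <- order(phen != "case")  # cases first, controls after
    geno[, pp$i] <- g1[ord]
    geno[, pp$j] <- g2[ord]
  }
  phenotype <- rep(c("case", "control"), c(config$n_case, config$n_ctrl))

  if (config$missing_rate > 0) {
    geno[stats::runif(length(geno)) < config$missing_rate] <- NA_integer_
  }
  rownames(geno) <- paste0(ifelse(phenotype == "case", "case", "ctrl"),
                           seq_len(n))
  variants <- data.frame(
    id = paste0("v", seq_len(nv)),
    chrom = as.character(((seq_len(nv) - 1) %% config$n_chromosomes) + 1),
    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  colnames(geno) <- variants$id
  genotype_dataset(geno, phenotype, variants)
}

#' Pure-interaction odds-multiplier table
#'
#' Builds a 3x3 table of positive disease-odds multipliers for the genotype
#' pairs of two variants such that, weighted by Hardy-Weinberg genotype
#' frequencies at the given MAFs, every row has the same weighted mean and
#' every column has the same weighted mean: the planted effect is pure
#' interaction with no marginal (single-variant) effect. The construction
#' starts from a checkerboard of `strength` versus 1 and removes marginal
#' effects by alternately rescaling rows and columns to unit weighted mean
#' (weighted Sinkhorn iteration), which preserves the table's cross-ratios.
#'
#' @param strength ratio between the high and low cells of the initial
#'   checkerboard (> 0); 1 gives the all-ones null table.
#' @param maf1,maf2 minor-allele frequencies of the two variants.
#' @return A 3x3 positive matrix with equal HWE-weighted row means and
#'   equal HWE-weighted column means.
#' @export
pure_interaction_table <- function(strength, maf1, maf2) {
  if (strength <= 0) stop("strength must be positive", call. = FALSE)
  R <- outer(0:2, 0:2, function(i, j) ifelse((i + j) %% 2 == 0, strength, 1))
  w1 <- hwe_probs(maf1)
  w2 <- hwe_probs(maf2)
  for (iter in 1:1000) {
    rm <- as.vector(R %*% w2)
    R <- R / rm
    cm <- as.vector(w1 %*% R)
    R <- sweep(R, 2, cm, "/")
    if (max(abs(as.vector(R %*% w2) - 1)) < 1e-13) break
  }
  unname(R)
}
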