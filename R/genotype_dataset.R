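#' Case-control genotype dataset
#'
#' Container for a biallelic genotype matrix with a binary phenotype and
#' per-variant metadata. Genotypes are coded as allele-A2 dosage: 0 = A1/A1
#' homozygote, 1 = A1/A2 heterozygote, 2 = A2/A2 homozygote, `NA` = missing
#' call. Phenotypes are `"case"` or `"control"`.
#'
#' @param genotypes integer matrix, individuals in rows and variants in
#'   columns, values in `{0, 1, 2, NA}`.
#' @param phenotype character vector of `"case"`/`"control"`, one per row of
#'   `genotypes`.
#' @param variants data frame with one row per genotype column and columns
#'   `id` (unique variant identifier), `chrom` (chromosome label, compared as
#'   a plain string), and optionally `a1`, `a2` (allele labels).
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `genotypes`, `phenotype` and `variants`.
#' @export
genotype_dataset <- function(genotypes, phenotype, variants) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (is.null(variants$a1)) variants$a1 <- NA_character_
  if (is.null(variants$a2)) variants$a2 <- NA_character_
  variants$id <- as.character(variants$id)
  variants$chrom <- as.character(variants$chrom)
  phenotype <- tolower(as.character(phenotype))
  ds <- structure(
    list(genotypes = genotypes, phenotype = phenotype, variants = variants),
    class = "genotype_dataset"
  )
  validate_genotype_dataset(ds)
  ds
}

#' @rdname genotype_dataset
#' @param x a `genotype_dataset`.
#' @export
validate_genotype_dataset <- function(x) {
  g <- x$genotypes
  bad <- !is.na(g) & !(g %in% 0:2)
  if (any(bad)) {
    stop("genotype codes must be 0, 1, 2 or NA; found ",
         paste(unique(g[bad]), collapse = ", "), call. = FALSE)
  }
  if (length(x$phenotype) != nrow(g)) {
    stop("phenotype length (", length(x$phenotype),
         ") does not match number of individuals (", nrow(g), ")",
         call. = FALSE)
  }
  if (!all(x$phenotype %in% c("case", "control"))) {
    stop("phenotype values must be 'case' or 'control'", call. = FALSE)
  }
  if (!any(x$phenotype == "case") || !any(x$phenotype == "control")) {
    stop("dataset must contain at least one case and one control",
         call. = FALSE)
  }
  if (nrow(x$variants) != ncol(g)) {
    stop("variant metadata rows (", nrow(x$variants),
         ") do not match genotype columns (", ncol(g), ")", call. = FALSE)
  }
  if (anyDuplicated(x$variants$id)) {
    stop("duplicate variant ids: ",
         paste(unique(x$variants$id[duplicated(x$variants$id)]),
               collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$genotypes), "individuals (",
      sum(x$phenotype == "case"), "cases /",
      sum(x$phenotype == "control"), "controls ) x",
      ncol(x$genotypes), "variants\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = " "), "\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing genotype rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

n_cases <- function(x) sum(x$phenotype == "case")
n_controls <- function(x) sum(x$phenotype == "control")
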