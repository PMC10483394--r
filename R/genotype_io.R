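# PLINK binary (.bed/.bim/.fam) and TSV input, results output.
#
# .bed layout: magic bytes 0x6C 0x1B, third byte 0x01 for SNP-major storage.
# Each variant occupies ceiling(n/4) bytes; each byte packs four individuals,
# lowest-order bit pair first. Bit-pair values: 00 hom A1, 01 missing,
# 10 het, 11 hom A2.

BED_MAGIC <- as.raw(c(0x6c, 0x1b))

#' Read a PLINK binary fileset
#'
#' Reads `prefix.bed` / `prefix.bim` / `prefix.fam` into a
#' [genotype_dataset]. Only the SNP-major bed layout is supported. The fam
#' phenotype column is interpreted as 2 = case, 1 = control; individuals with
#' any other phenotype code (0, -9, ...) are dropped with a message.
#'
#' @param prefix path prefix of the fileset (no extension).
#' @return A [genotype_dataset]. Genotype code 0 is homozygous for the bim A1
#'   allele, 2 homozygous for A2.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  bim <- utils::read.table(paths[2], header = FALSE, sep = "",
                           colClasses = "character")
  if (ncol(bim) < 6) stop("malformed bim file: ", paths[2], call. = FALSE)
  fam <- utils::read.table(paths[3], header = FALSE, sep = "",
                           colClasses = "character")
  if (ncol(fam) < 6) stop("malformed fam file: ", paths[3], call. = FALSE)
  n_ind <- nrow(fam)
  n_var <- nrow(bim)

  con <- file(paths[1], "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 3L)
  if (length(header) < 3L || !identical(header[1:2], BED_MAGIC)) {
    stop("not a PLINK bed file (bad magic bytes): ", paths[1], call. = FALSE)
  }
  if (header[3] == as.raw(0x00)) {
    stop("individual-major bed layout is not supported: ", paths[1],
         call. = FALSE)
  }
  if (header[3] != as.raw(0x01)) {
    stop("unrecognized bed mode byte: ", paths[1], call. = FALSE)
  }
  bytes_per_var <- ceiling(n_ind / 4)
  body <- readBin(con, "raw", n = bytes_per_var * n_var)
  if (length(body) != bytes_per_var * n_var) {
    stop("bed file truncated: expected ", bytes_per_var * n_var,
         " data bytes, got ", length(body), call. = FALSE)
  }
  geno <- decode_bed_body(body, n_ind, n_var, bytes_per_var)

  pheno_code <- fam[[6]]
  keep <- pheno_code %in% c("1", "2")
  if (!all(keep)) {
    message(sum(!keep), " individual(s) dropped for non-case/control ",
            "phenotype codes")
  }
  geno <- geno[keep, , drop = FALSE]
  phenotype <- ifelse(pheno_code[keep] == "2", "case", "control")
  rownames(geno) <- fam[[2]][keep]
  colnames(geno) <- bim[[2]]
  genotype_dataset(
    geno, phenotype,
    data.frame(id = bim[[2]], chrom = bim[[1]], a1 = bim[[5]], a2 = bim[[6]],
               stringsAsFactors = FALSE)
  )
}

# Unpack 2-bit genotype codes; vectorized over the whole body.
decode_bed_body <- function(body, n_ind, n_var, bytes_per_var) {
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8L)
  # four bit pairs per byte, low pair first; value = low bit + 2 * high bit
  vals <- bits[c(1L, 3L, 5L, 7L), , drop = FALSE] +
    2L * bits[c(2L, 4L, 6L, 8L), , drop = FALSE]
  vals <- matrix(as.vector(vals), nrow = 4L * bytes_per_var, ncol = n_var)
  vals <- vals[seq_len(n_ind), , drop = FALSE]
  # 0 -> hom A1, 1 -> missing, 2 -> het, 3 -> hom A2
  out <- ifelse(vals == 1L, NA_integer_,
                ifelse(vals == 2L, 1L, ifelse(vals == 3L, 2L, 0L)))
  storage.mode(out) <- "integer"
  out
}

#' Write a PLINK binary fileset
#'
#' Writes a [genotype_dataset] as SNP-major `prefix.bed` plus `prefix.bim`
#' and `prefix.fam`. Inverse of [read_plink()].
#'
#' @param dataset a [genotype_dataset].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(dataset, prefix) {
  validate_genotype_dataset(dataset)
  g <- dataset$genotypes
  n_ind <- nrow(g)
  n_var <- ncol(g)
  # genotype code -> bit-pair value
  vals <- matrix(3L, nrow = n_ind, ncol = n_var)
  vals[is.na(g)] <- 1L
  vals[!is.na(g) & g == 0L] <- 0L
  vals[!is.na(g) & g == 1L] <- 2L
  bytes_per_var <- ceiling(n_ind / 4)
  padded <- matrix(0L, nrow = 4L * bytes_per_var, ncol = n_var)
  padded[seq_len(n_ind), ] <- vals
  lo <- padded %% 2L
  hi <- padded %/% 2L
  bits <- matrix(0L, nrow = 8L, ncol = bytes_per_var * n_var)
  for (k in 1:4) {
    bits[2L * k - 1L, ] <- lo[seq(k, nrow(padded), by = 4L), ]
    bits[2L * k, ] <- hi[seq(k, nrow(padded), by = 4L), ]
  }
  body <- packBits(as.raw(as.vector(bits)), type = "raw")

  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(c(BED_MAGIC, as.raw(0x01)), con)
  writeBin(body, con)
  close(con)

  v <- dataset$variants
  ind_id <- rownames(g)
  if (is.null(ind_id)) ind_id <- paste0("ind", seq_len(n_ind))
  utils::write.table(
    data.frame(v$chrom, v$id, 0L, seq_len(n_var),
               ifelse(is.na(v$a1), "A", v$a1),
               ifelse(is.na(v$a2), "B", v$a2)),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(ind_id, ind_id, 0L, 0L, 0L,
               ifelse(dataset$phenotype == "case", 2L, 1L)),
    paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read genotypes from the package TSV dialect
#'
#' The TSV dialect has a header row naming the columns: an individual id
#' column, a phenotype column (`case`/`control`, case-insensitive), then one
#' column per variant. Genotype cells are `0`, `1`, `2`, with `NA` or `-1`
#' for missing. Chromosome labels come either from a sidecar file
#' (tab-separated, columns `id`, `chrom` and optionally `a1`, `a2`) or are
#' embedded in variant ids as `"chrom:rest"`.
#'
#' @param path path to the TSV file.
#' @param variant_file optional path to the variant sidecar; defaults to
#'   `paste0(path, ".variants")` when that file exists.
#' @return A [genotype_dataset].
#' @export
read_genotypes_tsv <- function(path, variant_file = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", na.strings = NULL)
  if (nrow(tab) == 0 || ncol(tab) < 3) {
    stop("TSV must have a header plus at least one row and one variant ",
         "column: ", path, call. = FALSE)
  }
  ids <- tab[[1]]
  phen <- tolower(tab[[2]])
  bad_phen <- !(phen %in% c("case", "control"))
  if (any(bad_phen)) {
    stop("unknown phenotype token '", tab[[2]][which(bad_phen)[1]],
         "' at row ", which(bad_phen)[1], call. = FALSE)
  }
  var_ids <- colnames(tab)[-(1:2)]
  if (anyDuplicated(var_ids)) {
    stop("duplicate variant id in header: ",
         var_ids[duplicated(var_ids)][1], call. = FALSE)
  }
  cells <- as.matrix(tab[, -(1:2), drop = FALSE])
  geno <- matrix(NA_integer_, nrow = nrow(cells), ncol = ncol(cells))
  known <- cells %in% c("0", "1", "2")
  missing_tok <- cells %in% c("NA", "-1")
  bad <- which(!known & !missing_tok)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(cells))
    stop("unknown genotype token '", cells[bad[1]], "' at row ", rc[1],
         ", variant ", var_ids[rc[2]], call. = FALSE)
  }
  geno[known] <- as.integer(cells[known])
  rownames(geno) <- ids
  colnames(geno) <- var_ids

  if (is.null(variant_file) && file.exists(paste0(path, ".variants"))) {
    variant_file <- paste0(path, ".variants")
  }
  if (!is.null(variant_file)) {
    vt <- utils::read.table(variant_file, header = TRUE, sep = "\t",
                            colClasses = "character")
    m <- match(var_ids, vt$id)
    if (anyNA(m)) {
      stop("variant(s) absent from sidecar: ",
           paste(var_ids[is.na(m)], collapse = ", "), call. = FALSE)
    }
    variants <- data.frame(id = var_ids, chrom = vt$chrom[m],
                           a1 = if (is.null(vt$a1)) NA_character_ else vt$a1[m],
                           a2 = if (is.null(vt$a2)) NA_character_ else vt$a2[m],
                           stringsAsFactors = FALSE)
  } else {
    if (!all(grepl(":", var_ids, fixed = TRUE))) {
      stop("no variant sidecar found and variant ids do not embed a ",
           "chromosome as 'chrom:rest'", call. = FALSE)
    }
    variants <- data.frame(id = var_ids,
                           chrom = sub(":.*$", "", var_ids),
                           stringsAsFactors = FALSE)
  }
  genotype_dataset(geno, phen, variants)
}

#' Write genotypes in the package TSV dialect
#'
#' @param dataset a [genotype_dataset].
#' @param path output TSV path; the variant sidecar is written to
#'   `paste0(path, ".variants")`.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(dataset, path) {
  validate_genotype_dataset(dataset)
  g <- dataset$genotypes
  ids <- rownames(g)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(g)))
  cells <- matrix(as.character(g), nrow = nrow(g))
  cells[is.na(cells)] <- "NA"
  out <- data.frame(individual = ids, phenotype = dataset$phenotype,
                    cells, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("individual", "phenotype", dataset$variants$id)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$variants, paste0(path, ".variants"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write scan results as TSV
#'
#' Writes pair or pattern results tab-separated with a fixed header, rows
#' sorted ascending by p-value then by pair id, p-values in scientific
#' notation with six significant digits.
#'
#' @param results a data frame of results from [scan_variant_pairs()],
#'   [scan_genotype_pairs()] or [pairsnps_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  results <- as.data.frame(results)
  if (nrow(results) > 0 && "p" %in% names(results)) {
    p_key <- ifelse(is.na(results$p), Inf, results$p)
    ord <- order(p_key, if (!is.null(results$pair_id)) results$pair_id
                 else seq_len(nrow(results)))
    results <- results[ord, , drop = FALSE]
  }
  for (col in intersect(c("p", "p_B"), names(results))) {
    results[[col]] <- ifelse(is.na(results[[col]]), "NA",
                             sprintf("%.5e", results[[col]]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
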