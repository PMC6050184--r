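#' Genotype matrix container
#'
#' Holds a panel of biallelic SNPs as alternate-allele dosages. Rows are
#' individuals, columns are loci; dosage values are 0, 1, 2 or `NA` (missing
#' call). Each locus carries its chromosome, 1-based position and REF/ALT
#' nucleotides. A locus identifier groups SNPs that come from the same
#' sequenced read (`locus_ids` need not be unique across columns before
#' one-SNP-per-locus filtering; `snp_ids`, the column names, must be).
#'
#' @param dosage integer matrix, individuals x SNPs, values in {0,1,2,NA}.
#' @param individual_ids character vector, one per row.
#' @param snp_ids character vector of unique SNP identifiers, one per column.
#' @param chrom,pos chromosome name and 1-based position per SNP.
#' @param ref,alt single-nucleotide reference / alternate alleles per SNP.
#' @param locus_ids read/locus grouping identifier per SNP; defaults to
#'   `snp_ids` (every SNP its own locus).
#' @return An object of class `stockload_genotypes`.
#' @export
genotypes <- function(dosage, individual_ids, snp_ids, chrom, pos, ref, alt,
                      locus_ids = snp_ids) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(
    nrow(dosage) == length(individual_ids),
    ncol(dosage) == length(snp_ids),
    length(chrom) == ncol(dosage), length(pos) == ncol(dosage),
    length(ref) == ncol(dosage), length(alt) == ncol(dosage),
    length(locus_ids) == ncol(dosage)
  )
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique")
  bad <- !(dosage %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(individual_ids, snp_ids)
  structure(
    list(dosage = dosage,
         individual_ids = as.character(individual_ids),
         snp_ids = as.character(snp_ids),
         chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         locus_ids = as.character(locus_ids)),
    class = "stockload_genotypes")
}

#' @export
print.stockload_genotypes <- function(x, ...) {
  cat(sprintf("<stockload_genotypes> %d individuals x %d SNPs (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.stockload_genotypes <- function(x) dim(x$dosage)

## column subset keeping all per-locus metadata aligned
subset_snps <- function(g, keep) {
  genotypes(g$dosage[, keep, drop = FALSE], g$individual_ids,
            g$snp_ids[keep], g$chrom[keep], g$pos[keep],
            g$ref[keep], g$alt[keep], g$locus_ids[keep])
}

subset_individuals <- function(g, keep) {
  genotypes(g$dosage[keep, , drop = FALSE], g$individual_ids[keep],
            g$snp_ids, g$chrom, g$pos, g$ref, g$alt, g$locus_ids)
}

#' Read a VCF file into a genotype matrix
#'
#' Loads biallelic records from a VCF 4.x file as alternate-allele dosages.
#' Multi-allelic records (comma in ALT) are excluded and counted; missing GT
#' fields become `NA`. Phased and unphased separators are accepted.
#'
#' @param path path to an (optionally gzipped) VCF file with GT data.
#' @return A [genotypes()] object. The number of excluded multi-allelic
#'   records is attached as attribute `"n_multiallelic_excluded"`.
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2L) stop("VCF has no sample columns")
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  n_multi <- sum(multi)
  if (all(multi)) stop("no biallelic records in VCF")
  v@fix <- v@fix[!multi, , drop = FALSE]
  v@gt <- v@gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  gt <- vcfR::extract.gt(v, element = "GT")
  allele1 <- substr(gt, 1, 1)
  allele3 <- substr(gt, 3, 3)
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  called <- allele1 %in% c("0", "1") & allele3 %in% c("0", "1")
  dos[called] <- (allele1 == "1")[called] + (allele3 == "1")[called]
  dos <- t(dos)  # individuals x SNPs
  ids <- fix$ID
  if (is.null(ids) || anyNA(ids) || any(ids == ".")) {
    ids <- paste0(fix$CHROM, "_", fix$POS)
  }
  ## convention used by the simulator: ID "<locus>_<n>" groups SNPs per read
  loc <- sub("_[0-9]+$", "", ids)
  g <- genotypes(dos, colnames(gt), ids, fix$CHROM, as.integer(fix$POS),
                 fix$REF, fix$ALT, locus_ids = loc)
  attr(g, "n_multiallelic_excluded") <- n_multi
  g
}

#' Write a genotype matrix to a VCF file
#'
#' Emits a minimal plain-text VCF 4.2 with unphased GT fields, the inverse of
#' [read_genotype_table()].
#'
#' @param g a [genotypes()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=stockload",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$individual_ids), collapse = "\t")),
             con)
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = ncol(g$dosage), ncol = nrow(g$dosage))
  d <- t(g$dosage)  # SNPs x individuals
  gt[!is.na(d)] <- code[d[!is.na(d)] + 1L]
  body <- paste(g$chrom, g$pos, g$snp_ids, g$ref, g$alt, ".", "PASS", ".",
                "GT", sep = "\t")
  writeLines(paste(body, apply(gt, 1L, paste, collapse = "\t"), sep = "\t"),
             con)
  invisible(path)
}

#' Read lake metadata, population map and optional stocking matrix
#'
#' @param lake_path CSV with columns
#'   `lake_code,area_ha,latitude,longitude,altitude,stocked` (extra columns
#'   such as `region` or sample size are kept).
#' @param popmap_path CSV with columns `individual_id,lake_code`.
#' @param stocking_path optional CSV; first column sink lake codes, remaining
#'   columns source codes, entries stocked mass in kg.
#' @return A list with elements `lakes` (data frame), `popmap` (data frame)
#'   and `stocking` (numeric matrix or `NULL`).
#' @export
read_metadata <- function(lake_path, popmap_path, stocking_path = NULL) {
  lakes <- utils::read.csv(lake_path, stringsAsFactors = FALSE)
  need <- c("lake_code", "area_ha", "latitude", "longitude", "altitude", "stocked")
  miss <- setdiff(need, names(lakes))
  if (length(miss)) stop("lake table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(lakes$lake_code)) stop("duplicate lake codes")
  if (any(lakes$area_ha <= 0)) stop("lake areas must be strictly positive")
  if (any(abs(lakes$latitude) > 90)) stop("latitude outside [-90, 90]")
  lakes$stocked <- as.logical(lakes$stocked)

  popmap <- utils::read.csv(popmap_path, stringsAsFactors = FALSE)
  if (!all(c("individual_id", "lake_code") %in% names(popmap))) {
    stop("population map must have columns individual_id, lake_code")
  }
  unknown <- setdiff(popmap$lake_code, lakes$lake_code)
  if (length(unknown)) {
    stop("population map refers to unknown lake(s): ",
         paste(unknown, collapse = ", "))
  }

  stocking <- NULL
  if (!is.null(stocking_path)) {
    s <- utils::read.csv(stocking_path, stringsAsFactors = FALSE, check.names = FALSE)
    stocking <- as.matrix(s[, -1, drop = FALSE])
    rownames(stocking) <- s[[1]]
    if (any(stocking < 0)) stop("stocking masses must be non-negative")
    bad <- setdiff(rownames(stocking), lakes$lake_code)
    if (length(bad)) stop("stocking matrix sink(s) not in lake table: ",
                          paste(bad, collapse = ", "))
  }
  list(lakes = lakes, popmap = popmap, stocking = stocking)
}

popmap_factor <- function(g, pm) {
  idx <- match(g$individual_ids, pm$individual_id)
  if (anyNA(idx)) {
    stop("individuals missing from population map: ",
         paste(utils::head(g$individual_ids[is.na(idx)]), collapse = ", "))
  }
  factor(pm$lake_code[idx])
}

#' Remove individuals with excessive missingness
#'
#' @param g a [genotypes()] object.
#' @param max_missing maximum tolerated fraction of missing genotypes per
#'   individual; individuals strictly above it are removed (default 0.30).
#' @return Filtered [genotypes()]; removed ids in attribute `"removed"`.
#' @export
filter_individuals <- function(g, max_missing = 0.30) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  frac <- rowMeans(is.na(g$dosage))
  keep <- frac <= max_missing
  if (!any(keep)) stop("all individuals exceed the missingness threshold")
  out <- subset_individuals(g, keep)
  attr(out, "removed") <- g$individual_ids[!keep]
  out
}

#' Filter SNPs on per-population call rate, global MAF and locus uniqueness
#'
#' A SNP is retained when (in this order, for attrition accounting) its call
#' rate is at least `min_pop_call_rate` in every population, its global minor
#' allele frequency (over all non-missing genotypes pooled) is strictly above
#' `min_global_maf`, and — when `one_per_locus` — it is the lowest-position
#' SNP of its locus among survivors of the earlier filters.
#'
#' @param g a [genotypes()] object.
#' @param pm population map data frame (`individual_id`, `lake_code`).
#' @param min_pop_call_rate minimum within-population call rate (default 0.5,
#'   inclusive).
#' @param min_global_maf global MAF threshold (default 0.05, exclusive).
#' @param one_per_locus keep a single SNP per locus identifier? (default TRUE)
#' @return Filtered [genotypes()]; attribute `"attrition"` is a named count of
#'   SNPs removed by each filter (each SNP attributed to the first filter it
#'   fails).
#' @export
filter_snps <- function(g, pm, min_pop_call_rate = 0.5, min_global_maf = 0.05,
                        one_per_locus = TRUE) {
  pop <- popmap_factor(g, pm)
  called <- !is.na(g$dosage)
  ## per-population call rates: pops x SNPs
  cr <- rowsum(called + 0, pop) / as.vector(table(pop))
  pass_cr <- colSums(cr < min_pop_call_rate) == 0L
  p_global <- colSums(g$dosage, na.rm = TRUE) / (2 * colSums(called))
  maf <- pmin(p_global, 1 - p_global)
  pass_maf <- !is.na(maf) & maf > min_global_maf
  keep <- pass_cr & pass_maf
  n_cr <- sum(!pass_cr)
  n_maf <- sum(pass_cr & !pass_maf)
  n_dup <- 0L
  if (one_per_locus) {
    idx <- which(keep)
    ord <- idx[order(g$locus_ids[idx], g$pos[idx])]
    first <- ord[!duplicated(g$locus_ids[ord])]
    n_dup <- length(idx) - length(first)
    keep <- logical(length(keep))
    keep[first] <- TRUE
  }
  if (!any(keep)) {
    stop(sprintf(paste0("no SNPs retained (removed: %d call-rate, %d MAF, ",
                        "%d duplicate-locus)"), n_cr, n_maf, n_dup))
  }
  out <- subset_snps(g, which(keep))
  attr(out, "attrition") <- c(call_rate = n_cr, maf = n_maf,
                              duplicate_locus = n_dup)
  out
}
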