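## Side-chain category of each amino acid (one-letter code, incl. Sec = U):
## Pos/Neg charged, polar Uncharged, Hydrophobic, and the four singletons.
AA_CATEGORY <- c(
  R = "Pos", H = "Pos", K = "Pos",
  D = "Neg", E = "Neg",
  S = "Unc", T = "Unc", N = "Unc", Q = "Unc",
  A = "Hyd", V = "Hyd", I = "Hyd", L = "Hyd",
  M = "Hyd", F = "Hyd", Y = "Hyd", W = "Hyd",
  C = "Cys", U = "Sel", G = "Gly", P = "Pro")

#' Filter protein BLAST hits on alignment identity
#'
#' A hit is retained when it has at least `min_identities` identical amino
#' acids and a percent identity of at least `min_pct`. Defaults emulate
#' "25 of 26 possible" identities for an 80-bp query against a reference
#' transcriptome and a 95% identity floor.
#'
#' @param hits data frame with columns `locus_id`, `aligned_aa_length`,
#'   `aa_identities`, `percent_identity` (fraction), `ref_codon`, `alt_codon`
#'   and optionally `effect_score`.
#' @param min_identities minimum identical amino acids (default 25).
#' @param min_pct minimum percent identity as a fraction (default 0.95).
#' @return Retained rows; rejection counts in attribute `"rejections"`.
#' @export
filter_protein_hits <- function(hits, min_identities = 25, min_pct = 0.95) {
  stopifnot(all(hits$aa_identities <= hits$aligned_aa_length))
  ok_id <- hits$aa_identities >= min_identities
  ok_pct <- hits$percent_identity >= min_pct
  keep <- ok_id & ok_pct
  out <- hits[keep, , drop = FALSE]
  if (any(is.na(out$ref_codon) | is.na(out$alt_codon))) {
    stop("retained hit(s) lack ref/alt codons")
  }
  attr(out, "rejections") <- c(identities = sum(!ok_id),
                               percent_identity = sum(ok_id & !ok_pct))
  out
}

#' Classify the codon change of a single hit
#'
#' Translates reference and alternate codons under the standard genetic code
#' and reports synonymy, the amino-acid change and its side-chain category
#' change, both directed (`from->to`) and undirected (alphabetical pair).
#' Changes producing a stop codon are flagged `nonsense = TRUE` (they carry
#' no category class and are excluded from class ANOVAs).
#'
#' @param ref_codon,alt_codon ACGT triplets differing at exactly one position.
#' @return One-row data frame with columns `synonymy`, `aa_from`, `aa_to`,
#'   `cat_from`, `cat_to`, `directed_class`, `undirected_class`, `nonsense`.
#' @export
annotate_codon_change <- function(ref_codon, alt_codon) {
  ref_codon <- toupper(ref_codon); alt_codon <- toupper(alt_codon)
  if (!grepl("^[ACGT]{3}$", ref_codon) || !grepl("^[ACGT]{3}$", alt_codon)) {
    stop("codons must be ACGT triplets")
  }
  ndiff <- sum(strsplit(ref_codon, "")[[1]] != strsplit(alt_codon, "")[[1]])
  if (ndiff != 1L) stop("codons must differ at exactly one position (got ",
                        ndiff, ")")
  code <- Biostrings::GENETIC_CODE
  aa_from <- unname(code[ref_codon]); aa_to <- unname(code[alt_codon])
  nonsense <- aa_from == "*" || aa_to == "*"
  syn <- if (aa_from == aa_to) "synonymous" else "nonsynonymous"
  cat_from <- if (nonsense) NA_character_ else unname(AA_CATEGORY[aa_from])
  cat_to <- if (nonsense) NA_character_ else unname(AA_CATEGORY[aa_to])
  data.frame(
    synonymy = syn, aa_from = aa_from, aa_to = aa_to,
    cat_from = cat_from, cat_to = cat_to,
    directed_class = if (nonsense) NA_character_ else
      paste0(cat_from, "->", cat_to),
    undirected_class = if (nonsense) NA_character_ else
      paste(sort(c(cat_from, cat_to)), collapse = ":"),
    nonsense = nonsense, stringsAsFactors = FALSE)
}

#' Classify effect scores against a deleterious threshold
#'
#' Scores strictly below the threshold are deleterious, strictly above are
#' neutral; scores exactly at the threshold, or absent, are unclassified.
#'
#' @param score numeric vector of alignment-based effect scores (more
#'   negative = more damaging); `NA` allowed.
#' @param threshold deleterious cutoff (default -2.5).
#' @return Character vector in `{"deleterious", "neutral", "unclassified"}`.
#' @export
classify_effect <- function(score, threshold = -2.5) {
  out <- rep("unclassified", length(score))
  out[!is.na(score) & score < threshold] <- "deleterious"
  out[!is.na(score) & score > threshold] <- "neutral"
  out
}

#' Annotate a table of protein hits
#'
#' Convenience wrapper: filters hits, classifies each codon change and each
#' effect score, and returns one annotation row per retained hit. Synonymous
#' changes and nonsense changes are never scored deleterious.
#'
#' @param hits see [filter_protein_hits()]; must carry `effect_score`.
#' @param threshold deleterious effect-score cutoff (default -2.5).
#' @param min_identities,min_pct passed to [filter_protein_hits()].
#' @return Data frame with the hit columns plus the [annotate_codon_change()]
#'   columns and `effect_class`.
#' @export
annotate_loci <- function(hits, threshold = -2.5, min_identities = 25,
                          min_pct = 0.95) {
  kept <- filter_protein_hits(hits, min_identities, min_pct)
  ann <- do.call(rbind, Map(annotate_codon_change, kept$ref_codon, kept$alt_codon))
  rownames(ann) <- NULL
  out <- cbind(kept, ann)
  out$effect_class <- ifelse(
    out$synonymy == "synonymous" | out$nonsense, "unclassified",
    classify_effect(out$effect_score, threshold))
  rownames(out) <- NULL
  out
}

#' Deleterious-load ratio
#'
#' The proportion of deleterious SNPs present in a population divided by its
#' proportion of polymorphic SNPs.
#'
#' @param del_proportion fraction of all deleterious SNPs present locally.
#' @param n_polymorphic locally polymorphic SNP count.
#' @param n_total panel size.
#' @return `del_proportion / (n_polymorphic / n_total)`.
#' @export
load_ratio <- function(del_proportion, n_polymorphic, n_total) {
  stopifnot(n_total > 0, all(n_polymorphic <= n_total))
  if (any(n_polymorphic == 0)) stop("load ratio undefined with no polymorphic SNPs")
  del_proportion / (n_polymorphic / n_total)
}

#' Per-population deleterious-load statistics
#'
#' The deleterious allele at each deleterious SNP is the globally minor
#' allele (pooled over all populations), so its local frequency can reach 1.
#' A deleterious SNP is "present" in a population when that allele has local
#' frequency > 0.
#'
#' @param g a [genotypes()] object (the filtered panel).
#' @param pm population map data frame.
#' @param ann annotation table from [annotate_loci()] with a `locus_id`
#'   matching `g$snp_ids`.
#' @param div matching [diversity_summary()] output (for the polymorphic-SNP
#'   denominator of the load ratio).
#' @return A list: `summary` (one row per lake: `del_present`,
#'   `del_proportion`, `load_ratio`, `mean_del_maf`, `n_fixed_del`,
#'   `prop_lowfreq`) and `class_freqs` (long data frame of local
#'   globally-minor-allele frequencies by SNP class, for group tests;
#'   present SNPs only).
#' @export
load_summary <- function(g, pm, ann, div) {
  cls <- ifelse(ann$effect_class == "deleterious", "deleterious",
         ifelse(ann$synonymy == "synonymous", "synonymous",
         ifelse(ann$effect_class == "neutral", "nonsynonymous_neutral",
                NA_character_)))
  ann_use <- data.frame(snp_id = ann$locus_id, class = cls,
                        stringsAsFactors = FALSE)
  ann_use <- ann_use[!is.na(ann_use$class) & ann_use$snp_id %in% g$snp_ids, ]
  del_ids <- ann_use$snp_id[ann_use$class == "deleterious"]
  if (!length(del_ids)) stop("no deleterious loci present in the panel")

  af <- allele_frequencies(g, pm)
  idx <- match(ann_use$snp_id, g$snp_ids)
  called <- colSums(!is.na(g$dosage[, idx, drop = FALSE]))
  p_glob <- colSums(g$dosage[, idx, drop = FALSE], na.rm = TRUE) / (2 * called)
  ## local frequency of the globally minor allele (ties resolved to ALT)
  minor_is_alt <- p_glob <= 0.5
  f_min <- af$freq[, idx, drop = FALSE]
  f_min[, !minor_is_alt] <- 1 - f_min[, !minor_is_alt, drop = FALSE]

  is_del <- ann_use$class == "deleterious"
  n_del_total <- sum(is_del)
  pops <- af$populations
  rows <- lapply(seq_along(pops), function(i) {
    fd <- f_min[i, is_del]
    present <- !is.na(fd) & fd > 0
    dp <- sum(present) / n_del_total
    drow <- div[div$lake_code == pops[i], ]
    data.frame(
      lake_code = pops[i],
      del_present = sum(present),
      del_proportion = dp,
      load_ratio = if (nrow(drow) && drow$n_polymorphic > 0)
        load_ratio(dp, drow$n_polymorphic, ncol(g$dosage)) else NA_real_,
      mean_del_maf = if (any(present)) mean(fd[present]) else NA_real_,
      n_fixed_del = sum(present & fd == 1),
      prop_lowfreq = if (any(present)) mean(fd[present] < 0.05) else NA_real_,
      stringsAsFactors = FALSE)
  })
  cf <- do.call(rbind, lapply(seq_along(pops), function(i) {
    f <- f_min[i, ]
    keep <- !is.na(f) & f > 0
    if (!any(keep)) return(NULL)
    data.frame(lake_code = pops[i], snp_id = ann_use$snp_id[keep],
               class = ann_use$class[keep], freq = f[keep],
               stringsAsFactors = FALSE)
  }))
  rownames(cf) <- NULL
  list(summary = do.call(rbind, rows), class_freqs = cf)
}
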