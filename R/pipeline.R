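#' Packaged lake metadata table
#'
#' The 24-lake survey metadata (lake code, surface area, sample size,
#' region, coordinates, altitude, stocking status) shipped with the package.
#'
#' @return Data frame with one row per lake.
#' @export
stockload_lakes <- function() {
  utils::read.csv(system.file("extdata", "lake_table.csv",
                              package = "stockload"),
                  stringsAsFactors = FALSE)
}

#' Packaged per-population summary table
#'
#' The printed per-lake genetic summary (genotype ratio, nucleotide
#' diversity, observed/expected heterozygosity for all and neutral SNPs,
#' polymorphic SNP counts, deleterious proportion, load ratio, mean
#' deleterious-allele MAF and fixed deleterious-allele counts) for the same
#' 24 lakes, on a panel of 4,982 SNPs.
#'
#' @return Data frame with one row per lake.
#' @export
stockload_population_summary <- function() {
  utils::read.csv(system.file("extdata", "population_summary.csv",
                              package = "stockload"),
                  stringsAsFactors = FALSE)
}

#' Group statistics from a printed per-population summary
#'
#' Recomputes, from per-lake summary columns alone (no genotypes), the
#' stocked-versus-unstocked contrasts: the Welch t test on the
#' deleterious-load ratio, the Welch t test and group means of neutral
#' expected heterozygosity, panel medians of the deleterious proportion and
#' nucleotide diversity, group means of the deleterious-allele MAF, and the
#' number of populations carrying at least one fixed deleterious allele.
#'
#' @param summary per-lake summary as in [stockload_population_summary()].
#' @param lakes lake table giving `lake_code` and logical `stocked`.
#' @param panel_size total SNP panel size behind the summary (default 4982).
#' @return A list of the statistics above.
#' @export
printed_summary_tests <- function(summary = stockload_population_summary(),
                                  lakes = stockload_lakes(),
                                  panel_size = 4982) {
  stocked <- lakes$stocked[match(summary$lake_code, lakes$lake_code)]
  if (anyNA(stocked)) stop("summary lakes missing from the lake table")
  st <- summary[stocked, ]; un <- summary[!stocked, ]
  list(
    load_ratio_test = welch_t_test(st$load_ratio, un$load_ratio),
    he_neutral_test = welch_t_test(st$he_neutral, un$he_neutral),
    median_del_proportion = stats::median(summary$del_proportion),
    median_pi = stats::median(summary$pi),
    mean_del_maf_stocked = mean(st$mean_del_maf),
    mean_del_maf_unstocked = mean(un$mean_del_maf),
    n_pops_with_fixed_del = sum(summary$n_fixed_del >= 1),
    load_ratio_check = data.frame(
      lake_code = summary$lake_code,
      recomputed = load_ratio(summary$del_proportion,
                              summary$n_polymorphic, panel_size),
      printed = summary$load_ratio, stringsAsFactors = FALSE))
}

#' Run the full analysis end to end
#'
#' Executes filtering, diversity, pairwise FST, deleterious-load statistics,
#' group tests, the spatial eigenvector basis and the constrained
#' ordinations on one dataset, in that order. All stochastic stages
#' (bootstraps, permutations, k-means restarts) derive from `seed`.
#'
#' @param g a [genotypes()] object (raw panel).
#' @param popmap population map data frame.
#' @param lakes lake table data frame.
#' @param stocking optional sink x source stocking mass matrix; when absent
#'   the stocking ordinations are skipped.
#' @param hits optional protein-hit table (see [annotate_loci()]); when
#'   absent the deleterious-load sections are skipped.
#' @param outlier_loci SNP ids to exclude from the "neutral" subset (e.g. a
#'   selection-outlier list produced elsewhere).
#' @param max_missing,min_pop_call_rate,min_global_maf filtering thresholds.
#' @param effect_threshold deleterious effect-score cutoff (default -2.5).
#' @param sites_per_locus pi scaling (see [diversity_summary()]).
#' @param n_boot FST bootstrap replicates.
#' @param n_perm ordination permutations.
#' @param min_axis_var PCo-axis retention fraction (default 0.05).
#' @param alpha forward-selection threshold.
#' @param k_max DAPC maximum cluster count.
#' @param seed integer seed.
#' @return A list of class `stockload_report` with elements `filtering`,
#'   `diversity`, `load`, `fst_neutral`, `fst_deleterious`, `group_tests`,
#'   `mem`, `ordination` and `provenance`. Sections whose inputs are absent
#'   are `NULL` and named in `provenance$skipped`.
#' @export
run_full_analysis <- function(g, popmap, lakes, stocking = NULL, hits = NULL,
                              outlier_loci = character(0),
                              max_missing = 0.30, min_pop_call_rate = 0.5,
                              min_global_maf = 0.05, effect_threshold = -2.5,
                              sites_per_locus = 1, n_boot = 100,
                              n_perm = 199, min_axis_var = 0.05,
                              alpha = 0.05, k_max = 30, seed = 1) {
  skipped <- character(0)
  n0 <- dim(g)
  g <- filter_individuals(g, max_missing)
  g <- filter_snps(g, popmap, min_pop_call_rate, min_global_maf,
                   one_per_locus = TRUE)
  popmap <- popmap[popmap$individual_id %in% g$individual_ids, ]
  filtering <- list(n_individuals_in = n0[1], n_snps_in = n0[2],
                    n_individuals = nrow(g$dosage), n_snps = ncol(g$dosage),
                    attrition = attr(g, "attrition"))

  neutral_ids <- setdiff(g$snp_ids, outlier_loci)
  g_neutral <- subset_snps(g, match(neutral_ids, g$snp_ids))
  div <- diversity_summary(g, popmap, sites_per_locus)
  div_neutral <- diversity_summary(g_neutral, popmap, sites_per_locus)
  fst_neutral <- pairwise_fst(g_neutral, popmap, n_boot = n_boot, seed = seed)
  stocked <- lakes$stocked[match(div$lake_code, lakes$lake_code)]

  load <- fst_del <- NULL
  tests <- list(
    he_neutral = welch_t_test(div_neutral$He[stocked],
                              div_neutral$He[!stocked]))
  if (!is.null(hits)) {
    ann <- annotate_loci(hits, threshold = effect_threshold)
    load <- load_summary(g, popmap, ann, div)
    del_ids <- intersect(ann$locus_id[ann$effect_class == "deleterious"],
                         g$snp_ids)
    if (length(del_ids) >= 2) {
      fst_del <- pairwise_fst(subset_snps(g, match(del_ids, g$snp_ids)),
                              popmap, n_boot = n_boot, seed = seed)
    }
    ls <- load$summary
    lstocked <- lakes$stocked[match(ls$lake_code, lakes$lake_code)]
    tests$load_ratio <- welch_t_test(ls$load_ratio[lstocked],
                                     ls$load_ratio[!lstocked])
    cf <- load$class_freqs
    cf$stocked <- lakes$stocked[match(cf$lake_code, lakes$lake_code)]
    maf_tests <- list()
    for (grp in c(TRUE, FALSE)) {
      sub <- cf[cf$stocked == grp, ]
      nm <- if (grp) "stocked" else "unstocked"
      maf_tests[[paste0(nm, "_del_vs_nonsyn")]] <- tryCatch(
        welch_t_test(sub$freq[sub$class == "deleterious"],
                     sub$freq[sub$class == "nonsynonymous_neutral"]),
        error = function(e) NULL)
      maf_tests[[paste0(nm, "_del_vs_syn")]] <- tryCatch(
        welch_t_test(sub$freq[sub$class == "deleterious"],
                     sub$freq[sub$class == "synonymous"]),
        error = function(e) NULL)
    }
    tests$maf_class <- maf_tests
    del_cf <- cf[cf$class == "deleterious", ]
    tests$manova <- tryCatch(
      population_effect_manova(del_cf$freq, del_cf$lake_code),
      error = function(e) NULL)
    scored <- ann[!is.na(ann$effect_score) & !ann$nonsense &
                    ann$synonymy == "nonsynonymous", ]
    tests$anova_directed <- tryCatch(
      one_way_anova(scored$effect_score, scored$directed_class),
      error = function(e) NULL)
    tests$anova_undirected <- tryCatch(
      one_way_anova(scored$effect_score, scored$undirected_class),
      error = function(e) NULL)
  } else skipped <- c(skipped, "deleterious_load")

  ## spatial basis and ordinations
  ord_lakes <- lakes[match(rownames(fst_neutral$theta), lakes$lake_code), ]
  xyz <- geo_to_meters(ord_lakes$latitude, ord_lakes$longitude,
                       ord_lakes$altitude)
  mem <- build_dbmem(xyz)
  mem_mat <- mem$vectors
  rownames(mem_mat) <- ord_lakes$lake_code

  ordination <- list()
  pc_fst <- pcoa(fst_dist(fst_neutral), min_axis_var)
  y_fst <- pc_fst$scores[, pc_fst$retained, drop = FALSE]
  if (!is.null(stocking)) {
    sm <- matrix(0, nrow(ord_lakes), ncol(stocking),
                 dimnames = list(ord_lakes$lake_code, colnames(stocking)))
    common <- intersect(rownames(stocking), rownames(sm))
    sm[common, ] <- stocking[common, ]
    hel <- hellinger_stocking(sm, ord_lakes)
    spca <- pca_broken_stick(hel)
    stock_pcs <- spca$scores[, spca$retained, drop = FALSE]
    if (ncol(stock_pcs) == 0) stock_pcs <- spca$scores[, 1, drop = FALSE]
    colnames(stock_pcs) <- paste0("stockPC", seq_len(ncol(stock_pcs)))
    candidates <- c(
      stats::setNames(lapply(seq_len(ncol(stock_pcs)),
                             function(j) stock_pcs[, j, drop = FALSE]),
                      colnames(stock_pcs)),
      stats::setNames(lapply(seq_len(ncol(mem_mat)),
                             function(j) mem_mat[, j, drop = FALSE]),
                      colnames(mem_mat)))
    run_rda_block <- function(y, label) {
      fs <- forward_select(y, candidates, alpha = alpha, n_perm = n_perm,
                           seed = seed)
      sel_stock <- grep("^stockPC", fs$selected, value = TRUE)
      sel_mem <- grep("^MEM", fs$selected, value = TRUE)
      xsel <- if (length(fs$selected))
        do.call(cbind, lapply(fs$selected, function(nm) candidates[[nm]]))
      global <- if (!is.null(xsel))
        rda_fit(y, xsel, NULL, n_perm = n_perm, seed = seed)
      partial <- if (length(sel_stock))
        partial_rda(y, do.call(cbind, lapply(sel_stock, \(nm) candidates[[nm]])),
                    if (ncol(mem_mat)) mem_mat else NULL,
                    n_perm = n_perm, seed = seed)
      list(response = label, selection = fs, global = global,
           partial_stocking = partial)
    }
    ordination$fst_neutral <- run_rda_block(y_fst, "neutral FST PCo axes")
    gi <- impute_by_population(g_neutral, popmap)
    dq <- dapc(gi, k_max = k_max, seed = seed)
    qlake <- apply(dq$Q, 2, function(col)
      tapply(col, popmap$lake_code[match(gi$individual_ids,
                                         popmap$individual_id)], mean))
    qlake <- qlake[rownames(mem_mat), , drop = FALSE]
    if (sum(apply(qlake, 2, stats::var)) > 1e-12) {
      qpca <- pca_broken_stick(qlake)
      keepq <- qpca$proportion >= min_axis_var
      y_q <- qpca$scores[, keepq, drop = FALSE]
      if (ncol(y_q) == 0) y_q <- qpca$scores[, 1, drop = FALSE]
      ordination$q_matrix <- c(run_rda_block(y_q, "Q-matrix PC axes"),
                               list(dapc_K = dq$K))
    } else {
      ## a single inferred cluster leaves no admixture structure to explain
      ordination$q_matrix <- list(dapc_K = dq$K)
      skipped <- c(skipped, "q_matrix_ordination")
    }
    if (!is.null(fst_del)) {
      pc_del <- pcoa(fst_dist(fst_del), min_axis_var)
      y_del <- pc_del$scores[, pc_del$retained, drop = FALSE]
      if (ncol(y_del) == 0) y_del <- pc_del$scores[, 1, drop = FALSE]
      ordination$fst_deleterious <- run_rda_block(y_del,
                                                  "deleterious FST PCo axes")
    }
  } else skipped <- c(skipped, "stocking_ordination")

  structure(list(
    filtering = filtering,
    diversity = list(all = div, neutral = div_neutral),
    load = load, fst_neutral = fst_neutral, fst_deleterious = fst_del,
    group_tests = tests, mem = mem, pcoa_fst = pc_fst,
    ordination = ordination,
    provenance = list(seed = seed, n_boot = n_boot, n_perm = n_perm,
                      thresholds = list(max_missing = max_missing,
                                        min_pop_call_rate = min_pop_call_rate,
                                        min_global_maf = min_global_maf,
                                        effect_threshold = effect_threshold,
                                        min_axis_var = min_axis_var,
                                        alpha = alpha),
                      skipped = skipped)),
    class = "stockload_report")
}

#' Write report tables to a directory
#'
#' Serializes the per-lake tables as TSV and the scalar statistics as JSON.
#'
#' @param report a [run_full_analysis()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(report$diversity$all, "diversity_summary.tsv")
  wt(report$diversity$neutral, "diversity_summary_neutral.tsv")
  if (!is.null(report$load)) wt(report$load$summary, "load_summary.tsv")
  utils::write.table(report$fst_neutral$theta, file.path(dir, "fst_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  wt(report$fst_neutral$pairs, "fst_pairs.tsv")
  rda_summ <- function(b) if (!is.null(b)) list(
    selected = b$selection$selected,
    global = if (!is.null(b$global)) b$global[c("r_squared", "adj_r_squared",
                                                "pseudo_f", "p_value", "max_vif")],
    partial_stocking = if (!is.null(b$partial_stocking))
      b$partial_stocking[c("r_squared", "adj_r_squared", "pseudo_f", "p_value")])
  jsonlite::write_json(list(
    filtering = report$filtering,
    group_tests = report$group_tests,
    ordination = lapply(report$ordination, rda_summ),
    provenance = report$provenance),
    file.path(dir, "rda_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(dir)
}
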