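#!/usr/bin/env Rscript

## Runs the full analysis end to end on the synthetic survey written by
## 02_simulate_survey.R (re-reading it from disk through the standard
## formats), and reports the survey-level findings: diversity and FST,
## deleterious-load contrasts, and the stocking/space ordinations.

suppressMessages(library(stockload))

if (!file.exists("results/synthetic_survey/genotypes.vcf")) {
  stop("run analysis/02_simulate_survey.R first")
}

g <- read_genotype_table("results/synthetic_survey/genotypes.vcf")
md <- read_metadata("results/synthetic_survey/lakes.csv",
                    "results/synthetic_survey/popmap.csv",
                    "results/synthetic_survey/stocking.csv")
hits <- read.delim("results/synthetic_survey/annotations.tsv",
                   stringsAsFactors = FALSE)

rep <- run_full_analysis(g, md$popmap, md$lakes, md$stocking, hits,
                         n_boot = 200, n_perm = 499, seed = 1)
write_report(rep, "results/synthetic_analysis")

cat("== Filtering ==\n")
cat(sprintf("%d/%d individuals, %d/%d SNPs retained (removed: %s)\n",
            rep$filtering$n_individuals, rep$filtering$n_individuals_in,
            rep$filtering$n_snps, rep$filtering$n_snps_in,
            paste(names(rep$filtering$attrition), rep$filtering$attrition,
                  collapse = ", ")))

th <- rep$fst_neutral$theta[upper.tri(rep$fst_neutral$theta)]
cat(sprintf("\n== Differentiation ==\npairwise theta: %.3f-%.3f (mean %.3f)\n",
            min(th), max(th), mean(th)))

cat("\n== Deleterious load ==\n")
lakes <- md$lakes
ls <- rep$load$summary
st <- lakes$stocked[match(ls$lake_code, lakes$lake_code)]
cat(sprintf("mean load ratio: stocked %.3f, unstocked %.3f\n",
            mean(ls$load_ratio[st]), mean(ls$load_ratio[!st])))
with(rep$group_tests$load_ratio, cat(sprintf(
  "Welch t = %.3f, df = %.2f, p = %.4f\n", t, df, p)))
with(rep$group_tests$he_neutral, cat(sprintf(
  "neutral He stocked %.3f vs unstocked %.3f (p = %.4f)\n",
  mean_x, mean_y, p)))
if (!is.null(rep$group_tests$manova)) {
  with(rep$group_tests$manova, cat(sprintf(
    "population effect on deleterious frequencies: F = %.2f, df = %d, p = %.3g\n",
    F, df_effect, p)))
}

cat("\n== Ordination ==\n")
for (nm in names(rep$ordination)) {
  b <- rep$ordination[[nm]]
  if (is.null(b$selection)) next
  if (!length(b$selection$selected)) {
    lg <- b$selection$log
    cat(sprintf(
      "%s: no predictor selected (best %s, adjusted p = %.2f > 0.05)\n",
      nm, lg$candidate[1], lg$p_adjusted[1]))
    next
  }
  cat(sprintf("%s: selected {%s}; global R2adj = %.3f (p = %.3f)",
              nm, paste(b$selection$selected, collapse = ", "),
              b$global$adj_r_squared, b$global$p_value))
  if (!is.null(b$partial_stocking)) {
    cat(sprintf("; stocking | space R2 = %.3f (p = %.3f)",
                b$partial_stocking$r_squared, b$partial_stocking$p_value))
  }
  cat("\n")
}
cat(sprintf("db-MEM axes: %d (truncation %.0f m)\n",
            ncol(rep$mem$vectors), rep$mem$truncation))
cat("\nwrote results/synthetic_analysis/\n")
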