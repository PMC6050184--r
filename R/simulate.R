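#' Configuration for the synthetic lake-survey generator
#'
#' Defaults emulate the sampling design of a 24-lake survey in which 9 lakes
#' were never stocked and 15 received supplementation at least once:
#' isolated demes founded from a shared ancestral pool, strong drift over
#' `generations` generations, three SNP classes (synonymous /
#' nonsynonymous-neutral / deleterious under purifying selection), and
#' stocking as directional admixture pulses whose migrant numbers derive
#' from a mass matrix through `fish_per_kg`.
#'
#' @param n_lakes number of demes (default 24).
#' @param n_unstocked how many of them are never stocked (default 9).
#' @param ne effective diploid size (default 80). With
#'   `scale_ne_with_area` this is the size of a median-area (900 ha) lake
#'   and per-lake sizes follow `ne * sqrt(area / 900)`, clamped to
#'   [20, 500]; otherwise a scalar or per-lake vector used as is.
#' @param scale_ne_with_area scale deme size with lake area? (default TRUE;
#'   diversity correlates with lake size in the surveyed system, and the
#'   resulting spread of drift intensities is what produces the survey's
#'   wide pairwise-FST range).
#' @param generations generations since founding (default 100).
#' @param n_loci number of unlinked biallelic loci (default 1000).
#' @param class_fractions named fractions (`synonymous`,
#'   `nonsynonymous_neutral`, `deleterious`) summing to 1; the default
#'   0.60/0.19/0.21 mirrors the composition of a transcriptome-anchored SNP
#'   panel.
#' @param s,h selection and dominance coefficients of the deleterious allele
#'   (fitness 1, 1-hs, 1-s; defaults 0.05 and 0.25).
#' @param founder founder allele-frequency law: `"beta"` (Beta(0.5, 2.5),
#'   skewed toward rare alternate alleles like a site-frequency spectrum) or
#'   `"uniform"`.
#' @param fish_per_kg conversion from stocked mass to migrant individuals
#'   (default 2).
#' @param sample_n individuals sampled per lake at the end (scalar or
#'   vector; default 24).
#' @param missing_rate uniform genotype missingness injected in the sample
#'   (default 0.10).
#' @param seed integer seed governing every random draw.
#' @return A list of class `stockload_sim_config`.
#' @export
simulation_config <- function(n_lakes = 24, n_unstocked = 9, ne = 80,
                              scale_ne_with_area = TRUE,
                              generations = 100, n_loci = 1000,
                              class_fractions = c(synonymous = 0.60,
                                                  nonsynonymous_neutral = 0.19,
                                                  deleterious = 0.21),
                              s = 0.05, h = 0.25, founder = c("beta", "uniform"),
                              fish_per_kg = 2, sample_n = 24,
                              missing_rate = 0.10, seed = 1) {
  stopifnot(abs(sum(class_fractions) - 1) < 1e-8, s >= 0, s <= 1,
            h >= 0, h <= 1, n_unstocked <= n_lakes, missing_rate >= 0,
            missing_rate < 1)
  structure(list(
    n_lakes = n_lakes, n_unstocked = n_unstocked,
    ne = rep_len(ne, n_lakes), scale_ne_with_area = scale_ne_with_area,
    generations = generations, n_loci = n_loci,
    class_fractions = class_fractions, s = s, h = h,
    founder = match.arg(founder), fish_per_kg = fish_per_kg,
    sample_n = rep_len(sample_n, n_lakes), missing_rate = missing_rate,
    seed = seed), class = "stockload_sim_config")
}

## all ordered codon pairs differing at one position, with synonymy flags
codon_neighbor_pairs <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- names(Biostrings::GENETIC_CODE)
  out <- list()
  for (cd in codons) {
    sp <- strsplit(cd, "")[[1]]
    for (pos in 1:3) for (b in setdiff(bases, sp[pos])) {
      alt <- sp; alt[pos] <- b
      out[[length(out) + 1L]] <- c(cd, paste(alt, collapse = ""))
    }
  }
  m <- do.call(rbind, out)
  aa1 <- Biostrings::GENETIC_CODE[m[, 1]]
  aa2 <- Biostrings::GENETIC_CODE[m[, 2]]
  data.frame(ref_codon = m[, 1], alt_codon = m[, 2],
             synonymous = aa1 == aa2, nonsense = aa1 == "*" | aa2 == "*",
             stringsAsFactors = FALSE)
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

## one generation of viability selection on the deleterious-allele frequency q
select_deleterious <- function(q, s, h) {
  waa <- 1 - s; wah <- 1 - h * s
  wbar <- q^2 * waa + 2 * q * (1 - q) * wah + (1 - q)^2
  (q^2 * waa + q * (1 - q) * wah) / wbar
}

#' Simulate a full synthetic lake-survey dataset
#'
#' Forward Wright-Fisher per lake at allele-frequency resolution (the
#' linkage-equilibrium limit of multiplicative viability selection):
#' founders are binomially drawn from a shared ancestral pool, each
#' generation applies the deterministic selection recursion at deleterious
#' loci followed by binomial resampling of 2Ne gametes, and scheduled
#' stocking pulses replace a fraction `n_migrants / Ne` of the sink gene
#' pool with allele frequencies drawn from the source. Individuals are
#' sampled under Hardy-Weinberg at the end, with uniform missingness.
#'
#' @param cfg a [simulation_config()].
#' @return A list of class `stockload_dataset`: `genotypes`
#'   ([genotypes()] with missing calls), `popmap`, `lakes`, `stocking`
#'   (sink x source kg matrix), `hits` (protein-hit/annotation input table
#'   with effect scores), `schedule`, and `manifest` (true parameters:
#'   per-locus class, founder frequencies, final per-lake frequencies).
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  nl <- cfg$n_loci
  n_lakes <- cfg$n_lakes
  lake_codes <- sprintf("L%02d", seq_len(n_lakes))
  stocked <- c(rep(FALSE, cfg$n_unstocked), rep(TRUE, n_lakes - cfg$n_unstocked))

  classes <- sample(rep(names(cfg$class_fractions),
                        times = round(cfg$class_fractions * nl))[seq_len(nl)])
  is_del <- classes == "deleterious"

  p0 <- switch(cfg$founder,
               beta = stats::rbeta(nl, 0.5, 2.5),
               uniform = stats::runif(nl))

  ## lake metadata: a regional survey footprint
  lakes <- data.frame(
    lake_code = lake_codes,
    area_ha = round(exp(stats::rnorm(n_lakes, log(900), 0.9))),
    latitude = round(stats::runif(n_lakes, 46, 50.5), 3),
    longitude = round(stats::runif(n_lakes, -79, -68), 3),
    altitude = round(stats::runif(n_lakes, 150, 500)),
    stocked = stocked,
    region = "synthetic", stringsAsFactors = FALSE)
  if (cfg$scale_ne_with_area) {
    cfg$ne <- pmin(500, pmax(20, round(cfg$ne * sqrt(lakes$area_ha / 900))))
  }

  ## stocking mass matrix and pulse schedule (sources are a subset of lakes,
  ## mostly large unstocked ones plus one stocked source)
  n_sources <- min(6, n_lakes - 1)
  source_codes <- lake_codes[order(-lakes$area_ha)][seq_len(n_sources)]
  stocking <- matrix(0, n_lakes, n_sources,
                     dimnames = list(lake_codes, source_codes))
  schedule <- list()
  for (i in which(stocked)) {
    k <- sample(1:2, 1)
    srcs <- sample(setdiff(source_codes, lake_codes[i]), k)
    for (src in srcs) {
      kg <- round(stats::runif(1, 10, 50), 1)
      stocking[i, src] <- stocking[i, src] + kg
      gen <- sample(seq(ceiling(cfg$generations / 2), cfg$generations), 1)
      n_mig <- min(max(1L, round(kg * cfg$fish_per_kg)),
                   floor(cfg$ne[i] / 2))
      schedule[[length(schedule) + 1L]] <- data.frame(
        sink = lake_codes[i], source = src, generation = gen,
        n_migrants = n_mig, stringsAsFactors = FALSE)
    }
  }
  schedule <- do.call(rbind, schedule)

  ## founding bottleneck from the shared pool
  freq <- matrix(NA_real_, n_lakes, nl, dimnames = list(lake_codes, NULL))
  for (i in seq_len(n_lakes)) {
    freq[i, ] <- stats::rbinom(nl, 2 * cfg$ne[i], p0) / (2 * cfg$ne[i])
  }
  pulses_by_gen <- if (is.null(schedule)) list() else
    split(schedule, schedule$generation)
  for (g in seq_len(cfg$generations)) {
    for (i in seq_len(n_lakes)) {
      q <- freq[i, ]
      q[is_del] <- select_deleterious(q[is_del], cfg$s, cfg$h)
      freq[i, ] <- stats::rbinom(nl, 2 * cfg$ne[i], q) / (2 * cfg$ne[i])
    }
    pg <- pulses_by_gen[[as.character(g)]]
    if (!is.null(pg)) for (k in seq_len(nrow(pg))) {
      sink <- pg$sink[k]; src <- pg$source[k]
      m <- pg$n_migrants[k] / cfg$ne[match(sink, lake_codes)]
      pmig <- stats::rbinom(nl, 2 * pg$n_migrants[k], freq[src, ]) /
        (2 * pg$n_migrants[k])
      freq[sink, ] <- (1 - m) * freq[sink, ] + m * pmig
    }
  }
  if (any(!is.finite(freq))) stop("simulation produced undefined frequencies")

  ## HWE sampling of individuals, then uniform missingness
  total_n <- sum(cfg$sample_n)
  dos <- matrix(NA_integer_, total_n, nl)
  ids <- character(total_n)
  popmap <- data.frame(individual_id = character(total_n),
                       lake_code = character(total_n), stringsAsFactors = FALSE)
  row <- 0L
  for (i in seq_len(n_lakes)) {
    ni <- cfg$sample_n[i]
    block <- matrix(stats::rbinom(ni * nl, 2, rep(freq[i, ], each = ni)), ni, nl)
    dos[row + seq_len(ni), ] <- block
    ids[row + seq_len(ni)] <- sprintf("%s_ind%02d", lake_codes[i], seq_len(ni))
    popmap$lake_code[row + seq_len(ni)] <- lake_codes[i]
    row <- row + ni
  }
  popmap$individual_id <- ids
  if (cfg$missing_rate > 0) {
    dos[stats::runif(length(dos)) < cfg$missing_rate] <- NA_integer_
  }
  snp_ids <- sprintf("LOC%04d_1", seq_len(nl))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nl, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  g <- genotypes(dos, ids, snp_ids,
                 chrom = rep("chr1", nl), pos = seq_len(nl) * 100L,
                 ref = ref, alt = alt,
                 locus_ids = sub("_1$", "", snp_ids))

  ## protein-hit table: every locus gets an alignment-quality pair of codons
  ## matching its class, plus an effect score for nonsynonymous loci
  pairs <- codon_neighbor_pairs()
  syn_pool <- pairs[pairs$synonymous & !pairs$nonsense, ]
  nonsyn_pool <- pairs[!pairs$synonymous & !pairs$nonsense, ]
  pick <- function(pool, n) pool[sample(nrow(pool), n, replace = TRUE), ]
  hits <- data.frame(locus_id = snp_ids, aligned_aa_length = 26L,
                     aa_identities = 26L, percent_identity = 1.0,
                     ref_codon = NA_character_, alt_codon = NA_character_,
                     effect_score = NA_real_, stringsAsFactors = FALSE)
  i_syn <- classes == "synonymous"
  i_nn <- classes == "nonsynonymous_neutral"
  cp <- pick(syn_pool, sum(i_syn))
  hits$ref_codon[i_syn] <- cp$ref_codon; hits$alt_codon[i_syn] <- cp$alt_codon
  cp <- pick(nonsyn_pool, sum(i_nn))
  hits$ref_codon[i_nn] <- cp$ref_codon; hits$alt_codon[i_nn] <- cp$alt_codon
  hits$effect_score[i_nn] <- rtrunc_norm(sum(i_nn), 0, 1, lower = -2.5)
  cp <- pick(nonsyn_pool, sum(is_del))
  hits$ref_codon[is_del] <- cp$ref_codon; hits$alt_codon[is_del] <- cp$alt_codon
  hits$effect_score[is_del] <- rtrunc_norm(sum(is_del), -5, 1.2, upper = -2.5)

  structure(list(
    genotypes = g, popmap = popmap, lakes = lakes, stocking = stocking,
    hits = hits, schedule = schedule,
    manifest = list(config = unclass(cfg), classes = classes,
                    founder_freq = p0, final_freq = freq)),
    class = "stockload_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Emits `genotypes.vcf`, `lakes.csv`, `popmap.csv`, `stocking.csv` and
#' `manifest.json` under `dir`.
#'
#' @param ds a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotype_vcf(ds$genotypes, file.path(dir, "genotypes.vcf"))
  utils::write.csv(ds$lakes, file.path(dir, "lakes.csv"), row.names = FALSE)
  utils::write.csv(ds$popmap, file.path(dir, "popmap.csv"), row.names = FALSE)
  utils::write.csv(data.frame(lake_code = rownames(ds$stocking),
                              ds$stocking, check.names = FALSE),
                   file.path(dir, "stocking.csv"), row.names = FALSE)
  utils::write.table(ds$hits, file.path(dir, "annotations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- ds$manifest
  manifest$final_freq <- NULL  # bulky; regenerate from the seed if needed
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
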