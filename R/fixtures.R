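# A complete self-contained demo dataset with known ground truth, written in
# exactly the formats the analysis modules read.

#' Build a synthetic SNP panel
#'
#' SNPs are spread over chromosomes 1-22 with positions on a regular 10-kb
#' lattice plus jitter, so 5-Mb jackknife blocks contain ~500 SNPs each.
#'
#' @param n_snps total SNP count.
#' @param seed integer seed.
#' @return a [snp_panel()].
#' @export
synthetic_panel <- function(n_snps, seed = 1L) {
  with_seed(seed, {
    chrom <- sort(rep_len(1:22, n_snps))
    pos <- integer(n_snps)
    for (ch in 1:22) {
      idx <- which(chrom == ch)
      pos[idx] <- sort(1e4 * seq_along(idx) + sample.int(5e3, length(idx), replace = TRUE))
    }
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, n_snps, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), "")
    snp_panel(sprintf("rs%07d", seq_len(n_snps)), as.character(chrom), pos, ref, alt)
  })
}

#' Simulate a full multi-sample genotype table
#'
#' Two focal samples with the requested relationship, plus unrelated reference
#' individuals from the same population and an outgroup population drawn from
#' an independent frequency vector.
#'
#' @param model a [population_model()] for the target population.
#' @param relationship relationship of the two focal samples (see
#'   [simulate_pair()]).
#' @param n_refs number of unrelated reference individuals.
#' @param n_outgroup number of outgroup individuals.
#' @param missing_rate per-call missingness for all samples.
#' @param contam_rate,error_rate applied to the focal pair only.
#' @param seed integer seed.
#' @return list: `table` ([genotype_table()]; samples `focalA`, `focalB`,
#'   `ref<i>`, `out<i>`), `freqs`, `outgroup_freqs`, `pair` (the
#'   `simulated_pair`), `populations` (sample -> population map).
#' @export
simulate_case_table <- function(model, relationship = "same_individual",
                                n_refs = 10L, n_outgroup = 4L,
                                missing_rate = 0.1, contam_rate = 0,
                                error_rate = 0, seed = 1L) {
  n <- model$n_snps
  seeds <- derive_seeds(seed, 4L + n_refs + n_outgroup)
  freqs <- draw_population(model)
  out_freqs <- with_seed(seeds[1], runif(n, 0.05, 0.95))
  pair <- simulate_pair(freqs, relationship,
                        error_rate = error_rate, contam_rate = contam_rate,
                        missing_rate = missing_rate, seed = seeds[2])
  one_sample <- function(p, s) {
    sp <- simulate_pair(p, "unrelated", missing_rate = missing_rate, seed = s)
    sp$genotypes_a
  }
  refs <- vapply(seq_len(n_refs),
                 function(i) one_sample(freqs, seeds[4L + i]), integer(n))
  outs <- vapply(seq_len(n_outgroup),
                 function(i) one_sample(out_freqs, seeds[4L + n_refs + i]), integer(n))
  samples <- c("focalA", "focalB",
               sprintf("ref%02d", seq_len(n_refs)),
               sprintf("out%02d", seq_len(n_outgroup)))
  calls <- cbind(pair$genotypes_a, pair$genotypes_b, refs, outs)
  colnames(calls) <- samples
  panel <- synthetic_panel(n, seed = seeds[3])
  populations <- setNames(c("FOCAL", "FOCAL",
                            rep("REF", n_refs), rep("OUTGROUP", n_outgroup)),
                          samples)
  list(table = genotype_table(panel, calls, samples),
       freqs = freqs, outgroup_freqs = out_freqs, pair = pair,
       populations = populations)
}

#' Simulate a base pileup over a SNP panel for one diploid individual
#'
#' Depth per site is Poisson; each base is drawn uniformly from the
#' individual's two alleles, given a Phred quality from `quality_range`, and
#' assigned read-end offsets uniform in `[0, read_length - 1]` (offsets sum
#' to `read_length - 1` per base).
#'
#' @param panel a [snp_panel()].
#' @param diploid n x 2 integer matrix of allele copies (0 = ref, 1 = alt).
#' @param mean_depth Poisson mean coverage per site (sites drawn at depth 0
#'   are absent from the pileup).
#' @param quality_range inclusive Phred range to sample from.
#' @param read_length nominal read length used for the end offsets.
#' @param seed integer seed.
#' @return a `pileup` data.frame (see [read_pileup()]).
#' @export
simulate_pileup <- function(panel, diploid, mean_depth = 1,
                            quality_range = c(20L, 40L), read_length = 50L,
                            seed = 1L) {
  stopifnot(inherits(panel, "snp_panel"), nrow(diploid) == nrow(panel))
  with_seed(seed, {
    depth <- rpois(nrow(panel), mean_depth)
    keep <- which(depth > 0L)
    rows <- lapply(keep, function(i) {
      d <- depth[i]
      alleles <- diploid[i, sample(c(1L, 2L), d, replace = TRUE)]
      bases <- ifelse(alleles == 0L, panel$ref_allele[i], panel$alt_allele[i])
      off5 <- sample.int(read_length, d, replace = TRUE) - 1L
      list(bases = bases,
           quals = sample(quality_range[1]:quality_range[2], d, replace = TRUE),
           off5 = off5, off3 = read_length - 1L - off5)
    })
    out <- data.frame(chromosome = panel$chromosome[keep],
                      position = panel$position[keep],
                      ref = panel$ref_allele[keep],
                      stringsAsFactors = FALSE)
    out$bases <- lapply(rows, `[[`, "bases")
    out$quals <- lapply(rows, `[[`, "quals")
    out$off5 <- lapply(rows, `[[`, "off5")
    out$off3 <- lapply(rows, `[[`, "off3")
    class(out) <- c("pileup", "data.frame")
    out
  })
}

#' Materialize a complete demo dataset on disk
#'
#' Writes every input [run_case()] needs: an EIGENSTRAT triplet, a pileup, a
#' per-chromosome coverage CSV, a radiocarbon date table, a calibration
#' curve, an isotope table, and a ready-to-run `config.json`. All ground
#' truth (relationship, sex, true age, contamination fractions) is chosen
#' here and recorded in the returned list.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param relationship truth for the focal pair.
#' @param n_snps panel size (default 10000).
#' @param true_age_bp true conventional age of the individual (default 13950
#'   14C yr BP, a terminal-Pleistocene age).
#' @param contamination_fractions modern-carbon fractions injected into the
#'   second and third date (default `c(0.014, 0.007)`).
#' @return list with the paths written and the ground truth, invisibly.
#' @export
write_demo_fixtures <- function(dir, seed = 1L,
                                relationship = "same_individual",
                                n_snps = 10000L,
                                true_age_bp = 13950,
                                contamination_fractions = c(0.014, 0.007)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(seed, 8L)
  model <- population_model(n_snps, seed = seeds[1])
  case <- simulate_case_table(model, relationship = relationship, seed = seeds[2])
  prefix <- file.path(dir, "demo")
  write_eigenstrat(case$table, prefix, populations = unname(case$populations))

  pop_path <- file.path(dir, "populations.tsv")
  write.table(data.frame(sample = names(case$populations),
                         population = unname(case$populations)),
              pop_path, sep = "\t", quote = FALSE, row.names = FALSE)

  # damage-bearing reads -> pileup over the first panel SNPs
  reads <- simulate_damaged_reads(2000, 50, damage_rate_5p = 0.081,
                                  seed = seeds[3])
  reads_path <- file.path(dir, "reads.tsv")
  write.table(reads, reads_path, sep = "\t", quote = FALSE, row.names = FALSE)

  pileup_path <- file.path(dir, "pileup.tsv")
  write_pileup(simulate_pileup(case$table$panel, case$pair$truth$diploid_a,
                               mean_depth = 0.5, seed = seeds[3]),
               pileup_path)

  cov_a <- simulate_coverage("XY", depth = 0.14, seed = seeds[4])
  cov_b <- simulate_coverage("XY", depth = 0.10, seed = seeds[5])
  cov_path <- file.path(dir, "coverage.csv")
  write.table(data.frame(sample = rep(c("focalA", "focalB"), each = 24L),
                         chromosome = rep(names(cov_a), 2L),
                         depth = c(unname(cov_a), unname(cov_b))),
              cov_path, sep = ",", quote = FALSE, row.names = FALSE)

  # three dates of one true age: one clean, two with modern contamination
  d1 <- simulate_c14(true_age_bp, 0, measurement_sigma = 45,
                     seed = seeds[6], lab_code = "LAB-0001")
  d2 <- simulate_c14(true_age_bp, contamination_fractions[1],
                     measurement_sigma = 55, seed = seeds[7], lab_code = "LAB-0002")
  d3 <- simulate_c14(true_age_bp, contamination_fractions[2],
                     measurement_sigma = 35, seed = seeds[8], lab_code = "LAB-0003")
  dates_path <- file.path(dir, "dates.csv")
  write.table(data.frame(lab_code = c(d1$lab_code, d2$lab_code, d3$lab_code),
                         age_bp = round(c(d1$age_bp, d2$age_bp, d3$age_bp)),
                         sigma = c(d1$sigma, d2$sigma, d3$sigma)),
              dates_path, sep = ",", quote = FALSE, row.names = FALSE)

  curve_path <- file.path(dir, "curve.14c")
  curve <- synthetic_identity_curve(0, 25000, by = 5, sigma_curve = 15)
  writeLines(c("# synthetic identity calibration curve (cal BP, 14C age, 1 sigma)",
               sprintf("%d,%d,%d", curve$cal_bp, curve$mu, curve$sigma_curve)),
             curve_path)

  iso_path <- file.path(dir, "isotopes.csv")
  iso <- rbind(
    data.frame(specimen = "femur", group = "consumer", element = "bone",
               d13c = -18.5, d15n = 13.5, pct_c = 41.2, pct_n = 14.9),
    data.frame(specimen = "rib", group = "consumer", element = "bone",
               d13c = -18.4, d15n = 13.0, pct_c = 40.5, pct_n = 14.6),
    data.frame(specimen = "molar", group = "consumer", element = "dentine",
               d13c = -19.5, d15n = 11.5, pct_c = 39.8, pct_n = 14.2),
    data.frame(specimen = sprintf("herb%02d", 1:8), group = "herbivore",
               element = "bone",
               d13c = c(-19.8, -20.1, -19.5, -20.4, -19.2, -19.9, -20.2, -19.6),
               d15n = c(1.2, 1.7, 2.1, 2.5, 4.2, 4.7, 5.3, 5.8),
               pct_c = c(42.1, 40.8, 41.5, 39.9, 41.0, 42.3, 40.2, 41.8),
               pct_n = c(15.1, 14.6, 14.9, 14.3, 14.8, 15.2, 14.5, 15.0)))
  write.table(iso, iso_path, sep = ",", quote = FALSE, row.names = FALSE)

  config <- list(
    eigenstrat_prefix = prefix,
    sample_a = "focalA", sample_b = "focalB",
    reference_samples = sprintf("ref%02d", 1:10),
    outgroup_samples = sprintf("out%02d", 1:4),
    reads = reads_path,
    pileup = pileup_path,
    coverage = cov_path,
    dates = dates_path,
    curve = curve_path,
    isotopes = iso_path,
    consumer_specimens = c("femur", "rib"),
    prey_group = "herbivore",
    element_pairs = list(c("femur", "rib"), c("femur", "molar")),
    seed = seed
  )
  config_path <- file.path(dir, "config.json")
  jsonlite::write_json(config, config_path, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(dir = dir, config = config_path,
                 truth = list(relationship = relationship, sex = "XY",
                              true_age_bp = true_age_bp,
                              contamination_fractions = contamination_fractions,
                              damage_rate_5p = 0.081,
                              expected_heterozygosity = model$expected_heterozygosity)))
}
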