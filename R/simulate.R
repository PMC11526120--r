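#' Define a low-heterozygosity population model
#'
#' A population is described by an allele-frequency law; its expected
#' heterozygosity `E[2p(1-p)]` is derived analytically from the law. The
#' default frequency law avoids monomorphic loci so that mismatch-rate ratios
#' stay well defined. Small effective population sizes, as inferred for
#' post-glacial Italian hunter-gatherers, correspond to laws concentrated near
#' the boundaries (low heterozygosity).
#'
#' @param n_snps number of SNP loci (>= 1).
#' @param freq_law a list describing the allele-frequency distribution:
#'   `list(family = "uniform", min =, max =)`, `list(family = "beta",
#'   shape1 =, shape2 =)` (rescaled into `(eps, 1-eps)` to avoid fixation), or
#'   `list(family = "fixed", p =)`.
#' @param seed integer seed used by [draw_population()].
#' @return an object of class `population_model` with fields `n_snps`,
#'   `freq_law`, `expected_heterozygosity`, `seed`.
#' @examples
#' m <- population_model(1000, seed = 1)
#' m$expected_heterozygosity
#' @export
population_model <- function(n_snps,
                             freq_law = list(family = "uniform", min = 0.05, max = 0.95),
                             seed = 1L) {
  stopifnot(is.numeric(n_snps), length(n_snps) == 1L, n_snps >= 1)
  n_snps <- as.integer(n_snps)
  het <- expected_heterozygosity(freq_law)
  structure(
    list(n_snps = n_snps, freq_law = freq_law,
         expected_heterozygosity = het, seed = seed),
    class = "population_model"
  )
}

# E[2p(1-p)] = 2(E[p] - E[p^2]) under the stated law, in closed form.
expected_heterozygosity <- function(freq_law) {
  fam <- freq_law$family
  if (identical(fam, "fixed")) {
    p <- freq_law$p
    stopifnot(is.numeric(p), all(p > 0 & p < 1))
    return(mean(2 * p * (1 - p)))
  }
  if (identical(fam, "uniform")) {
    a <- freq_law$min; b <- freq_law$max
    stopifnot(is.numeric(a), is.numeric(b), a < b, a > 0, b < 1)
    m1 <- (a + b) / 2
    m2 <- (a^2 + a * b + b^2) / 3
    return(2 * (m1 - m2))
  }
  if (identical(fam, "beta")) {
    s1 <- freq_law$shape1; s2 <- freq_law$shape2
    stopifnot(is.numeric(s1), is.numeric(s2), s1 > 0, s2 > 0)
    eps <- freq_law$eps %||% 0.01
    # p = eps + (1 - 2 eps) q with q ~ Beta(s1, s2)
    m1q <- s1 / (s1 + s2)
    m2q <- s1 * (s1 + 1) / ((s1 + s2) * (s1 + s2 + 1))
    k <- 1 - 2 * eps
    m1 <- eps + k * m1q
    m2 <- eps^2 + 2 * eps * k * m1q + k^2 * m2q
    return(2 * (m1 - m2))
  }
  stop("unknown frequency-law family: ", fam)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw an allele-frequency vector from a population model
#'
#' @param model a [population_model()].
#' @return numeric vector of length `model$n_snps` with values in (0, 1);
#'   bit-reproducible under the model's seed.
#' @examples
#' draw_population(population_model(4, list(family = "fixed", p = 0.5)))
#' @export
draw_population <- function(model) {
  stopifnot(inherits(model, "population_model"))
  law <- model$freq_law
  n <- model$n_snps
  with_seed(model$seed, {
    p <- switch(law$family,
      fixed   = rep_len(law$p, n),
      uniform = runif(n, law$min, law$max),
      beta    = {
        eps <- law$eps %||% 0.01
        eps + (1 - 2 * eps) * stats::rbeta(n, law$shape1, law$shape2)
      },
      stop("unknown frequency-law family: ", law$family)
    )
    if (any(p <= 0 | p >= 1)) stop("invalid distribution parameters: frequencies must lie in (0,1)")
    p
  })
}

#' Simulate a pair of pseudo-haploid samples with known relationship
#'
#' Draws diploid genotypes under Hardy-Weinberg at the supplied frequencies,
#' then reduces each individual to pseudo-haploid form: at every locus one of
#' the two alleles is selected with equal probability, which is what makes the
#' expected mismatch rate of two observations of the *same* diploid genome
#' equal to half the unrelated baseline. Contamination replaces a call with a
#' draw from an independent population, error flips the call, and missingness
#' blanks it.
#'
#' @param freqs alt-allele frequency vector (the truth).
#' @param relationship one of `"same_individual"`, `"identical_twin"`,
#'   `"unrelated"`, `"first_degree"`. Same-individual and identical-twin pairs
#'   share one underlying diploid genotype; first-degree pairs share exactly
#'   one allele identical-by-descent per locus.
#' @param error_rate,contam_rate,missing_rate per-call probabilities in
#'   `[0, 1]`.
#' @param contam_freqs frequency vector of the contaminant population
#'   (defaults to an independent uniform redraw — a stand-in for modern human
#'   contamination).
#' @param seed integer seed.
#' @return list of class `simulated_pair` with haploid call vectors
#'   `genotypes_a`, `genotypes_b` (0 = ref, 1 = alt, `NA` = missing),
#'   `relationship`, and `truth` (diploid genotypes and the frequency vectors
#'   used).
#' @export
simulate_pair <- function(freqs, relationship,
                          error_rate = 0, contam_rate = 0,
                          contam_freqs = NULL, missing_rate = 0,
                          seed = 1L) {
  relationship <- match.arg(relationship,
    c("same_individual", "identical_twin", "unrelated", "first_degree"))
  stopifnot(is.numeric(freqs), all(freqs >= 0 & freqs <= 1))
  rates <- c(error_rate, contam_rate, missing_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  n <- length(freqs)

  with_seed(seed, {
    if (is.null(contam_freqs)) contam_freqs <- runif(n, 0.05, 0.95)
    stopifnot(length(contam_freqs) == n)

    # diploid truth: two allele columns per individual
    dip_a <- cbind(rbinom(n, 1L, freqs), rbinom(n, 1L, freqs))
    dip_b <- switch(relationship,
      same_individual = ,
      identical_twin  = dip_a,
      unrelated       = cbind(rbinom(n, 1L, freqs), rbinom(n, 1L, freqs)),
      first_degree    = {
        # one allele IBD from A (random chromosome), one fresh from the population
        shared <- dip_a[cbind(seq_len(n), sample(c(1L, 2L), n, replace = TRUE))]
        cbind(shared, rbinom(n, 1L, freqs))
      }
    )

    observe <- function(dip) {
      call <- dip[cbind(seq_len(n), sample(c(1L, 2L), n, replace = TRUE))]
      if (contam_rate > 0) {
        hit <- runif(n) < contam_rate
        call[hit] <- rbinom(sum(hit), 1L, contam_freqs[hit])
      }
      if (error_rate > 0) {
        flip <- runif(n) < error_rate
        call[flip] <- 1L - call[flip]
      }
      if (missing_rate > 0) call[runif(n) < missing_rate] <- NA_integer_
      call
    }

    structure(
      list(genotypes_a = observe(dip_a), genotypes_b = observe(dip_b),
           relationship = relationship,
           truth = list(diploid_a = dip_a, diploid_b = dip_b,
                        freqs = freqs, contam_freqs = contam_freqs)),
      class = "simulated_pair"
    )
  })
}

#' Simulate reads carrying terminal deamination damage
#'
#' Post-mortem cytosine deamination shows up as C-to-T substitutions at the 5'
#' terminus and, on the complementary strand, G-to-A at the 3' terminus, with
#' a rate decaying into the read. At 5'-terminal position `k` (1-based), each
#' reference C is observed as T with probability
#' `damage_rate_5p * exp(-(k - 1) / decay_constant)`; G-to-A mirrors this from
#' the 3' end. All other positions are copied faithfully (add sequencing error
#' separately if needed via `error_rate`).
#'
#' @param n_reads number of reads.
#' @param read_length read length in bp (> 0).
#' @param damage_rate_5p terminal damage probability in `[0, 1]`.
#' @param decay_constant exponential decay constant in positions (default 2.5).
#' @param error_rate independent per-base substitution error applied after
#'   damage (default 0).
#' @param seed integer seed.
#' @return data.frame of class `read_set` with columns `read_id`, `ref`
#'   (reference sequence), `obs` (observed sequence).
#' @export
simulate_damaged_reads <- function(n_reads, read_length,
                                   damage_rate_5p, decay_constant = 2.5,
                                   error_rate = 0, seed = 1L) {
  if (read_length <= 0) stop("read_length must be positive")
  stopifnot(damage_rate_5p >= 0, damage_rate_5p <= 1, decay_constant > 0)
  bases <- c("A", "C", "G", "T")

  with_seed(seed, {
    L <- as.integer(read_length)
    ref <- matrix(sample(bases, n_reads * L, replace = TRUE), nrow = n_reads)
    obs <- ref
    k <- seq_len(L)
    p5 <- damage_rate_5p * exp(-(k - 1) / decay_constant)       # 5' C->T
    p3 <- rev(p5)                                               # 3' G->A
    for (j in k) {
      if (p5[j] > 0) {
        isC <- ref[, j] == "C"
        hit <- isC & runif(n_reads) < p5[j]
        obs[hit, j] <- "T"
      }
      if (p3[j] > 0) {
        isG <- ref[, j] == "G"
        hit <- isG & runif(n_reads) < p3[j]
        obs[hit, j] <- "A"
      }
    }
    if (error_rate > 0) {
      err <- matrix(runif(n_reads * L) < error_rate, nrow = n_reads)
      if (any(err)) {
        idx <- which(err)
        cur <- obs[idx]
        obs[idx] <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), "")
      }
    }
    out <- data.frame(
      read_id = sprintf("read%06d", seq_len(n_reads)),
      ref = apply(ref, 1, paste0, collapse = ""),
      obs = apply(obs, 1, paste0, collapse = ""),
      stringsAsFactors = FALSE
    )
    class(out) <- c("read_set", "data.frame")
    out
  })
}

#' Simulate a radiocarbon measurement of a contaminated sample
#'
#' Contamination mixes linearly on the fraction-modern scale:
#' `F_obs = (1 - c) * F(true_age) + c * contaminant_f14c`. The observed F is
#' converted to a conventional age and Gaussian measurement noise (in 14C yr)
#' is added. A modern contaminant (`contaminant_f14c` above the sample's F)
#' always biases the date younger; a reservoir-depleted contaminant biases it
#' older.
#'
#' @param true_age true conventional age, 14C yr BP.
#' @param contamination_fraction contaminant mass fraction `c` in `[0, 1]`.
#' @param contaminant_f14c fraction modern of the contaminant (> 0; 1.0 =
#'   modern standard, post-bomb values > 1 are allowed).
#' @param measurement_sigma 1-sigma measurement error, 14C yr (>= 0; the
#'   reported date keeps this as its quoted sigma, floored at 1 yr).
#' @param seed integer seed (only used when `measurement_sigma > 0`).
#' @param lab_code label for the resulting date.
#' @return a [radiocarbon_date()] with attribute `truth` holding the inputs.
#' @export
simulate_c14 <- function(true_age, contamination_fraction = 0,
                         contaminant_f14c = 1.0, measurement_sigma = 35,
                         seed = 1L, lab_code = "SIM") {
  c_ <- contamination_fraction
  stopifnot(c_ >= 0, c_ <= 1, contaminant_f14c > 0, measurement_sigma >= 0)
  f_true <- f14c_from_age(true_age)
  f_obs <- (1 - c_) * f_true + c_ * contaminant_f14c
  if (f_obs <= 0) stop("mixed F14C is non-positive")
  age <- age_from_f14c(f_obs)
  if (measurement_sigma > 0) {
    age <- with_seed(seed, age + rnorm(1, 0, measurement_sigma))
  }
  d <- radiocarbon_date(lab_code, age, max(measurement_sigma, 1))
  attr(d, "truth") <- list(true_age = true_age,
                           contamination_fraction = c_,
                           contaminant_f14c = contaminant_f14c,
                           measurement_sigma = measurement_sigma)
  d
}

#' Simulate per-chromosome mean coverage for a known genetic sex
#'
#' Autosomes receive the full depth; X and Y receive half depth each for a
#' male (XY) and X full / Y zero for a female (XX). Counts are Poisson over
#' `n_sites` targeted positions per chromosome, so low depths carry realistic
#' sampling noise. A trickle of mismapped reads gives Y a small nonzero floor
#' for females.
#'
#' @param sex `"XY"` or `"XX"` (truth).
#' @param depth mean autosomal depth (x-fold).
#' @param n_sites targeted sites per chromosome.
#' @param mismap_rate fraction of depth appearing on Y regardless of sex.
#' @param seed integer seed.
#' @return named numeric vector of mean depths for chromosomes `"1"`..`"22"`,
#'   `"X"`, `"Y"`.
#' @export
simulate_coverage <- function(sex = c("XY", "XX"), depth = 0.1,
                              n_sites = 10000L, mismap_rate = 0.002,
                              seed = 1L) {
  sex <- match.arg(sex)
  stopifnot(depth > 0, n_sites >= 1)
  chroms <- c(as.character(1:22), "X", "Y")
  mult <- c(rep(1, 22),
            if (sex == "XY") c(0.5, 0.5) else c(1, 0))
  mult[24] <- mult[24] + mismap_rate
  with_seed(seed, {
    counts <- rpois(24L, depth * mult * n_sites)
    setNames(counts / n_sites, chroms)
  })
}
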