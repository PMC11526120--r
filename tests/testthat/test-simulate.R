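# Synthetic-data generators: ground truth, determinism, closed-form checks.

test_that("draw_population honours degenerate and parametric laws", {
  m <- population_model(4, list(family = "fixed", p = 0.5))
  expect_identical(draw_population(m), rep(0.5, 4))

  # frozen oracle: E[2p(1-p)] over U(0.1, 0.9) = 2*(1/2 - 0.91/3) = 0.3933333
  m <- population_model(1e5, list(family = "uniform", min = 0.1, max = 0.9),
                        seed = 11)
  p <- draw_population(m)
  het <- 2 * p * (1 - p)
  mc_se <- sd(het) / sqrt(length(het))
  expect_lt(abs(mean(het) - 0.39333333), 3 * mc_se)
  expect_equal(m$expected_heterozygosity, 0.39333333, tolerance = 1e-7)

  # same seed -> identical vector; different seed -> different
  m2 <- population_model(100, seed = 42)
  expect_identical(draw_population(m2), draw_population(m2))
  expect_false(identical(draw_population(m2),
                         draw_population(population_model(100, seed = 43))))
  expect_error(draw_population(population_model(5, list(family = "gamma"))),
               "unknown frequency-law")
})

test_that("expected_heterozygosity matches Monte Carlo for each family", {
  laws <- list(list(family = "uniform", min = 0.05, max = 0.95),
               list(family = "beta", shape1 = 0.3, shape2 = 0.3),
               list(family = "fixed", p = 0.25))
  for (law in laws) {
    m <- population_model(2e5, law, seed = 5)
    het <- 2 * draw_population(m) * (1 - draw_population(m))
    se <- max(sd(het) / sqrt(length(het)), 1e-12)
    expect_lt(abs(mean(het) - m$expected_heterozygosity), 3 * se + 1e-12)
  }
})

test_that("simulate_pair produces the stated mismatch expectations", {
  # monomorphic: everything ref, zero mismatch
  sp <- simulate_pair(rep(0, 100), "unrelated", seed = 1)
  expect_true(all(sp$genotypes_a == 0L) && all(sp$genotypes_b == 0L))

  # same individual at p = 0.5: E[PMR] = het/2 = 0.25
  n <- 1e5
  sp <- simulate_pair(rep(0.5, n), "same_individual", seed = 2)
  mm <- mean(sp$genotypes_a != sp$genotypes_b)
  expect_lt(abs(mm - 0.25), 3 * sqrt(0.25 * 0.75 / n))

  # unrelated at p = 0.5: E[PMR] = 2p(1-p) = 0.5
  sp <- simulate_pair(rep(0.5, n), "unrelated", seed = 3)
  mm <- mean(sp$genotypes_a != sp$genotypes_b)
  expect_lt(abs(mm - 0.5), 3 * sqrt(0.5 * 0.5 / n))

  # twins share the identical diploid truth; locus ordering is shared
  sp <- simulate_pair(runif(50), "identical_twin", seed = 4)
  expect_identical(sp$truth$diploid_a, sp$truth$diploid_b)

  # first-degree: exactly one allele per locus is IBD
  sp <- simulate_pair(rep(0.5, 200), "first_degree", seed = 5)
  shared <- sp$truth$diploid_b[, 1] %in% c(sp$truth$diploid_a[, 1],
                                           sp$truth$diploid_a[, 2])
  expect_true(all(shared))

  expect_error(simulate_pair(0.5, "cousin"), "arg")
  expect_error(simulate_pair(0.5, "unrelated", error_rate = 1.5), "rates")
})

test_that("simulate_pair missingness and determinism behave", {
  sp <- simulate_pair(rep(0.5, 5000), "unrelated", missing_rate = 0.3, seed = 6)
  miss <- mean(is.na(sp$genotypes_a))
  expect_lt(abs(miss - 0.3), 3 * sqrt(0.3 * 0.7 / 5000))
  expect_identical(simulate_pair(rep(0.5, 100), "unrelated", seed = 7),
                   simulate_pair(rep(0.5, 100), "unrelated", seed = 7))
})

test_that("simulate_damaged_reads applies the terminal damage model", {
  # no damage: observed identical to reference
  r <- simulate_damaged_reads(50, 30, damage_rate_5p = 0, seed = 1)
  expect_identical(r$ref, r$obs)

  # saturation: with rate 1 and huge decay every terminal C reads as T
  r <- simulate_damaged_reads(200, 20, damage_rate_5p = 1,
                              decay_constant = 1e9, seed = 2)
  first_ref <- substr(r$ref, 1, 1)
  first_obs <- substr(r$obs, 1, 1)
  expect_true(all(first_obs[first_ref == "C"] == "T"))
  # ...and with rate 1, decay 1e9: *every* position's C is hit
  expect_false(any(grepl("C", r$obs)))

  # recovery: position-1 C->T frequency ~ 0.08 within 3 binomial SE
  r <- simulate_damaged_reads(1e4, 40, damage_rate_5p = 0.08, seed = 3)
  isC <- substr(r$ref, 1, 1) == "C"
  phat <- mean(substr(r$obs[isC], 1, 1) == "T")
  expect_lt(abs(phat - 0.08), 3 * sqrt(0.08 * 0.92 / sum(isC)))

  expect_error(simulate_damaged_reads(10, 0, 0.1), "read_length")
})

test_that("simulate_c14 implements the linear F14C mixing model", {
  # identity: no contamination, no noise
  d <- simulate_c14(5000, 0, measurement_sigma = 0)
  expect_equal(d$age_bp, 5000, tolerance = 1e-9)

  # forward formula, computed independently here
  t0 <- 13900; c_ <- 0.007
  d <- simulate_c14(t0, c_, contaminant_f14c = 1.0, measurement_sigma = 0)
  expected <- -8033 * log((1 - c_) * exp(-t0 / 8033) + c_)
  expect_equal(d$age_bp, expected, tolerance = 1e-9)
  expect_lt(d$age_bp, t0)  # modern contaminant -> younger

  # full replacement
  d <- simulate_c14(9999, 1, contaminant_f14c = 0.8, measurement_sigma = 0)
  expect_equal(d$age_bp, -8033 * log(0.8), tolerance = 1e-9)

  # truth retained for recovery tests
  expect_equal(attr(d, "truth")$contamination_fraction, 1)
})

test_that("contamination directionality is monotone", {
  t0 <- 13900
  ages_mod <- vapply(c(0.001, 0.01, 0.05, 0.1, 0.2), function(c_)
    simulate_c14(t0, c_, contaminant_f14c = 1.0, measurement_sigma = 0)$age_bp, 0)
  expect_true(all(diff(ages_mod) < 0))          # modern carbon -> ever younger
  ages_res <- vapply(c(0.01, 0.05, 0.1), function(c_)
    simulate_c14(t0, c_, contaminant_f14c = 0.05, measurement_sigma = 0)$age_bp, 0)
  expect_true(all(ages_res > t0))               # depleted contaminant -> older
})

test_that("simulate_coverage reflects the stated sex and is reproducible", {
  xy <- simulate_coverage("XY", depth = 0.2, seed = 1)
  xx <- simulate_coverage("XX", depth = 0.2, seed = 1)
  expect_lt(abs(xy[["X"]] / mean(xy[as.character(1:22)]) - 0.5), 0.15)
  expect_lt(xx[["Y"]], 0.01)
  expect_identical(simulate_coverage("XY", 0.1, seed = 3),
                   simulate_coverage("XY", 0.1, seed = 3))
})
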