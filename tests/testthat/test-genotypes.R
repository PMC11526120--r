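# EIGENSTRAT and pileup I/O, end trimming, pseudo-haploid calling.

write_triplet <- function(dir, geno, snp, ind) {
  writeLines(geno, file.path(dir, "fix.geno"))
  writeLines(snp, file.path(dir, "fix.snp"))
  writeLines(ind, file.path(dir, "fix.ind"))
  file.path(dir, "fix")
}

test_that("read_eigenstrat parses a hand-written triplet literally", {
  dir <- withr_tempdir()
  prefix <- write_triplet(dir,
    geno = c("09", "20", "92"),
    snp = c("rs1\t1\t0\t100\tA\tG",
            "rs2\t1\t0\t200\tC\tT",
            "rs3\t2\t0\t150\tG\tA"),
    ind = c("sampleX\tM\tPOP1", "sampleY\tF\tPOP2"))
  es <- read_eigenstrat(prefix)
  # geno digit = alt count: 0 -> ref(0), 2 -> alt(1), 9 -> NA
  expect_identical(unname(es$table$calls[, "sampleX"]), c(0L, 1L, NA))
  expect_identical(unname(es$table$calls[, "sampleY"]), c(NA, 0L, 1L))
  expect_identical(es$panel$alt_allele, c("G", "T", "A"))
  expect_identical(es$ind$population, c("POP1", "POP2"))
})

test_that("read_eigenstrat validates structure and symbols", {
  dir <- withr_tempdir()
  snp <- c("rs1\t1\t0\t100\tA\tG", "rs2\t1\t0\t200\tC\tT")
  ind <- "s1\tU\tPOP"
  p <- write_triplet(dir, c("0", "3"), snp, ind)
  expect_error(read_eigenstrat(p), "line 2")
  p <- write_triplet(dir, c("00", "0"), snp, ind)
  expect_error(read_eigenstrat(p), "ragged")
  p <- write_triplet(dir, c("1", "0"), snp, ind)
  expect_error(read_eigenstrat(p), "heterozygous")
  expect_silent(read_eigenstrat(p, haploid = FALSE))
  expect_error(read_eigenstrat(file.path(dir, "nope")), "missing input")
})

test_that("write then read is the identity on 1000 random calls", {
  set.seed(99)
  n <- 1000L
  calls <- matrix(sample(c(0L, 1L, NA), n * 3, replace = TRUE), ncol = 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  tab <- genotype_table(
    snp_panel(sprintf("rs%d", 1:n), rep("1", n), seq_len(n) * 10L,
              rep("A", n), rep("G", n)),
    calls)
  prefix <- file.path(withr_tempdir(), "rt")
  write_eigenstrat(tab, prefix)
  back <- read_eigenstrat(prefix)
  expect_identical(back$table$calls, tab$calls)
  expect_equal(back$panel$position, tab$panel$position)
})

test_that("trim_ends masks terminal bases and flags degenerate reads", {
  reads <- data.frame(read_id = c("r1", "r2"),
                      ref = c(strrep("A", 30), strrep("A", 4)),
                      obs = c(strrep("A", 30), strrep("A", 4)))
  t2 <- trim_ends(reads, 2)
  expect_identical(t2$n_callable, c(26L, 0L))
  expect_identical(t2$fully_masked, c(FALSE, TRUE))
  expect_identical(t2$callable_start[1], 3L)
  t0 <- trim_ends(reads, 0)
  expect_identical(t0$n_callable, c(30L, 4L))
})

test_that("pseudo_haploid_call follows the quality and allele rules", {
  # single qualifying base
  expect_identical(pseudo_haploid_call("A", 40L, "A", "G"), 0L)
  # nothing at Q >= 30 -> missing
  expect_identical(pseudo_haploid_call(c("A", "G"), c(29L, 20L), "A", "G"), NA_integer_)
  # tri-allelic bases discarded before the draw
  expect_identical(pseudo_haploid_call(c("T", "C"), c(40L, 40L), "A", "G"), NA_integer_)
  # terminal-offset exclusion
  expect_identical(
    pseudo_haploid_call("A", 40L, "A", "G", end_offsets = 1L, trim = 2L),
    NA_integer_)

  # 50/50 ref/alt over 1e4 independent draws: ref fraction ~ 0.5 (binomial)
  n <- 1e4
  calls <- with_seed_for_test(123, vapply(seq_len(n), function(i)
    pseudo_haploid_call(c("A", "G"), c(35L, 35L), "A", "G"), 0L))
  expect_lt(abs(mean(calls == 0L) - 0.5), 3 * sqrt(0.25 / n))
  # and calls never leave {ref, alt}
  expect_true(all(calls %in% c(0L, 1L)))
})

test_that("missingness is monotone non-decreasing in min_quality", {
  set.seed(7)
  cols <- replicate(50, list(bases = sample(c("A", "G", "T"), 8, replace = TRUE),
                             quals = sample(10:45, 8, replace = TRUE)),
                    simplify = FALSE)
  miss_at <- function(q) {
    mean(vapply(seq_along(cols), function(i)
      is.na(pseudo_haploid_call(cols[[i]]$bases, cols[[i]]$quals, "A", "G",
                                min_quality = q, seed = i)), TRUE))
  }
  rates <- vapply(c(10, 20, 30, 40, 46), miss_at, 0)
  expect_true(all(diff(rates) >= 0))
})

test_that("pileup round-trips and call_genotypes recovers homozygous truth", {
  panel <- synthetic_panel(200, seed = 1)
  diploid <- cbind(rep(c(0L, 1L), 100), rep(c(0L, 1L), 100))  # all homozygous
  pu <- simulate_pileup(panel, diploid, mean_depth = 3, seed = 2)

  path <- file.path(withr_tempdir(), "p.tsv")
  write_pileup(pu, path)
  back <- read_pileup(path)
  expect_identical(back$position, pu$position)
  expect_identical(back$bases, pu$bases)
  expect_identical(back$quals, pu$quals)

  tab <- call_genotypes(back, panel, sample = "s1", min_quality = 30,
                        trim = 0, seed = 3)
  called <- which(!is.na(tab$calls[, 1]))
  expect_gt(length(called), 50)
  expect_identical(unname(tab$calls[called, 1]), diploid[called, 1])
})
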