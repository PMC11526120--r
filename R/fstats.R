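# Outgroup-f3 shared-drift statistics with weighted block-jackknife errors.
#
# f3(O; A, B) = mean over usable SNPs of (o - a)(o - b), where o/a/b are
# alt-allele frequencies. In outgroup mode no heterozygosity normalization or
# inbreeding correction is applied, so the statistic is a direct measure of
# the drift shared by A and B relative to O. For two pseudo-haploid
# observations of one individual, E[f3] exceeds 0.5 exactly when the source
# population's heterozygosity is low — which is how a value much larger than
# 0.5 doubles as evidence of small effective population size.

#' Per-SNP alternate-allele frequencies for a set of samples
#'
#' Frequency is the alt-call fraction among non-missing haploid calls. Sites
#' where every member is missing are `NA` (unusable).
#'
#' @param table a [genotype_table()].
#' @param population character vector of sample labels forming the population.
#' @return list: `freq` (numeric, `NA` where unusable), `n_calls` (non-missing
#'   call count per site).
#' @export
allele_frequencies <- function(table, population) {
  stopifnot(inherits(table, "genotype_table"))
  if (!length(population)) stop("population is empty")
  unknown <- setdiff(population, table$samples)
  if (length(unknown)) stop("unknown sample label(s): ", paste(unknown, collapse = ", "))
  calls <- table$calls[, population, drop = FALSE]
  n_calls <- as.integer(rowSums(!is.na(calls)))
  freq <- rowSums(calls, na.rm = TRUE) / n_calls
  freq[n_calls == 0L] <- NA_real_
  list(freq = freq, n_calls = n_calls)
}

#' Assign SNPs to contiguous jackknife blocks
#'
#' Default blocks are 5 Mb of physical distance within each chromosome; if a
#' chromosome's span fits in one block it simply forms a per-chromosome block.
#' Block length is a free parameter — any contiguous scheme that is large
#' relative to linkage disequilibrium is acceptable.
#'
#' @param panel a [snp_panel()].
#' @param block_size_bp block length in bp (default 5e6).
#' @return integer vector of block ids, one per SNP.
#' @export
assign_blocks <- function(panel, block_size_bp = 5e6) {
  stopifnot(inherits(panel, "snp_panel"), block_size_bp > 0)
  key <- paste(panel$chromosome, panel$position %/% block_size_bp)
  match(key, unique(key))
}

#' Outgroup f3 with weighted block-jackknife standard error
#'
#' Point estimate: mean over usable SNPs (non-missing in all three
#' populations) of `(o - a)(o - b)`. Standard error: delete-one-block
#' jackknife with blocks weighted by their SNP counts, as used with uneven
#' genomic blocks. The per-block pseudo-values are the block means of the
#' per-SNP products, so the weighted average of pseudo-values recombines to
#' the point estimate exactly.
#'
#' @param freqs_o,freqs_a,freqs_b per-SNP frequency vectors (`NA` = unusable),
#'   or the lists returned by [allele_frequencies()].
#' @param block_assignment integer block id per SNP (see [assign_blocks()]).
#' @return list of class `f3_result`: `f3`, `se`, `z`, `n_blocks`,
#'   `n_snps_used`, `block_estimates` (data.frame of per-block means and SNP
#'   counts).
#' @export
f3_outgroup <- function(freqs_o, freqs_a, freqs_b, block_assignment) {
  getf <- function(x) if (is.list(x)) x$freq else x
  o <- getf(freqs_o); a <- getf(freqs_a); b <- getf(freqs_b)
  stopifnot(length(o) == length(a), length(a) == length(b),
            length(block_assignment) == length(o))
  use <- !is.na(o) & !is.na(a) & !is.na(b)
  n <- sum(use)
  if (n == 0L) stop("zero usable SNPs")
  prod <- (o[use] - a[use]) * (o[use] - b[use])
  blk <- block_assignment[use]
  ids <- unique(blk)
  g <- length(ids)
  if (g < 2L) stop("need at least 2 jackknife blocks, got ", g)

  m_j <- vapply(ids, function(id) sum(blk == id), 0L)        # block SNP counts
  s_j <- vapply(ids, function(id) sum(prod[blk == id]), 0)   # block sums
  theta <- sum(s_j) / n
  theta_j <- (sum(s_j) - s_j) / (n - m_j)                    # delete-one estimates
  h_j <- n / m_j
  # Busing-style weighted jackknife
  theta_dot <- g * theta - sum((1 - m_j / n) * theta_j)
  tau_j <- h_j * theta - (h_j - 1) * theta_j                 # = block means
  var_j <- sum((tau_j - theta_dot)^2 / (h_j - 1)) / g
  se <- sqrt(var_j)
  structure(list(f3 = theta, se = se,
                 z = if (se > 0) theta / se else NA_real_,
                 n_blocks = g, n_snps_used = n,
                 block_estimates = data.frame(block = ids, n_snps = m_j,
                                              mean = s_j / m_j,
                                              delete_one = theta_j)),
            class = "f3_result")
}

#' @export
print.f3_result <- function(x, ...) {
  cat(sprintf("f3 = %.4f +/- %.4f (Z = %.2f; %d SNPs, %d blocks)\n",
              x$f3, x$se, x$z, x$n_snps_used, x$n_blocks))
  invisible(x)
}

#' All pairwise outgroup-f3 statistics among a set of individuals
#'
#' @param table a [genotype_table()].
#' @param individuals two or more sample labels (each treated as a
#'   single-member population with 0/1 pseudo-haploid "frequencies").
#' @param outgroup sample labels of the outgroup population; must not overlap
#'   `individuals`.
#' @param block_assignment integer block ids (default: [assign_blocks()] on
#'   the table's panel).
#' @return list of class `f3_matrix`: `f3` and `se` (symmetric matrices with
#'   `NA` diagonals), `pairs` (long data.frame with f3, se, z per pair).
#' @export
pairwise_f3_matrix <- function(table, individuals, outgroup,
                               block_assignment = assign_blocks(table$panel)) {
  if (length(individuals) < 2L) stop("need at least 2 individuals")
  if (length(intersect(individuals, outgroup)))
    stop("outgroup overlaps the individual set")
  fo <- allele_frequencies(table, outgroup)
  fr <- lapply(individuals, function(s) allele_frequencies(table, s))
  names(fr) <- individuals
  k <- length(individuals)
  f3m <- sem <- matrix(NA_real_, k, k, dimnames = list(individuals, individuals))
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      r <- f3_outgroup(fo, fr[[i]], fr[[j]], block_assignment)
      f3m[i, j] <- f3m[j, i] <- r$f3
      sem[i, j] <- sem[j, i] <- r$se
      rows[[length(rows) + 1L]] <- data.frame(
        x1 = individuals[i], x2 = individuals[j],
        f3 = r$f3, se = r$se, z = r$z,
        n_snps = r$n_snps_used, n_blocks = r$n_blocks)
    }
  }
  structure(list(f3 = f3m, se = sem, pairs = do.call(rbind, rows)),
            class = "f3_matrix")
}
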