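# Pairwise mismatch rate (PMR) relatedness testing.
#
# Two pseudo-haploid observations of the SAME diploid genome disagree only at
# heterozygous sites, and there only half the time, giving E[PMR] = H/2 where
# H is the individual's heterozygosity. Two unrelated individuals from a
# population with mean heterozygosity H disagree at rate ~H. Hence the
# identity rule: a pair whose PMR is half the unrelated baseline is the same
# individual or identical twins.

#' Pairwise mismatch rate between two samples
#'
#' Mismatches are counted at every SNP where both calls are non-missing and
#' differ. The standard error is the binomial-style
#' `sqrt(pmr * (1 - pmr) / n_overlap)`.
#'
#' @param table a [genotype_table()] (or a `simulated_pair`, in which case
#'   `a`/`b` default to its two members).
#' @param a,b sample labels.
#' @param min_overlap warn below this many overlapping SNPs (default 500 —
#'   chosen so that damage-filtered datasets of a few thousand SNPs are not
#'   rejected).
#' @return list of class `pmr_result`: `sample_a`, `sample_b`, `n_overlap`,
#'   `n_mismatch`, `pmr`, `se`, `low_overlap` flag.
#' @export
pmr <- function(table, a, b, min_overlap = 500L) {
  if (inherits(table, "simulated_pair")) {
    va <- table$genotypes_a; vb <- table$genotypes_b
    if (missing(a)) a <- "A"
    if (missing(b)) b <- "B"
  } else {
    stopifnot(inherits(table, "genotype_table"))
    for (s in c(a, b)) {
      if (!s %in% table$samples) stop("unknown sample label: ", s)
    }
    va <- table$calls[, a]; vb <- table$calls[, b]
  }
  both <- !is.na(va) & !is.na(vb)
  n_overlap <- sum(both)
  if (n_overlap == 0L) stop("zero overlapping SNPs between ", a, " and ", b)
  n_mismatch <- sum(va[both] != vb[both])
  p <- n_mismatch / n_overlap
  low <- n_overlap < min_overlap
  if (low) warning("only ", n_overlap, " overlapping SNPs (< ", min_overlap, ")")
  structure(list(sample_a = a, sample_b = b, n_overlap = n_overlap,
                 n_mismatch = n_mismatch, pmr = p,
                 se = sqrt(p * (1 - p) / n_overlap), low_overlap = low),
            class = "pmr_result")
}

#' @export
print.pmr_result <- function(x, ...) {
  cat(sprintf("PMR(%s, %s) = %.4f +/- %.4f (%d mismatches / %d SNPs)\n",
              x$sample_a, x$sample_b, x$pmr, x$se, x$n_mismatch, x$n_overlap))
  invisible(x)
}

#' Unrelated-pair PMR baseline
#'
#' PMR of a target sample against each of a set of putatively unrelated
#' reference samples, summarized by mean (the headline statistic), median and
#' quartiles.
#'
#' @param table a [genotype_table()].
#' @param reference_samples two or more reference labels.
#' @param target the focal sample label.
#' @param ... passed to [pmr()].
#' @return list of class `pmr_baseline`: `pair_results`, `mean`, `median`,
#'   `quartiles`.
#' @export
pmr_baseline <- function(table, reference_samples, target, ...) {
  if (!length(reference_samples)) stop("empty reference set")
  res <- lapply(reference_samples, function(r) pmr(table, target, r, ...))
  vals <- vapply(res, `[[`, 0, "pmr")
  structure(list(pair_results = res, mean = mean(vals),
                 median = median(vals),
                 quartiles = quantile(vals, c(0.25, 0.75), names = FALSE)),
            class = "pmr_baseline")
}

#' Classify a pair from its PMR relative to the unrelated baseline
#'
#' The ratio `pmr / baseline_mean` has expectation 0.5 for the same individual
#' or identical twins, 0.75 for first-degree relatives, and 1 for unrelated
#' pairs (by pseudo-haploid allele sampling). Class bands default to the
#' midpoints between those expectations and are reported alongside the raw
#' ratio; they are a package convention, not a published rule.
#'
#' @param result a [pmr()] result.
#' @param baseline a [pmr_baseline()] (or a single number, the baseline mean).
#' @param bands upper ratio bounds for `identical_or_twin` and `first_degree`
#'   (default `c(0.625, 0.875)`).
#' @return list of class `pmr_classification`: `class`, `ratio`, `bands`,
#'   `pmr`, `baseline_mean`.
#' @export
classify_pair <- function(result, baseline, bands = c(0.625, 0.875)) {
  base_mean <- if (inherits(baseline, "pmr_baseline")) baseline$mean else baseline
  if (!is.finite(base_mean) || base_mean <= 0) stop("baseline mean must be positive")
  if (!is.finite(result$pmr)) stop("undefined PMR")
  ratio <- result$pmr / base_mean
  cls <- if (ratio < bands[1]) "identical_or_twin"
         else if (ratio < bands[2]) "first_degree"
         else "unrelated"
  structure(list(class = cls, ratio = ratio, bands = bands,
                 pmr = result$pmr, baseline_mean = base_mean),
            class = "pmr_classification")
}

#' @export
print.pmr_classification <- function(x, ...) {
  cat(sprintf("PMR ratio %.3f (pmr %.4f / baseline %.4f) -> %s [bands %.3f, %.3f]\n",
              x$ratio, x$pmr, x$baseline_mean, x$class, x$bands[1], x$bands[2]))
  invisible(x)
}

#' Long table of all PMR pairs (plot-ready)
#'
#' @param table a [genotype_table()].
#' @param target focal sample.
#' @param others comparison samples.
#' @param ... passed to [pmr()].
#' @return data.frame with one row per pair: `sample_a`, `sample_b`,
#'   `n_overlap`, `n_mismatch`, `pmr`, `se`.
#' @export
pmr_long_table <- function(table, target, others, ...) {
  res <- lapply(others, function(r) pmr(table, target, r, ...))
  do.call(rbind, lapply(res, function(x)
    data.frame(sample_a = x$sample_a, sample_b = x$sample_b,
               n_overlap = x$n_overlap, n_mismatch = x$n_mismatch,
               pmr = x$pmr, se = x$se)))
}
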