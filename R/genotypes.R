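# Genotype container and I/O.
#
# Internal haploid coding: integer matrix `calls` (SNPs x samples) with
# 0 = ref allele, 1 = alt allele, NA = missing. The on-disk EIGENSTRAT geno
# digit is the count of the ALT allele (0 = hom-ref, 1 = het, 2 = hom-alt,
# 9 = missing); pseudo-haploid samples therefore only ever emit 0/2/9.

#' Construct a SNP panel
#'
#' @param snp_id character SNP names.
#' @param chromosome chromosome labels (autosomes `"1"`..`"22"`, `"X"`, `"Y"`).
#' @param position 1-based physical coordinates, strictly increasing within a
#'   chromosome.
#' @param ref_allele,alt_allele single distinct bases.
#' @return data.frame of class `snp_panel`.
#' @export
snp_panel <- function(snp_id, chromosome, position, ref_allele, alt_allele) {
  panel <- data.frame(snp_id = as.character(snp_id),
                      chromosome = as.character(chromosome),
                      position = as.integer(position),
                      ref_allele = toupper(as.character(ref_allele)),
                      alt_allele = toupper(as.character(alt_allele)),
                      stringsAsFactors = FALSE)
  if (any(panel$ref_allele == panel$alt_allele))
    stop("ref and alt alleles must differ")
  for (ch in unique(panel$chromosome)) {
    pos <- panel$position[panel$chromosome == ch]
    if (is.unsorted(pos, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' Construct a genotype table
#'
#' @param panel a [snp_panel()].
#' @param calls integer matrix (SNPs x samples), values 0 (ref), 1 (alt),
#'   `NA` (missing). Pseudo-haploid data never contains heterozygous calls;
#'   set `haploid = TRUE` (default) to enforce 0/1/NA only.
#' @param samples sample labels (defaults to `colnames(calls)`).
#' @param haploid enforce the haploid coding.
#' @return object of class `genotype_table` with fields `panel`, `calls`,
#'   `samples`.
#' @export
genotype_table <- function(panel, calls, samples = colnames(calls),
                           haploid = TRUE) {
  stopifnot(inherits(panel, "snp_panel"))
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(panel))
    stop("call matrix has ", nrow(calls), " rows but panel has ", nrow(panel), " SNPs")
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(calls)))
  if (length(samples) != ncol(calls)) stop("one label per sample column required")
  storage.mode(calls) <- "integer"
  ok <- calls %in% if (haploid) c(0L, 1L) else c(0L, 1L, 2L)
  if (!all(ok | is.na(calls)))
    stop("calls must be ", if (haploid) "0/1/NA (haploid)" else "0/1/2/NA")
  colnames(calls) <- samples
  structure(list(panel = panel, calls = calls, samples = samples),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d SNPs x %d samples (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Read an EIGENSTRAT genotype triplet
#'
#' Reads `<prefix>.geno` (one row per SNP, one digit per sample),
#' `<prefix>.snp` (id, chromosome, genetic position, physical position, ref,
#' alt) and `<prefix>.ind` (sample, sex, population). The geno digit is the
#' alt-allele count: 0 = hom-ref, 1 = het, 2 = hom-alt, 9 = missing.
#' Heterozygous (1) entries are only accepted with `haploid = FALSE`.
#'
#' @param prefix path prefix of the triplet.
#' @param haploid require pseudo-haploid (0/2/9) coding.
#' @return list with `panel` ([snp_panel()]), `table` ([genotype_table()]),
#'   and `ind` (data.frame sample/sex/population).
#' @export
read_eigenstrat <- function(prefix, haploid = TRUE) {
  files <- paste0(prefix, c(".geno", ".snp", ".ind"))
  missing <- files[!file.exists(files)]
  if (length(missing)) stop("missing input file(s): ", paste(missing, collapse = ", "))

  ind <- read.table(files[3], header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("sample", "sex", "population"))
  snp <- read.table(files[2], header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("snp_id", "chromosome", "genetic_pos",
                                  "position", "ref_allele", "alt_allele"))
  panel <- snp_panel(snp$snp_id, snp$chromosome, snp$position,
                     snp$ref_allele, snp$alt_allele)

  lines <- readLines(files[1])
  if (length(lines) != nrow(panel))
    stop(".geno has ", length(lines), " rows but .snp has ", nrow(panel))
  widths <- nchar(lines)
  if (length(unique(widths)) != 1L)
    stop("ragged .geno line(s), first at line ", which(widths != widths[1])[1])
  if (widths[1] != nrow(ind))
    stop(".geno has ", widths[1], " columns but .ind has ", nrow(ind), " samples")

  digits <- matrix(utf8ToInt(paste0(lines, collapse = "")) - utf8ToInt("0"),
                   nrow = nrow(panel), byrow = TRUE)
  bad <- matrix(!(digits %in% c(0L, 1L, 2L, 9L)), nrow = nrow(digits))
  if (any(bad)) {
    row <- which(rowSums(bad) > 0)[1]
    stop("invalid genotype symbol at .geno line ", row,
         " (allowed: 0, 1, 2, 9)")
  }
  calls <- digits
  calls[digits == 9L] <- NA_integer_
  if (haploid) {
    if (any(digits == 1L, na.rm = TRUE))
      stop("heterozygous calls present; use haploid = FALSE for diploid data")
    calls[digits == 2L] <- 1L  # alt-count 2 -> haploid alt
  }
  table <- genotype_table(panel, calls, ind$sample, haploid = haploid)
  list(panel = panel, table = table, ind = ind)
}

#' Write an EIGENSTRAT genotype triplet
#'
#' Inverse of [read_eigenstrat()]: `write_eigenstrat` then `read_eigenstrat`
#' is the identity on panel, calls and sample labels.
#'
#' @param table a [genotype_table()].
#' @param prefix output path prefix.
#' @param populations population label per sample (default `"POP"`).
#' @param sex sex code per sample (default `"U"`).
#' @return `prefix`, invisibly.
#' @export
write_eigenstrat <- function(table, prefix, populations = "POP", sex = "U") {
  stopifnot(inherits(table, "genotype_table"))
  panel <- table$panel
  digits <- table$calls
  digits[digits == 1L] <- 2L   # haploid alt -> alt-count 2
  digits[is.na(table$calls)] <- 9L
  lines <- apply(digits, 1, paste0, collapse = "")
  writeLines(lines, paste0(prefix, ".geno"))
  snp <- data.frame(panel$snp_id, panel$chromosome, 0, panel$position,
                    panel$ref_allele, panel$alt_allele)
  write.table(snp, paste0(prefix, ".snp"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ind <- data.frame(table$samples,
                    rep_len(sex, length(table$samples)),
                    rep_len(populations, length(table$samples)))
  write.table(ind, paste0(prefix, ".ind"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Mask the terminal bases of each read
#'
#' Post-mortem deamination concentrates at read termini; masking the first and
#' last `n_bases` of every read keeps damaged positions out of genotype
#' calling. Reads shorter than `2 * n_bases` are fully masked and flagged.
#'
#' @param reads a `read_set` data.frame (columns `read_id`, `ref`, `obs`).
#' @param n_bases number of bases to mask at each end (>= 0).
#' @return the read set with columns `callable_start`, `callable_end`,
#'   `n_callable`, `fully_masked` added.
#' @export
trim_ends <- function(reads, n_bases = 2L) {
  stopifnot(is.data.frame(reads), n_bases >= 0)
  n_bases <- as.integer(n_bases)
  len <- nchar(reads$obs)
  reads$callable_start <- pmin(n_bases + 1L, len + 1L)
  reads$callable_end <- len - n_bases
  reads$n_callable <- pmax(0L, len - 2L * n_bases)
  reads$fully_masked <- reads$n_callable == 0L
  reads$callable_end[reads$fully_masked] <- 0L
  reads
}

#' Read a text pileup
#'
#' Tab-separated columns: CHROM, POS (1-based), REF, BASES (string), QUALS
#' (comma-separated Phred integers), OFF5, OFF3 (comma-separated distances of
#' each base from its read's 5' and 3' ends, 0-based).
#'
#' @param path pileup file.
#' @return data.frame of class `pileup` with list-columns `bases`, `quals`,
#'   `off5`, `off3`.
#' @export
read_pileup <- function(path) {
  raw <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("chromosome", "position", "ref",
                                  "bases", "quals", "off5", "off3"),
                    colClasses = c("character", "integer", "character",
                                   "character", "character", "character",
                                   "character"))
  split_int <- function(s) lapply(strsplit(s, ",", fixed = TRUE), as.integer)
  out <- data.frame(chromosome = raw$chromosome, position = raw$position,
                    ref = toupper(raw$ref), stringsAsFactors = FALSE)
  out$bases <- lapply(strsplit(toupper(raw$bases), ""), identity)
  out$quals <- split_int(raw$quals)
  out$off5 <- split_int(raw$off5)
  out$off3 <- split_int(raw$off3)
  if (any(unlist(out$quals) < 0)) stop("negative base quality")
  if (any(unlist(out$off5) < 0) || any(unlist(out$off3) < 0))
    stop("negative read-end offset")
  class(out) <- c("pileup", "data.frame")
  out
}

#' Write a text pileup
#'
#' @param pileup a `pileup` data.frame as returned by [read_pileup()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  join <- function(col) vapply(col, paste0, "", collapse = ",")
  lines <- paste(pileup$chromosome, pileup$position, pileup$ref,
                 vapply(pileup$bases, paste0, "", collapse = ""),
                 join(pileup$quals), join(pileup$off5), join(pileup$off3),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Pseudo-haploid call at one pileup column
#'
#' Representing a low-coverage diploid individual by a single randomly chosen
#' allele per site. One base is drawn uniformly from the bases with Phred
#' quality at least `min_quality` that match the panel's ref or alt allele
#' (bases matching neither are discarded first); there is deliberately no
#' majority rule. If nothing qualifies the site is missing — a value, not an
#' error.
#'
#' @param bases character vector of observed bases at the site.
#' @param quals integer Phred qualities, same length.
#' @param ref_allele,alt_allele the panel alleles at the site.
#' @param min_quality Phred threshold (default 30).
#' @param end_offsets optional minimum distance of each base from its read's
#'   ends; bases closer than `trim` are excluded.
#' @param trim terminal exclusion in bp (default 0; calling on pre-trimmed
#'   input).
#' @param seed integer seed (optional; the draw uses the current RNG stream
#'   when `NULL`).
#' @return 0 (ref), 1 (alt) or `NA` (missing).
#' @export
pseudo_haploid_call <- function(bases, quals, ref_allele, alt_allele,
                                min_quality = 30, end_offsets = NULL,
                                trim = 0, seed = NULL) {
  stopifnot(length(bases) == length(quals))
  keep <- quals >= min_quality & bases %in% c(ref_allele, alt_allele)
  if (!is.null(end_offsets)) keep <- keep & end_offsets >= trim
  cand <- bases[keep]
  if (!length(cand)) return(NA_integer_)
  draw <- function() {
    b <- if (length(cand) == 1L) cand else sample(cand, 1L)
    if (b == ref_allele) 0L else 1L
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Call pseudo-haploid genotypes for one sample over a panel
#'
#' Applies [pseudo_haploid_call()] at every panel SNP found in the pileup;
#' panel SNPs without a pileup column are missing.
#'
#' @param pileup a `pileup` data.frame.
#' @param panel a [snp_panel()].
#' @param sample label for the resulting single-sample table.
#' @param min_quality Phred threshold (default 30).
#' @param trim terminal bases to exclude via the pileup's end offsets
#'   (default 2, matching 2-bp end trimming).
#' @param seed integer seed for the random draws.
#' @return a single-sample [genotype_table()].
#' @export
call_genotypes <- function(pileup, panel, sample = "sample1",
                           min_quality = 30, trim = 2L, seed = 1L) {
  stopifnot(inherits(panel, "snp_panel"))
  key <- paste(panel$chromosome, panel$position)
  idx <- match(paste(pileup$chromosome, pileup$position), key)
  calls <- rep(NA_integer_, nrow(panel))
  with_seed(seed, {
    for (i in which(!is.na(idx))) {
      j <- idx[i]
      off <- pmin(pileup$off5[[i]], pileup$off3[[i]])
      calls[j] <- pseudo_haploid_call(
        pileup$bases[[i]], pileup$quals[[i]],
        panel$ref_allele[j], panel$alt_allele[j],
        min_quality = min_quality, end_offsets = off, trim = trim)
    }
  })
  genotype_table(panel, matrix(calls, ncol = 1), sample)
}
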