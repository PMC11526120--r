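# Collagen stable-isotope quality control and dietary-offset evaluation.
#
# Well-preserved bone collagen has a C:N atomic ratio between 2.9 and 3.6
# with carbon and nitrogen contents above 8% and 3% by mass; measurements
# outside those bounds may reflect degraded or contaminated collagen and are
# failed with explicit reasons. Trophic enrichment from prey to consumer
# collagen is about +1 permil in d13C and +3 to +5 permil in d15N; a d15N
# shift beyond the upper bound suggests aquatic resource consumption.

#' C:N atomic ratio from mass percentages
#'
#' @param pct_c,pct_n carbon and nitrogen content, mass %.
#' @return atomic ratio `(pct_c / 12.011) / (pct_n / 14.007)`.
#' @export
cn_atomic <- function(pct_c, pct_n) {
  (pct_c / 12.011) / (pct_n / 14.007)
}

#' Construct a collagen isotope measurement
#'
#' @param specimen specimen label.
#' @param d13c delta-13C, permil vs V-PDB.
#' @param d15n delta-15N, permil vs AIR.
#' @param pct_c,pct_n elemental content, mass %.
#' @param element_type `"bone"`, `"dentine"` or `"other"`.
#' @return list of class `isotope_measurement` with derived `cn_atomic` and
#'   the [qc_collagen()] verdict attached as `qc`.
#' @export
isotope_measurement <- function(specimen, d13c, d15n, pct_c, pct_n,
                                element_type = c("bone", "dentine", "other")) {
  element_type <- match.arg(element_type)
  m <- structure(list(specimen = as.character(specimen),
                      element_type = element_type,
                      d13c = d13c, d15n = d15n,
                      pct_c = pct_c, pct_n = pct_n,
                      cn_atomic = if (pct_n > 0) cn_atomic(pct_c, pct_n) else NA_real_),
                 class = "isotope_measurement")
  m$qc <- qc_collagen(m)
  m
}

#' Collagen quality-control verdict
#'
#' Pass requires the C:N atomic ratio within `cn_range` (inclusive), %C
#' strictly above `min_pct_c` and %N strictly above `min_pct_n`. Every
#' violated rule is reported; an undefined ratio (%N = 0) is an automatic
#' fail.
#'
#' @param m an [isotope_measurement()], or a list with `pct_c`, `pct_n`
#'   (and optionally `cn_atomic`).
#' @param cn_range inclusive C:N bounds (default `c(2.9, 3.6)`).
#' @param min_pct_c,min_pct_n exclusive elemental thresholds (defaults 8, 3).
#' @return list of class `qc_verdict`: `pass` (logical), `reasons`
#'   (character, empty when passing), `cn_atomic`.
#' @export
qc_collagen <- function(m, cn_range = c(2.9, 3.6), min_pct_c = 8, min_pct_n = 3) {
  reasons <- character()
  ratio <- if (!is.null(m$cn_atomic) && !is.na(m$cn_atomic)) {
    m$cn_atomic
  } else if (m$pct_n > 0) {
    cn_atomic(m$pct_c, m$pct_n)
  } else {
    NA_real_
  }
  if (is.na(ratio)) {
    reasons <- c(reasons, "C:N ratio undefined (%N = 0)")
  } else if (ratio < cn_range[1] || ratio > cn_range[2]) {
    reasons <- c(reasons, sprintf("C:N atomic ratio %.2f outside [%.1f, %.1f]",
                                  ratio, cn_range[1], cn_range[2]))
  }
  if (!(m$pct_c > min_pct_c))
    reasons <- c(reasons, sprintf("%%C = %.1f not above %.0f%%", m$pct_c, min_pct_c))
  if (!(m$pct_n > min_pct_n))
    reasons <- c(reasons, sprintf("%%N = %.1f not above %.0f%%", m$pct_n, min_pct_n))
  structure(list(pass = length(reasons) == 0L, reasons = reasons,
                 cn_atomic = ratio),
            class = "qc_verdict")
}

#' Isotopic difference between two skeletal elements
#'
#' Absolute d13C and d15N differences with a same-individual consistency
#' verdict: two bones of one individual are expected to differ by less than
#' `bounds[1]` permil in d13C and `bounds[2]` permil in d15N (defaults 0.5
#' and 0.9; both inclusive verdict thresholds).
#'
#' @param a,b [isotope_measurement()]s (or lists with `d13c`, `d15n`).
#' @param bounds consistency bounds, permil (`c(d13c, d15n)`).
#' @return list of class `element_difference`: `delta_d13c`, `delta_d15n`
#'   (absolute), `consistent` (logical), `bounds`.
#' @export
element_difference <- function(a, b, bounds = c(0.5, 0.9)) {
  d13 <- abs(a$d13c - b$d13c)
  d15 <- abs(a$d15n - b$d15n)
  structure(list(delta_d13c = d13, delta_d15n = d15,
                 consistent = d13 <= bounds[1] && d15 <= bounds[2],
                 bounds = bounds),
            class = "element_difference")
}

#' Consumer-prey trophic shift and aquatic-resource flag
#'
#' Shifts are consumer minus the arithmetic mean of the prey group. The
#' terrestrial expectation is about +1 permil d13C and +3 to +5 permil d15N
#' per trophic level; a d15N shift exceeding the upper bound
#' (`aquatic_threshold`) flags probable aquatic resource consumption (marine
#' vs freshwater attribution is deliberately not decided).
#'
#' @param consumer an [isotope_measurement()] (or list with `d13c`, `d15n`).
#' @param prey_group non-empty list of measurements.
#' @param expected_shift list with `d13c` (scalar) and `d15n` (range) for
#'   reporting.
#' @param aquatic_threshold d15N shift (permil) above which the aquatic flag
#'   is raised (default 5).
#' @return list of class `trophic_comparison`: `delta13c_shift`,
#'   `delta15n_shift`, `prey_mean_d13c`, `prey_mean_d15n`, `aquatic_flag`,
#'   `expected_shift`, `n_prey`.
#' @export
trophic_shift <- function(consumer, prey_group,
                          expected_shift = list(d13c = 1, d15n = c(3, 5)),
                          aquatic_threshold = 5) {
  if (!length(prey_group)) stop("empty prey group")
  p13 <- mean(vapply(prey_group, `[[`, 0, "d13c"))
  p15 <- mean(vapply(prey_group, `[[`, 0, "d15n"))
  s13 <- consumer$d13c - p13
  s15 <- consumer$d15n - p15
  structure(list(delta13c_shift = s13, delta15n_shift = s15,
                 prey_mean_d13c = p13, prey_mean_d15n = p15,
                 aquatic_flag = s15 > aquatic_threshold,
                 expected_shift = expected_shift,
                 n_prey = length(prey_group)),
            class = "trophic_comparison")
}

#' Split a herbivore baseline into two d15N groups
#'
#' One-dimensional two-cluster split by the largest gap on sorted d15N —
#' useful for separating, e.g., a high-elevation herbivore guild (depleted
#' d15N) from a low-elevation one. If all values are identical a single group
#' is returned, flagged.
#'
#' @param herbivores list of measurements (or a bare numeric d15N vector);
#'   length >= 2.
#' @return list of class `baseline_split`: `low`, `high` (value vectors,
#'   sorted), `gap` (size of the largest gap), `split_at` (midpoint),
#'   `single_group` (logical).
#' @export
split_baseline_groups <- function(herbivores) {
  vals <- if (is.numeric(herbivores)) herbivores
          else vapply(herbivores, `[[`, 0, "d15n")
  if (length(vals) < 2L) stop("need at least 2 measurements")
  s <- sort(vals)
  gaps <- diff(s)
  if (all(gaps == 0)) {
    return(structure(list(low = s, high = numeric(0), gap = 0,
                          split_at = NA_real_, single_group = TRUE),
                     class = "baseline_split"))
  }
  i <- which.max(gaps)
  structure(list(low = s[seq_len(i)], high = s[(i + 1L):length(s)],
                 gap = gaps[i], split_at = (s[i] + s[i + 1L]) / 2,
                 single_group = FALSE),
            class = "baseline_split")
}

#' Read a CSV table of isotope measurements
#'
#' Columns: `specimen`, `element` (bone/dentine/other; optional, default
#' bone), `d13c`, `d15n`, `pct_c`, `pct_n`; extra columns (site, taxon, group)
#' are carried through as attributes on each measurement.
#'
#' @param path CSV file.
#' @return named list of [isotope_measurement()]s.
#' @export
read_isotope_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("specimen", "d13c", "d15n", "pct_c", "pct_n")
  if (!all(need %in% names(df)))
    stop("isotope table needs columns: ", paste(need, collapse = ", "))
  if (is.null(df$element)) df$element <- "bone"
  out <- lapply(seq_len(nrow(df)), function(i) {
    m <- isotope_measurement(df$specimen[i], df$d13c[i], df$d15n[i],
                             df$pct_c[i], df$pct_n[i],
                             element_type = df$element[i])
    extra <- setdiff(names(df), c(need, "element"))
    for (col in extra) attr(m, col) <- df[[col]][i]
    m
  })
  setNames(out, df$specimen)
}
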