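# Radiocarbon arithmetic, single-date calibration, Ward-Wilson combination,
# and the fraction-modern-carbon contamination mixing model.

#' Convert between conventional 14C age and fraction modern carbon
#'
#' F14C is the sample's 14C/12C ratio relative to the modern reference
#' standard; the conventional age is `t = -8033 * ln(F)` (Libby mean-life).
#' The two functions are mutually inverse to better than 1e-9.
#'
#' @param age_bp conventional 14C age, yr BP.
#' @return `f14c_from_age`: fraction modern; `age_from_f14c`: 14C yr BP.
#' @export
f14c_from_age <- function(age_bp) exp(-age_bp / .LIBBY_MEAN_LIFE)

#' @rdname f14c_from_age
#' @param f14c fraction modern carbon (> 0).
#' @export
age_from_f14c <- function(f14c) {
  if (any(f14c <= 0)) stop("F14C must be positive")
  -.LIBBY_MEAN_LIFE * log(f14c)
}

#' Construct a radiocarbon date
#'
#' @param lab_code laboratory code.
#' @param age_bp conventional 14C age, yr BP.
#' @param sigma 1-sigma measurement error, 14C yr (> 0).
#' @return list of class `radiocarbon_date` with the F14C equivalent
#'   (`f14c`, `f14c_sigma`) attached.
#' @export
radiocarbon_date <- function(lab_code, age_bp, sigma) {
  stopifnot(is.numeric(age_bp), is.numeric(sigma), sigma > 0)
  f <- f14c_from_age(age_bp)
  structure(list(lab_code = as.character(lab_code), age_bp = age_bp,
                 sigma = sigma, f14c = f,
                 f14c_sigma = f * sigma / .LIBBY_MEAN_LIFE),
            class = "radiocarbon_date")
}

#' @export
print.radiocarbon_date <- function(x, ...) {
  cat(sprintf("%s: %.0f +/- %.0f 14C BP (F14C = %.5f)\n",
              x$lab_code, x$age_bp, x$sigma, x$f14c))
  invisible(x)
}

#' Read a calibration curve table
#'
#' Accepts the usual calibration-curve dialect: three leading columns cal BP,
#' 14C age, 1-sigma; comma- or whitespace-separated; `#` header lines and a
#' non-numeric first line are skipped.
#'
#' @param path curve file.
#' @return object of class `calibration_curve`: data.frame with `cal_bp`,
#'   `mu`, `sigma_curve`, sorted by increasing `cal_bp`.
#' @export
read_calibration_curve <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  first <- strsplit(trimws(lines[1]), "[,[:space:]]+")[[1]][1]
  if (is.na(suppressWarnings(as.numeric(first)))) lines <- lines[-1]
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  num <- t(vapply(parts, function(p) as.numeric(p[1:3]), numeric(3)))
  if (any(!is.finite(num))) stop("malformed curve line(s)")
  calibration_curve(num[, 1], num[, 2], num[, 3])
}

#' @rdname read_calibration_curve
#' @param cal_bp calendar grid, yr BP.
#' @param mu curve 14C age at each grid point.
#' @param sigma_curve curve 1-sigma (> 0).
#' @export
calibration_curve <- function(cal_bp, mu, sigma_curve) {
  ord <- order(cal_bp)
  cal_bp <- cal_bp[ord]; mu <- mu[ord]; sigma_curve <- sigma_curve[ord]
  if (any(duplicated(cal_bp))) stop("calendar grid must be strictly monotone")
  if (any(sigma_curve <= 0)) stop("curve sigma must be positive")
  structure(data.frame(cal_bp = cal_bp, mu = mu, sigma_curve = sigma_curve),
            class = c("calibration_curve", "data.frame"))
}

#' A synthetic identity calibration curve for tests and demos
#'
#' `mu(theta) = theta` with constant curve error: calibrating against it
#' reproduces a Gaussian posterior in calendar time, which makes closed-form
#' checks possible.
#'
#' @param from,to calendar span, yr BP.
#' @param by grid step, yr.
#' @param sigma_curve constant curve 1-sigma.
#' @return a [calibration_curve()].
#' @export
synthetic_identity_curve <- function(from = 0, to = 25000, by = 5,
                                     sigma_curve = 10) {
  grid <- seq(from, to, by = by)
  calibration_curve(grid, grid, rep(sigma_curve, length(grid)))
}

#' Calibrate a single radiocarbon date
#'
#' The curve is interpolated onto a 1-yr calendar grid and the posterior is
#' the normalized likelihood
#' `exp(-(age - mu(theta))^2 / (2 * (sigma^2 + sigma_curve(theta)^2)))`
#' (Gaussian on the 14C-age scale — standard for this age range). Ranges are
#' highest-posterior-density regions at 68.3% and 95.4% (possibly
#' multi-interval), endpoints rounded outward to `rounding` years; a
#' central-interval mode is also available. The median comes from the
#' posterior CDF.
#'
#' @param date a [radiocarbon_date()].
#' @param curve a [calibration_curve()].
#' @param rounding round range endpoints outward to this many years
#'   (default 10, matching the convention of printed ranges).
#' @param range_style `"hpd"` (default) or `"central"`.
#' @param grid_step calendar grid step in yr (default 1).
#' @return list of class `calibrated_date`: `lab_code`, `cal_bp` (grid),
#'   `posterior` (sums to 1), `median`, `ranges_1sigma`, `ranges_2sigma`
#'   (data.frames `older`/`younger`/`mass`), plus the inputs.
#' @export
calibrate <- function(date, curve, rounding = 10, range_style = c("hpd", "central"),
                      grid_step = 1) {
  stopifnot(inherits(date, "radiocarbon_date"), inherits(curve, "calibration_curve"))
  range_style <- match.arg(range_style)
  span <- range(curve$cal_bp)
  grid <- seq(span[1], span[2], by = grid_step)
  mu <- approx(curve$cal_bp, curve$mu, grid)$y
  sc <- approx(curve$cal_bp, curve$sigma_curve, grid)$y
  tot_sd <- sqrt(date$sigma^2 + sc^2)
  like <- dnorm(date$age_bp, mu, tot_sd)
  if (!any(like > 0)) stop("date lies outside the calibration curve span")
  # guard: mass piling up at the grid edge means the curve does not cover the date
  if (which.max(like) %in% c(1L, length(grid)))
    stop("date at the edge of curve coverage; supply a wider curve")
  post <- like / sum(like)

  cdf <- cumsum(post)
  med <- grid[which(cdf >= 0.5)[1]]

  hpd_ranges <- function(level) {
    ord <- order(post, decreasing = TRUE)
    need <- cumsum(post[ord]) < level
    k <- sum(need) + 1L              # smallest HPD set reaching the level
    sel <- sort(ord[seq_len(k)])
    runs <- split(sel, cumsum(c(1L, diff(sel) != 1L)))
    do.call(rbind, lapply(runs, function(r) {
      data.frame(older = ceiling(grid[max(r)] / rounding) * rounding,
                 younger = floor(grid[min(r)] / rounding) * rounding,
                 mass = sum(post[r]))
    }))
  }
  central_ranges <- function(level) {
    lo <- grid[which(cdf >= (1 - level) / 2)[1]]
    hi <- grid[which(cdf >= 1 - (1 - level) / 2)[1]]
    data.frame(older = ceiling(hi / rounding) * rounding,
               younger = floor(lo / rounding) * rounding,
               mass = level)
  }
  rng <- if (range_style == "hpd") hpd_ranges else central_ranges
  structure(list(lab_code = date$lab_code, cal_bp = grid, posterior = post,
                 median = med,
                 ranges_1sigma = rng(0.683), ranges_2sigma = rng(0.954),
                 date = date, range_style = range_style,
                 rounding = rounding),
            class = "calibrated_date")
}

#' @export
print.calibrated_date <- function(x, ...) {
  fmt <- function(r) paste(sprintf("%d-%d", r$older, r$younger), collapse = ", ")
  cat(sprintf("%s: median %.0f cal BP\n  68.3%%: %s\n  95.4%%: %s\n",
              x$lab_code, x$median, fmt(x$ranges_1sigma), fmt(x$ranges_2sigma)))
  invisible(x)
}

#' Separation between two calibrated medians
#'
#' @param cal_a,cal_b [calibrate()] results on the same curve.
#' @return list: `years` (absolute separation), `signed` (median_a -
#'   median_b; positive when `a` is older).
#' @export
median_separation <- function(cal_a, cal_b) {
  d <- cal_a$median - cal_b$median
  list(years = abs(d), signed = d)
}

#' Ward-Wilson test of combinability and pooled age
#'
#' Inverse-variance pooled mean with the chi-square homogeneity statistic
#' `sum(((age_i - pooled) / sigma_i)^2)` on `n - 1` degrees of freedom. Dates
#' are declared combinable when the statistic is below the 95% critical value.
#'
#' @param dates list of two or more [radiocarbon_date()]s.
#' @return list of class `ww_combination`: `combinable`, `chi2`, `df`,
#'   `critical`, `p_value`, `pooled_age`, `pooled_sigma`.
#' @export
ward_wilson_combine <- function(dates) {
  if (length(dates) < 2L) stop("need at least 2 dates to combine")
  ages <- vapply(dates, `[[`, 0, "age_bp")
  sig <- vapply(dates, `[[`, 0, "sigma")
  w <- 1 / sig^2
  pooled <- sum(w * ages) / sum(w)
  chi2 <- sum(((ages - pooled) / sig)^2)
  df <- length(dates) - 1L
  crit <- qchisq(0.95, df)
  structure(list(combinable = chi2 < crit, chi2 = chi2, df = df,
                 critical = crit, p_value = pchisq(chi2, df, lower.tail = FALSE),
                 pooled_age = pooled, pooled_sigma = sqrt(1 / sum(w))),
            class = "ww_combination")
}

#' @export
print.ww_combination <- function(x, ...) {
  cat(sprintf("pooled %.0f +/- %.0f 14C BP; chi2 = %.2f (df %d, crit %.2f) -> %s\n",
              x$pooled_age, x$pooled_sigma, x$chi2, x$df, x$critical,
              if (x$combinable) "combinable" else "NOT combinable"))
  invisible(x)
}

#' Contamination fraction required to shift one date onto another
#'
#' Inverts the linear F14C mixing model: if the true sample has fraction
#' modern `F_true` and the measurement shows `F_obs`, a contaminant of
#' fraction modern `f_contaminant` must make up
#' `c = (F_obs - F_true) / (f_contaminant - F_true)` of the carbon. A small
#' modern contamination therefore suffices to make an old sample look
#' substantially younger. `c` outside `[0, 1)` is flagged as
#' inconsistent-direction (e.g. an observed age *older* than truth cannot be
#' produced by a modern contaminant).
#'
#' @param true_date,observed_date [radiocarbon_date()]s (or bare ages in 14C
#'   yr BP).
#' @param f_contaminant fraction modern of the contaminant (default 1.0 =
#'   modern; post-bomb values > 1 allowed).
#' @return list of class `contamination_estimate`: `c` (fraction),
#'   `percent`, `consistent` (logical), `f_true`, `f_obs`, `f_contaminant`.
#' @export
required_contamination <- function(true_date, observed_date, f_contaminant = 1.0) {
  f_of <- function(d) if (inherits(d, "radiocarbon_date")) d$f14c else f14c_from_age(d)
  f_true <- f_of(true_date)
  f_obs <- f_of(observed_date)
  if (abs(f_contaminant - f_true) < 1e-12)
    stop("contaminant F14C equals the true sample F14C; mixing fraction undefined")
  c_ <- (f_obs - f_true) / (f_contaminant - f_true)
  structure(list(c = c_, percent = 100 * c_,
                 consistent = c_ >= 0 && c_ < 1,
                 f_true = f_true, f_obs = f_obs,
                 f_contaminant = f_contaminant),
            class = "contamination_estimate")
}

#' @export
print.contamination_estimate <- function(x, ...) {
  cat(sprintf("required contamination: %.2f%%%s\n", x$percent,
              if (x$consistent) "" else " (inconsistent direction)"))
  invisible(x)
}

#' Read a CSV table of radiocarbon dates
#'
#' Columns: `lab_code`, `age_bp`, `sigma`.
#'
#' @param path CSV file.
#' @return list of [radiocarbon_date()]s, named by lab code.
#' @export
read_c14_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("lab_code", "age_bp", "sigma")
  if (!all(need %in% names(df)))
    stop("date table needs columns: ", paste(need, collapse = ", "))
  out <- Map(radiocarbon_date, df$lab_code, df$age_bp, df$sigma)
  setNames(out, df$lab_code)
}
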