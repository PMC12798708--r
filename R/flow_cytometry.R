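#' Fit and correct exponential fluorescence decay
#'
#' Potentiometric dyes export from cells during a flow-cytometry session, so
#' the mean signal of repeated passes over the same samples decays
#' exponentially. The decay rate constant is estimated by log-linear least
#' squares of `log(signal)` on time, and the corrected signal is the fitted
#' signal at time zero. In pooled mode one rate is shared within each group
#' (strain x experiment, "each set of samples") with per-sample intercepts.
#'
#' @param series tibble with columns `sample`, `group`, `time_min`,
#'   `mean_signal`; at least two passes per fit (three or more
#'   recommended), strictly increasing times, positive signals.
#' @param pooled share one decay rate per group (default FALSE).
#' @return tibble with one row per sample: `sample`, `group`,
#'   `rate_constant` (per minute), `signal_t0`, `r_squared` (of the
#'   log-linear fit the sample participated in), `n_passes`.
#' @export
fit_decay <- function(series, pooled = FALSE) {
  need <- c("sample", "group", "time_min", "mean_signal")
  if (!all(need %in% names(series))) {
    stop("series must have columns: ", paste(need, collapse = ", "))
  }
  if (any(series$mean_signal <= 0)) {
    stop("non-positive signals: log-linear decay fit undefined")
  }
  fit_one <- function(df) {
    # one sample, or one group's samples with per-sample intercepts
    if (any(table(df$sample) < 2)) {
      stop("each sample needs at least 2 passes to fit a decay rate")
    }
    for (s in unique(df$sample)) {
      ts <- df$time_min[df$sample == s]
      if (any(diff(ts) <= 0)) stop("pass times must be strictly increasing")
    }
    multi <- length(unique(df$sample)) > 1
    fml <- if (multi) log(mean_signal) ~ 0 + sample + time_min else
      log(mean_signal) ~ time_min
    m <- lm(fml, data = df)
    # summary.lm warns on zero-residual (exactly exponential) input
    r2 <- suppressWarnings(summary(m)$r.squared)
    cf <- coef(m)
    rate <- -unname(cf[["time_min"]])
    ints <- if (multi) {
      setNames(unname(cf[paste0("sample", unique(df$sample))]),
               unique(df$sample))
    } else {
      setNames(unname(cf[[1]]), df$sample[1])
    }
    tibble::tibble(sample = names(ints),
                   group = df$group[match(names(ints), df$sample)],
                   rate_constant = rate,
                   signal_t0 = exp(unname(ints)),
                   r_squared = r2,
                   n_passes = as.integer(table(df$sample)[names(ints)]))
  }
  if (pooled) {
    dplyr::bind_rows(lapply(split(series, series$group), fit_one))
  } else {
    dplyr::bind_rows(lapply(split(series, series$sample), fit_one))
  }
}

#' Background-subtracted ratiometric TMRM signal of a plate well
#'
#' For paired signal/background wells read at two excitation wavelengths
#' (emission 605 nm, excitation 546 and 572 nm): the background well means
#' are subtracted per wavelength, the 572/546 ratio is formed per timepoint,
#' and timepoints are averaged into the final per-well value. Timepoints
#' with a non-positive background-subtracted denominator are flagged
#' invalid and excluded.
#'
#' @param signal tibble with columns `time`, `ex546`, `ex572` for the
#'   signal well.
#' @param background tibble in the same shape for the condition's
#'   background wells (averaged over wells and timepoints per wavelength).
#' @return list: `ratio_series` (tibble `time`, `ratio`, `valid`),
#'   `mean_ratio` (over valid timepoints), `n_invalid`.
#' @export
tmrm_ratio <- function(signal, background) {
  stopifnot(all(c("time", "ex546", "ex572") %in% names(signal)),
            all(c("ex546", "ex572") %in% names(background)))
  bg546 <- mean(background$ex546)
  bg572 <- mean(background$ex572)
  den <- signal$ex546 - bg546
  num <- signal$ex572 - bg572
  valid <- den > 0
  ratio <- ifelse(valid, num / den, NA_real_)
  if (!any(valid)) {
    stop("no valid timepoints: background exceeds signal at 546 nm throughout")
  }
  list(ratio_series = tibble::tibble(time = signal$time, ratio = ratio,
                                     valid = valid),
       mean_ratio = mean(ratio[valid]),
       n_invalid = sum(!valid))
}

#' Mitochondrial-mass adjustment of an MMP-sensitive signal
#'
#' The MMP-insensitive channel tracks mitochondrial mass; a mutant's
#' fractional change `d = mmpi_mutant / mmpi_wt - 1` relative to wild type
#' rescales its MMP-sensitive estimate so that mass differences do not
#' masquerade as potential differences. The default direction multiplies by
#' `(1 + d)`; `direction = "divide"` normalises by mass instead. Wild type
#' itself has `d = 0` and is unchanged either way.
#'
#' @param mmps_mutant the mutant's MMP-sensitive signal estimate (> 0).
#' @param mmpi_mutant_mean,mmpi_wt_mean mean MMP-insensitive signals of the
#'   mutant and of wild type (> 0; from young cells, 0-5 divisions).
#' @param direction `"multiply"` (default) or `"divide"`.
#' @return list of class `mass_adjustment`: `d`, `adjusted_mmps`,
#'   `direction`.
#' @export
mass_adjust <- function(mmps_mutant, mmpi_mutant_mean, mmpi_wt_mean,
                        direction = c("multiply", "divide")) {
  direction <- match.arg(direction)
  stopifnot(mmps_mutant > 0, mmpi_mutant_mean > 0, mmpi_wt_mean > 0)
  d <- mmpi_mutant_mean / mmpi_wt_mean - 1
  if (d <= -1) stop("fractional change d must exceed -1")
  adjusted <- if (direction == "multiply") mmps_mutant * (1 + d) else
    mmps_mutant / (1 + d)
  structure(list(d = d, adjusted_mmps = adjusted, direction = direction),
            class = "mass_adjustment")
}

#' Mitochondrial oxygen consumption rate
#'
#' Difference between the averaged OCR before and after addition of
#' antimycin A (which abolishes mitochondrial respiration), i.e. the
#' antimycin-sensitive portion of total OCR.
#'
#' @param before,after numeric OCR measurements in each phase (>= 1 each).
#' @return scalar mitochondrial OCR, `mean(before) - mean(after)`.
#' @export
mito_ocr <- function(before, after) {
  if (!length(before) || !length(after)) {
    stop("both measurement phases must be non-empty")
  }
  mean(before) - mean(after)
}
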