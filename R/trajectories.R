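#' Filter single-cell MMP trajectories
#'
#' Retains trajectories that (i) start at `start_time`, (ii) stop before the
#' `max_timepoint`-th sample on the fluorescence grid (guarding against
#' false event calls at the end of a run), and (iii) keep both reporter
#' signals above `min_signal` at every sample. The removal counts per
#' criterion are attached as the `"removed"` attribute (a cell failing
#' several criteria is counted under each).
#'
#' @param trajectories tidy trajectory tibble: `cell_id`, `experiment`,
#'   `time_h`, `divisions`, `mmp_s`, `mmp_i`, `died`, `divisions_at_death`.
#' @param start_time required first sample time (hours).
#' @param max_timepoint maximum number of samples per trajectory (a bound on
#'   the sampling-grid index; trajectories with `>= max_timepoint` samples
#'   are dropped).
#' @param min_signal strict lower bound applied to both `mmp_s` and `mmp_i`.
#' @return the filtered tibble (a pure selection of input rows), with
#'   attribute `removed = c(start, length, signal)` counting removed cells.
#' @export
filter_trajectories <- function(trajectories, start_time = 0,
                                max_timepoint = 300, min_signal = 50) {
  tr <- trajectories
  if (nrow(tr) == 0) {
    attr(tr, "removed") <- c(start = 0L, length = 0L, signal = 0L)
    return(tr)
  }
  key <- paste(tr$experiment, tr$cell_id, sep = "\r")
  per <- dplyr::summarise(dplyr::group_by(tibble::tibble(
    key = key, time_h = tr$time_h, mmp_s = tr$mmp_s, mmp_i = tr$mmp_i),
    .data$key),
    ok_start = min(.data$time_h) == start_time,
    ok_len = dplyr::n() < max_timepoint,
    ok_sig = all(.data$mmp_s > min_signal & .data$mmp_i > min_signal),
    .groups = "drop")
  keep_key <- per$key[per$ok_start & per$ok_len & per$ok_sig]
  out <- tr[key %in% keep_key, , drop = FALSE]
  attr(out, "removed") <- c(start = sum(!per$ok_start),
                            length = sum(!per$ok_len),
                            signal = sum(!per$ok_sig))
  out
}

#' MMP ratio of a trajectory table
#'
#' Adds the elementwise `ratio = mmp_s / mmp_i` column; the time base is
#' unchanged. Requires `mmp_i > 0` (guaranteed after filtering).
#'
#' @param trajectories trajectory tibble.
#' @return the tibble with a `ratio` column.
#' @export
mmp_ratio <- function(trajectories) {
  if (any(trajectories$mmp_i <= 0)) stop("mmp_i must be positive")
  dplyr::mutate(trajectories, ratio = .data$mmp_s / .data$mmp_i)
}

#' Center a ratio series by its mean
#'
#' Divides each value by the series mean, so the centered series has mean
#' exactly 1. Applied per cell when comparing trajectories across cells.
#'
#' @param ratio numeric series with positive mean.
#' @return centered series.
#' @export
center_trajectory <- function(ratio) {
  m <- mean(ratio)
  if (!is.finite(m) || m <= 0) stop("series mean must be positive")
  ratio / m
}

# per-cell centered ratio column added to a trajectory table
add_centered_ratio <- function(trajectories) {
  tr <- mmp_ratio(trajectories)
  dplyr::mutate(dplyr::group_by(tr, .data$experiment, .data$cell_id),
                centered = center_trajectory(.data$ratio)) |>
    dplyr::ungroup()
}

#' Early-life mean MMP ratio of one cell
#'
#' Mean of the MMP ratio over samples taken at division counts in
#' `[0, max_divisions]` inclusive (the cell's "young" window). Raw (not
#' centered) ratios are averaged, so the predictor carries no information
#' from the rest of the trajectory.
#'
#' @param divisions,ratio aligned per-sample vectors for one cell.
#' @param max_divisions inclusive upper bound of the young window.
#' @return scalar mean, or `NA` when no sample qualifies.
#' @export
early_life_mean <- function(divisions, ratio, max_divisions = 5) {
  sel <- divisions >= 0 & divisions <= max_divisions
  if (!any(sel)) return(NA_real_)
  mean(ratio[sel])
}

#' Correlation between early-life MMP ratio and replicative lifespan
#'
#' Pearson correlation (with two-sided p-value from [stats::cor.test()])
#' between each cell's early-life mean MMP ratio and the number of
#' divisions it completed before death. Only cells observed to die and with
#' a defined early-life mean enter.
#'
#' @param trajectories trajectory tibble.
#' @param max_divisions inclusive young-window bound (default 5 divisions).
#' @return list of class `correlation_result`: `r`, `p`, `n`.
#' @export
lifespan_correlation <- function(trajectories, max_divisions = 5) {
  tr <- mmp_ratio(trajectories)
  per <- dplyr::summarise(
    dplyr::group_by(tr, .data$experiment, .data$cell_id),
    early = early_life_mean(.data$divisions, .data$ratio, max_divisions),
    died = .data$died[1],
    lifespan = .data$divisions_at_death[1],
    .groups = "drop")
  per <- per[per$died & !is.na(per$early) & !is.na(per$lifespan), ]
  if (nrow(per) < 3) {
    stop("lifespan correlation needs at least 3 dead cells with a defined ",
         "early-life mean")
  }
  ct <- cor.test(per$early, per$lifespan, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = nrow(per)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f, p = %.3g, n = %d\n",
              x$r, x$p, x$n))
  invisible(x)
}

#' Mean trajectory with error band
#'
#' Bins the per-cell centered MMP ratios along time or division count and
#' returns the across-cell mean with two-SEM error bounds per bin. Cells
#' contributing several samples to one bin are first averaged within the
#' cell, so the SEM reflects between-cell variation.
#'
#' @param trajectories trajectory tibble.
#' @param axis `"time"` (hours) or `"divisions"`.
#' @param bin_width bin width on the chosen axis.
#' @param center divide each cell's ratio series by its mean first
#'   (default TRUE).
#' @return tibble: `bin` (left edge), `mean`, `sem`, `n_cells`,
#'   `low_n` flag for bins with fewer than 2 cells.
#' @export
mean_trajectory <- function(trajectories, axis = c("time", "divisions"),
                            bin_width = 2, center = TRUE) {
  axis <- match.arg(axis)
  stopifnot(nrow(trajectories) > 0, bin_width > 0)
  tr <- if (center) add_centered_ratio(trajectories) else
    dplyr::mutate(mmp_ratio(trajectories), centered = .data$ratio)
  ax <- if (axis == "time") tr$time_h else tr$divisions
  tr$bin <- floor(ax / bin_width) * bin_width
  per_cell <- dplyr::summarise(
    dplyr::group_by(tr, .data$bin, .data$experiment, .data$cell_id),
    v = mean(.data$centered), .groups = "drop")
  out <- dplyr::summarise(
    dplyr::group_by(per_cell, .data$bin),
    mean = mean(.data$v),
    sem = if (dplyr::n() > 1) sd(.data$v) / sqrt(dplyr::n()) else 0,
    n_cells = dplyr::n(),
    .groups = "drop")
  out$low_n <- out$n_cells < 2
  out
}

#' Windowed MMP-ratio summary with bootstrap confidence interval
#'
#' Mean of the log10 MMP ratio over all samples in the age window
#' `[t0, t1]` hours, per group, with a nonparametric bootstrap CI obtained
#' by resampling cells (not samples), respecting the within-cell
#' correlation of repeated measures.
#'
#' @param trajectories trajectory tibble.
#' @param t0,t1 window bounds in hours (defaults 21.5 and 26.5, the window
#'   used for 24-h-old cells).
#' @param group name of the grouping column (default `"experiment"`).
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap.
#' @return tibble per group: `group`, `n_cells`, `n_samples`,
#'   `mean_log10_ratio`, `ci_lower`, `ci_upper`, `empty` flag for groups
#'   with no samples in the window.
#' @export
window_mean <- function(trajectories, t0 = 21.5, t1 = 26.5,
                        group = "experiment", n_boot = 1000, conf = 0.95,
                        seed = 1L) {
  if (t1 <= t0) stop("window must be non-degenerate (t1 > t0)")
  tr <- mmp_ratio(trajectories)
  set.seed(as.integer(seed))
  groups <- unique(tr[[group]])
  rows <- lapply(groups, function(g) {
    sub <- tr[tr[[group]] == g & tr$time_h >= t0 & tr$time_h <= t1, ]
    if (nrow(sub) == 0) {
      return(tibble::tibble(group = g, n_cells = 0L, n_samples = 0L,
                            mean_log10_ratio = NA_real_,
                            ci_lower = NA_real_, ci_upper = NA_real_,
                            empty = TRUE))
    }
    cells <- split(log10(sub$ratio), sub$cell_id)
    est <- mean(unlist(cells))
    boots <- vapply(seq_len(n_boot), function(b) {
      mean(unlist(cells[sample.int(length(cells), replace = TRUE)]))
    }, numeric(1))
    qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                   names = FALSE)
    tibble::tibble(group = g, n_cells = length(cells),
                   n_samples = nrow(sub), mean_log10_ratio = est,
                   ci_lower = qs[1], ci_upper = qs[2], empty = FALSE)
  })
  dplyr::bind_rows(rows)
}
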