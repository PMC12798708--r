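#' Strain-by-sample sorted-bin count matrix
#'
#' Container for barcode counts across FACS-sorted bins: a non-negative
#' integer matrix (strains x samples) plus a sample sheet with bin,
#' timepoint, replicate and experiment labels.
#'
#' @param counts non-negative integer matrix, rownames = strain ids.
#' @param samples tibble with columns `sample`, `bin` (one of
#'   `low`/`medium`/`high`), `timepoint`, `replicate`, `experiment`; rows
#'   match the columns of `counts`.
#' @return list of class `bin_count_matrix` with elements `counts`,
#'   `samples`.
#' @export
bin_count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  need <- c("sample", "bin", "timepoint", "replicate", "experiment")
  if (!all(need %in% names(samples))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(samples) != ncol(counts)) {
    stop("sample sheet rows must match count columns")
  }
  if (anyNA(samples$bin) || anyNA(samples$timepoint)) {
    stop("every sample needs bin and timepoint labels")
  }
  bad <- setdiff(unique(samples$bin), c("low", "medium", "high"))
  if (length(bad)) stop("unknown bin label(s): ", paste(bad, collapse = ", "))
  colnames(counts) <- samples$sample
  structure(list(counts = counts, samples = tibble::as_tibble(samples)),
            class = "bin_count_matrix")
}

#' @export
print.bin_count_matrix <- function(x, ...) {
  cat(sprintf("<bin_count_matrix> %d strains x %d samples (bins: %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sort(unique(x$samples$bin)), collapse = "/")))
  invisible(x)
}

# Pool technical replicates by summation within the high and low bins.
pool_high_low <- function(bcm) {
  stopifnot(inherits(bcm, "bin_count_matrix"))
  hi <- bcm$samples$bin == "high"
  lo <- bcm$samples$bin == "low"
  if (!any(hi) || !any(lo)) {
    stop("matrix must contain at least one high and one low sample")
  }
  c_high <- rowSums(bcm$counts[, hi, drop = FALSE])
  c_low <- rowSums(bcm$counts[, lo, drop = FALSE])
  if (sum(c_high) == 0 || sum(c_low) == 0) {
    stop("all-zero library in the high or low bin")
  }
  list(c_high = c_high, c_low = c_low,
       N_high = sum(c_high), N_low = sum(c_low))
}

#' Per-strain log2 enrichment, high vs low bin
#'
#' Pseudocounted log2 fold change of a strain's relative abundance in the
#' pooled high-bin libraries versus the pooled low-bin libraries:
#' `log2((c_hi + pc) / (N_hi + S*pc)) - log2((c_lo + pc) / (N_lo + S*pc))`
#' with `S` the number of strains and `N` the pooled library sizes.
#'
#' @param bcm a [bin_count_matrix()] with >= 1 high and >= 1 low sample.
#' @param pseudocount added per strain per bin (default 0.5, the standard
#'   half-integer correction keeping zero-count fold changes finite).
#' @return named numeric vector of per-strain log2 fold changes.
#' @export
log2_enrichment <- function(bcm, pseudocount = 0.5) {
  stopifnot(pseudocount > 0)
  p <- pool_high_low(bcm)
  S <- length(p$c_high)
  log2((p$c_high + pseudocount) / (p$N_high + S * pseudocount)) -
    log2((p$c_low + pseudocount) / (p$N_low + S * pseudocount))
}

#' Per-strain exact binomial enrichment test
#'
#' Conditional on a strain's pooled total `c_hi + c_lo`, tests whether the
#' split between bins departs from the library-size expectation
#' `p0 = N_hi / (N_hi + N_lo)` with a two-sided exact binomial test
#' (minimal-likelihood rule: outcomes with probability at most that of the
#' observed count contribute to the p-value). Strains with zero pooled
#' counts get p = 1 by convention.
#'
#' @param bcm a [bin_count_matrix()].
#' @return named numeric vector of p-values in (0, 1].
#' @export
enrichment_test <- function(bcm) {
  p <- pool_high_low(bcm)
  p0 <- p$N_high / (p$N_high + p$N_low)
  tot <- p$c_high + p$c_low
  pv <- rep(1, length(tot))
  nz <- which(tot > 0)
  pv[nz] <- vapply(nz, function(i) {
    binom.test(p$c_high[i], tot[i], p = p0)$p.value
  }, numeric(1))
  pmin(pv, 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1 (delegates to [stats::p.adjust()]).
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  p.adjust(p_values, method = "BH")
}

#' Rank strains by high-vs-low enrichment
#'
#' Convenience wrapper running [log2_enrichment()], [enrichment_test()] and
#' [bh_adjust()] on one matrix.
#'
#' @inheritParams log2_enrichment
#' @return tibble: `strain_id`, `counts_high`, `counts_low`, `log2fc`,
#'   `p_value`, `q_value`.
#' @export
enrich_strains <- function(bcm, pseudocount = 0.5) {
  p <- pool_high_low(bcm)
  lfc <- log2_enrichment(bcm, pseudocount)
  pv <- enrichment_test(bcm)
  tibble::tibble(strain_id = rownames(bcm$counts),
                 counts_high = p$c_high,
                 counts_low = p$c_low,
                 log2fc = unname(lfc),
                 p_value = unname(pv),
                 q_value = unname(bh_adjust(pv)))
}

#' Select the top-ranked strains
#'
#' Strains are ordered by ascending q-value, then descending log2 fold
#' change, then strain id (a total order, so the selection is deterministic
#' under input permutation).
#'
#' @param results tibble from [enrich_strains()].
#' @param n number of strains to return.
#' @return the first `n` rows of the ranked results, with a `rank` column.
#' @export
select_top <- function(results, n = 35) {
  stopifnot(nrow(results) > 0, n >= 0)
  ord <- order(results$q_value, -results$log2fc, results$strain_id)
  ranked <- results[ord, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  if (n > nrow(ranked)) {
    warning(sprintf("requested top %d of %d strains; returning all", n,
                    nrow(ranked)))
    n <- nrow(ranked)
  }
  ranked[seq_len(n), , drop = FALSE]
}

#' Deming errors-in-variables regression
#'
#' Closed-form fit of a line when both variables carry measurement error,
#' minimising the sum of weighted perpendicular (at `lambda = 1`,
#' orthogonal) squared distances. `lambda` is the ratio of the error
#' variance in `y` to that in `x`; at `lambda = 1` the fit is symmetric in
#' the axes (swapping x and y inverts the slope), and as `lambda` grows the
#' fit approaches ordinary least squares of y on x.
#'
#' @param x,y paired numeric vectors, at least two distinct points.
#' @param lambda positive error-variance ratio (default 1).
#' @return list of class `deming_fit`: `slope`, `intercept`, `lambda`, `n`.
#' @export
deming_fit <- function(x, y, lambda = 1) {
  stopifnot(length(x) == length(y), lambda > 0)
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (nrow(unique(cbind(x, y))) < 2) {
    stop("Deming regression needs at least two distinct points")
  }
  s_xx <- mean((x - mean(x))^2)
  s_yy <- mean((y - mean(y))^2)
  s_xy <- mean((x - mean(x)) * (y - mean(y)))
  if (s_xy == 0) {
    if (isTRUE(all.equal(s_yy, lambda * s_xx))) {
      stop("orientation undefined: zero covariance with balanced variances")
    }
    if (s_yy > lambda * s_xx) {
      stop("orientation undefined: best fit is a vertical line")
    }
    slope <- 0
  } else {
    disc <- (s_yy - lambda * s_xx)^2 + 4 * lambda * s_xy^2
    slope <- (s_yy - lambda * s_xx + sqrt(disc)) / (2 * s_xy)
  }
  structure(list(slope = slope,
                 intercept = mean(y) - slope * mean(x),
                 lambda = lambda,
                 n = length(x)),
            class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("<deming_fit> slope %.4f, intercept %.4f (lambda = %g, n = %d)\n",
              x$slope, x$intercept, x$lambda, x$n))
  invisible(x)
}
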