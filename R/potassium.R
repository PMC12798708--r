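#' Spherical cell volume from diameter
#'
#' Cells are approximated as spheres, so a Coulter diameter `d` in
#' micrometres maps to a volume of `pi/6 * d^3` femtolitres
#' (1 cubic micrometre = 1 fL).
#'
#' @param d diameter(s) in micrometres, > 0.
#' @return volume(s) in fL.
#' @export
volume_from_diameter <- function(d) {
  if (any(d <= 0)) stop("diameter must be positive")
  pi / 6 * d^3
}

#' Blank-subtracted potassium measurement
#'
#' Total elemental potassium collected from a filtered cell sample, with
#' the filter blank subtracted. A negative blank-subtracted amount is
#' reported as 0 with a warning flag rather than propagated.
#'
#' @param raw_mol raw potassium on the filter (mol).
#' @param blank_mol potassium on the blank filter (mol).
#' @param n_cells number of cells collected (> 0).
#' @return list of class `potassium_measurement`: `total_potassium_mol`
#'   (blank-subtracted), `blank_potassium_mol`, `n_cells_sampled`,
#'   `negative_after_blank` flag.
#' @export
potassium_measurement <- function(raw_mol, blank_mol, n_cells) {
  stopifnot(raw_mol >= 0, blank_mol >= 0, n_cells > 0)
  net <- raw_mol - blank_mol
  negative <- net < 0
  if (negative) {
    warning("blank exceeds raw potassium; total set to 0")
    net <- 0
  }
  structure(list(total_potassium_mol = net,
                 blank_potassium_mol = blank_mol,
                 n_cells_sampled = n_cells,
                 negative_after_blank = negative),
            class = "potassium_measurement")
}

# mM = mol / (cells * fL); 1 fL = 1e-15 L and 1 mM = 1e-3 mol/L, so the
# mol-per-(cell fL) quantity converts by 1e18.
MM_PER_MOL_FL <- 1e18

#' Internal potassium concentration of a cell population
#'
#' Converts a blank-subtracted total potassium amount into an internal
#' concentration using the cell count and the mean spherical cell volume:
#' `concentration = total / (n_cells * mean_volume)`.
#'
#' @param meas a [potassium_measurement()].
#' @param mean_volume_fl mean cell volume in fL (> 0).
#' @return concentration in mM (0, with the measurement's warning flag,
#'   when the blank exceeded the raw signal).
#' @export
internal_concentration <- function(meas, mean_volume_fl) {
  stopifnot(inherits(meas, "potassium_measurement"), mean_volume_fl > 0)
  meas$total_potassium_mol /
    (meas$n_cells_sampled * mean_volume_fl) * MM_PER_MOL_FL
}

# log-sum-exp-free mixture log-likelihood: densities here are far from
# underflow on the diameter scale
gmm_loglik <- function(x, w, mu, sigma) {
  dens <- vapply(1:3, function(j) w[j] * dnorm(x, mu[j], sigma[j]),
                 numeric(length(x)))
  sum(log(rowSums(dens) + .Machine$double.xmin))
}

# k-means++-style seeded initial means: first mean a random data point,
# subsequent means drawn with probability proportional to squared distance
# from the nearest already-chosen mean.
gmm_init <- function(x, k = 3L) {
  mu <- numeric(k)
  mu[1] <- x[sample.int(length(x), 1L)]
  for (j in 2:k) {
    d2 <- vapply(seq_len(j - 1L), function(i) (x - mu[i])^2,
                 numeric(length(x)))
    nearest <- if (j == 2L) d2[, 1] else apply(d2, 1L, min)
    if (all(nearest == 0)) {
      mu[j] <- x[sample.int(length(x), 1L)]
    } else {
      mu[j] <- x[sample.int(length(x), 1L, prob = nearest)]
    }
  }
  mu
}

#' Three-component Gaussian mixture fit of a size distribution
#'
#' Maximum-likelihood univariate three-Gaussian mixture, fit by
#' expectation-maximisation with seeded random restarts; the best
#' log-likelihood across starts is kept. Components are relabeled by
#' ascending mean, and the smallest-mean component is designated the
#' daughter class (`daughter_index = 1`). The per-iteration log-likelihood
#' trace of the winning start is returned, and is non-decreasing by
#' construction of EM.
#'
#' @param diameters numeric vector of cell diameters (micrometres),
#'   at least 30 observations.
#' @param n_starts random restarts (default 10).
#' @param max_iter EM iteration cap per start.
#' @param tol convergence tolerance on the relative log-likelihood change.
#' @param var_floor variance floor in square micrometres; components
#'   collapsing below it are floored and flagged degenerate.
#' @param seed integer seed for the restarts.
#' @return list of class `mixture_fit`: `components` (tibble `mean`, `sd`,
#'   `weight`, ascending mean), `daughter_index` (always 1 after
#'   relabeling), `log_likelihood`, `ll_trace`, `converged`, `degenerate`,
#'   `n_iter`, `n_obs`.
#' @export
fit_gmm3 <- function(diameters, n_starts = 10, max_iter = 1000,
                     tol = 1e-8, var_floor = 1e-4, seed = 1L) {
  x <- diameters[!is.na(diameters)]
  if (length(x) < 30) stop("need at least 30 diameter observations")
  stopifnot(n_starts >= 1, max_iter >= 1, tol > 0, var_floor > 0)
  set.seed(as.integer(seed))
  n <- length(x)
  best <- NULL
  for (s in seq_len(n_starts)) {
    mu <- gmm_init(x)
    sigma <- rep(max(sd(x) / 2, sqrt(var_floor)), 3)
    w <- rep(1 / 3, 3)
    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    degenerate <- FALSE
    for (it in seq_len(max_iter)) {
      dens <- vapply(1:3, function(j) w[j] * dnorm(x, mu[j], sigma[j]),
                     numeric(n))
      row_tot <- rowSums(dens) + .Machine$double.xmin
      resp <- dens / row_tot
      ll <- sum(log(row_tot))
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      nk <- colSums(resp)
      nk[nk == 0] <- .Machine$double.eps
      w <- nk / n
      mu <- colSums(resp * x) / nk
      v <- vapply(1:3, function(j) {
        sum(resp[, j] * (x - mu[j])^2) / nk[j]
      }, numeric(1))
      if (any(v < var_floor)) {
        degenerate <- TRUE
        v <- pmax(v, var_floor)
      }
      sigma <- sqrt(v)
    }
    cand <- list(w = w, mu = mu, sigma = sigma, ll = ll_trace[length(ll_trace)],
                 ll_trace = ll_trace, converged = converged,
                 degenerate = degenerate, n_iter = length(ll_trace))
    if (is.null(best) || cand$ll > best$ll) best <- cand
  }
  ord <- order(best$mu)
  structure(list(
    components = tibble::tibble(mean = best$mu[ord], sd = best$sigma[ord],
                                weight = best$w[ord]),
    daughter_index = 1L,
    log_likelihood = best$ll,
    ll_trace = best$ll_trace,
    converged = best$converged,
    degenerate = best$degenerate,
    n_iter = best$n_iter,
    n_obs = n), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(paste0("<mixture_fit> 3 Gaussians on %d diameters, ",
                     "logLik %.2f (%s%s)\n"),
              x$n_obs, x$log_likelihood,
              if (x$converged) "converged" else "NOT converged",
              if (x$degenerate) ", degenerate component floored" else ""))
  print(x$components)
  cat(sprintf("  daughter component: %d (smallest mean)\n", x$daughter_index))
  invisible(x)
}

#' Split an aged culture into daughter and old-mother populations
#'
#' Apportions the culture's cell count to the fitted mixture components:
#' the smallest-mean component is the daughter class, the two larger
#' components are summed into the old-cell class. Mean class volumes use
#' the sphere of the component mean diameter by default; the
#' moment-correct alternative uses `E[d^3] = mu^3 + 3 mu sigma^2` for
#' Gaussian diameters (the sphere-of-mean choice underestimates the mean
#' volume by the Jensen gap).
#'
#' @param fit a [fit_gmm3()] result (must have converged).
#' @param total_cell_count cells in the sampled culture.
#' @param volume `"sphere-of-mean"` (default) or `"moment"`.
#' @return list of class `population_split`: `n_daughter`, `n_old` (summing
#'   exactly to the total), `mean_volume_daughter_fl`, `mean_volume_old_fl`.
#' @export
split_population <- function(fit, total_cell_count,
                             volume = c("sphere-of-mean", "moment")) {
  volume <- match.arg(volume)
  stopifnot(inherits(fit, "mixture_fit"), total_cell_count > 0)
  if (!fit$converged) stop("mixture fit did not converge")
  comp <- fit$components
  vol <- if (volume == "moment") {
    pi / 6 * (comp$mean^3 + 3 * comp$mean * comp$sd^2)
  } else {
    volume_from_diameter(comp$mean)
  }
  w_old <- comp$weight[2:3] / sum(comp$weight[2:3])
  n_daughter <- comp$weight[1] * total_cell_count
  structure(list(n_daughter = n_daughter,
                 n_old = total_cell_count - n_daughter,
                 mean_volume_daughter_fl = vol[1],
                 mean_volume_old_fl = sum(w_old * vol[2:3])),
            class = "population_split")
}

#' Bounded estimates of old-cell internal potassium
#'
#' An aged culture mixes old mothers with contaminating daughters, so its
#' total potassium cannot be attributed directly. Two estimates bound the
#' old-cell concentration: assuming daughters carry the young-culture
#' concentration `c_young` yields the point estimate
#' `(K_total - n_d * V_d * c_young) / (n_o * V_o)`; assuming daughters
#' carry none yields the maximum upper bound `K_total / (n_o * V_o)`. A
#' negative point estimate is reported with a warning flag, never clipped.
#'
#' @param split a [split_population()] result.
#' @param meas a [potassium_measurement()] for the same culture sample
#'   (its `n_cells_sampled` should equal the split's total).
#' @param c_young young-culture internal potassium (mM, >= 0).
#' @return list of class `potassium_estimate`:
#'   `estimate_young_daughters` (mM), `upper_bound` (mM),
#'   `negative_estimate` flag.
#' @export
old_cell_potassium <- function(split, meas, c_young) {
  stopifnot(inherits(split, "population_split"),
            inherits(meas, "potassium_measurement"), c_young >= 0)
  if (split$n_old <= 0) stop("no old cells in the split")
  k_daughters_mol <- split$n_daughter * split$mean_volume_daughter_fl *
    c_young / MM_PER_MOL_FL
  denom <- split$n_old * split$mean_volume_old_fl / MM_PER_MOL_FL
  estimate <- (meas$total_potassium_mol - k_daughters_mol) / denom
  upper <- meas$total_potassium_mol / denom
  negative <- estimate < 0
  if (negative) {
    warning("daughter-corrected estimate is negative: the assumed young ",
            "concentration overexplains the measured potassium")
  }
  structure(list(estimate_young_daughters = estimate,
                 upper_bound = upper,
                 negative_estimate = negative),
            class = "potassium_estimate")
}

#' @export
print.potassium_estimate <- function(x, ...) {
  cat(sprintf(paste0("<potassium_estimate> old cells: %.1f mM ",
                     "(upper bound %.1f mM)%s\n"),
              x$estimate_young_daughters, x$upper_bound,
              if (x$negative_estimate) " [negative estimate!]" else ""))
  invisible(x)
}
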