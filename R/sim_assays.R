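#' Simulate an exponentially decaying fluorescence signal
#'
#' Emulates repeated flow-cytometry passes over the same stained samples:
#' dye export makes the mean signal decay exponentially over the course of
#' the analysis, so the signal at pass time `t` is
#' `initial * exp(-rate * t) * (1 + eps)` with `eps` mean-zero multiplicative
#' noise of coefficient of variation `noise_cv`.
#'
#' @param n_passes number of repeated measurement passes (>= 2; the decay
#'   rate is unidentifiable from a single pass).
#' @param rate decay rate constant per minute (>= 0).
#' @param initial signal at time zero (> 0).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @param interval_min minutes between passes.
#' @param sample,group sample and group labels carried into the output.
#' @return tibble with columns `sample`, `group`, `time_min`, `mean_signal`,
#'   timestamps strictly increasing.
#' @export
simulate_decay <- function(n_passes, rate, initial, noise_cv = 0,
                           seed = 1L, interval_min = 5,
                           sample = "s1", group = "g1") {
  if (n_passes < 2) stop("n_passes must be >= 2: decay is unidentifiable")
  stopifnot(rate >= 0, initial > 0, noise_cv >= 0, interval_min > 0)
  set.seed(as.integer(seed))
  t <- seq(0, by = interval_min, length.out = n_passes)
  eps <- if (noise_cv > 0) rnorm(n_passes, 0, noise_cv) else rep(0, n_passes)
  tibble::tibble(sample = sample, group = group, time_min = t,
                 mean_signal = initial * exp(-rate * t) * (1 + eps))
}

#' Size-distribution simulation configuration
#'
#' Parameters of the aged-culture cell-size generator: cell diameters come
#' from a three-component Gaussian mixture (small newly budded daughters
#' plus two larger old-mother classes), and each cell carries potassium at
#' its class concentration. Defaults describe an aged culture with heavy
#' daughter contamination in which old mothers hold less potassium than
#' young cells.
#'
#' @param component_means three component mean diameters (micrometres).
#' @param component_sds three component sds (micrometres, > 0).
#' @param component_weights three mixing weights summing to 1.
#' @param n_cells number of cells drawn.
#' @param daughter_concentration internal potassium of the daughter class
#'   (mM); the daughter class is the component with the smallest mean.
#' @param old_concentration internal potassium of the two old-mother
#'   classes (mM).
#' @param seed integer seed.
#' @return list of class `size_sim_config`.
#' @export
size_sim_config <- function(component_means = c(3, 5, 6.5),
                            component_sds = c(0.3, 0.3, 0.3),
                            component_weights = c(0.5, 0.3, 0.2),
                            n_cells = 50000,
                            daughter_concentration = 200,
                            old_concentration = 150,
                            seed = 1L) {
  stopifnot(length(component_means) == 3, length(component_sds) == 3,
            length(component_weights) == 3)
  if (any(component_means <= 0)) stop("component means must be positive")
  if (any(component_sds <= 0)) stop("component sds must be positive")
  if (abs(sum(component_weights) - 1) > 1e-8) {
    stop("component weights must sum to 1")
  }
  stopifnot(n_cells >= 1, daughter_concentration >= 0,
            old_concentration >= 0)
  structure(list(component_means = component_means,
                 component_sds = component_sds,
                 component_weights = component_weights,
                 n_cells = as.integer(n_cells),
                 daughter_concentration = daughter_concentration,
                 old_concentration = old_concentration,
                 seed = as.integer(seed)),
            class = "size_sim_config")
}

#' Simulate an aged-culture size distribution with per-class potassium
#'
#' Diameters are drawn from the configured three-Gaussian mixture (negative
#' draws are rejected and resampled, with the rejection count reported).
#' Cells generated by the smallest-mean component are the daughter class and
#' carry `daughter_concentration` of potassium; the other two classes carry
#' `old_concentration`. The sample's total potassium is the sum over cells
#' of spherical cell volume times class concentration.
#'
#' @param cfg a [size_sim_config()].
#' @return list with `sizes` (tibble `diameter_um`, `component`),
#'   `total_potassium_mol`, `n_rejected` and `truth` (the generating
#'   parameters plus the daughter component index).
#' @export
simulate_sizes <- function(cfg) {
  stopifnot(inherits(cfg, "size_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_cells
  comp <- sample.int(3L, n, replace = TRUE, prob = cfg$component_weights)
  d <- rnorm(n, cfg$component_means[comp], cfg$component_sds[comp])
  n_rejected <- 0L
  bad <- which(d <= 0)
  while (length(bad)) {
    n_rejected <- n_rejected + length(bad)
    d[bad] <- rnorm(length(bad), cfg$component_means[comp[bad]],
                    cfg$component_sds[comp[bad]])
    bad <- bad[d[bad] <= 0]
  }
  daughter <- which.min(cfg$component_means)
  conc <- ifelse(comp == daughter, cfg$daughter_concentration,
                 cfg$old_concentration)
  total_K <- sum(volume_from_diameter(d) * conc) * 1e-18  # fL * mM -> mol
  list(sizes = tibble::tibble(diameter_um = d, component = comp),
       total_potassium_mol = total_K,
       n_rejected = n_rejected,
       truth = list(component_means = cfg$component_means,
                    component_sds = cfg$component_sds,
                    component_weights = cfg$component_weights,
                    daughter_component = daughter,
                    daughter_concentration = cfg$daughter_concentration,
                    old_concentration = cfg$old_concentration))
}
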