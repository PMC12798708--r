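#' Trajectory simulation configuration
#'
#' Parameters of the single-cell MMP-trajectory generator, which emulates
#' microfluidic lifespan microscopy of mother cells carrying a two-channel
#' MMP reporter: an MMP-sensitive signal (`mmp_s`) that declines
#' multiplicatively with each division and an MMP-insensitive signal
#' (`mmp_i`) that stays roughly constant, so the MMP ratio `mmp_s / mmp_i`
#' declines with age. A correlation between the early-life mean ratio and
#' replicative lifespan is planted at `target_correlation`.
#'
#' @param n_cells number of mother cells.
#' @param target_correlation planted Pearson correlation, in (-1, 1),
#'   between the early-life (0-5 division) mean MMP ratio and divisions at
#'   death.
#' @param decline_per_division fractional loss of `mmp_s` per division.
#' @param noise_sd sd of multiplicative log-normal measurement noise on each
#'   channel sample.
#' @param censor_fraction fraction of cells censored (washed out) before
#'   death.
#' @param sample_interval_h fluorescence sampling interval (hours).
#' @param division_interval_h nominal time per division (hours); divisions
#'   advance deterministically on this grid.
#' @param mean_lifespan,sd_lifespan mean and sd of the latent lifespan
#'   distribution (divisions).
#' @param seed integer seed.
#' @return list of class `trajectory_sim_config`.
#' @export
trajectory_sim_config <- function(n_cells = 1000,
                                  target_correlation = 0.55,
                                  decline_per_division = 0.05,
                                  noise_sd = 0.1,
                                  censor_fraction = 0.1,
                                  sample_interval_h = 2,
                                  division_interval_h = 1.5,
                                  mean_lifespan = 25,
                                  sd_lifespan = 8,
                                  seed = 1L) {
  if (abs(target_correlation) >= 1) {
    stop("target_correlation must lie strictly inside (-1, 1)")
  }
  if (censor_fraction < 0 || censor_fraction > 1) {
    stop("censor_fraction must be a probability")
  }
  stopifnot(n_cells >= 1, decline_per_division > 0, decline_per_division < 1,
            noise_sd >= 0, sample_interval_h > 0, division_interval_h > 0,
            mean_lifespan > 6, sd_lifespan > 0)
  structure(list(n_cells = as.integer(n_cells),
                 target_correlation = target_correlation,
                 decline_per_division = decline_per_division,
                 noise_sd = noise_sd,
                 censor_fraction = censor_fraction,
                 sample_interval_h = sample_interval_h,
                 division_interval_h = division_interval_h,
                 mean_lifespan = mean_lifespan,
                 sd_lifespan = sd_lifespan,
                 seed = as.integer(seed)),
            class = "trajectory_sim_config")
}

#' Simulate single-cell MMP-ratio trajectories with a planted lifespan link
#'
#' Each cell's `mmp_s` starts at a log-normally dispersed baseline and loses
#' `decline_per_division` of its value per division; `mmp_i` is constant up
#' to noise. Divisions advance on a fixed time grid (one division per
#' `division_interval_h`). Lifespans are drawn from a Gaussian whose latent
#' score mixes the cell's realised early-life mean ratio with independent
#' noise so that the population correlation between early-life mean ratio
#' and divisions at death equals `target_correlation` (up to rounding of the
#' lifespan to whole divisions). A `censor_fraction` of cells is censored at
#' a uniform time before death.
#'
#' @param cfg a [trajectory_sim_config()].
#' @param experiment experiment label carried into the output.
#' @return tibble with columns `cell_id`, `experiment`, `time_h`,
#'   `divisions`, `mmp_s`, `mmp_i`, `died`, `divisions_at_death` (NA when
#'   censored); one row per sample, samples in time order within cell.
#' @export
simulate_trajectories <- function(cfg, experiment = "sim") {
  stopifnot(inherits(cfg, "trajectory_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_cells
  rho <- cfg$target_correlation
  # generation horizon: past essentially all lifespans
  max_div <- ceiling(cfg$mean_lifespan + 4.5 * cfg$sd_lifespan)
  t_grid <- seq(0, max_div * cfg$division_interval_h,
                by = cfg$sample_interval_h)
  div_grid <- pmin(floor(t_grid / cfg$division_interval_h), max_div)
  nt <- length(t_grid)

  s0 <- 400 * exp(rnorm(n, 0, 0.15))   # baseline MMP_s, log-normal spread
  i0 <- 200                            # common MMP_i baseline
  decline <- (1 - cfg$decline_per_division) ^ div_grid
  mmp_s <- outer(decline, s0) * exp(matrix(rnorm(nt * n, 0, cfg$noise_sd),
                                           nt, n))
  mmp_i <- matrix(i0, nt, n) * exp(matrix(rnorm(nt * n, 0, cfg$noise_sd),
                                          nt, n))
  ratio <- mmp_s / mmp_i

  early <- div_grid <= 5
  early_mean <- colMeans(ratio[early, , drop = FALSE])
  z_m <- as.numeric(scale(early_mean))
  latent <- rho * z_m + sqrt(1 - rho^2) * rnorm(n)
  lifespan <- pmax(6L, as.integer(round(cfg$mean_lifespan +
                                          cfg$sd_lifespan * latent)))

  censored <- runif(n) < cfg$censor_fraction
  death_time <- lifespan * cfg$division_interval_h
  end_time <- ifelse(censored,
                     runif(n, min = 10, max = pmax(10.5, death_time)),
                     death_time)

  cell_len <- vapply(end_time, function(e) sum(t_grid < e), integer(1))
  idx <- sequence(cell_len)
  cell_of <- rep.int(seq_len(n), cell_len)
  flat <- idx + (cell_of - 1L) * nt
  tibble::tibble(
    cell_id = sprintf("cell_%05d", cell_of),
    experiment = experiment,
    time_h = t_grid[idx],
    divisions = div_grid[idx],
    mmp_s = mmp_s[flat],
    mmp_i = mmp_i[flat],
    died = !censored[cell_of],
    divisions_at_death = ifelse(censored[cell_of], NA_integer_,
                                lifespan[cell_of]))
}
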