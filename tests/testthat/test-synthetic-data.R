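test_that("catalog generation enforces uniqueness, separation, determinism", {
  cfg <- screen_sim_config(n_strains = 10, barcode_length = 20,
                           min_pairwise_hamming = 5, n_hit_strains = 0,
                           seed = 1)
  cat1 <- make_catalog(cfg)
  expect_equal(nrow(cat1), 10)
  expect_false(anyDuplicated(cat1$barcode) > 0)
  expect_false(anyDuplicated(cat1$strain_id) > 0)
  # exhaustive pairwise Hamming check
  mats <- lapply(cat1$barcode, function(b) strsplit(b, "")[[1]])
  for (i in 1:9) for (j in (i + 1):10) {
    expect_gte(sum(mats[[i]] != mats[[j]]), 5)
  }
  # seeded determinism: byte-identical
  cat2 <- make_catalog(cfg)
  expect_identical(cat1$barcode, cat2$barcode)
  expect_identical(cat1$strain_id, cat2$strain_id)
})

test_that("infeasible separation fails with an explicit error", {
  expect_error(screen_sim_config(n_strains = 5, barcode_length = 2,
                                 min_pairwise_hamming = 3,
                                 n_hit_strains = 0),
               "min_pairwise_hamming")
  # feasible config but impossible packing: 4^1 = 4 sequences at distance 1
  cfg <- screen_sim_config(n_strains = 5, barcode_length = 1,
                           min_pairwise_hamming = 1, n_hit_strains = 0,
                           seed = 1)
  expect_error(make_catalog(cfg, max_attempts_per_strain = 20),
               "infeasible")
})

test_that("error-free screen reads contain exact catalog barcodes between exact flanks", {
  cfg <- screen_sim_config(n_strains = 8, read_depth = 60, n_hit_strains = 2,
                           substitution_rate = 0, flank_mismatch_rate = 0,
                           junk_read_fraction = 0, n_replicates = 1, seed = 4)
  catalog <- make_catalog(cfg)
  scr <- simulate_screen(catalog, cfg)
  pat <- paste0(cfg$flank_up, "([ACGT]{20})", cfg$flank_down)
  for (p in scr$pairs) {
    expect_equal(nrow(p), 60)
    hits <- regmatches(p$sense_seq, regexec(pat, p$sense_seq))
    bc <- vapply(hits, function(h) h[2], "")
    expect_false(anyNA(bc))
    expect_true(all(bc %in% catalog$barcode))
    # antisense mate is the exact reverse complement in the no-error limit
    expect_identical(revcomp(p$antisense_seq), p$sense_seq)
  }
})

test_that("null screen gives equal bin probabilities and centered enrichment", {
  cfg <- screen_sim_config(n_strains = 30, n_hit_strains = 5, hit_effect = 0,
                           read_depth = 20000, n_replicates = 1, seed = 2)
  catalog <- make_catalog(cfg)
  sim <- simulate_bin_counts(catalog, cfg)
  # with hit_effect = 0 all strains share one Gaussian: every bin membership
  # probability is exactly 1/3
  expect_equal(sim$truth$p_low, rep(1 / 3, 30), tolerance = 1e-8)
  expect_equal(sim$truth$p_high, rep(1 / 3, 30), tolerance = 1e-8)
  # Monte-Carlo: high-vs-low log2 enrichment of "hits" centers on 0
  lfcs <- vapply(1:100, function(s) {
    cfg_s <- screen_sim_config(n_strains = 30, n_hit_strains = 5,
                               hit_effect = 0, read_depth = 20000,
                               n_replicates = 1, seed = 1000 + s)
    sim_s <- simulate_bin_counts(catalog, cfg_s)
    mean(log2_enrichment(sim_s$counts)[sim_s$truth$is_hit])
  }, numeric(1))
  expect_lt(abs(mean(lfcs)), 3 * sd(lfcs) / sqrt(length(lfcs)) + 0.01)
})

test_that("strong hits exceed a 1/3 high-bin share, matching numerical integration", {
  cfg <- screen_sim_config(n_strains = 20, n_hit_strains = 3, hit_effect = 2,
                           read_depth = 0, abundance_dispersion = 0.5,
                           seed = 9)
  catalog <- make_catalog(cfg)
  sim <- simulate_bin_counts(catalog, cfg)
  truth <- sim$truth
  expect_true(all(truth$p_high[truth$is_hit] > 1 / 3))
  # independent oracle: integrate the strain's Gaussian over the tertile
  # cut verified against numerical integration of the pooled mixture mass
  w <- truth$abundance
  mix_dens <- function(x) {
    rowSums(vapply(seq_len(nrow(truth)),
                   function(i) w[i] * dnorm(x, truth$mu[i], 1),
                   numeric(length(x))))
  }
  bp <- bin_probabilities(truth$mu, truth$abundance)
  mass_below_q2 <- integrate(mix_dens, -12, bp$cuts[2],
                             rel.tol = 1e-10)$value
  expect_equal(mass_below_q2, 2 / 3, tolerance = 1e-6)
  for (i in which(truth$is_hit)) {
    p_high_oracle <- integrate(function(x) dnorm(x, truth$mu[i], 1),
                               bp$cuts[2], Inf, rel.tol = 1e-10)$value
    expect_equal(truth$p_high[i], p_high_oracle, tolerance = 1e-6)
  }
})

test_that("screen generators are pure functions of their config seed", {
  cfg <- screen_sim_config(n_strains = 6, read_depth = 40,
                           substitution_rate = 0.02,
                           flank_mismatch_rate = 0.1,
                           junk_read_fraction = 0.1, n_replicates = 1,
                           n_hit_strains = 1, seed = 5)
  catalog <- make_catalog(cfg)
  s1 <- simulate_screen(catalog, cfg)
  s2 <- simulate_screen(catalog, cfg)
  expect_identical(s1$pairs, s2$pairs)
  expect_identical(s1$counts$counts, s2$counts$counts)
})

test_that("zero read depth yields empty (but valid) FASTQ files", {
  cfg <- screen_sim_config(n_strains = 4, read_depth = 0, n_hit_strains = 0,
                           n_replicates = 1, seed = 6)
  catalog <- make_catalog(cfg)
  dir <- withr::local_tempdir()
  scr <- simulate_screen(catalog, cfg, dir = dir)
  expect_true(all(file.exists(scr$files$r1)))
  expect_identical(read_fastq_pairs(scr$files$r1[1], scr$files$r2[1]),
                   scr$pairs[[1]][0, ])
})

test_that("FASTQ round trip preserves sequences and qualities", {
  cfg <- screen_sim_config(n_strains = 5, read_depth = 30, n_hit_strains = 0,
                           n_replicates = 1, junk_read_fraction = 0.1,
                           seed = 8)
  catalog <- make_catalog(cfg)
  dir <- withr::local_tempdir()
  scr <- simulate_screen(catalog, cfg, dir = dir)
  back <- read_fastq_pairs(scr$files$r1[1], scr$files$r2[1])
  expect_equal(back, scr$pairs[[1]])
})

test_that("noiseless trajectories follow the closed-form multiplicative decline", {
  cfg <- trajectory_sim_config(n_cells = 20, decline_per_division = 0.05,
                               noise_sd = 0, censor_fraction = 0, seed = 3)
  tr <- simulate_trajectories(cfg)
  r0 <- dplyr::summarise(dplyr::group_by(mmp_ratio(tr), cell_id),
                         r0 = ratio[divisions == 0][1],
                         .groups = "drop")
  tr2 <- dplyr::left_join(mmp_ratio(tr), r0, by = "cell_id")
  expect_equal(tr2$ratio, tr2$r0 * 0.95^tr2$divisions, tolerance = 1e-12)
  # determinism
  expect_identical(tr, simulate_trajectories(cfg))
})

test_that("trajectory config rejects out-of-range correlations", {
  expect_error(trajectory_sim_config(target_correlation = 1),
               "target_correlation")
  expect_error(trajectory_sim_config(target_correlation = -1.2),
               "target_correlation")
})

test_that("decay series follows initial*exp(-rate*t) and validates inputs", {
  expect_error(simulate_decay(1, 0.05, 100), "n_passes")
  d0 <- simulate_decay(3, 0, 42, noise_cv = 0, seed = 1)
  expect_equal(d0$mean_signal, rep(42, 3))
  d1 <- simulate_decay(3, 0.05, 100, noise_cv = 0, seed = 1)
  expect_equal(d1$time_min, c(0, 5, 10))
  expect_equal(d1$mean_signal, 100 * exp(-0.05 * c(0, 5, 10)))
  expect_true(all(diff(d1$time_min) > 0))
})

test_that("size simulation matches the potassium arithmetic oracle", {
  # single dominant component, almost-zero spread: total K is n * V * c
  cfg <- size_sim_config(component_means = c(10, 10.0001, 10.0002),
                        component_sds = rep(1e-9, 3),
                        component_weights = c(1 - 2e-12, 1e-12, 1e-12),
                        n_cells = 1000, daughter_concentration = 200,
                        old_concentration = 200, seed = 2)
  sim <- simulate_sizes(cfg)
  oracle <- 1000 * (pi / 6 * 10^3) * 200 * 1e-18
  expect_equal(sim$total_potassium_mol, oracle, tolerance = 1e-6)
  # determinism
  expect_identical(sim$sizes, simulate_sizes(cfg)$sizes)
})

test_that("component draw fractions match the configured weights", {
  cfg <- size_sim_config(component_weights = c(0.5, 0.3, 0.2),
                        n_cells = 50000, seed = 12)
  sim <- simulate_sizes(cfg)
  frac <- tabulate(sim$sizes$component, 3) / 50000
  # exact multinomial 99.9% CI half-widths
  for (j in 1:3) {
    w <- cfg$component_weights[j]
    ci <- qnorm(0.9995) * sqrt(w * (1 - w) / 50000)
    expect_lt(abs(frac[j] - w), ci + 1e-12)
  }
  expect_equal(sim$truth$daughter_component, 1)
})
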