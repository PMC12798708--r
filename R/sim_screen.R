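#' Sorted-bin membership probabilities under the screen model
#'
#' The generator's population model: strain `i` contributes cells whose log
#' MMP ratio is Normal with mean `mu[i]` and unit sd; the pooled live-mother
#' population (a mixture weighted by strain abundance) is sorted into
#' low/medium/high bins at the empirical tertiles of the pooled ratio
#' distribution, mirroring a FACS sort that splits the distribution into
#' thirds. Tertile cutpoints are the roots of the mixture CDF at 1/3 and 2/3.
#'
#' @param mu per-strain mean log MMP ratio.
#' @param abundance per-strain pool abundance (normalised internally).
#' @return list with `cuts` (the two tertile cutpoints on the log-ratio
#'   scale) and `probs`, a strains x 3 matrix of per-strain bin membership
#'   probabilities (columns `low`, `medium`, `high`; rows sum to 1).
#' @export
bin_probabilities <- function(mu, abundance = rep(1, length(mu))) {
  stopifnot(length(mu) == length(abundance), all(abundance > 0))
  w <- abundance / sum(abundance)
  mix_cdf <- function(x) sum(w * pnorm(x - mu))
  lo <- min(mu) - 8
  hi <- max(mu) + 8
  q1 <- uniroot(function(x) mix_cdf(x) - 1 / 3, c(lo, hi), tol = 1e-10)$root
  q2 <- uniroot(function(x) mix_cdf(x) - 2 / 3, c(lo, hi), tol = 1e-10)$root
  p_low <- pnorm(q1 - mu)
  p_med <- pnorm(q2 - mu) - p_low
  p_high <- 1 - pnorm(q2 - mu)
  list(cuts = c(q1, q2),
       probs = cbind(low = p_low, medium = p_med, high = p_high))
}

# Strain abundances and planted hits for one simulated screen; shared by the
# count-level and read-level generators. Assumes set.seed was already called.
screen_truth_draw <- function(catalog, cfg) {
  n <- nrow(catalog)
  abundance <- rlnorm(n, meanlog = 0, sdlog = cfg$abundance_dispersion)
  abundance <- abundance / sum(abundance)
  hit_idx <- if (cfg$n_hit_strains > 0) {
    sort(sample.int(n, cfg$n_hit_strains))
  } else {
    integer(0)
  }
  mu <- rep(0, n)
  mu[hit_idx] <- cfg$hit_effect
  bp <- bin_probabilities(mu, abundance)
  tibble::tibble(strain_id = catalog$strain_id,
                 is_hit = seq_len(n) %in% hit_idx,
                 mu = mu,
                 abundance = abundance,
                 p_low = bp$probs[, "low"],
                 p_medium = bp$probs[, "medium"],
                 p_high = bp$probs[, "high"])
}

#' Simulate sorted-bin barcode counts (count level, no reads)
#'
#' Draws the per-bin strain counts of a pooled MMP screen without emitting
#' sequencing reads: per bin and replicate, `read_depth` reads are a
#' multinomial draw over strains with probability proportional to
#' `abundance * P(bin | strain)`.
#'
#' @param catalog a [barcode_catalog()].
#' @param cfg a [screen_sim_config()].
#' @param timepoint sample timepoint label.
#' @param experiment experiment label.
#' @return list with `counts` (a [bin_count_matrix()]) and `truth` (tibble of
#'   per-strain abundance, planted-hit flag and bin probabilities).
#' @export
simulate_bin_counts <- function(catalog, cfg, timepoint = "T24",
                                experiment = "sim") {
  stopifnot(inherits(catalog, "barcode_catalog"),
            inherits(cfg, "screen_sim_config"))
  set.seed(cfg$seed)
  truth <- screen_truth_draw(catalog, cfg)
  bins <- c("low", "medium", "high")
  samples <- tibble::tibble(
    sample = paste(experiment, timepoint,
                   rep(bins, each = cfg$n_replicates),
                   paste0("rep", rep(seq_len(cfg$n_replicates),
                                     times = length(bins))),
                   sep = "_"),
    bin = rep(bins, each = cfg$n_replicates),
    timepoint = timepoint,
    replicate = rep(seq_len(cfg$n_replicates), times = length(bins)),
    experiment = experiment)
  counts <- matrix(0L, nrow = nrow(catalog), ncol = nrow(samples),
                   dimnames = list(catalog$strain_id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    p <- truth$abundance * truth[[paste0("p_", samples$bin[j])]]
    if (cfg$read_depth > 0) {
      counts[, j] <- as.integer(rmultinom(1, cfg$read_depth, p / sum(p)))
    }
  }
  list(counts = bin_count_matrix(counts, samples), truth = truth)
}

# Apply substitution errors at `rate` per base to an integer base matrix
# (L x n, codes 1..4); substituted bases move to one of the 3 other bases.
apply_substitutions <- function(mat, rate) {
  if (rate <= 0) return(mat)
  hit <- which(runif(length(mat)) < rate)
  if (length(hit)) {
    mat[hit] <- ((mat[hit] - 1L + sample.int(3L, length(hit),
                                             replace = TRUE)) %% 4L) + 1L
  }
  mat
}

seq_to_codes <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
}

codes_to_seqs <- function(mat) {
  # L x n matrix of codes 1..4 -> n sequences
  apply(mat, 2L, function(v) paste(DNA_BASES[v], collapse = ""))
}

# Random Phred+33 quality strings, qualities uniform in [30, 40]
random_quals <- function(n, len) {
  vapply(seq_len(n), function(i) {
    int_to_phred(sample(30:40, len, replace = TRUE))
  }, character(1))
}

# Emit n read pairs for the given barcode codes (L x n), with flank
# corruption, substitution errors and junk reads, as a tibble of sequences
# and qualities. Pads of 3 random nt are added at both ends so the flanks
# are internal, as in a sequenced amplicon.
emit_read_pairs <- function(barcode_codes, cfg, id_prefix) {
  n <- ncol(barcode_codes)
  if (n == 0) {
    return(tibble::tibble(read_id = character(0), sense_seq = character(0),
                          sense_qual = character(0),
                          antisense_seq = character(0),
                          antisense_qual = character(0)))
  }
  fu <- seq_to_codes(cfg$flank_up)
  fd <- seq_to_codes(cfg$flank_down)
  pad <- 3L
  L_read <- pad + length(fu) + nrow(barcode_codes) + length(fd) + pad
  construct <- rbind(
    matrix(sample.int(4L, pad * n, replace = TRUE), nrow = pad),
    matrix(rep(fu, n), ncol = n),
    barcode_codes,
    matrix(rep(fd, n), ncol = n),
    matrix(sample.int(4L, pad * n, replace = TRUE), nrow = pad))
  # flank corruption: with prob flank_mismatch_rate per flank copy, plant two
  # substitutions inside that flank (per mate, drawn independently below via
  # shared construct corruption before strand copies are made)
  corrupt_flank <- function(mat, offset, flen) {
    hit <- which(runif(ncol(mat)) < cfg$flank_mismatch_rate)
    for (j in hit) {
      pos <- offset + sample.int(flen, 2L)
      mat[pos, j] <- ((mat[pos, j] - 1L +
                         sample.int(3L, 2L, replace = TRUE)) %% 4L) + 1L
    }
    mat
  }
  construct <- corrupt_flank(construct, pad, length(fu))
  construct <- corrupt_flank(construct, pad + length(fu) +
                               nrow(barcode_codes), length(fd))
  sense <- apply_substitutions(construct, cfg$substitution_rate)
  anti <- apply_substitutions((5L - construct)[rev(seq_len(L_read)), ,
                                               drop = FALSE],
                              cfg$substitution_rate)
  n_junk <- if (cfg$junk_read_fraction > 0 && n > 0) {
    max(0L, as.integer(round(n * cfg$junk_read_fraction /
                               (1 - cfg$junk_read_fraction))))
  } else 0L
  if (n_junk > 0) {
    junk1 <- matrix(sample.int(4L, L_read * n_junk, replace = TRUE),
                    nrow = L_read)
    junk2 <- matrix(sample.int(4L, L_read * n_junk, replace = TRUE),
                    nrow = L_read)
    sense <- cbind(sense, junk1)
    anti <- cbind(anti, junk2)
  }
  n_tot <- n + n_junk
  ids <- sprintf("%s_read%06d%s", id_prefix, seq_len(n_tot),
                 c(rep("", n), rep("_junk", n_junk)))
  tibble::tibble(read_id = ids,
                 sense_seq = unname(codes_to_seqs(sense)),
                 sense_qual = random_quals(n_tot, L_read),
                 antisense_seq = unname(codes_to_seqs(anti)),
                 antisense_qual = random_quals(n_tot, L_read))
}

#' Simulate a full pooled screen: paired FASTQ, truth counts, planted hits
#'
#' Runs the count-level generator ([simulate_bin_counts()]) and then emits
#' each counted read as a sense/antisense pair (the antisense mate is the
#' reverse complement of the amplicon before errors; errors are drawn
#' independently per mate). Junk read pairs of uniform random sequence are
#' appended in addition to the counted reads, so the returned truth counts
#' always refer to real reads.
#'
#' @inheritParams simulate_bin_counts
#' @param dir directory into which per-sample FASTQ pairs are written;
#'   created if missing. `NULL` keeps the reads in memory only.
#' @return list with `pairs` (named list of read-pair tibbles, one per
#'   sample), `files` (manifest tibble of written FASTQ paths, or `NULL`),
#'   `counts` (truth [bin_count_matrix()]) and `truth` (per-strain tibble).
#' @export
simulate_screen <- function(catalog, cfg, dir = NULL, timepoint = "T24",
                            experiment = "sim") {
  sim <- simulate_bin_counts(catalog, cfg, timepoint = timepoint,
                             experiment = experiment)
  counts <- sim$counts
  barcode_codes <- vapply(catalog$barcode, seq_to_codes,
                          integer(cfg$barcode_length))  # L x n_strains
  pairs <- vector("list", ncol(counts$counts))
  names(pairs) <- colnames(counts$counts)
  for (j in seq_along(pairs)) {
    cts <- counts$counts[, j]
    strain_rep <- rep.int(seq_along(cts), cts)
    strain_rep <- sample(strain_rep)  # shuffle read order within the sample
    pairs[[j]] <- emit_read_pairs(
      barcode_codes[, strain_rep, drop = FALSE], cfg,
      id_prefix = names(pairs)[j])
  }
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- tibble::tibble(sample = names(pairs),
                            r1 = file.path(dir, paste0(names(pairs),
                                                       "_R1.fastq")),
                            r2 = file.path(dir, paste0(names(pairs),
                                                       "_R2.fastq")))
    for (j in seq_along(pairs)) {
      write_fastq_pairs(pairs[[j]], files$r1[j], files$r2[j])
    }
  }
  list(pairs = pairs, files = files, counts = counts, truth = sim$truth)
}

#' Write / read paired FASTQ files
#'
#' Order-matched mates with `/1` and `/2` name suffixes, Phred+33 qualities.
#' I/O goes through Biostrings.
#'
#' @param pairs tibble with columns `read_id`, `sense_seq`, `sense_qual`,
#'   `antisense_seq`, `antisense_qual`.
#' @param r1,r2 file paths for the sense and antisense mates.
#' @return `write_fastq_pairs` returns the paths invisibly;
#'   `read_fastq_pairs` returns a read-pair tibble.
#' @export
write_fastq_pairs <- function(pairs, r1, r2) {
  write_one <- function(seqs, quals, ids, suffix, path) {
    # Biostrings notes dropped metadata columns on conversion; irrelevant here
    x <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs),
      Biostrings::PhredQuality(quals)))
    names(x) <- paste0(ids, suffix)
    Biostrings::writeQualityScaledXStringSet(x, path)
  }
  if (nrow(pairs) == 0) {
    file.create(r1)
    file.create(r2)
  } else {
    write_one(pairs$sense_seq, pairs$sense_qual, pairs$read_id, "/1", r1)
    write_one(pairs$antisense_seq, pairs$antisense_qual, pairs$read_id,
              "/2", r2)
  }
  invisible(c(r1, r2))
}

#' @rdname write_fastq_pairs
#' @export
read_fastq_pairs <- function(r1, r2) {
  read_one <- function(path) {
    if (file.size(path) == 0) {
      return(list(ids = character(0), seqs = character(0),
                  quals = character(0)))
    }
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    list(ids = sub("/[12]$", "", sub(" .*$", "", names(x))),
         seqs = unname(as.character(x)),
         quals = unname(as.character(Biostrings::quality(x))))
  }
  a <- read_one(r1)
  b <- read_one(r2)
  if (length(a$ids) != length(b$ids) || !all(a$ids == b$ids)) {
    stop("mate files are not order-matched")
  }
  tibble::tibble(read_id = a$ids,
                 sense_seq = a$seqs, sense_qual = a$quals,
                 antisense_seq = b$seqs, antisense_qual = b$quals)
}
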