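#' Barcode catalog
#'
#' A catalog of known strain barcodes, the reference against which extracted
#' barcodes are assigned. Modeled on the yeast deletion collection, in which
#' every nonessential-gene deletion strain carries a unique 20-nt barcode
#' bracketed by constant priming sequences (the "flanks").
#'
#' @param strain_id character vector of unique strain identifiers.
#' @param gene character vector of gene names (same length).
#' @param barcode character vector of unique barcode sequences over
#'   `{A,C,G,T}`.
#' @param flank_up,flank_down the constant sequences immediately upstream and
#'   downstream of the barcode in the amplicon.
#' @return A tibble of class `barcode_catalog` with columns `strain_id`,
#'   `gene`, `barcode` and attributes `flank_up`, `flank_down`.
#' @export
barcode_catalog <- function(strain_id, gene, barcode, flank_up, flank_down) {
  stopifnot(length(strain_id) == length(gene),
            length(strain_id) == length(barcode))
  if (anyDuplicated(strain_id)) stop("strain_ids must be unique")
  if (anyDuplicated(barcode)) stop("barcodes must be unique")
  if (any(grepl("[^ACGT]", barcode))) {
    stop("barcodes must contain only A, C, G, T")
  }
  if (!nzchar(flank_up) || !nzchar(flank_down)) stop("flanks must be nonempty")
  if (any(grepl("[^ACGT]", c(flank_up, flank_down)))) {
    stop("flanks must contain only A, C, G, T")
  }
  out <- tibble::tibble(strain_id = as.character(strain_id),
                        gene = as.character(gene),
                        barcode = toupper(barcode))
  attr(out, "flank_up") <- toupper(flank_up)
  attr(out, "flank_down") <- toupper(flank_down)
  class(out) <- c("barcode_catalog", class(out))
  out
}

#' @export
print.barcode_catalog <- function(x, ...) {
  cat(sprintf("<barcode_catalog> %d strains, barcode length %d nt\n",
              nrow(x), nchar(x$barcode[1])))
  cat(sprintf("  flank_up:   %s\n  flank_down: %s\n",
              attr(x, "flank_up"), attr(x, "flank_down")))
  NextMethod()
}

catalog_flanks <- function(catalog) {
  list(up = attr(catalog, "flank_up"), down = attr(catalog, "flank_down"))
}

#' Write / read a barcode catalog as TSV
#'
#' The TSV carries columns `strain_id`, `gene`, `barcode`; the flanks are
#' stored in `# flank_up=` / `# flank_down=` header comment lines so that the
#' file is self-contained.
#'
#' @param catalog a [barcode_catalog()].
#' @param path file path.
#' @return `write_catalog` returns `path` invisibly; `read_catalog` returns a
#'   `barcode_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  fl <- catalog_flanks(catalog)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# flank_up=%s", fl$up),
               sprintf("# flank_down=%s", fl$down),
               paste(c("strain_id", "gene", "barcode"), collapse = "\t")), con)
  writeLines(paste(catalog$strain_id, catalog$gene, catalog$barcode,
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  hdr <- readLines(path, n = 2L)
  fu <- sub("^# flank_up=", "", hdr[1])
  fd <- sub("^# flank_down=", "", hdr[2])
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  barcode_catalog(df$strain_id, df$gene, df$barcode, fu, fd)
}

#' Screen simulation configuration
#'
#' Bundles all parameters of the pooled-screen generator. Defaults emulate a
#' deletion-collection screen: ~4,700 strains with unique 20-nt barcodes,
#' log-normal pool skew, and sequencing substitution errors.
#'
#' @param n_strains number of strains in the pool.
#' @param barcode_length barcode length in nt.
#' @param min_pairwise_hamming minimum pairwise Hamming distance enforced
#'   between catalog barcodes.
#' @param flank_up,flank_down constant sequences around the barcode.
#' @param substitution_rate per-base substitution error probability.
#' @param flank_mismatch_rate probability that a flank copy is corrupted
#'   (receives two random substitutions).
#' @param junk_read_fraction fraction of emitted reads that are uniform
#'   random sequence (flank-search decoys); junk reads are additional to the
#'   counted reads, so truth counts refer to real reads only.
#' @param read_depth reads per sorted bin per replicate.
#' @param n_hit_strains number of planted hit strains.
#' @param hit_effect upward shift of the hit strains' mean log MMP ratio, in
#'   units of the cell-level log-ratio standard deviation (fixed at 1).
#' @param abundance_dispersion log-normal sd of strain abundance in the pool.
#' @param n_replicates technical replicates per bin.
#' @param seed integer seed; every generator is a pure function of its
#'   config including the seed.
#' @return list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_strains = 4700,
                              barcode_length = 20,
                              min_pairwise_hamming = 5,
                              flank_up = "GATGTCCACGAGGTCTCT",
                              flank_down = "CGTACGCTGCAGGTCGAC",
                              substitution_rate = 0.005,
                              flank_mismatch_rate = 0.02,
                              junk_read_fraction = 0.01,
                              read_depth = 1e6,
                              n_hit_strains = 35,
                              hit_effect = 2,
                              abundance_dispersion = 0.5,
                              n_replicates = 2,
                              seed = 1L) {
  probs <- c(substitution_rate, flank_mismatch_rate, junk_read_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  stopifnot(n_strains >= 1, barcode_length >= 1, min_pairwise_hamming >= 0,
            read_depth >= 0, n_hit_strains >= 0, hit_effect >= 0,
            abundance_dispersion > 0, n_replicates >= 1)
  if (n_hit_strains > n_strains) stop("n_hit_strains must be <= n_strains")
  if (min_pairwise_hamming > barcode_length) {
    stop("min_pairwise_hamming cannot exceed barcode_length")
  }
  structure(list(n_strains = as.integer(n_strains),
                 barcode_length = as.integer(barcode_length),
                 min_pairwise_hamming = as.integer(min_pairwise_hamming),
                 flank_up = toupper(flank_up),
                 flank_down = toupper(flank_down),
                 substitution_rate = substitution_rate,
                 flank_mismatch_rate = flank_mismatch_rate,
                 junk_read_fraction = junk_read_fraction,
                 read_depth = as.integer(read_depth),
                 n_hit_strains = as.integer(n_hit_strains),
                 hit_effect = hit_effect,
                 abundance_dispersion = abundance_dispersion,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "screen_sim_config")
}

#' Generate a barcode catalog with enforced pairwise separation
#'
#' Barcodes are drawn uniformly over `{A,C,G,T}^L` and accepted only if their
#' Hamming distance to every previously accepted barcode is at least
#' `min_pairwise_hamming`. Rejection is bounded; infeasible separation
#' requests fail with an explicit error rather than looping forever.
#'
#' @param cfg a [screen_sim_config()].
#' @param max_attempts_per_strain rejection budget per requested strain.
#' @return a [barcode_catalog()] with `cfg$n_strains` records; deterministic
#'   given `cfg$seed`.
#' @export
make_catalog <- function(cfg, max_attempts_per_strain = 200L) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  n <- cfg$n_strains
  L <- cfg$barcode_length
  minh <- cfg$min_pairwise_hamming
  if (minh > L) stop("separation infeasible: min_pairwise_hamming > length")
  set.seed(cfg$seed)
  # accepted barcodes as an L x n integer matrix (base codes 1..4)
  acc <- matrix(0L, nrow = L, ncol = n)
  n_acc <- 0L
  attempts <- 0L
  budget <- max_attempts_per_strain * n
  while (n_acc < n) {
    if (attempts >= budget) {
      stop(sprintf(paste0("separation infeasible: could not place %d barcodes",
                          " of length %d at min pairwise Hamming %d within ",
                          "%d attempts"), n, L, minh, budget))
    }
    attempts <- attempts + 1L
    cand <- sample.int(4L, L, replace = TRUE)
    ok <- TRUE
    if (minh > 0L && n_acc > 0L) {
      d <- .colSums(acc[, seq_len(n_acc), drop = FALSE] != cand, L, n_acc)
      ok <- all(d >= minh)
    }
    if (ok) {
      n_acc <- n_acc + 1L
      acc[, n_acc] <- cand
    }
  }
  seqs <- apply(acc, 2L, function(v) paste(DNA_BASES[v], collapse = ""))
  if (minh == 0L && anyDuplicated(seqs)) {
    # uniqueness is still required even when no separation is requested
    while (anyDuplicated(seqs)) {
      dup <- which(duplicated(seqs))
      seqs[dup] <- vapply(dup, function(i) {
        paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
      }, character(1))
    }
  }
  width <- max(4L, nchar(as.character(n)))
  barcode_catalog(strain_id = sprintf(paste0("strain_%0", width, "d"),
                                      seq_len(n)),
                  gene = sprintf(paste0("GENE%0", width, "d"), seq_len(n)),
                  barcode = seqs,
                  flank_up = cfg$flank_up,
                  flank_down = cfg$flank_down)
}
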