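#' Locate the constant flanks around a barcode in a single read
#'
#' Sliding-window Hamming scan for `flank_up` and `flank_down` as contiguous
#' substrings of the read, each tolerating up to `max_mismatch` mismatches
#' (the budget applies per flank; `N` bases count as mismatches; indels are
#' not modeled). Among admissible placements, the pair with the fewest total
#' mismatches wins; ties resolve to the leftmost upstream window, then the
#' leftmost downstream window. `flank_up` must end at or before `flank_down`
#' starts.
#'
#' @param seq read sequence (single string over `{A,C,G,T,N}`).
#' @param flank_up,flank_down the constant sequences.
#' @param max_mismatch per-flank Hamming mismatch budget (default 2).
#' @return `NULL` when either flank cannot be placed within budget;
#'   otherwise a list with `start`, `end` (0-based half-open interval of the
#'   enclosed barcode region) and `up_mismatches`, `down_mismatches`.
#' @export
find_flanks <- function(seq, flank_up, flank_down, max_mismatch = 2) {
  stopifnot(length(seq) == 1, nchar(flank_up) >= 1, nchar(flank_down) >= 1,
            max_mismatch >= 0)
  m <- cpp_find_flanks(toupper(seq), toupper(flank_up), toupper(flank_down),
                       as.integer(max_mismatch))
  if (m[1, 5] == 0L) return(NULL)
  list(start = m[1, 1], end = m[1, 2],
       up_mismatches = m[1, 3], down_mismatches = m[1, 4])
}

#' Extract the barcode (and its qualities) from one mate
#'
#' Locates the flanks with [find_flanks()] and slices out the enclosed
#' barcode with its aligned Phred qualities. Antisense mates are reverse
#' complemented (and their qualities reversed) before the search, so the
#' extracted barcode is always in sense orientation.
#'
#' @param seq read sequence.
#' @param qual Phred+33 quality string, same length as `seq`.
#' @param flank_up,flank_down constant sequences in sense orientation.
#' @param max_mismatch per-flank mismatch budget.
#' @param orientation `"sense"` or `"antisense"`.
#' @return `NULL` if the flanks cannot be placed; otherwise a list with
#'   `barcode`, `qual` (the quality slice) and `flank` (the
#'   [find_flanks()] result). A zero-length barcode (adjacent flanks) is
#'   returned as an empty string and flagged invalid downstream.
#' @export
extract_barcode <- function(seq, qual, flank_up, flank_down,
                            max_mismatch = 2,
                            orientation = c("sense", "antisense")) {
  orientation <- match.arg(orientation)
  stopifnot(nchar(seq) == nchar(qual))
  if (orientation == "antisense") {
    seq <- revcomp(seq)
    qual <- str_reverse(qual)
  }
  fl <- find_flanks(seq, flank_up, flank_down, max_mismatch)
  if (is.null(fl)) return(NULL)
  list(barcode = substr(seq, fl$start + 1L, fl$end),
       qual = substr(qual, fl$start + 1L, fl$end),
       flank = fl)
}

#' Reconcile the sense and antisense barcode extractions of a read pair
#'
#' If both mates yielded a barcode and the sequences are identical, or only
#' one mate yielded one, that sequence is the call. If both are present with
#' equal length but differ, the per-position base with the higher Phred
#' score is taken (ties go to the sense base). Unequal-length conflicts have
#' no per-base merge; the mate with fewer total flank mismatches wins (tie:
#' higher mean barcode quality).
#'
#' @param sense_result,antisense_result extraction results from
#'   [extract_barcode()] (`NULL` when that mate failed).
#' @return list with `barcode` (string or `NA`) and `provenance`, one of
#'   `"both-identical"`, `"sense-only"`, `"antisense-only"`,
#'   `"quality-merged"`, `"none"`.
#' @export
reconcile_pair <- function(sense_result, antisense_result) {
  s <- sense_result
  a <- antisense_result
  if (is.null(s) && is.null(a)) {
    return(list(barcode = NA_character_, provenance = "none"))
  }
  if (is.null(a)) return(list(barcode = s$barcode, provenance = "sense-only"))
  if (is.null(s)) {
    return(list(barcode = a$barcode, provenance = "antisense-only"))
  }
  if (identical(s$barcode, a$barcode)) {
    return(list(barcode = s$barcode, provenance = "both-identical"))
  }
  if (nchar(s$barcode) == nchar(a$barcode)) {
    sb <- strsplit(s$barcode, "", fixed = TRUE)[[1]]
    ab <- strsplit(a$barcode, "", fixed = TRUE)[[1]]
    sq <- phred_to_int(s$qual)
    aq <- phred_to_int(a$qual)
    merged <- ifelse(aq > sq, ab, sb)  # tie -> sense base
    return(list(barcode = paste(merged, collapse = ""),
                provenance = "quality-merged"))
  }
  s_mm <- s$flank$up_mismatches + s$flank$down_mismatches
  a_mm <- a$flank$up_mismatches + a$flank$down_mismatches
  pick <- if (s_mm < a_mm) {
    s
  } else if (a_mm < s_mm) {
    a
  } else if (mean(phred_to_int(s$qual)) >= mean(phred_to_int(a$qual))) {
    s
  } else {
    a
  }
  list(barcode = pick$barcode, provenance = "quality-merged")
}

#' k-mer count vector of a sequence
#'
#' Counts all overlapping k-mers; k-mers containing `N` are skipped.
#'
#' @param seq sequence string, `nchar(seq) >= k`.
#' @param k k-mer size.
#' @return named integer vector of k-mer counts.
#' @export
kmer_vector <- function(seq, k = 3) {
  if (nchar(seq) < k) {
    stop(sprintf("sequence length %d is shorter than k = %d",
                 nchar(seq), k))
  }
  starts <- seq_len(nchar(seq) - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  tab <- table(kmers)
  setNames(as.integer(tab), names(tab))
}

# All 4^k DNA k-mers in lexicographic order (column space of k-mer count
# matrices). Guarded so the dense representation stays small.
all_kmers <- function(k) {
  if (k > 8) stop("k > 8 is not supported by the dense k-mer representation")
  do.call(paste0, rev(expand.grid(rep(list(DNA_BASES), k),
                                  stringsAsFactors = FALSE)))
}

# n x 4^k k-mer count matrix for a vector of sequences. Sequences shorter
# than k (incl. empty) get all-zero rows; N-containing k-mers are skipped.
kmer_matrix <- function(seqs, k) {
  universe <- all_kmers(k)
  n <- length(seqs)
  m <- matrix(0L, nrow = n, ncol = length(universe))
  lens <- nchar(seqs)
  usable <- which(!is.na(seqs) & lens >= k)
  if (length(usable)) {
    nk <- lens[usable] - k + 1L
    row_id <- rep.int(usable, nk)
    starts <- sequence(nk)
    kmers <- substring(seqs[row_id], starts, starts + k - 1L)
    col_id <- match(kmers, universe)   # NA for k-mers containing N
    ok <- !is.na(col_id)
    if (any(ok)) {
      flat <- (col_id[ok] - 1L) * n + row_id[ok]  # column-major linear index
      cts <- tabulate(flat, nbins = n * length(universe))
      nz <- which(cts > 0L)
      m[nz] <- cts[nz]
    }
  }
  m
}

# Row-normalise to unit Euclidean norm; all-zero rows stay zero.
row_unit <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- Inf
  m / nrm
}

#' Assign one barcode to its best catalog entry by k-mer cosine similarity
#'
#' The barcode and every catalog barcode are embedded as k-mer count
#' vectors; the cosine similarity `dot(b, c) / (|b| |c|)` is the match score
#' and doubles as the confidence in the assignment. The highest-scoring
#' catalog entry is returned; when two or more entries tie for the maximum
#' within `1e-12` the call is flagged ambiguous.
#'
#' @param barcode barcode string.
#' @param catalog a [barcode_catalog()].
#' @param k k-mer size (default 3; see Details).
#' @return list with `strain_id`, `score` and `ambiguous`. A zero-norm
#'   barcode (shorter than `k` or all `N`) yields `strain_id = NA`,
#'   `score = NA`.
#' @details With k = 3, a single substitution in a 20-nt barcode disturbs at
#'   most three of its eighteen 3-mers, so single-error barcodes keep a
#'   cosine score of about 15/18 ~ 0.833 against their origin, above the
#'   conservative 0.8 acceptance threshold.
#' @export
cosine_match <- function(barcode, catalog, k = 3) {
  stopifnot(inherits(catalog, "barcode_catalog"), nrow(catalog) > 0)
  res <- cosine_match_many(barcode, catalog, k)
  list(strain_id = res$matched_id[1], score = res$confidence[1],
       ambiguous = res$ambiguous[1])
}

#' @rdname cosine_match
#' @param barcodes character vector of barcodes (vectorised interface;
#'   duplicates are matched once and results recycled).
#' @return `cosine_match_many` returns a tibble with one row per input:
#'   `matched_id`, `confidence`, `ambiguous`.
#' @export
cosine_match_many <- function(barcodes, catalog, k = 3) {
  stopifnot(inherits(catalog, "barcode_catalog"), nrow(catalog) > 0, k >= 1)
  ub <- unique(barcodes[!is.na(barcodes)])
  out <- tibble::tibble(matched_id = rep(NA_character_, length(barcodes)),
                        confidence = NA_real_,
                        ambiguous = FALSE)
  if (!length(ub)) return(out)
  cat_m <- t(row_unit(kmer_matrix(catalog$barcode, k)))  # 4^k x n_catalog
  bc_m <- row_unit(kmer_matrix(ub, k))
  matched <- character(length(ub))
  score <- numeric(length(ub))
  amb <- logical(length(ub))
  chunk <- max(1L, floor(4e6 / nrow(catalog)))
  for (i0 in seq(1L, length(ub), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, length(ub))
    s <- bc_m[i0:i1, , drop = FALSE] %*% cat_m
    best <- max.col(s, ties.method = "first")
    rows <- seq_len(nrow(s))
    bscore <- s[cbind(rows, best)]
    s[cbind(rows, best)] <- -Inf
    second <- s[cbind(rows, max.col(s, ties.method = "first"))]
    matched[i0:i1] <- catalog$strain_id[best]
    score[i0:i1] <- bscore
    amb[i0:i1] <- (bscore - second) <= 1e-12
  }
  score <- pmin(score, 1)  # guard rounding above 1 for identical vectors
  # exact string matches score exactly 1 against their own entry
  exact <- match(ub, catalog$barcode)
  hit_exact <- !is.na(exact)
  matched[hit_exact] <- catalog$strain_id[exact[hit_exact]]
  score[hit_exact] <- 1
  zero <- rowSums(bc_m^2) == 0  # unit rows have norm 1; zero rows stay 0
  matched[zero] <- NA_character_
  score[zero] <- NA_real_
  amb[zero] <- FALSE
  j <- match(barcodes, ub)
  hit <- !is.na(j)
  out$matched_id[hit] <- matched[j[hit]]
  out$confidence[hit] <- score[j[hit]]
  out$ambiguous[hit] <- amb[j[hit]]
  out
}

#' Call barcodes for a stream of read pairs
#'
#' Full composition of the paired-end detection algorithm: per-mate flank
#' location and barcode extraction (antisense mates reverse complemented
#' first), sense/antisense reconciliation with quality-based consensus, and
#' k-mer cosine assignment against the catalog with an acceptance threshold
#' of `min_score` (default 0.8, a conservative cutoff at which single-error
#' barcodes are still accepted at k = 3). Ambiguous best matches never pass
#' the threshold.
#'
#' @param pairs tibble of read pairs as returned by [read_fastq_pairs()]:
#'   columns `read_id`, `sense_seq`, `sense_qual`, `antisense_seq`,
#'   `antisense_qual`.
#' @param catalog a [barcode_catalog()].
#' @param k k-mer size for cosine matching.
#' @param max_mismatch per-flank Hamming mismatch budget.
#' @param min_score minimum cosine similarity for a call to pass.
#' @return list with `calls` (tibble: `read_id`, `barcode`, `provenance`,
#'   `matched_id`, `confidence`, `ambiguous`, `pass`) and `summary` (list:
#'   `n_reads`, `fraction_flank_identified`, `fraction_barcode_recovered`,
#'   `fraction_above_threshold`), all fractions over the full input.
#' @export
call_reads <- function(pairs, catalog, k = 3, max_mismatch = 2,
                       min_score = 0.8) {
  stopifnot(inherits(catalog, "barcode_catalog"))
  need <- c("read_id", "sense_seq", "sense_qual", "antisense_seq",
            "antisense_qual")
  if (!all(need %in% names(pairs))) {
    stop("pairs must have columns: ", paste(need, collapse = ", "))
  }
  ok_rec <- nchar(pairs$sense_seq) == nchar(pairs$sense_qual) &
    nchar(pairs$antisense_seq) == nchar(pairs$antisense_qual)
  n_malformed <- sum(!ok_rec)
  if (n_malformed > 0) {
    warning(sprintf("skipping %d malformed record(s)", n_malformed))
    pairs <- pairs[ok_rec, , drop = FALSE]
  }
  n <- nrow(pairs)
  fl <- catalog_flanks(catalog)
  if (n == 0) {
    return(list(calls = tibble::tibble(read_id = character(0),
                                       barcode = character(0),
                                       provenance = character(0),
                                       matched_id = character(0),
                                       confidence = numeric(0),
                                       ambiguous = logical(0),
                                       pass = logical(0)),
                summary = call_summary(0, 0, 0, 0, n_malformed)))
  }
  sense_seq <- toupper(pairs$sense_seq)
  anti_seq <- revcomp(toupper(pairs$antisense_seq))
  anti_qual <- str_reverse(pairs$antisense_qual)
  fs <- cpp_find_flanks(sense_seq, fl$up, fl$down, as.integer(max_mismatch))
  fa <- cpp_find_flanks(anti_seq, fl$up, fl$down, as.integer(max_mismatch))
  s_found <- fs[, 5] == 1L
  a_found <- fa[, 5] == 1L
  s_bc <- ifelse(s_found, substr(sense_seq, fs[, 1] + 1L, fs[, 2]),
                 NA_character_)
  a_bc <- ifelse(a_found, substr(anti_seq, fa[, 1] + 1L, fa[, 2]),
                 NA_character_)

  barcode <- rep(NA_character_, n)
  provenance <- rep("none", n)
  both <- s_found & a_found
  same <- both & s_bc == a_bc
  barcode[same] <- s_bc[same]
  provenance[same] <- "both-identical"
  only_s <- s_found & !a_found
  barcode[only_s] <- s_bc[only_s]
  provenance[only_s] <- "sense-only"
  only_a <- a_found & !s_found
  barcode[only_a] <- a_bc[only_a]
  provenance[only_a] <- "antisense-only"
  conflict <- which(both & s_bc != a_bc)
  if (length(conflict)) {
    s_q <- substr(pairs$sense_qual[conflict], fs[conflict, 1] + 1L,
                  fs[conflict, 2])
    a_q <- substr(anti_qual[conflict], fa[conflict, 1] + 1L, fa[conflict, 2])
    for (ii in seq_along(conflict)) {
      i <- conflict[ii]
      rec <- reconcile_pair(
        list(barcode = s_bc[i], qual = s_q[ii],
             flank = list(up_mismatches = fs[i, 3],
                          down_mismatches = fs[i, 4])),
        list(barcode = a_bc[i], qual = a_q[ii],
             flank = list(up_mismatches = fa[i, 3],
                          down_mismatches = fa[i, 4])))
      barcode[i] <- rec$barcode
      provenance[i] <- rec$provenance
    }
  }

  mt <- cosine_match_many(barcode, catalog, k)
  pass <- !is.na(mt$confidence) & mt$confidence >= min_score & !mt$ambiguous
  calls <- tibble::tibble(read_id = pairs$read_id,
                          barcode = barcode,
                          provenance = provenance,
                          matched_id = mt$matched_id,
                          confidence = mt$confidence,
                          ambiguous = mt$ambiguous,
                          pass = pass)
  summary <- call_summary(n,
                          frac_flank = mean(s_found | a_found),
                          frac_recovered = mean(!is.na(barcode) &
                                                  nzchar(barcode)),
                          frac_pass = mean(pass),
                          n_malformed = n_malformed)
  list(calls = calls, summary = summary)
}

call_summary <- function(n, frac_flank, frac_recovered, frac_pass,
                         n_malformed = 0L) {
  structure(list(n_reads = n,
                 fraction_flank_identified = frac_flank,
                 fraction_barcode_recovered = frac_recovered,
                 fraction_above_threshold = frac_pass,
                 n_malformed = n_malformed),
            class = "call_summary")
}

#' @export
print.call_summary <- function(x, ...) {
  cat(sprintf(paste0("<call_summary> %d read pairs\n",
                     "  flank identified (>=1 direction): %.1f%%\n",
                     "  barcode recovered:                %.1f%%\n",
                     "  above confidence threshold:       %.1f%%\n"),
              x$n_reads, 100 * x$fraction_flank_identified,
              100 * x$fraction_barcode_recovered,
              100 * x$fraction_above_threshold))
  if (x$n_malformed > 0) {
    cat(sprintf("  malformed records skipped: %d\n", x$n_malformed))
  }
  invisible(x)
}

#' Tabulate passing calls into a strain-by-sample count matrix
#'
#' One increment per passing, unambiguous call; rows are the full catalog
#' (zero-filled for unobserved strains), columns are samples described by
#' the sample sheet.
#'
#' @param calls tibble of calls with a `sample` column added (rbind of
#'   per-sample [call_reads()] outputs).
#' @param catalog a [barcode_catalog()].
#' @param samples sample sheet tibble: `sample`, `bin`, `timepoint`,
#'   `replicate`, `experiment`. Every sample must carry a bin label.
#' @return a [bin_count_matrix()].
#' @export
count_barcodes <- function(calls, catalog, samples) {
  stopifnot(inherits(catalog, "barcode_catalog"))
  need <- c("sample", "bin", "timepoint", "replicate", "experiment")
  if (!all(need %in% names(samples))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  if (anyNA(samples$bin)) stop("every sample must have a bin label")
  if (!"sample" %in% names(calls)) stop("calls must carry a sample column")
  counts <- matrix(0L, nrow = nrow(catalog), ncol = nrow(samples),
                   dimnames = list(catalog$strain_id, samples$sample))
  use <- calls$pass & !calls$ambiguous & !is.na(calls$matched_id)
  kept <- calls[use, , drop = FALSE]
  if (nrow(kept)) {
    tab <- table(factor(kept$matched_id, levels = catalog$strain_id),
                 factor(kept$sample, levels = samples$sample))
    counts[] <- as.integer(tab)
  }
  bin_count_matrix(counts, samples)
}
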