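test_that("flank search honors the per-flank mismatch budget", {
  bc <- "ACGTACGTACGTACGTACGT"
  read <- make_read(bc)
  fl <- find_flanks(read, FLANK_UP, FLANK_DOWN, max_mismatch = 2)
  expect_equal(fl$start, 2 + nchar(FLANK_UP))
  expect_equal(fl$end, fl$start + 20)
  expect_equal(substr(read, fl$start + 1, fl$end), bc)
  expect_equal(fl$up_mismatches, 0)
  expect_equal(fl$down_mismatches, 0)

  # two substitutions in the upstream flank: still found, counted
  read2 <- substitute_at(read, c(4, 9),
                         vapply(c(4, 9),
                                function(p) flip_base(substr(read, p, p)),
                                ""))
  fl2 <- find_flanks(read2, FLANK_UP, FLANK_DOWN, max_mismatch = 2)
  expect_equal(fl2$up_mismatches, 2)
  expect_equal(substr(read2, fl2$start + 1, fl2$end), bc)

  # three substitutions: over budget, absent
  read3 <- substitute_at(read, c(4, 9, 13),
                         vapply(c(4, 9, 13),
                                function(p) flip_base(substr(read, p, p)),
                                ""))
  expect_null(find_flanks(read3, FLANK_UP, FLANK_DOWN, max_mismatch = 2))
  # ...but found with a looser budget
  expect_equal(find_flanks(read3, FLANK_UP, FLANK_DOWN,
                           max_mismatch = 3)$up_mismatches, 3)
})

test_that("N bases count as flank mismatches", {
  read <- make_read("ACGTACGTACGTACGTACGT")
  readN <- substitute_at(read, c(4, 9, 13), c("N", "N", "N"))
  expect_null(find_flanks(readN, FLANK_UP, FLANK_DOWN, max_mismatch = 2))
})

test_that("barcode extraction slices sequence and aligned qualities", {
  bc <- "GACCAGGCCTATACGGTGTT"
  read <- make_read(bc)
  qual <- paste(rep(LETTERS[1:20], length.out = nchar(read)), collapse = "")
  ex <- extract_barcode(read, qual, FLANK_UP, FLANK_DOWN)
  expect_equal(ex$barcode, bc)
  start <- 2 + nchar(FLANK_UP)
  expect_equal(ex$qual, substr(qual, start + 1, start + 20))
  expect_null(extract_barcode("ACGTACGT", "IIIIIIII", FLANK_UP, FLANK_DOWN))
})

test_that("antisense extraction returns the sense-orientation barcode", {
  bc <- "GACCAGGCCTATACGGTGTT"
  read <- make_read(bc)
  qual <- const_qual(read)
  rc_read <- revcomp(read)
  ex_anti <- extract_barcode(rc_read, qual, FLANK_UP, FLANK_DOWN,
                             orientation = "antisense")
  ex_sense <- extract_barcode(read, qual, FLANK_UP, FLANK_DOWN)
  expect_equal(ex_anti$barcode, ex_sense$barcode)
})

test_that("pair reconciliation follows the consensus rules", {
  bc <- "ACGTACGTACGTACGTACGT"
  mk <- function(barcode, qual, up_mm = 0, down_mm = 0) {
    list(barcode = barcode, qual = qual,
         flank = list(up_mismatches = up_mm, down_mismatches = down_mm))
  }
  q38 <- const_qual(bc, 38)
  # identical in both directions
  rec <- reconcile_pair(mk(bc, q38), mk(bc, q38))
  expect_equal(rec, list(barcode = bc, provenance = "both-identical"))
  # one direction only
  expect_equal(reconcile_pair(mk(bc, q38), NULL)$provenance, "sense-only")
  expect_equal(reconcile_pair(NULL, mk(bc, q38))$provenance,
               "antisense-only")
  expect_equal(reconcile_pair(NULL, mk(bc, q38))$barcode, bc)
  expect_equal(reconcile_pair(NULL, NULL),
               list(barcode = NA_character_, provenance = "none"))
  # quality merge: conflicting position takes the higher-Phred base
  sense_bc <- substitute_at(bc, 5, "G")
  anti_bc <- substitute_at(bc, 5, "T")
  sense_q <- substitute_at(q38, 5, intToUtf8(30 + 33))  # Q30
  anti_q <- substitute_at(q38, 5, intToUtf8(38 + 33))   # Q38
  rec2 <- reconcile_pair(mk(sense_bc, sense_q), mk(anti_bc, anti_q))
  expect_equal(rec2$provenance, "quality-merged")
  expect_equal(substr(rec2$barcode, 5, 5), "T")
  # Phred tie goes to the sense base
  rec3 <- reconcile_pair(mk(sense_bc, q38), mk(anti_bc, q38))
  expect_equal(substr(rec3$barcode, 5, 5), "G")
  # unequal lengths: fewer total flank mismatches wins
  short <- substr(bc, 1, 19)
  rec4 <- reconcile_pair(mk(bc, q38, up_mm = 0),
                         mk(short, substr(q38, 1, 19), up_mm = 2))
  expect_equal(rec4$barcode, bc)
  expect_equal(rec4$provenance, "quality-merged")
})

test_that("reconciliation of identical inputs is idempotent", {
  bc <- "TTTTGGGGCCCCAAAATTTT"
  r <- list(barcode = bc, qual = const_qual(bc),
            flank = list(up_mismatches = 1, down_mismatches = 0))
  expect_equal(reconcile_pair(r, r)$barcode, bc)
  expect_equal(reconcile_pair(r, r)$provenance, "both-identical")
})

test_that("k-mer vectors enumerate overlapping k-mers", {
  expect_equal(kmer_vector("AAAA", 2), c(AA = 3L))
  expect_equal(kmer_vector("ACGT", 4), c(ACGT = 1L))
  expect_error(kmer_vector("AC", 3), "shorter than k")
  # conservation: counts sum to len - k + 1 for N-free sequences
  s <- "GACCAGGCCTATACGGTGTT"
  expect_equal(sum(kmer_vector(s, 3)), nchar(s) - 2L)
  # N-containing k-mers are skipped
  expect_equal(sum(kmer_vector("AANTT", 2)), 2L)
})

test_that("cosine matching scores identical barcodes at 1 and single errors at 15/18", {
  # frozen sequence whose eighteen 3-mers are all distinct; substituting
  # position 10 (A->C) creates three new distinct 3-mers, so 15 of 18
  # 3-mers are shared and the cosine is 15/18
  orig <- "CTGGTGACCAGGCGCATCTA"
  mut <- "CTGGTGACCCGGCGCATCTA"
  expect_equal(anyDuplicated(enum_kmers(orig)), 0L)
  expect_equal(anyDuplicated(enum_kmers(mut)), 0L)
  expect_equal(sum(enum_kmers(mut) %in% enum_kmers(orig)), 15L)
  catalog <- tiny_catalog(c(orig, "TTTTGGGGCCCCAAAATTTT",
                            "GACCAGGCCTATACGGTGTT"))
  exact <- cosine_match(orig, catalog, k = 3)
  expect_equal(exact$strain_id, "s01")
  expect_equal(exact$score, 1.0)
  one_err <- cosine_match(mut, catalog, k = 3)
  expect_equal(one_err$strain_id, "s01")
  expect_equal(one_err$score, 15 / 18, tolerance = 1e-12)
  expect_gte(one_err$score, 0.8)  # single errors pass the 0.8 threshold
})

test_that("cosine matching equals the naive nearest-neighbor oracle", {
  set.seed(42)
  rand_seq <- function(n, L) {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    }, "")
  }
  cat_bc <- unique(rand_seq(120, 20))[1:100]
  catalog <- barcode_catalog(sprintf("s%03d", 1:100), sprintf("g%03d", 1:100),
                             cat_bc, FLANK_UP, FLANK_DOWN)
  # queries: half perturbed catalog entries, half random
  queries <- c(vapply(sample(cat_bc, 25), function(b) {
    p <- sample(20, 1)
    substitute_at(b, p, flip_base(substr(b, p, p)))
  }, ""), rand_seq(25, 20))
  res <- cosine_match_many(queries, catalog, k = 3)
  for (i in seq_along(queries)) {
    scores <- vapply(cat_bc, brute_cosine, 0, a = queries[i])
    expect_equal(res$confidence[i], max(scores), tolerance = 1e-12)
    if (!res$ambiguous[i]) {
      expect_equal(res$matched_id[i],
                   catalog$strain_id[which.max(scores)])
    } else {
      expect_gte(sum(abs(scores - max(scores)) <= 1e-12), 2)
    }
  }
})

test_that("cosine score is symmetric, bounded, and 1 on self", {
  set.seed(7)
  seqs <- vapply(1:20, function(i) {
    paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  }, "")
  catalog <- barcode_catalog(sprintf("s%02d", 1:20), sprintf("g%02d", 1:20),
                             unique(seqs), FLANK_UP, FLANK_DOWN)
  for (s in seqs[1:5]) {
    m <- cosine_match(s, catalog, k = 3)
    expect_equal(m$score, 1.0)
    expect_true(m$score >= 0 && m$score <= 1)
    expect_equal(brute_cosine(s, seqs[7]), brute_cosine(seqs[7], s))
  }
})

test_that("zero-norm barcodes yield no match", {
  catalog <- tiny_catalog()
  m <- cosine_match("AC", catalog, k = 3)  # shorter than k
  expect_true(is.na(m$strain_id))
  expect_true(is.na(m$score))
})

test_that("call_reads recovers everything on error-free pairs and reports fractions", {
  catalog <- tiny_catalog()
  reads <- make_read(rep(catalog$barcode, times = c(5, 3, 2)))
  pairs <- pairs_from_seqs(reads)
  res <- call_reads(pairs, catalog)
  expect_equal(res$summary$fraction_flank_identified, 1.0)
  expect_equal(res$summary$fraction_barcode_recovered, 1.0)
  expect_equal(res$summary$fraction_above_threshold, 1.0)
  expect_true(all(res$calls$confidence == 1.0))
  expect_true(all(res$calls$provenance == "both-identical"))
  expect_equal(as.vector(table(res$calls$matched_id)[catalog$strain_id]),
               c(5L, 3L, 2L))
})

test_that("junk-only input produces no passing calls", {
  set.seed(11)
  junk <- vapply(1:200, function(i) {
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  }, "")
  res <- call_reads(pairs_from_seqs(junk), tiny_catalog())
  expect_equal(res$summary$fraction_above_threshold, 0)
  # false-positive flank placement in uniform sequence is rare: each flank
  # needs an 18-mer window within 2 mismatches (p < 1e-7 per window)
  expect_lt(res$summary$fraction_flank_identified, 0.05)
})

test_that("lowering the confidence threshold only enlarges the passing set", {
  cfg <- screen_sim_config(n_strains = 20, read_depth = 300,
                           n_hit_strains = 0, substitution_rate = 0.03,
                           flank_mismatch_rate = 0.1,
                           junk_read_fraction = 0.05, n_replicates = 1,
                           seed = 21)
  catalog <- make_catalog(cfg)
  scr <- simulate_screen(catalog, cfg)
  p <- scr$pairs[[1]]
  strict <- call_reads(p, catalog, min_score = 0.8)$calls
  loose <- call_reads(p, catalog, min_score = 0.5)$calls
  expect_true(all(strict$read_id[strict$pass] %in%
                    loose$read_id[loose$pass]))
  expect_gte(sum(loose$pass), sum(strict$pass))
})

test_that("malformed records are skipped with a warning, not silently", {
  catalog <- tiny_catalog()
  pairs <- pairs_from_seqs(make_read(catalog$barcode[1:2]))
  pairs$sense_qual[2] <- substr(pairs$sense_qual[2], 1, 5)
  expect_warning(res <- call_reads(pairs, catalog), "malformed")
  expect_equal(res$summary$n_reads, 1)
})

test_that("count_barcodes tabulates passing unambiguous calls per sample", {
  catalog <- tiny_catalog()
  samples <- tibble::tibble(sample = c("A", "B"), bin = c("high", "low"),
                            timepoint = "T24", replicate = 1,
                            experiment = "e1")
  calls <- tibble::tibble(
    read_id = sprintf("r%d", 1:6),
    sample = c("A", "A", "A", "B", "B", "B"),
    matched_id = c("s01", "s01", "s01", "s02", "s02", "s03"),
    confidence = c(1, 1, 1, 1, 0.7, 1),
    ambiguous = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    pass = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  bcm <- count_barcodes(calls, catalog, samples)
  expect_equal(bcm$counts["s01", "A"], 3L)
  expect_equal(bcm$counts["s02", "B"], 1L)
  expect_equal(bcm$counts["s03", "B"], 0L)  # ambiguous contributes 0
  # conservation: column sums equal passing unambiguous calls per sample
  expect_equal(unname(colSums(bcm$counts)), c(3, 1))
  expect_error(count_barcodes(calls, catalog,
                              dplyr::mutate(samples, bin = NA)),
               "bin")
})
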