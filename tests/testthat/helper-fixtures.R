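# Shared fixtures: a tiny hand-built catalog and read constructors.

FLANK_UP <- "GATGTCCACGAGGTCTCT"
FLANK_DOWN <- "CGTACGCTGCAGGTCGAC"

tiny_catalog <- function(barcodes = c("ACGTACGTACGTACGTACGT",
                                      "TTTTGGGGCCCCAAAATTTT",
                                      "GACCAGGCCTATACGGTGTT")) {
  barcode_catalog(strain_id = sprintf("s%02d", seq_along(barcodes)),
                  gene = sprintf("G%02d", seq_along(barcodes)),
                  barcode = barcodes,
                  flank_up = FLANK_UP, flank_down = FLANK_DOWN)
}

# amplicon read with the barcode between exact flanks and 2-nt pads
make_read <- function(barcode, pad5 = "AA", pad3 = "TT",
                      flank_up = FLANK_UP, flank_down = FLANK_DOWN) {
  paste0(pad5, flank_up, barcode, flank_down, pad3)
}

const_qual <- function(seq, q = 38L) {
  strrep(intToUtf8(q + 33L), nchar(seq))
}

# substitute positions (1-based) of a sequence with given bases
substitute_at <- function(seq, pos, bases) {
  for (i in seq_along(pos)) substr(seq, pos[i], pos[i]) <- bases[i]
  seq
}

# a different base than the one present (deterministic choice)
flip_base <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]

# k-mer list of a sequence (test-side enumeration, independent of the
# package's k-mer machinery)
enum_kmers <- function(s, k = 3) {
  substring(s, seq_len(nchar(s) - k + 1), seq(k, nchar(s)))
}

# brute-force cosine similarity between two sequences via k-mer tables
brute_cosine <- function(a, b, k = 3) {
  ka <- table(enum_kmers(a, k))
  kb <- table(enum_kmers(b, k))
  keys <- union(names(ka), names(kb))
  va <- as.numeric(ka[keys]); va[is.na(va)] <- 0
  vb <- as.numeric(kb[keys]); vb[is.na(vb)] <- 0
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

# read-pair tibble from sense sequences (antisense = exact reverse
# complement), constant qualities
pairs_from_seqs <- function(seqs, q = 38L) {
  tibble::tibble(read_id = sprintf("r%04d", seq_along(seqs)),
                 sense_seq = seqs,
                 sense_qual = vapply(seqs, const_qual, "", q = q),
                 antisense_seq = mmpscreen::revcomp(seqs),
                 antisense_qual = vapply(seqs, const_qual, "", q = q))
}

# minimal trajectory tibble builder: one row per (time, division) sample
make_traj <- function(cell_id, time_h, divisions, mmp_s, mmp_i,
                      died = TRUE, divisions_at_death = max(divisions),
                      experiment = "e1") {
  dad <- if (died) as.integer(divisions_at_death) else NA_integer_
  tibble::tibble(cell_id = cell_id, experiment = experiment,
                 time_h = time_h, divisions = divisions,
                 mmp_s = mmp_s, mmp_i = mmp_i, died = died,
                 divisions_at_death = dad)
}
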