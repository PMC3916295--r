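# two-sample intersection and sequence-context analyses

mk_calls <- function(type, chrom, start, end = start, size = end - start,
                     sv_seq = "", weight = 1L, site_chrom = NA_character_,
                     site_pos = NA_integer_) {
  data.frame(type = type, chrom = chrom, start = start, end = end,
             size = size, sv_seq = sv_seq, site_chrom = site_chrom,
             site_pos = site_pos, weight = weight, zygosity = NA_character_,
             sample = "s", stringsAsFactors = FALSE)
}

test_that("call intersection applies per-type tolerances and stays 1-to-1", {
  a <- rbind(mk_calls("deletion", "chr1", 100L, 200L),
             mk_calls("insertion", "chr1", 500L, 500L, 5L, "ACGTA"),
             mk_calls("inversion", "chr1", 1000L, 1400L))
  b <- rbind(mk_calls("deletion", "chr1", 100L, 200L),
             mk_calls("insertion", "chr1", 501L, 501L, 5L, "CGTAA"),
             mk_calls("inversion", "chr1", 1007L, 1393L))
  ix <- intersect_calls(a, b)
  expect_identical(nrow(ix$common), 3L)        # 1 bp / 10 bp tolerances
  ix0 <- intersect_calls(a, b, tol_indel = 0L, tol_complex = 1L)
  expect_identical(nrow(ix0$common), 1L)
  expect_identical(nrow(ix0$a_specific), 2L)
  expect_identical(nrow(ix0$b_specific), 2L)
  # symmetry of the common count
  expect_identical(nrow(intersect_calls(b, a)$common), nrow(ix$common))
  # insertions must also agree in length
  b2 <- mk_calls("insertion", "chr1", 500L, 500L, 6L, "ACGTAA")
  expect_identical(nrow(intersect_calls(a[2, ], b2)$common), 0L)
})

test_that("shared fraction increases with the weight cutoff under noise", {
  germline <- rbind(mk_calls("insertion", "chr1", seq(1000L, 9000L, 1000L),
                             seq(1000L, 9000L, 1000L), 3L, "ACA", weight = 5L))
  noise_a <- mk_calls("insertion", "chr1", seq(150L, 550L, 100L),
                      seq(150L, 550L, 100L), 3L, "TTT", weight = 1L)
  noise_b <- mk_calls("insertion", "chr2", seq(150L, 550L, 100L),
                      seq(150L, 550L, 100L), 3L, "GGG", weight = 1L)
  tb <- overlap_vs_weight(rbind(germline, noise_a), rbind(germline, noise_b),
                          w_range = 1:4)
  expect_identical(tb$n_common, rep(9L, 4))
  expect_true(all(diff(tb$shared_a) >= 0))
  expect_gt(tb$shared_a[2], tb$shared_a[1])
  empty <- overlap_vs_weight(germline[0, ], germline[0, ], w_range = 1:2)
  expect_identical(empty$n_common, c(0L, 0L))
})

test_that("size distribution signs indels and recovers planted sizes", {
  calls <- rbind(mk_calls("deletion", "chr1", 100L, 105L),
                 mk_calls("deletion", "chr1", 300L, 305L),
                 mk_calls("insertion", "chr1", 500L, 500L, 2L, "AC"),
                 mk_calls("inversion", "chr1", 900L, 1200L))
  sd <- size_distribution(calls)
  expect_identical(sd$size, c(-5L, 2L))
  expect_identical(sd$count, c(2L, 1L))
})

test_that("top inserted sequences rank by count with lexicographic ties", {
  calls <- rbind(mk_calls("insertion", "chr1", c(1L, 2L, 3L), c(1L, 2L, 3L),
                          1L, "T"),
                 mk_calls("insertion", "chr1", c(4L, 5L), c(4L, 5L), 2L, "CA"),
                 mk_calls("insertion", "chr1", c(6L, 7L), c(6L, 7L), 2L, "AG"))
  top <- top_inserted_sequences(calls, n = 2L)
  expect_identical(top$seq, c("T", "AG"))
  expect_identical(top$count, c(3L, 2L))
  expect_lte(sum(top$count), 7L)
})

test_that("simple-repeat fractions follow the minimum run length rule", {
  ref <- c(chr = "GGCCAAAAGGTTTCCAAACCGGG")
  #             123456789012345678901234   (1-based)
  # run of 4 As at 0-based [4,8); run of 3 As at [15,18); run of 3 Ts at [10,13)
  calls <- rbind(
    mk_calls("insertion", "chr", 6L, 6L, 1L, "A"),    # inside AAAA -> counted
    mk_calls("insertion", "chr", 15L, 15L, 1L, "A"),  # run of 3 -> not counted
    mk_calls("deletion", "chr", 5L, 6L, 1L),          # deleted A within AAAA
    mk_calls("insertion", "chr", 10L, 10L, 1L, "T"))  # TTT run of 3 -> not
  fr <- simple_repeat_fraction(calls, ref, min_run = 4L)
  a_row <- fr[fr$base == "A", ]
  expect_identical(a_row$n_total, 3L)
  expect_identical(a_row$n_in_repeat, 2L)
  expect_identical(fr$n_in_repeat[fr$base == "T"], 0L)
  expect_true(all(fr$fraction >= 0 & fr$fraction <= 1, na.rm = TRUE))

  # brute-force recount oracle on random single-base insertions
  set.seed(601)
  g <- random_dna(2000)
  pos <- sample(50:1950, 60)
  base <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  rnd <- mk_calls("insertion", "chr", as.integer(pos), as.integer(pos), 1L, base)
  fr2 <- simple_repeat_fraction(rnd, c(chr = g), min_run = 4L)
  brute <- vapply(seq_along(pos), function(i) {
    p <- pos[i]; b <- base[i]
    run <- 0L; q <- p - 1L
    while (q >= 0 && substr(g, q + 1, q + 1) == b) { run <- run + 1L; q <- q - 1L }
    q <- p
    while (q < 2000 && substr(g, q + 1, q + 1) == b) { run <- run + 1L; q <- q + 1L }
    run >= 4L
  }, TRUE)
  for (b in c("A", "C", "G", "T"))
    expect_identical(fr2$n_in_repeat[fr2$base == b], sum(brute[base == b]))
})

test_that("direct-repeat insertions require length > 2 and flank identity", {
  ref <- c(chr = paste0("TTGCA", "ACGTT", "GGATC", strrep("A", 6), "CCGGACT"))
  calls <- rbind(
    # insert "ACGTT" right after genomic ACGTT (0-based site 10)
    mk_calls("insertion", "chr", 10L, 10L, 5L, "ACGTT"),
    # insert "AAAA" inside the A run: direct repeat but simple
    mk_calls("insertion", "chr", 19L, 19L, 4L, "AAAA"),
    # length-2 insertion excluded
    mk_calls("insertion", "chr", 10L, 10L, 2L, "AC"),
    # no flank identity
    mk_calls("insertion", "chr", 3L, 3L, 3L, "CCC"))
  dr <- direct_repeat_insertions(calls, ref)
  expect_identical(nrow(dr$direct), 2L)
  expect_identical(sort(dr$direct$sv_seq), c("AAAA", "ACGTT"))
  expect_identical(dr$nonsimple$sv_seq, "ACGTT")
})

test_that("breakpoint densities per genome compartment are length-normalized", {
  gff <- c("##gff-version 3",
           paste("chr1", "src", "gene", 1001, 3000, ".", "+", ".", "ID=g1", sep = "\t"),
           paste("chr1", "src", "exon", 1001, 1400, ".", "+", ".", "Parent=g1", sep = "\t"),
           paste("chr1", "src", "exon", 2601, 3000, ".", "+", ".", "Parent=g1", sep = "\t"),
           paste("chr1", "src", "CDS", 1101, 1400, ".", "+", ".", "Parent=g1", sep = "\t"),
           # two overlapping genes: excluded from the unique-gene subsets
           paste("chr1", "src", "gene", 5001, 6000, ".", "+", ".", "ID=g2", sep = "\t"),
           paste("chr1", "src", "gene", 5501, 6500, ".", "-", ".", "ID=g3", sep = "\t"),
           paste("chr1", "src", "exon", 5001, 6000, ".", "+", ".", "Parent=g2", sep = "\t"))
  gp <- tempfile(fileext = ".gff3")
  writeLines(gff, gp)
  ref <- c(chr1 = strrep("A", 10000))

  bp_intron <- data.frame(chrom = "chr1", pos = c(1500L, 2000L, 2500L))
  d <- breakpoint_compartment_density(bp_intron, gp, ref)
  expect_identical(d$n_breakpoints[d$compartment == "intronic"], 3L)
  expect_identical(d$n_breakpoints[d$compartment == "CDS"], 0L)
  expect_identical(d$n_breakpoints[d$compartment == "intergenic"], 0L)
  expect_equal(d$density[d$compartment == "genome"], 3 / 10000)
  # intron length = 2000 - 800 = 1200
  expect_equal(d$total_bp[d$compartment == "intronic"], 1200)
  # overlapping genes are not part of the exonic subset
  bp_olap <- data.frame(chrom = "chr1", pos = 5500L)
  d2 <- breakpoint_compartment_density(bp_olap, gp, ref)
  expect_identical(d2$n_breakpoints[d2$compartment == "exonic"], 0L)
  expect_identical(d2$n_breakpoints[d2$compartment == "overlapping_genes"], 1L)

  expect_error(breakpoint_compartment_density(
    bp_intron, GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10)), ref),
    "type")
})
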