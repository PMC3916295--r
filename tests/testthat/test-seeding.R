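# seed extraction, placement, exact classification, alignability

test_that("seeds are the 5' prefixes of both reads", {
  set.seed(201)
  p <- pair_from_fragment(random_dna(250))
  s <- extract_seeds(p, k = 30)
  expect_identical(s$seed1, substr(p$seq1, 1, 30))
  expect_identical(s$seed2, substr(p$seq2, 1, 30))
  expect_identical(extract_seeds(p, k = 150)$seed1, p$seq1)
  expect_error(extract_seeds(p, k = 151), "read length")
})

test_that("the internal aligner places seeds uniquely, both strands, <=1 mismatch", {
  set.seed(202)
  ref <- c(chrX = random_dna(100000))
  frag <- substr(ref[["chrX"]], 40001, 40250)
  p <- pair_from_fragment(frag)
  a <- align_seed_pairs(p, ref)
  expect_true(a$usable)
  expect_identical(a$pos1, 40000L)            # 0-based 5' base
  expect_identical(a$strand1, 1L)
  expect_identical(a$pos2, 40249L)            # reverse strand, rightmost base
  expect_identical(a$strand2, -1L)

  # one planted mismatch in a seed is still found
  p2 <- p
  s1 <- p2$seq1; substr(s1, 10, 10) <- chartr("ACGT", "GTAC", substr(s1, 10, 10))
  p2$seq1 <- s1
  a2 <- align_seed_pairs(p2, ref)
  expect_true(a2$usable)
  expect_identical(a2$pos1, 40000L)
  expect_identical(a2$mm1, 1L)

  # a sequence present twice makes its seed non-unique and the pair unusable
  dup <- paste0(ref[["chrX"]], substr(ref[["chrX"]], 40001, 40500))
  a3 <- align_seed_pairs(p, c(chrX = dup))
  expect_false(a3$usable)
  expect_false(a3$unique1)
})

test_that("classification is exact: D == l_f, inward orientation required", {
  set.seed(203)
  ref <- c(chrX = random_dna(60000))
  # unrearranged library: every usable pair is concordant
  pairs <- simulate_reads(ref, coverage = 3, seed = 204)
  frags <- reconstruct_fragments(pairs)
  aln <- align_seed_pairs(pairs, ref)
  cls <- classify_pairs(aln, frags)
  usable <- cls[cls$label != "unusable", ]
  expect_gt(nrow(usable), 100)
  expect_true(all(usable$label == "concordant"))
  expect_true(all(usable$D == usable$l_f))

  # a fragment spanning a 50 bp deletion: D = l_f + 50
  g <- ref[["chrX"]]
  hap <- c(chrX = paste0(substr(g, 1, 30000), substr(g, 30051, 60000)))
  frag <- substr(hap[["chrX"]], 29901, 30150)
  p <- pair_from_fragment(frag)
  cd <- classify_pairs(align_seed_pairs(p, ref), reconstruct_fragments(p))
  expect_identical(cd$label, "discordant")
  expect_identical(cd$D, cd$l_f + 50L)

  # both seeds on the same strand: discordant regardless of D
  inv <- c(chrX = paste0(substr(g, 1, 30000), rc(substr(g, 30001, 30400)),
                         substr(g, 30401, 60000)))
  fragi <- substr(inv[["chrX"]], 29901, 30150)
  pi <- pair_from_fragment(fragi)
  ci <- classify_pairs(align_seed_pairs(pi, ref), reconstruct_fragments(pi))
  expect_identical(ci$label, "discordant")
  expect_identical(ci$strand1, ci$strand2)
})

test_that("unique alignability tiles the genome and is monotone in k", {
  set.seed(205)
  ref <- c(chr = random_dna(30000))
  ua <- unique_alignability(ref, k = 30)
  expect_gt(ua$fraction_unique, 0.999)
  expect_equal(ua$n_tiles, 30000 - 30 + 1)

  homo <- c(chr = strrep("A", 1000))
  expect_equal(unique_alignability(homo, k = 30)$fraction_unique, 0)

  # two identical 5 kb copies: k-mers inside the copies are multiple
  g <- random_dna(20000)
  twocopy <- c(chr = paste0(g, substr(g, 1, 5000), random_dna(5000)))
  u2 <- unique_alignability(twocopy, k = 20)
  expect_gt(u2$n_multiple, 8000)
  expect_gt(u2$n_unique, 15000)

  # monotone: fraction_unique non-decreasing in k
  fr <- vapply(c(10, 14, 20), function(k)
    unique_alignability(twocopy, k = k)$fraction_unique, 0)
  expect_true(all(diff(fr) >= 0))

  expect_error(unique_alignability(c(chr = "ACGT"), k = 30), "exceeds")
})

test_that("SAM ingestion enforces unique pairwise placements", {
  ref_names <- "chrX"
  sam <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chrX\tLN:60000",
    # clean unique pair: mate1 forward at 101 (1-based), mate2 reverse at 371
    paste("ok", 99, "chrX", 101, 42, "30M", "=", 371, 300, strrep("A", 30), "*", sep = "\t"),
    paste("ok", 147, "chrX", 371, 42, "30M", "=", 101, -300, strrep("A", 30), "*", sep = "\t"),
    # one mate unmapped
    paste("orphan", 73, "chrX", 201, 42, "30M", "*", 0, 0, strrep("C", 30), "*", sep = "\t"),
    paste("orphan", 133, "*", 0, 0, "*", "*", 0, 0, strrep("C", 30), "*", sep = "\t"),
    # mate2 reported twice -> multi-mapping -> unusable
    paste("multi", 99, "chrX", 301, 42, "30M", "=", 501, 230, strrep("G", 30), "*", sep = "\t"),
    paste("multi", 147, "chrX", 501, 42, "30M", "=", 301, -230, strrep("G", 30), "*", sep = "\t"),
    paste("multi", 403, "chrX", 801, 0, "30M", "=", 301, 0, strrep("G", 30), "*", sep = "\t"))
  sp <- tempfile(fileext = ".sam")
  writeLines(sam, sp)
  a <- ingest_alignments(sp, k = 30)
  a <- a[order(a$pair_id), ]
  expect_identical(a$pair_id, c("multi", "ok", "orphan"))
  expect_identical(a$usable, c(FALSE, TRUE, FALSE))
  ok <- a[a$pair_id == "ok", ]
  expect_identical(ok$pos1, 100L)        # 0-based
  expect_identical(ok$pos2, 370L + 29L)  # reverse strand 5' base
  expect_identical(ok$strand2, -1L)
})
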