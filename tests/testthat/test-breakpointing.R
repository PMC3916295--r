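# minimal reference, affine-gap alignment, gap -> breakpoint mapping,
# co-optimal placement enumeration

test_that("affine-gap DP score matches an independent row-vectorized oracle", {
  set.seed(301)
  params <- align_params()
  for (i in 1:300) {
    n <- sample(5:60, 1); m <- sample(5:60, 1)
    q <- random_dna(n); s <- random_dna(m)
    got <- global_align_affine(q, s, params, anchored = TRUE, max_gap_runs = 0)
    expect_equal(got$score, oracle_affine_score(q, s), tolerance = 1e-9,
                 info = paste("case", i))
  }
})

test_that("DP score agrees with Biostrings pairwiseAlignment on global alignments", {
  set.seed(302)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -3)
  for (i in 1:25) {
    q <- random_dna(sample(20:60, 1)); s <- random_dna(sample(20:60, 1))
    got <- global_align_affine(q, s, anchored = TRUE, max_gap_runs = 0)
    ref <- Biostrings::pairwiseAlignment(q, s, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 10, gapExtension = 0.5,
                                         scoreOnly = TRUE)
    expect_equal(got$score, ref, tolerance = 1e-9)
  }
})

test_that("simple gap structures are recovered with deterministic traceback", {
  set.seed(303)
  s <- random_dna(120)
  # internal deletion of 5 bases from the query
  q_del <- paste0(substr(s, 1, 60), substr(s, 66, 120))
  a <- global_align_affine(q_del, s)
  r <- rle(a$ops)
  expect_identical(r$values, c(0L, 1L, 0L))
  expect_identical(r$lengths[2], 5L)
  expect_equal(a$score, 115 - (10 + 0.5 * 5))
  # 1 bp insertion into the query
  q_ins <- paste0(substr(s, 1, 60), "A", substr(s, 61, 120))
  b <- global_align_affine(q_ins, s)
  rb <- rle(b$ops)
  expect_identical(rb$values[rb$lengths > 0 & rb$values != 0], 2L)
  expect_equal(b$score, 120 - 10.5, tolerance = 1e-9)
  # identical sequences: gapless, full score; fitting mode on a substring
  expect_equal(global_align_affine(s, s)$score, 120)
  sub <- substr(s, 31, 90)
  fit <- global_align_affine(sub, s, anchored = FALSE)
  expect_equal(fit$score, 60)
  expect_identical(sum(fit$ops == 3L), 60L)
})

test_that("minimal reference windows follow seed strands and orientation", {
  set.seed(304)
  ref <- c(chrX = random_dna(60000))
  g <- ref[["chrX"]]
  # deletion-spanning pair: two forward windows flanking the deletion
  hap <- paste0(substr(g, 1, 30000), substr(g, 30101, 60000))
  p <- pair_from_fragment(substr(hap, 29901, 30150))
  aln <- classify_pairs(align_seed_pairs(p, ref), reconstruct_fragments(p))
  mr <- build_minimal_reference(aln, aln$l_f, ref)
  expect_identical(mr$left_window$start, 29900L)
  expect_identical(mr$left_window$strand, 1L)
  expect_identical(mr$right_window$end, 30250L)
  expect_identical(mr$right_window$strand, 1L)
  expect_equal(nchar(mr$seq), 2L * aln$l_f)
  expect_identical(mr$junction_offset, aln$l_f)

  # inversion junction: right window reverse-complemented, fragment aligns
  # across the junction with one gap
  inv <- paste0(substr(g, 1, 30000), rc(substr(g, 30001, 30400)),
                substr(g, 30401, 60000))
  pi <- pair_from_fragment(substr(inv, 29901, 30150))
  ai <- classify_pairs(align_seed_pairs(pi, ref), reconstruct_fragments(pi))
  mi <- build_minimal_reference(ai, ai$l_f, ref)
  expect_identical(mi$right_window$strand, -1L)
  ga <- global_align_affine(reconstruct_fragments(pi)$seq, mi)
  expect_identical(sum(rle(ga$ops)$values == 1L), 1L)
  expect_equal(ga$nmatch, ai$l_f)
})

test_that("planted indel breakpoints are recovered at single-base resolution", {
  set.seed(305)
  ref <- generate_reference(c(chr = 100000), seed = 306)
  pl <- plant_svs(ref, c(deletion = 5L, insertion = 5L),
                  unambiguous_flanks = TRUE, seed = 307)
  pairs <- simulate_reads(pl$haplotypes[[1]], coverage = 15, seed = 308)
  res <- run_pipeline(ref, pairs = pairs)
  truth <- pl$truth
  for (i in seq_len(nrow(truth))) {
    hit <- res$calls[res$calls$type == truth$type[i] &
                     res$calls$start == truth$start[i] &
                     res$calls$end == truth$end[i], ]
    expect_identical(nrow(hit), 1L, info = paste(truth$type[i], truth$start[i]))
    if (truth$type[i] == "insertion")
      expect_identical(hit$sv_seq, truth$seq[i])
  }
})

test_that("co-optimal placements of repeat-context indels are enumerated fully", {
  # homopolymer rule: inserting A into a run of n As has n+1 placements
  left <- "GCGTTCGC"; run <- strrep("A", 3); right <- "CCTGTCGA"
  ref <- c(chr = paste0(left, run, right))
  pl <- enumerate_optimal_placements(ref, "ins", "chr", 8L, sv_seq = "A")
  expect_identical(nrow(pl), 4L)
  expect_identical(pl$u, 8:11)
  expect_true(all(pl$sv_seq == "A"))

  for (n in c(1L, 5L, 9L)) {
    refn <- c(chr = paste0(left, strrep("A", n), right))
    pn <- enumerate_optimal_placements(refn, "ins", "chr", 8L, sv_seq = "A")
    expect_identical(nrow(pn), n + 1L)
  }

  # deletion placements agree with an exhaustive enumeration oracle
  s <- paste0("GCCGTC", "ATATAT", "GGCAAC")
  refd <- c(chr = s)
  pd <- enumerate_optimal_placements(refd, "b", "chr", 6L, "chr", 8L)
  oracle <- oracle_deletion_placements(s, at = 6L, len = 2L)
  expect_identical(sort(pd$u), oracle)
  expect_identical(nrow(pd), 5L)

  # non-repetitive context: exactly one placement
  set.seed(309)
  g <- "TTGACGTCCAAGGCTA"
  p1 <- enumerate_optimal_placements(c(chr = g), "b", "chr", 4L, "chr", 9L)
  expect_identical(nrow(p1),
                   length(oracle_deletion_placements(g, at = 4L, len = 5L)))
})
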