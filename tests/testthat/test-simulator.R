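# reference generation, SV planting, read simulation, recall evaluation

test_that("reference generation is seeded and respects base composition", {
  r1 <- generate_reference(c(chrA = 20000, chrB = 5000), gc = 0.6, seed = 701)
  r2 <- generate_reference(c(chrA = 20000, chrB = 5000), gc = 0.6, seed = 701)
  expect_identical(r1, r2)
  expect_identical(nchar(r1[["chrA"]]), 20000L)
  gc <- sum(strsplit(r1[["chrA"]], "")[[1]] %in% c("G", "C")) / 20000
  expect_equal(gc, 0.6, tolerance = 0.02)
})

test_that("planted SVs rewrite the haplotype exactly as recorded in the truth", {
  ref <- generate_reference(c(chrA = 60000, chrB = 30000), seed = 702)
  pl <- plant_svs(ref, c(deletion = 1L, insertional_duplication_intra_up_inv = 1L),
                  seed = 703)
  hap <- pl$haplotypes[[1]]
  tr <- pl$truth
  for (ch in names(ref)) {
    exp_len <- nchar(ref[[ch]]) -
      sum(tr$size[tr$type == "deletion" & tr$chrom == ch]) +
      sum(tr$size[tr$type != "deletion" & tr$site_chrom %in% ch])
    expect_identical(nchar(hap[[ch]]), as.integer(exp_len))
  }
  idup <- tr[tr$type != "deletion", ]
  g <- ref[[idup$chrom]]
  donor <- substr(g, idup$start + 1, idup$end)
  # donor region intact and an inverted copy inserted upstream at the site
  expect_true(grepl(donor, hap[[idup$chrom]], fixed = TRUE))
  want <- paste0(substr(g, idup$site_pos - 19, idup$site_pos),
                 rc(donor),
                 substr(g, idup$site_pos + 1, idup$site_pos + 20))
  expect_true(grepl(want, hap[[idup$chrom]], fixed = TRUE))
  expect_lt(idup$site_pos, idup$start)   # upstream
})

test_that("diploid planting respects haplotype assignments", {
  ref <- generate_reference(c(chrA = 100000), seed = 704)
  pl <- plant_svs(ref, c(deletion = 10L), ploidy = 2L, hom_fraction = 0.5,
                  seed = 705)
  expect_length(pl$haplotypes, 2L)
  het <- pl$truth[pl$truth$haps == "1", ]
  hom <- pl$truth[pl$truth$haps == "1,2", ]
  expect_gt(nrow(het), 0); expect_gt(nrow(hom), 0)
  expect_identical(nchar(pl$haplotypes[[2]][["chrA"]]),
                   100000L - sum(hom$size))
  expect_identical(nchar(pl$haplotypes[[1]][["chrA"]]),
                   100000L - sum(pl$truth$size))
})

test_that("read simulation is reproducible and error-rate aware", {
  ref <- generate_reference(c(chrA = 50000), seed = 706)
  p1 <- simulate_reads(ref, coverage = 5, seed = 707)
  p2 <- simulate_reads(ref, coverage = 5, seed = 707)
  expect_identical(p1, p2)
  # expected fragment count at the configured mean size
  expect_equal(nrow(p1), 5 * 50000 / 243.5, tolerance = 0.05)
  # error-free reads all reconstruct with score 1
  rec <- reconstruct_fragments(p1)
  expect_true(all(rec$accepted))
  # byte-identical FASTQ on re-simulation
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile(); f4 <- tempfile()
  write_fastq_pairs(p1, f1, f2)
  write_fastq_pairs(simulate_reads(ref, coverage = 5, seed = 707), f3, f4)
  expect_identical(readLines(f1), readLines(f3))
  # substitution errors push some pairs below the perfect-overlap filter
  pe <- simulate_reads(ref, coverage = 5, error_rate = 0.01, seed = 708)
  expect_lt(mean(reconstruct_fragments(pe)$accepted), 1)
})

test_that("recall evaluation enforces type, tolerance and 1-to-1 matching", {
  truth <- data.frame(id = c("sv1", "sv2"), type = "deletion", chrom = "chrA",
                      start = c(1000L, 5000L), end = c(1100L, 5200L),
                      size = c(100L, 200L), seq = "",
                      site_chrom = NA_character_, site_pos = NA_integer_,
                      haps = "1", stringsAsFactors = FALSE)
  perfect <- data.frame(type = "deletion", chrom = "chrA",
                        start = c(1000L, 5000L), end = c(1100L, 5200L),
                        size = c(100L, 200L), sv_seq = "",
                        site_chrom = NA_character_, site_pos = NA_integer_,
                        weight = 2L, zygosity = NA_character_, sample = "s",
                        stringsAsFactors = FALSE)
  ev <- evaluate_calls(perfect, truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  # one breakpoint off by delta + 1 is not recalled at delta = 0
  off <- perfect; off$end[1] <- 1101L
  ev2 <- evaluate_calls(off, truth, delta = 0L)
  expect_identical(ev2$n_recalled, 1L)
  # but is recalled at delta = 1
  ev3 <- evaluate_calls(off, truth, delta = 1L)
  expect_identical(ev3$n_recalled, 2L)
  # wrong type never matches
  astype <- perfect; astype$type <- "tandem_duplication"
  tmp <- astype; tmp$start <- rev(tmp$start)
  ev4 <- evaluate_calls(astype, truth)
  expect_identical(ev4$n_recalled, 0L)
})

test_that("insertional-duplication calls count as partial translocation matches", {
  truth <- data.frame(id = "sv1", type = "translocation_intra_up", chrom = "chrA",
                      start = 5000L, end = 5400L, size = 400L, seq = "",
                      site_chrom = "chrA", site_pos = 2000L, haps = "1",
                      stringsAsFactors = FALSE)
  partial <- data.frame(type = "insertional_duplication_intra_up", chrom = "chrA",
                        start = 5000L, end = 5400L, size = 400L, sv_seq = "",
                        site_chrom = "chrA", site_pos = 2000L, weight = 3L,
                        zygosity = NA_character_, sample = "s",
                        stringsAsFactors = FALSE)
  ev <- evaluate_calls(partial, truth)
  expect_identical(ev$n_recalled, 0L)
  expect_identical(ev$n_partial, 1L)
})
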