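# discordant graph: canonical edges, clustering, components, prototypes,
# isomorphism matching, calls

test_that("edge canonicalization folds orientation-swapped edges together", {
  cn <- canonicalize_edge("c", "chr1", 500L, "chr1", 100L)
  expect_identical(cn$type, "b")
  expect_identical(cn$u, 100L)
  expect_identical(cn$v, 500L)
  ca <- canonicalize_edge("a", "chr1", 900L, "chr1", 200L)
  expect_identical(c(ca$u, ca$v), c(200L, 900L))
  cb <- canonicalize_edge("b", "chr1", 100L, "chr1", 500L)
  expect_false(cb$swapped)
  # across chromosomes, ordering is by (chrom, pos)
  cd <- canonicalize_edge("d", "chr2", 100L, "chr1", 900L)
  expect_identical(cd$chrom_u, "chr1")
})

test_that("swapping read labels leaves canonical evidence unchanged", {
  set.seed(401)
  ref <- generate_reference(c(chr = 80000), seed = 402)
  pl <- plant_svs(ref, c(deletion = 1L, inversion = 1L, tandem_duplication = 1L),
                  seed = 403)
  pairs <- simulate_reads(pl$haplotypes[[1]], coverage = 10, seed = 404)
  run <- function(p) {
    frags <- reconstruct_fragments(p)
    cls <- classify_pairs(align_seed_pairs(p, ref), frags)
    ev <- fragment_breakpoints(cls, frags, ref)
    ev[order(ev$pair_id, ev$type, ev$u, ev$v),
       c("pair_id", "type", "chrom_u", "u", "chrom_v", "v")]
  }
  swapped <- pairs
  names(swapped)[match(c("seq1", "seq2"), names(swapped))] <- c("seq2", "seq1")
  swapped <- swapped[, names(pairs)]
  class(swapped) <- class(pairs)
  ev1 <- run(pairs); ev2 <- run(swapped)
  rownames(ev1) <- rownames(ev2) <- NULL
  expect_identical(ev1, ev2)
})

test_that("parallel evidence merges into weighted edges; SVs become components", {
  ev <- data.frame(
    pair_id = c("a", "b", "c", "d"),
    type = c("b", "b", "a", "d"),
    chrom_u = "chr1", u = c(1000L, 1000L, 5000L, 5000L),
    chrom_v = "chr1", v = c(1200L, 1200L, 5400L, 5400L),
    lo = 0L, hi = 0L, sv_seq = "", stringsAsFactors = FALSE)
  ref <- c(chr1 = strrep("ACGT", 2000))
  g <- build_discordant_graph(ev, ref)
  expect_identical(nrow(g$vertices), 4L)
  expect_identical(nrow(g$edges), 3L)
  expect_identical(g$edges$weight[g$edges$type == "b"], 2L)
  comps <- graph_components(g)
  expect_length(comps, 2L)

  empty <- build_discordant_graph(ev[0, ], ref)
  expect_identical(nrow(empty$vertices), 0L)
  expect_length(graph_components(empty), 0L)
})

test_that("the prototype catalog has 16 connected signatures of arity 1 to 3", {
  cat16 <- prototype_catalog()
  expect_length(cat16, 16L)
  kinds <- sub("_(intra|inter).*$", "", names(cat16))
  expect_identical(as.vector(table(kinds)[c("translocation", "insertional_duplication")]),
                   c(6L, 6L))
  for (p in cat16) {
    expect_true(length(p$roles) %in% 1:3)
    # connected: every role appears in the required edge set (self-loop for
    # the 1-vertex insertion prototype)
    expect_setequal(unique(c(p$required$r1, p$required$r2)), p$roles)
  }
  # the upstream inverted insertional duplication carries the a/d junction
  # signature plus the optional donor-adjacency edge
  p <- cat16$insertional_duplication_intra_up_inv
  expect_setequal(p$required$type, c("a", "d"))
  expect_identical(p$optional$type, "e")
})

test_that("typed isomorphism matching respects edge types and coordinates", {
  cat16 <- prototype_catalog()
  del_comp <- list(
    vertices = data.frame(chrom = "chr1", pos = c(100L, 400L)),
    edges = data.frame(type = "b", ui = 1L, vi = 2L, weight = 3L, sv_seq = "x"))
  class(del_comp) <- "detsv_graph"
  m <- match_component(del_comp, cat16$deletion)
  expect_identical(m$start$pos, 100L)
  expect_identical(m$end$pos, 400L)
  expect_identical(attr(m, "weight"), 3L)
  expect_null(match_component(del_comp, cat16$inversion))
  expect_null(match_component(del_comp, cat16$tandem_duplication))

  # reversed coordinate order on the same b edge is a tandem duplication
  td_comp <- del_comp
  td_comp$vertices$pos <- c(400L, 100L)
  expect_null(match_component(td_comp, cat16$deletion))
  mt <- match_component(td_comp, cat16$tandem_duplication)
  expect_identical(mt$start$pos, 100L)
  expect_identical(mt$end$pos, 400L)

  # Y-Z duplicated, inverted, upstream-inserted at X: a(X,Z) + d(X,Y)
  idup <- list(
    vertices = data.frame(chrom = "chr1", pos = c(1000L, 5000L, 5400L)),
    edges = data.frame(type = c("a", "d"), ui = c(1L, 1L), vi = c(3L, 2L),
                       weight = c(2L, 4L), sv_seq = ""))
  class(idup) <- "detsv_graph"
  mi <- match_component(idup, cat16$insertional_duplication_intra_up_inv)
  expect_identical(mi$site$pos, 1000L)
  expect_identical(mi$donor_start$pos, 5000L)
  expect_identical(mi$donor_end$pos, 5400L)
  expect_identical(attr(mi, "weight"), 2L)
  expect_null(match_component(idup, cat16$insertional_duplication_intra_down_inv))
  expect_null(match_component(idup, cat16$insertional_duplication_intra_up))
})

test_that("calls respect the minimum required weight and report residuals", {
  ev <- data.frame(
    pair_id = c("a", "b", "c"),
    type = c("b", "b", "b"),
    chrom_u = "chr1", u = c(1000L, 1000L, 7000L),
    chrom_v = "chr1", v = c(1300L, 1300L, 7100L),
    lo = 0L, hi = 0L, sv_seq = "", stringsAsFactors = FALSE)
  ref <- c(chr1 = strrep("ACGT", 2500))
  g <- build_discordant_graph(ev, ref)
  calls1 <- call_svs(g, mrw = 1L)
  expect_identical(nrow(calls1), 2L)
  calls4 <- call_svs(g, mrw = 2L)
  expect_identical(nrow(calls4), 1L)
  expect_identical(calls4$weight, 2L)
  expect_identical(nrow(filter_by_weight(calls1, 2L)), 1L)
  expect_identical(call_svs(build_discordant_graph(ev[0, ], ref)) |> nrow(), 0L)

  # an unmatched component (lone e edge is no prototype) lands in residuals
  ev2 <- data.frame(pair_id = "z", type = "e", chrom_u = "chr1", u = 50L,
                    chrom_v = "chr1", v = 90L, lo = 0L, hi = 0L, sv_seq = "",
                    stringsAsFactors = FALSE)
  g2 <- build_discordant_graph(ev2, ref)
  c2 <- call_svs(g2)
  expect_identical(nrow(c2), 0L)
  expect_length(attr(c2, "residual"), 1L)
})

test_that("doubling coverage doubles weights but fixes coordinates", {
  set.seed(405)
  ref <- generate_reference(c(chr = 80000), seed = 406)
  pl <- plant_svs(ref, c(deletion = 3L), seed = 407)
  call_at <- function(cov) {
    pairs <- simulate_reads(pl$haplotypes[[1]], coverage = cov, seed = 408)
    run_pipeline(ref, pairs = pairs)$calls
  }
  c10 <- call_at(10); c20 <- call_at(20)
  expect_identical(c10[, c("type", "chrom", "start", "end")],
                   c20[, c("type", "chrom", "start", "end")])
  ratio <- sum(c20$weight) / sum(c10$weight)
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.8)
})
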