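# shared fixtures and independent oracles

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# cut a read pair from a fragment exactly as the sequencer would
pair_from_fragment <- function(frag, L = 150L, id = "p1") {
  read_pair_table(id, substr(frag, 1, L),
                  rc(substr(frag, nchar(frag) - L + 1, nchar(frag))))
}

# Independent affine-gap global alignment score (Gotoh), strict global with
# charged terminal gaps and no run budget. Row-vectorized formulation: the
# within-row X recurrence is solved by a running cummax, so the code shares
# nothing with the package's cell-by-cell DP.
oracle_affine_score <- function(q, s, match = 1, mismatch = -3,
                                open = 10, ext = 0.5) {
  qv <- strsplit(q, "")[[1]]; sv <- strsplit(s, "")[[1]]
  n <- length(qv); m <- length(sv)
  NEG <- -1e18
  openc <- open + ext
  Mrow <- c(0, rep(NEG, m))
  Xrow <- c(NEG, -(open + ext * seq_len(m)))
  Yrow <- rep(NEG, m + 1)
  for (i in seq_len(n)) {
    sub <- ifelse(sv == qv[i] & sv %in% c("A", "C", "G", "T"), match, mismatch)
    prev_best <- pmax(Mrow, Xrow, Yrow)
    Mnew <- c(NEG, prev_best[seq_len(m)] + sub)
    Ynew <- pmax(pmax(Mrow, Xrow) - openc, Yrow - ext)
    # X(i, j) = max over t < j of (max(M(i,t), Y(i,t)) - openc) - ext*(j-t-1)
    a <- pmax(Mnew, Ynew) - openc + ext * (0:m)
    Xnew <- c(NEG, cummax(a)[seq_len(m)] - ext * (seq_len(m) - 1L))
    # one refinement pass: Y may feed from X within the same row order? No -
    # Y only looks at the previous row, so a single pass is exact.
    Mrow <- Mnew; Xrow <- Xnew; Yrow <- Ynew
  }
  max(Mrow[m + 1], Xrow[m + 1], Yrow[m + 1])
}

# enumerate every placement of a deletion of `len` bases from `s` that yields
# the same remaining sequence as deleting at `at` (independent of the slide
# arithmetic in the package)
oracle_deletion_placements <- function(s, at, len) {
  target <- paste0(substr(s, 1, at), substr(s, at + len + 1, nchar(s)))
  which(vapply(0:(nchar(s) - len), function(p)
    paste0(substr(s, 1, p), substr(s, p + len + 1, nchar(s))) == target,
    TRUE)) - 1L
}

# a tiny deterministic benchmark fixture shared by several acceptance checks;
# computed at most once per test run
bench_env <- new.env(parent = emptyenv())
deletion_benchmark <- function() {
  if (!is.null(bench_env$del)) return(bench_env$del)
  ref <- generate_reference(c(chr1 = 1e6, chr2 = 1e6), seed = 21)
  pl <- plant_svs(ref, c(deletion = 200L), seed = 22)
  pairs <- simulate_reads(pl$haplotypes[[1]], coverage = 20, seed = 23)
  res <- run_pipeline(ref, pairs = pairs)
  bench_env$del <- list(ref = ref, truth = pl$truth, pairs = pairs, res = res)
  bench_env$del
}
translocation_benchmark <- function() {
  if (!is.null(bench_env$tra)) return(bench_env$tra)
  ref <- generate_reference(c(chr1 = 1e6, chr2 = 1e6), seed = 21)
  pl <- plant_svs(ref, c(translocation_intra_up = 50L,
                         translocation_intra_down = 50L,
                         translocation_intra_up_inv = 50L,
                         translocation_intra_down_inv = 50L), seed = 32)
  pairs <- simulate_reads(pl$haplotypes[[1]], coverage = 20, seed = 33)
  res <- run_pipeline(ref, pairs = pairs)
  bench_env$tra <- list(ref = ref, truth = pl$truth, pairs = pairs, res = res)
  bench_env$tra
}
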