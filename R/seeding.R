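# Seed placement and exact pair classification.
#
# Seeds are the high-confidence 5' prefixes of the reads. Placed uniquely on
# the reference (allowing one mismatch), they anchor the reconstructed
# fragment: with D the outer span implied by the two seed placements, a pair
# in inward forward/reverse orientation is concordant exactly when D equals
# the reconstructed fragment length l_f. No fragment-size distribution enters
# the rule.

#' Extract 5'-end seeds from read pairs
#'
#' @param pairs A `detsv_pairs` table.
#' @param k Seed length (default 30); must not exceed the read length.
#' @return `data.frame` with `pair_id`, `seed1`, `seed2`.
#' @export
extract_seeds <- function(pairs, k = 30L) {
  L <- nchar(pairs$seq1)
  if (any(k > L)) stop("seed length k exceeds the read length")
  data.frame(pair_id = pairs$id,
             seed1 = substr(pairs$seq1, 1, k),
             seed2 = substr(pairs$seq2, 1, k),
             stringsAsFactors = FALSE)
}

# place one vector of seeds; returns data.frame with chrom name, 0-based pos5
# of the seed's 5' base (forward coordinates), strand, mismatches, unique flag
place_seeds <- function(seeds, seqs, max_mismatch = 1L) {
  hits <- cpp_seed_align(unname(seqs), seeds, as.integer(max_mismatch))
  data.frame(chrom = ifelse(is.na(hits$chrom), NA_character_,
                            names(seqs)[hits$chrom]),
             pos5 = hits$pos5,
             strand = hits$strand,
             mm = hits$mm,
             unique = !is.na(hits$nhits) & hits$nhits == 1,
             stringsAsFactors = FALSE)
}

#' Align seed pairs with the built-in exhaustive aligner
#'
#' Places the 5' seeds of both mates on the reference (both strands, at most
#' `max_mismatch` mismatches; `N` counts as a mismatch). A seed is unique if
#' exactly one placement exists genome-wide; a pair is usable only when both
#' seeds are unique. Intended for genomes up to roughly 10 Mb; for larger
#' genomes run an external seed aligner and use [ingest_alignments()].
#'
#' @param pairs A `detsv_pairs` table.
#' @param reference Reference accepted by [load_reference()].
#' @param k Seed length (default 30).
#' @param max_mismatch Maximum mismatches per seed (default 1).
#' @return A seed-alignment-pair `data.frame`: per mate `chrom`, `pos`
#'   (0-based position of the seed's 5' base in forward coordinates),
#'   `strand` (+1/-1), `mm`, `unique`, plus `usable`.
#' @export
align_seed_pairs <- function(pairs, reference, k = 30L, max_mismatch = 1L) {
  seqs <- load_reference(reference)
  seeds <- extract_seeds(pairs, k)
  a1 <- place_seeds(seeds$seed1, seqs, max_mismatch)
  a2 <- place_seeds(seeds$seed2, seqs, max_mismatch)
  out <- data.frame(pair_id = pairs$id,
                    chrom1 = a1$chrom, pos1 = a1$pos5, strand1 = a1$strand,
                    mm1 = a1$mm, unique1 = a1$unique,
                    chrom2 = a2$chrom, pos2 = a2$pos5, strand2 = a2$strand,
                    mm2 = a2$mm, unique2 = a2$unique,
                    stringsAsFactors = FALSE)
  out$usable <- out$unique1 & out$unique2
  class(out) <- c("detsv_seedaln", "data.frame")
  out
}

#' Ingest external seed alignments from SAM/BAM
#'
#' Reads mate-paired seed alignments produced by an external aligner. Records
#' flagged secondary/supplementary, or mates reported at more than one
#' placement, make the seed non-unique and the pair unusable, as do unmapped
#' mates and orphaned records.
#'
#' @param sam_path Path to a SAM or BAM file with mate pairing intact.
#' @param k Seed length used by the aligner (needed to recover the 5' base
#'   position of reverse-strand placements).
#' @return A seed-alignment-pair `data.frame` as from [align_seed_pairs()].
#' @export
ingest_alignments <- function(sam_path, k = 30L) {
  bam <- if (grepl("\\.sam$", sam_path, ignore.case = TRUE)) {
    Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else sam_path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  if (n == 0) stop("no records in ", sam_path)
  flag <- x$flag
  mate <- ifelse(bitwAnd(flag, 64L) > 0, 1L, ifelse(bitwAnd(flag, 128L) > 0, 2L, NA_integer_))
  secondary <- bitwAnd(flag, 256L) > 0 | bitwAnd(flag, 2048L) > 0
  unmapped <- bitwAnd(flag, 4L) > 0 | is.na(x$pos)
  skipped <- sum(is.na(mate))
  if (skipped > 0)
    message("ingest_alignments: skipped ", skipped, " records without mate flags")
  keep <- !is.na(mate)
  rec <- data.frame(qname = x$qname[keep], mate = mate[keep],
                    secondary = secondary[keep], unmapped = unmapped[keep],
                    chrom = as.character(x$rname)[keep],
                    pos0 = x$pos[keep] - 1L,
                    strand = ifelse(as.character(x$strand)[keep] == "-", -1L, 1L),
                    stringsAsFactors = FALSE)
  ids <- unique(rec$qname)
  key <- paste(rec$qname, rec$mate)
  placements <- table(key[!rec$unmapped])
  one_mate <- function(m) {
    r <- rec[rec$mate == m & !rec$unmapped & !rec$secondary, ]
    r <- r[!duplicated(r$qname), ]
    idx <- match(ids, r$qname)
    nplace <- as.integer(placements[paste(ids, m)])
    nplace[is.na(nplace)] <- 0L
    uniq <- !is.na(idx) & nplace == 1L
    data.frame(chrom = ifelse(uniq, r$chrom[idx], NA_character_),
               pos5 = as.integer(ifelse(uniq,
                                        ifelse(r$strand[idx] == 1L, r$pos0[idx],
                                               r$pos0[idx] + k - 1L),
                                        NA_integer_)),
               strand = as.integer(ifelse(uniq, r$strand[idx], NA_integer_)),
               unique = uniq, stringsAsFactors = FALSE)
  }
  a1 <- one_mate(1L); a2 <- one_mate(2L)
  out <- data.frame(pair_id = ids,
                    chrom1 = a1$chrom, pos1 = a1$pos5, strand1 = a1$strand,
                    mm1 = NA_integer_, unique1 = a1$unique,
                    chrom2 = a2$chrom, pos2 = a2$pos5, strand2 = a2$strand,
                    mm2 = NA_integer_, unique2 = a2$unique,
                    stringsAsFactors = FALSE)
  out$usable <- out$unique1 & out$unique2
  class(out) <- c("detsv_seedaln", "data.frame")
  out
}

#' Classify read pairs as concordant or discordant
#'
#' A usable pair (both seeds unique) is concordant if and only if both seeds
#' lie on the same chromosome, in inward forward/reverse orientation, and the
#' outer mapping distance D equals the reconstructed fragment length exactly:
#' with read 1 on the forward strand at 5' position `p1` and read 2 on the
#' reverse strand with 5' base at `p2`, `D = p2 - p1 + 1` (the mirror case is
#' symmetric). Everything else - same-strand seeds, different chromosomes,
#' outward orientation, or `D != l_f` - is discordant.
#'
#' @param aln Seed-alignment pairs from [align_seed_pairs()] or
#'   [ingest_alignments()].
#' @param frags Reconstruction results from [reconstruct_fragments()]; only
#'   pairs reconstructed with score 1 can be classified.
#' @return `aln` with columns `l_f`, `D` and
#'   `label` (`"concordant"`, `"discordant"` or `"unusable"`).
#' @export
classify_pairs <- function(aln, frags) {
  m <- match(aln$pair_id, frags$pair_id)
  l_f <- frags$l_f[m]
  ok <- aln$usable & !is.na(l_f)
  D <- rep(NA_integer_, nrow(aln))
  inward_fr <- ok & aln$chrom1 == aln$chrom2 & aln$strand1 == 1L & aln$strand2 == -1L
  inward_rf <- ok & aln$chrom1 == aln$chrom2 & aln$strand1 == -1L & aln$strand2 == 1L
  D[which(inward_fr)] <- aln$pos2[which(inward_fr)] - aln$pos1[which(inward_fr)] + 1L
  D[which(inward_rf)] <- aln$pos1[which(inward_rf)] - aln$pos2[which(inward_rf)] + 1L
  label <- ifelse(!ok, "unusable",
                  ifelse(!is.na(D) & D == l_f & D > 0, "concordant", "discordant"))
  out <- aln
  out$l_f <- l_f
  out$D <- D
  out$label <- label
  out
}

#' Unique alignability of genomic k-mers
#'
#' Tiles every position of every reference sequence (step 1) and reports the
#' fraction of k-mers placeable at exactly one position genome-wide allowing
#' `max_mismatch` mismatches, versus more than one. k-mers containing `N` are
#' excluded from the fractions' denominator's complement (they count in
#' `n_tiles` but are neither unique nor multiple).
#'
#' @inheritParams align_seed_pairs
#' @param k k-mer length.
#' @return `data.frame` with one row per sequence: `chrom`, `n_tiles`,
#'   `n_unique`, `n_multiple`, `fraction_unique`, `fraction_multiple`.
#' @export
unique_alignability <- function(reference, k, max_mismatch = 1L) {
  seqs <- load_reference(reference)
  if (k < 1) stop("k must be >= 1")
  res <- cpp_unique_alignability(unname(seqs), as.integer(k), as.integer(max_mismatch))
  data.frame(chrom = names(seqs),
             n_tiles = res$n_tiles,
             n_unique = res$n_unique,
             n_multiple = res$n_multiple,
             fraction_unique = res$n_unique / res$n_tiles,
             fraction_multiple = res$n_multiple / res$n_tiles,
             stringsAsFactors = FALSE)
}

#' Export seeds as FASTA for an external aligner
#'
#' @param pairs A `detsv_pairs` table.
#' @param path Output FASTA path; mate is encoded in the record name as
#'   `<pair_id>/1` and `<pair_id>/2`.
#' @param k Seed length.
#' @return Invisibly, the path.
#' @export
write_seed_fasta <- function(pairs, path, k = 30L) {
  s <- extract_seeds(pairs, k)
  x <- Biostrings::DNAStringSet(c(s$seed1, s$seed2))
  names(x) <- c(paste0(s$pair_id, "/1"), paste0(s$pair_id, "/2"))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
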