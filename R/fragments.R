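# Fragment reconstruction: merge each overlapping read pair into the exact
# fragment sequence through its central overlap.
#
# Read 1 is taken forward as sequenced; read 2 is reverse-complemented. For an
# overlap starting at offset i of read 1 the score is the fraction of matching
# bases between seq1[i..L) and the length-(L-i) prefix of revcomp(seq2), so a
# perfect overlap of any admissible length scores exactly 1. Only pairs whose
# maximum score equals 1 are merged; the fragment is seq1[0..i) + revcomp(seq2)
# and its exact length is l_f = i + L.

#' Construct a read-pair table
#'
#' @param id Character vector of pair identifiers.
#' @param seq1,seq2 Reads 1 and 2, forward as sequenced, equal length within a
#'   pair (alphabet `A`,`C`,`G`,`T`,`N`).
#' @param qual1,qual2 Optional per-base quality strings, carried through but
#'   never used by scoring.
#' @return A `data.frame` with class `detsv_pairs`.
#' @export
read_pair_table <- function(id, seq1, seq2, qual1 = NA_character_, qual2 = NA_character_) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (length(seq1) != length(seq2)) stop("seq1 and seq2 must have equal length")
  if (any(nchar(seq1) != nchar(seq2)))
    stop("reads of a pair must have equal length")
  if (anyDuplicated(id)) stop("pair ids must be unique")
  df <- data.frame(id = as.character(id), seq1 = seq1, seq2 = seq2,
                   qual1 = qual1, qual2 = qual2, stringsAsFactors = FALSE)
  class(df) <- c("detsv_pairs", "data.frame")
  df
}

#' Read paired FASTQ files
#'
#' Mate order must be preserved between the two files.
#'
#' @param fq1,fq2 Paths to the read-1 and read-2 FASTQ files.
#' @return A `detsv_pairs` table (see [read_pair_table()]).
#' @export
read_fastq_pairs <- function(fq1, fq2) {
  r1 <- Biostrings::readDNAStringSet(fq1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(fq2, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2))
    stop("FASTQ files contain different numbers of reads")
  if (length(r1) == 0) stop("empty FASTQ input")
  ids1 <- sub("[/ ].*$", "", names(r1))
  ids2 <- sub("[/ ].*$", "", names(r2))
  if (!identical(ids1, ids2))
    stop("mate order differs between the two FASTQ files")
  q1 <- S4Vectors::mcols(r1)$qualities
  q2 <- S4Vectors::mcols(r2)$qualities
  read_pair_table(ids1, as.character(r1), as.character(r2),
                  if (is.null(q1)) NA_character_ else as.character(q1),
                  if (is.null(q2)) NA_character_ else as.character(q2))
}

#' Position-dependent overlap score of a read pair
#'
#' Fraction of matching positions between `seq1[offset..L)` and the
#' length-`L - offset` prefix of `revcomp(seq2)`. `N` never matches, not even
#' another `N`. The score is 1 if and only if the overlap is a perfect match.
#'
#' @param seq1,seq2 The two reads (equal length `L`), forward as sequenced.
#' @param offset 0-based start of the overlap within read 1; must satisfy
#'   `0 <= offset <= L - m_min`.
#' @param m_min Minimum required overlap length (default 13).
#' @return A number in `[0, 1]`.
#' @export
overlap_score <- function(seq1, seq2, offset, m_min = 13L) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  L <- nchar(seq1)
  if (nchar(seq2) != L) stop("reads must have equal length")
  if (offset < 0 || offset > L - m_min)
    stop("offset must be in [0, L - m_min]")
  ov <- L - offset
  a <- strsplit(substr(seq1, offset + 1, L), "")[[1]]
  b <- strsplit(substr(rc_chr(seq2), 1, ov), "")[[1]]
  sum(a == b & a %in% DNA_BASES) / ov
}

#' Reconstruct fragment sequences from overlapping read pairs
#'
#' Evaluates the overlap score at every offset with overlap at least `m_min`
#' and merges a pair only when the maximum score equals 1 (a perfect overlap).
#' When several offsets reach score 1 the smallest offset (longest overlap,
#' shortest fragment) is chosen and the pair is flagged ambiguous.
#'
#' @param pairs A `detsv_pairs` table.
#' @param m_min Minimum required overlap in bases (default 13, giving a false
#'   positive overlap probability of about `4^-13` per offset).
#' @return A `data.frame` with one row per input pair: `pair_id`, `accepted`,
#'   `score` (maximum over offsets), `offset`, `overlap_len`, `l_f`,
#'   `ambiguous`, and `seq` (the fragment sequence; `NA` for rejected pairs).
#' @export
reconstruct_fragments <- function(pairs, m_min = 13L) {
  stopifnot(nrow(pairs) >= 1)
  res <- cpp_reconstruct(pairs$seq1, pairs$seq2, as.integer(m_min))
  L <- nchar(pairs$seq1)
  accepted <- res$score == 1
  out <- data.frame(pair_id = pairs$id,
                    accepted = accepted,
                    score = res$score,
                    offset = ifelse(accepted, res$offset, NA_integer_),
                    overlap_len = ifelse(accepted, L - res$offset, NA_integer_),
                    l_f = ifelse(accepted, res$offset + L, NA_integer_),
                    ambiguous = res$n_perfect > 1,
                    seq = NA_character_,
                    stringsAsFactors = FALSE)
  if (any(accepted)) {
    i <- which(accepted)
    out$seq[i] <- paste0(substr(pairs$seq1[i], 1, res$offset[i]),
                         rc_chr(pairs$seq2[i]))
  }
  class(out) <- c("detsv_fragments", "data.frame")
  out
}

#' Reconstruct a single read pair
#'
#' @inheritParams reconstruct_fragments
#' @param pair A one-row `detsv_pairs` table or a list with `id`, `seq1`,
#'   `seq2`.
#' @return A list describing the reconstructed fragment, or `NULL` when the
#'   pair is not overlapping (maximum score below 1).
#' @export
reconstruct_fragment <- function(pair, m_min = 13L) {
  if (!is.data.frame(pair))
    pair <- read_pair_table(pair$id, pair$seq1, pair$seq2)
  r <- reconstruct_fragments(pair, m_min)
  if (!r$accepted[1]) return(NULL)
  list(pair_id = r$pair_id[1], seq = r$seq[1], l_f = r$l_f[1],
       overlap_start = r$offset[1], overlap_len = r$overlap_len[1],
       score = r$score[1], ambiguous = r$ambiguous[1])
}

#' Distribution of maximum overlap scores
#'
#' On libraries mixing fragments shorter and longer than `2L - m_min` the
#' distribution is bimodal, with a mode near 0 (non-overlapping pairs, random
#' sequence similarity) and a mode near 1 (overlapping pairs).
#'
#' @inheritParams reconstruct_fragments
#' @param breaks Histogram breaks over `[0, 1]`.
#' @return Object of class `histogram` over the per-pair maximum scores.
#' @export
score_distribution <- function(pairs, m_min = 13L, breaks = seq(0, 1, by = 0.02)) {
  if (nrow(pairs) == 0) stop("empty pair stream")
  res <- cpp_reconstruct(pairs$seq1, pairs$seq2, as.integer(m_min))
  graphics::hist(res$score, breaks = breaks, plot = FALSE)
}

#' Write reconstructed fragments
#'
#' Writes accepted fragments as FASTA (header: `pair_id l_f=<n> offset=<i>`)
#' and a per-pair TSV of maximum score and offset.
#'
#' @param frags Result of [reconstruct_fragments()].
#' @param fasta_path,tsv_path Output paths (`NULL` to skip either).
#' @return Invisibly, `frags`.
#' @export
write_fragments <- function(frags, fasta_path = NULL, tsv_path = NULL) {
  if (!is.null(fasta_path)) {
    acc <- frags[frags$accepted, ]
    x <- Biostrings::DNAStringSet(acc$seq)
    names(x) <- sprintf("%s l_f=%d offset=%d", acc$pair_id, acc$l_f, acc$offset)
    Biostrings::writeXStringSet(x, fasta_path)
  }
  if (!is.null(tsv_path)) {
    write.table(frags[, c("pair_id", "score", "offset", "accepted", "ambiguous")],
                tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(frags)
}
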