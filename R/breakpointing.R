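# Breakpoint localization for discordant pairs.
#
# The minimal reference is the smallest reference construct guaranteed to
# contain the fragment if the seeds are placed correctly: two windows of
# length l_f, one grown from each seed placement in the read's 3' direction
# (reverse-strand windows are reverse-complemented so the joined sequence is
# collinear with the fragment). The fragment is aligned to it with affine gap
# penalties, the fragment fully, the minimal reference with free end gaps, and
# the gap endpoints are mapped back through the window coordinates to
# reference breakpoints with an approach side (left/right).

#' Alignment scoring defaults
#'
#' Gap costs follow the method's published parameters (opening 10, extension
#' 0.5 per base). Substitution scores must be chosen relative to them: with a
#' cheap gap extension, a large match reward lets the optimizer weave the
#' fragment through both (often overlapping) minimal-reference windows,
#' harvesting short spurious match runs between cheap gaps and fragmenting
#' the alignment. With match +1 / mismatch -3 a gap open (10) outweighs any
#' random match run short of eleven bases, so the optimal alignment keeps the
#' single SV-induced gap, while a true indel still beats mismatched
#' placements by the downstream frame shift it avoids. All configurable.
#'
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Affine gap penalties (a gap of length g costs
#'   `gap_open + g * gap_extend`).
#' @return List of scoring parameters.
#' @export
align_params <- function(match = 1, mismatch = -3, gap_open = 10, gap_extend = 0.5) {
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

#' Build the minimal reference for a discordant pair
#'
#' @param aln One row of a seed-alignment-pair table (see
#'   [align_seed_pairs()]); must be usable.
#' @param l_f Reconstructed fragment length.
#' @param reference Reference accepted by [load_reference()].
#' @return A `detsv_minref` list with both windows (chrom, 0-based half-open
#'   start/end, strand), the joined sequence and `junction_offset`, or `NULL`
#'   when a window would be empty (seed at a contig edge).
#' @export
build_minimal_reference <- function(aln, l_f, reference) {
  seqs <- load_reference(reference)
  win <- function(chrom, pos5, strand, mate) {
    len <- chrom_len(seqs, chrom)
    # extension in the read's 3' direction, clipped at the contig ends
    if (strand == 1L) {
      start <- max(pos5, 0L); end <- min(pos5 + l_f, len)
    } else {
      start <- max(pos5 + 1L - l_f, 0L); end <- min(pos5 + 1L, len)
    }
    if (end <= start) return(NULL)
    # window orientation in the joined sequence: mate 2 enters the fragment
    # reverse-complemented, so its window orientation is the opposite of its
    # seed strand
    ws <- if (mate == 1L) strand else -strand
    seq <- ref_slice(seqs, chrom, start, end)
    if (ws == -1L) seq <- rc_chr(seq)
    list(chrom = chrom, start = start, end = end, strand = ws, seq = seq)
  }
  w1 <- win(aln$chrom1, aln$pos1, aln$strand1, 1L)
  w2 <- win(aln$chrom2, aln$pos2, aln$strand2, 2L)
  if (is.null(w1) || is.null(w2)) return(NULL)
  out <- list(left_window = w1, right_window = w2,
              seq = paste0(w1$seq, w2$seq),
              junction_offset = nchar(w1$seq))
  class(out) <- "detsv_minref"
  out
}

#' Global alignment of a fragment against a minimal reference
#'
#' Needleman-Wunsch with affine gap penalties (Gotoh), deterministic
#' traceback. The fragment aligns end to end. In the default anchored mode
#' the minimal reference does too: its two windows are grown from the seed
#' placements, so the fragment's first base coincides with the start of the
#' left window and its last base with the end of the right window, and the
#' surplus reference between the anchors is absorbed by the junction gap that
#' the alignment must localize. With `anchored = FALSE` unaligned subject
#' ends are free (fitting alignment against an arbitrary subject).
#'
#' @param fragment Fragment sequence (character).
#' @param minref A `detsv_minref`, or any subject sequence as a character.
#' @param params Scoring parameters from [align_params()].
#' @param anchored Charge terminal subject gaps (default `TRUE`).
#' @param max_gap_runs Maximum number of gap runs in the alignment (default
#'   2: one SV gap plus the window-junction gap; a fragment carries at most
#'   one SV). 0 means unlimited.
#' @return A `detsv_alignment` list: `score`, `ops` (per-column codes: 0
#'   aligned pair, 1 subject over query gap, 2 query over subject gap, 3 free
#'   subject skip), `nmatch`, and the input sequences.
#' @export
global_align_affine <- function(fragment, minref, params = align_params(),
                                anchored = TRUE, max_gap_runs = 2L) {
  subject <- if (inherits(minref, "detsv_minref")) minref$seq else minref
  if (nchar(fragment) == 0 || nchar(subject) == 0) stop("empty sequence")
  r <- cpp_fit_align(fragment, subject, params$match, params$mismatch,
                     params$gap_open, params$gap_extend,
                     free_ends = !isTRUE(anchored),
                     max_runs = as.integer(max_gap_runs))
  structure(list(score = r$score, ops = r$ops, nmatch = r$nmatch,
                 query = fragment, subject = subject),
            class = "detsv_alignment")
}

#' Render an alignment in pairwise text format
#'
#' @param aln A `detsv_alignment`.
#' @return Character vector of three lines (fragment row, bars, reference
#'   row), for debugging.
#' @export
format_alignment <- function(aln) {
  q <- strsplit(aln$query, "")[[1]]; s <- strsplit(aln$subject, "")[[1]]
  qi <- 0L; sj <- 0L; qrow <- srow <- bars <- character(length(aln$ops))
  for (i in seq_along(aln$ops)) {
    op <- aln$ops[i]
    if (op == 0L) {
      qi <- qi + 1L; sj <- sj + 1L
      qrow[i] <- q[qi]; srow[i] <- s[sj]
      bars[i] <- if (q[qi] == s[sj]) "|" else "."
    } else if (op == 1L || op == 3L) {
      sj <- sj + 1L; qrow[i] <- "-"; srow[i] <- s[sj]
      bars[i] <- if (op == 3L) " " else "-"
    } else {
      qi <- qi + 1L; qrow[i] <- q[qi]; srow[i] <- "-"; bars[i] <- "-"
    }
  }
  c(paste(qrow, collapse = ""), paste(bars, collapse = ""),
    paste(srow, collapse = ""))
}

# For collinear same-chromosome windows whose span is shorter than the
# fragment, the pair carries a pure insertion of known length
# iota = l_f - span, and both fragment ends are seed-anchored. The insertion
# is then recovered exactly by longest matching prefix/suffix against the two
# windows (choosing the rightmost placement; central selection happens later
# with the other equivalent placements). Returns NULL when the flanks do not
# match exactly (e.g. sequencing errors), in which case the caller falls back
# to alignment-derived events.
exact_insertion_event <- function(query, minref) {
  w1 <- minref$left_window; w2 <- minref$right_window
  if (w1$chrom != w2$chrom || w1$strand != w2$strand) return(NULL)
  l_f <- nchar(query)
  span <- if (w1$strand == 1L) w2$end - w1$start else w1$end - w2$start
  iota <- l_f - span
  if (iota <= 0 || span <= 0) return(NULL)
  q <- utf8ToInt(query)
  valid <- q %in% utf8ToInt("ACGT")
  s1 <- utf8ToInt(w1$seq); s2 <- utf8ToInt(w2$seq)
  n1 <- min(l_f, length(s1))
  mis <- which(q[1:n1] != s1[1:n1] | !valid[1:n1])
  a <- if (length(mis)) mis[1] - 1L else n1
  n2 <- min(l_f, length(s2))
  qr <- rev(q)[1:n2]; vr <- rev(valid)[1:n2]
  mis2 <- which(qr != rev(s2)[1:n2] | !vr)
  b <- if (length(mis2)) mis2[1] - 1L else n2
  keep <- l_f - iota
  a_prime <- min(a, keep)
  if (b < keep - a_prime) return(NULL)
  sv <- substr(query, a_prime + 1L, a_prime + iota)
  if (w1$strand == 1L) {
    at <- w1$start + a_prime
  } else {
    at <- w1$end - a_prime
    sv <- rc_chr(sv)
  }
  data.frame(chrom_u = w1$chrom, u = at, side_u = "L",
             chrom_v = w1$chrom, v = at, side_v = "R",
             kind = "insertion", sv_seq = sv, stringsAsFactors = FALSE)
}

# map a minimal-reference boundary (0..2*l_f) to a reference coordinate and
# approach side. `segment_left` says whether the aligned segment adjoining the
# boundary lies to the boundary's left in minimal-reference coordinates.
map_boundary <- function(minref, t, segment_left) {
  joff <- minref$junction_offset
  use_left <- if (segment_left) t <= joff else t < joff
  w <- if (use_left) minref$left_window else minref$right_window
  o <- if (use_left) t else t - joff
  if (w$strand == 1L) {
    pos <- w$start + o
    side <- if (segment_left) "L" else "R"
  } else {
    pos <- w$end - o
    side <- if (segment_left) "R" else "L"
  }
  list(chrom = w$chrom, pos = pos, side = side)
}

#' Breakpoints from a gapped alignment
#'
#' Maps the endpoints of internal alignment gaps back through the minimal
#' reference windows (undoing reverse complement where applicable) to
#' reference coordinates with approach sides, and extracts the inserted or
#' deleted sequence.
#'
#' @param aln A `detsv_alignment` of the fragment against `minref`.
#' @param minref The `detsv_minref` used for the alignment.
#' @param reference Reference accepted by [load_reference()] (used to recover
#'   deleted sequences that extend beyond the windows).
#' @param min_identity Minimum fraction of matching bases over aligned
#'   (non-gap) columns; alignments below it are discarded (returns `NULL`).
#' @param max_events Fragments yielding more than this many gap events are
#'   discarded as complex (default 2).
#' @return `data.frame` of events with breakpoints `chrom_u`, `u`, `side_u`,
#'   `chrom_v`, `v`, `side_v`, the event `kind` (`"insertion"`, `"deletion"`
#'   or `"junction"`) and `sv_seq`, or `NULL` when the fragment is discarded.
#' @export
breakpoints_from_alignment <- function(aln, minref, reference,
                                       min_identity = 0.95, max_events = 2L) {
  seqs <- load_reference(reference)
  # pure-insertion pairs are resolved exactly from the seed-anchored flanks
  rep <- exact_insertion_event(aln$query, minref)
  if (!is.null(rep)) return(rep)
  ops <- aln$ops
  n_aligned <- sum(ops == 0L)
  if (n_aligned == 0) return(NULL)
  if (aln$nmatch / n_aligned < min_identity) return(NULL)
  r <- rle(ops)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # query/subject consumed before each run
  dq <- ifelse(r$values %in% c(0L, 2L), r$lengths, 0L)
  ds <- ifelse(r$values %in% c(0L, 1L, 3L), r$lengths, 0L)
  q0 <- c(0L, cumsum(dq))[seq_along(r$values)]
  s0 <- c(0L, cumsum(ds))[seq_along(r$values)]
  nr <- length(r$values)
  # internal gap runs: flanked by aligned columns on both sides
  has_m_before <- cumsum(r$values == 0L) > 0
  has_m_after <- rev(cumsum(rev(r$values == 0L)) > 0)
  ev <- list()
  for (i in seq_len(nr)) {
    v <- r$values[i]
    if (v != 1L && v != 2L) next
    if (!((i > 1 && has_m_before[i - 1]) && (i < nr && has_m_after[i + 1]))) next
    if (v == 1L) {               # subject consumed: deletion or junction
      sj1 <- s0[i]; sj2 <- s0[i] + r$lengths[i]
      b1 <- map_boundary(minref, sj1, segment_left = TRUE)
      b2 <- map_boundary(minref, sj2, segment_left = FALSE)
      if (b1$side == "L" && b2$side == "R" && b1$chrom == b2$chrom &&
          b2$pos == b1$pos)
        next   # the two windows are adjacent here: no structural junction
      kind <- "junction"; sv <- ""
      if (b1$side == "L" && b2$side == "R" && b1$chrom == b2$chrom &&
          b2$pos > b1$pos) {
        kind <- "deletion"
        sv <- ref_slice(seqs, b1$chrom, b1$pos, b2$pos)
      }
      ev[[length(ev) + 1L]] <- data.frame(
        chrom_u = b1$chrom, u = b1$pos, side_u = b1$side,
        chrom_v = b2$chrom, v = b2$pos, side_v = b2$side,
        kind = kind, sv_seq = sv, stringsAsFactors = FALSE)
    } else {                     # query consumed: inserted sequence
      qi1 <- q0[i]; qi2 <- q0[i] + r$lengths[i]
      sj <- s0[i]
      b1 <- map_boundary(minref, sj, segment_left = TRUE)
      b2 <- map_boundary(minref, sj, segment_left = FALSE)
      sv <- substr(aln$query, qi1 + 1L, qi2)
      kind <- if (b1$chrom == b2$chrom && b1$pos == b2$pos &&
                  b1$side == "L" && b2$side == "R") "insertion" else "junction"
      ev[[length(ev) + 1L]] <- data.frame(
        chrom_u = b1$chrom, u = b1$pos, side_u = b1$side,
        chrom_v = b2$chrom, v = b2$pos, side_v = b2$side,
        kind = kind, sv_seq = sv, stringsAsFactors = FALSE)
    }
  }
  if (length(ev) == 0 || length(ev) > max_events) return(NULL)
  ev <- do.call(rbind, ev)
  # When the inserted sequence happens to share its edge bases with the
  # reference around the insertion point, the optimal alignment matches those
  # bases and splits the event into a shorter insertion plus a small
  # back-junction (u > v). Both describe the same sample sequence, so they
  # are folded back into the canonical full-length insertion at u.
  if (nrow(ev) == 2L) {
    ii <- which(ev$kind == "insertion")
    jj <- which(ev$kind == "junction")
    if (length(ii) == 1L && length(jj) == 1L) {
      ei <- ev[ii, ]; ej <- ev[jj, ]
      if (ej$side_u == "L" && ej$side_v == "R" &&
          ej$chrom_u == ej$chrom_v && ej$chrom_u == ei$chrom_u &&
          ej$u > ej$v && ei$u >= ej$v && ei$u <= ej$u) {
        # canonical placement: the left flank ends at the junction's left
        # boundary u; the inserted sequence (the short insertion plus the
        # duplicated stretch) is cut out of the fragment itself, so the
        # implied sample sequence is exact even when flanking alignment
        # columns carry mismatches
        at <- if (ii < jj) ei$u else ej$u
        len <- nchar(ei$sv_seq) + (ej$u - ej$v)
        w1 <- minref$left_window
        o_at <- if (w1$strand == 1L) at - w1$start else w1$end - at
        sv <- substr(aln$query, o_at + 1L, o_at + len)
        if (nchar(sv) == len) {
          ev <- data.frame(chrom_u = ei$chrom_u, u = at, side_u = "L",
                           chrom_v = ei$chrom_u, v = at, side_v = "R",
                           kind = "insertion", sv_seq = sv,
                           stringsAsFactors = FALSE)
        }
      }
    }
  }
  ev
}

# ---------------------------------------------------------------------------
# Equivalent placements (micro-homology / repeat slides)
# ---------------------------------------------------------------------------

# Shift validity conditions per canonical edge type. A shift delta moves the
# junction along the sample sequence; positive delta moves it rightward along
# the fragment. Coordinates move as:
#   b (left -> right): (u + delta, v + delta)
#   a (left,left):     (u + delta, v - delta)
#   d (right,right):   (u - delta, v + delta)
#   insertion loop:    (p + delta) with the inserted sequence rotated
slide_range <- function(seqs, type, chrom_u, u, chrom_v, v, sv_seq = "",
                        max_slide = 200L) {
  base_at <- function(chrom, pos) {
    if (pos < 0 || pos >= chrom_len(seqs, chrom)) return(NA_character_)
    ref_base(seqs, chrom, pos)
  }
  ok <- function(b1, b2) !is.na(b1) && !is.na(b2) && b1 %in% DNA_BASES && b1 == b2
  hi <- 0L; lo <- 0L
  if (type == "ins") {
    S <- strsplit(sv_seq, "")[[1]]; n <- length(S)
    s <- S
    while (hi < max_slide && ok(base_at(chrom_u, u + hi), s[1])) {
      s <- c(s[-1], base_at(chrom_u, u + hi)); hi <- hi + 1L
    }
    s <- S
    while (lo > -max_slide && ok(base_at(chrom_u, u + lo - 1L), s[n])) {
      s <- c(base_at(chrom_u, u + lo - 1L), s[-n]); lo <- lo - 1L
    }
  } else if (type == "b") {
    while (hi < max_slide && ok(base_at(chrom_u, u + hi), base_at(chrom_v, v + hi)))
      hi <- hi + 1L
    while (lo > -max_slide && ok(base_at(chrom_u, u + lo - 1L), base_at(chrom_v, v + lo - 1L)))
      lo <- lo - 1L
  } else if (type == "a") {
    cb <- function(x) chartr("ACGT", "TGCA", x)
    while (hi < max_slide && ok(base_at(chrom_u, u + hi), cb(base_at(chrom_v, v - 1L - hi))))
      hi <- hi + 1L
    while (lo > -max_slide && ok(base_at(chrom_u, u + lo - 1L), cb(base_at(chrom_v, v - lo))))
      lo <- lo - 1L
  } else if (type == "d") {
    cb <- function(x) chartr("ACGT", "TGCA", x)
    while (hi < max_slide && ok(base_at(chrom_v, v + hi), cb(base_at(chrom_u, u - 1L - hi))))
      hi <- hi + 1L
    while (lo > -max_slide && ok(base_at(chrom_v, v + lo - 1L), cb(base_at(chrom_u, u - lo))))
      lo <- lo - 1L
  } else {
    # e edges carry no junction of their own
  }
  c(lo = lo, hi = hi)
}

# realize the inserted sequence after shifting an insertion by delta
shift_insertion_seq <- function(seqs, chrom, p, sv_seq, delta) {
  s <- strsplit(sv_seq, "")[[1]]; n <- length(s)
  if (delta > 0) {
    for (i in seq_len(delta)) {
      b <- ref_base(seqs, chrom, p + i - 1L)
      s <- c(s[-1], b)
    }
  } else if (delta < 0) {
    for (i in seq_len(-delta)) {
      b <- ref_base(seqs, chrom, p - i)
      s <- c(b, s[-n])
    }
  }
  paste(s, collapse = "")
}

#' Enumerate co-optimal breakpoint placements
#'
#' Within repeats, several alignments of the fragment against the minimal
#' reference are score-identical and therefore indistinguishable: inserting a
#' single `A` into a homopolymer of n `A`s admits n+1 placements. This
#' enumerates every placement whose implied sample sequence is identical to
#' the called one (equivalently, every gap placement with the optimal score),
#' optionally widened by a tolerance in bases.
#'
#' @param reference Reference accepted by [load_reference()].
#' @param type Canonical edge type: `"ins"`, `"b"`, `"a"` or `"d"`.
#' @param chrom_u,u,chrom_v,v Breakpoints of the called placement (for
#'   insertions, `chrom_u`/`u` only).
#' @param sv_seq Inserted sequence (insertions only).
#' @param tolerance Extra bases beyond the exact-score range (default 0).
#' @return `data.frame` of equivalent placements (`u`, `v`, `sv_seq`), one
#'   row per placement, ordered by shift; the input placement is included.
#' @export
enumerate_optimal_placements <- function(reference, type, chrom_u, u,
                                         chrom_v = chrom_u, v = u,
                                         sv_seq = "", tolerance = 0L) {
  seqs <- load_reference(reference)
  r <- slide_range(seqs, type, chrom_u, u, chrom_v, v, sv_seq)
  lo <- r["lo"] - tolerance; hi <- r["hi"] + tolerance
  deltas <- seq.int(lo, hi)
  sign_u <- switch(type, ins = 1L, b = 1L, a = 1L, d = -1L, 0L)
  sign_v <- switch(type, ins = 1L, b = 1L, a = -1L, d = 1L, 0L)
  out <- data.frame(delta = deltas,
                    u = u + sign_u * deltas,
                    v = v + sign_v * deltas,
                    sv_seq = sv_seq,
                    stringsAsFactors = FALSE)
  if (type == "ins" && nzchar(sv_seq)) {
    within <- deltas >= r["lo"] & deltas <= r["hi"]
    out$sv_seq[within] <- vapply(deltas[within], function(d)
      shift_insertion_seq(seqs, chrom_u, u, sv_seq, d), "")
  }
  out
}
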