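# From discordant fragments to typed breakpoint evidence.
#
# Each gap event of a fragment alignment yields one directed edge from the
# read-1-side breakpoint to the read-2-side breakpoint, typed by the pair of
# approach sides: a = (left,left), b = (left,right), c = (right,left),
# d = (right,right). Since fragment orientation during sequencing is
# arbitrary, orientation-swapped edges carry the same information and are
# folded onto canonical representatives:
#   a(u,v) == a(v,u);  d(u,v) == d(v,u);  b(u,v) == c(v,u).
# Canonical a/d edges store their endpoints in (chrom, pos) order; c edges are
# rewritten as b with swapped endpoints. A perfectly reconstructed insertion
# (both boundaries at one coordinate) is the self-loop edge type "ins".

edge_type_from_sides <- function(side_u, side_v) {
  paste0(ifelse(side_u == "L", "l", "r"), ifelse(side_v == "L", "l", "r"))
}

#' Canonicalize a discordant edge
#'
#' Applies the orientation-swap equivalences and returns the canonical
#' representative: `c(u,v)` becomes `b(v,u)`; `a` and `d` edges (and `e`
#' edges) get their endpoints sorted by (chrom, pos).
#'
#' @param type One of `"a"`, `"b"`, `"c"`, `"d"`, `"e"`, `"ins"`.
#' @param chrom_u,u,chrom_v,v Edge endpoints (0-based positions).
#' @return List with canonical `type`, `chrom_u`, `u`, `chrom_v`, `v` and
#'   `swapped` (whether the endpoints were exchanged).
#' @export
canonicalize_edge <- function(type, chrom_u, u, chrom_v, v) {
  swapped <- FALSE
  if (type == "c") {
    type <- "b"
    tmp <- list(chrom_u, u); chrom_u <- chrom_v; u <- v
    chrom_v <- tmp[[1]]; v <- tmp[[2]]
    swapped <- TRUE
  } else if (type %in% c("a", "d", "e")) {
    if (chrom_v < chrom_u || (chrom_v == chrom_u && v < u)) {
      tmp <- list(chrom_u, u); chrom_u <- chrom_v; u <- v
      chrom_v <- tmp[[1]]; v <- tmp[[2]]
      swapped <- TRUE
    }
  }
  list(type = type, chrom_u = chrom_u, u = u, chrom_v = chrom_v, v = v,
       swapped = swapped)
}

#' Derive canonical edges from one fragment's gap events
#'
#' @param events Event table from [breakpoints_from_alignment()].
#' @param pair_id Supporting pair identifier.
#' @param reference Reference accepted by [load_reference()] (for the
#'   equivalent-placement ranges).
#' @param e_max Maximum span for an auxiliary donor-adjacency `e` edge; when a
#'   single fragment pins three distinct coordinates, the same-chromosome
#'   boundary pair no further apart than this is joined by an `e` edge.
#' @return Evidence `data.frame`: `pair_id`, `type`, `chrom_u`, `u`,
#'   `chrom_v`, `v`, `lo`, `hi` (equivalent-shift range), `sv_seq`.
#' @export
edge_from_fragment <- function(events, pair_id, reference, e_max = 287L) {
  seqs <- load_reference(reference)
  rows <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    if (ev$kind == "insertion") {
      type <- "ins"
      can <- list(type = "ins", chrom_u = ev$chrom_u, u = ev$u,
                  chrom_v = ev$chrom_v, v = ev$v)
    } else {
      raw <- edge_type_from_sides(ev$side_u, ev$side_v)
      type <- c(ll = "a", lr = "b", rl = "c", rr = "d")[[raw]]
      can <- canonicalize_edge(type, ev$chrom_u, ev$u, ev$chrom_v, ev$v)
    }
    sl <- slide_range(seqs, can$type, can$chrom_u, can$u, can$chrom_v, can$v,
                      ev$sv_seq)
    data.frame(pair_id = pair_id, type = can$type,
               chrom_u = can$chrom_u, u = can$u,
               chrom_v = can$chrom_v, v = can$v,
               lo = sl[["lo"]], hi = sl[["hi"]],
               sv_seq = ev$sv_seq, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # a single fragment pinning three distinct coordinates also pins the
  # same-chromosome boundary adjacency (donor excision/retention evidence)
  if (nrow(out) == 2L) {
    ends <- unique(data.frame(
      chrom = c(out$chrom_u, out$chrom_v), pos = c(out$u, out$v),
      stringsAsFactors = FALSE))
    if (nrow(ends) == 3L) {
      per_edge <- lapply(1:2, function(i)
        paste(c(out$chrom_u[i], out$chrom_v[i]), c(out$u[i], out$v[i])))
      keys <- paste(ends$chrom, ends$pos)
      shared_key <- intersect(per_edge[[1]], per_edge[[2]])
      others <- ends[!(keys %in% shared_key), ]
      if (nrow(others) == 2L && others$chrom[1] == others$chrom[2] &&
          abs(others$pos[2] - others$pos[1]) <= e_max) {
        o <- order(others$pos)
        out <- rbind(out, data.frame(
          pair_id = pair_id, type = "e",
          chrom_u = others$chrom[o[1]], u = others$pos[o[1]],
          chrom_v = others$chrom[o[2]], v = others$pos[o[2]],
          lo = 0L, hi = 0L, sv_seq = "", stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Localize breakpoints for all discordant pairs
#'
#' For every usable discordant pair: build the minimal reference, align the
#' reconstructed fragment to it with affine gap penalties, convert the optimal
#' gap(s) to breakpoints, and emit canonical typed edges with their
#' equivalent-placement ranges.
#'
#' @param classified Classified pairs from [classify_pairs()].
#' @param frags Fragments from [reconstruct_fragments()].
#' @param reference Reference accepted by [load_reference()].
#' @param params Alignment scoring from [align_params()].
#' @param min_identity Minimum identity outside gaps (default 0.95).
#' @return Evidence `data.frame` (see [edge_from_fragment()]); attribute
#'   `n_dropped` counts discordant pairs yielding no usable evidence.
#' @export
fragment_breakpoints <- function(classified, frags, reference,
                                 params = align_params(), min_identity = 0.95) {
  seqs <- load_reference(reference)
  disc <- classified[classified$label == "discordant", , drop = FALSE]
  fr <- frags[match(disc$pair_id, frags$pair_id), ]
  out <- vector("list", nrow(disc))
  dropped <- 0L
  for (i in seq_len(nrow(disc))) {
    mr <- build_minimal_reference(disc[i, ], fr$l_f[i], seqs)
    if (is.null(mr)) { dropped <- dropped + 1L; next }
    al <- global_align_affine(fr$seq[i], mr, params)
    ev <- breakpoints_from_alignment(al, mr, seqs, min_identity = min_identity)
    if (is.null(ev)) { dropped <- dropped + 1L; next }
    out[[i]] <- edge_from_fragment(ev, disc$pair_id[i], seqs)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(pair_id = character(), type = character(),
                      chrom_u = character(), u = integer(),
                      chrom_v = character(), v = integer(),
                      lo = integer(), hi = integer(), sv_seq = character(),
                      stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- dropped
  out
}
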