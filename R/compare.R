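# Two-sample comparison and sequence-context analyses of called SVs.

call_tolerance <- function(type, tol_indel, tol_complex) {
  ifelse(type %in% c("insertion", "deletion"), tol_indel, tol_complex)
}

#' Intersect two call sets
#'
#' Two calls match when they have the same type and chromosome(s), every
#' corresponding breakpoint lies within the per-type tolerance (1 bp for
#' indels, to absorb equivalent alignments; 10 bp for the junction types),
#' and, for insertions, the inserted sequences have identical length.
#' Matching is 1-to-1 greedy by proximity.
#'
#' @param a,b Call sets from [call_svs()].
#' @param tol_indel Breakpoint tolerance for insertions/deletions (default 1).
#' @param tol_complex Tolerance for all other types (default 10).
#' @return List with `common` (matched `a` rows, with `b_index` pointing into
#'   `b`), `a_specific` and `b_specific`.
#' @export
intersect_calls <- function(a, b, tol_indel = 1L, tol_complex = 10L) {
  a_match <- rep(NA_integer_, nrow(a))
  b_used <- rep(FALSE, nrow(b))
  for (ty in intersect(unique(a$type), unique(b$type))) {
    ai <- which(a$type == ty); bi <- which(b$type == ty)
    tol <- call_tolerance(ty, tol_indel, tol_complex)
    has_site <- grepl("duplication_|translocation", ty)
    abp <- cbind(a$start[ai], a$end[ai], if (has_site) a$site_pos[ai])
    bbp <- cbind(b$start[bi], b$end[bi], if (has_site) b$site_pos[bi])
    akey <- paste(a$chrom[ai], if (has_site) a$site_chrom[ai] else "")
    bkey <- paste(b$chrom[bi], if (has_site) b$site_chrom[bi] else "")
    for (i in seq_along(ai)) {
      dev <- apply(abs(sweep(bbp, 2, abp[i, ], `-`)), 1, max)
      dev[b_used[bi] | bkey != akey[i]] <- Inf
      if (ty == "insertion")
        dev[b$size[bi] != a$size[ai[i]]] <- Inf
      j <- which.min(dev)
      if (length(j) && is.finite(dev[j]) && dev[j] <= tol) {
        a_match[ai[i]] <- bi[j]
        b_used[bi[j]] <- TRUE
      }
    }
  }
  common <- a[!is.na(a_match), , drop = FALSE]
  common$b_index <- a_match[!is.na(a_match)]
  rownames(common) <- NULL
  list(common = common,
       a_specific = a[is.na(a_match), , drop = FALSE],
       b_specific = b[!b_used, , drop = FALSE])
}

#' Shared fraction of calls as a function of the minimum required weight
#'
#' High-confidence events are more likely to be present in both samples
#' (germline rather than sample-specific artifacts), so the shared fraction
#' grows with the weight cutoff.
#'
#' @param a,b Call sets.
#' @param w_range Weight cutoffs to evaluate (default 1:4).
#' @param type Optional single type to restrict to.
#' @inheritParams intersect_calls
#' @return `data.frame` per cutoff: `w`, `n_a`, `n_b`, `n_common`,
#'   `shared_a`, `shared_b`.
#' @export
overlap_vs_weight <- function(a, b, w_range = 1:4, type = NULL,
                              tol_indel = 1L, tol_complex = 10L) {
  if (!is.null(type)) {
    a <- a[a$type == type, , drop = FALSE]
    b <- b[b$type == type, , drop = FALSE]
  }
  rows <- lapply(w_range, function(w) {
    aw <- filter_by_weight(a, w); bw <- filter_by_weight(b, w)
    ix <- intersect_calls(aw, bw, tol_indel, tol_complex)
    data.frame(w = w, n_a = nrow(aw), n_b = nrow(bw),
               n_common = nrow(ix$common),
               shared_a = if (nrow(aw)) nrow(ix$common) / nrow(aw) else NA_real_,
               shared_b = if (nrow(bw)) nrow(ix$common) / nrow(bw) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Signed size distribution of indel calls
#'
#' @param calls Calls from [call_svs()].
#' @return `data.frame` with `size` (positive for insertions, negative for
#'   deletions) and `count`, sorted by size.
#' @export
size_distribution <- function(calls) {
  x <- calls[calls$type %in% c("insertion", "deletion"), , drop = FALSE]
  signed <- ifelse(x$type == "insertion", x$size, -x$size)
  tb <- table(signed)
  out <- data.frame(size = as.integer(names(tb)), count = as.integer(tb))
  out[order(out$size), , drop = FALSE]
}

#' Most frequently inserted sequences
#'
#' @param calls Calls from [call_svs()].
#' @param n Number of top sequences (default 10); ties broken
#'   lexicographically.
#' @return `data.frame` with `seq` and `count`, most frequent first.
#' @export
top_inserted_sequences <- function(calls, n = 10L) {
  x <- calls[calls$type == "insertion" & nzchar(calls$sv_seq), , drop = FALSE]
  tb <- table(x$sv_seq)
  out <- data.frame(seq = names(tb), count = as.integer(tb),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  head(out, n)
}

# length of the run of base `base` through/around reference position, given
# the two flank start positions (0-based): left flank scans down from
# `left_from`, right flank scans up from `right_from`, plus `self` for a
# deleted base sitting on the reference
run_length_at <- function(seqs, chrom, base, left_from, right_from, self = 0L) {
  n <- chrom_len(seqs, chrom)
  l <- 0L
  while (left_from - l >= 0 && ref_base(seqs, chrom, left_from - l) == base) l <- l + 1L
  r <- 0L
  while (right_from + r < n && ref_base(seqs, chrom, right_from + r) == base) r <- r + 1L
  l + r + self
}

#' Fraction of single-base indels inside simple repeats
#'
#' A single-base event counts as "within a simple repeat" when its breakpoint
#' abuts or lies inside a run of at least `min_run` copies of the same base
#' as the inserted/deleted base, assessed on the reference and allowed to
#' span both flanks of the site.
#'
#' @param calls Calls from [call_svs()].
#' @param reference Reference accepted by [load_reference()].
#' @param min_run Minimum run length (default 4).
#' @return `data.frame` per base: `base`, `n_total`, `n_in_repeat`,
#'   `fraction`.
#' @export
simple_repeat_fraction <- function(calls, reference, min_run = 4L) {
  seqs <- load_reference(reference)
  x <- calls[calls$type %in% c("insertion", "deletion") & calls$size == 1L, ,
             drop = FALSE]
  base <- ifelse(x$type == "insertion", x$sv_seq,
                 vapply(seq_len(nrow(x)), function(i)
                   ref_base(seqs, x$chrom[i], x$start[i]), ""))
  in_rep <- vapply(seq_len(nrow(x)), function(i) {
    if (x$type[i] == "insertion") {
      run_length_at(seqs, x$chrom[i], base[i], x$start[i] - 1L, x$start[i]) >= min_run
    } else {
      run_length_at(seqs, x$chrom[i], base[i], x$start[i] - 1L, x$start[i] + 1L,
                    self = 1L) >= min_run
    }
  }, TRUE)
  out <- do.call(rbind, lapply(DNA_BASES, function(b) {
    idx <- base == b
    data.frame(base = b, n_total = sum(idx), n_in_repeat = sum(in_rep[idx]),
               fraction = if (sum(idx)) sum(in_rep[idx]) / sum(idx) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Insertions forming direct repeats
#'
#' An insertion longer than two bp qualifies as a direct repeat when the
#' inserted sequence is identical to the reference sequence immediately left
#' or immediately right of the insertion site - the footprint left by
#' conservative excision of a DNA transposon. The non-simple subset
#' additionally requires at least three distinct bases in the inserted
#' sequence (excluding low-complexity slippage products).
#'
#' @param calls Calls from [call_svs()].
#' @param reference Reference accepted by [load_reference()].
#' @return List with `direct` (qualifying insertion calls) and `nonsimple`
#'   (its >= 3-distinct-base subset).
#' @export
direct_repeat_insertions <- function(calls, reference) {
  seqs <- load_reference(reference)
  x <- calls[calls$type == "insertion" & calls$size >= 3L, , drop = FALSE]
  is_dr <- vapply(seq_len(nrow(x)), function(i) {
    p <- x$start[i]; len <- x$size[i]; ch <- x$chrom[i]
    n <- chrom_len(seqs, ch)
    left <- if (p - len >= 0) ref_slice(seqs, ch, p - len, p) else ""
    right <- if (p + len <= n) ref_slice(seqs, ch, p, p + len) else ""
    x$sv_seq[i] == left || x$sv_seq[i] == right
  }, TRUE)
  direct <- x[is_dr, , drop = FALSE]
  distinct <- vapply(strsplit(direct$sv_seq, ""), function(s)
    length(unique(s)), 0L)
  rownames(direct) <- NULL
  nonsimple <- direct[distinct >= 3L, , drop = FALSE]
  rownames(nonsimple) <- NULL
  list(direct = direct, nonsimple = nonsimple)
}

#' Breakpoints of a call set
#'
#' @param calls Calls from [call_svs()].
#' @return `data.frame` with `chrom` and `pos` (0-based), one row per
#'   breakpoint (insertion site included for duplicative events).
#' @export
call_breakpoints <- function(calls) {
  bp <- rbind(data.frame(chrom = calls$chrom, pos = calls$start),
              data.frame(chrom = calls$chrom, pos = calls$end),
              data.frame(chrom = calls$site_chrom, pos = calls$site_pos))
  bp <- bp[!is.na(bp$chrom), , drop = FALSE]
  bp <- unique(bp)
  rownames(bp) <- NULL
  bp
}

#' Breakpoint density per functional genome compartment
#'
#' Partitions the genome into functional compartments from a gene annotation
#' and reports the breakpoint density (breakpoints per bp) in each: whole
#' genome, unique genes (sharing no position with another gene), overlapping
#' genes, exonic/CDS/UTR subsets (taken from unique genes only, to avoid
#' ambiguity), introns, intergenic space, and 2 bp donor/acceptor splice
#' sites.
#'
#' @param breakpoints `data.frame` with `chrom`, `pos` (0-based), e.g. from
#'   [call_breakpoints()].
#' @param annotation GFF3 file path or a `GRanges` with `type` metadata
#'   (`gene`, `exon`, `CDS`, `five_prime_UTR`, `three_prime_UTR`).
#' @param reference Reference accepted by [load_reference()] (for chromosome
#'   lengths).
#' @return `data.frame` per compartment: `compartment`, `total_bp`,
#'   `n_breakpoints`, `density`.
#' @export
breakpoint_compartment_density <- function(breakpoints, annotation, reference) {
  seqs <- load_reference(reference)
  gr <- if (is.character(annotation)) rtracklayer::import(annotation) else annotation
  if (is.null(gr$type)) stop("annotation lacks required field 'type'")
  lens <- setNames(nchar(seqs), names(seqs))
  sl <- GenomicRanges::GRanges(names(lens), IRanges::IRanges(1, unname(lens)))
  feat <- function(ty) {
    x <- gr[gr$type == ty]
    if (ty == "gene" && length(x) == 0) stop("annotation lacks required field 'gene'")
    GenomicRanges::reduce(x, ignore.strand = TRUE)
  }
  genes_all <- gr[gr$type == "gene"]
  if (length(genes_all) == 0) stop("annotation lacks required field 'gene'")
  ov <- GenomicRanges::countOverlaps(genes_all, genes_all, ignore.strand = TRUE)
  unique_genes <- GenomicRanges::reduce(genes_all[ov == 1], ignore.strand = TRUE)
  overlapping_genes <- GenomicRanges::reduce(genes_all[ov > 1], ignore.strand = TRUE)
  restrict_u <- function(x)
    GenomicRanges::intersect(x, unique_genes, ignore.strand = TRUE)
  exonic <- restrict_u(feat("exon"))
  comp <- list(genome = GenomicRanges::reduce(sl),
               unique_genes = unique_genes,
               overlapping_genes = overlapping_genes,
               exonic = exonic)
  for (ty in c("CDS", "five_prime_UTR", "three_prime_UTR")) {
    x <- gr[gr$type == ty]
    if (length(x))
      comp[[sub("five_prime_UTR", "utr5",
                sub("three_prime_UTR", "utr3", ty))]] <- restrict_u(
        GenomicRanges::reduce(x, ignore.strand = TRUE))
  }
  intronic <- GenomicRanges::setdiff(unique_genes, exonic, ignore.strand = TRUE)
  comp$intronic <- intronic
  comp$intergenic <- GenomicRanges::setdiff(
    sl, GenomicRanges::reduce(genes_all, ignore.strand = TRUE),
    ignore.strand = TRUE)
  if (length(intronic)) {
    # splice sites are the first/last 2 bp of each intron
    comp$splice_sites <- GenomicRanges::reduce(c(
      GenomicRanges::resize(intronic, 2, fix = "start"),
      GenomicRanges::resize(intronic, 2, fix = "end")))
  }
  bp_gr <- GenomicRanges::GRanges(breakpoints$chrom,
                                  IRanges::IRanges(breakpoints$pos + 1L, width = 1))
  out <- do.call(rbind, lapply(names(comp), function(nm) {
    reg <- comp[[nm]]
    tot <- sum(GenomicRanges::width(reg))
    nbp <- sum(GenomicRanges::countOverlaps(bp_gr, reg, ignore.strand = TRUE) > 0)
    data.frame(compartment = nm, total_bp = tot, n_breakpoints = nbp,
               density = if (tot > 0) nbp / tot else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
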