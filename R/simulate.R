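# Simulation: random references, planted SVs of the sixteen types on one or
# two haplotypes, overlapping paired-end reads, and recall evaluation against
# the planted truth.

#' The sixteen SV type names
#'
#' @return Character vector of the catalog's type names.
#' @export
sv_type_names <- function() names(prototype_catalog())

#' Default planted-SV size ranges
#'
#' Indel and tandem-duplication defaults follow the size ranges validated by
#' PCR for this method (insertions 22-133 bp, deletions 22-245 bp, tandem
#' duplications 293-889 bp); inversion and donor sizes use the same scale as
#' tandem duplications. All are configurable per call.
#'
#' @return Named list of `c(min, max)` sizes per type.
#' @export
default_sv_sizes <- function() {
  sizes <- list(insertion = c(22L, 133L), deletion = c(22L, 245L),
                tandem_duplication = c(293L, 889L), inversion = c(300L, 900L))
  for (nm in sv_type_names())
    if (is.null(sizes[[nm]])) sizes[[nm]] <- c(300L, 900L)
  sizes
}

#' Generate a random reference genome
#'
#' @param lengths Integer vector of chromosome lengths (named or not; unnamed
#'   chromosomes are called `chr1`, `chr2`, ...).
#' @param gc GC content (default 0.5).
#' @param seed Optional RNG seed.
#' @param repeat_cassette Optional length of an exact repeat cassette planted
#'   twice per chromosome (alignability stress tests); 0 disables.
#' @return Named character vector of chromosome sequences.
#' @export
generate_reference <- function(lengths, gc = 0.5, seed = NULL,
                               repeat_cassette = 0L) {
  if (!is.null(seed)) set.seed(seed)
  nm <- names(lengths) %||% paste0("chr", seq_along(lengths))
  if (is.null(names(lengths))) names(lengths) <- nm
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- vapply(lengths, function(n)
    paste(sample(DNA_BASES, n, replace = TRUE, prob = prob), collapse = ""), "")
  if (repeat_cassette > 0) {
    for (i in seq_along(seqs)) {
      n <- nchar(seqs[i])
      if (n < 4L * repeat_cassette) next
      cas <- substr(seqs[i], n %/% 4 + 1L, n %/% 4 + repeat_cassette)
      substr(seqs[i], (3L * n) %/% 4 + 1L, (3L * n) %/% 4 + repeat_cassette) <- cas
    }
  }
  seqs
}

rand_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# Choose non-interacting event loci. Events are laid out sequentially along
# the chromosomes with at least `spacing` bp between footprints, so no two
# signatures share fragments.
#' Plant structural variants into a reference
#'
#' Applies SVs of the requested types to one or two haplotype copies of the
#' reference and records the exact reference coordinates of every breakpoint
#' as ground truth. Planted events are spaced so that their read-pair
#' signatures cannot interact (nested or overlapping SVs are excluded by
#' design, matching the caller's scope).
#'
#' @param reference Reference accepted by [load_reference()].
#' @param counts Named integer vector: events per type (names from
#'   [sv_type_names()]).
#' @param sizes Named list of `c(min, max)` per type (default
#'   [default_sv_sizes()]).
#' @param ploidy 1 (haploid) or 2 (diploid).
#' @param hom_fraction For diploid planting, the fraction of events planted on
#'   both haplotypes (the rest are heterozygous, haplotype 1).
#' @param spacing Minimum gap between event footprints in bp (default 700).
#' @param site_distance Range of donor-to-insertion-site distances for
#'   intrachromosomal duplicative events (default 2000-3000 bp).
#' @param unambiguous_flanks Redraw indel positions/sequences until the
#'   junction admits a single optimal placement (exact-breakpoint tests).
#' @param seed Optional RNG seed.
#' @return List with `haplotypes` (list of named character vectors, one per
#'   haplotype) and `truth` (`data.frame`: `id`, `type`, `chrom`, `start`,
#'   `end`, `size`, `seq`, `site_chrom`, `site_pos`, `haps`).
#' @export
plant_svs <- function(reference, counts, sizes = default_sv_sizes(), ploidy = 1L,
                      hom_fraction = 0.5, spacing = 700L,
                      site_distance = c(2000L, 3000L),
                      unambiguous_flanks = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- load_reference(reference)
  chroms <- names(seqs)
  lens <- nchar(seqs)
  bad <- setdiff(names(counts), sv_type_names())
  if (length(bad)) stop("unknown SV type(s): ", paste(bad, collapse = ", "))
  types <- rep(names(counts), counts)
  if (length(types) == 0) stop("no events requested")
  types <- sample(types)
  if (any(grepl("inter", types)) && length(seqs) < 2)
    stop("interchromosomal events need at least 2 chromosomes")
  cursor <- setNames(rep(1000L, length(seqs)), chroms)
  take <- function(block, not_chrom = NA) {
    ok <- chroms[cursor + block + 1000L < lens &
                 (is.na(not_chrom) | chroms != not_chrom)]
    if (length(ok) == 0) stop("genome too small for the requested events")
    ch <- if (length(ok) == 1) ok else sample(ok, 1L)
    at <- cursor[[ch]]
    cursor[[ch]] <<- at + block + spacing + sample.int(200L, 1L)
    list(chrom = ch, at = at)
  }
  events <- vector("list", length(types))
  for (i in seq_along(types)) {
    ty <- types[i]
    sz <- sizes[[ty]]
    size <- sample.int(sz[2] - sz[1] + 1L, 1L) + sz[1] - 1L
    ev <- list(id = sprintf("sv%04d", i), type = ty, size = size,
               seq = "", site_chrom = NA_character_, site_pos = NA_integer_)
    if (ty %in% c("insertion", "deletion", "tandem_duplication", "inversion")) {
      loc <- take(size + 200L)
      s <- loc$at + 100L
      if (ty == "insertion") {
        ev$seq <- rand_dna(size)
        if (unambiguous_flanks) {
          for (try in 1:50) {
            r <- slide_range(seqs, "ins", loc$chrom, s, loc$chrom, s, ev$seq)
            if (r[["lo"]] == 0L && r[["hi"]] == 0L) break
            ev$seq <- rand_dna(size)
          }
        }
        ev$chrom <- loc$chrom; ev$start <- s; ev$end <- s
      } else {
        if (ty == "deletion" && unambiguous_flanks) {
          for (try in 1:50) {
            r <- slide_range(seqs, "b", loc$chrom, s, loc$chrom, s + size)
            if (r[["lo"]] == 0L && r[["hi"]] == 0L) break
            s <- s + 1L
          }
        }
        ev$chrom <- loc$chrom; ev$start <- s; ev$end <- s + size
      }
    } else {
      # duplicative / translocated events: donor [start, end), insertion site
      placement <- sub("^(insertional_duplication|translocation)_", "", ty)
      placement <- sub("_inv$", "", placement)
      dist <- sample.int(site_distance[2] - site_distance[1] + 1L, 1L) +
        site_distance[1] - 1L
      if (placement == "inter") {
        donor <- take(size + 200L)
        site <- take(200L, not_chrom = donor$chrom)
        ev$chrom <- donor$chrom; ev$start <- donor$at + 100L
        ev$end <- ev$start + size
        ev$site_chrom <- site$chrom; ev$site_pos <- site$at + 100L
      } else {
        loc <- take(size + dist + 200L)
        if (placement == "intra_up") {
          ev$site_pos <- loc$at + 100L
          ev$start <- ev$site_pos + dist
        } else {
          ev$start <- loc$at + 100L
          ev$site_pos <- ev$start + size + dist
        }
        ev$chrom <- loc$chrom; ev$end <- ev$start + size
        ev$site_chrom <- loc$chrom
      }
    }
    ev$haps <- if (ploidy == 1L) "1"
      else if (runif(1) < hom_fraction) "1,2" else "1"
    events[[i]] <- ev
  }
  truth <- do.call(rbind, lapply(events, function(e)
    data.frame(id = e$id, type = e$type, chrom = e$chrom, start = e$start,
               end = e$end, size = e$size, seq = e$seq,
               site_chrom = e$site_chrom, site_pos = e$site_pos,
               haps = e$haps, stringsAsFactors = FALSE)))
  truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  haplotypes <- lapply(seq_len(ploidy), function(h)
    apply_truth(seqs, truth[grepl(as.character(h), truth$haps), , drop = FALSE]))
  list(haplotypes = haplotypes, truth = truth)
}

# apply planted events to reference sequences by string surgery
apply_truth <- function(seqs, truth) {
  edits <- list()
  push <- function(chrom, s, e, repl)
    edits[[length(edits) + 1L]] <<- data.frame(chrom = chrom, s = s, e = e,
                                               repl = repl, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(truth))) {
    ev <- truth[i, ]
    donor <- function() ref_slice(seqs, ev$chrom, ev$start, ev$end)
    inv <- grepl("_inv$", ev$type)
    if (ev$type == "insertion") push(ev$chrom, ev$start, ev$start, ev$seq)
    else if (ev$type == "deletion") push(ev$chrom, ev$start, ev$end, "")
    else if (ev$type == "tandem_duplication") push(ev$chrom, ev$end, ev$end, donor())
    else if (ev$type == "inversion") push(ev$chrom, ev$start, ev$end, rc_chr(donor()))
    else if (grepl("^insertional_duplication", ev$type)) {
      push(ev$site_chrom, ev$site_pos, ev$site_pos,
           if (inv) rc_chr(donor()) else donor())
    } else if (grepl("^translocation", ev$type)) {
      push(ev$chrom, ev$start, ev$end, "")
      push(ev$site_chrom, ev$site_pos, ev$site_pos,
           if (inv) rc_chr(donor()) else donor())
    } else stop("unknown type ", ev$type)
  }
  if (length(edits) == 0) return(seqs)
  edits <- do.call(rbind, edits)
  out <- seqs
  for (ch in unique(edits$chrom)) {
    e <- edits[edits$chrom == ch, , drop = FALSE]
    e <- e[order(e$s), , drop = FALSE]
    if (any(e$s[-1] < e$e[-nrow(e)])) stop("overlapping edits on ", ch)
    pieces <- character(2L * nrow(e) + 1L)
    prev <- 0L
    for (i in seq_len(nrow(e))) {
      pieces[2L * i - 1L] <- ref_slice(seqs, ch, prev, e$s[i])
      pieces[2L * i] <- e$repl[i]
      prev <- e$e[i]
    }
    pieces[2L * nrow(e) + 1L] <- ref_slice(seqs, ch, prev, chrom_len(seqs, ch))
    out[[ch]] <- paste(pieces, collapse = "")
  }
  out
}

#' Simulate overlapping paired-end reads
#'
#' Fragments start uniformly along each haplotype; read 1 is the fragment's
#' first `L` bases, read 2 the reverse complement of its last `L`. In the
#' default overlap-guaranteed mode fragment sizes are drawn uniformly from
#' `[frag_min, frag_max]` with `frag_max <= 2L - m_min`, so every error-free
#' pair reconstructs; the untruncated normal mode (`frag_dist = "normal"`
#' with large `frag_sd`/`frag_max`) also produces non-overlapping pairs and
#' reproduces the bimodal overlap-score distribution of real libraries.
#'
#' @param haplotypes Named character vector of sequences, or a list of them
#'   (one per haplotype; coverage is split evenly).
#' @param coverage Total base coverage.
#' @param L Read length (default 150).
#' @param frag_dist `"uniform"` or `"normal"`.
#' @param frag_min,frag_max Fragment size bounds (defaults 200 and 287).
#' @param frag_mean,frag_sd Normal-mode parameters (defaults 250, 30).
#' @param error_rate Per-base substitution error rate (default 0).
#' @param seed Optional RNG seed.
#' @param prefix Pair-id prefix.
#' @return A `detsv_pairs` table.
#' @export
simulate_reads <- function(haplotypes, coverage, L = 150L,
                           frag_dist = c("uniform", "normal"),
                           frag_min = 200L, frag_max = 287L,
                           frag_mean = 250, frag_sd = 30,
                           error_rate = 0, seed = NULL, prefix = "p") {
  frag_dist <- match.arg(frag_dist)
  if (!is.null(seed)) set.seed(seed)
  if (!is.list(haplotypes)) haplotypes <- list(haplotypes)
  mean_len <- if (frag_dist == "uniform") (frag_min + frag_max) / 2 else frag_mean
  s1 <- s2 <- character(0)
  for (hap in haplotypes) {
    for (ch in names(hap)) {
      n <- nchar(hap[[ch]])
      nfrag <- round(coverage / length(haplotypes) * n / mean_len)
      if (nfrag == 0) next
      lens <- if (frag_dist == "uniform") {
        frag_min + sample.int(frag_max - frag_min + 1L, nfrag, replace = TRUE) - 1L
      } else {
        pmax(L, pmin(frag_max, round(rnorm(nfrag, frag_mean, frag_sd))))
      }
      lens <- pmin(lens, n)
      starts <- floor(runif(nfrag, 0, n - lens + 1))
      frag_head <- substr(rep(hap[[ch]], nfrag), starts + 1L, starts + L)
      frag_tail <- substr(rep(hap[[ch]], nfrag), starts + lens - L + 1L, starts + lens)
      s1 <- c(s1, frag_head)
      s2 <- c(s2, rc_chr(frag_tail))
    }
  }
  if (length(s1) == 0) stop("no fragments simulated; raise coverage")
  if (error_rate > 0) {
    mutate <- function(reads) {
      nerr <- rbinom(length(reads), nchar(reads), error_rate)
      for (i in which(nerr > 0)) {
        pos <- sample.int(nchar(reads[i]), nerr[i])
        for (p in pos) {
          old <- substr(reads[i], p, p)
          substr(reads[i], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
        }
      }
      reads
    }
    s1 <- mutate(s1); s2 <- mutate(s2)
  }
  read_pair_table(sprintf("%s%07d", prefix, seq_along(s1)), s1, s2)
}

#' Write read pairs as paired FASTQ
#'
#' @param pairs A `detsv_pairs` table.
#' @param fq1,fq2 Output paths for mates 1 and 2.
#' @return Invisibly, `c(fq1, fq2)`.
#' @export
write_fastq_pairs <- function(pairs, fq1, fq2) {
  one <- function(ids, seqs, quals, path) {
    q <- ifelse(is.na(quals), strrep("I", nchar(seqs)), quals)
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", q), path)
  }
  one(pairs$id, pairs$seq1, pairs$qual1, fq1)
  one(pairs$id, pairs$seq2, pairs$qual2, fq2)
  invisible(c(fq1, fq2))
}

#' Write a truth set as BED and JSON
#'
#' @param truth Truth table from [plant_svs()].
#' @param bed_path,json_path Output paths (`NULL` to skip).
#' @return Invisibly, `truth`.
#' @export
write_truth <- function(truth, bed_path = NULL, json_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = truth$chrom, start = truth$start,
                      end = pmax(truth$end, truth$start + 1L),
                      name = paste0(truth$id, ":", truth$type))
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(truth, json_path, dataframe = "rows", auto_unbox = TRUE)
  invisible(truth)
}

# default per-type evaluation tolerances: exact for indels, 10 bp for
# junction-sliding-prone types (mirroring the intersection tolerances)
default_eval_delta <- function() {
  d <- setNames(rep(10L, length(sv_type_names())), sv_type_names())
  d[c("insertion", "deletion")] <- 0L
  d
}

# canonical representative of a planted indel junction: the central placement
# of its equivalent range (the same rule the caller applies)
canonicalize_truth <- function(truth, reference) {
  seqs <- load_reference(reference)
  for (i in seq_len(nrow(truth))) {
    ty <- truth$type[i]
    if (ty == "deletion") {
      r <- slide_range(seqs, "b", truth$chrom[i], truth$start[i],
                       truth$chrom[i], truth$end[i])
      d <- lower_median(r[["lo"]], r[["hi"]])
      truth$start[i] <- truth$start[i] + d
      truth$end[i] <- truth$end[i] + d
    } else if (ty == "insertion") {
      r <- slide_range(seqs, "ins", truth$chrom[i], truth$start[i],
                       truth$chrom[i], truth$start[i], truth$seq[i])
      d <- lower_median(r[["lo"]], r[["hi"]])
      truth$start[i] <- truth$start[i] + d
      truth$end[i] <- truth$start[i]
    }
  }
  truth
}

#' Evaluate calls against a planted truth set
#'
#' A planted event is recalled when a call of the same type places every
#' corresponding breakpoint within the tolerance delta. Matching is 1-to-1
#' greedy by proximity. Planted indel junctions inside repeats admit ranges
#' of equivalent, indistinguishable placements; when `reference` is supplied
#' the truth coordinates are first moved to the central placement of their
#' equivalent range - the same canonical representative the caller reports -
#' so delta measures genuine localization error. For translocations,
#' insertional-duplication calls at the same locus are tallied separately as
#' partial-signature matches.
#'
#' @param calls Calls from [call_svs()].
#' @param truth Truth table from [plant_svs()].
#' @param delta Named per-type tolerance in bp (default: 0 for indels, 10
#'   otherwise), or a single number for all types.
#' @param reference Optional reference for truth canonicalization.
#' @return `data.frame` with one row per planted type: `type`, `n_truth`,
#'   `n_calls`, `n_recalled`, `recall`, `n_partial`, `precision`.
#' @export
evaluate_calls <- function(calls, truth, delta = default_eval_delta(),
                           reference = NULL) {
  if (length(delta) == 1 && is.null(names(delta)))
    delta <- setNames(rep(as.integer(delta), length(sv_type_names())),
                      sv_type_names())
  if (!is.null(reference)) truth <- canonicalize_truth(truth, reference)
  bp_cols <- function(df, type) {
    cols <- cbind(df$start, df$end)
    if (grepl("duplication_|translocation", type)) cols <- cbind(cols, df$site_pos)
    cols
  }
  chrom_key <- function(df) paste(df$chrom, ifelse(is.na(df$site_chrom), "", df$site_chrom))
  match_type <- function(tt, ct, type, tol) {
    # greedy 1-to-1: truths in order claim the nearest unused call
    used <- rep(FALSE, nrow(ct))
    hit <- rep(FALSE, nrow(tt))
    if (nrow(ct) == 0 || nrow(tt) == 0) return(list(hit = hit, used = used))
    tb <- bp_cols(tt, type); cb <- bp_cols(ct, type)
    tk <- chrom_key(tt); ck <- chrom_key(ct)
    for (i in seq_len(nrow(tt))) {
      dev <- apply(abs(sweep(cb, 2, tb[i, ], `-`)), 1, max)
      dev[used | ck != tk[i]] <- Inf
      if (type == "insertion")
        dev[abs(ct$size - tt$size[i]) > tol] <- Inf
      j <- which.min(dev)
      if (length(j) && is.finite(dev[j]) && dev[j] <= tol) {
        hit[i] <- TRUE; used[j] <- TRUE
      }
    }
    list(hit = hit, used = used)
  }
  out <- list()
  for (ty in unique(truth$type)) {
    tt <- truth[truth$type == ty, , drop = FALSE]
    ct <- calls[calls$type == ty, , drop = FALSE]
    tol <- unname(delta[ty])
    m <- match_type(tt, ct, ty, tol)
    n_partial <- 0L
    if (grepl("^translocation", ty)) {
      alt <- sub("^translocation", "insertional_duplication", ty)
      ca <- calls[calls$type == alt, , drop = FALSE]
      ma <- match_type(tt, ca, ty, tol)
      n_partial <- sum(ma$hit)
    }
    out[[ty]] <- data.frame(type = ty, n_truth = nrow(tt), n_calls = nrow(ct),
                            n_recalled = sum(m$hit),
                            recall = sum(m$hit) / nrow(tt),
                            n_partial = n_partial,
                            precision = if (nrow(ct)) sum(m$used) / nrow(ct) else NA_real_,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
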