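# Concordant and discordant coverage tracks and zygosity inference.
#
# The two tracks behave oppositely over true SVs: losing both wildtype
# alleles (homozygous) drives the concordant coverage to zero across the
# event, while a heterozygous event retains one wildtype allele and shows
# about half the flanking concordant coverage.

#' Compute a coverage track
#'
#' Concordant pairs increment every base of the fragment-projected reference
#' interval (the outer span of length l_f). Discordant pairs increment both
#' seed-anchored windows of length l_f (the fragment's two anchor regions).
#'
#' @param classified Classified pairs from [classify_pairs()].
#' @param reference Reference accepted by [load_reference()].
#' @param class `"concordant"` or `"discordant"`.
#' @return A `detsv_coverage`: named list of integer vectors (one per
#'   chromosome, length = chromosome length) with attribute `class`.
#' @export
compute_coverage <- function(classified, reference, class = c("concordant", "discordant")) {
  class <- match.arg(class)
  seqs <- load_reference(reference)
  lens <- setNames(nchar(seqs), names(seqs))
  add <- function(acc, chrom, start, end) {
    # difference-array increments on [start, end)
    ok <- !is.na(chrom) & !is.na(start) & !is.na(end)
    chrom <- chrom[ok]; start <- pmax(start[ok], 0L); end <- end[ok]
    for (ch in unique(chrom)) {
      idx <- chrom == ch
      s <- start[idx]; e <- pmin(end[idx], lens[[ch]])
      keep <- e > s
      if (!any(keep)) next
      acc[[ch]] <- acc[[ch]] +
        tabulate(s[keep] + 1L, nbins = lens[[ch]] + 1L) -
        tabulate(e[keep] + 1L, nbins = lens[[ch]] + 1L)
    }
    acc
  }
  acc <- lapply(lens, function(n) integer(n + 1L))
  x <- classified[classified$label == class, , drop = FALSE]
  if (class == "concordant") {
    left <- pmin(x$pos1, x$pos2)
    acc <- add(acc, x$chrom1, left, left + x$l_f)
  } else {
    w1s <- ifelse(x$strand1 == 1L, x$pos1, x$pos1 + 1L - x$l_f)
    acc <- add(acc, x$chrom1, w1s, w1s + x$l_f)
    w2s <- ifelse(x$strand2 == 1L, x$pos2, x$pos2 + 1L - x$l_f)
    acc <- add(acc, x$chrom2, w2s, w2s + x$l_f)
  }
  track <- lapply(acc, function(d) cumsum(d)[-length(d)])
  structure(track, class = "detsv_coverage", coverage_class = class)
}

#' Infer zygosity of SV calls from concordant coverage
#'
#' The wildtype allele contributes concordant pairs spanning the breakpoints
#' (positions the variant allele no longer covers concordantly), the variant
#' allele contributes the call's discordant weight, and both sample the same
#' locus, so their ratio cancels local coverage fluctuations. With C the
#' mean concordant coverage at the breakpoint columns (the first and last
#' affected bases; the site column for insertions) and W the weight, the wildtype
#' fraction r = C / (C + W) is about 0 for homozygous events (no wildtype
#' allele left, concordant coverage drops to zero) and about 0.5 for
#' heterozygous ones (comparable concordant and discordant coverage):
#' r <= `hom_max` is homozygous, `het_min` <= r <= `het_max` heterozygous,
#' and anything else - including calls whose discordant weight is small
#' relative to the flanking background coverage, the signature of technical
#' artifacts - is low confidence.
#'
#' @param calls Calls from [call_svs()].
#' @param conc Concordant `detsv_coverage` from [compute_coverage()].
#' @param flank Background window half-width in bp (default 1000).
#' @param hom_max,het_min,het_max Ratio thresholds (defaults 0.1, 0.3, 0.7).
#' @param min_weight_fraction Calls with `weight` below this fraction of the
#'   background coverage are low confidence (default 0.15).
#' @return `calls` with the `zygosity` column filled
#'   (`"homozygous"`, `"heterozygous"` or `"low_confidence"`).
#' @export
infer_zygosity <- function(calls, conc, flank = 1000L, hom_max = 0.1,
                           het_min = 0.3, het_max = 0.7,
                           min_weight_fraction = 0.15) {
  res <- attr(calls, "residual")
  zyg <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    cov <- conc[[cl$chrom]]
    n <- length(cov)
    # breakpoint columns: the first and last affected bases (track index is
    # 1-based, coordinates 0-based); insertions sample the site column
    idx <- unique(pmin(pmax(c(cl$start + 1L, cl$end), 1L), n))
    at_bp <- mean(cov[idx])
    win <- c(seq.int(max(1L, cl$start - flank + 1L), max(1L, cl$start)),
             seq.int(min(n, cl$end + 2L), min(n, cl$end + 1L + flank)))
    bg <- median(cov[unique(win)])
    zyg[i] <- if (bg <= 0) "low_confidence"
    else if (cl$weight / bg < min_weight_fraction) "low_confidence"
    else {
      r <- at_bp / (at_bp + cl$weight)
      if (r <= hom_max) "homozygous"
      else if (r >= het_min && r <= het_max) "heterozygous"
      else "low_confidence"
    }
  }
  calls$zygosity <- zyg
  attr(calls, "residual") <- res
  calls
}

#' Write a coverage track as bedGraph
#'
#' Adjacent positions with equal values are merged into one interval;
#' zero-coverage intervals are omitted.
#'
#' @param track A `detsv_coverage`.
#' @param path Output path.
#' @param name Track name for the header line.
#' @return Invisibly, the path.
#' @export
write_bedgraph <- function(track, path, name = attr(track, "coverage_class") %||% "coverage") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  for (ch in names(track)) {
    r <- rle(track[[ch]])
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%d", ch, s[keep], e[keep], r$values[keep]), con)
  }
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' @param path bedGraph path.
#' @param seqlens Named integer vector of chromosome lengths.
#' @return A `detsv_coverage`.
#' @export
read_bedgraph <- function(path, seqlens) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines)]
  track <- lapply(seqlens, integer)
  if (length(lines)) {
    df <- read.table(text = lines, sep = "\t", col.names = c("chrom", "start", "end", "value"))
    for (i in seq_len(nrow(df)))
      track[[df$chrom[i]]][(df$start[i] + 1L):df$end[i]] <- df$value[i]
  }
  structure(track, class = "detsv_coverage")
}
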