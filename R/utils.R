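# shared internal helpers

DNA_BASES <- c("A", "C", "G", "T")

# vectorized reverse complement on character vectors
rc_chr <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_chr <- function(x) {
  as.character(Biostrings::complement(Biostrings::DNAStringSet(x)))
}

#' Load a reference genome
#'
#' Accepts a FASTA path, a [Biostrings::DNAStringSet], or a named character
#' vector, and returns a named character vector of uppercase chromosome
#' sequences (the internal representation; all coordinates are 0-based).
#'
#' @param reference FASTA file path, `DNAStringSet`, or named character vector.
#' @return Named character vector of chromosome sequences.
#' @export
load_reference <- function(reference) {
  if (inherits(reference, "detsv_ref")) return(reference)
  if (is.character(reference) && length(reference) == 1 && file.exists(reference) &&
      is.null(names(reference))) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (is(reference, "DNAStringSet")) {
    out <- setNames(as.character(reference), names(reference))
  } else if (is.character(reference)) {
    out <- reference
  } else {
    stop("reference must be a FASTA path, DNAStringSet or named character vector")
  }
  if (length(out) == 0) stop("empty reference")
  if (is.null(names(out)) || any(!nzchar(names(out))))
    stop("reference sequences must be named")
  # FASTA headers may carry descriptions after the first word
  nm <- vapply(strsplit(names(out), "\\s+"), `[`, "", 1)
  out <- toupper(out)
  names(out) <- nm
  class(out) <- c("detsv_ref", "character")
  out
}

# substring by 0-based half-open interval
ref_slice <- function(seqs, chrom, start, end) {
  s <- seqs[[chrom]]
  if (start < 0 || end > nchar(s) || start > end)
    stop("slice [", start, ",", end, ") outside sequence '", chrom, "'")
  substr(s, start + 1, end)
}

ref_base <- function(seqs, chrom, pos) {
  substr(seqs[[chrom]], pos + 1, pos + 1)
}

chrom_len <- function(seqs, chrom) nchar(seqs[[chrom]])

# deterministic lower median of an integer range [lo, hi]
lower_median <- function(lo, hi) lo + (hi - lo) %/% 2L

`%||%` <- function(a, b) if (is.null(a)) b else a
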