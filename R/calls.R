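# Typed SV calls from matched components, plus exporters.

#' Call structural variants from a discordant graph
#'
#' Matches every connected component against the prototype catalog (in
#' specificity order) and reports matched components whose minimum
#' required-edge weight reaches `mrw`. Components matching no prototype are
#' returned as residuals (counted, not typed).
#'
#' @param graph A `detsv_graph` from [build_discordant_graph()].
#' @param catalog Prototype list from [prototype_catalog()].
#' @param mrw Minimum required weight: the smallest number of read pairs
#'   supporting every required edge of the call (default 1).
#' @param sample Sample identifier carried into the calls.
#' @return `data.frame` of calls: `type`, `chrom`, `start`, `end` (the
#'   affected reference interval; for duplications/translocations the donor),
#'   `size`, `sv_seq`, `site_chrom`, `site_pos` (insertion site for
#'   duplicative/translocated events), `weight`, `zygosity`, `sample`.
#'   Attribute `residual` holds the unmatched components.
#' @export
call_svs <- function(graph, catalog = prototype_catalog(), mrw = 1L,
                     sample = "sample") {
  comps <- graph_components(graph)
  rows <- list(); residual <- list()
  base_kind <- function(nm) sub("_(intra|inter).*$", "", nm)
  for (comp in comps) {
    # a cut-and-paste translocation of [Y,Z) downstream to X is also one of
    # [Z,X) upstream to Y, so all prototypes of the most specific matching
    # kind are tried and the reading with the shortest donor is kept
    m <- NULL; type <- NULL
    for (proto in catalog) {
      cand <- match_component(comp, proto)
      if (is.null(cand)) next
      if (is.null(m)) { m <- cand; type <- proto$name; next }
      if (base_kind(proto$name) != base_kind(type)) break
      span <- function(x) {
        ds <- x[["donor_start"]]
        if (is.null(ds)) 0L else x[["donor_end"]]$pos - ds$pos
      }
      if (span(cand) < span(m)) { m <- cand; type <- proto$name }
    }
    if (is.null(m)) { residual[[length(residual) + 1L]] <- comp; next }
    w <- attr(m, "weight")
    if (w < mrw) next
    sv <- attr(m, "sv_seq")
    row <- if (type == "insertion") {
      data.frame(type = type, chrom = m$site$chrom, start = m$site$pos,
                 end = m$site$pos, size = nchar(sv), sv_seq = sv,
                 site_chrom = NA_character_, site_pos = NA_integer_,
                 stringsAsFactors = FALSE)
    } else if (type %in% c("deletion", "tandem_duplication", "inversion")) {
      s <- m$start$pos; e <- m$end$pos
      data.frame(type = type, chrom = m$start$chrom, start = s, end = e,
                 size = e - s, sv_seq = if (type == "deletion") sv else "",
                 site_chrom = NA_character_, site_pos = NA_integer_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(type = type, chrom = m$donor_start$chrom,
                 start = m$donor_start$pos, end = m$donor_end$pos,
                 size = m$donor_end$pos - m$donor_start$pos, sv_seq = "",
                 site_chrom = m$site$chrom, site_pos = m$site$pos,
                 stringsAsFactors = FALSE)
    }
    row$weight <- w
    row$zygosity <- NA_character_
    row$sample <- sample
    rows[[length(rows) + 1L]] <- row
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(), chrom = character(), start = integer(),
               end = integer(), size = integer(), sv_seq = character(),
               site_chrom = character(), site_pos = integer(),
               weight = integer(), zygosity = character(), sample = character(),
               stringsAsFactors = FALSE)
  calls <- calls[order(calls$chrom, calls$start, calls$type), , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "residual") <- residual
  calls
}

#' Filter calls by minimum required weight
#'
#' @param calls Calls from [call_svs()].
#' @param w Minimum weight.
#' @return The calls with `weight >= w`.
#' @export
filter_by_weight <- function(calls, w) {
  out <- calls[calls$weight >= w, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export calls as VCF 4.2
#'
#' Insertions and deletions are written with explicit sequences; tandem
#' duplications, inversions, insertional duplications and translocations as
#' symbolic alleles with `END`/`SVLEN` and, where applicable, the insertion
#' site in `SITECHROM`/`SITEPOS`.
#'
#' @param calls Calls from [call_svs()].
#' @param reference Reference accepted by [load_reference()] (for anchor
#'   bases).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_vcf <- function(calls, reference, path) {
  seqs <- load_reference(reference)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=detsv",
           sprintf("##contig=<ID=%s,length=%d>", names(seqs), nchar(seqs)),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of the affected interval\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##INFO=<ID=WEIGHT,Number=1,Type=Integer,Description=\"Supporting read pairs (minimum over required edges)\">",
           "##INFO=<ID=ZYG,Number=1,Type=String,Description=\"Inferred zygosity\">",
           "##INFO=<ID=SITECHROM,Number=1,Type=String,Description=\"Insertion-site chromosome\">",
           "##INFO=<ID=SITEPOS,Number=1,Type=Integer,Description=\"Insertion-site position (1-based)\">",
           "##ALT=<ID=DUP:TANDEM,Description=\"Tandem duplication\">",
           "##ALT=<ID=INV,Description=\"Inversion\">",
           "##ALT=<ID=DUP:INS,Description=\"Insertional duplication\">",
           "##ALT=<ID=TRA,Description=\"Cut-and-paste translocation\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 sep = "\t"))
  lines <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    info <- sprintf("WEIGHT=%d", cl$weight)
    if (!is.na(cl$zygosity)) info <- paste0(info, ";ZYG=", cl$zygosity)
    if (cl$type == "insertion") {
      # anchor base before the insertion point (1-based POS = start)
      anchor <- ref_base(seqs, cl$chrom, cl$start - 1L)
      fields <- c(cl$chrom, cl$start, sprintf("detsv_%d", i), anchor,
                  paste0(anchor, cl$sv_seq), ".", "PASS",
                  paste0("SVTYPE=INS;SVLEN=", cl$size, ";", info))
    } else if (cl$type == "deletion") {
      anchor <- ref_base(seqs, cl$chrom, cl$start - 1L)
      fields <- c(cl$chrom, cl$start, sprintf("detsv_%d", i),
                  paste0(anchor, cl$sv_seq), anchor, ".", "PASS",
                  paste0("SVTYPE=DEL;END=", cl$end, ";SVLEN=-", cl$size, ";", info))
    } else {
      svtype <- switch(sub("_(intra|inter).*$", "", cl$type),
                       tandem_duplication = "DUP:TANDEM",
                       inversion = "INV",
                       insertional_duplication = "DUP:INS",
                       translocation = "TRA")
      anchor <- ref_base(seqs, cl$chrom, cl$start)
      if (!is.na(cl$site_pos))
        info <- paste0(info, ";SITECHROM=", cl$site_chrom,
                       ";SITEPOS=", cl$site_pos + 1L)
      fields <- c(cl$chrom, cl$start + 1L, sprintf("detsv_%d", i), anchor,
                  paste0("<", svtype, ">"), ".", "PASS",
                  paste0("SVTYPE=", sub(":.*$", "", svtype), ";END=", cl$end,
                         ";SVLEN=", cl$size, ";", info))
    }
    lines[i] <- paste(fields, collapse = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Export calls as TSV
#'
#' @param calls Calls from [call_svs()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_calls_tsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a discordant graph as an edge-list TSV
#'
#' @param graph A `detsv_graph`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_graph_tsv <- function(graph, path) {
  e <- graph$edges
  v <- graph$vertices
  df <- data.frame(type = e$type,
                   chrom_u = v$chrom[e$ui], u = v$pos[e$ui],
                   chrom_v = v$chrom[e$vi], v = v$pos[e$vi],
                   weight = e$weight, sv_seq = e$sv_seq,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export residual (unmatched) components as JSON
#'
#' @param calls Calls from [call_svs()] (whose `residual` attribute holds the
#'   unmatched components).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_residual_json <- function(calls, path) {
  res <- attr(calls, "residual") %||% list()
  x <- lapply(res, function(comp) {
    list(vertices = comp$vertices,
         edges = data.frame(type = comp$edges$type,
                            chrom_u = comp$vertices$chrom[comp$edges$ui],
                            u = comp$vertices$pos[comp$edges$ui],
                            chrom_v = comp$vertices$chrom[comp$edges$vi],
                            v = comp$vertices$pos[comp$edges$vi],
                            weight = comp$edges$weight,
                            stringsAsFactors = FALSE))
  })
  jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}
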