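# Pipeline orchestration: reconstruct -> seed/classify -> breakpoint ->
# graph -> call -> zygosity -> report.

#' Pipeline configuration
#'
#' All tunables of the workflow with their defaults: read length `L` (150),
#' minimum perfect overlap `m_min` (13, so the maximum reconstructable
#' fragment is `2L - m_min` = 287 bp), seed length `k` (30, chosen where
#' unique alignability saturates), seed mismatches `max_mismatch` (1),
#' alignment scores (match 1, mismatch -3, gap opening 10, gap extension
#' 0.5; see [align_params()]), the minimum required weight `mrw` (1), the equivalent-placement
#' merge tolerance (0 = exact-score ties only), intersection tolerances
#' (1 bp indels / 10 bp junction types), minimum fragment identity outside
#' gaps (0.95), and the zygosity ratio thresholds.
#'
#' @param L,m_min,k,max_mismatch,match,mismatch,gap_open,gap_extend,mrw
#'   See description.
#' @param tolerance,tol_indel,tol_complex,min_identity See description.
#' @param hom_max,het_min,het_max Zygosity ratio thresholds.
#' @param seed RNG seed recorded in the configuration (the pipeline itself is
#'   deterministic; the seed is used by simulation helpers).
#' @return Validated configuration list of class `detsv_config`.
#' @export
sv_config <- function(L = 150L, m_min = 13L, k = 30L, max_mismatch = 1L,
                      match = 1, mismatch = -3, gap_open = 10, gap_extend = 0.5,
                      mrw = 1L, tolerance = 0L, tol_indel = 1L,
                      tol_complex = 10L, min_identity = 0.95,
                      hom_max = 0.1, het_min = 0.3, het_max = 0.7,
                      seed = 1L) {
  cfg <- list(L = as.integer(L), m_min = as.integer(m_min), k = as.integer(k),
              max_mismatch = as.integer(max_mismatch), match = match,
              mismatch = mismatch, gap_open = gap_open, gap_extend = gap_extend,
              mrw = as.integer(mrw), tolerance = as.integer(tolerance),
              tol_indel = as.integer(tol_indel),
              tol_complex = as.integer(tol_complex),
              min_identity = min_identity, hom_max = hom_max,
              het_min = het_min, het_max = het_max, seed = as.integer(seed))
  stopifnot(cfg$m_min >= 1, cfg$m_min <= cfg$L, cfg$k >= 8, cfg$k <= cfg$L,
            cfg$max_mismatch %in% 0:1, cfg$gap_open >= 0, cfg$gap_extend >= 0,
            cfg$mrw >= 1, cfg$min_identity > 0, cfg$min_identity <= 1)
  class(cfg) <- "detsv_config"
  cfg
}

#' Run the full SV-calling pipeline
#'
#' Stages: fragment reconstruction, seed placement, exact classification,
#' breakpoint localization, discordant-graph construction, prototype
#' matching with the minimum-required-weight filter, coverage tracks and
#' zygosity inference. Deterministic given inputs and configuration.
#'
#' @param reference Reference accepted by [load_reference()].
#' @param pairs A `detsv_pairs` table, or `NULL` if `fq1`/`fq2` given.
#' @param fq1,fq2 Paired FASTQ paths (alternative to `pairs`).
#' @param config A `detsv_config` from [sv_config()].
#' @param sample Sample name.
#' @param output_dir If non-`NULL`, writes `calls.vcf`, `calls.tsv`,
#'   `graph.tsv`, `residual.json`, and the two coverage bedGraphs there.
#' @return List with elements `fragments`, `alignments`, `classified`,
#'   `evidence`, `graph`, `calls` (zygosity-annotated), `coverage_concordant`,
#'   `coverage_discordant`, `config`.
#' @export
run_pipeline <- function(reference, pairs = NULL, fq1 = NULL, fq2 = NULL,
                         config = sv_config(), sample = "sample",
                         output_dir = NULL) {
  seqs <- load_reference(reference)
  if (is.null(pairs)) {
    if (is.null(fq1) || is.null(fq2))
      stop("provide either `pairs` or both `fq1` and `fq2`")
    pairs <- read_fastq_pairs(fq1, fq2)
  }
  frags <- reconstruct_fragments(pairs, m_min = config$m_min)
  aln <- align_seed_pairs(pairs, seqs, k = config$k,
                          max_mismatch = config$max_mismatch)
  classified <- classify_pairs(aln, frags)
  params <- align_params(config$match, config$mismatch, config$gap_open,
                         config$gap_extend)
  evidence <- fragment_breakpoints(classified, frags, seqs, params = params,
                                   min_identity = config$min_identity)
  graph <- build_discordant_graph(evidence, seqs, tolerance = config$tolerance)
  calls <- call_svs(graph, mrw = config$mrw, sample = sample)
  conc <- compute_coverage(classified, seqs, "concordant")
  disc <- compute_coverage(classified, seqs, "discordant")
  calls <- infer_zygosity(calls, conc, hom_max = config$hom_max,
                          het_min = config$het_min, het_max = config$het_max)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(calls, seqs, file.path(output_dir, "calls.vcf"))
    write_calls_tsv(calls, file.path(output_dir, "calls.tsv"))
    write_graph_tsv(graph, file.path(output_dir, "graph.tsv"))
    write_residual_json(calls, file.path(output_dir, "residual.json"))
    write_bedgraph(conc, file.path(output_dir, "concordant.bedGraph"))
    write_bedgraph(disc, file.path(output_dir, "discordant.bedGraph"))
  }
  list(fragments = frags, alignments = aln, classified = classified,
       evidence = evidence, graph = graph, calls = calls,
       coverage_concordant = conc, coverage_discordant = disc,
       config = config)
}
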