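# The full marker-development pipeline: scan -> precursors -> primer design
# -> e-PCR validation -> deduplication -> screens -> distribution statistics
# -> duplication blocks, with per-stage logging and a reproducibility
# manifest (input checksums, seed, parameters).

# Precursor-table adapters feeding design_markers().
ssr_precursor_table <- function(pre, species) {
  data.frame(
    source_id = sprintf("%s_%d_%s", pre$seq_id, pre$start, pre$motif),
    type = "SSR", species = species, seq_id = pre$seq_id,
    locus_start = pre$start, locus_end = pre$end,
    motif = pre$motif, repeat_count = pre$repeat_count,
    left_flank = pre$left_flank, right_flank = pre$right_flank,
    reject_reason = pre$reject_reason, stringsAsFactors = FALSE)
}

ilp_precursor_table <- function(pre, species) {
  data.frame(
    source_id = sprintf("%s_intron%d", pre$gene_id, pre$ordinal),
    type = "ILP", species = species, seq_id = pre$seq_id,
    locus_start = pre$start, locus_end = pre$end,
    motif = NA_character_, repeat_count = NA_integer_,
    left_flank = pre$left_flank, right_flank = pre$right_flank,
    reject_reason = pre$reject_reason, stringsAsFactors = FALSE)
}

#' Run the full marker-development pipeline on one genome
#'
#' Stages: SSR scan, precursor cutting, primer design (SSR and, when an
#' annotation is given, ILP), e-PCR validation against the source genome,
#' deduplication, polymorphism screen, distribution statistics, and
#' SSR-anchor duplication-block detection. All artifacts are written to
#' `out_dir` together with a run manifest.
#'
#' @param genome a [genome_set()] or path to a FASTA file.
#' @param genes optional `gene_models` or path to a GFF3 file.
#' @param out_dir output directory.
#' @param min_repeats per-class SSR thresholds.
#' @param constraints a [design_constraints()] object.
#' @param params an [epcr_params()] object.
#' @param seed seed for the stochastic steps (polymorphism-screen
#'   subsampling).
#' @param max_polymorphism_markers markers sampled for the polymorphism
#'   screen (default 20000).
#' @param min_block,max_gap chaining parameters (see [chain_anchors()]).
#' @param quiet suppress progress messages.
#' @return list with `markers` (validated, deduplicated), `loci`, `introns`,
#'   `hits`, `polymorphism`, `blocks`, `summary`, `manifest`.
#' @export
run_marker_pipeline <- function(genome, genes = NULL, out_dir,
                                min_repeats = default_min_repeats(),
                                constraints = design_constraints(),
                                params = epcr_params(), seed = 1L,
                                max_polymorphism_markers = 20000L,
                                min_block = 5L, max_gap = 25L,
                                quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  inputs <- list()
  if (is.character(genome)) {
    if (!file.exists(genome)) stop("pre-flight: FASTA not found: ", genome, call. = FALSE)
    inputs$fasta <- genome
    genome <- read_genome_fasta(genome)
  }
  if (is.character(genes)) {
    if (!file.exists(genes)) stop("pre-flight: GFF3 not found: ", genes, call. = FALSE)
    inputs$gff <- genes
    genes <- read_gene_models(genes, genome)
  }
  stopifnot(inherits(genome, "genome_set"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # scan
  loci <- run_stage("scan", scan_ssr(genome, min_repeats))
  say("scan: %d SSR loci (%s)", nrow(loci),
      paste(sprintf("%d-mer %d", 1:7, ssr_class_table(loci)$count), collapse = ", "))
  loci_to_bed(loci, file.path(out_dir, "ssr_loci.bed"))

  # precursors + design
  pre_ssr <- run_stage("precursors", {
    ssr_precursor_table(ssr_precursors(loci, genome), genome$species_id)
  })
  markers <- run_stage("design", design_markers(pre_ssr, constraints))
  say("design: %d SSR candidates (%d precursor/design rejections)",
      nrow(markers), nrow(pre_ssr) - nrow(markers))

  introns <- NULL
  if (!is.null(genes)) {
    introns <- run_stage("introns", extract_introns(genes))
    pre_ilp <- run_stage("ilp-precursors", {
      ilp_precursor_table(ilp_precursors(introns, genes, genome), genome$species_id)
    })
    ilp <- run_stage("ilp-design", design_markers(pre_ilp, constraints))
    say("ilp: %d introns -> %d ILP candidates", nrow(introns), nrow(ilp))
    markers <- rbind(markers, ilp)
  }

  # validate
  validated <- run_stage("epcr-validate", validate_markers(markers, genome, params))
  hits <- attr(validated, "hits")
  markers <- validated[validated$status == "validated", , drop = FALSE]
  markers$reject_reason <- NULL
  say("epcr-validate: %d/%d markers validated", nrow(markers), nrow(validated))

  # dedup
  markers <- run_stage("dedup", dedup_markers(markers))
  say("dedup: %d removed, %d markers kept", attr(markers, "n_removed"), nrow(markers))
  markers <- order_markers(markers)
  write_marker_table(markers, file.path(out_dir, "markers.tsv"))
  export_marker_tracks(markers, out_dir)

  # polymorphism screen
  poly <- run_stage("polymorphism", {
    idx <- seq_len(nrow(markers))
    if (length(idx) > max_polymorphism_markers) {
      idx <- with_seed(seed, sort(sample(idx, max_polymorphism_markers)))
    }
    classify_polymorphism(markers[idx, , drop = FALSE], genome, params)
  })
  say("polymorphism: %d monomorphic, %d polymorphic",
      sum(poly$label == "monomorphic"), sum(poly$label == "polymorphic"))
  write.table(poly, file.path(out_dir, "polymorphism.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # distribution statistics
  conc_rate <- NA_real_
  if (!is.null(genes) && any(markers$type == "ILP")) {
    amp <- amplicon_intervals(markers)
    conc <- concomitance(amp[markers$type == "SSR", , drop = FALSE],
                         amp[markers$type == "ILP", , drop = FALSE])
    conc_rate <- conc$rate
    say("concomitance: %.2f%% of SSR markers intersect an ILP amplicon",
        100 * conc_rate)
  }
  summary_df <- marker_summary(markers, genome, conc_rate)
  write.table(summary_df, file.path(out_dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # duplication blocks from multi-site markers
  hits_poly <- attr(poly, "hits")
  anchors <- run_stage("dupes", ssr_anchors(hits_poly[hits_poly$marker_id %in%
                                                        markers$marker_id, , drop = FALSE]))
  blocks <- run_stage("dupes", chain_anchors(anchors[!anchors$tandem, , drop = FALSE],
                                             min_block = min_block, max_gap = max_gap))
  say("dupes: %d anchors (%d tandem), %d blocks",
      nrow(anchors), sum(anchors$tandem), nrow(blocks))
  write_block_table(blocks, file.path(out_dir, "blocks.tsv"))

  manifest <- list(
    package = "treemarker",
    version = as.character(utils::packageVersion("treemarker")),
    seed = seed,
    inputs = lapply(inputs, function(p) list(path = p,
                                             md5 = unname(tools::md5sum(p)))),
    species = genome$species_id,
    genome_size = genome_size(genome),
    min_repeats = min_repeats,
    epcr = unclass(params),
    design = unclass(constraints),
    counts = list(loci = nrow(loci), markers = nrow(markers),
                  introns = if (is.null(introns)) 0L else nrow(introns),
                  blocks = nrow(blocks)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(markers = markers, loci = loci, introns = introns,
                 hits = hits, polymorphism = poly, blocks = blocks,
                 summary = summary_df, manifest = manifest))
}
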