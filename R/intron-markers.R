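# Intron-based markers. ILP markers come from annotated genomes: introns are
# the gaps between consecutive exons, and primer precursors are cut from the
# exonic side of each intron boundary so the product length tracks the intron
# length. PIP markers come from ESTs: an EST is aligned to a model-species
# CDS, annotated intron positions of the model gene are projected through the
# alignment onto the EST, and precursors are cut around the projected points.

#' Extract introns from gene models
#'
#' Introns are the gaps between consecutive exons. Ordinals are assigned in
#' transcription order (5' to 3' of the transcript), so on the minus strand
#' intron 1 is the genomically last gap. Single-exon genes contribute
#' nothing; no length filtering is applied.
#'
#' @param genes a `gene_models` object from [read_gene_models()].
#' @return data frame with `gene_id`, `seq_id`, `strand`, `start`, `end`
#'   (0-based half-open), `ordinal`, `length`.
#' @export
extract_introns <- function(genes) {
  rows <- list()
  for (gm in genes) {
    ex <- gm$exons
    if (nrow(ex) > 1L) {
      if (any(ex[-1L, "start"] < ex[-nrow(ex), "end"])) {
        stop(sprintf("gene '%s' has overlapping exons", gm$gene_id), call. = FALSE)
      }
      st <- ex[-nrow(ex), "end"]
      en <- ex[-1L, "start"]
      ord <- if (gm$strand == "-") rev(seq_along(st)) else seq_along(st)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gm$gene_id, seq_id = gm$seq_id, strand = gm$strand,
        start = as.integer(st), end = as.integer(en),
        ordinal = as.integer(ord), length = as.integer(en - st),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(0), seq_id = character(0),
                      strand = character(0), start = integer(0), end = integer(0),
                      ordinal = integer(0), length = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cut exonic precursor flanks around introns
#'
#' For each intron the `flank_len` bases immediately left and right of the
#' intron are taken. Both flanks must be entirely exonic (inside an exon of
#' the same gene), untruncated and N-free; otherwise the intron is rejected
#' with a reason.
#'
#' @param introns data frame from [extract_introns()].
#' @param genes the `gene_models` the introns came from.
#' @param genome the [genome_set()].
#' @param flank_len flank length in bases (default 60).
#' @return the intron table with `left_flank`, `right_flank` and
#'   `reject_reason` columns added.
#' @export
ilp_precursors <- function(introns, genes, genome, flank_len = 60L) {
  n <- nrow(introns)
  left <- right <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  inside_exon <- function(ex, s, e) any(ex[, "start"] <= s & e <= ex[, "end"])
  for (i in seq_len(n)) {
    gm <- genes[[introns$gene_id[i]]]
    s <- genome$seq[[introns$seq_id[i]]]
    st <- introns$start[i]; en <- introns$end[i]
    ls <- st - flank_len; re <- en + flank_len
    if (ls < 0L || re > nchar(s)) { reason[i] <- "flank truncated"; next }
    if (!inside_exon(gm$exons, ls, st) || !inside_exon(gm$exons, en, re)) {
      reason[i] <- "flank not fully exonic"; next
    }
    lf <- substr(s, ls + 1L, st)
    rf <- substr(s, en + 1L, re)
    if (grepl("N", lf, fixed = TRUE) || grepl("N", rf, fixed = TRUE)) {
      reason[i] <- "ambiguous flank"; next
    }
    left[i] <- lf; right[i] <- rf
  }
  cbind(introns, data.frame(left_flank = left, right_flank = right,
                            reject_reason = reason, stringsAsFactors = FALSE))
}

#' Intron positions in spliced-CDS coordinates of a model gene
#'
#' Returns the cumulative exon lengths, walking the transcript 5' to 3', at
#' which introns interrupt the spliced sequence: position `p` means the
#' intron falls immediately after the `p`-th spliced base.
#'
#' @param gene one gene model (an element of a `gene_models` object).
#' @return integer vector of positions (empty for single-exon genes).
#' @export
cds_intron_positions <- function(gene) {
  ex <- gene$exons
  if (nrow(ex) <= 1L) return(integer(0))
  lens <- ex[, "end"] - ex[, "start"]
  if (gene$strand == "-") lens <- rev(lens)
  as.integer(cumsum(lens)[-length(lens)])
}

#' Spliced transcript sequence of a gene model
#'
#' Concatenates exon sequences in transcription order (reverse complemented
#' for minus-strand genes).
#'
#' @param gene one gene model.
#' @param genome the [genome_set()].
#' @return DNA string.
#' @export
spliced_sequence <- function(gene, genome) {
  s <- genome$seq[[gene$seq_id]]
  pieces <- substring(s, gene$exons[, "start"] + 1L, gene$exons[, "end"])
  spliced <- paste0(pieces, collapse = "")
  if (gene$strand == "-") rev_comp(spliced) else spliced
}

#' Align an EST to a model-species CDS
#'
#' Best local (Smith-Waterman) alignment with match +1, mismatch -2, gap
#' open 5, gap extension 1, tried on both strands of the EST; the better
#' strand is kept. The alignment is returned only if its identity over
#' aligned columns reaches `min_identity` across at least `min_length`
#' columns.
#'
#' @param est,cds DNA strings.
#' @param min_identity minimum identity fraction over aligned columns
#'   (default 0.85).
#' @param min_length minimum number of aligned columns (default 100).
#' @return `NULL` on failure, else a list with `est_start`, `est_end`,
#'   `cds_start`, `cds_end` (1-based inclusive, on the original EST
#'   orientation), `strand`, `identity`, `n_columns`, and the aligned
#'   strings `est_aln`, `cds_aln` (in the aligned orientation).
#' @export
align_est_to_cds <- function(est, cds, min_identity = 0.85, min_length = 100L) {
  stopifnot(nchar(est) > 0L, nchar(cds) > 0L)
  mat <- matrix(-2, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                          c("A", "C", "G", "T", "N")))
  diag(mat) <- 1
  mat["N", ] <- -2; mat[, "N"] <- -2
  try_one <- function(est_seq, strand) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(est_seq), Biostrings::DNAString(cds),
      type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 1)
    list(aln = aln, strand = strand, score = Biostrings::score(aln))
  }
  cand <- list(try_one(est, "+"), try_one(rev_comp(est), "-"))
  best <- cand[[which.max(vapply(cand, `[[`, 0, "score"))]]
  aln <- best$aln
  est_al <- as.character(Biostrings::alignedPattern(aln))
  cds_al <- as.character(Biostrings::alignedSubject(aln))
  ncol_aln <- nchar(est_al)
  ident <- Biostrings::nmatch(aln) / ncol_aln
  if (ncol_aln < min_length || ident < min_identity) return(NULL)
  p <- Biostrings::pattern(aln); s <- Biostrings::subject(aln)
  es <- BiocGenerics::start(p); ee <- BiocGenerics::end(p)
  if (best$strand == "-") {
    n <- nchar(est)
    tmp <- es
    es <- n - ee + 1L
    ee <- n - tmp + 1L
  }
  list(est_start = es, est_end = ee,
       cds_start = BiocGenerics::start(s), cds_end = BiocGenerics::end(s),
       strand = best$strand, identity = ident, n_columns = ncol_aln,
       est_aln = est_al, cds_aln = cds_al)
}

#' Project model intron positions onto an EST through an alignment
#'
#' For every spliced-CDS intron position falling strictly inside the aligned
#' CDS region, the corresponding EST coordinate (number of EST bases 5' of
#' the projected junction, on the original EST orientation) is returned.
#'
#' @param aln result of [align_est_to_cds()].
#' @param cds_positions integer vector from [cds_intron_positions()].
#' @param est_length length of the original EST in bases.
#' @return data frame with `cds_position` and `est_position` (strictly
#'   increasing in `cds_position`).
#' @export
project_intron_positions <- function(aln, cds_positions, est_length) {
  out <- data.frame(cds_position = integer(0), est_position = integer(0))
  if (is.null(aln) || length(cds_positions) == 0L) return(out)
  ec <- strsplit(aln$est_aln, "", fixed = TRUE)[[1]]
  cc <- strsplit(aln$cds_aln, "", fixed = TRUE)[[1]]
  # aligned-orientation EST start of the aligned region
  est_start_aln <- if (aln$strand == "+") aln$est_start
                   else est_length - aln$est_end + 1L
  cds_pos <- aln$cds_start - 1L
  est_pos <- est_start_aln - 1L
  proj <- integer(0); proj_cds <- integer(0)
  targets <- sort(cds_positions[cds_positions > aln$cds_start - 1L &
                                  cds_positions < aln$cds_end])
  if (length(targets) == 0L) return(out)
  ti <- 1L
  for (i in seq_along(cc)) {
    if (cc[i] != "-") cds_pos <- cds_pos + 1L
    if (ec[i] != "-") est_pos <- est_pos + 1L
    while (ti <= length(targets) && cc[i] != "-" && cds_pos == targets[ti]) {
      proj <- c(proj, est_pos)
      proj_cds <- c(proj_cds, targets[ti])
      ti <- ti + 1L
    }
    if (ti > length(targets)) break
  }
  if (aln$strand == "-") proj <- est_length - proj
  ord <- order(proj_cds)
  data.frame(cds_position = proj_cds[ord], est_position = as.integer(proj[ord]))
}

#' Cut PIP precursor flanks from an EST
#'
#' For every projected intron position with at least `flank_len` EST bases on
#' each side, a pair of precursor flanks is cut from the EST around the
#' position.
#'
#' @param projection data frame from [project_intron_positions()].
#' @param est DNA string of the EST.
#' @param est_id,model_gene_id provenance identifiers.
#' @param flank_len flank length in bases (default 60).
#' @return precursor data frame in the layout accepted by [design_markers()]
#'   (`type = "PIP"`, locus interval = the zero-length junction point).
#' @export
pip_precursors <- function(projection, est, est_id, model_gene_id,
                           flank_len = 60L) {
  rows <- list()
  n <- nchar(est)
  for (i in seq_len(nrow(projection))) {
    pos <- projection$est_position[i]
    reason <- NA_character_
    lf <- rf <- NA_character_
    if (pos - flank_len < 0L || pos + flank_len > n) {
      reason <- "flank truncated"
    } else {
      lf <- substr(est, pos - flank_len + 1L, pos)
      rf <- substr(est, pos + 1L, pos + flank_len)
      if (grepl("N", lf, fixed = TRUE) || grepl("N", rf, fixed = TRUE)) {
        reason <- "ambiguous flank"; lf <- rf <- NA_character_
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      source_id = sprintf("%s_junc%d", est_id, projection$cds_position[i]),
      type = "PIP", species = model_gene_id, seq_id = est_id,
      locus_start = pos, locus_end = pos, motif = NA_character_,
      repeat_count = NA_integer_, left_flank = lf, right_flank = rf,
      reject_reason = reason, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(source_id = character(0), type = character(0),
                      species = character(0), seq_id = character(0),
                      locus_start = integer(0), locus_end = integer(0),
                      motif = character(0), repeat_count = integer(0),
                      left_flank = character(0), right_flank = character(0),
                      reject_reason = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Develop PIP markers from ESTs and a model-species annotation
#'
#' For every EST, the best-matching model CDS is found by aligning the EST to
#' each CDS and keeping the highest-scoring acceptable alignment; annotated
#' intron positions of that model gene are projected onto the EST and primer
#' pairs designed around each projected junction.
#'
#' @param ests [genome_set()] holding EST sequences.
#' @param model_genes `gene_models` of the model species.
#' @param model_genome [genome_set()] of the model species (for splicing the
#'   CDS of each model gene).
#' @param min_identity,min_length alignment acceptance thresholds (see
#'   [align_est_to_cds()]).
#' @param constraints a [design_constraints()] object.
#' @param flank_len precursor flank length (default 60).
#' @return marker data frame of PIP candidates (see [design_markers()]).
#' @export
pip_markers <- function(ests, model_genes, model_genome,
                        min_identity = 0.85, min_length = 100L,
                        constraints = design_constraints(), flank_len = 60L) {
  cds_seqs <- lapply(model_genes, spliced_sequence, genome = model_genome)
  pre <- list()
  for (est_id in names(ests$seq)) {
    est <- ests$seq[[est_id]]
    best <- NULL; best_gene <- NULL
    for (gid in names(model_genes)) {
      a <- align_est_to_cds(est, cds_seqs[[gid]], min_identity, min_length)
      if (!is.null(a) && (is.null(best) || a$identity * a$n_columns >
                            best$identity * best$n_columns)) {
        best <- a; best_gene <- gid
      }
    }
    if (is.null(best)) next
    pos <- cds_intron_positions(model_genes[[best_gene]])
    proj <- project_intron_positions(best, pos, nchar(est))
    if (nrow(proj) == 0L) next
    pre[[length(pre) + 1L]] <- pip_precursors(proj, est, est_id, best_gene,
                                              flank_len)
  }
  if (length(pre) == 0L) return(design_markers(
    pip_precursors(data.frame(cds_position = integer(0), est_position = integer(0)),
                   "", "none", "none")))
  design_markers(do.call(rbind, pre), constraints)
}
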