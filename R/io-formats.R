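# Readers and writers for all external formats, and the single place where
# coordinate conventions are fixed: everything is 0-based half-open inside the
# package; GFF3 and the marker TSV are 1-based inclusive on disk; BED stays
# 0-based half-open.

#' Construct a genome set
#'
#' A genome set holds the uppercased sequences of one assembly, keyed by
#' sequence id, together with a species identifier.
#'
#' @param species_id single character species/assembly label.
#' @param seqs named character vector of uppercase DNA sequences.
#' @return object of class `genome_set` with elements `species_id` and `seq`.
#' @export
genome_set <- function(species_id, seqs) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("every sequence needs a name (seq_id)", call. = FALSE)
  }
  if (anyDuplicated(names(seqs))) {
    dup <- names(seqs)[duplicated(names(seqs))][1]
    stop(sprintf("duplicate seq_id '%s' in genome '%s'", dup, species_id), call. = FALSE)
  }
  seqs <- toupper(seqs)
  assert_dna(seqs, "genome sequence")
  structure(list(species_id = species_id, seq = seqs), class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf("<genome_set> %s: %d sequence(s), %s bp total\n",
              x$species_id, length(x$seq),
              format(genome_size(x), big.mark = ",")))
  invisible(x)
}

#' Total genome size in bases
#' @param genome a `genome_set`.
#' @return total number of bases.
#' @export
genome_size <- function(genome) sum(nchar(genome$seq))

#' Read a genome FASTA file
#'
#' Sequences are uppercased; any character outside \{A,C,G,T,N\} is replaced
#' by `N` with a warning. Record order is preserved.
#'
#' @param path FASTA file (plain or gzipped).
#' @param species_id species label; defaults to the file name without extension.
#' @return a [genome_set()].
#' @export
read_genome_fasta <- function(path, species_id = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (is.null(species_id)) {
    species_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  }
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))  # first token of header
  if (anyDuplicated(names(seqs))) {
    dup <- names(seqs)[duplicated(names(seqs))][1]
    stop(sprintf("duplicate seq_id '%s' in %s", dup, path), call. = FALSE)
  }
  n_bad <- sum(nchar(gsub("[ACGTN]", "", seqs)))
  if (n_bad > 0L) {
    warning(sprintf("%d non-ACGTN character(s) replaced by N in %s", n_bad, path),
            call. = FALSE)
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1))
  }
  genome_set(species_id, seqs)
}

#' Write a genome set as FASTA
#' @param genome a `genome_set`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene models (GFF3)

#' Read gene models from GFF3
#'
#' Coordinates are converted from the 1-based inclusive GFF3 convention to
#' 0-based half-open. For genes with several transcripts, the representative
#' is the transcript with the longest summed exon length (ties broken by the
#' lexicographically smallest transcript id). Genes without exon features are
#' skipped with a warning; an exon outside its sequence is an error.
#'
#' @param path GFF3 file with gene/mRNA/exon features.
#' @param genome optional `genome_set` used for bounds checking.
#' @return object of class `gene_models`: a list of gene models, each with
#'   `gene_id`, `transcript_id`, `seq_id`, `strand` and an `exons` matrix
#'   (columns `start`, `end`; 0-based half-open, sorted, non-overlapping).
#' @export
read_gene_models <- function(path, genome = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  g <- as.data.frame(rtracklayer::readGFF(path))
  need <- c("seqid", "type", "start", "end", "strand")
  if (!all(need %in% names(g))) stop("not a parseable GFF3 file: ", path, call. = FALSE)
  first_chr <- function(x) {
    vapply(x, function(v) {
      v <- as.character(unlist(v))
      if (length(v) == 0L) NA_character_ else v[1]
    }, character(1))
  }
  ids <- if ("ID" %in% names(g)) as.character(g$ID) else rep(NA_character_, nrow(g))
  parents <- if ("Parent" %in% names(g)) first_chr(g$Parent) else rep(NA_character_, nrow(g))

  genes <- g[g$type == "gene", , drop = FALSE]
  gene_ids <- ids[g$type == "gene"]
  mrna <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  mrna_ids <- ids[g$type %in% c("mRNA", "transcript")]
  mrna_parent <- parents[g$type %in% c("mRNA", "transcript")]
  ex <- g[g$type == "exon", , drop = FALSE]
  ex_parent <- parents[g$type == "exon"]

  out <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- gene_ids[i]
    tr_ids <- mrna_ids[!is.na(mrna_parent) & mrna_parent == gid]
    cand <- list()
    if (length(tr_ids) > 0L) {
      for (tid in tr_ids) {
        exi <- ex[!is.na(ex_parent) & ex_parent == tid, , drop = FALSE]
        if (nrow(exi) > 0L) cand[[tid]] <- exi
      }
    }
    # exons attached directly to the gene
    exg <- ex[!is.na(ex_parent) & ex_parent == gid, , drop = FALSE]
    if (nrow(exg) > 0L) cand[[gid]] <- exg
    if (length(cand) == 0L) {
      warning(sprintf("gene '%s' has no exon features; skipped", gid), call. = FALSE)
      next
    }
    lens <- vapply(cand, function(e) sum(e$end - e$start + 1L), numeric(1))
    best <- names(cand)[order(-lens, names(cand))][1]
    exi <- cand[[best]]
    exi <- exi[order(exi$start), , drop = FALSE]
    exons <- cbind(start = as.integer(exi$start) - 1L, end = as.integer(exi$end))
    if (any(exons[, "start"] < 0L) ||
        (nrow(exons) > 1L && any(exons[-1L, "start"] < exons[-nrow(exons), "end"]))) {
      stop(sprintf("gene '%s': overlapping or invalid exons", gid), call. = FALSE)
    }
    seq_id <- as.character(exi$seqid[1])
    if (!is.null(genome)) {
      if (!seq_id %in% names(genome$seq)) {
        stop(sprintf("gene '%s': unknown sequence '%s'", gid, seq_id), call. = FALSE)
      }
      if (max(exons[, "end"]) > nchar(genome$seq[[seq_id]])) {
        stop(sprintf("gene '%s': exon beyond end of '%s'", gid, seq_id), call. = FALSE)
      }
    }
    out[[gid]] <- list(gene_id = gid, transcript_id = best, seq_id = seq_id,
                       strand = as.character(exi$strand[1]), exons = exons)
  }
  structure(out, class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d gene(s)\n", length(x)))
  invisible(x)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and exon rows with 1-based inclusive coordinates.
#'
#' @param genes a `gene_models` object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (gm in genes) {
    gs <- min(gm$exons[, "start"]) + 1L
    ge <- max(gm$exons[, "end"])
    lines <- c(lines,
      sprintf("%s\ttreemarker\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              gm$seq_id, gs, ge, gm$strand, gm$gene_id),
      sprintf("%s\ttreemarker\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              gm$seq_id, gs, ge, gm$strand, gm$transcript_id, gm$gene_id),
      sprintf("%s\ttreemarker\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              gm$seq_id, gm$exons[, "start"] + 1L, gm$exons[, "end"],
              gm$strand, gm$transcript_id))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Marker tables

marker_table_cols <- c("marker_id", "type", "species", "seq_id",
                       "locus_start_1based", "locus_end_1based", "motif",
                       "repeat_count", "forward_primer", "reverse_primer",
                       "expected_product_bp", "status")

# Deterministic row order shared by writer and internal pipelines.
order_markers <- function(m) {
  m[order(m$species, m$seq_id, m$locus_start, m$marker_id), , drop = FALSE]
}

#' Write a marker table as TSV
#'
#' Fixed 12-column header (`marker_id`, `type`, `species`, `seq_id`,
#' `locus_start_1based`, `locus_end_1based`, `motif`, `repeat_count`,
#' `forward_primer`, `reverse_primer`, `expected_product_bp`, `status`), rows
#' deterministically sorted by (species, seq_id, start). Internal 0-based
#' half-open locus coordinates are converted to 1-based inclusive on output.
#'
#' @param markers marker data frame (internal representation with 0-based
#'   `locus_start`/`locus_end`).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_marker_table <- function(markers, path) {
  m <- order_markers(markers)
  out <- data.frame(
    marker_id = m$marker_id, type = m$type, species = m$species,
    seq_id = m$seq_id,
    locus_start_1based = m$locus_start + 1L,
    locus_end_1based = m$locus_end,
    motif = m$motif, repeat_count = m$repeat_count,
    forward_primer = m$forward_primer, reverse_primer = m$reverse_primer,
    expected_product_bp = m$expected_product_bp, status = m$status,
    stringsAsFactors = FALSE)
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write marker table: ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a marker table written by [write_marker_table()]
#' @param path TSV path.
#' @return marker data frame in the internal representation (0-based
#'   half-open `locus_start`/`locus_end`).
#' @export
read_marker_table <- function(path) {
  m <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                  colClasses = c(repeat_count = "integer"))
  if (!identical(names(m), marker_table_cols)) {
    stop("not a marker table (unexpected columns): ", path, call. = FALSE)
  }
  data.frame(
    marker_id = as.character(m$marker_id), type = as.character(m$type),
    species = as.character(m$species), seq_id = as.character(m$seq_id),
    locus_start = m$locus_start_1based - 1L, locus_end = m$locus_end_1based,
    motif = as.character(m$motif), repeat_count = m$repeat_count,
    forward_primer = as.character(m$forward_primer),
    reverse_primer = as.character(m$reverse_primer),
    expected_product_bp = as.integer(m$expected_product_bp),
    status = as.character(m$status), stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# BLAST tabular and BED

#' Read 12-column BLAST tabular output
#'
#' Self-identical rows (query == subject with identical coordinates) are
#' dropped; a row with the wrong column count is an error naming the line.
#'
#' @param path BLAST `-outfmt 6` file.
#' @return data frame with the 12 standard columns (`query`, `subject`,
#'   `identity`, `length`, `mismatches`, `gap_opens`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore`).
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cols <- c("query", "subject", "identity", "length", "mismatches", "gap_opens",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (length(lines) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), 12), cols))
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1]
    stop(sprintf("line %d of %s has %d columns (expected 12)", bad, path, nf[bad]),
         call. = FALSE)
  }
  m <- do.call(rbind, parts)
  out <- data.frame(query = m[, 1], subject = m[, 2],
                    identity = as.numeric(m[, 3]), length = as.integer(m[, 4]),
                    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
                    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
                    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
                    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
                    stringsAsFactors = FALSE)
  self <- out$query == out$subject & out$qstart == out$sstart & out$qend == out$send
  out[!self, , drop = FALSE]
}

#' Write intervals as BED6
#'
#' @param df data frame with `seq_id`, `start`, `end` (0-based half-open),
#'   `name`, and optionally `score` and `strand`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(
    chrom = df$seq_id, start = df$start, end = df$end,
    name = if ("name" %in% names(df)) df$name else ".",
    score = if ("score" %in% names(df)) df$score else 0L,
    strand = if ("strand" %in% names(df)) df$strand else ".",
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#' @param path BED path.
#' @return data frame with `seq_id`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(seq_id = character(0), start = integer(0), end = integer(0),
                      name = character(0), score = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  b <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  setNames(b[, 1:6], c("seq_id", "start", "end", "name", "score", "strand"))
}
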