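# Deterministic synthetic fixtures: genomes with planted SSR loci, gene
# models with known introns, spliced ESTs, and duplicated segments, plus the
# recorded ground truth every test consumes. The background is rejection
# sampled so that it contains no reportable SSR at all: any background window
# forming a locus above threshold is redrawn until the scan of the background
# is empty, which makes specificity assertions exact.

default_fixture_motifs <- function() {
  list(`1` = c("A", "C"),
       `2` = c("AC", "AG", "AT"),
       `3` = c("AAT", "AAG", "AGG"),
       `4` = c("AAAT", "AACG", "AGAT"),
       `5` = c("AAAAT", "AACGT"),
       `6` = c("AAAAAT", "AACGTG"),
       `7` = c("AAAAAAT", "AACGATG"))
}

#' Specification of a synthetic fixture
#'
#' The defaults describe the standard test genome: 2 Mb over two scaffolds,
#' 200 planted SSR loci (20 designated to each of the 3 duplicated segments),
#' 50 genes carrying 149 introns in total, and 3 segmental duplications of
#' 60 kb copied with 2 percent per-base substitution.
#'
#' @param seed single integer driving all randomness.
#' @param scaffold_lengths named integer vector of scaffold lengths.
#' @param n_ssr_per_class planted loci per motif class 1-7.
#' @param motifs list (classes 1-7) of canonical motifs to draw from.
#' @param repeat_extra repeat counts are drawn from threshold..threshold+this.
#' @param n_genes number of genes.
#' @param introns_per_gene integer vector (length `n_genes`) of intron counts.
#' @param exon_length_range,intron_length_range length ranges in bases.
#' @param n_duplications number of duplicated segments.
#' @param segment_length duplicated segment length in bases.
#' @param mutation_rate per-base substitution rate applied to each copy.
#' @param ssr_per_duplication planted SSR loci inside each source segment
#'   (taken from the per-class totals).
#' @param est_mutation_rate per-base substitution rate of the emitted ESTs.
#' @param base_freq background base frequencies (A, C, G, T).
#' @param min_repeats per-class thresholds (see [default_min_repeats()]).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 42L,
                         scaffold_lengths = c(ctg1 = 1200000L, ctg2 = 800000L),
                         n_ssr_per_class = c(20L, 40L, 30L, 30L, 20L, 40L, 20L),
                         motifs = default_fixture_motifs(),
                         repeat_extra = 3L,
                         n_genes = 50L,
                         introns_per_gene = c(rep(3L, 49L), 2L),
                         exon_length_range = c(130L, 250L),
                         intron_length_range = c(80L, 400L),
                         n_duplications = 3L,
                         segment_length = 60000L,
                         mutation_rate = 0.02,
                         ssr_per_duplication = 20L,
                         est_mutation_rate = 0.02,
                         base_freq = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                         min_repeats = default_min_repeats()) {
  stopifnot(length(introns_per_gene) == n_genes,
            length(n_ssr_per_class) == 7L,
            n_duplications * ssr_per_duplication <= sum(n_ssr_per_class))
  spec <- structure(as.list(environment()), class = "fixture_spec")
  planted <- sum(n_ssr_per_class) * 30 +
    n_genes * (max(exon_length_range) * (max(introns_per_gene) + 1) +
                 max(intron_length_range) * max(introns_per_gene)) +
    2 * n_duplications * segment_length
  if (planted >= sum(scaffold_lengths) / 2) {
    stop("infeasible fixture spec: planted features exceed half the genome",
         call. = FALSE)
  }
  spec
}

sample_bases <- function(n, freq) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freq)
}

# Interval allocator over a set of scaffolds. `occupied` is a per-scaffold
# list of matrices [start, end); allocation leaves `margin` bases around
# every reserved interval.
make_allocator <- function(lengths, margin = 200L) {
  occ <- lapply(lengths, function(...) matrix(integer(0), ncol = 2))
  env <- environment()
  list(
    alloc = function(len, scaffold = NULL, within = NULL, avoid_near = NULL,
                     near_dist = 0L) {
      for (try in 1:2000) {
        sid <- if (!is.null(scaffold)) scaffold
               else sample(names(lengths), 1L, prob = as.numeric(lengths))
        lo <- margin; hi <- lengths[[sid]] - len - margin
        if (!is.null(within)) { sid <- within$seq_id; lo <- within$start + margin
          hi <- within$end - len - margin }
        if (hi <= lo) next
        st <- lo + sample.int(hi - lo, 1L)
        en <- st + len
        o <- env$occ[[sid]]
        if (nrow(o) > 0L && any(ivl_overlaps(st - margin, en + margin, o[, 1], o[, 2]))) next
        if (!is.null(avoid_near) && sid == avoid_near$seq_id &&
            ivl_overlaps(st - near_dist, en + near_dist,
                         avoid_near$start, avoid_near$end)) next
        env$occ[[sid]] <- rbind(o, c(st, en))
        return(list(seq_id = sid, start = st, end = en))
      }
      stop("fixture allocator failed: genome too crowded", call. = FALSE)
    })
}

#' Generate a synthetic fixture genome with recorded ground truth
#'
#' @param spec a [fixture_spec()].
#' @return list of class `fixture` with elements `genome` ([genome_set()]),
#'   `genes` (`gene_models`), `ests` ([genome_set()] of EST sequences),
#'   `truth` (list: `ssr` data frame of planted loci with `in_duplication`,
#'   `introns` data frame, `segments` data frame of duplication coordinate
#'   pairs, `est` data frame of true junction positions), and `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    lens <- as.list(spec$scaffold_lengths)
    chars <- lapply(lens, function(L) sample_bases(L, spec$base_freq))

    as_genome <- function() {
      genome_set("fixture", vapply(chars, paste0, "", collapse = ""))
    }
    redraw <- function(sid, start, end, protect = NULL) {
      # redraw bases in [start, end) that are not inside a protected interval
      pos <- seq(start + 1L, end)            # 1-based char indices
      if (!is.null(protect) && nrow(protect) > 0L) {
        p <- protect[protect$seq_id == sid, , drop = FALSE]
        if (nrow(p) > 0L) {
          keep <- !vapply(pos, function(x) any(p$start < x & x <= p$end), logical(1))
          pos <- pos[keep]
        }
      }
      if (length(pos) > 0L) {
        chars[[sid]][pos] <<- sample_bases(length(pos), spec$base_freq)
      }
      length(pos)
    }

    # 1. SSR-free background by rejection sampling
    for (iter in 1:100) {
      found <- scan_ssr(as_genome(), spec$min_repeats)
      if (nrow(found) == 0L) break
      if (iter == 100L) stop("background rejection sampling did not converge")
      for (i in seq_len(nrow(found))) redraw(found$seq_id[i], found$start[i], found$end[i])
    }

    alloc <- make_allocator(lens)

    # 2. reserve duplication source and target segments
    segments <- NULL
    if (spec$n_duplications > 0L) {
      seg_rows <- list()
      for (i in seq_len(spec$n_duplications)) {
        src <- alloc$alloc(spec$segment_length)
        tgt <- alloc$alloc(spec$segment_length, avoid_near = src, near_dist = 20000L)
        seg_rows[[i]] <- data.frame(
          segment_id = paste0("seg", i),
          src_seq = src$seq_id, src_start = src$start, src_end = src$end,
          tgt_seq = tgt$seq_id, tgt_start = tgt$start, tgt_end = tgt$end,
          orientation = "same", stringsAsFactors = FALSE)
      }
      segments <- do.call(rbind, seg_rows)
    } else {
      segments <- data.frame(segment_id = character(0), src_seq = character(0),
                             src_start = integer(0), src_end = integer(0),
                             tgt_seq = character(0), tgt_start = integer(0),
                             tgt_end = integer(0), orientation = character(0),
                             stringsAsFactors = FALSE)
    }

    # 3. plan SSR loci: per-class counts, the first ssr_per_duplication of the
    # schedule cycling through the segments, the rest anywhere free.
    # In-segment loci use a per-segment allocator (the segment itself is
    # already reserved in the global one), offset 150 bp from segment edges
    # so the primer flanks stay inside the copied region.
    seg_allocs <- lapply(seq_len(nrow(segments)), function(i) {
      make_allocator(setNames(list(spec$segment_length - 300L),
                              segments$segment_id[i]), margin = 100L)
    })
    classes <- rep(1:7, times = spec$n_ssr_per_class)
    classes <- sample(classes)               # shuffle planting order
    n_in_seg <- spec$n_duplications * spec$ssr_per_duplication
    ssr_rows <- list()
    for (i in seq_along(classes)) {
      k <- classes[i]
      motif <- sample(spec$motifs[[as.character(k)]], 1L)
      rc <- spec$min_repeats[k] + sample.int(spec$repeat_extra + 1L, 1L) - 1L
      len <- rc * k
      if (i <= n_in_seg) {
        idx <- ((i - 1L) %% spec$n_duplications) + 1L
        seg <- segments[idx, ]
        w <- seg_allocs[[idx]]$alloc(len, scaffold = seg$segment_id)
        off <- seg$src_start + 150L
        where <- list(seq_id = seg$src_seq, start = off + w$start,
                      end = off + w$end)
        in_dup <- seg$segment_id
      } else {
        where <- alloc$alloc(len)
        in_dup <- NA_character_
      }
      ssr_rows[[i]] <- data.frame(
        seq_id = where$seq_id, start = where$start, end = where$end,
        class_k = k, motif = canonical_motif(motif), motif_as_found = motif,
        repeat_count = rc, in_duplication = in_dup, stringsAsFactors = FALSE)
    }
    ssr <- if (length(ssr_rows) > 0L) do.call(rbind, ssr_rows) else
      data.frame(seq_id = character(0), start = integer(0), end = integer(0),
                 class_k = integer(0), motif = character(0),
                 motif_as_found = character(0), repeat_count = integer(0),
                 in_duplication = character(0), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(ssr))) {
      run <- strsplit(strrep(ssr$motif_as_found[i], ssr$repeat_count[i]), "")[[1]]
      chars[[ssr$seq_id[i]]][(ssr$start[i] + 1L):ssr$end[i]] <- run
    }

    # 4. plan genes (outside segments, which are already reserved)
    gene_list <- list()
    intron_rows <- list()
    for (g in seq_len(spec$n_genes)) {
      n_int <- spec$introns_per_gene[g]
      n_ex <- n_int + 1L
      ex_lens <- sample(seq(spec$exon_length_range[1], spec$exon_length_range[2]),
                        n_ex, replace = TRUE)
      in_lens <- if (n_int > 0L) {
        sample(seq(spec$intron_length_range[1], spec$intron_length_range[2]),
               n_int, replace = TRUE)
      } else integer(0)
      glen <- sum(ex_lens) + sum(in_lens)
      where <- alloc$alloc(glen)
      strand <- sample(c("+", "-"), 1L)
      starts <- where$start + cumsum(c(0L, head(ex_lens, -1L) + in_lens))
      exons <- cbind(start = as.integer(starts), end = as.integer(starts + ex_lens))
      gid <- sprintf("gene%02d", g)
      gene_list[[gid]] <- list(gene_id = gid, transcript_id = paste0(gid, ".t1"),
                               seq_id = where$seq_id, strand = strand, exons = exons)
      if (n_int > 0L) {
        ist <- exons[-n_ex, "end"]; ien <- exons[-1L, "start"]
        ord <- if (strand == "-") rev(seq_len(n_int)) else seq_len(n_int)
        intron_rows[[g]] <- data.frame(
          gene_id = gid, seq_id = where$seq_id, strand = strand,
          start = as.integer(ist), end = as.integer(ien),
          ordinal = as.integer(ord), length = as.integer(ien - ist),
          stringsAsFactors = FALSE)
      }
    }
    genes <- structure(gene_list, class = "gene_models")
    introns <- if (length(intron_rows) > 0L) do.call(rbind, intron_rows) else
      data.frame(gene_id = character(0), seq_id = character(0), strand = character(0),
                 start = integer(0), end = integer(0), ordinal = integer(0),
                 length = integer(0), stringsAsFactors = FALSE)
    rownames(introns) <- NULL

    # 5. junction repair: the scan of the genome must equal the planted set
    # exactly; any discrepancy redraws the non-planted bases involved
    key <- function(df) paste(df$seq_id, df$start, df$end, df$class_k,
                              df$motif, df$repeat_count)
    for (iter in 1:100) {
      found <- scan_ssr(as_genome(), spec$min_repeats)
      extra <- found[!(key(found) %in% key(ssr)), , drop = FALSE]
      missing <- ssr[!(key(ssr) %in% key(found)), , drop = FALSE]
      if (nrow(extra) == 0L && nrow(missing) == 0L) break
      if (iter == 100L) stop("fixture junction repair did not converge")
      for (i in seq_len(nrow(extra))) {
        n_red <- redraw(extra$seq_id[i], max(extra$start[i] - 1L, 0L),
                        min(extra$end[i] + 1L, length(chars[[extra$seq_id[i]]])),
                        protect = ssr)
        if (n_red == 0L) stop("fixture repair stuck on overlapping planted loci")
      }
    }

    # 6. apply duplications (copy with substitution)
    for (i in seq_len(nrow(segments))) {
      s <- segments[i, ]
      src <- chars[[s$src_seq]][(s$src_start + 1L):s$src_end]
      mut <- runif(length(src)) < spec$mutation_rate
      if (any(mut)) {
        src[mut] <- vapply(src[mut], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }, character(1))
      }
      chars[[s$tgt_seq]][(s$tgt_start + 1L):s$tgt_end] <- src
    }

    genome <- as_genome()

    # 7. ESTs: spliced transcripts with per-base substitution
    est_seqs <- character(0)
    est_rows <- list()
    for (gid in names(genes)) {
      sp <- spliced_sequence(genes[[gid]], genome)
      ch <- strsplit(sp, "", fixed = TRUE)[[1]]
      mut <- runif(length(ch)) < spec$est_mutation_rate
      if (any(mut)) {
        ch[mut] <- vapply(ch[mut], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }, character(1))
      }
      est_id <- paste0("est_", gid)
      est_seqs[est_id] <- paste0(ch, collapse = "")
      pos <- cds_intron_positions(genes[[gid]])
      if (length(pos) > 0L) {
        est_rows[[length(est_rows) + 1L]] <- data.frame(
          est_id = est_id, gene_id = gid, junction = pos, stringsAsFactors = FALSE)
      }
    }
    est_truth <- if (length(est_rows) > 0L) do.call(rbind, est_rows) else
      data.frame(est_id = character(0), gene_id = character(0),
                 junction = integer(0), stringsAsFactors = FALSE)

    ssr_out <- ssr[order(ssr$seq_id, ssr$start), , drop = FALSE]
    ssr_out <- cbind(species = "fixture", ssr_out, stringsAsFactors = FALSE)
    rownames(ssr_out) <- NULL

    structure(list(
      genome = genome, genes = genes,
      ests = if (length(est_seqs) > 0L) genome_set("fixture_est", est_seqs) else NULL,
      truth = list(ssr = ssr_out, introns = introns, segments = segments,
                   est = est_truth),
      spec = spec), class = "fixture")
  })
}

#' @export
print.fixture <- function(x, ...) {
  cat(sprintf("<fixture> %s bp, %d planted SSR loci, %d genes, %d duplication(s)\n",
              format(genome_size(x$genome), big.mark = ","),
              nrow(x$truth$ssr), length(x$genes), nrow(x$truth$segments)))
  invisible(x)
}

#' Write a fixture to disk
#'
#' Emits `genome.fa`, `genes.gff3`, `ests.fa` and the truth tables
#' (`truth_ssr.tsv`, `truth_introns.tsv`, `truth_segments.tsv`,
#' `truth_est.tsv`).
#'
#' @param fixture a fixture from [generate_fixture()].
#' @param dir output directory (created if missing).
#' @return invisibly, `dir`.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(fixture$genome, file.path(dir, "genome.fa"))
  write_gff3(fixture$genes, file.path(dir, "genes.gff3"))
  if (!is.null(fixture$ests)) {
    write_genome_fasta(fixture$ests, file.path(dir, "ests.fa"))
  }
  wt <- function(df, name) write.table(df, file.path(dir, name), sep = "\t",
                                       quote = FALSE, row.names = FALSE)
  wt(fixture$truth$ssr, "truth_ssr.tsv")
  wt(fixture$truth$introns, "truth_introns.tsv")
  wt(fixture$truth$segments, "truth_segments.tsv")
  wt(fixture$truth$est, "truth_est.tsv")
  invisible(dir)
}

# Plant primer cassettes (forward primer + spacer + revcomp(reverse primer))
# into background character vectors. Used by the screen fixtures.
random_primer <- function(n = 20L) {
  repeat {
    p <- paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    if (max_homopolymer(p) <= 4L && gc_frac(p) >= 0.35 && gc_frac(p) <= 0.65) return(p)
  }
}

#' Fixture genome with known marker copy numbers
#'
#' Builds one genome in which synthetic primer cassettes are planted with
#' exact copy numbers (no mutation), together with the matching marker table.
#' The resulting e-PCR site counts are the planted copy numbers.
#'
#' @param seed RNG seed.
#' @param copy_numbers integer vector: planted copies for each marker
#'   (default 70 single-copy, 20 double, 10 triple).
#' @param product_bp cassette product length (default 120).
#' @param genome_length background length in bases (default 400000).
#' @param min_copy_spacing minimum distance between two copies of the same
#'   marker, kept above the e-PCR maximum product size so copies cannot
#'   amplify cross-copy products (default 6000).
#' @return list with `genome`, `markers` (status `validated`) and
#'   `copy_numbers` (named by marker_id).
#' @export
generate_copy_number_fixture <- function(seed = 1L,
                                         copy_numbers = rep(c(1L, 2L, 3L), c(70L, 20L, 10L)),
                                         product_bp = 120L,
                                         genome_length = 400000L,
                                         min_copy_spacing = 6000L) {
  with_seed(seed, {
    chars <- list(chrom = sample_bases(genome_length, rep(0.25, 4)))
    alloc <- make_allocator(list(chrom = genome_length), margin = 50L)
    rows <- list()
    cn_out <- integer(0)
    for (i in seq_along(copy_numbers)) {
      fp <- random_primer(); rp <- random_primer()
      spacer_len <- product_bp - nchar(fp) - nchar(rp)
      stopifnot(spacer_len > 0L)
      cassette <- strsplit(paste0(fp, paste0(sample_bases(spacer_len, rep(0.25, 4)),
                                             collapse = ""), rev_comp(rp)), "")[[1]]
      first <- NULL
      placed <- integer(0)
      for (cp in seq_len(copy_numbers[i])) {
        for (try in 1:500) {
          where <- alloc$alloc(product_bp, scaffold = "chrom")
          if (length(placed) == 0L ||
              all(abs(placed - where$start) >= min_copy_spacing)) break
          if (try == 500L) stop("cannot space marker copies", call. = FALSE)
        }
        placed <- c(placed, where$start)
        chars$chrom[(where$start + 1L):where$end] <- cassette
        if (is.null(first)) first <- where
      }
      mid <- sprintf("cnm%03d", i)
      rows[[i]] <- data.frame(
        marker_id = mid, type = "SSR", species = "cn_fixture", seq_id = "chrom",
        locus_start = first$start, locus_end = first$end,
        motif = NA_character_, repeat_count = NA_integer_,
        forward_primer = fp, reverse_primer = rp,
        expected_product_bp = product_bp, status = "validated",
        stringsAsFactors = FALSE)
      cn_out[mid] <- copy_numbers[i]
    }
    genome <- genome_set("cn_fixture", c(chrom = paste0(chars$chrom, collapse = "")))
    list(genome = genome, markers = do.call(rbind, rows), copy_numbers = cn_out)
  })
}

#' Fixture panel for the universal-marker screen
#'
#' Builds `n_genomes` genomes and a marker set of which the first
#' `n_universal` markers are planted in every genome and the rest only in the
#' first genome.
#'
#' @param seed RNG seed.
#' @param n_markers total markers (default 10).
#' @param n_universal markers planted in all genomes (default 4).
#' @param n_genomes panel size (default 3).
#' @param product_bp cassette product length (default 150).
#' @param genome_length per-genome background length (default 100000).
#' @return list with `genomes` (list of [genome_set()]), `markers`, and
#'   `universal_ids`.
#' @export
generate_universal_fixture <- function(seed = 1L, n_markers = 10L,
                                       n_universal = 4L, n_genomes = 3L,
                                       product_bp = 150L,
                                       genome_length = 100000L) {
  stopifnot(n_universal <= n_markers)
  with_seed(seed, {
    charsets <- lapply(seq_len(n_genomes), function(i)
      sample_bases(genome_length, rep(0.25, 4)))
    allocs <- lapply(seq_len(n_genomes), function(i)
      make_allocator(list(chrom = genome_length), margin = 50L))
    rows <- list()
    for (i in seq_len(n_markers)) {
      fp <- random_primer(); rp <- random_primer()
      spacer_len <- product_bp - nchar(fp) - nchar(rp)
      cassette <- strsplit(paste0(fp, paste0(sample_bases(spacer_len, rep(0.25, 4)),
                                             collapse = ""), rev_comp(rp)), "")[[1]]
      targets <- if (i <= n_universal) seq_len(n_genomes) else 1L
      first <- NULL
      for (gidx in targets) {
        where <- allocs[[gidx]]$alloc(product_bp, scaffold = "chrom")
        charsets[[gidx]][(where$start + 1L):where$end] <- cassette
        if (gidx == 1L) first <- where
      }
      rows[[i]] <- data.frame(
        marker_id = sprintf("uni%02d", i), type = "SSR", species = "species1",
        seq_id = "chrom", locus_start = first$start, locus_end = first$end,
        motif = NA_character_, repeat_count = NA_integer_,
        forward_primer = fp, reverse_primer = rp,
        expected_product_bp = product_bp, status = "validated",
        stringsAsFactors = FALSE)
    }
    genomes <- lapply(seq_len(n_genomes), function(i)
      genome_set(paste0("species", i),
                 c(chrom = paste0(charsets[[i]], collapse = ""))))
    markers <- do.call(rbind, rows)
    list(genomes = genomes, markers = markers,
         universal_ids = markers$marker_id[seq_len(n_universal)])
  })
}
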