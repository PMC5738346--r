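# Intron extraction, exonic ILP flanks, and EST projection for PIP markers.

mk_gene <- function(id, seq_id, strand, exons) {
  structure(setNames(list(list(gene_id = id, transcript_id = paste0(id, ".t1"),
                               seq_id = seq_id, strand = strand,
                               exons = cbind(start = exons[, 1], end = exons[, 2]))),
                     id),
            class = "gene_models")
}

test_that("introns are the exon gaps, strand-aware ordinals", {
  g <- mk_gene("g1", "s1", "+", cbind(c(10L, 30L), c(20L, 40L)))
  introns <- extract_introns(g)
  expect_equal(nrow(introns), 1L)
  expect_equal(c(introns$start, introns$end, introns$ordinal, introns$length),
               c(20L, 30L, 1L, 10L))

  gm <- mk_gene("g1", "s1", "-", cbind(c(10L, 30L, 50L), c(20L, 40L, 60L)))
  introns <- extract_introns(gm)
  expect_equal(introns$start, c(20L, 40L))
  expect_equal(introns$ordinal, c(2L, 1L))  # transcription order on minus strand

  single <- mk_gene("g1", "s1", "+", cbind(10L, 40L))
  expect_equal(nrow(extract_introns(single)), 0L)

  bad <- mk_gene("g1", "s1", "+", cbind(c(10L, 15L), c(20L, 40L)))
  expect_error(extract_introns(bad), "overlapping exons")
})

test_that("introns and exons tile the gene span", {
  fx <- small_fixture()
  introns <- extract_introns(fx$genes)
  expect_equal(introns[order(introns$gene_id, introns$start),
                       c("gene_id", "start", "end", "ordinal")],
               fx$truth$introns[order(fx$truth$introns$gene_id,
                                      fx$truth$introns$start),
                                c("gene_id", "start", "end", "ordinal")],
               ignore_attr = TRUE)
  for (gm in fx$genes) {
    ins <- introns[introns$gene_id == gm$gene_id, , drop = FALSE]
    span <- max(gm$exons[, "end"]) - min(gm$exons[, "start"])
    expect_equal(sum(gm$exons[, "end"] - gm$exons[, "start"]) +
                   sum(ins$end - ins$start), span)
  }
})

test_that("ILP flanks must be exonic, untruncated and N-free", {
  s <- strrep("ACGTGGTCAT", 100)
  g <- genome_set("sp", c(s1 = s))
  genes <- mk_gene("g1", "s1", "+", cbind(c(100L, 300L), c(200L, 400L)))
  introns <- extract_introns(genes)
  pre <- ilp_precursors(introns, genes, g)
  expect_true(is.na(pre$reject_reason))
  expect_equal(pre$left_flank, substr(s, 141, 200))
  expect_equal(pre$right_flank, substr(s, 301, 360))

  # short terminal exon: flank would leave the exon
  genes2 <- mk_gene("g1", "s1", "+", cbind(c(100L, 300L), c(140L, 400L)))
  pre2 <- ilp_precursors(extract_introns(genes2), genes2, g)
  expect_equal(pre2$reject_reason, "flank not fully exonic")

  # flank would cross into the next intron of the same gene
  genes3 <- mk_gene("g1", "s1", "+",
                    cbind(c(100L, 300L, 340L), c(200L, 330L, 500L)))
  pre3 <- ilp_precursors(extract_introns(genes3), genes3, g)
  expect_equal(pre3$reject_reason[1], "flank not fully exonic")  # right flank too wide
  expect_true(is.na(pre3$reject_reason[2]) ||
                pre3$reject_reason[2] == "flank not fully exonic")

  # truncation at the sequence start
  g_small <- genome_set("sp", c(s1 = substr(s, 1, 500)))
  genes4 <- mk_gene("g1", "s1", "+", cbind(c(0L, 150L), c(40L, 400L)))
  pre4 <- ilp_precursors(extract_introns(genes4), genes4, g_small)
  expect_equal(pre4$reject_reason, "flank truncated")
})

test_that("spliced-CDS intron positions are cumulative exon lengths", {
  g <- mk_gene("g1", "s1", "+", cbind(c(0L, 150L), c(100L, 200L)))
  expect_equal(cds_intron_positions(g[["g1"]]), 100L)
  g3 <- mk_gene("g1", "s1", "+", cbind(c(0L, 40L, 80L), c(30L, 70L, 110L)))
  expect_equal(cds_intron_positions(g3[["g1"]]), c(30L, 60L))
  # minus strand: spell out the spliced transcript and find the junction
  gm <- mk_gene("g1", "s1", "-", cbind(c(0L, 100L), c(30L, 170L)))
  genome <- genome_set("sp", setNames(random_dna(200), "s1"))
  spliced <- spliced_sequence(gm[["g1"]], genome)
  # transcript = revcomp(exon2) + revcomp(exon1): junction after 70 bases
  expect_equal(nchar(spliced), 100L)
  expect_identical(substr(spliced, 1, 70),
                   rev_comp(substr(genome$seq[["s1"]], 101, 170)))
  expect_equal(cds_intron_positions(gm[["g1"]]), 70L)
  single <- mk_gene("g1", "s1", "+", cbind(0L, 90L))
  expect_length(cds_intron_positions(single[["g1"]]), 0L)
})

test_that("EST aligns to CDS on either strand with correct identity", {
  set.seed(15)
  cds <- random_dna(600)
  aln <- align_est_to_cds(cds, cds)
  expect_equal(aln$identity, 1)
  expect_equal(aln$strand, "+")
  expect_equal(c(aln$est_start, aln$est_end), c(1L, 600L))

  aln_rc <- align_est_to_cds(rev_comp(cds), cds)
  expect_equal(aln_rc$identity, 1)
  expect_equal(aln_rc$strand, "-")
  expect_equal(c(aln_rc$cds_start, aln_rc$cds_end), c(1L, 600L))

  # ~10% substitutions: alignment recovered with identity near 0.9
  est <- strsplit(cds, "")[[1]]
  mut <- sample(600, 60)
  est[mut] <- vapply(est[mut], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  aln_mut <- align_est_to_cds(paste0(est, collapse = ""), cds, min_identity = 0.85)
  expect_false(is.null(aln_mut))
  expect_equal(aln_mut$identity, 0.9, tolerance = 0.03)

  # unrelated sequence fails the screen
  expect_null(align_est_to_cds(random_dna(300), random_dna(300)))
})

test_that("projected junctions match planted truth (0% exact, 5% within 2 bp)", {
  fx0 <- generate_fixture(fixture_spec(
    seed = 23L, scaffold_lengths = c(ctgA = 90000L),
    n_ssr_per_class = c(1L, 1L, 1L, 1L, 1L, 1L, 1L),
    n_genes = 4L, introns_per_gene = rep(2L, 4L),
    n_duplications = 0L, ssr_per_duplication = 0L,
    est_mutation_rate = 0))
  for (gid in names(fx0$genes)) {
    est_id <- paste0("est_", gid)
    est <- fx0$ests$seq[[est_id]]
    cds <- spliced_sequence(fx0$genes[[gid]], fx0$genome)
    aln <- align_est_to_cds(est, cds)
    truth <- fx0$truth$est[fx0$truth$est$est_id == est_id, "junction"]
    proj <- project_intron_positions(aln, cds_intron_positions(fx0$genes[[gid]]),
                                     nchar(est))
    # at 0% mutation the EST is the spliced CDS: positions map exactly
    expect_equal(proj$est_position, truth)
  }

  fx5 <- generate_fixture(fixture_spec(
    seed = 23L, scaffold_lengths = c(ctgA = 90000L),
    n_ssr_per_class = c(1L, 1L, 1L, 1L, 1L, 1L, 1L),
    n_genes = 4L, introns_per_gene = rep(2L, 4L),
    n_duplications = 0L, ssr_per_duplication = 0L,
    est_mutation_rate = 0.05))
  n_checked <- 0L
  for (gid in names(fx5$genes)) {
    est_id <- paste0("est_", gid)
    est <- fx5$ests$seq[[est_id]]
    cds <- spliced_sequence(fx5$genes[[gid]], fx5$genome)
    aln <- align_est_to_cds(est, cds)
    if (is.null(aln)) next
    truth <- fx5$truth$est[fx5$truth$est$est_id == est_id, "junction"]
    proj <- project_intron_positions(aln, cds_intron_positions(fx5$genes[[gid]]),
                                     nchar(est))
    for (i in seq_len(nrow(proj))) {
      expect_lte(min(abs(truth - proj$est_position[i])), 2L)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 4L)
})

test_that("PIP markers are developed around projected junctions", {
  fx <- generate_fixture(fixture_spec(
    seed = 29L, scaffold_lengths = c(ctgA = 90000L),
    n_ssr_per_class = c(1L, 1L, 1L, 1L, 1L, 1L, 1L),
    n_genes = 3L, introns_per_gene = rep(2L, 3L),
    n_duplications = 0L, ssr_per_duplication = 0L,
    est_mutation_rate = 0))
  m <- pip_markers(fx$ests, fx$genes, fx$genome)
  expect_true(all(m$type == "PIP"))
  # both junctions of each EST fall inside the full-length alignment,
  # and flanks fit, so each gene should yield 2 candidates (minus any
  # design rejections)
  expect_gte(nrow(m), 4L)
  # marker locus sits at the projected junction on the EST
  truth <- fx$truth$est
  for (i in seq_len(nrow(m))) {
    t_est <- truth[truth$est_id == m$seq_id[i], "junction"]
    expect_true(m$locus_start[i] %in% t_est)
  }
  # precursor arithmetic around a projected point
  proj <- data.frame(cds_position = 100L, est_position = 200L)
  est <- random_dna(500)
  pre <- pip_precursors(proj, est, "e1", "g1")
  expect_identical(pre$left_flank, substr(est, 141, 200))
  expect_identical(pre$right_flank, substr(est, 201, 260))
  pre_edge <- pip_precursors(data.frame(cds_position = 1L, est_position = 30L),
                             est, "e1", "g1")
  expect_equal(pre_edge$reject_reason, "flank truncated")
})
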