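# The e-PCR engine and the validation/dedup/polymorphism/universal screens.

mk_marker <- function(id, fp, rp, seq_id = "s1", start = 0L, end = 0L,
                      product = NA_integer_, status = "candidate") {
  data.frame(marker_id = id, type = "SSR", species = "sp", seq_id = seq_id,
             locus_start = start, locus_end = end, motif = NA_character_,
             repeat_count = NA_integer_, forward_primer = fp, reverse_primer = rp,
             expected_product_bp = product, status = status,
             stringsAsFactors = FALSE)
}

test_that("planted cassettes are amplified as constructed", {
  set.seed(51)
  F <- random_dna(20); R <- random_dna(20)
  mid <- random_dna(100)
  g <- genome_set("sp", c(
    s1 = paste0(random_dna(50), F, mid, rev_comp(R), random_dna(40)),
    s2 = paste0(random_dna(10), F, mid, rev_comp(R), random_dna(10))))
  hits <- epcr(mk_marker("m1", F, R), g)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$product_bp, c(140L, 140L))
  expect_equal(hits$start, c(50L, 10L))
  expect_equal(hits$strand, c("+", "+"))
  # the same cassette is found on the reverse strand of a flipped genome
  g_flip <- genome_set("sp", c(s1 = rev_comp(g$seq[["s1"]])))
  hits_flip <- epcr(mk_marker("m1", F, R), g_flip)
  expect_equal(nrow(hits_flip), 1L)
  expect_equal(hits_flip$strand, "-")
  expect_equal(hits_flip$product_bp, 140L)
})

test_that("a 3'-terminal mismatch kills the site even with mismatches allowed", {
  set.seed(52)
  F <- random_dna(20); R <- random_dna(20)
  F_bad <- paste0(substr(F, 1, 19),
                  setdiff(c("A", "C", "G", "T"), substr(F, 20, 20))[1])
  g <- genome_set("sp", c(s1 = paste0(random_dna(30), F_bad, random_dna(80),
                                      rev_comp(R), random_dna(30))))
  p1 <- epcr_params(max_mismatches = 1L)
  expect_equal(nrow(epcr(mk_marker("m", F, R), g, p1)), 0L)
  # the same mismatch away from the 3' end is tolerated at max_mismatches = 1
  F_mid <- paste0(substr(F, 1, 9),
                  setdiff(c("A", "C", "G", "T"), substr(F, 10, 10))[1],
                  substr(F, 11, 20))
  g2 <- genome_set("sp", c(s1 = paste0(random_dna(30), F_mid, random_dna(80),
                                       rev_comp(R), random_dna(30))))
  expect_equal(nrow(epcr(mk_marker("m", F, R), g2, p1)), 1L)
  expect_equal(nrow(epcr(mk_marker("m", F, R), g2, epcr_params())), 0L)
})

test_that("epcr equals the naive all-positions oracle on random genomes", {
  set.seed(53)
  for (trial in 1:6) {
    # genome with planted structure so hits actually occur
    F <- random_dna(18); R <- random_dna(18)
    pieces <- c(random_dna(3000),
                F, random_dna(60), rev_comp(R),        # normal cassette
                random_dna(500),
                R, random_dna(45), rev_comp(F),        # inverted orientation
                random_dna(500),
                F, random_dna(2), rev_comp(R),         # product below min
                random_dna(400),
                F, random_dna(80), rev_comp(R),
                random_dna(1000))
    g <- genome_set("sp", c(c1 = paste0(pieces, collapse = ""),
                            c2 = random_dna(2000)))
    for (mm in 0:1) {
      params <- epcr_params(max_mismatches = mm)
      got <- epcr(mk_marker("m", F, R), g, params)
      want <- oracle_epcr(list(forward_primer = F, reverse_primer = R), g, params)
      expect_equal(got[, c("seq_id", "start", "end", "strand", "product_bp")],
                   want, ignore_attr = TRUE)
    }
  }
})

test_that("validation requires an on-target product of the expected size", {
  set.seed(54)
  F1 <- random_dna(20); R1 <- random_dna(20)
  F2 <- random_dna(20); R2 <- random_dna(20)
  locus1 <- strrep("AC", 8)
  s1 <- paste0(random_dna(60), F1, random_dna(40), locus1, random_dna(40),
               rev_comp(R1), random_dna(50),
               F2, random_dna(30), strrep("AG", 8), random_dna(30),
               rev_comp(R2), random_dna(60))
  g <- genome_set("sp", c(s1 = s1))
  st1 <- 60L + 20L + 40L
  m1 <- mk_marker("m1", F1, R1, start = st1, end = st1 + 16L, product = 132L)
  st2 <- 60L + 20L + 40L + 16L + 40L + 20L + 50L + 20L + 30L
  m2 <- mk_marker("m2", F2, R2, start = st2, end = st2 + 16L, product = 112L)
  v <- validate_markers(rbind(m1, m2), g)
  expect_equal(v$status, c("validated", "validated"))
  # swapping primer pairs between markers breaks on-target amplification
  swapped <- rbind(mk_marker("m1", F2, R2, start = st1, end = st1 + 16L, product = 132L),
                   mk_marker("m2", F1, R1, start = st2, end = st2 + 16L, product = 112L))
  v2 <- validate_markers(swapped, g)
  expect_equal(v2$status, c("rejected", "rejected"))
  expect_equal(unique(v2$reject_reason), "no on-target product")
  # off-target-only marker is rejected but the off-target hit is recorded
  m_off <- mk_marker("m3", F1, R1, seq_id = "s1", start = 5000L, end = 5016L,
                     product = 132L)
  v3 <- validate_markers(m_off, g)
  expect_equal(v3$status, "rejected")
  expect_equal(nrow(attr(v3, "hits")), 1L)
})

test_that("deduplication groups by shared primer with transitive closure", {
  m <- rbind(
    mk_marker("mA", "ACGTACGTACGTACGTACGA", "TTTTGGGGCCCCAAAATTTT", start = 10L),
    mk_marker("mB", "ACGTACGTACGTACGTACGA", "GGGGTTTTAAAACCCCGGGG", start = 20L),
    mk_marker("mC", "CCCCAAAATTTTGGGGCCCC", "GGGGTTTTAAAACCCCGGGG", start = 30L))
  d <- dedup_markers(m)
  expect_equal(nrow(d), 1L)              # A~B (forward), B~C (reverse)
  expect_equal(d$marker_id, "mA")        # smallest locus_start survives
  expect_equal(attr(d, "n_removed"), 2L)

  # brute-force closure cross-check on random small sets
  set.seed(55)
  for (trial in 1:20) {
    n <- sample(2:8, 1)
    fps <- sample(c("F1", "F2", "F3"), n, replace = TRUE)
    rps <- sample(c("R1", "R2", "R3"), n, replace = TRUE)
    mm <- do.call(rbind, lapply(seq_len(n), function(i)
      mk_marker(sprintf("m%02d", i), fps[i], rps[i], start = i * 10L)))
    got <- dedup_markers(mm)
    # naive closure: iterate merging until stable (empty vector = consumed)
    groups <- as.list(seq_len(n))
    repeat {
      merged <- FALSE
      for (i in seq_along(groups)) {
        if (length(groups[[i]]) == 0L) next
        for (j in seq_along(groups)) {
          if (j <= i || length(groups[[j]]) == 0L) next
          share <- any(fps[groups[[i]]] %in% fps[groups[[j]]]) ||
            any(rps[groups[[i]]] %in% rps[groups[[j]]])
          if (share) {
            groups[[i]] <- c(groups[[i]], groups[[j]])
            groups[[j]] <- integer(0)
            merged <- TRUE
          }
        }
      }
      if (!merged) break
    }
    n_groups <- sum(lengths(groups) > 0L)
    expect_equal(nrow(got), n_groups)
  }

  # distinct primers: identity, and dedup is idempotent
  set.seed(56)
  distinct <- do.call(rbind, lapply(1:5, function(i)
    mk_marker(paste0("d", i), random_dna(20), random_dna(20), start = i * 5L)))
  expect_equal(nrow(dedup_markers(distinct)), 5L)
  once <- dedup_markers(m)
  expect_equal(dedup_markers(once)$marker_id, once$marker_id)
})

test_that("polymorphism classification counts genome-wide sites", {
  fx <- generate_copy_number_fixture(seed = 61L,
                                     copy_numbers = rep(c(1L, 2L, 3L), c(7L, 2L, 1L)),
                                     genome_length = 60000L)
  cls <- classify_polymorphism(fx$markers, fx$genome)
  expect_equal(setNames(cls$site_count, cls$marker_id), fx$copy_numbers)
  expect_equal(cls$label,
               unname(ifelse(fx$copy_numbers >= 2, "polymorphic", "monomorphic")))
  expect_equal(site_histogram(cls), c(`1` = 7L, `2` = 2L, `3` = 1L))
})

test_that("universal screen keeps exactly the markers present in all genomes", {
  fx <- generate_universal_fixture(seed = 62L, n_markers = 10L, n_universal = 4L,
                                   n_genomes = 3L)
  res <- universal_screen(fx$markers, fx$genomes)
  expect_setequal(res$universal$marker_id, fx$universal_ids)
  expect_equal(dim(res$hit_matrix), c(10L, 3L))
  expect_true(all(res$hit_matrix[fx$universal_ids, ] >= 1L))
  # single-genome degenerate case: equals the markers amplifying there
  res1 <- universal_screen(fx$markers, fx$genomes[1])
  expect_setequal(res1$universal$marker_id, fx$markers$marker_id)
})
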