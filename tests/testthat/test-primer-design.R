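# Nearest-neighbour Tm and the deterministic primer designer.

# Independent Tm recomputation: explicit table lookup, term-by-term sums, the
# way one would do it in a spreadsheet.
hand_tm <- function(p, na = 0.05, ct = 250e-9) {
  dH_tab <- c(AA = -7.9, AT = -7.2, AC = -8.4, AG = -7.8,
              TA = -7.2, TT = -7.9, TC = -8.2, TG = -8.5,
              CA = -8.5, CT = -7.8, CC = -8.0, CG = -10.6,
              GA = -8.2, GT = -8.4, GC = -9.8, GG = -8.0)
  dS_tab <- c(AA = -22.2, AT = -20.4, AC = -22.4, AG = -21.0,
              TA = -21.3, TT = -22.2, TC = -22.2, TG = -22.7,
              CA = -22.7, CT = -21.0, CC = -19.9, CG = -27.2,
              GA = -22.2, GT = -22.4, GC = -24.4, GG = -19.9)
  ch <- strsplit(p, "")[[1]]
  dH <- 0; dS <- 0
  for (i in seq_len(length(ch) - 1)) {
    key <- paste0(ch[i], ch[i + 1])
    dH <- dH + dH_tab[[key]]; dS <- dS + dS_tab[[key]]
  }
  for (b in c(ch[1], ch[length(ch)])) {
    if (b %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  sym <- p == rev_comp(p)
  if (sym) dS <- dS - 1.4
  dS <- dS + 0.368 * (length(ch) - 1) * log(na)
  1000 * dH / (dS + 1.9872 * log(ct / if (sym) 1 else 4)) - 273.15
}

test_that("Tm matches a hand-summed nearest-neighbour recomputation", {
  primers <- c("ACGTACGTACGTACGTACGT", "GGCATCGATCGGATCCTAGG",
               "TTATTAGCGCAATTAACGCA", "GAATTCGAATTC",  # palindromic
               "AAAAAAAATTTTTTTT")
  for (p in primers) {
    expect_equal(primer_tm(p), hand_tm(p), tolerance = 1e-9)
  }
  set.seed(42)
  for (i in 1:25) {
    p <- random_dna(sample(18:27, 1))
    expect_equal(primer_tm(p), hand_tm(p), tolerance = 1e-9)
  }
})

test_that("Tm is GC-sensitive, duplex-symmetric and rejects bad input", {
  expect_lt(primer_tm(strrep("A", 20)), primer_tm(strrep("GC", 10)))
  set.seed(5)
  for (i in 1:10) {
    p <- random_dna(20)
    expect_equal(primer_tm(p), primer_tm(rev_comp(p)), tolerance = 1e-9)
  }
  expect_error(primer_tm("ACGTNACGTACG"), "non-ACGT")
  expect_error(primer_tm("ACGT"), "too short")
})

test_that("windowed Tm equals the scalar Tm on every window", {
  set.seed(9)
  flank <- random_dna(60)
  w <- treemarker:::tm_windows(flank, c(18L, 27L))
  idx <- sample(nrow(w), 30)
  expect_equal(w$tm[idx], primer_tm(w$seq[idx]), tolerance = 1e-9)
})

test_that("design is deterministic and the unique passing pair is found", {
  set.seed(31)
  lf <- random_dna(60); rf <- random_dna(60)
  d1 <- design_primer_pair(lf, rf, insert_len = 24L)
  d2 <- design_primer_pair(lf, rf, insert_len = 24L)
  expect_identical(d1, d2)

  # homopolymer flank fails
  expect_false(design_primer_pair(strrep("A", 60), rf)$ok)

  # exhaustive-enumeration cross-check: the returned pair is the best-scoring
  # pair among all windows that pass the hard constraints
  cons <- design_constraints()
  fw <- treemarker:::passing_windows(lf, cons, cap = 1000L)
  rw <- treemarker:::passing_windows(rf, cons, cap = 1000L, as_revcomp = TRUE)
  rw$primer <- rev_comp(rw$seq)
  best <- Inf
  for (i in seq_len(nrow(fw))) for (j in seq_len(nrow(rw))) {
    if (abs(fw$tm[i] - rw$tm[j]) > cons$max_tm_diff) next
    sc <- abs(fw$tm[i] - cons$opt_tm) + abs(rw$tm[j] - cons$opt_tm) +
      0.25 * (abs(fw$len[i] - cons$opt_len) + abs(rw$len[j] - cons$opt_len)) +
      max(0, treemarker:::comp_any(fw$seq[i], rw$primer[j]) - cons$max_anycomp) +
      max(0, max(treemarker:::comp_3prime(fw$seq[i], rw$primer[j]),
                 treemarker:::comp_3prime(rw$primer[j], fw$seq[i])) -
            cons$max_3prime_selfcomp)
    best <- min(best, sc)
  }
  d <- design_primer_pair(lf, rf)
  got_score <- abs(d$tm_forward - cons$opt_tm) + abs(d$tm_reverse - cons$opt_tm) +
    0.25 * (abs(d$f_len - cons$opt_len) + abs(d$r_len - cons$opt_len)) +
    max(0, treemarker:::comp_any(d$forward, d$reverse) - cons$max_anycomp) +
    max(0, max(treemarker:::comp_3prime(d$forward, d$reverse),
               treemarker:::comp_3prime(d$reverse, d$forward)) -
          cons$max_3prime_selfcomp)
  expect_equal(got_score, best, tolerance = 1e-9)
})

test_that("returned primers always satisfy the hard constraints", {
  set.seed(77)
  cons <- design_constraints()
  n_ok <- 0L
  for (i in 1:300) {
    lf <- random_dna(60, freq = c(0.3, 0.2, 0.2, 0.3))
    rf <- random_dna(60, freq = c(0.3, 0.2, 0.2, 0.3))
    d <- design_primer_pair(lf, rf, insert_len = 50L, constraints = cons)
    if (!d$ok) next
    n_ok <- n_ok + 1L
    for (p in c(d$forward, d$reverse)) {
      expect_gte(nchar(p), cons$len_range[1])
      expect_lte(nchar(p), cons$len_range[2])
      tm <- primer_tm(p)
      expect_gte(tm, cons$tm_range[1]); expect_lte(tm, cons$tm_range[2])
      gc <- gc_frac <- nchar(gsub("[^GC]", "", p)) / nchar(p)
      expect_gte(gc, cons$gc_range[1]); expect_lte(gc, cons$gc_range[2])
      expect_lte(treemarker:::max_homopolymer(p), cons$max_homopolymer)
      expect_lte(treemarker:::comp_any(p, p), cons$max_anycomp)
      expect_lte(treemarker:::comp_3prime(p, p), cons$max_3prime_selfcomp)
    }
    expect_lte(abs(d$tm_forward - d$tm_reverse), cons$max_tm_diff)
    # product geometry: forward inside left flank, reverse inside right flank
    expect_identical(substr(lf, d$f_start + 1, d$f_start + d$f_len), d$forward)
    expect_identical(rev_comp(substr(rf, d$r_start + 1, d$r_start + d$r_len)),
                     d$reverse)
    expect_equal(d$expected_product_bp,
                 (60 - d$f_start) + 50L + d$r_start + d$r_len)
  }
  expect_gt(n_ok, 100L)  # most random flanks should be designable
})

test_that("tightening the Tm range never converts rejection into acceptance", {
  set.seed(13)
  wide <- design_constraints()
  narrow <- design_constraints(tm_range = c(58, 61))
  n_wide <- 0L; n_narrow <- 0L
  for (i in 1:60) {
    lf <- random_dna(60); rf <- random_dna(60)
    d_wide <- design_primer_pair(lf, rf, constraints = wide)
    d_narrow <- design_primer_pair(lf, rf, constraints = narrow)
    if (!d_wide$ok) expect_false(d_narrow$ok)
    n_wide <- n_wide + d_wide$ok
    n_narrow <- n_narrow + d_narrow$ok
  }
  expect_lte(n_narrow, n_wide)
  expect_gt(n_wide, 0L)
})

test_that("symmetric flanks give mirrored primers", {
  set.seed(21)
  repeat {
    lf <- random_dna(60)
    d <- design_primer_pair(lf, rev_comp(lf))
    if (d$ok) break
  }
  expect_identical(d$forward, d$reverse)
})
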