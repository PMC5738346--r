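# Band matrix construction, distance coefficients, UPGMA and bootstrap.

test_that("band binning emulates gel resolution", {
  hits <- data.frame(sample = c("a", "b", "a", "b"),
                     marker_id = c("m1", "m1", "m2", "m2"),
                     product_bp = c(150L, 152L, 150L, 160L))
  m <- band_matrix(hits, bin_width = 5L)
  expect_equal(m["a", "m1@150"], 1L)
  expect_equal(m["b", "m1@150"], 1L)          # 150 and 152 share a bin
  expect_true(all(c("m2@150", "m2@160") %in% colnames(m)))
  expect_equal(m["a", "m2@160"], 0L)          # 150 vs 160 are different bands
})

test_that("distance coefficients match hand arithmetic and the counting oracle", {
  m <- rbind(a = c(1L, 1L, 0L), b = c(1L, 0L, 1L))
  expect_equal(band_distance(m, "dice")["a", "b"], 0.5)
  expect_equal(band_distance(m, "jaccard")["a", "b"], 1 - 1 / 3)
  expect_equal(band_distance(m, "simple_matching")["a", "b"], 2 / 3)
  m_same <- rbind(a = c(1L, 0L, 1L), b = c(1L, 0L, 1L))
  expect_equal(band_distance(m_same, "dice")["a", "b"], 0)

  set.seed(81)
  for (trial in 1:10) {
    mm <- matrix(rbinom(40, 1, 0.5), 5, 8,
                 dimnames = list(paste0("s", 1:5), NULL))
    mm[1, ] <- pmax(mm[1, ], 1L)  # avoid all-zero rows
    for (coef in c("dice", "simple_matching", "jaccard")) {
      got <- suppressWarnings(band_distance(mm, coef))
      expect_equal(got, oracle_band_distance(mm, coef), tolerance = 1e-12)
    }
  }
  m0 <- rbind(a = c(0L, 0L), b = c(0L, 0L), c = c(1L, 0L))
  expect_warning(d0 <- band_distance(m0, "dice"), "undefined")
  expect_true(is.na(d0["a", "b"]))   # both samples bandless: undefined pair
  expect_equal(d0["a", "c"], 1)      # one-sided zero row is simply distance 1
})

test_that("UPGMA solves the textbook three-taxon case", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(d)
  parts <- ape::prop.part(tr)
  sets <- lapply(parts, function(p) sort(attr(parts, "labels")[p]))
  expect_true(any(vapply(sets, identical, logical(1), y = c("A", "B"))))
  h <- tip_heights(tr)
  expect_equal(unname(h), c(2, 2, 2))
  # A and B coalesce at height 1: their pairwise tree distance is 2
  expect_equal(unname(ape::cophenetic.phylo(tr)["A", "B"]), 2)
  expect_equal(unname(ape::cophenetic.phylo(tr)["A", "C"]), 4)
  expect_error(upgma(matrix(c(0, 1, 2, 0), 2, 2)), "not symmetric")
  expect_error(upgma(matrix(c(0, -1, -1, 0), 2, 2)), "negative")
})

test_that("equal distances resolve by the lexicographic tie-break, same heights", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  tr <- upgma(d)
  expect_equal(ape::Ntip(tr), 4L)
  expect_equal(unname(tip_heights(tr)), rep(0.5, 4))
  # first merge is {a,b}, the lexicographically smallest pair
  parts <- ape::prop.part(tr)
  sets <- lapply(parts, function(p) sort(attr(parts, "labels")[p]))
  expect_true(any(vapply(sets, identical, logical(1), y = c("a", "b"))))
})

test_that("UPGMA recovers a known ultrametric tree exactly", {
  set.seed(82)
  for (trial in 1:5) {
    # build a random ultrametric tree by simulating UPGMA merges upward
    n <- 8L
    labs <- paste0("t", 1:n)
    height <- setNames(rep(0, n), labs)
    groups <- as.list(labs)
    d <- matrix(0, n, n, dimnames = list(labs, labs))
    h <- 0
    while (length(groups) > 1L) {
      h <- h + runif(1, 0.5, 2)
      i <- sample.int(length(groups), 1L)
      others <- setdiff(seq_along(groups), i)
      j <- others[sample.int(length(others), 1L)]
      for (x in groups[[i]]) for (y in groups[[j]]) d[x, y] <- d[y, x] <- 2 * h
      groups[[i]] <- c(groups[[i]], groups[[j]])
      groups[[j]] <- NULL
    }
    tr <- upgma(d)
    expect_equal(as.matrix(ape::cophenetic.phylo(tr))[labs, labs], d,
                 tolerance = 1e-9)
  }
})

test_that("UPGMA output is ultrametric and label-permutation invariant", {
  set.seed(83)
  for (trial in 1:20) {
    n <- sample(4:10, 1)
    pts <- matrix(runif(n * 3), n)
    rownames(pts) <- paste0("s", seq_len(n))
    d <- as.matrix(dist(pts))
    tr <- upgma(d)
    expect_lt(diff(range(tip_heights(tr))), 1e-9)
    # agreement with average-linkage hclust on tie-free input
    hc <- stats::hclust(as.dist(d), method = "average")
    tr_hc <- ape::as.phylo(hc)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr_hc)), 0,
                 ignore_attr = TRUE)
    # permuting the input order leaves the topology unchanged
    perm <- sample(n)
    tr_p <- upgma(d[perm, perm])
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr_p)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap support is seeded, bounded, and high for a planted clade", {
  # 8 samples, each with 5 bands private to itself (no shared signal), plus a
  # clade of four samples sharing 10 private bands absent elsewhere
  m <- matrix(0L, 8, 50, dimnames = list(paste0("w", 1:8), NULL))
  for (i in 1:8) m[i, (i - 1) * 5 + 1:5] <- 1L
  clade <- paste0("w", 1:4)
  m[clade, 41:50] <- 1L
  tr1 <- upgma_bootstrap(m, replicates = 200L, seed = 99L)
  tr2 <- upgma_bootstrap(m, replicates = 200L, seed = 99L)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  sup <- as.numeric(tr1$node.label)
  expect_true(all(sup >= 0 & sup <= 100))
  parts <- ape::prop.part(tr1)
  labs <- attr(parts, "labels")
  clade_node <- which(vapply(parts, function(p)
    identical(sort(labs[p]), sort(clade)), logical(1)))
  expect_length(clade_node, 1L)
  expect_gte(sup[clade_node], 95)
  # single replicate with a fixed seed is deterministic
  tr_one <- upgma_bootstrap(m, replicates = 1L, seed = 5L)
  expect_true(all(as.numeric(tr_one$node.label) %in% c(0, 100)))
})
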