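# Dominant-marker diversity analysis: band presence/absence matrix from
# e-PCR products (gel-resolution binning), Dice/simple-matching/Jaccard
# distances, UPGMA clustering with a deterministic tie-break, and bootstrap
# support by column resampling.

#' Build a band presence/absence matrix from amplification products
#'
#' Each (marker, product-size bin) pair becomes one band column; a cell is 1
#' when the sample has at least one product in that bin. Bin edges sit at
#' multiples of `bin_width`, emulating gel resolving power.
#'
#' @param hits data frame with `sample`, `marker_id`, `product_bp`.
#' @param bin_width size-bin width in bp (default 5).
#' @return binary matrix, samples in rows, bands in columns (named
#'   `marker_id@binstart`).
#' @export
band_matrix <- function(hits, bin_width = 5L) {
  stopifnot(all(c("sample", "marker_id", "product_bp") %in% names(hits)))
  bin <- (hits$product_bp %/% bin_width) * bin_width
  band <- paste0(hits$marker_id, "@", bin)
  samples <- sort(unique(hits$sample))
  bands <- sort(unique(band))
  m <- matrix(0L, length(samples), length(bands),
              dimnames = list(samples, bands))
  m[cbind(match(hits$sample, samples), match(band, bands))] <- 1L
  m
}

#' Pairwise distances from a band matrix
#'
#' Dice distance is `1 - 2a/(2a+b+c)`, simple matching `1 - (a+d)/n`, Jaccard
#' `1 - a/(a+b+c)`, where `a` counts shared presences, `b`/`c` private
#' presences and `d` shared absences. Pairs undefined under Dice or Jaccard
#' (both samples all-zero) are flagged `NA` with a warning.
#'
#' @param m binary matrix from [band_matrix()].
#' @param coefficient one of `"dice"`, `"simple_matching"`, `"jaccard"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
band_distance <- function(m, coefficient = c("dice", "simple_matching", "jaccard")) {
  coefficient <- match.arg(coefficient)
  stopifnot(is.matrix(m), all(m %in% c(0L, 1L)), nrow(m) >= 2L)
  storage.mode(m) <- "double"
  a <- tcrossprod(m)
  ones <- rowSums(m)
  nb <- ncol(m)
  d <- switch(coefficient,
    dice = {
      denom <- outer(ones, ones, `+`)
      out <- 1 - 2 * a / denom
      out[denom == 0] <- NA_real_
      out
    },
    simple_matching = {
      dd <- tcrossprod(1 - m)
      1 - (a + dd) / nb
    },
    jaccard = {
      denom <- outer(ones, ones, `+`) - a
      out <- 1 - a / denom
      out[denom == 0] <- NA_real_
      out
    })
  diag(d) <- 0
  if (anyNA(d)) warning("distance undefined for all-zero sample pair(s); set to NA",
                        call. = FALSE)
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Standard agglomeration with cluster-size-weighted arithmetic-mean linkage;
#' a merge at distance `d` sits at height `d/2`, so the tree is ultrametric.
#' Ties are broken deterministically: among the candidate pairs at the
#' minimum distance, the pair whose merged leaf set is lexicographically
#' smallest is merged first.
#'
#' @param d symmetric non-negative distance matrix with labelled rows, or a
#'   `dist` object.
#' @return rooted ultrametric tree of class `phylo` (ape).
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2L)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (anyNA(d)) stop("distance matrix contains NA", call. = FALSE)
  if (any(d < 0)) stop("distance matrix has negative entries", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric", call. = FALSE)

  labels <- rownames(d)
  n <- nrow(d)
  active <- seq_len(n)
  members <- lapply(labels, identity)         # sorted label vectors
  keys <- vapply(members, function(m) paste(m, collapse = "\001"), character(1))
  heights <- rep(0, n)
  newick <- labels
  sizes <- rep(1L, n)
  D <- d

  for (step in seq_len(n - 1L)) {
    # minimum over active pairs
    best <- NULL; dmin <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_len(ii - 1L)) {
        i <- active[ii]; j <- active[jj]
        if (D[i, j] < dmin - 1e-15) {
          dmin <- D[i, j]; best <- list(c(i, j))
        } else if (abs(D[i, j] - dmin) <= 1e-15) {
          best[[length(best) + 1L]] <- c(i, j)
        }
      }
    }
    if (length(best) > 1L) {
      merged_keys <- vapply(best, function(p) {
        paste(sort(c(members[[p[1]]], members[[p[2]]])), collapse = "\001")
      }, character(1))
      best <- best[order(merged_keys)]
    }
    i <- best[[1]][1]; j <- best[[1]][2]
    h <- dmin / 2
    k <- length(members) + 1L
    members[[k]] <- sort(c(members[[i]], members[[j]]))
    heights[k] <- h
    sizes[k] <- sizes[i] + sizes[j]
    # put the lexicographically smaller child first for a canonical newick
    ord <- order(c(keys[i], keys[j]))
    ch <- c(i, j)[ord]
    newick[k] <- sprintf("(%s:%.12g,%s:%.12g)",
                         newick[ch[1]], h - heights[ch[1]],
                         newick[ch[2]], h - heights[ch[2]])
    keys[k] <- paste(members[[k]], collapse = "\001")
    # weighted-average update
    D <- rbind(cbind(D, 0), 0)
    for (m2 in active) {
      if (m2 == i || m2 == j) next
      D[k, m2] <- D[m2, k] <- (sizes[i] * D[i, m2] + sizes[j] * D[j, m2]) /
        (sizes[i] + sizes[j])
    }
    active <- c(setdiff(active, c(i, j)), k)
  }
  tree <- ape::read.tree(text = paste0(newick[length(newick)], ";"))
  tree
}

# Canonical key of the bipartition separating `clade` from the other labels.
split_key <- function(clade, all_labels) {
  other <- setdiff(all_labels, clade)
  a <- paste(sort(clade), collapse = "\001")
  b <- paste(sort(other), collapse = "\001")
  if (a < b) a else b
}

# Bipartition keys of every internal node of a phylo tree, in node order.
tree_split_keys <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- tree$tip.label
  vapply(pp, function(idx) split_key(labs[idx], labs), character(1))
}

#' UPGMA tree with bootstrap support
#'
#' Band columns are resampled with replacement `replicates` times; the tree
#' is rebuilt on each resample and the support of every internal node of the
#' full-data tree is the percentage of replicate trees containing the same
#' leaf bipartition. Fully reproducible for a given seed.
#'
#' @param m binary band matrix (samples x bands).
#' @param replicates bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param coefficient distance coefficient (see [band_distance()]).
#' @return `phylo` tree of the full data with `node.label` holding percent
#'   support (0-100).
#' @export
upgma_bootstrap <- function(m, replicates = 1000L, seed = 1L,
                            coefficient = "dice") {
  stopifnot(replicates >= 1L)
  full <- upgma(band_distance(m, coefficient))
  keys <- tree_split_keys(full)
  counts <- setNames(rep(0L, length(keys)), keys)
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      dr <- suppressWarnings(band_distance(m[, cols, drop = FALSE], coefficient))
      if (anyNA(dr)) next  # degenerate resample: no shared bands for a pair
      tr <- upgma(dr)
      rk <- unique(tree_split_keys(tr))
      present <- keys %in% rk
      counts[present] <- counts[present] + 1L
    }
  })
  full$node.label <- as.character(round(100 * counts / replicates))
  full
}

#' Root-to-tip heights of an ultrametric tree
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return numeric vector of root-to-tip path lengths, one per tip.
#' @export
tip_heights <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  setNames(depths[seq_along(tree$tip.label)], tree$tip.label)
}
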