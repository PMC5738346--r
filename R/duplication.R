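# Duplication-block detection from anchor pairs: multi-site markers (e-PCR
# hits of the same marker at two or more genomic sites) or gene pairs from
# protein BLAST, chained into collinear blocks by a longest-increasing /
# longest-decreasing subsequence DP with an ordinal gap constraint.

empty_anchors <- function() {
  data.frame(anchor_id = character(0), a_seq = character(0), b_seq = character(0),
             a_pos = integer(0), b_pos = integer(0),
             a_start = integer(0), a_end = integer(0),
             b_start = integer(0), b_end = integer(0),
             source = character(0), tandem = logical(0), stringsAsFactors = FALSE)
}

#' Anchor pairs from multi-site marker hits
#'
#' Every marker with at least `min_sites` e-PCR hits contributes one anchor
#' per unordered pair of its hits. Ordinal positions (`a_pos`, `b_pos`) are
#' the ranks of the hit start positions among all hits supplied, per
#' sequence (the marker analogue of gene rank along a chromosome). Pairs whose two hits overlap are dropped; pairs
#' on one sequence closer than `tandem_dist` are flagged `tandem` (they
#' represent tandem rather than segmental duplication and are excluded from
#' chaining).
#'
#' @param hits e-PCR hit data frame (from [epcr()]).
#' @param min_sites minimum number of sites per marker (default 2).
#' @param tandem_dist distance in bp below which a same-sequence pair is
#'   tandem (default 10000).
#' @return anchor data frame: `anchor_id`, `a_seq`, `b_seq`, `a_pos`,
#'   `b_pos`, `a_start`, `a_end`, `b_start`, `b_end`, `source`, `tandem`;
#'   ordered so that (a_seq, a_pos) <= (b_seq, b_pos).
#' @export
ssr_anchors <- function(hits, min_sites = 2L, tandem_dist = 10000L) {
  counts <- table(hits$marker_id)
  multi <- names(counts)[counts >= min_sites]
  if (length(multi) == 0L) return(empty_anchors())
  # ordinal rank of each hit along its sequence, over ALL hits supplied (the
  # marker analogue of gene rank), so gap constraints see the true spacing
  h <- hits
  h$rank <- NA_integer_
  for (sid in unique(h$seq_id)) {
    i <- which(h$seq_id == sid)
    h$rank[i] <- rank(h$start[i], ties.method = "first")
  }
  h <- h[h$marker_id %in% multi, , drop = FALSE]
  rows <- list()
  for (mk in multi) {
    hm <- h[h$marker_id == mk, , drop = FALSE]
    n <- nrow(hm)
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        x <- hm[i, ]; y <- hm[j, ]
        # orient so a <= b by (seq, rank)
        if (x$seq_id > y$seq_id || (x$seq_id == y$seq_id && x$rank > y$rank)) {
          tmp <- x; x <- y; y <- tmp
        }
        if (x$seq_id == y$seq_id && ivl_overlaps(x$start, x$end, y$start, y$end)) next
        tandem <- x$seq_id == y$seq_id && (y$start - x$end) < tandem_dist
        rows[[length(rows) + 1L]] <- data.frame(
          anchor_id = sprintf("%s|%s:%d|%s:%d", mk, x$seq_id, x$start, y$seq_id, y$start),
          a_seq = x$seq_id, b_seq = y$seq_id,
          a_pos = x$rank, b_pos = y$rank,
          a_start = x$start, a_end = x$end, b_start = y$start, b_end = y$end,
          source = "ssr", tandem = tandem, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$anchor_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Anchor pairs from protein BLAST hits and gene positions
#'
#' Each BLAST row linking two annotated genes becomes one anchor; ordinals
#' are gene ranks along their sequences (by start position). Symmetric
#' duplicates (A-B and B-A) collapse to one anchor.
#'
#' @param blast data frame from [read_blast_tabular()].
#' @param genes a `gene_models` object providing gene positions.
#' @param tandem_dist see [ssr_anchors()].
#' @return anchor data frame in the [ssr_anchors()] layout, `source = "gene"`.
#' @export
gene_anchors <- function(blast, genes, tandem_dist = 10000L) {
  if (length(genes) == 0L || nrow(blast) == 0L) return(empty_anchors())
  info <- data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    seq_id = vapply(genes, `[[`, "", "seq_id"),
    start = vapply(genes, function(g) min(g$exons[, "start"]), integer(1)),
    end = vapply(genes, function(g) max(g$exons[, "end"]), integer(1)),
    stringsAsFactors = FALSE)
  info$rank <- NA_integer_
  for (sid in unique(info$seq_id)) {
    i <- which(info$seq_id == sid)
    info$rank[i] <- rank(info$start[i], ties.method = "first")
  }
  rownames(info) <- info$gene_id
  keep <- blast$query %in% info$gene_id & blast$subject %in% info$gene_id &
    blast$query != blast$subject
  b <- blast[keep, , drop = FALSE]
  if (nrow(b) == 0L) return(empty_anchors())
  rows <- list()
  for (i in seq_len(nrow(b))) {
    x <- info[b$query[i], ]; y <- info[b$subject[i], ]
    if (x$seq_id > y$seq_id || (x$seq_id == y$seq_id && x$rank > y$rank)) {
      tmp <- x; x <- y; y <- tmp
    }
    tandem <- x$seq_id == y$seq_id && (y$start - x$end) < tandem_dist
    rows[[length(rows) + 1L]] <- data.frame(
      anchor_id = sprintf("%s|%s", x$gene_id, y$gene_id),
      a_seq = x$seq_id, b_seq = y$seq_id, a_pos = x$rank, b_pos = y$rank,
      a_start = x$start, a_end = x$end, b_start = y$start, b_end = y$end,
      source = "gene", tandem = tandem, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$anchor_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Longest valid chain among anchors (rows of `a`, sorted by (a_pos, b_pos)),
# for one orientation. Returns the lexicographically smallest maximum-length
# chain as a vector of row indices, or integer(0).
best_chain_dp <- function(a, orientation, max_gap) {
  n <- nrow(a)
  if (n == 0L) return(integer(0))
  ok_edge <- function(i, j) {
    # i precedes j
    da <- a$a_pos[j] - a$a_pos[i]
    if (da <= 0L || da > max_gap) return(FALSE)
    db <- a$b_pos[j] - a$b_pos[i]
    if (orientation == "same") db > 0L && db <= max_gap
    else db < 0L && -db <= max_gap
  }
  # L[i]: longest chain starting at i (computed right to left)
  L <- rep(1L, n)
  for (i in seq(n, 1L)) {
    for (j in seq_len(n)) {
      if (j > i && ok_edge(i, j) && L[j] + 1L > L[i]) L[i] <- L[j] + 1L
    }
  }
  maxlen <- max(L)
  if (maxlen < 1L) return(integer(0))
  # greedy forward extraction of the lexicographically smallest max chain
  chain <- integer(0)
  need <- maxlen
  prev <- 0L
  while (need > 0L) {
    for (i in seq_len(n)) {
      if (i <= prev) next
      if (L[i] == need && (prev == 0L || ok_edge(prev, i))) {
        chain <- c(chain, i); prev <- i; break
      }
    }
    need <- need - 1L
  }
  chain
}

#' Chain anchors into collinear duplication blocks
#'
#' Anchors of one (a_seq, b_seq) pair are chained by a longest-increasing
#' (same orientation) and longest-decreasing (inverted) subsequence dynamic
#' programme under the constraint that consecutive chain members are at most
#' `max_gap` ordinals apart on both axes. Blocks are extracted greedily:
#' the maximum-length chain is removed (same orientation preferred on ties;
#' among equal-length chains the lexicographically smallest index sequence is
#' taken), and the process repeats until no chain reaches `min_block`. No
#' anchor belongs to two blocks.
#'
#' @param anchors anchor data frame (see [ssr_anchors()]); `tandem` rows
#'   should be filtered out by the caller.
#' @param min_block minimum chain length of a reported block (default 5).
#' @param max_gap maximum ordinal gap between consecutive anchors (default 25).
#' @return data frame of blocks: `block_id`, `a_seq`, `a_start`, `a_end`,
#'   `b_seq`, `b_start`, `b_end`, `orientation`, `n_anchors`, plus a list
#'   column `anchor_ids`; ordered by (a_seq, a_start).
#' @export
chain_anchors <- function(anchors, min_block = 5L, max_gap = 25L) {
  empty <- data.frame(block_id = character(0), a_seq = character(0),
                      a_start = integer(0), a_end = integer(0),
                      b_seq = character(0), b_start = integer(0), b_end = integer(0),
                      orientation = character(0), n_anchors = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(anchors) == 0L) { empty$anchor_ids <- list(); return(empty) }
  blocks <- list()
  for (grp in split(seq_len(nrow(anchors)),
                    paste(anchors$a_seq, anchors$b_seq, sep = "\001"))) {
    a <- anchors[grp, , drop = FALSE]
    a <- a[order(a$a_pos, a$b_pos), , drop = FALSE]
    repeat {
      c_same <- best_chain_dp(a, "same", max_gap)
      c_inv <- best_chain_dp(a, "inverted", max_gap)
      len_same <- length(c_same); len_inv <- length(c_inv)
      if (max(len_same, len_inv) < min_block) break
      if (len_same >= len_inv) { ch <- c_same; orientation <- "same" }
      else { ch <- c_inv; orientation <- "inverted" }
      sel <- a[ch, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <- data.frame(
        a_seq = sel$a_seq[1], a_start = min(sel$a_start), a_end = max(sel$a_end),
        b_seq = sel$b_seq[1], b_start = min(sel$b_start), b_end = max(sel$b_end),
        orientation = orientation, n_anchors = nrow(sel),
        anchor_ids = I(list(sel$anchor_id)), stringsAsFactors = FALSE)
      a <- a[-ch, , drop = FALSE]
      if (nrow(a) == 0L) break
    }
  }
  if (length(blocks) == 0L) { empty$anchor_ids <- list(); return(empty) }
  out <- do.call(rbind, blocks)
  out <- out[order(out$a_seq, out$a_start, out$b_seq, out$b_start), , drop = FALSE]
  out <- cbind(block_id = sprintf("block_%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Overlap statistics between two block sets
#'
#' Two blocks overlap when both their spans intersect under either pairing of
#' axes (a-a and b-b, or a-b and b-a).
#'
#' @param gene_blocks,ssr_blocks block data frames from [chain_anchors()].
#' @return list with `n_gene`, `n_ssr`, `n_gene_overlapping`,
#'   `n_ssr_overlapping`, `pct_gene`, `pct_ssr`.
#' @export
block_overlap <- function(gene_blocks, ssr_blocks) {
  span_hits <- function(x, y) {
    # does block x overlap block y under either axis pairing?
    direct <- x$a_seq == y$a_seq && ivl_overlaps(x$a_start, x$a_end, y$a_start, y$a_end) &&
      x$b_seq == y$b_seq && ivl_overlaps(x$b_start, x$b_end, y$b_start, y$b_end)
    crossed <- x$a_seq == y$b_seq && ivl_overlaps(x$a_start, x$a_end, y$b_start, y$b_end) &&
      x$b_seq == y$a_seq && ivl_overlaps(x$b_start, x$b_end, y$a_start, y$a_end)
    direct || crossed
  }
  g_hit <- rep(FALSE, nrow(gene_blocks))
  s_hit <- rep(FALSE, nrow(ssr_blocks))
  for (i in seq_len(nrow(gene_blocks))) {
    for (j in seq_len(nrow(ssr_blocks))) {
      if (span_hits(gene_blocks[i, ], ssr_blocks[j, ])) {
        g_hit[i] <- TRUE; s_hit[j] <- TRUE
      }
    }
  }
  list(n_gene = nrow(gene_blocks), n_ssr = nrow(ssr_blocks),
       n_gene_overlapping = sum(g_hit), n_ssr_overlapping = sum(s_hit),
       pct_gene = if (nrow(gene_blocks) == 0L) NA_real_ else 100 * mean(g_hit),
       pct_ssr = if (nrow(ssr_blocks) == 0L) NA_real_ else 100 * mean(s_hit))
}

#' Write duplication blocks as TSV, plus a two-interval link list
#'
#' @param blocks block data frame from [chain_anchors()].
#' @param path output TSV path; the link list goes to `<path>.links.tsv`.
#' @return invisibly, `path`.
#' @export
write_block_table <- function(blocks, path) {
  cols <- c("block_id", "a_seq", "a_start", "a_end", "b_seq", "b_start",
            "b_end", "orientation", "n_anchors")
  write.table(blocks[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  links <- blocks[, c("a_seq", "a_start", "a_end", "b_seq", "b_start", "b_end"),
                  drop = FALSE]
  write.table(links, paste0(path, ".links.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
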