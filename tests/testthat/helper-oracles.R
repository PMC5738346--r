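# Brute-force reference implementations, deliberately written along different
# routes than the package code, plus shared random-sequence helpers.

random_dna <- function(n, freq = rep(0.25, 4)) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freq),
         collapse = "")
}

# --- SSR scanning oracle: explicit motif-copy extension from every start ----
# A locus starts at i (1-based) for motif length k when two full copies sit at
# i, the region is leftmost (the lag-k equality fails just before i), the unit
# is primitive and N-free, and the number of consecutive full copies reaches
# the class threshold.
oracle_scan_ssr <- function(seq, min_repeats = default_min_repeats()) {
  n <- nchar(seq)
  rows <- list()
  for (k in 1:7) {
    if (n < 2L * k || n < k * min_repeats[k]) next
    starts <- seq_len(n - 2L * k + 1L)
    first <- substring(seq, starts, starts + k - 1L)
    second <- substring(seq, starts + k, starts + 2L * k - 1L)
    cand <- starts[first == second & !grepl("N", first)]
    for (i in cand) {
      if (i > 1L && substr(seq, i - 1L, i - 1L) == substr(seq, i + k - 1L, i + k - 1L)) {
        next  # not the leftmost phase of its periodic region
      }
      motif <- substr(seq, i, i + k - 1L)
      if (!is_primitive_motif(motif)) next
      copies <- 2L
      while (i + (copies + 1L) * k - 1L <= n &&
             substr(seq, i + copies * k, i + (copies + 1L) * k - 1L) == motif) {
        copies <- copies + 1L
      }
      if (copies < min_repeats[k]) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = i - 1L, end = i - 1L + copies * k, class_k = k,
        motif = canonical_motif(motif), motif_as_found = motif,
        repeat_count = copies, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), class_k = integer(0),
                      motif = character(0), motif_as_found = character(0),
                      repeat_count = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$class_k), , drop = FALSE]
}

# --- naive e-PCR oracle: test every genome position directly ---------------
# 0-based starts where `primer` (as given) matches with <= mm mismatches and
# zero mismatches in the `tpe` bases at the `end3` end of the match.
oracle_sites <- function(gchars, primer, mm, tpe, end3) {
  pc <- strsplit(primer, "", fixed = TRUE)[[1]]
  len <- length(pc)
  n <- length(gchars)
  if (n < len) return(integer(0))
  n_pos <- n - len + 1L
  mism <- integer(n_pos)
  tail_mism <- integer(n_pos)
  tail_off <- if (end3 == "right") seq(len - min(tpe, len) + 1L, len)
              else seq_len(min(tpe, len))
  for (j in seq_len(len)) {
    bad <- gchars[j:(j + n_pos - 1L)] != pc[j]
    mism <- mism + bad
    if (j %in% tail_off) tail_mism <- tail_mism + bad
  }
  which(mism <= mm & tail_mism == 0L) - 1L
}

oracle_epcr <- function(marker, genome, params) {
  fp <- marker$forward_primer; rp <- marker$reverse_primer
  lf <- nchar(fp); lr <- nchar(rp)
  rows <- list()
  for (sid in names(genome$seq)) {
    gchars <- strsplit(genome$seq[[sid]], "", fixed = TRUE)[[1]]
    fP <- oracle_sites(gchars, fp, params$max_mismatches, params$three_prime_exact, "right")
    rM <- oracle_sites(gchars, rev_comp(rp), params$max_mismatches,
                       params$three_prime_exact, "left")
    for (s1 in fP) for (s2 in rM) {
      if (s2 < s1 + lf) next
      prod <- s2 + lr - s1
      if (prod < params$min_product || prod > params$max_product) next
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = sid, start = s1, end = s2 + lr, strand = "+",
        product_bp = as.integer(prod), stringsAsFactors = FALSE)
    }
    fM <- oracle_sites(gchars, rev_comp(fp), params$max_mismatches,
                       params$three_prime_exact, "left")
    rP <- oracle_sites(gchars, rp, params$max_mismatches, params$three_prime_exact, "right")
    for (t1 in fM) for (t2 in rP) {
      if (t1 < t2 + lr) next
      prod <- t1 + lf - t2
      if (prod < params$min_product || prod > params$max_product) next
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = sid, start = t2, end = t1 + lf, strand = "-",
        product_bp = as.integer(prod), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(seq_id = character(0), start = integer(0), end = integer(0),
                      strand = character(0), product_bp = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$seq_id, out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- band-distance oracle: per-pair cell counting ---------------------------
oracle_band_distance <- function(m, coefficient) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- sum(m[i, ] == 1 & m[j, ] == 1)
    b <- sum(m[i, ] == 1 & m[j, ] == 0)
    c <- sum(m[i, ] == 0 & m[j, ] == 1)
    dd <- sum(m[i, ] == 0 & m[j, ] == 0)
    d[i, j] <- switch(coefficient,
      dice = if (2 * a + b + c == 0) NA_real_ else 1 - 2 * a / (2 * a + b + c),
      simple_matching = 1 - (a + dd) / ncol(m),
      jaccard = if (a + b + c == 0) NA_real_ else 1 - a / (a + b + c))
  }
  d
}

# --- collinear-chaining oracle: exhaustive DFS over all valid chains --------
# Mirrors the package contract (greedy extraction of the maximum-length chain,
# same orientation preferred on ties, lexicographically smallest index
# sequence) but finds each best chain by enumerating every chain.
oracle_best_chain <- function(a, orientation, max_gap) {
  n <- nrow(a)
  if (n == 0L) return(integer(0))
  ok <- function(i, j) {
    da <- a$a_pos[j] - a$a_pos[i]
    if (da <= 0L || da > max_gap) return(FALSE)
    db <- a$b_pos[j] - a$b_pos[i]
    if (orientation == "same") db > 0L && db <= max_gap
    else db < 0L && -db <= max_gap
  }
  best <- integer(0)
  dfs <- function(chain) {
    if (length(chain) > length(best)) best <<- chain
    last <- chain[length(chain)]
    for (j in seq_len(n)) {
      if (j > last && ok(last, j)) dfs(c(chain, j))
    }
  }
  for (i in seq_len(n)) dfs(i)
  best
}

oracle_chain_anchors <- function(anchors, min_block = 5L, max_gap = 25L) {
  blocks <- list()
  for (grp in split(seq_len(nrow(anchors)),
                    paste(anchors$a_seq, anchors$b_seq, sep = "\001"))) {
    a <- anchors[grp, , drop = FALSE]
    a <- a[order(a$a_pos, a$b_pos), , drop = FALSE]
    repeat {
      cs <- oracle_best_chain(a, "same", max_gap)
      ci <- oracle_best_chain(a, "inverted", max_gap)
      if (max(length(cs), length(ci)) < min_block) break
      if (length(cs) >= length(ci)) { ch <- cs; ori <- "same" }
      else { ch <- ci; ori <- "inverted" }
      sel <- a[ch, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <- data.frame(
        a_seq = sel$a_seq[1], a_start = min(sel$a_start), a_end = max(sel$a_end),
        b_seq = sel$b_seq[1], b_start = min(sel$b_start), b_end = max(sel$b_end),
        orientation = ori, n_anchors = nrow(sel), stringsAsFactors = FALSE)
      a <- a[-ch, , drop = FALSE]
      if (nrow(a) == 0L) break
    }
  }
  if (length(blocks) == 0L) {
    return(data.frame(a_seq = character(0), a_start = integer(0), a_end = integer(0),
                      b_seq = character(0), b_start = integer(0), b_end = integer(0),
                      orientation = character(0), n_anchors = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, blocks)
  out <- out[order(out$a_seq, out$a_start, out$b_seq, out$b_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random anchor sets for the chaining property test
random_anchors <- function(n, n_pos = 15L) {
  data.frame(anchor_id = paste0("a", seq_len(n)),
             a_seq = "s1", b_seq = "s2",
             a_pos = sample.int(n_pos, n, replace = TRUE),
             b_pos = sample.int(n_pos, n, replace = TRUE),
             a_start = integer(n), a_end = integer(n) + 1L,
             b_start = integer(n), b_end = integer(n) + 1L,
             source = "ssr", tandem = FALSE, stringsAsFactors = FALSE)
}
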