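# SSR mining: detection of perfect tandem repeats of 1-7 bp motifs under
# per-class minimum repeat-count thresholds, canonical motif normalization
# (equivalence under cyclic rotation and reverse complementation), and
# composition statistics over the detected loci.

#' Default per-class minimum repeat counts
#'
#' Monomers require at least 12 repeats, dimers 6, trimers 4, tetramers 3,
#' pentamers 3, hexamers 2 and heptamers 2.
#'
#' @return integer vector of length 7, `min_repeats[k]` for motif length `k`.
#' @export
default_min_repeats <- function() c(12L, 6L, 4L, 3L, 3L, 2L, 2L)

#' Is a motif primitive?
#'
#' A motif is primitive when it is not a whole-number repetition of a shorter
#' motif (`ATAT` is not a primitive tetramer).
#'
#' @param motif character vector of DNA motifs.
#' @return logical vector.
#' @export
is_primitive_motif <- function(motif) {
  vapply(motif, function(m) {
    k <- nchar(m)
    if (k <= 1L) return(TRUE)
    for (d in seq_len(k - 1L)) {
      if (k %% d == 0L && strrep(substr(m, 1L, d), k / d) == m) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

rotations <- function(m) {
  k <- nchar(m)
  vapply(seq_len(k) - 1L,
         function(i) paste0(substr(m, i + 1L, k), substr(m, 1L, i)),
         character(1))
}

#' Canonical form of an SSR motif
#'
#' The canonical motif is the lexicographically smallest string among all
#' cyclic rotations of the motif and of its reverse complement, so that for
#' example `AC`, `CA`, `TG` and `GT` all normalize to `AC`. Motifs containing
#' `N` or non-primitive motifs are rejected.
#'
#' @param motif character vector of primitive DNA motifs (length 1-7).
#' @return character vector of canonical motifs.
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    if (grepl("[^ACGT]", m)) stop("motif must be over {A,C,G,T}: ", m, call. = FALSE)
    if (nchar(m) < 1L || nchar(m) > 7L) stop("motif length must be 1-7: ", m, call. = FALSE)
    if (!is_primitive_motif(m)) stop("motif is not primitive: ", m, call. = FALSE)
    min(c(rotations(m), rotations(rev_comp(m))))
  }, character(1), USE.NAMES = FALSE)
}

# Scan one sequence string for perfect SSR loci. For each motif length k the
# lag-k character equality vector is run-length encoded; a TRUE run of length
# m marks a periodic region of m+k bases containing floor((m+k)/k) full motif
# copies. The locus is placed at the leftmost phase of the region, which makes
# it maximal: it cannot be extended by one full motif copy on either side.
# Positions holding N never match, so runs break at N.
scan_one_seq <- function(seq, seq_id, species_id, min_repeats) {
  n <- nchar(seq)
  res <- list()
  if (n >= 2L) {
    x <- charToRaw(seq)
    is_n <- x == as.raw(78L)  # 'N'
    for (k in 1:7) {
      need <- k * min_repeats[k]
      if (n < need) next
      eq <- x[seq_len(n - k)] == x[(k + 1L):n]
      eq[is_n[seq_len(n - k)] | is_n[(k + 1L):n]] <- FALSE
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- which(r$values & r$lengths >= k * (min_repeats[k] - 1L))
      for (j in keep) {
        i <- starts[j]                      # 1-based start of periodic region
        rc <- (r$lengths[j] + k) %/% k      # full motif copies
        unit <- substr(seq, i, i + k - 1L)
        if (!is_primitive_motif(unit)) next
        res[[length(res) + 1L]] <- list(
          seq_id = seq_id, start = i - 1L, end = i - 1L + rc * k,
          class_k = k, motif = canonical_motif(unit), motif_as_found = unit,
          repeat_count = rc, species = species_id)
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(species = character(0), seq_id = character(0),
                      start = integer(0), end = integer(0), class_k = integer(0),
                      motif = character(0), motif_as_found = character(0),
                      repeat_count = integer(0), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    species = vapply(res, `[[`, "", "species"),
    seq_id = vapply(res, `[[`, "", "seq_id"),
    start = vapply(res, `[[`, 0L, "start"),
    end = vapply(res, `[[`, 0L, "end"),
    class_k = vapply(res, `[[`, 0L, "class_k"),
    motif = vapply(res, `[[`, "", "motif"),
    motif_as_found = vapply(res, `[[`, "", "motif_as_found"),
    repeat_count = vapply(res, `[[`, 0L, "repeat_count"),
    stringsAsFactors = FALSE)
  df[order(df$start, df$class_k), , drop = FALSE]
}

#' Scan a genome for perfect SSR loci
#'
#' Every maximal perfect tandem run of a primitive 1-7 bp motif meeting its
#' class threshold is reported exactly once, with the motif stored in
#' canonical form and the phase actually present at the locus start kept in
#' `motif_as_found`. Each motif-length class is scanned independently. Runs
#' never cross an `N`.
#'
#' @param genome a [genome_set()].
#' @param min_repeats integer vector of length 7: minimum repeat count per
#'   motif length (defaults to [default_min_repeats()]).
#' @return data frame of loci: `species`, `seq_id`, `start`, `end` (0-based
#'   half-open), `class_k`, `motif`, `motif_as_found`, `repeat_count`,
#'   sorted by (seq_id, start, class_k).
#' @export
scan_ssr <- function(genome, min_repeats = default_min_repeats()) {
  stopifnot(inherits(genome, "genome_set"), length(min_repeats) == 7L,
            all(min_repeats >= 2L))
  min_repeats <- as.integer(min_repeats)
  parts <- lapply(names(genome$seq), function(sid) {
    scan_one_seq(genome$seq[[sid]], sid, genome$species_id, min_repeats)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Per-class counts and percentages of SSR loci
#'
#' @param loci data frame from [scan_ssr()].
#' @return data frame with `class_k` (1-7), `count` and `percent`;
#'   percentages are `NA` when the input is empty.
#' @export
ssr_class_table <- function(loci) {
  counts <- vapply(1:7, function(k) sum(loci$class_k == k), integer(1))
  total <- sum(counts)
  pct <- if (total == 0L) rep(NA_real_, 7) else 100 * counts / total
  data.frame(class_k = 1:7, count = counts, percent = pct)
}

#' A/T versus G/C base composition over SSR locus spans
#'
#' Counts A+T and G+C characters across the genomic spans of the given loci.
#'
#' @param loci data frame from [scan_ssr()].
#' @param genome the scanned [genome_set()].
#' @return list with `at`, `gc` and `ratio` (AT/GC; `Inf` when GC is zero).
#' @export
ssr_base_composition <- function(loci, genome) {
  at <- 0L; gc <- 0L
  if (nrow(loci) > 0L) {
    for (i in seq_len(nrow(loci))) {
      s <- substr(genome$seq[[loci$seq_id[i]]], loci$start[i] + 1L, loci$end[i])
      n_gc <- nchar(gsub("[^GC]", "", s))
      n_at <- nchar(gsub("[^AT]", "", s))
      at <- at + n_at; gc <- gc + n_gc
    }
  }
  list(at = at, gc = gc, ratio = if (gc == 0L) Inf else at / gc)
}

#' Cut 60-bp primer precursor flanks around loci
#'
#' Returns, for each locus, the `flank_len` bases immediately to the left and
#' right of its interval. A locus is rejected when either flank would be
#' truncated by a sequence end or contains `N`.
#'
#' @param loci data frame with `seq_id`, `start`, `end` (and optionally
#'   `motif`, `repeat_count`) as from [scan_ssr()].
#' @param genome the [genome_set()] the loci live on.
#' @param flank_len flank length in bases (default 60).
#' @return the input data frame with added columns `left_flank`,
#'   `right_flank` and `reject_reason` (`NA` for usable loci).
#' @export
ssr_precursors <- function(loci, genome, flank_len = 60L) {
  n <- nrow(loci)
  left <- right <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- genome$seq[[loci$seq_id[i]]]
    st <- loci$start[i]; en <- loci$end[i]
    if (st - flank_len < 0L) { reason[i] <- "left flank truncated"; next }
    if (en + flank_len > nchar(s)) { reason[i] <- "right flank truncated"; next }
    lf <- substr(s, st - flank_len + 1L, st)
    rf <- substr(s, en + 1L, en + flank_len)
    if (grepl("N", lf, fixed = TRUE) || grepl("N", rf, fixed = TRUE)) {
      reason[i] <- "ambiguous flank"; next
    }
    left[i] <- lf; right[i] <- rf
  }
  cbind(loci, data.frame(left_flank = left, right_flank = right,
                         reject_reason = reason, stringsAsFactors = FALSE))
}

#' Export SSR loci as a BED6 track
#'
#' The BED name is `motif x repeat_count` (e.g. `ACx6`).
#'
#' @param loci data frame from [scan_ssr()].
#' @param path output BED path.
#' @return invisibly, `path`.
#' @export
loci_to_bed <- function(loci, path) {
  df <- data.frame(seq_id = loci$seq_id, start = loci$start, end = loci$end,
                   name = paste0(loci$motif, "x", loci$repeat_count),
                   score = 0L, strand = "+", stringsAsFactors = FALSE)
  write_bed(df, path)
}
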