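# Deterministic primer design from 60-bp precursor flanks. One primer pair is
# chosen per flank pair by exhaustive window enumeration under hard
# constraints (length, Tm, GC, homopolymer, self-complementarity) with a
# transparent score; ties break to the leftmost forward, then leftmost
# reverse primer, so identical inputs always yield identical primers.

#' Primer design constraints
#'
#' @param len_range primer length range in nt (default 18-27).
#' @param opt_len optimum primer length (default 20).
#' @param tm_range allowed melting temperature range in degrees C (default 55-63).
#' @param opt_tm optimum Tm in degrees C (default 60).
#' @param gc_range allowed GC fraction range (default 0.35-0.65).
#' @param max_tm_diff maximum |Tm forward - Tm reverse| in degrees C (default 3).
#' @param max_homopolymer maximum homopolymer run inside a primer (default 4).
#' @param max_3prime_selfcomp maximum 3'-anchored self-complementary stretch
#'   (default 4).
#' @param max_anycomp maximum self-complementary stretch anywhere (default 8).
#' @return list of class `design_constraints`.
#' @export
design_constraints <- function(len_range = c(18L, 27L), opt_len = 20L,
                               tm_range = c(55, 63), opt_tm = 60,
                               gc_range = c(0.35, 0.65), max_tm_diff = 3,
                               max_homopolymer = 4L, max_3prime_selfcomp = 4L,
                               max_anycomp = 8L) {
  stopifnot(len_range[1] <= len_range[2], tm_range[1] <= tm_range[2],
            gc_range[1] <= gc_range[2])
  structure(list(len_range = as.integer(len_range), opt_len = as.integer(opt_len),
                 tm_range = tm_range, opt_tm = opt_tm, gc_range = gc_range,
                 max_tm_diff = max_tm_diff,
                 max_homopolymer = as.integer(max_homopolymer),
                 max_3prime_selfcomp = as.integer(max_3prime_selfcomp),
                 max_anycomp = as.integer(max_anycomp)),
            class = "design_constraints")
}

# SantaLucia (1998) unified nearest-neighbour parameters.
# dH in kcal/mol, dS in cal/(mol K), keyed by the top-strand dinucleotide.
nn_params <- local({
  dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
          GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
          CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, TG = -22.7,
          GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
          CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
  list(dH = dH, dS = dS,
       init_dH = c(AT = 2.3, GC = 0.1), init_dS = c(AT = 4.1, GC = -2.8),
       sym_dS = -1.4, R = 1.9872)
})

tm_from_sums <- function(dH, dS, len, symmetric, na_molar = 0.05, ct_molar = 250e-9) {
  dS <- dS + 0.368 * (len - 1) * log(na_molar)
  x <- ifelse(symmetric, 1, 4)
  1000 * dH / (dS + nn_params$R * log(ct_molar / x)) - 273.15
}

#' Nearest-neighbour melting temperature
#'
#' Duplex Tm from the unified nearest-neighbour thermodynamic parameter set,
#' with entropic salt correction at 50 mM Na+ and a total strand concentration
#' of 250 nM. Self-complementary primers get the symmetry correction and a
#' concentration factor of 1 instead of 4.
#'
#' @param primer character vector of DNA primers (length >= 8, no `N`).
#' @param na_molar monovalent cation concentration in mol/L (default 0.05).
#' @param ct_molar total strand concentration in mol/L (default 250e-9).
#' @return numeric vector of Tm in degrees C.
#' @export
primer_tm <- function(primer, na_molar = 0.05, ct_molar = 250e-9) {
  vapply(primer, function(p) {
    if (nchar(p) < 8L) stop("primer too short for NN Tm: ", p, call. = FALSE)
    if (grepl("[^ACGT]", p)) stop("primer contains non-ACGT characters: ", p, call. = FALSE)
    ch <- strsplit(p, "", fixed = TRUE)[[1]]
    nn <- paste0(ch[-length(ch)], ch[-1])
    dH <- sum(nn_params$dH[nn])
    dS <- sum(nn_params$dS[nn])
    for (endb in c(ch[1], ch[length(ch)])) {
      key <- if (endb %in% c("G", "C")) "GC" else "AT"
      dH <- dH + nn_params$init_dH[[key]]
      dS <- dS + nn_params$init_dS[[key]]
    }
    sym <- p == rev_comp(p)
    if (sym) dS <- dS + nn_params$sym_dS
    tm_from_sums(dH, dS, nchar(p), sym, na_molar, ct_molar)
  }, numeric(1), USE.NAMES = FALSE)
}

# All candidate windows of a flank with Tm computed from cumulative NN sums
# (identical result to primer_tm, O(1) per window).
tm_windows <- function(flank, len_range) {
  n <- nchar(flank)
  ch <- strsplit(flank, "", fixed = TRUE)[[1]]
  if (n < 2L) return(NULL)
  nn <- paste0(ch[-n], ch[-1])
  cumH <- c(0, cumsum(nn_params$dH[nn]))
  cumS <- c(0, cumsum(nn_params$dS[nn]))
  out <- list()
  for (len in seq(len_range[1], min(len_range[2], n))) {
    starts <- seq_len(n - len + 1L)              # 1-based window starts
    ends <- starts + len - 1L
    seqs <- substring(flank, starts, ends)
    endkey <- function(b) ifelse(b %in% c("G", "C"), "GC", "AT")
    k1 <- endkey(ch[starts]); k2 <- endkey(ch[ends])
    dH <- cumH[ends] - cumH[starts] +
      nn_params$init_dH[k1] + nn_params$init_dH[k2]
    dS <- cumS[ends] - cumS[starts] +
      nn_params$init_dS[k1] + nn_params$init_dS[k2]
    sym <- seqs == rev_comp(seqs)
    dS <- dS + ifelse(sym, nn_params$sym_dS, 0)
    out[[length(out) + 1L]] <- data.frame(
      start = starts - 1L, len = len, seq = seqs,
      tm = tm_from_sums(dH, dS, len, sym), gc = gc_frac(seqs),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Longest contiguous antiparallel complementary stretch between a and b:
# longest common substring of a and rev_comp(b), found by scanning the
# diagonals of the character-equality matrix.
comp_any <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(rev_comp(b), "", fixed = TRUE)[[1]]
  m <- length(x); n <- length(y)
  best <- 0L
  for (d in seq(-(m - 1L), n - 1L)) {
    i <- max(1L, 1L - d); j <- i + d
    L <- min(m - i, n - j) + 1L
    if (L <= best) next
    eq <- x[i:(i + L - 1L)] == y[j:(j + L - 1L)]
    r <- rle(eq)
    mx <- suppressWarnings(max(r$lengths[r$values], 0L))
    if (mx > best) best <- mx
  }
  best
}

# Longest 3'-anchored complementary stretch: largest L such that the reverse
# complement of a's 3'-terminal L bases occurs somewhere in b.
comp_3prime <- function(a, b) {
  la <- nchar(a)
  for (L in seq(min(la, nchar(b)), 1L)) {
    probe <- rev_comp(substr(a, la - L + 1L, la))
    if (grepl(probe, b, fixed = TRUE)) return(L)
  }
  0L
}

passing_windows <- function(flank, constraints, cap = 60L, as_revcomp = FALSE) {
  if (nchar(flank) < constraints$len_range[1]) return(NULL)
  w <- tm_windows(flank, constraints$len_range)
  if (is.null(w)) return(NULL)
  ok <- w$tm >= constraints$tm_range[1] & w$tm <= constraints$tm_range[2] &
    w$gc >= constraints$gc_range[1] & w$gc <= constraints$gc_range[2] &
    !grepl("N", w$seq, fixed = TRUE)
  w <- w[ok, , drop = FALSE]
  if (nrow(w) == 0L) return(w)
  w <- w[vapply(w$seq, max_homopolymer, integer(1)) <= constraints$max_homopolymer, ,
         drop = FALSE]
  if (nrow(w) == 0L) return(w)
  # keep the most promising candidates before the quadratic self-comp checks
  w <- w[order(abs(w$tm - constraints$opt_tm), w$start, w$len), , drop = FALSE]
  w <- head(w, cap)
  # self-complementarity applies to the primer as synthesized: for right
  # flanks that is the reverse complement of the window
  primer <- if (as_revcomp) rev_comp(w$seq) else w$seq
  keep <- vapply(primer, function(s) {
    comp_any(s, s) <= constraints$max_anycomp &&
      comp_3prime(s, s) <= constraints$max_3prime_selfcomp
  }, logical(1))
  w[keep, , drop = FALSE]
}

#' Design one primer pair from two precursor flanks
#'
#' The forward primer is a substring of the left flank; the reverse primer is
#' the reverse complement of a substring of the right flank. All windows
#' satisfying the hard constraints are enumerated; candidate pairs within
#' `max_tm_diff` are scored by summed |Tm - optimum|, length deviation, and
#' cross-complementarity penalties, and the single lowest-scoring pair is
#' returned (ties to the leftmost forward, then leftmost reverse primer).
#'
#' @param left_flank,right_flank DNA strings (normally 60 bp, N-free).
#' @param insert_len number of bases between the two flanks on the source
#'   sequence (the SSR or intron length); used for `expected_product_bp`.
#' @param constraints a [design_constraints()] object.
#' @return list with `ok = TRUE`, `forward`, `reverse`, `tm_forward`,
#'   `tm_reverse`, `gc_forward`, `gc_reverse`, `expected_product_bp`,
#'   `self_complementary`, and window bookkeeping (`f_start`, `f_len`,
#'   `r_start`, `r_len`); or `ok = FALSE` with a `reason`.
#' @export
design_primer_pair <- function(left_flank, right_flank, insert_len = 0L,
                               constraints = design_constraints()) {
  flank_len_l <- nchar(left_flank); flank_len_r <- nchar(right_flank)
  if (flank_len_l < constraints$len_range[1] || flank_len_r < constraints$len_range[1]) {
    return(list(ok = FALSE, reason = "flank shorter than minimum primer length"))
  }
  fw <- passing_windows(left_flank, constraints)
  if (is.null(fw) || nrow(fw) == 0L) {
    return(list(ok = FALSE, reason = "no passing forward window"))
  }
  rw <- passing_windows(right_flank, constraints, as_revcomp = TRUE)
  if (is.null(rw) || nrow(rw) == 0L) {
    return(list(ok = FALSE, reason = "no passing reverse window"))
  }
  # reverse primer is the revcomp of the right-flank window
  rw$primer <- rev_comp(rw$seq)

  fi <- rep(seq_len(nrow(fw)), each = nrow(rw))
  ri <- rep(seq_len(nrow(rw)), times = nrow(fw))
  ok_tm <- abs(fw$tm[fi] - rw$tm[ri]) <= constraints$max_tm_diff
  if (!any(ok_tm)) return(list(ok = FALSE, reason = "no pair within max_tm_diff"))
  fi <- fi[ok_tm]; ri <- ri[ok_tm]
  base <- abs(fw$tm[fi] - constraints$opt_tm) + abs(rw$tm[ri] - constraints$opt_tm) +
    0.25 * (abs(fw$len[fi] - constraints$opt_len) + abs(rw$len[ri] - constraints$opt_len))
  ord <- order(base, fw$start[fi], rw$start[ri], fw$len[fi], rw$len[ri])

  # lazy cross-complementarity penalty: scan pairs in base-score order and
  # stop once no remaining pair can beat the current best total
  best <- NULL; best_score <- Inf
  for (idx in ord) {
    if (base[idx] >= best_score) break
    f <- fw[fi[idx], ]; r <- rw[ri[idx], ]
    ca <- comp_any(f$seq, r$primer)
    c3 <- max(comp_3prime(f$seq, r$primer), comp_3prime(r$primer, f$seq))
    pen <- max(0L, ca - constraints$max_anycomp) +
      max(0L, c3 - constraints$max_3prime_selfcomp)
    score <- base[idx] + pen
    if (score < best_score) {
      best_score <- score
      best <- list(f = f, r = r,
                   selfcomp = ca > constraints$max_anycomp ||
                     c3 > constraints$max_3prime_selfcomp)
    }
  }
  f <- best$f; r <- best$r
  product <- (flank_len_l - f$start) + insert_len + (r$start + r$len)
  list(ok = TRUE, forward = f$seq, reverse = r$primer,
       tm_forward = f$tm, tm_reverse = r$tm,
       gc_forward = f$gc, gc_reverse = r$gc,
       expected_product_bp = as.integer(product),
       self_complementary = best$selfcomp,
       f_start = f$start, f_len = f$len, r_start = r$start, r_len = r$len)
}

#' Design primers for a precursor table
#'
#' Runs [design_primer_pair()] on every row of a precursor table and emits
#' the internal marker data frame. Precursor rows carrying a rejection reason
#' or failing design are dropped; their reasons are kept in the
#' `"rejections"` attribute of the result.
#'
#' @param precursors data frame with columns `source_id`, `type`, `species`,
#'   `seq_id`, `locus_start`, `locus_end`, `motif`, `repeat_count`,
#'   `left_flank`, `right_flank`, `reject_reason`.
#' @param constraints a [design_constraints()] object.
#' @return marker data frame (`marker_id`, `type`, `species`, `seq_id`,
#'   `locus_start`, `locus_end`, `motif`, `repeat_count`, `forward_primer`,
#'   `reverse_primer`, `expected_product_bp`, `status = "candidate"`).
#' @export
design_markers <- function(precursors, constraints = design_constraints()) {
  rows <- list(); rejections <- list()
  for (i in seq_len(nrow(precursors))) {
    p <- precursors[i, ]
    if (!is.na(p$reject_reason)) {
      rejections[[length(rejections) + 1L]] <-
        data.frame(source_id = p$source_id, reason = p$reject_reason,
                   stringsAsFactors = FALSE)
      next
    }
    d <- design_primer_pair(p$left_flank, p$right_flank,
                            insert_len = p$locus_end - p$locus_start,
                            constraints = constraints)
    if (!d$ok) {
      rejections[[length(rejections) + 1L]] <-
        data.frame(source_id = p$source_id, reason = d$reason,
                   stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      marker_id = paste0(p$type, "_", p$source_id),
      type = p$type, species = p$species, seq_id = p$seq_id,
      locus_start = p$locus_start, locus_end = p$locus_end,
      motif = p$motif, repeat_count = p$repeat_count,
      forward_primer = d$forward, reverse_primer = d$reverse,
      expected_product_bp = d$expected_product_bp,
      status = "candidate", stringsAsFactors = FALSE)
  }
  markers <- if (length(rows) > 0L) do.call(rbind, rows) else data.frame(
    marker_id = character(0), type = character(0), species = character(0),
    seq_id = character(0), locus_start = integer(0), locus_end = integer(0),
    motif = character(0), repeat_count = integer(0),
    forward_primer = character(0), reverse_primer = character(0),
    expected_product_bp = integer(0), status = character(0),
    stringsAsFactors = FALSE)
  rownames(markers) <- NULL
  attr(markers, "rejections") <-
    if (length(rejections) > 0L) do.call(rbind, rejections) else NULL
  markers
}
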