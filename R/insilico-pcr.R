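# Electronic PCR engine and the screens built on it: validation against the
# source genome, primer-identity deduplication, monomorphic/polymorphic
# classification, and the cross-genome universal-marker screen.

#' Electronic PCR parameters
#'
#' @param max_mismatches maximum mismatches allowed per primer site (default 0).
#' @param three_prime_exact number of 3'-terminal primer bases that must match
#'   exactly (default 3).
#' @param max_product maximum product size in bp (default 5000).
#' @param min_product minimum product size in bp (default 40).
#' @param max_hits_per_genome cap on reported hits per marker per genome
#'   (default 1000; exceeding it truncates with a warning).
#' @return list of class `epcr_params`.
#' @export
epcr_params <- function(max_mismatches = 0L, three_prime_exact = 3L,
                        max_product = 5000L, min_product = 40L,
                        max_hits_per_genome = 1000L) {
  structure(list(max_mismatches = as.integer(max_mismatches),
                 three_prime_exact = as.integer(three_prime_exact),
                 max_product = as.integer(max_product),
                 min_product = as.integer(min_product),
                 max_hits_per_genome = as.integer(max_hits_per_genome)),
            class = "epcr_params")
}

# 0-based start positions where `primer` binds the plus strand of `subject`
# (a DNAString) with <= mm mismatches; N in the genome never matches. The
# primer's `tpe` 3'-terminal bases must be exact. `end3` says which end of the
# plus-strand match carries the primer's 3' end ("right" for a plus-strand
# primer, "left" when the pattern is the primer's reverse complement).
match_sites <- function(subject, pattern, mm, tpe, end3) {
  if (nchar(pattern) > length(subject)) return(integer(0))
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                                max.mismatch = mm, fixed = TRUE)
  starts <- BiocGenerics::start(m)
  if (length(starts) == 0L || (mm == 0L && tpe >= 0L)) return(starts - 1L)
  plen <- nchar(pattern)
  tpe <- min(tpe, plen)
  if (tpe == 0L) return(starts - 1L)
  tail_pat <- if (end3 == "right") substr(pattern, plen - tpe + 1L, plen)
              else substr(pattern, 1L, tpe)
  keep <- vapply(starts, function(s) {
    w <- if (end3 == "right") {
      as.character(Biostrings::subseq(subject, s + plen - tpe, s + plen - 1L))
    } else {
      as.character(Biostrings::subseq(subject, s, s + tpe - 1L))
    }
    w == tail_pat
  }, logical(1))
  starts[keep] - 1L
}

#' Electronic PCR of markers against a genome
#'
#' A hit is reported wherever the forward primer binds one strand and the
#' reverse primer binds the opposite strand downstream, with the primer sites
#' disjoint and the 5'-to-5' product size within the configured bounds. Both
#' orientations are scanned; overlapping products of the same pair are all
#' reported. `N` in the genome matches nothing.
#'
#' @param markers marker data frame (needs `marker_id`, `forward_primer`,
#'   `reverse_primer`).
#' @param genome a [genome_set()].
#' @param params an [epcr_params()] object.
#' @return data frame of hits: `marker_id`, `species`, `seq_id`, `start`,
#'   `end` (0-based half-open), `strand` (of the forward primer),
#'   `product_bp`, sorted by (marker_id, seq_id, start).
#' @export
epcr <- function(markers, genome, params = epcr_params()) {
  subjects <- lapply(genome$seq, Biostrings::DNAString)
  hits <- list()
  empty <- data.frame(marker_id = character(0), species = character(0),
                      seq_id = character(0), start = integer(0), end = integer(0),
                      strand = character(0), product_bp = integer(0),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(markers))) {
    fp <- markers$forward_primer[i]; rp <- markers$reverse_primer[i]
    lf <- nchar(fp); lr <- nchar(rp)
    mk_hits <- list()
    for (sid in names(subjects)) {
      subj <- subjects[[sid]]
      # orientation +: F on plus strand, revcomp(R) downstream on plus strand
      f_plus <- match_sites(subj, fp, params$max_mismatches,
                            params$three_prime_exact, "right")
      r_minus <- match_sites(subj, rev_comp(rp), params$max_mismatches,
                             params$three_prime_exact, "left")
      if (length(f_plus) > 0L && length(r_minus) > 0L) {
        for (s1 in f_plus) {
          s2 <- r_minus[r_minus >= s1 + lf]
          prod <- s2 + lr - s1
          keep <- prod >= params$min_product & prod <= params$max_product
          if (any(keep)) {
            mk_hits[[length(mk_hits) + 1L]] <- data.frame(
              seq_id = sid, start = s1, end = s2[keep] + lr, strand = "+",
              product_bp = as.integer(prod[keep]), stringsAsFactors = FALSE)
          }
        }
      }
      # orientation -: revcomp(F) on plus strand, R upstream on plus strand
      f_minus <- match_sites(subj, rev_comp(fp), params$max_mismatches,
                             params$three_prime_exact, "left")
      r_plus <- match_sites(subj, rp, params$max_mismatches,
                            params$three_prime_exact, "right")
      if (length(f_minus) > 0L && length(r_plus) > 0L) {
        for (t1 in f_minus) {
          t2 <- r_plus[t1 >= r_plus + lr]
          prod <- t1 + lf - t2
          keep <- prod >= params$min_product & prod <= params$max_product
          if (any(keep)) {
            mk_hits[[length(mk_hits) + 1L]] <- data.frame(
              seq_id = sid, start = t2[keep], end = t1 + lf, strand = "-",
              product_bp = as.integer(prod[keep]), stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(mk_hits) == 0L) next
    h <- do.call(rbind, mk_hits)
    h <- h[order(h$seq_id, h$start, h$end, h$strand), , drop = FALSE]
    if (nrow(h) > params$max_hits_per_genome) {
      warning(sprintf("marker %s: %d hits capped at %d in genome %s",
                      markers$marker_id[i], nrow(h), params$max_hits_per_genome,
                      genome$species_id), call. = FALSE)
      h <- head(h, params$max_hits_per_genome)
    }
    hits[[length(hits) + 1L]] <- cbind(
      data.frame(marker_id = markers$marker_id[i], species = genome$species_id,
                 stringsAsFactors = FALSE), h)
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Validate markers by e-PCR against their source genome
#'
#' A marker is `validated` when at least one hit overlaps its source locus
#' with a product size within 20 percent of the expected product; otherwise it
#' is `rejected` with a reason.
#'
#' @param markers marker data frame.
#' @param genome the source [genome_set()].
#' @param params an [epcr_params()] object.
#' @param product_tol relative product-size tolerance (default 0.2).
#' @return the marker data frame with updated `status` and a `reject_reason`
#'   column; all hits are attached as attribute `"hits"`.
#' @export
validate_markers <- function(markers, genome, params = epcr_params(),
                             product_tol = 0.2) {
  hits <- epcr(markers, genome, params)
  status <- rep("rejected", nrow(markers))
  reason <- rep(NA_character_, nrow(markers))
  for (i in seq_len(nrow(markers))) {
    h <- hits[hits$marker_id == markers$marker_id[i], , drop = FALSE]
    if (nrow(h) == 0L) { reason[i] <- "no product"; next }
    exp_bp <- markers$expected_product_bp[i]
    on_target <- h$seq_id == markers$seq_id[i] &
      ivl_overlaps(h$start, h$end, markers$locus_start[i], markers$locus_end[i]) &
      abs(h$product_bp - exp_bp) <= product_tol * exp_bp
    if (any(on_target)) status[i] <- "validated"
    else reason[i] <- "no on-target product"
  }
  out <- markers
  out$status <- status
  out$reject_reason <- reason
  attr(out, "hits") <- hits
  out
}

#' Deduplicate markers sharing a primer
#'
#' Two markers are the same marker when their forward primers are identical
#' or their reverse primers are identical; the relation is closed
#' transitively. One representative survives per group: the marker with the
#' smallest (seq_id, locus_start), ties broken by marker_id.
#'
#' @param markers marker data frame.
#' @return deduplicated marker data frame; the number of removed duplicates
#'   is attached as attribute `"n_removed"`.
#' @export
dedup_markers <- function(markers) {
  n <- nrow(markers)
  if (n <= 1L) { attr(markers, "n_removed") <- 0L; return(markers) }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  for (key in list(markers$forward_primer, markers$reverse_primer)) {
    groups <- split(seq_len(n), key)
    for (g in groups) if (length(g) > 1L) for (j in g[-1]) union2(g[1], j)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  keep <- logical(n)
  for (g in split(seq_len(n), roots)) {
    g <- g[order(markers$seq_id[g], markers$locus_start[g], markers$marker_id[g])]
    keep[g[1]] <- TRUE
  }
  out <- markers[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- n - nrow(out)
  out
}

#' Classify markers as monomorphic or polymorphic
#'
#' The number of amplification sites of each marker genome-wide is counted by
#' e-PCR; a marker amplifying exactly one site is monomorphic, two or more
#' sites polymorphic.
#'
#' @param markers validated marker data frame.
#' @param genome the marker's own [genome_set()].
#' @param params an [epcr_params()] object.
#' @return data frame with `marker_id`, `site_count` and `label`; the hit
#'   table is attached as attribute `"hits"`.
#' @export
classify_polymorphism <- function(markers, genome, params = epcr_params()) {
  hits <- epcr(markers, genome, params)
  counts <- table(hits$marker_id)
  site_count <- as.integer(counts[markers$marker_id])
  site_count[is.na(site_count)] <- 0L
  if (any(site_count == 0L & markers$status == "validated")) {
    stop("validated marker with zero e-PCR sites: internal inconsistency",
         call. = FALSE)
  }
  out <- data.frame(marker_id = markers$marker_id, site_count = site_count,
                    label = ifelse(site_count >= 2L, "polymorphic", "monomorphic"),
                    stringsAsFactors = FALSE)
  attr(out, "hits") <- hits
  out
}

#' Histogram of amplification-site counts
#'
#' @param classification result of [classify_polymorphism()].
#' @return named integer vector: number of markers per site-count bin.
#' @export
site_histogram <- function(classification) {
  tab <- table(classification$site_count)
  setNames(as.integer(tab), names(tab))
}

#' Universal-marker screen across genomes
#'
#' Keeps the markers that amplify at least one product in every genome of the
#' panel.
#'
#' @param markers marker data frame.
#' @param genomes list of [genome_set()] objects (at least 2).
#' @param params an [epcr_params()] object.
#' @return list with `universal` (subset of `markers`) and `hit_matrix`
#'   (marker x species site counts).
#' @export
universal_screen <- function(markers, genomes, params = epcr_params()) {
  stopifnot(length(genomes) >= 1L)
  species <- vapply(genomes, function(g) g$species_id, character(1))
  mat <- matrix(0L, nrow = nrow(markers), ncol = length(genomes),
                dimnames = list(markers$marker_id, species))
  for (j in seq_along(genomes)) {
    hits <- epcr(markers, genomes[[j]], params)
    counts <- table(hits$marker_id)
    got <- intersect(names(counts), rownames(mat))
    mat[got, j] <- as.integer(counts[got])
  }
  keep <- rowSums(mat >= 1L) == length(genomes)
  universal <- markers[keep, , drop = FALSE]
  rownames(universal) <- NULL
  list(universal = universal, hit_matrix = mat)
}
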