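# Marker distribution statistics: density per Mb, windowed counts,
# SSR/ILP concomitance, and BED track exports.

#' Marker density profile of one sequence
#'
#' Overall density is `count * 1e6 / sequence length`; per-window counts bin
#' intervals by their start position.
#'
#' @param intervals data frame with `start` (0-based) positions on the
#'   sequence.
#' @param seq_length sequence length in bases (> 0).
#' @param window window size in bases (default 100000).
#' @param seq_id sequence label.
#' @return list of class `density_profile`: `seq_id`, `window`, `counts`
#'   (one per window), `density_per_mb` (full precision) and
#'   `density_per_mb_report` (rounded to integer).
#' @export
marker_density <- function(intervals, seq_length, window = 100000L,
                           seq_id = NA_character_) {
  if (seq_length <= 0L) stop("sequence length must be positive", call. = FALSE)
  n_win <- max(1L, ceiling(seq_length / window))
  counts <- tabulate(pmin(intervals$start %/% window + 1L, n_win), nbins = n_win)
  dens <- nrow(intervals) * 1e6 / seq_length
  structure(list(seq_id = seq_id, window = as.integer(window),
                 counts = counts, density_per_mb = dens,
                 density_per_mb_report = round(dens)),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> %s: %d markers, %d per Mb\n",
              x$seq_id, sum(x$counts), x$density_per_mb_report))
  invisible(x)
}

#' Concomitance of SSR and ILP markers
#'
#' An SSR marker is concomitant when its interval shares at least one base
#' with any ILP interval (half-open intervals; a shared boundary does not
#' count). By default the designed amplicon interval (forward primer 5' end
#' to reverse primer 5' end) is what overlaps are computed on, so pass
#' amplicon intervals; locus intervals can be passed instead for the
#' by-locus variant.
#'
#' @param ssr,ilp data frames with `seq_id`, `start`, `end` (0-based
#'   half-open) on the same genome.
#' @return list with `n_ssr_only`, `n_ilp_only`, `n_concomitant_ssr`,
#'   `n_concomitant_ilp` and `rate` (= concomitant SSR / total SSR).
#' @export
concomitance <- function(ssr, ilp) {
  overlaps_any <- function(a, b) {
    out <- logical(nrow(a))
    for (sid in unique(a$seq_id)) {
      ai <- which(a$seq_id == sid)
      bi <- which(b$seq_id == sid)
      if (length(bi) == 0L) next
      bs <- b$start[bi]; be <- b$end[bi]
      ord <- order(bs)
      bs <- bs[ord]; be <- be[ord]
      cummax_be <- cummax(be)
      for (i in ai) {
        # candidates: b intervals with start < a_end; overlap iff any end > a_start
        k <- findInterval(a$end[i] - 1L, bs)
        if (k >= 1L && cummax_be[k] > a$start[i]) out[i] <- TRUE
      }
    }
    out
  }
  ssr_con <- overlaps_any(ssr, ilp)
  ilp_con <- overlaps_any(ilp, ssr)
  list(n_ssr_only = sum(!ssr_con), n_ilp_only = sum(!ilp_con),
       n_concomitant_ssr = sum(ssr_con), n_concomitant_ilp = sum(ilp_con),
       rate = if (nrow(ssr) == 0L) NA_real_ else sum(ssr_con) / nrow(ssr))
}

#' Amplicon intervals of designed markers
#'
#' The designed amplicon runs from the forward primer 5' end to the reverse
#' primer 5' end around the source locus. The marker table keeps only the
#' total product size, so the flanking portion
#' (`expected_product_bp` minus the locus length, at most one flank length
#' per side) is split evenly between the two sides. Used for the
#' marker-level concomitance statistic.
#'
#' @param markers marker data frame.
#' @return data frame with `seq_id`, `start`, `end` of amplicon intervals.
#' @export
amplicon_intervals <- function(markers) {
  locus_len <- markers$locus_end - markers$locus_start
  extra <- pmax(markers$expected_product_bp - locus_len, 0L)
  left <- extra %/% 2L
  data.frame(seq_id = markers$seq_id,
             start = pmax(markers$locus_start - left, 0L),
             end = markers$locus_end + (extra - left),
             stringsAsFactors = FALSE)
}

#' Export marker tracks as BED6, one file per marker type
#'
#' @param markers marker data frame.
#' @param dir output directory (created if missing).
#' @return invisibly, named character vector of written paths.
#' @export
export_marker_tracks <- function(markers, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  colors <- c(SSR = "255,0,0", ILP = "0,0,255", PIP = "0,128,0")
  paths <- character(0)
  for (ty in unique(markers$type)) {
    m <- markers[markers$type == ty, , drop = FALSE]
    path <- file.path(dir, paste0(tolower(ty), "_markers.bed"))
    df <- data.frame(seq_id = m$seq_id, start = m$locus_start, end = m$locus_end,
                     name = m$marker_id, score = 0L, strand = "+",
                     stringsAsFactors = FALSE)
    write_bed(df, path)
    paths[ty] <- path
  }
  invisible(paths)
}

#' Per-species marker summary table
#'
#' @param markers marker data frame.
#' @param genome the [genome_set()] the markers live on.
#' @param concomitance_rate optional precomputed SSR/ILP concomitance rate.
#' @return data frame with `species`, `type`, `count`, `density_per_mb`,
#'   `concomitance_rate`.
#' @export
marker_summary <- function(markers, genome, concomitance_rate = NA_real_) {
  gsize <- genome_size(genome)
  tys <- sort(unique(markers$type))
  data.frame(
    species = genome$species_id, type = tys,
    count = vapply(tys, function(t) sum(markers$type == t), integer(1)),
    density_per_mb = vapply(tys, function(t) sum(markers$type == t) * 1e6 / gsize,
                            numeric(1)),
    concomitance_rate = concomitance_rate, stringsAsFactors = FALSE)
}
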