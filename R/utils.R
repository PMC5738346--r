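# Shared internal helpers. DNA is handled as uppercase character strings over
# {A,C,G,T,N}; N never matches anything during scanning or primer matching.

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA strings over \{A,C,G,T,N\}.
#' @return character vector of reverse complements.
#' @examples
#' rev_comp(c("ACGT", "AAN"))
#' @export
rev_comp <- function(x) {
  out <- vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
  chartr("ACGTNacgtn", "TGCANtgcan", out)
}

# GC fraction of a DNA string (N counted in the denominator).
gc_frac <- function(x) {
  vapply(x, function(s) {
    n <- nchar(s)
    if (n == 0L) return(NA_real_)
    gc <- n - nchar(gsub("[GCgc]", "", s))
    gc / n
  }, numeric(1), USE.NAMES = FALSE)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Half-open interval overlap (vectorised).
ivl_overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# Longest homopolymer run length in a DNA string.
max_homopolymer <- function(s) {
  if (nchar(s) == 0L) return(0L)
  r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
  max(r$lengths)
}

# Stop unless all characters are in {A,C,G,T,N}.
assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}", what), call. = FALSE)
  }
  invisible(x)
}
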