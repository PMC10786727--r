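#' @keywords internal
#' @noRd
lnx_check_sequence <- function(sequence, arg = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    abort(sprintf("`%s` must be a single string.", arg))
  }
  s <- toupper(gsub("U", "T", toupper(sequence), fixed = TRUE))
  if (grepl("[^ACGTN]", s)) {
    abort(sprintf("`%s` contains characters outside {A,C,G,T,U,N}.", arg))
  }
  s
}

# Encode a sequence as integers 1..4 (A,C,G,T); N -> NA.
#' @noRd
lnx_encode <- function(sequence) {
  v <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- match(v, LNX_BASES)
  idx
}

#' @noRd
lnx_revcomp <- function(sequence) {
  comp <- chartr("ACGTN", "TGCAN", sequence)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# Validate a tibble of 0-based half-open intervals.
#' @noRd
lnx_check_intervals <- function(x, len = NULL) {
  stopifnot(all(c("start", "end") %in% names(x)))
  if (any(x$start < 0) || any(x$start >= x$end)) {
    abort("Intervals must satisfy 0 <= start < end.")
  }
  if (!is.null(len) && any(x$end > len)) {
    abort("Interval end exceeds sequence length.")
  }
  invisible(x)
}

# Merge sorted disjoint union of a set of intervals (matrix/tibble with start,end).
#' @noRd
lnx_union_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(tibble(start = integer(), end = integer()))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  out_s <- start[1]
  out_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= out_e[length(out_e)]) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], end[i])
    } else {
      out_s <- c(out_s, start[i])
      out_e <- c(out_e, end[i])
    }
  }
  tibble(start = out_s, end = out_e)
}

# Complement of a disjoint sorted interval set within [0, len).
#' @noRd
lnx_complement_intervals <- function(intervals, len) {
  if (nrow(intervals) == 0L) {
    return(tibble(start = 0L, end = as.integer(len)))
  }
  starts <- c(0L, intervals$end)
  ends <- c(intervals$start, as.integer(len))
  keep <- starts < ends
  tibble(start = starts[keep], end = ends[keep])
}

# Derive a stream-specific seed below 2^31 from a base seed.
#' @noRd
lnx_substream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103L + stream * 12347L) %% 2147483629)
}
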