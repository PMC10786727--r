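#' Cluster motif matches into motif blocks
#'
#' Two matches belong to the same block when they overlap by at least half
#' of the shorter match; clusters are the single-linkage closure of that
#' relation. Each block records its union span, its centre in nucleotides,
#' and the number of matches per motif class (the per-class site counts
#' that feed the block similarity score).
#'
#' @param matches Tibble of matches on one transcript, as produced by
#'   [scan_motifs()] (needs `start`, `end`, `motif_class`).
#' @param seq_id Transcript id; defaults to the single id found in `matches`.
#' @param seq_length Transcript length in nt (needed for position nulls and
#'   plotting; inferred as the max match end when omitted).
#' @return A `block_profile`: a tibble of blocks sorted by start with columns
#'   `start`, `end`, `center`, `n_matches` and the list-column `counts`
#'   (named integer vector per block), carrying `seq_id` and `seq_length`
#'   attributes.
#' @export
cluster_matches <- function(matches, seq_id = NULL, seq_length = NULL) {
  if (is.null(seq_id)) {
    ids <- unique(matches$seq_id %||% character())
    if (length(ids) > 1) {
      abort("`matches` spans several transcripts; cluster one at a time.")
    }
    seq_id <- if (length(ids) == 1) ids else NA_character_
  }
  if (is.null(seq_length)) {
    seq_length <- if (nrow(matches) > 0) max(matches$end) else 0L
  }
  n <- nrow(matches)
  if (n == 0) {
    return(new_block_profile(
      tibble(start = integer(), end = integer(), center = numeric(),
             n_matches = integer(), counts = list()),
      seq_id = seq_id, seq_length = seq_length))
  }
  o <- order(matches$start, matches$end)
  st <- matches$start[o]
  en <- matches$end[o]
  cls <- matches$motif_class[o]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    j <- i + 1L
    while (j <= n && st[j] < en[i]) {
      ov <- min(en[i], en[j]) - max(st[i], st[j])
      shorter <- min(en[i] - st[i], en[j] - st[j])
      if (ov >= 0.5 * shorter) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
      j <- j + 1L
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  blocks <- map(groups, function(idx) {
    b_start <- min(st[idx])
    b_end <- max(en[idx])
    counts_tab <- table(cls[idx])
    tibble(start = b_start, end = b_end, center = (b_start + b_end) / 2,
           n_matches = length(idx),
           counts = list(setNames(as.integer(counts_tab), names(counts_tab))))
  })
  out <- bind_rows(blocks) |> arrange(.data$start, .data$end)
  new_block_profile(out, seq_id = seq_id, seq_length = seq_length)
}

#' Construct a block profile directly
#'
#' Builds the ordered block list of one transcript from explicit blocks,
#' bypassing [cluster_matches()]. Useful for simulations and for feeding
#' externally derived block tables into the alignment functions.
#'
#' @param blocks Tibble with `start`, `end` and the list-column `counts`
#'   (named positive integer vector per block); `center` defaults to the
#'   span midpoint and `n_matches` to the count total.
#' @param seq_id Transcript id.
#' @param seq_length Transcript length in nt.
#' @return A `block_profile`.
#' @export
block_profile <- function(blocks, seq_id, seq_length) {
  blocks <- as_tibble(blocks)
  stopifnot(all(c("start", "end", "counts") %in% names(blocks)))
  if (any(blocks$start >= blocks$end) || any(blocks$start < 0) ||
      any(blocks$end > seq_length)) {
    abort("Blocks must satisfy 0 <= start < end <= seq_length.")
  }
  if (is.unsorted(blocks$start)) {
    abort("Blocks must be sorted by start.")
  }
  if (any(vapply(blocks$counts, function(x) any(x < 1) || is.null(names(x)),
                 logical(1)))) {
    abort("Block counts must be named vectors of positive counts.")
  }
  if (!"center" %in% names(blocks)) {
    blocks$center <- (blocks$start + blocks$end) / 2
  }
  if (!"n_matches" %in% names(blocks)) {
    blocks$n_matches <- vapply(blocks$counts, function(x) as.integer(sum(x)),
                               integer(1))
  }
  new_block_profile(blocks[, c("start", "end", "center", "n_matches", "counts")],
                    seq_id = seq_id, seq_length = seq_length)
}

#' @noRd
new_block_profile <- function(blocks, seq_id, seq_length) {
  structure(blocks, seq_id = seq_id, seq_length = as.numeric(seq_length),
            class = c("block_profile", class(blocks)))
}

#' Build block profiles for many transcripts at once
#'
#' @param matches Tibble of matches over several transcripts.
#' @param seq_lengths Named numeric vector of transcript lengths.
#' @return Named list of `block_profile` objects, one per transcript in
#'   `seq_lengths` (transcripts without matches get empty profiles).
#' @export
block_profiles <- function(matches, seq_lengths) {
  ids <- names(seq_lengths)
  setNames(map(ids, function(id) {
    cluster_matches(filter(matches, .data$seq_id == id),
                    seq_id = id, seq_length = seq_lengths[[id]])
  }), ids)
}

#' @export
print.block_profile <- function(x, ...) {
  cat(sprintf("<block_profile> %s: %d block(s) over %g nt\n",
              attr(x, "seq_id"), nrow(x), attr(x, "seq_length")))
  NextMethod()
}
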