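#' Read transcript sequences from a FASTA file
#'
#' Sequences are uppercased and RNA `U` is normalised to DNA `T`, so motif
#' scanning can treat transcript and genomic sequence uniformly. Only
#' `A`, `C`, `G`, `T`, `U` and `N` are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences over `{A,C,G,T,N}`;
#'   names are the sequence ids (first whitespace-delimited token of each
#'   header line).
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">tx1", "acgu", ">tx2", "NNTT"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("Malformed FASTA in %s: %s", path, conditionMessage(e)))
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate sequence id in %s: %s", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (any(nchar(seqs) == 0L)) {
    abort(sprintf("Empty sequence record in %s (id: %s)", path,
                  paste(ids[nchar(seqs) == 0L], collapse = ", ")))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(sprintf("Sequence %s contains characters outside {A,C,G,T,U,N}.",
                  ids[which(bad)[1]]))
  }
  setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' Round-trips with [read_fasta()]: `read_fasta(write_fasta(x, f))` equals `x`.
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    abort("`sequences` must be a named character vector.")
  }
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
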