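#' Read a BED file of intervals
#'
#' BED coordinates are 0-based half-open, which is also the package's
#' internal convention, so they pass through unchanged.
#'
#' @param path Path to a BED (3-6 column) file.
#' @return A tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE, comment = "#")
  if (ncol(x) < 3) abort(sprintf("%s: BED needs at least 3 columns.", path))
  names(x)[1:3] <- c("chrom", "start", "end")
  extra <- c("name", "score", "strand")
  if (ncol(x) > 3) names(x)[4:min(ncol(x), 6)] <- extra[seq_len(min(ncol(x), 6) - 3)]
  x <- as_tibble(x[, seq_len(min(ncol(x), 6))])
  if (!is.numeric(x$start) || !is.numeric(x$end)) {
    abort(sprintf("%s: BED start/end must be integers.", path))
  }
  if (any(x$start < 0)) abort(sprintf("%s: negative coordinate.", path))
  if (any(x$start >= x$end)) abort(sprintf("%s: interval with start >= end.", path))
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x
}

#' Write intervals as BED
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optional
#'   `name`, `score`, `strand` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  keep <- cols[seq_len(max(which(c("chrom", "start", "end", "name", "score", "strand") %in% cols)))]
  readr::write_tsv(intervals[, keep], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a GTF-lite annotation
#'
#' Nine-column GTF with `gene_id`/`transcript_id` attributes. GTF is 1-based
#' closed; coordinates are converted to the internal 0-based half-open
#' convention on read and restored by [write_gtf_lite()].
#'
#' @param path Path to a GTF file.
#' @return Tibble with `chrom`, `source`, `feature`, `start`, `end`,
#'   `score`, `strand`, `frame`, `gene_id`, `transcript_id`.
#' @export
read_gtf_lite <- function(path) {
  if (!file.exists(path)) abort(sprintf("GTF file not found: %s", path))
  x <- readr::read_tsv(path, col_names = c("chrom", "source", "feature", "start",
                                           "end", "score", "strand", "frame",
                                           "attributes"),
                       col_types = "cccddcccc", comment = "#",
                       show_col_types = FALSE, progress = FALSE)
  if (any(x$start < 1) || any(x$start > x$end)) {
    abort(sprintf("%s: GTF requires 1 <= start <= end.", path))
  }
  attr_field <- function(a, key) {
    m <- regmatches(a, regexpr(sprintf('%s "[^"]*"', key), a))
    ifelse(lengths(regmatches(a, gregexpr(sprintf('%s "[^"]*"', key), a))) > 0,
           sub(sprintf('%s "([^"]*)"', key), "\\1", m), NA_character_)
  }
  gid <- vapply(x$attributes, function(a) {
    m <- regmatches(a, regexpr('gene_id "[^"]*"', a))
    if (length(m)) sub('gene_id "([^"]*)"', "\\1", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  tid <- vapply(x$attributes, function(a) {
    m <- regmatches(a, regexpr('transcript_id "[^"]*"', a))
    if (length(m)) sub('transcript_id "([^"]*)"', "\\1", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  tibble(chrom = x$chrom, source = x$source, feature = x$feature,
         start = as.integer(x$start - 1L), end = as.integer(x$end),
         score = x$score, strand = x$strand, frame = x$frame,
         gene_id = gid, transcript_id = tid)
}

#' Write a GTF-lite annotation
#'
#' Converts internal 0-based half-open coordinates back to GTF's 1-based
#' closed convention.
#'
#' @param annotation Tibble as returned by [read_gtf_lite()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf_lite <- function(annotation, path) {
  a <- annotation
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";', a$gene_id,
                   a$transcript_id %||% a$gene_id)
  out <- tibble(a$chrom, a$source %||% "lnchomex", a$feature, a$start + 1L,
                a$end, a$score %||% ".", a$strand, a$frame %||% ".", attrs)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE,
                   quote = "none", escape = "none")
  invisible(path)
}

# ---- typed TSV tables ------------------------------------------------------

#' Read a typed TSV table against a schema
#'
#' @param path Path to a TSV file with a header row.
#' @param schema One of `"anchors"`, `"homolog_pairs"`, `"variants"`,
#'   `"transcripts"`, `"screen_counts"`.
#' @return A validated tibble. Anchors and homolog pairs are checked for
#'   one-to-one correspondence (duplicate ids are rejected).
#' @export
read_table_schema <- function(path, schema = c("anchors", "homolog_pairs",
                                               "variants", "transcripts",
                                               "screen_counts")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort(sprintf("Table not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- switch(schema,
    anchors = c("anchor_id", "chrom_a", "start_a", "end_a",
                "chrom_b", "start_b", "end_b"),
    homolog_pairs = c("gene_a", "gene_b", "evidence"),
    variants = c("position", "allele_frequency"),
    transcripts = c("transcript_id", "gene_id", "chrom", "strand", "start",
                    "end", "biotype", "length_nt", "fpkm", "coding_potential"),
    screen_counts = c("pair_id", "gene_id", "control")
  )
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing column(s) %s for schema '%s'.",
                  path, paste(missing, collapse = ", "), schema))
  }
  if (schema == "anchors") {
    if (anyDuplicated(x$anchor_id)) {
      abort(sprintf("%s: duplicated anchor_id breaks one-to-one correspondence.", path))
    }
    if (any(x$start_a >= x$end_a) || any(x$start_b >= x$end_b) ||
        any(x$start_a < 0) || any(x$start_b < 0)) {
      abort(sprintf("%s: anchor loci must satisfy 0 <= start < end.", path))
    }
  }
  if (schema == "homolog_pairs") {
    dup <- x |> count(.data$evidence, .data$gene_a) |> filter(.data$n > 1)
    dup2 <- x |> count(.data$evidence, .data$gene_b) |> filter(.data$n > 1)
    if (nrow(dup) > 0 || nrow(dup2) > 0) {
      abort(sprintf("%s: homolog pairs are not one-to-one within evidence class.", path))
    }
  }
  if (schema == "variants") {
    if (any(x$allele_frequency < 0 | x$allele_frequency > 1)) {
      abort(sprintf("%s: allele_frequency outside [0,1].", path))
    }
  }
  if (schema == "transcripts") {
    validate_transcripts(x)
  }
  if (schema == "screen_counts") {
    countcols <- setdiff(names(x), required)
    if (!all(vapply(x[countcols], is.numeric, logical(1)))) {
      abort(sprintf("%s: non-numeric count column.", path))
    }
    if (any(as.matrix(x[countcols]) < 0)) {
      abort(sprintf("%s: negative counts.", path))
    }
  }
  x
}

#' @noRd
validate_transcripts <- function(x) {
  if (any(x$start >= x$end)) abort("Transcript records need start < end.")
  if (any(x$length_nt < 1)) abort("Transcript length_nt must be >= 1.")
  if (any(x$coding_potential < 0 | x$coding_potential > 1)) {
    abort("coding_potential must lie in [0,1].")
  }
  if (any(x$fpkm < 0)) abort("fpkm must be non-negative.")
  if (!all(x$strand %in% c("+", "-"))) abort("strand must be '+' or '-'.")
  invisible(x)
}

#' Filter a transcript table down to curated lncRNA candidates
#'
#' Retains transcripts at least `min_len` nucleotides long, expressed above
#' `min_fpkm` (strict inequality) and with coding potential no greater than
#' `max_coding` (a CPAT-style score above 0.5 marks a transcript as likely
#' coding and excludes it).
#'
#' @param records Tibble of transcript records (see
#'   `read_table_schema(..., "transcripts")`).
#' @param min_len Minimum transcript length in nt (default 200, inclusive).
#' @param min_fpkm Minimum expression (default 0.5, exclusive).
#' @param max_coding Maximum coding-potential score (default 0.5, inclusive).
#' @return The retained rows, as a tibble.
#' @export
filter_lncrna_candidates <- function(records, min_len = 200, min_fpkm = 0.5,
                                     max_coding = 0.5) {
  validate_transcripts(records)
  records |>
    filter(.data$length_nt >= min_len,
           .data$fpkm > min_fpkm,
           .data$coding_potential <= max_coding)
}
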