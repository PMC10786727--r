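#' Read a MEME minimal-format motif file
#'
#' Parses the MEME minimal motif format (a `MEME version` line, an optional
#' `ALPHABET=` line, optional background frequencies, then `MOTIF` stanzas
#' each with a `letter-probability matrix:` header). The RNA alphabet `ACGU`
#' is accepted and stored as DNA.
#'
#' @param path Path to a motif file.
#' @param species Species label attached to every motif (default `NA`).
#' @param pseudocount Pseudocount passed to [pwm()].
#' @return A list of [pwm()] objects.
#' @export
read_meme_motifs <- function(path, species = NA_character_, pseudocount = 1e-3) {
  if (!file.exists(path)) abort(sprintf("Motif file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (!any(grepl("^MEME version", lines))) {
    abort(sprintf("%s: missing 'MEME version' line.", path))
  }
  alpha_line <- grep("^ALPHABET=", lines, value = TRUE)
  if (length(alpha_line) > 0) {
    alpha <- gsub("\\s", "", sub("^ALPHABET=", "", alpha_line[1]))
    if (!alpha %in% c("ACGT", "ACGU")) {
      abort(sprintf("%s: unknown alphabet '%s' (expected ACGT or ACGU).", path, alpha))
    }
  }
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) > 0 && bg_at[1] < length(lines)) {
    bg_tokens <- strsplit(lines[bg_at[1] + 1L], "\\s+")[[1]]
    if (length(bg_tokens) >= 8) {
      vals <- suppressWarnings(as.numeric(bg_tokens[seq(2, 8, by = 2)]))
      if (!anyNA(vals)) background <- vals / sum(vals)
    }
  }

  motif_at <- grep("^MOTIF\\b", lines)
  if (length(motif_at) == 0) abort(sprintf("%s: no MOTIF stanzas.", path))
  pwms <- vector("list", length(motif_at))
  for (k in seq_along(motif_at)) {
    i <- motif_at[k]
    tokens <- strsplit(lines[i], "\\s+")[[1]]
    motif_id <- tokens[2]
    rbp_name <- if (length(tokens) >= 3) tokens[3] else motif_id
    j <- i + 1L
    while (j <= length(lines) && !grepl("^letter-probability matrix", lines[j])) {
      if (grepl("^MOTIF\\b", lines[j])) {
        abort(sprintf("%s: motif %s has no letter-probability matrix.", path, motif_id))
      }
      j <- j + 1L
    }
    if (j > length(lines)) {
      abort(sprintf("%s: motif %s has no letter-probability matrix.", path, motif_id))
    }
    w <- suppressWarnings(as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[j])))
    rows <- list()
    j <- j + 1L
    while (j <= length(lines) && grepl("^[0-9.eE+-]", lines[j])) {
      vals <- suppressWarnings(as.numeric(strsplit(lines[j], "\\s+")[[1]]))
      if (anyNA(vals) || length(vals) != 4L) {
        abort(sprintf("%s: malformed matrix row for motif %s: '%s'", path, motif_id, lines[j]))
      }
      rows[[length(rows) + 1L]] <- vals
      j <- j + 1L
    }
    mat <- do.call(rbind, rows)
    if (!is.na(w) && nrow(mat) != w) {
      abort(sprintf("%s: motif %s declares w=%d but has %d rows.", path, motif_id, w, nrow(mat)))
    }
    if (any(abs(rowSums(mat) - 1) > 0.01)) {
      abort(sprintf("%s: motif %s has matrix rows not summing to 1 (max deviation %.3g).",
                    path, motif_id, max(abs(rowSums(mat) - 1))))
    }
    pwms[[k]] <- pwm(mat, motif_id = motif_id, rbp_name = rbp_name,
                     species = species, background = background,
                     pseudocount = pseudocount)
  }
  ids <- map_chr(pwms, "motif_id")
  if (anyDuplicated(ids)) {
    abort(sprintf("%s: duplicate motif id %s.", path, ids[duplicated(ids)][1]))
  }
  pwms
}

#' Write motifs in MEME minimal format
#'
#' Round-trips with [read_meme_motifs()] up to pseudocount regularisation.
#'
#' @param pwms List of [pwm()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bg <- pwms[[1]]$background
  writeLines(c(
    "MEME version 4",
    "",
    "ALPHABET= ACGT",
    "",
    "strands: +",
    "",
    "Background letter frequencies",
    sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]),
    ""
  ), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s %s", p$motif_id, p$rbp_name), con)
    writeLines(sprintf("letter-probability matrix: alphabet= 4 w= %d nsites= 20 E= 0",
                       pwm_width(p)), con)
    apply(p$matrix, 1, function(r) {
      writeLines(sprintf("%.8f %.8f %.8f %.8f", r[1], r[2], r[3], r[4]), con)
    })
    writeLines("", con)
  }
  invisible(path)
}
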