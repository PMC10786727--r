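# Null distributions are deterministic in the PWM, so memoise them across
# scan calls (keyed by the motif's full content).
lnx_null_cache <- new.env(parent = emptyenv())

#' @noRd
lnx_pwm_null_cached <- function(x) {
  key <- paste(c(x$motif_id, dim(x$matrix), sprintf("%.15g", x$matrix),
                 sprintf("%.15g", x$background), x$pseudocount),
               collapse = "|")
  hit <- lnx_null_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (length(ls(lnx_null_cache)) > 500) {
    rm(list = ls(lnx_null_cache), envir = lnx_null_cache)
  }
  val <- lnx_pwm_null(x)
  assign(key, val, envir = lnx_null_cache)
  val
}

# Exact null distribution of the log-odds score under the background model.
#
# For widths <= 8 the full 4^w enumeration is exact; wider motifs use a
# dynamic program over scores discretised to 1e-3 bit bins. Both return the
# same structure: sorted score support plus tail probabilities.
#' @noRd
lnx_pwm_null <- function(x) {
  lo <- pwm_logodds(x)
  w <- nrow(lo)
  bg <- x$background
  if (w <= 8L) {
    scores <- 0
    probs <- 1
    for (j in seq_len(w)) {
      scores <- rep(scores, each = 4L) + lo[j, ]
      probs <- rep(probs, each = 4L) * bg
    }
    ord <- order(scores)
    s <- scores[ord]
    tailp <- rev(cumsum(rev(probs[ord])))
    list(exact = TRUE, scores = s, tailp = tailp, lo_int = NULL)
  } else {
    lo_int <- round(lo * 1000)
    lo_min <- sum(apply(lo_int, 1, min))
    lo_max <- sum(apply(lo_int, 1, max))
    n_bins <- lo_max - lo_min + 1L
    dp <- numeric(n_bins)
    # offsets of partial sums relative to the running minimum
    cur_min <- 0
    dp[1] <- 1
    cur_len <- 1L
    for (j in seq_len(w)) {
      row <- lo_int[j, ]
      new_min <- cur_min + min(row)
      new_len <- cur_len + (max(row) - min(row))
      ndp <- numeric(new_len)
      for (b in 1:4) {
        sh <- row[b] - min(row)
        idx <- seq_len(cur_len) + sh
        ndp[idx] <- ndp[idx] + dp[seq_len(cur_len)] * bg[b]
      }
      dp <- ndp
      cur_min <- new_min
      cur_len <- new_len
    }
    s <- (cur_min + seq_len(cur_len) - 1L) / 1000
    tailp <- rev(cumsum(rev(dp)))
    keep <- dp > 0
    list(exact = FALSE, scores = s[keep], tailp = tailp[keep], lo_int = lo_int)
  }
}

# P(null score >= s) for each observed score, with a small tolerance so that
# scores recomputed in a different summation order still match their own
# support point.
#' @noRd
lnx_null_pvalue <- function(null, s) {
  idx <- findInterval(s - 1e-9, null$scores) + 1L
  idx <- pmin(idx, length(null$tailp))
  p <- null$tailp[idx]
  pmax(p, .Machine$double.xmin)
}

#' Scan a sequence for PWM motif matches
#'
#' Slides the motif over the sense strand of each sequence and scores every
#' offset as the sum of per-position log-odds (`log2(p(base)/bg(base))`,
#' bits). P-values come from the exact null distribution of the score under
#' the background model: full enumeration of all w-mers for widths up to 8,
#' a dynamic program over 1e-3-bit score bins for wider motifs. Offsets
#' whose p-value is at most `p_threshold` are reported. Windows containing
#' `N` never match.
#'
#' @param x A [pwm()].
#' @param sequences Named character vector of sequences (`A,C,G,T,U,N`).
#' @param p_threshold Maximum match p-value (default `1e-4`).
#' @return A tibble of matches: `seq_id`, `motif_id`, `motif_class` (the RBP
#'   name), `start`, `end` (0-based half-open transcript coordinates),
#'   `score` (bits), `p_value`.
#' @export
#' @examples
#' p <- pwm(matrix(rep(c(0.997, 0.001, 0.001, 0.001), 4), 4, 4, byrow = TRUE),
#'          motif_id = "polyA", rbp_name = "RBP_A")
#' scan_motifs(p, c(tx = "TTTAAAATTT"))
scan_motifs <- function(x, sequences, p_threshold = 1e-4) {
  stopifnot(inherits(x, "pwm"))
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  lo <- pwm_logodds(x)
  w <- nrow(lo)
  null <- lnx_pwm_null_cached(x)
  out <- vector("list", length(sequences))
  for (k in seq_along(sequences)) {
    s <- lnx_check_sequence(sequences[[k]], names(sequences)[k])
    L <- nchar(s)
    if (L < w) {
      out[[k]] <- NULL
      next
    }
    enc <- lnx_encode(s)
    n_off <- L - w + 1L
    score <- numeric(n_off)
    binned <- if (!null$exact) integer(n_off) else NULL
    for (j in seq_len(w)) {
      bases <- enc[j:(j + n_off - 1L)]
      score <- score + unname(lo[j, ])[bases]
      if (!null$exact) binned <- binned + unname(null$lo_int[j, ])[bases]
    }
    ok <- is.finite(score)
    if (!any(ok)) next
    pv <- rep(NA_real_, n_off)
    pv[ok] <- if (null$exact) {
      lnx_null_pvalue(null, score[ok])
    } else {
      lnx_null_pvalue(null, binned[ok] / 1000)
    }
    hit <- which(ok & pv <= p_threshold)
    if (length(hit) == 0) next
    out[[k]] <- tibble(
      seq_id = names(sequences)[k],
      motif_id = x$motif_id,
      motif_class = x$rbp_name,
      start = hit - 1L,
      end = hit - 1L + w,
      score = score[hit],
      p_value = pv[hit]
    )
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(seq_id = character(), motif_id = character(),
                  motif_class = character(), start = integer(), end = integer(),
                  score = numeric(), p_value = numeric())
  }
  res
}

#' Scan sequences against a whole motif library
#'
#' @param pwms List of [pwm()] objects.
#' @param sequences Named character vector.
#' @inheritParams scan_motifs
#' @return Row-bound matches from [scan_motifs()] over all motifs, sorted by
#'   sequence and start.
#' @export
scan_motif_library <- function(pwms, sequences, p_threshold = 1e-4) {
  res <- bind_rows(map(pwms, scan_motifs, sequences = sequences,
                       p_threshold = p_threshold))
  if (nrow(res) > 0) res <- arrange(res, .data$seq_id, .data$start, .data$end)
  res
}
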