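#' Compare two PWMs by best-offset column correlation
#'
#' Slides one matrix over the other (ungapped, minimum overlap 4 columns)
#' and reports the offset maximising the Pearson correlation of the
#' flattened overlapping columns, with a permutation p-value obtained by
#' shuffling the columns of `b` and re-maximising.
#'
#' @param a,b [pwm()] objects, both at least 4 columns wide.
#' @param n_perm Column permutations for the p-value (default 1000).
#' @param seed Integer seed.
#' @return A one-row tibble: `motif_a`, `motif_b`, `offset` (columns `b` is
#'   shifted relative to `a`), `correlation`, `p_value`, `comparable`.
#'   When no offset yields a 4-column overlap, `comparable` is `FALSE`.
#' @export
pwm_similarity <- function(a, b, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(a, "pwm"), inherits(b, "pwm"))
  best_corr <- function(ma, mb) {
    wa <- nrow(ma); wb <- nrow(mb)
    best <- c(corr = -Inf, offset = NA_real_)
    for (off in seq(-(wb - 4L), wa - 4L)) {
      ia <- max(1L, 1L + off):min(wa, wb + off)
      if (length(ia) < 4L) next
      ib <- ia - off
      r <- suppressWarnings(cor(as.vector(t(ma[ia, , drop = FALSE])),
                                as.vector(t(mb[ib, , drop = FALSE]))))
      if (is.na(r)) next
      if (r > best["corr"]) best <- c(corr = r, offset = off)
    }
    best
  }
  if (pwm_width(a) < 4L || pwm_width(b) < 4L) {
    return(tibble(motif_a = a$motif_id, motif_b = b$motif_id,
                  offset = NA_integer_, correlation = NA_real_,
                  p_value = NA_real_, comparable = FALSE))
  }
  obs <- best_corr(a$matrix, b$matrix)
  if (!is.finite(obs["corr"])) {
    return(tibble(motif_a = a$motif_id, motif_b = b$motif_id,
                  offset = NA_integer_, correlation = NA_real_,
                  p_value = NA_real_, comparable = FALSE))
  }
  set.seed(seed)
  wb <- pwm_width(b)
  null <- vapply(seq_len(n_perm), function(k) {
    best_corr(a$matrix, b$matrix[sample.int(wb), , drop = FALSE])["corr"]
  }, numeric(1))
  p <- (1 + sum(null >= obs["corr"] - 1e-12)) / (n_perm + 1)
  tibble(motif_a = a$motif_id, motif_b = b$motif_id,
         offset = as.integer(obs["offset"]), correlation = unname(obs["corr"]),
         p_value = p, comparable = TRUE)
}

#' Extrapolate a motif to a new species by iterative mapping and refinement
#'
#' Repeatedly scans the target sequences with the current PWM, builds a
#' count matrix from the matched sites, and blends it with the current
#' matrix (`blend_weight * old + (1 - blend_weight) * normalised counts`)
#' until the largest cell change falls below `tol` or `max_iter` is hit.
#' An iteration with zero matches returns the last PWM flagged unconverged.
#'
#' @param x Seed [pwm()] (e.g. the human motif).
#' @param target_sequences Named character vector of target-species
#'   transcript sequences.
#' @param p_threshold Scan threshold passed to [scan_motifs()].
#' @param blend_weight Weight on the old matrix per iteration (default 0.5).
#' @param max_iter Maximum refinement iterations (default 10).
#' @param tol Convergence threshold on the max absolute cell change
#'   (default 0.01).
#' @return The refined `pwm` with attributes `converged` (logical) and
#'   `iterations`.
#' @export
extrapolate_motif <- function(x, target_sequences, p_threshold = 1e-4,
                              blend_weight = 0.5, max_iter = 10L, tol = 0.01) {
  stopifnot(inherits(x, "pwm"), length(target_sequences) > 0)
  current <- x
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    hits <- scan_motifs(current, target_sequences, p_threshold = p_threshold)
    if (nrow(hits) == 0) {
      attr(current, "converged") <- FALSE
      attr(current, "iterations") <- iterations
      return(current)
    }
    w <- pwm_width(current)
    counts <- matrix(0, w, 4, dimnames = list(NULL, LNX_BASES))
    for (r in seq_len(nrow(hits))) {
      site <- substr(target_sequences[[hits$seq_id[r]]],
                     hits$start[r] + 1L, hits$end[r])
      enc <- lnx_encode(site)
      ok <- !is.na(enc)
      counts[cbind(which(ok), enc[ok])] <- counts[cbind(which(ok), enc[ok])] + 1
    }
    freq <- (counts + current$pseudocount) / rowSums(counts + current$pseudocount)
    new_mat <- blend_weight * current$matrix + (1 - blend_weight) * freq
    delta <- max(abs(new_mat - current$matrix))
    current <- pwm(new_mat, motif_id = x$motif_id, rbp_name = x$rbp_name,
                   species = x$species, background = x$background,
                   pseudocount = x$pseudocount)
    iterations <- it
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  attr(current, "converged") <- converged
  attr(current, "iterations") <- iterations
  current
}

#' Replace RBP-binding sites with their antisense sequence
#'
#' Rescue-fragment design control: each site's subsequence is replaced by
#' its reverse complement, destroying the binding motif while preserving
#' length and base composition.
#'
#' @param sequence A single sequence string.
#' @param sites Tibble (or data frame) of disjoint 0-based half-open
#'   intervals with columns `start`, `end`.
#' @return The mutated sequence (same length).
#' @export
#' @examples
#' mutate_rbp_sites("AAACGTAA", tibble::tibble(start = 3, end = 6)) # "AAAACGAA"
mutate_rbp_sites <- function(sequence, sites) {
  s <- lnx_check_sequence(sequence)
  if (nrow(sites) == 0) return(s)
  sites <- arrange(as_tibble(sites), .data$start)
  lnx_check_intervals(sites, len = nchar(s))
  if (any(sites$start[-1] < sites$end[-nrow(sites)])) {
    abort("`sites` must be pairwise disjoint.")
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  for (r in seq_len(nrow(sites))) {
    idx <- (sites$start[r] + 1L):sites$end[r]
    sub <- paste(chars[idx], collapse = "")
    chars[idx] <- strsplit(lnx_revcomp(sub), "", fixed = TRUE)[[1]]
  }
  paste(chars, collapse = "")
}
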