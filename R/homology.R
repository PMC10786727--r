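#' Block similarity score between two motif blocks
#'
#' Over the union of motif classes present in either block, sums
#' `min(x_i, y_i) / max(x_i, y_i)` where `x_i` and `y_i` are the numbers of
#' matched motif sites of class `i` in the two blocks. A class absent from
#' both contributes nothing; the score is symmetric and bounded by the
#' number of shared classes.
#'
#' @param counts_a,counts_b Named integer vectors of per-class site counts.
#' @return The block similarity score (non-negative real).
#' @export
#' @examples
#' block_similarity(c(M1 = 2, M2 = 1), c(M1 = 1, M2 = 2)) # 0.5 + 0.5
block_similarity <- function(counts_a, counts_b) {
  if (length(counts_a) == 0 || length(counts_b) == 0) return(0)
  shared <- intersect(names(counts_a), names(counts_b))
  if (length(shared) == 0) return(0)
  x <- as.numeric(counts_a[shared])
  y <- as.numeric(counts_b[shared])
  sum(pmin(x, y) / pmax(x, y))
}

# Pairwise block-similarity matrix between two profiles.
#' @noRd
lnx_sim_matrix <- function(a, b) {
  n <- nrow(a)
  m <- nrow(b)
  sim <- matrix(0, n, m)
  if (n == 0 || m == 0) return(sim)
  for (i in seq_len(n)) {
    ca <- a$counts[[i]]
    for (j in seq_len(m)) {
      sim[i, j] <- block_similarity(ca, b$counts[[j]])
    }
  }
  sim
}

# Score-only MPSS dynamic program (maximum-weight non-crossing matching,
# free skips). Used on the permutation-null hot path.
#' @noRd
lnx_mpss_value <- function(sim) {
  n <- nrow(sim)
  m <- ncol(sim)
  if (n == 0 || m == 0) return(0)
  prev <- numeric(m + 1L)
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    for (j in seq_len(m)) {
      cur[j + 1L] <- max(prev[j + 1L], cur[j], prev[j] + sim[i, j])
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Align two block profiles by dynamic programming (MPSS)
#'
#' Finds the monotone (non-crossing) set of block pairs maximising the sum
#' of block similarity scores; that maximum is the motif pattern similarity
#' score (MPSS). Unaligned blocks are skipped freely. Among co-optimal
#' alignments the one minimising the sum of squared inter-block distance
#' deviations (the GPS numerator) is returned, with remaining ties broken
#' towards the lexicographically smallest pair list, so the result is
#' deterministic. Zero-similarity block pairs are never matched.
#'
#' @param a,b `block_profile` objects (see [cluster_matches()]).
#' @return A `block_alignment`: list with `pairs` (tibble `idx_a`, `idx_b`,
#'   `similarity`), `mpss`, `gps`, and the two profiles.
#' @export
align_blocks <- function(a, b) {
  stopifnot(inherits(a, "block_profile"), inherits(b, "block_profile"))
  sim <- lnx_sim_matrix(a, b)
  cand <- which(sim > 0, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(new_block_alignment(tibble(idx_a = integer(), idx_b = integer(),
                                      similarity = numeric()), 0, a, b))
  }
  # order candidate pairs lexicographically by (i, j)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  np <- nrow(cand)
  ca <- a$center
  cb <- b$center
  best_score <- numeric(np)   # best MPSS of a chain ending at pair k
  best_ssq <- numeric(np)     # secondary: sum of squared distance deviations
  best_prev <- integer(np)    # predecessor pair index, 0 = chain start
  for (k in seq_len(np)) {
    i <- cand[k, 1]; j <- cand[k, 2]
    s <- sim[i, j]
    bs <- s; bq <- 0; bp <- 0L
    if (k > 1) {
      for (p in seq_len(k - 1L)) {
        if (cand[p, 1] < i && cand[p, 2] < j) {
          dev <- (ca[i] - ca[cand[p, 1]]) - (cb[j] - cb[cand[p, 2]])
          sc <- best_score[p] + s
          sq <- best_ssq[p] + dev^2
          if (sc > bs + 1e-12 ||
              (abs(sc - bs) <= 1e-12 && sq < bq - 1e-12)) {
            bs <- sc; bq <- sq; bp <- p
          }
        }
      }
    }
    best_score[k] <- bs
    best_ssq[k] <- bq
    best_prev[k] <- bp
  }
  end <- 1L
  for (k in seq_len(np)) {
    if (best_score[k] > best_score[end] + 1e-12 ||
        (abs(best_score[k] - best_score[end]) <= 1e-12 &&
         best_ssq[k] < best_ssq[end] - 1e-12)) {
      end <- k
    }
  }
  chain <- integer()
  k <- end
  while (k != 0L) {
    chain <- c(k, chain)
    k <- best_prev[k]
  }
  pairs <- tibble(
    idx_a = unname(cand[chain, 1]),
    idx_b = unname(cand[chain, 2]),
    similarity = unname(sim[cand[chain, , drop = FALSE]])
  )
  new_block_alignment(pairs, best_score[end], a, b)
}

#' @noRd
new_block_alignment <- function(pairs, mpss, a, b) {
  al <- structure(
    list(pairs = pairs, mpss = mpss, gps = NA_real_,
         profile_a = a, profile_b = b),
    class = "block_alignment"
  )
  al$gps <- gap_penalty(al)
  al
}

#' @export
print.block_alignment <- function(x, ...) {
  cat(sprintf("<block_alignment> %s vs %s: %d aligned pair(s), MPSS %.3f, GPS %.3f\n",
              attr(x$profile_a, "seq_id"), attr(x$profile_b, "seq_id"),
              nrow(x$pairs), x$mpss, x$gps))
  invisible(x)
}

#' Gap penalty score (GPS) of a block alignment
#'
#' With `n` aligned pairs and consecutive centre-to-centre distances `x_i`
#' (first profile) and `y_i` (second profile),
#' `GPS = sqrt(sum((x_i - y_i)^2)) / (n - 1)`. Low GPS means conserved
#' inter-block spacing. Alignments with at most one pair have GPS 0.
#'
#' @param alignment A `block_alignment`, or a pairs tibble when `centers_a`
#'   and `centers_b` are given.
#' @param centers_a,centers_b Optional block-centre vectors overriding the
#'   profiles stored in `alignment` (used by the position-shuffle null).
#' @return The gap penalty score (non-negative real).
#' @export
gap_penalty <- function(alignment, centers_a = NULL, centers_b = NULL) {
  pairs <- if (inherits(alignment, "block_alignment")) alignment$pairs else alignment
  n <- nrow(pairs)
  if (n <= 1) return(0)
  ca <- centers_a %||% alignment$profile_a$center
  cb <- centers_b %||% alignment$profile_b$center
  x <- diff(ca[pairs$idx_a])
  y <- diff(cb[pairs$idx_b])
  sqrt(sum((x - y)^2)) / (n - 1)
}

#' Motif pattern similarity score of two profiles
#'
#' Convenience wrapper returning just the MPSS (fast path, no traceback).
#'
#' @param a,b `block_profile` objects.
#' @return The MPSS (non-negative real).
#' @export
mpss <- function(a, b) lnx_mpss_value(lnx_sim_matrix(a, b))

#' Empirical MPSS null from random cross-species lncRNA pairs
#'
#' Samples transcript pairs uniformly from two profile libraries and records
#' their MPSS. The resulting null is shared by every candidate pair of the
#' species pair (computed once, reused).
#'
#' @param profiles_a,profiles_b Lists of `block_profile` objects (one per
#'   lncRNA of each species); each needs at least 2 profiles.
#' @param n_perm Number of sampled pairs (default 100000; scale down for
#'   interactive work).
#' @param seed Integer seed.
#' @return An object of class `mpss_null` holding the sampled null scores.
#' @export
null_mpss <- function(profiles_a, profiles_b, n_perm = 1e5, seed = 1L) {
  if (length(profiles_a) < 2 || length(profiles_b) < 2) {
    abort("Both profile libraries need at least 2 profiles.")
  }
  set.seed(seed)
  ia <- sample.int(length(profiles_a), n_perm, replace = TRUE)
  ib <- sample.int(length(profiles_b), n_perm, replace = TRUE)
  null <- vapply(seq_len(n_perm), function(k) {
    mpss(profiles_a[[ia[k]]], profiles_b[[ib[k]]])
  }, numeric(1))
  structure(list(null = null, n_perm = n_perm, seed = seed),
            class = "mpss_null")
}

#' MPSS permutation p-value
#'
#' Add-one empirical tail: `p = (1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @param null An `mpss_null` from [null_mpss()].
#' @param observed Observed MPSS value(s).
#' @return P-value(s) in (0, 1].
#' @export
mpss_p_value <- function(null, observed) {
  stopifnot(inherits(null, "mpss_null"))
  vapply(observed, function(o) {
    (1 + sum(null$null >= o - 1e-12)) / (null$n_perm + 1)
  }, numeric(1))
}

#' GPS position-shuffle p-value
#'
#' Re-draws the block centres of both profiles uniformly within their
#' transcripts (order re-sorted), keeps the alignment pairing, and
#' recomputes GPS; significance is a low observed GPS, so
#' `p = (1 + #(null <= observed)) / (n_shuffle + 1)`. Alignments with at
#' most one pair return p = 1.
#'
#' @param alignment A `block_alignment`.
#' @param n_shuffle Number of shuffles (default 1000).
#' @param seed Integer seed.
#' @return P-value in (0, 1].
#' @export
null_gps <- function(alignment, n_shuffle = 1000L, seed = 1L) {
  stopifnot(inherits(alignment, "block_alignment"))
  if (nrow(alignment$pairs) <= 1) return(1)
  len_a <- attr(alignment$profile_a, "seq_length")
  len_b <- attr(alignment$profile_b, "seq_length")
  na <- nrow(alignment$profile_a)
  nb <- nrow(alignment$profile_b)
  obs <- alignment$gps
  set.seed(seed)
  null <- vapply(seq_len(n_shuffle), function(k) {
    ca <- sort(runif(na, 0, len_a))
    cb <- sort(runif(nb, 0, len_b))
    gap_penalty(alignment$pairs, centers_a = ca, centers_b = cb)
  }, numeric(1))
  (1 + sum(null <= obs + 1e-12)) / (n_shuffle + 1)
}

#' Call coPARSE homologs from scored candidate pairs
#'
#' A candidate is called `coPARSE` when both permutation p-values are below
#' `alpha` and its MPSS exceeds `ratio` times the maximum MPSS among the
#' query's candidates; otherwise it is `rejected`.
#'
#' @param candidates Tibble with one row per candidate pair and columns
#'   `query_id`, `target_id`, `mpss`, `p_mpss`, `p_gps`.
#' @param alpha Significance level for both tests (default 0.05).
#' @param ratio Fraction of the per-query maximum MPSS a candidate must
#'   exceed (default 0.8, strict inequality).
#' @return The input tibble with `max_mpss` and `verdict` columns added.
#' @export
call_homologs <- function(candidates, alpha = 0.05, ratio = 0.8) {
  stopifnot(all(c("query_id", "target_id", "mpss", "p_mpss", "p_gps") %in%
                  names(candidates)))
  candidates |>
    group_by(.data$query_id) |>
    mutate(max_mpss = max(.data$mpss)) |>
    ungroup() |>
    mutate(verdict = if_else(
      .data$p_mpss < alpha & .data$p_gps < alpha &
        .data$mpss > ratio * .data$max_mpss,
      "coPARSE", "rejected"))
}

#' Homologous region implied by a block alignment
#'
#' Per transcript, the region runs from the start of the first motif match
#' inside the first aligned block to the end of the last motif match inside
#' the last aligned block.
#'
#' @param alignment A `block_alignment` with at least one pair.
#' @param matches_a,matches_b Match tibbles (from [scan_motifs()]) for the
#'   two transcripts.
#' @return A tibble with one row per transcript: `seq_id`, `start`, `end`,
#'   `defined`. When the alignment is empty both rows are flagged
#'   `defined = FALSE` with `NA` coordinates.
#' @export
homologous_region <- function(alignment, matches_a, matches_b) {
  stopifnot(inherits(alignment, "block_alignment"))
  ids <- c(attr(alignment$profile_a, "seq_id"),
           attr(alignment$profile_b, "seq_id"))
  if (nrow(alignment$pairs) == 0) {
    return(tibble(seq_id = ids, start = NA_integer_, end = NA_integer_,
                  defined = FALSE))
  }
  region_for <- function(profile, idx, matches) {
    first_blk <- profile[min(idx), ]
    last_blk <- profile[max(idx), ]
    m_first <- filter(matches, .data$start >= first_blk$start,
                      .data$end <= first_blk$end)
    m_last <- filter(matches, .data$start >= last_blk$start,
                     .data$end <= last_blk$end)
    c(min(m_first$start), max(m_last$end))
  }
  ra <- region_for(alignment$profile_a, alignment$pairs$idx_a, matches_a)
  rb <- region_for(alignment$profile_b, alignment$pairs$idx_b, matches_b)
  tibble(seq_id = ids, start = c(ra[1], rb[1]), end = c(ra[2], rb[2]),
         defined = TRUE)
}
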