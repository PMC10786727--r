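# Independent oracles used across the suite. Each re-derives the quantity it
# checks from first principles, never through the package's own code path.

# Naive exact substring search: all 0-based start offsets of `pattern` in `s`.
oracle_substring_find <- function(pattern, s) {
  w <- nchar(pattern)
  hits <- integer()
  for (i in seq_len(nchar(s) - w + 1L)) {
    if (substr(s, i, i + w - 1L) == pattern) hits <- c(hits, i - 1L)
  }
  hits
}

# Exhaustive maximum over monotone matchings: enumerate every pair of
# equal-size index subsets of the two sides (order within a monotone matching
# is forced, ascending-to-ascending) and take the best total similarity.
oracle_mpss_enumerate <- function(sim) {
  n <- nrow(sim)
  m <- ncol(sim)
  best <- 0
  for (k in seq_len(min(n, m))) {
    sub_a <- utils::combn(n, k, simplify = FALSE)
    sub_b <- utils::combn(m, k, simplify = FALSE)
    for (sa in sub_a) {
      for (sb in sub_b) {
        tot <- sum(sim[cbind(sa, sb)])
        if (tot > best) best <- tot
      }
    }
  }
  best
}

# Quadratic-time recount of the nine flank numbers for one evidence class.
oracle_flank_recount <- function(gene_a, gene_b, corr, flank_bp) {
  label_one <- function(gene, chrom, start, end) {
    mid <- (start + end) / 2
    if (chrom != gene$chrom) return(NA_character_)
    if (gene$strand == "+") {
      if (mid >= gene$start - flank_bp && mid < gene$start) return("u")
      if (mid >= gene$end && mid < gene$end + flank_bp) return("d")
    } else {
      if (mid >= gene$end && mid < gene$end + flank_bp) return("u")
      if (mid >= gene$start - flank_bp && mid < gene$start) return("d")
    }
    NA_character_
  }
  out <- list()
  for (ev in c("anchor", "protein")) {
    rows <- corr[corr$evidence == ev, ]
    la <- character(nrow(rows))
    lb <- character(nrow(rows))
    for (r in seq_len(nrow(rows))) {
      la[r] <- label_one(gene_a, rows$chrom_a[r], rows$start_a[r], rows$end_a[r])
      lb[r] <- label_one(gene_b, rows$chrom_b[r], rows$start_b[r], rows$end_b[r])
    }
    for (rg in c("u", "d")) {
      out[[paste(ev, rg)]] <- data.frame(
        evidence = ev, region = rg,
        m1 = sum(la == rg, na.rm = TRUE),
        m2 = sum(lb == rg, na.rm = TRUE),
        m = sum(la == rg & lb == rg, na.rm = TRUE))
    }
    out[[paste(ev, "f")]] <- data.frame(
      evidence = ev, region = "f",
      m1 = sum(la %in% c("u", "d")),
      m2 = sum(lb %in% c("u", "d")),
      m = sum(la == lb & la %in% c("u", "d"), na.rm = TRUE))
  }
  do.call(rbind, out)
}

# Rank-sum AUC of scores against binary labels.
oracle_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Build a block profile directly from centres and per-block class counts
# (bypasses scanning; each block spans +/- 4 nt around its centre, clipped
# to the transcript, but keeps the exact centre).
make_profile <- function(centers, counts_list, seq_id = "p", seq_length = 1000) {
  o <- order(centers)
  centers <- centers[o]
  counts_list <- counts_list[o]
  block_profile(
    tibble::tibble(
      start = pmax(centers - 4, 0),
      end = pmin(centers + 4, seq_length),
      center = centers,
      counts = counts_list),
    seq_id = seq_id, seq_length = seq_length)
}

# Random block profile for pure-null fixtures: `n_blocks` well-separated
# blocks, 1-2 classes per block from a 15-class alphabet, counts 1-5.
random_null_profile <- function(n_blocks = 8, seq_length = 2000, id = "p") {
  centers <- sort(runif(n_blocks, 20, seq_length - 20))
  while (any(diff(centers) < 10)) {
    centers <- sort(runif(n_blocks, 20, seq_length - 20))
  }
  counts <- lapply(seq_len(n_blocks), function(i) {
    k <- sample(1:2, 1)
    cls <- sample(sprintf("RBP%02d", 1:15), k)
    stats::setNames(sample(1:5, k, replace = TRUE), cls)
  })
  make_profile(centers, counts, seq_id = id, seq_length = seq_length)
}
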