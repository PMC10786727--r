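point_mass_pwm <- function(word, id = "pm") {
  bases <- strsplit(word, "", fixed = TRUE)[[1]]
  mat <- matrix(0.001, nchar(word), 4)
  mat[cbind(seq_along(bases), match(bases, c("A", "C", "G", "T")))] <- 0.997
  pwm(mat, motif_id = id, rbp_name = id)
}

test_that("point-mass PWM scanning reduces to exact substring search", {
  # the exact w-mer has null probability 0.25^w; any threshold below the
  # next score class (1-mismatch words) admits exactly the substring hits
  p <- point_mass_pwm("ACGT")
  hits <- scan_motifs(p, c(s = "TTACGTT"), p_threshold = 1.3 * 0.25^4)
  expect_equal(hits$start, 2L)
  expect_equal(hits$end, 6L)

  set.seed(31)
  for (i in 1:100) {
    w <- sample(4:7, 1)
    word <- paste(sample(c("A", "C", "G", "T"), w, TRUE), collapse = "")
    s <- paste(sample(c("A", "C", "G", "T"), sample(50:200, 1), TRUE),
               collapse = "")
    # plant the word once so non-trivial cases occur often
    at <- sample(nchar(s) - w, 1)
    s <- paste0(substr(s, 1, at), word, substr(s, at + w + 1, nchar(s)))
    got <- scan_motifs(point_mass_pwm(word), c(s = s),
                       p_threshold = 1.3 * 0.25^w)$start
    expect_equal(got, oracle_substring_find(word, s))
  }
})

test_that("uniform PWM never matches and N windows never match", {
  u <- pwm(matrix(0.25, 5, 4), motif_id = "u")
  expect_equal(nrow(scan_motifs(u, c(s = "ACGTACGTACGT"))), 0)
  p <- point_mass_pwm("ACGT")
  expect_equal(nrow(scan_motifs(p, c(s = "TTACGNT"), p_threshold = 0.005)), 0)
  # shorter than motif width: empty, not an error
  expect_equal(nrow(scan_motifs(p, c(s = "AC"))), 0)
  expect_error(scan_motifs(p, c(s = "ACXT")), "outside")
})

test_that("width-4 scan p-values equal exhaustive 4-mer enumeration", {
  set.seed(32)
  for (trial in 1:5) {
    mat <- matrix(stats::rgamma(16, 1), 4, 4)
    mat <- mat / rowSums(mat)
    p <- pwm(mat, motif_id = "w4", pseudocount = 1e-9)
    # oracle: score and null mass of every 4-mer, computed independently
    lo <- log2(p$matrix / 0.25)
    kmers <- expand.grid(b1 = 1:4, b2 = 1:4, b3 = 1:4, b4 = 1:4)
    oracle_score <- unname(lo[1, kmers$b1] + lo[2, kmers$b2] + lo[3, kmers$b3] +
                             lo[4, kmers$b4])
    oracle_p <- vapply(oracle_score, function(s)
      sum(oracle_score >= s - 1e-9) / 256, numeric(1))
    seqs <- setNames(
      apply(kmers, 1, function(r) paste(c("A", "C", "G", "T")[r], collapse = "")),
      sprintf("k%03d", seq_len(256)))
    hits <- scan_motifs(p, seqs, p_threshold = 1)
    expect_equal(nrow(hits), 256)
    idx <- match(hits$seq_id, names(seqs))
    expect_equal(hits$p_value, oracle_p[idx], tolerance = 1e-12)
    expect_equal(hits$score, unname(oracle_score[idx]), tolerance = 1e-6)
  }
})

test_that("binned-DP p-values for wide motifs agree with enumeration at the boundary", {
  # width 9 uses the 1e-3-bit binned dynamic program; cross-check its tail
  # probabilities against direct enumeration of all 4^9 words
  set.seed(33)
  mat <- matrix(stats::rgamma(36, 2), 9, 4)
  mat <- mat / rowSums(mat)
  p <- pwm(mat, motif_id = "w9", pseudocount = 1e-9)
  lo <- log2(p$matrix / 0.25)
  scores <- 0
  for (j in 1:9) scores <- rep(scores, each = 4) + lo[j, ]
  hits <- scan_motifs(p, c(s = paste(rep(pwm_consensus(p), 1), collapse = "")),
                      p_threshold = 1)
  oracle_p <- sum(scores >= max(scores) - 1e-6) / 4^9
  expect_equal(hits$p_value[1], oracle_p, tolerance = 1e-3)
})

test_that("scanning is translation-equivariant", {
  set.seed(34)
  lib <- make_motif_library(n_motifs = 3, seed = 34)
  s <- make_homolog_pair(lib, n_blocks = 3, seed = 34)$seq_a
  base <- scan_motif_library(lib, c(s = s))
  for (k in c(1, 7, 40)) {
    shifted <- scan_motif_library(lib, c(s = paste0(strrep("A", k), s)))
    shifted <- shifted[shifted$start >= k, ] # ignore edge artefacts in the pad
    expect_equal(shifted$start, base$start + k)
    expect_equal(shifted$motif_id, base$motif_id)
  }
})

test_that("match clustering follows the half-overlap rule", {
  mk <- function(starts, ends, cls = "X") tibble::tibble(
    seq_id = "s", motif_id = cls, motif_class = cls,
    start = starts, end = ends, score = 1, p_value = 1e-5)
  # overlap 4 >= half of the shorter (8) -> one block
  one <- cluster_matches(mk(c(0L, 4L), c(8L, 12L)), seq_length = 20)
  expect_equal(nrow(one), 1)
  expect_equal(one$start, 0L)
  expect_equal(one$end, 12L)
  # overlap 2 < 4 -> two blocks
  two <- cluster_matches(mk(c(0L, 6L), c(8L, 14L)), seq_length = 20)
  expect_equal(nrow(two), 2)
  # empty input -> empty profile
  empty <- cluster_matches(mk(integer(), integer()), seq_id = "s",
                           seq_length = 20)
  expect_equal(nrow(empty), 0)
})

test_that("clustering conserves matches, ignores input order and is idempotent", {
  set.seed(35)
  lib <- make_motif_library(seed = 35)
  for (i in 1:20) {
    hp <- make_homolog_pair(lib, seed = 400 + i)
    m <- scan_motif_library(lib, c(s = hp$seq_a))
    prof <- cluster_matches(m, seq_length = 1000)
    # every match lands in exactly one block
    expect_equal(sum(vapply(prof$counts, sum, numeric(1))), nrow(m))
    # input order is irrelevant
    shuf <- cluster_matches(m[sample.int(nrow(m)), ], seq_length = 1000)
    expect_equal(as.data.frame(prof), as.data.frame(shuf))
    # re-clustering the block spans leaves them unchanged
    spans <- tibble::tibble(seq_id = "s", motif_id = "b", motif_class = "b",
                            start = prof$start, end = prof$end,
                            score = 1, p_value = 1e-5)
    expect_equal(cluster_matches(spans, seq_length = 1000)$start, prof$start)
  }
})

test_that("PWM similarity finds identity and calibrates its permutation null", {
  lib <- make_motif_library(n_motifs = 6, seed = 36)
  self <- pwm_similarity(lib[[1]], lib[[1]], n_perm = 100, seed = 1)
  expect_equal(self$offset, 0L)
  expect_equal(self$correlation, 1, tolerance = 1e-12)
  expect_true(self$p_value < 0.05)

  # reversing the columns of a non-palindromic motif breaks the correlation
  rev_mat <- lib[[1]]$matrix[rev(seq_len(pwm_width(lib[[1]]))), ]
  revp <- pwm(rev_mat, motif_id = "rev")
  at0 <- cor(as.vector(t(lib[[1]]$matrix)), as.vector(t(revp$matrix)))
  expect_lt(at0, 1)

  # a motif against its own column-shuffled self: the permutation p-value
  # should rarely be significant
  set.seed(37)
  nonsig <- 0
  n_trials <- 40
  for (t in seq_len(n_trials)) {
    shuffled <- pwm(lib[[2]]$matrix[sample.int(pwm_width(lib[[2]])), ],
                    motif_id = "shuf")
    r <- pwm_similarity(lib[[2]], shuffled, n_perm = 200, seed = 1000 + t)
    if (r$p_value >= 0.05) nonsig <- nonsig + 1
  }
  expect_gte(nonsig / n_trials, 0.95)

  # width-4 vs wide motif still has a 4-column overlap to compare
  narrow <- point_mass_pwm("ACGT")
  expect_true(pwm_similarity(narrow, lib[[1]], n_perm = 50)$comparable)
})

test_that("motif extrapolation refines towards the sites it maps", {
  lib <- make_motif_library(n_motifs = 3, seed = 38)
  p <- lib[[1]]
  cons <- pwm_consensus(p)
  set.seed(38)
  bg <- function() paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  targets <- setNames(
    vapply(1:20, function(i) paste0(bg(), cons, bg()), character(1)),
    paste0("t", 1:20))
  # consensus present verbatim: immediate fixed point
  out <- extrapolate_motif(p, targets, tol = 0.05)
  expect_true(attr(out, "converged"))
  expect_equal(pwm_consensus(out), cons)

  # no matches at all: input returned, flagged unconverged
  none <- extrapolate_motif(p, c(x = strrep("A", 100)))
  expect_false(attr(none, "converged"))
  expect_equal(unname(none$matrix), unname(p$matrix))

  # sites carrying a single-base variant pull the consensus towards it
  var <- cons
  substr(var, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                               substr(cons, 3, 3))[1]
  var_targets <- setNames(
    vapply(1:50, function(i) paste0(bg(), var, bg()), character(1)),
    paste0("v", 1:50))
  refined <- extrapolate_motif(p, var_targets, p_threshold = 2e-3,
                               max_iter = 10, tol = 1e-4)
  expect_equal(pwm_consensus(refined), var)
  # row-stochasticity is preserved
  expect_true(all(abs(rowSums(refined$matrix) - 1) < 1e-6))
})

test_that("RBP-site mutation replaces sites with their antisense sequence", {
  expect_equal(mutate_rbp_sites("AAACGTAA", tibble::tibble(start = 3, end = 6)),
               "AAAACGAA")
  expect_equal(mutate_rbp_sites("ACGTACGT", tibble::tibble(start = integer(),
                                                           end = integer())),
               "ACGTACGT")
  # a reverse-complement palindrome is invariant
  expect_equal(mutate_rbp_sites("TTACGTTT", tibble::tibble(start = 2, end = 6)),
               "TTACGTTT")
  expect_error(
    mutate_rbp_sites("ACGTACGT", tibble::tibble(start = c(0, 2), end = c(4, 6))),
    "disjoint")
})
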