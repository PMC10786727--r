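test_that("block similarity follows the min/max per-class formula", {
  expect_equal(block_similarity(c(M1 = 3), c(M1 = 3)), 1)
  expect_equal(block_similarity(c(M1 = 2, M2 = 1), c(M1 = 1, M2 = 2)), 1)
  expect_equal(block_similarity(c(M1 = 2), c(M2 = 2)), 0)
  # symmetric, and classes absent from both contribute nothing
  set.seed(41)
  for (i in 1:50) {
    a <- setNames(sample(1:5, 3, TRUE), sample(LETTERS, 3))
    b <- setNames(sample(1:5, 3, TRUE), sample(LETTERS, 3))
    expect_equal(block_similarity(a, b), block_similarity(b, a))
    shared <- intersect(names(a), names(b))
    direct <- sum(vapply(shared, function(k)
      min(a[k], b[k]) / max(a[k], b[k]), numeric(1)))
    expect_equal(block_similarity(a, b), direct, tolerance = 1e-12)
  }
})

test_that("MPSS dynamic programming equals exhaustive monotone matching", {
  prof1 <- make_profile(500, list(c(X = 1)), "a")
  prof2 <- make_profile(300, list(c(X = 1)), "b")
  al <- align_blocks(prof1, prof2)
  expect_equal(al$mpss, 1)
  expect_equal(al$pairs$idx_a, 1L)

  set.seed(42)
  for (i in 1:300) {
    na <- sample(1:7, 1)
    nb <- sample(1:7, 1)
    a <- random_null_profile(na, id = "a")
    b <- random_null_profile(nb, id = "b")
    sim <- outer(seq_len(na), seq_len(nb), Vectorize(function(x, y)
      block_similarity(a$counts[[x]], b$counts[[y]])))
    oracle <- oracle_mpss_enumerate(matrix(sim, na, nb))
    expect_equal(align_blocks(a, b)$mpss, oracle, tolerance = 1e-12)
    expect_equal(mpss(a, b), oracle, tolerance = 1e-12)
    # symmetry
    expect_equal(mpss(b, a), oracle, tolerance = 1e-12)
  }
})

test_that("appending a block never decreases the MPSS", {
  set.seed(43)
  for (i in 1:30) {
    a <- random_null_profile(5, id = "a")
    b <- random_null_profile(5, id = "b")
    base <- mpss(a, b)
    b2 <- random_null_profile(6, id = "b")
    # reuse b's first five blocks, append a fresh sixth
    b2$counts[1:5] <- b$counts
    expect_gte(mpss(a, b2), mpss(a, b2[1:5, ]) - 1e-12)
  }
})

test_that("gap penalty matches the printed formula", {
  # three aligned pairs, inter-block distances x = (100, 200), y = (100, 230)
  a <- make_profile(c(100, 200, 400), list(c(X = 1), c(Y = 1), c(Z = 1)), "a")
  b <- make_profile(c(100, 200, 430), list(c(X = 1), c(Y = 1), c(Z = 1)), "b")
  al <- align_blocks(a, b)
  expect_equal(nrow(al$pairs), 3)
  expect_equal(al$gps, sqrt(0 + 900) / 2)
  expect_equal(al$gps, 15)

  # identical spacing: zero
  b0 <- make_profile(c(300, 400, 600), list(c(X = 1), c(Y = 1), c(Z = 1)), "b")
  expect_equal(align_blocks(a, b0)$gps, 0)

  # a single aligned pair has no distances
  one <- align_blocks(make_profile(100, list(c(X = 1)), "a"),
                      make_profile(700, list(c(X = 1)), "b"))
  expect_equal(one$gps, 0)
  # GPS is symmetric
  expect_equal(align_blocks(b, a)$gps, al$gps)
})

test_that("MPSS p-values use the add-one convention on a shared null", {
  set.seed(44)
  lib_a <- lapply(1:10, function(i) random_null_profile(id = paste0("a", i)))
  lib_b <- lapply(1:10, function(i) random_null_profile(id = paste0("b", i)))
  null <- null_mpss(lib_a, lib_b, n_perm = 200, seed = 9)
  expect_equal(mpss_p_value(null, max(null$null) + 1), 1 / 201)
  expect_equal(mpss_p_value(null, -1), 1)
  med <- median(null$null)
  expect_equal(mpss_p_value(null, med), 0.5, tolerance = 0.15)
  expect_error(null_mpss(lib_a[1], lib_b, n_perm = 10), "at least 2")
})

test_that("GPS shuffle p-values flag conserved spacing and respect conventions", {
  a <- make_profile(c(100, 300, 500, 700), lapply(1:4, function(i)
    setNames(1L, paste0("C", i))), "a", seq_length = 1000)
  b <- make_profile(c(120, 320, 520, 720), lapply(1:4, function(i)
    setNames(1L, paste0("C", i))), "b", seq_length = 1000)
  al <- align_blocks(a, b)
  expect_equal(al$gps, 0) # identical spacing
  expect_equal(null_gps(al, n_shuffle = 200, seed = 5), 1 / 201)
  # one aligned pair: conventionally p = 1
  one <- align_blocks(make_profile(100, list(c(X = 1)), "a"),
                      make_profile(500, list(c(X = 1)), "b"))
  expect_equal(null_gps(one), 1)
})

test_that("GPS shuffle p-values are uniform under the positional null", {
  # profiles whose alignment is forced (distinct class per rank) and whose
  # observed centres are themselves uniform draws: p should be U(0, 1]
  set.seed(45)
  n_trials <- 400
  pv <- vapply(seq_len(n_trials), function(t) {
    cls <- lapply(1:6, function(i) setNames(1L, paste0("C", i)))
    # observed centres drawn from exactly the distribution the null redraws
    a <- make_profile(sort(runif(6, 0, 2000)), cls, "a", seq_length = 2000)
    b <- make_profile(sort(runif(6, 0, 2000)), cls, "b", seq_length = 2000)
    al <- align_blocks(a, b)
    null_gps(al, n_shuffle = 200, seed = 5000 + t)
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("homolog calling applies both p-value gates and the MPSS ratio", {
  cand <- tibble::tibble(
    query_id = c("q1", "q2", "q2", "q3"),
    target_id = c("t1", "t2", "t3", "t4"),
    mpss = c(4, 10, 7.9, 6),
    p_mpss = c(0.01, 0.01, 0.01, 0.01),
    p_gps = c(0.01, 0.01, 0.01, 0.06))
  calls <- call_homologs(cand)
  # a single significant candidate is its own maximum
  expect_equal(calls$verdict[calls$target_id == "t1"], "coPARSE")
  # 7.9 <= 0.8 * 10 fails the ratio gate
  expect_equal(calls$verdict[calls$target_id == "t2"], "coPARSE")
  expect_equal(calls$verdict[calls$target_id == "t3"], "rejected")
  # p_gps = 0.06 rejects regardless of MPSS
  expect_equal(calls$verdict[calls$target_id == "t4"], "rejected")
})

test_that("homologous regions span first to last aligned motif match", {
  m <- function(starts, ends, cls) tibble::tibble(
    seq_id = "s", motif_id = cls, motif_class = cls,
    start = starts, end = ends, score = 1, p_value = 1e-5)
  # one block on each side containing two matches
  ma <- m(c(10L, 30L), c(18L, 38L), "X")
  mb <- m(c(50L, 70L), c(58L, 78L), "X")
  pa <- cluster_matches(dplyr::mutate(ma, start = c(10L, 12L), end = c(18L, 20L)),
                        seq_id = "a", seq_length = 100)
  pb <- cluster_matches(dplyr::mutate(mb, start = c(50L, 52L), end = c(58L, 60L)),
                        seq_id = "b", seq_length = 100)
  al <- align_blocks(pa, pb)
  reg <- homologous_region(al,
                           dplyr::mutate(ma, start = c(10L, 12L), end = c(18L, 20L)),
                           dplyr::mutate(mb, start = c(50L, 52L), end = c(58L, 60L)))
  expect_equal(reg$start, c(10L, 50L))
  expect_equal(reg$end, c(20L, 60L))
  expect_true(all(reg$defined))

  # no alignment: undefined flag
  pz <- make_profile(500, list(c(Z = 1)), "z")
  py <- make_profile(500, list(c(Y = 1)), "y")
  none <- homologous_region(align_blocks(pz, py), ma, mb)
  expect_false(any(none$defined))
})

test_that("planted block patterns are called while shuffled decoys are not", {
  lib <- make_motif_library(seed = 46)
  n_inst <- 30
  profs <- list()
  for (i in seq_len(n_inst)) {
    hp <- make_homolog_pair(lib, seed = 4600 + i)
    hd <- make_homolog_pair(lib, decoy = TRUE, seed = 4600 + i)
    profs[[i]] <- list(
      q = cluster_matches(scan_motif_library(lib, c(q = hp$seq_a)),
                          seq_id = "q", seq_length = 1000),
      t = cluster_matches(scan_motif_library(lib, c(t = hp$seq_b)),
                          seq_id = "t", seq_length = 1000),
      d = cluster_matches(scan_motif_library(lib, c(d = hd$seq_b)),
                          seq_id = "d", seq_length = 1000))
  }
  null <- null_mpss(lapply(profs, `[[`, "q"),
                    c(lapply(profs, `[[`, "t"), lapply(profs, `[[`, "d")),
                    n_perm = 1000, seed = 46)
  rows <- purrr::map_dfr(seq_len(n_inst), function(i) {
    purrr::map_dfr(c("t", "d"), function(kind) {
      al <- align_blocks(profs[[i]]$q, profs[[i]][[kind]])
      tibble::tibble(
        query_id = paste0("q", i), target_id = kind, mpss = al$mpss,
        p_mpss = mpss_p_value(null, al$mpss),
        p_gps = null_gps(al, n_shuffle = 200, seed = 460 + i))
    })
  })
  calls <- call_homologs(rows)
  planted_rate <- mean(calls$verdict[calls$target_id == "t"] == "coPARSE")
  decoy_rate <- mean(calls$verdict[calls$target_id == "d"] == "coPARSE")
  expect_gte(planted_rate, 0.9)
  expect_lte(decoy_rate, 0.1)
})
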