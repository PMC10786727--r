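# A small deterministic toy genome shared by the crRNA filter tests.
toy_genome <- function(seed = 71, len = 4000) {
  set.seed(seed)
  g <- paste(sample(c("A", "C", "G", "T"), len, TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  c(chrT = g)
}

# Enumerate every TTTV-PAM protospacer on the forward strand of a genome.
enumerate_crrnas <- function(genome, gene_id = "lncT", strand = "+") {
  g <- genome[[1]]
  out <- list()
  for (i in seq_len(nchar(g) - 27L)) {
    pam <- substr(g, i, i + 3L)
    if (grepl("^TTT[ACG]$", pam)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        crrna_id = sprintf("cr%04d", i), gene_id = gene_id,
        chrom = names(genome)[1], start = i + 3L, end = i + 26L,
        strand = strand,
        protospacer = substr(g, i + 4L, i + 26L), pam = pam)
    }
  }
  dplyr::bind_rows(out)
}

test_that("crRNA filters apply PAM, GC, poly-U and off-target rules", {
  genome <- toy_genome()
  base <- enumerate_crrnas(genome)[1, ]
  ok <- filter_crrna(base, genome)
  expect_true(ok$accept)

  bad_pam <- dplyr::mutate(base, pam = "TTTT")
  expect_match(filter_crrna(bad_pam, genome)$reasons, "PAM")

  gc_low <- base
  gc_low$protospacer <- paste0(strrep("A", 20), "CGT")
  expect_match(filter_crrna(gc_low, genome)$reasons, "GC")

  poly_u <- base
  poly_u$protospacer <- paste0("GCGC", "TTTT", substr(base$protospacer, 9, 23))
  expect_match(filter_crrna(poly_u, genome)$reasons, "polyU")

  # a protospacer absent from the genome fails mapping
  absent <- base
  absent$protospacer <- paste(rep("GCAT", 6), collapse = "")
  absent$protospacer <- substr(paste0(absent$protospacer, "G"), 1, 23)
  res <- filter_crrna(absent, genome)
  expect_match(res$reasons, "no_map")

  # duplicating the locus elsewhere makes it multi-mapping
  dup_genome <- genome
  dup_genome[["chrT"]] <- paste0(genome[["chrT"]], base$protospacer)
  expect_match(filter_crrna(base, dup_genome)$reasons, "multi_map")

  # a 1-mismatch second locus violates the >= 2 mismatch rule
  near <- base$protospacer
  substr(near, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                  substr(near, 11, 11))[1]
  near_genome <- genome
  near_genome[["chrT"]] <- paste0(genome[["chrT"]], near)
  expect_match(filter_crrna(base, near_genome)$reasons, "off_target")
})

test_that("accepted crRNAs equal an independent brute-force rule check", {
  genome <- toy_genome(72)
  cand <- enumerate_crrnas(genome)
  got <- filter_crrna(cand, genome)

  g <- genome[[1]]
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  grc <- rc(g)
  hamming_hits <- function(word, subject, maxd) {
    w <- nchar(word)
    wv <- strsplit(word, "")[[1]]
    n <- 0L
    for (i in seq_len(nchar(subject) - w + 1L)) {
      d <- sum(strsplit(substr(subject, i, i + w - 1L), "")[[1]] != wv)
      if (d <= maxd) n <- n + 1L
    }
    n
  }
  for (r in sample(seq_len(nrow(cand)), 12)) {
    p <- cand$protospacer[r]
    gc <- mean(strsplit(p, "")[[1]] %in% c("G", "C"))
    exact <- hamming_hits(p, g, 0) + hamming_hits(p, grc, 0)
    near <- hamming_hits(p, g, 1) + hamming_hits(p, grc, 1)
    ok <- grepl("^TTT[ACG]$", cand$pam[r]) && gc >= 0.2 && gc <= 0.9 &&
      !grepl("TTTT", p, fixed = TRUE) && exact == 1 && near == 1
    expect_equal(got$accept[r], ok)
  }
})

test_that("crRNA pairing enforces TSS flanking, exon avoidance and strand", {
  lnc <- tibble::tibble(gene_id = "lncT", chrom = "chrT", start = 2000L,
                        end = 2600L, strand = "+")
  crrnas <- tibble::tibble(
    crrna_id = c("up1", "up2", "dn1", "exonic", "wrong_strand"),
    gene_id = "lncT", chrom = "chrT",
    start = c(1500L, 1700L, 2200L, 2300L, 2250L),
    end = c(1523L, 1723L, 2223L, 2323L, 2273L),
    strand = c("+", "+", "+", "+", "-"))
  exons <- tibble::tibble(chrom = "chrT", start = 2290L, end = 2400L)
  pairs <- filter_crrna_pairs(crrnas, lnc, exons)
  # only upstream x downstream combinations of clean sense-strand crRNAs
  expect_setequal(paste(pairs$crrna_1, pairs$crrna_2),
                  c("up1 dn1", "up2 dn1"))
  # both-upstream pairs must not appear
  expect_false(any(pairs$crrna_1 == "up1" & pairs$crrna_2 == "up2"))

  # brute-force enumeration over all candidate pairs agrees
  cand_idx <- utils::combn(nrow(crrnas), 2)
  manual <- character()
  for (k in seq_len(ncol(cand_idx))) {
    i <- cand_idx[1, k]; j <- cand_idx[2, k]
    ci <- crrnas[i, ]; cj <- crrnas[j, ]
    mid_i <- (ci$start + ci$end) / 2; mid_j <- (cj$start + cj$end) / 2
    in_exon <- function(x) any(exons$start < x$end & exons$end > x$start)
    if (ci$strand == "+" && cj$strand == "+" &&
        !in_exon(ci) && !in_exon(cj) &&
        ((mid_i < 2000) != (mid_j < 2000))) {
      manual <- c(manual, paste(ci$crrna_id, cj$crrna_id))
    }
  }
  expect_setequal(paste(pairs$crrna_1, pairs$crrna_2), manual)

  # essential-gene overlap flags but keeps the pair
  essential <- tibble::tibble(chrom = "chrT", start = 1400L, end = 1600L)
  flagged <- filter_crrna_pairs(crrnas, lnc, exons, essential)
  expect_true(flagged$essential_flag[flagged$crrna_1 == "up1"][1])
  expect_equal(nrow(flagged), nrow(pairs))
})

test_that("the cubic trend interpolates four timepoints exactly", {
  days <- c(0, 15, 30, 45)
  # counts generated from a known cubic in log2 space
  coefs <- c(9, 0.08, -0.004, 0.00005)
  logf <- function(d) coefs[1] + coefs[2] * d + coefs[3] * d^2 + coefs[4] * d^3
  tab <- tibble::tibble(
    pair_id = c("p1", "c1", "c2"), gene_id = c("g1", "AAVS1", "AAVS1"),
    control = c(FALSE, TRUE, TRUE))
  for (i in seq_along(days)) {
    tab[[paste0("d", days[i])]] <- c(2^logf(days[i]) - 1, 500, 500)
  }
  tr <- fit_time_trend(tab, days)
  expect_equal(tr$trend_raw[1], logf(45) - logf(0), tolerance = 1e-9)
  # flat controls have zero raw trend, so centring leaves p1 unchanged
  expect_equal(tr$trend_raw[2], 0, tolerance = 1e-9)
  expect_equal(tr$trend_stat[1], tr$trend_raw[1], tolerance = 1e-9)

  # adding a constant to all counts in log space cancels in the statistic
  tab2 <- tab
  for (d in paste0("d", days)) tab2[[d]] <- (tab[[d]] + 1) * 4 - 1
  tr2 <- fit_time_trend(tab2, days)
  expect_equal(tr2$trend_stat, tr$trend_stat, tolerance = 1e-9)

  expect_error(fit_time_trend(tab[, 1:6], days[1:3]), "4 distinct")
})

test_that("crRNA ranking is ascending, normalised and tie-averaged", {
  tr <- tibble::tibble(pair_id = paste0("p", 1:4), gene_id = "g",
                       control = FALSE,
                       trend_raw = 0, trend_stat = c(-2, 0, 0, 1))
  rk <- rank_crrnas(tr)
  expect_equal(rk$norm_rank[1], 1 / 4)
  expect_equal(rk$norm_rank[2:3], c(2.5 / 4, 2.5 / 4))
  all_tied <- rank_crrnas(dplyr::mutate(tr, trend_stat = 7))
  expect_equal(all_tied$norm_rank, rep((4 + 1) / (2 * 4), 4))
})

test_that("RRA rho equals closed-form Beta order-statistic values", {
  mk_ranks <- function(gene_ranks) {
    # one control row keeps the pool realistic without affecting gene scores
    tibble::tibble(
      pair_id = paste0("p", seq_len(length(gene_ranks) + 1)),
      gene_id = c(rep("g1", length(gene_ranks)), "AAVS1"),
      control = c(rep(FALSE, length(gene_ranks)), TRUE),
      norm_rank = c(gene_ranks, 0.5))
  }
  r1 <- rra_gene_scores(mk_ranks(0.2), n_perm = 100, seed = 1)
  expect_equal(r1$rho, 0.2, tolerance = 1e-12)
  r2 <- rra_gene_scores(mk_ranks(c(0.1, 0.9)), n_perm = 100, seed = 1)
  expect_equal(r2$rho, min(1 - (1 - 0.1)^2, 0.9^2), tolerance = 1e-12)
  expect_equal(r2$rho, 0.19, tolerance = 1e-12)
  # improving a rank never increases rho
  set.seed(73)
  for (i in 1:20) {
    r <- sort(runif(4))
    rho_of <- function(rr) min(pbeta(sort(rr), 1:4, 4:1 + 0))
    better <- r; j <- sample(4, 1); better[j] <- better[j] * 0.5
    expect_lte(rho_of(better), rho_of(r) + 1e-12)
  }
})

test_that("simulated screens recover planted depletions with calibrated nulls", {
  sim <- make_screen(n_genes = 500, seed = 74)
  tr <- fit_time_trend(sim$screen_table, c(0, 15, 30, 45))
  rk <- rank_crrnas(tr)
  rra <- rra_gene_scores(rk, n_perm = 2000, seed = 74)
  merged <- dplyr::inner_join(as.data.frame(rra), sim$truth, by = "gene_id")
  top_decile <- merged$rank <= ceiling(nrow(merged) / 10)
  expect_gte(mean(top_decile[merged$depleted]), 0.9)
  # false positive rate among null genes at p < 0.05
  fpr <- mean(merged$p_value[!merged$depleted] < 0.05)
  expect_lt(abs(fpr - 0.05), 0.02)
  expect_true(all(rra$rho > 0 & rra$rho <= 1))
})

test_that("the CNV diagnostic flags planted confounds and handles degeneracy", {
  sim <- make_screen(n_genes = 300, seed = 75)
  tr <- fit_time_trend(sim$screen_table, c(0, 15, 30, 45))
  rra <- rra_gene_scores(rank_crrnas(tr), n_perm = 500, seed = 75)
  set.seed(75)
  indep <- tibble::tibble(gene_id = rra$gene_id, cnv = rnorm(nrow(rra)))
  chk <- cnv_bias_check(rra, indep)
  expect_true(chk$defined)
  expect_false(chk$flagged)
  # CNV deterministically tied to rho must raise the flag
  confound <- tibble::tibble(gene_id = rra$gene_id, cnv = -rank(rra$rho))
  expect_true(cnv_bias_check(rra, confound)$flagged)
  const <- tibble::tibble(gene_id = rra$gene_id, cnv = 2)
  expect_false(cnv_bias_check(rra, const)$defined)
})
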