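#' Overlap score between two lncRNA annotation sets
#'
#' `0.5 * (m/n1 + m/n2)` where `n1`, `n2` are the set sizes and `m` the
#' number of common lncRNAs.
#'
#' @param n1,n2 Positive set sizes.
#' @param m Number of shared members, `m <= min(n1, n2)`.
#' @return The overlap score in \[0, 1\].
#' @export
overlap_score <- function(n1, n2, m) {
  if (any(n1 <= 0) || any(n2 <= 0)) abort("`n1` and `n2` must be positive.")
  if (any(m > pmin(n1, n2)) || any(m < 0)) abort("`m` must lie in [0, min(n1, n2)].")
  0.5 * (m / n1 + m / n2)
}

#' Jaccard index of cross-species gene conservation
#'
#' `n / (x + y - n)` where `x` and `y` are the gene counts in the two
#' species and `n` the number of homologous genes.
#'
#' @param x,y Gene counts per species.
#' @param n Number of homologous genes, `n <= min(x, y)`.
#' @return The Jaccard index in \[0, 1\].
#' @export
jaccard_index <- function(x, y, n) {
  if (any(n > pmin(x, y)) || any(n < 0)) abort("`n` must lie in [0, min(x, y)].")
  n / (x + y - n)
}

#' Classify homolog pairs by sequence similarity of alignment hits
#'
#' A pair is `homolog_ss` (sequence-similar) when any hit passes all three
#' strict thresholds (E-value below `evalue_max`, hit length above
#' `min_hit_len`, overall identity above `min_identity`), otherwise
#' `homolog_nss`. The `"rbp"` preset applies the homologous-RBP rule
#' instead: alignment coverage and identity both at least 0.7.
#'
#' @param hits Tibble with `pair_id`, `evalue`, `hit_length`, `identity`
#'   and, for the RBP preset, `coverage`.
#' @param evalue_max,min_hit_len,min_identity Defaults 1e-4, 50 nt, 0.5.
#' @param preset `"lncrna"` (default) or `"rbp"`.
#' @return Tibble `pair_id`, `label` with one row per pair (pairs with no
#'   hits must still appear in `hits` with `NA` metrics to be labelled).
#' @export
sequence_homology_classify <- function(hits, evalue_max = 1e-4,
                                       min_hit_len = 50, min_identity = 0.5,
                                       preset = c("lncrna", "rbp")) {
  preset <- match.arg(preset)
  pass <- if (preset == "lncrna") {
    !is.na(hits$evalue) & hits$evalue < evalue_max &
      hits$hit_length > min_hit_len & hits$identity > min_identity
  } else {
    !is.na(hits$identity) & hits$coverage >= 0.7 & hits$identity >= 0.7
  }
  hits |>
    mutate(.pass = pass & !is.na(pass)) |>
    group_by(.data$pair_id) |>
    summarise(label = if_else(any(.data$.pass), "homolog_ss", "homolog_nss"),
              .groups = "drop")
}

#' Common histone modification site rate of a lncRNA pair
#'
#' `sum(min(x_i, y_i)) / sum(max(x_i, y_i))` over histone modification
#' types, where `x_i` and `y_i` are per-type site counts for the two genes
#' (gene body plus nearby regions). Returns 0 when both vectors are all
#' zero.
#'
#' @param x,y Non-negative count vectors of equal length.
#' @return The rate in \[0, 1\].
#' @export
common_histone_rate <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (any(x < 0) || any(y < 0)) abort("Counts must be non-negative.")
  denom <- sum(pmax(x, y))
  if (denom == 0) return(0)
  sum(pmin(x, y)) / denom
}

#' Partition a transcript into motif and nonmotif regions
#'
#' Motif regions are the union of motif-match intervals; nonmotif regions
#' are their complement within the transcript.
#'
#' @param transcript_length Transcript length in nt.
#' @param matches Match tibble with `start`, `end` (from [scan_motifs()]).
#' @return Tibble of disjoint intervals with a `region` column
#'   (`"motif"` / `"nonmotif"`); interval lengths sum to
#'   `transcript_length`.
#' @export
motif_region_partition <- function(transcript_length, matches) {
  motif <- lnx_union_intervals(matches$start, pmin(matches$end, transcript_length))
  nonmotif <- lnx_complement_intervals(motif, transcript_length)
  bind_rows(
    if (nrow(motif)) mutate(motif, region = "motif"),
    if (nrow(nonmotif)) mutate(nonmotif, region = "nonmotif")
  ) |> arrange(.data$start)
}

#' Variant density per kilobase of an interval set
#'
#' @param intervals Tibble of disjoint intervals (`start`, `end`).
#' @param variants Tibble with a `position` column (0-based).
#' @return Variants per kb over the union of the intervals (`NA` for an
#'   empty interval set).
#' @export
snp_density <- function(intervals, variants) {
  total <- sum(intervals$end - intervals$start)
  if (total == 0) return(NA_real_)
  inside <- map_lgl(variants$position, function(p) {
    any(p >= intervals$start & p < intervals$end)
  })
  1000 * sum(inside) / total
}

#' Compare SNP measures between motif and nonmotif regions
#'
#' Splits variants by whether they fall in motif or nonmotif regions of a
#' partition and compares a per-variant measure (e.g. allele frequency)
#' between the two groups with a two-sided Mann-Whitney U test.
#'
#' @param partition Output of [motif_region_partition()].
#' @param variants Tibble with `position` and the measure column.
#' @param measure Name of the measure column (default
#'   `"allele_frequency"`).
#' @return A one-row tibble: group medians, the U statistic and p-value.
#' @export
snp_motif_test <- function(partition, variants, measure = "allele_frequency") {
  motif_iv <- filter(partition, .data$region == "motif")
  in_motif <- map_lgl(variants$position, function(p) {
    any(p >= motif_iv$start & p < motif_iv$end)
  })
  x <- variants[[measure]][in_motif]
  y <- variants[[measure]][!in_motif]
  if (length(x) == 0 || length(y) == 0) {
    return(tibble(median_motif = median(x), median_nonmotif = median(y),
                  statistic = NA_real_, p_value = NA_real_))
  }
  wt <- wilcox.test(x, y, alternative = "two.sided", exact = FALSE)
  tibble(median_motif = median(x), median_nonmotif = median(y),
         statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Permutation enrichment of an annotation in a target set
#'
#' Compares the number of annotated ids in the target set against random
#' draws of the same size from the universe. Enrichment is the observed
#' count over the mean count across draws; the p-value is the add-one
#' upper-tail fraction.
#'
#' @param target_ids Character vector, the target set (e.g. called
#'   coPARSE-lncRNAs).
#' @param universe_ids Character vector to draw from (must contain the
#'   targets).
#' @param annotated_ids Ids carrying the annotation (e.g. a ClinVar
#'   variant).
#' @param n_perm Number of draws (default 100000).
#' @param seed Integer seed.
#' @return One-row tibble: `observed`, `expected`, `enrichment`, `p_value`,
#'   `defined` (`FALSE` when the annotation never appears in any draw).
#' @export
interval_enrichment_permutation <- function(target_ids, universe_ids,
                                            annotated_ids, n_perm = 1e5,
                                            seed = 1L) {
  obs <- sum(target_ids %in% annotated_ids)
  k <- length(target_ids)
  is_annot <- universe_ids %in% annotated_ids
  set.seed(seed)
  draws <- vapply(seq_len(n_perm), function(i) {
    sum(is_annot[sample.int(length(universe_ids), k)])
  }, numeric(1))
  expected <- mean(draws)
  if (expected == 0) {
    return(tibble(observed = obs, expected = 0, enrichment = NA_real_,
                  p_value = NA_real_, defined = FALSE))
  }
  tibble(observed = obs, expected = expected, enrichment = obs / expected,
         p_value = (1 + sum(draws >= obs)) / (n_perm + 1), defined = TRUE)
}

#' Differential-expression odds ratio with Fisher's exact test
#'
#' `OR = (a/b) / (c/d)` — the printed ratio of ratios — where `a`/`b` are
#' the differentially/normally expressed counts in the focal group (e.g.
#' coPARSE-lncRNAs) and `c`/`d` in the comparison group; the p-value is a
#' two-sided Fisher's exact test on the 2x2 table.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return One-row tibble: `odds_ratio`, `p_value`, `defined` (`FALSE` when
#'   `b` or `d` is zero, leaving the ratio undefined; no continuity
#'   correction is applied).
#' @export
de_odds_ratio <- function(a, b, c, d) {
  ft <- fisher.test(matrix(c(a, b, c, d), 2, 2, byrow = TRUE))
  if (b == 0 || d == 0) {
    return(tibble(odds_ratio = NA_real_, p_value = ft$p.value, defined = FALSE))
  }
  tibble(odds_ratio = (a / b) / (c / d), p_value = ft$p.value, defined = TRUE)
}

#' Tau tissue-specificity scores
#'
#' Tau on log2(x + 1)-scaled expression:
#' `sum(1 - e_i / max(e)) / (k - 1)` over `k` tissues. 1 means expression
#' confined to a single tissue, 0 uniform expression; genes silent in every
#' tissue score 0.
#'
#' @param expression Tibble with `gene_id` and one numeric column per
#'   tissue (non-negative normalised expression).
#' @return Tibble `gene_id`, `tau`.
#' @export
tissue_specificity <- function(expression) {
  vals <- as.matrix(expression[setdiff(names(expression), "gene_id")])
  if (any(vals < 0)) abort("Expression values must be non-negative.")
  e <- log2(vals + 1)
  k <- ncol(e)
  tau <- apply(e, 1, function(r) {
    mx <- max(r)
    if (mx == 0) return(0)
    sum(1 - r / mx) / (k - 1)
  })
  tibble(gene_id = expression$gene_id, tau = unname(tau))
}

#' Correlation of tissue-specificity scores across homolog pairs
#'
#' @param pairs Tibble with `tau_a`, `tau_b` (one row per homolog pair).
#' @return One-row tibble: Pearson `r`, `p_value`, `n`.
#' @export
homolog_specificity_correlation <- function(pairs) {
  if (sd(pairs$tau_a) == 0 || sd(pairs$tau_b) == 0) {
    r <- if (all(pairs$tau_a == pairs$tau_b)) 1 else NA_real_
    return(tibble(r = r, p_value = NA_real_, n = nrow(pairs)))
  }
  ct <- cor.test(pairs$tau_a, pairs$tau_b, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(pairs))
}
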