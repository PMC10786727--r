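#' Filter candidate crRNAs for a Cas12a knockout library
#'
#' Applies the library-design rules: the PAM must match `TTTV`
#' (V = A, C or G), protospacer GC content must lie in `[0.2, 0.9]`, the
#' protospacer must not contain a `TTTT` run (a `UUUU` polymer in the
#' crRNA), and the protospacer must map to exactly one genomic locus with
#' every other locus at Hamming distance at least 2 (checked by exhaustive
#' scanning of both strands; practical on toy genomes only).
#'
#' @param crrnas Tibble with `crrna_id`, `protospacer` (23 nt), `pam`
#'   (4 nt) and any positional columns.
#' @param genome Named character vector of chromosome sequences.
#' @return `crrnas` with `accept` (logical) and `reasons`
#'   (comma-separated reject codes: `PAM`, `GC`, `polyU`, `multi_map`,
#'   `no_map`, `off_target`).
#' @export
filter_crrna <- function(crrnas, genome) {
  subjects <- Biostrings::DNAStringSet(genome)
  subjects_rc <- Biostrings::reverseComplement(subjects)
  check_one <- function(protospacer, pam) {
    reasons <- character()
    if (nchar(protospacer) != 23L) reasons <- c(reasons, "length")
    if (!grepl("^TTT[ACG]$", pam)) reasons <- c(reasons, "PAM")
    gc <- lnx_gc(protospacer)
    if (gc < 0.2 || gc > 0.9) reasons <- c(reasons, "GC")
    if (grepl("TTTT", protospacer, fixed = TRUE)) reasons <- c(reasons, "polyU")
    pat <- Biostrings::DNAString(protospacer)
    n_exact <- sum(Biostrings::vcountPattern(pat, subjects)) +
      sum(Biostrings::vcountPattern(pat, subjects_rc))
    n_near <- sum(Biostrings::vcountPattern(pat, subjects, max.mismatch = 1)) +
      sum(Biostrings::vcountPattern(pat, subjects_rc, max.mismatch = 1))
    if (n_exact == 0) reasons <- c(reasons, "no_map")
    if (n_exact > 1) reasons <- c(reasons, "multi_map")
    if (n_exact == 1 && n_near > 1) reasons <- c(reasons, "off_target")
    reasons
  }
  res <- map2(crrnas$protospacer, crrnas$pam, check_one)
  crrnas |>
    mutate(accept = lengths(res) == 0,
           reasons = map_chr(res, paste, collapse = ","))
}

#' @noRd
lnx_gc <- function(s) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  mean(v %in% c("G", "C"))
}

#' Pair accepted crRNAs around lncRNA transcription start sites
#'
#' Enumerates pairs of accepted crRNAs targeting the same lncRNA and keeps
#' those where (1) the two cut positions flank the lncRNA's TSS, (2)
#' neither crRNA overlaps any coding exon and (3) both crRNAs target the
#' nontranscribed (sense) strand, i.e. the crRNA strand equals the gene
#' strand. Pairs overlapping an essential-gene span are flagged, not
#' dropped.
#'
#' @param crrnas Tibble of accepted crRNAs with `crrna_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`.
#' @param lnc_annotation Tibble with `gene_id`, `chrom`, `start`, `end`,
#'   `strand` for the target lncRNAs (TSS = `start` on `+`, `end` on `-`).
#' @param coding_exons Tibble of coding-exon intervals (`chrom`, `start`,
#'   `end`).
#' @param essential_spans Optional tibble of essential-gene spans
#'   (`chrom`, `start`, `end`).
#' @return Tibble of retained pairs: `pair_id`, `gene_id`, `crrna_1`,
#'   `crrna_2`, `essential_flag`.
#' @export
filter_crrna_pairs <- function(crrnas, lnc_annotation, coding_exons,
                               essential_spans = NULL) {
  overlaps_any <- function(chrom, start, end, spans) {
    if (is.null(spans) || nrow(spans) == 0) return(rep(FALSE, length(start)))
    vapply(seq_along(start), function(i) {
      any(spans$chrom == chrom[i] & spans$start < end[i] & spans$end > start[i])
    }, logical(1))
  }
  out <- list()
  for (g in unique(crrnas$gene_id)) {
    lnc <- filter(lnc_annotation, .data$gene_id == g)
    if (nrow(lnc) != 1) next
    tss <- if (lnc$strand == "+") lnc$start else lnc$end
    cr <- filter(crrnas, .data$gene_id == g, .data$chrom == lnc$chrom,
                 .data$strand == lnc$strand)
    if (nrow(cr) < 2) next
    cr <- mutate(cr,
                 mid = (.data$start + .data$end) / 2,
                 in_exon = overlaps_any(.data$chrom, .data$start, .data$end,
                                        coding_exons),
                 in_essential = overlaps_any(.data$chrom, .data$start,
                                             .data$end, essential_spans))
    cr <- filter(cr, !.data$in_exon)
    if (nrow(cr) < 2) next
    combos <- utils::combn(seq_len(nrow(cr)), 2)
    for (k in seq_len(ncol(combos))) {
      i <- combos[1, k]; j <- combos[2, k]
      flank <- (cr$mid[i] < tss) != (cr$mid[j] < tss)
      if (!flank) next
      out[[length(out) + 1L]] <- tibble(
        gene_id = g,
        crrna_1 = cr$crrna_id[min(i, j)],
        crrna_2 = cr$crrna_id[max(i, j)],
        essential_flag = cr$in_essential[i] || cr$in_essential[j]
      )
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(pair_id = character(), gene_id = character(),
                  crrna_1 = character(), crrna_2 = character(),
                  essential_flag = logical()))
  }
  res |> mutate(pair_id = paste(.data$gene_id, .data$crrna_1, .data$crrna_2,
                                sep = "_"), .before = 1)
}

#' Cubic time-trend statistic per crRNA pair
#'
#' Fits `log2(count + 1)` against day with a cubic polynomial by least
#' squares (replicate columns of the same day are pooled) and takes the
#' fitted end-to-end change (fitted value at the last day minus the first),
#' centred by the median statistic of the control (AAVS1-background) rows.
#' With exactly four distinct days the cubic interpolates the points
#' exactly.
#'
#' @param screen_table Tibble with `pair_id`, `gene_id`, `control`
#'   (logical) and one numeric column per timepoint/replicate of
#'   pre-normalised counts.
#' @param days Numeric vector, the day of each count column (in column
#'   order). At least 4 distinct days are required.
#' @param count_cols Names of the count columns (default: every column
#'   after the three metadata columns, in order).
#' @return Tibble `pair_id`, `gene_id`, `control`, `trend_raw`,
#'   `trend_stat` (centred).
#' @export
fit_time_trend <- function(screen_table, days,
                           count_cols = setdiff(names(screen_table),
                                                c("pair_id", "gene_id", "control"))) {
  if (length(days) != length(count_cols)) {
    abort("`days` must give the day of every count column.")
  }
  if (length(unique(days)) < 4) {
    abort("A cubic time trend needs at least 4 distinct timepoints.")
  }
  counts <- as.matrix(screen_table[count_cols])
  if (anyNA(counts)) abort("Missing counts in the screen table.")
  if (!any(screen_table$control)) abort("Screen table has no control rows.")
  y <- log2(counts + 1)
  X <- cbind(1, days, days^2, days^3)
  # row-wise least squares in one multiply: beta_rows = Y X (X'X)^-1
  beta <- y %*% X %*% solve(crossprod(X))
  x_first <- c(1, min(days), min(days)^2, min(days)^3)
  x_last <- c(1, max(days), max(days)^2, max(days)^3)
  raw <- as.numeric(beta %*% (x_last - x_first))
  center <- median(raw[screen_table$control])
  tibble(pair_id = screen_table$pair_id, gene_id = screen_table$gene_id,
         control = screen_table$control, trend_raw = raw,
         trend_stat = raw - center)
}

#' Normalised ascending ranks of trend statistics
#'
#' The most depleted crRNA pair (most negative statistic) gets rank `1/N`;
#' ties take the average rank.
#'
#' @param trend Output of [fit_time_trend()] (needs `trend_stat`).
#' @return `trend` with a `norm_rank` column in (0, 1].
#' @export
rank_crrnas <- function(trend) {
  n <- nrow(trend)
  trend |> mutate(norm_rank = rank(.data$trend_stat, ties.method = "average") / n)
}

#' Robust rank aggregation of crRNA ranks to gene scores
#'
#' For a gene whose `k` crRNA-pair ranks sort to `r_(1) <= ... <= r_(k)`,
#' the rho score is `min_j P(Beta(j, k - j + 1) <= r_(j))` — the smallest
#' Beta order-statistic tail probability. Small rho marks consistent
#' depletion. Gene p-values come from a two-pass permutation null: a first
#' pass against the full rank pool flags clearly depleted genes
#' (`p < flag_alpha`); the final null pool is the control
#' (AAVS1-background) rows plus the rows of unflagged genes, and for each
#' guide-count `k` null rho values are drawn by sampling `k` ranks without
#' replacement from that pool (add-one convention). Holding flagged genes
#' out keeps null genes calibrated even when strong true hits crowd the
#' bottom of the ranking.
#'
#' @param ranks Output of [rank_crrnas()]; control rows are excluded from
#'   gene scoring and help define the null rank pool.
#' @param n_perm Permutations per guide-count group (default 10000).
#' @param flag_alpha First-pass p-value below which a gene's rows are held
#'   out of the final null pool (default 0.005).
#' @param seed Integer seed.
#' @return An `rra_result` tibble: `gene_id`, `rho`, `p_value`, `rank`,
#'   `n_crrnas`, ordered by rho.
#' @export
rra_gene_scores <- function(ranks, n_perm = 1e4, flag_alpha = 0.005, seed = 1L) {
  genes <- ranks |> filter(!.data$control)
  rho_of <- function(r) {
    r <- sort(r)
    k <- length(r)
    min(pbeta(r, seq_len(k), k - seq_len(k) + 1))
  }
  obs <- genes |>
    group_by(.data$gene_id) |>
    summarise(rho = rho_of(.data$norm_rank), n_crrnas = n(), .groups = "drop")
  set.seed(seed)
  p_against <- function(obs_tbl, pool) {
    p_by_k <- map(sort(unique(obs_tbl$n_crrnas)), function(k) {
      null <- vapply(seq_len(n_perm), function(i) {
        rho_of(sample(pool, k))
      }, numeric(1))
      list(k = k, null = sort(null))
    })
    names(p_by_k) <- map_chr(p_by_k, ~ as.character(.x$k))
    map2_dbl(obs_tbl$rho, obs_tbl$n_crrnas, function(r, k) {
      null <- p_by_k[[as.character(k)]]$null
      (1 + sum(null <= r + 1e-15)) / (n_perm + 1)
    })
  }
  # two-pass empirical null: a first pass against the full rank pool flags
  # clearly depleted genes; the final null pool is the control rows plus the
  # rows of unflagged genes, so strong true hits cannot contaminate it
  p1 <- p_against(obs, ranks$norm_rank)
  flagged <- obs$gene_id[p1 < flag_alpha]
  keep <- ranks$control | !(ranks$gene_id %in% flagged)
  pool <- if (sum(keep) >= 20) ranks$norm_rank[keep] else ranks$norm_rank
  obs <- obs |>
    mutate(p_value = p_against(obs, pool)) |>
    arrange(.data$rho) |>
    mutate(rank = row_number()) |>
    select("gene_id", "rho", "p_value", "rank", "n_crrnas")
  structure(obs, class = c("rra_result", class(obs)))
}

#' Copy-number bias diagnostic for screen results
#'
#' Spearman correlation between gene rho scores and genomic copy-number
#' values; a strong correlation would indicate that depletion calls track
#' amplification rather than function.
#'
#' @param rra An `rra_result` from [rra_gene_scores()].
#' @param cnv Tibble with `gene_id` and `cnv`.
#' @param threshold Absolute correlation raising the flag (default 0.3).
#' @return One-row tibble: `rho_spearman`, `p_value`, `flagged`, `defined`
#'   (`FALSE` when CNV is constant and the correlation undefined).
#' @export
cnv_bias_check <- function(rra, cnv, threshold = 0.3) {
  merged <- inner_join(as_tibble(rra), cnv, by = "gene_id")
  if (sd(merged$cnv) == 0) {
    return(tibble(rho_spearman = NA_real_, p_value = NA_real_,
                  flagged = FALSE, defined = FALSE))
  }
  ct <- suppressWarnings(cor.test(merged$rho, merged$cnv, method = "spearman"))
  tibble(rho_spearman = unname(ct$estimate), p_value = ct$p.value,
         flagged = abs(unname(ct$estimate)) > threshold, defined = TRUE)
}
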