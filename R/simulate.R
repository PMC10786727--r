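# Seeded generators for every input the pipeline consumes, each with a
# planted-ground-truth record so downstream callers can be scored without
# re-deriving truth. All are pure functions of their seed.

#' @noRd
lnx_random_seq <- function(n, base_probs = rep(0.25, 4)) {
  paste(sample(LNX_BASES, n, replace = TRUE, prob = base_probs), collapse = "")
}

#' Simulate an RBP motif library
#'
#' Each motif has one dominant base per column (probability
#' `dominant_prob`), giving a mean information content above 1 bit/column,
#' and belongs to its own RBP (one motif class per motif).
#'
#' @param n_motifs Number of motifs (default 15).
#' @param width_range Motif width range (default 7-9 nt, wide enough that a
#'   consensus site is significant at the default scan threshold).
#' @param dominant_prob Probability of the consensus base per column
#'   (default 0.85).
#' @param seed Integer seed.
#' @return List of [pwm()] objects with ids `M01`, `M02`, ... and RBP names
#'   `RBP01`, ...
#' @export
make_motif_library <- function(n_motifs = 15L, width_range = c(7L, 9L),
                               dominant_prob = 0.85, seed = 1L) {
  set.seed(seed)
  map(seq_len(n_motifs), function(i) {
    w <- sample(width_range[1]:width_range[2], 1)
    cons <- sample.int(4, w, replace = TRUE)
    mat <- matrix((1 - dominant_prob) / 3, w, 4)
    mat[cbind(seq_len(w), cons)] <- dominant_prob
    pwm(mat, motif_id = sprintf("M%02d", i), rbp_name = sprintf("RBP%02d", i),
        species = "synthetic")
  })
}

#' Simulate one lncRNA homolog pair with a planted block pattern
#'
#' Both sequences are i.i.d. random background with the same ordered set of
#' motif-class blocks embedded (consensus sites, spacing jittered by up to
#' `jitter` nt). A decoy partner carries the same blocks in shuffled class
#' order (a derangement), destroying the pattern while keeping content.
#'
#' @param library Motif library from [make_motif_library()].
#' @param seq_length Transcript length (default 1000 nt).
#' @param n_blocks Number of planted blocks (default 5).
#' @param spacing Nominal inter-block spacing in nt (default 150).
#' @param jitter Maximum positional jitter per block in nt (default 20).
#' @param decoy Shuffle the class order of the second sequence?
#' @param seed Integer seed.
#' @return List with `seq_a`, `seq_b` (single strings) and `truth`, a
#'   tibble of planted sites (`member`, `block`, `motif_id`, `motif_class`,
#'   `start`, `end`).
#' @export
make_homolog_pair <- function(library, seq_length = 1000L, n_blocks = 5L,
                              spacing = 150L, jitter = 20L, decoy = FALSE,
                              seed = 1L) {
  stopifnot(n_blocks <= length(library))
  set.seed(seed)
  picks <- sample.int(length(library), n_blocks)
  offset <- 60L
  base_pos <- offset + (seq_len(n_blocks) - 1L) * spacing
  jit <- function() if (jitter > 0) sample(-jitter:jitter, n_blocks, TRUE) else rep(0L, n_blocks)
  pos_a <- base_pos + jit()
  pos_b <- base_pos + jit()
  order_b <- if (decoy && n_blocks > 1) {
    repeat {
      o <- sample.int(n_blocks)
      if (all(o != seq_len(n_blocks))) break
    }
    o
  } else {
    seq_len(n_blocks)
  }
  embed_sites <- function(len, positions, motif_idx) {
    s <- strsplit(lnx_random_seq(len), "", fixed = TRUE)[[1]]
    truth <- map(seq_along(positions), function(b) {
      p <- library[[motif_idx[b]]]
      site <- strsplit(pwm_consensus(p), "", fixed = TRUE)[[1]]
      at <- positions[b]
      s[(at + 1L):(at + length(site))] <<- site
      tibble(block = b, motif_id = p$motif_id, motif_class = p$rbp_name,
             start = at, end = at + length(site))
    })
    list(seq = paste(s, collapse = ""), truth = bind_rows(truth))
  }
  a <- embed_sites(seq_length, pos_a, picks)
  b <- embed_sites(seq_length, pos_b, picks[order_b])
  truth <- bind_rows(mutate(a$truth, member = "a", .before = 1),
                     mutate(b$truth, member = "b", .before = 1))
  list(seq_a = a$seq, seq_b = b$seq, truth = truth)
}

#' Simulate two toy genomes with planted syntenic lncRNA pairs
#'
#' Lays out `n_loci` independent neighbourhoods on one chromosome per
#' species. Each neighbourhood carries a one-to-one protein homolog pair
#' (plus `proteins_per_locus - 1` extra flanking protein pairs) and a
#' number of corresponding genomic anchors. Planted syntenic lncRNA pairs
#' sit in the same neighbourhood and share its correspondences; decoy
#' pairs combine lncRNAs from different neighbourhoods and share none.
#'
#' @param n_loci Number of neighbourhoods (default 60).
#' @param anchors_per_locus Corresponding anchors per neighbourhood
#'   (single number or a vector recycled over loci, so planted pairs can
#'   share varying anchor counts).
#' @param proteins_per_locus Protein homolog pairs per neighbourhood
#'   (default 3; recycled over loci like `anchors_per_locus`).
#' @param noise_anchors Non-corresponding anchors scattered per species
#'   (default 50): present on one side only.
#' @param anchor_spread Half-width of the uniform window (centred on the
#'   neighbourhood) that anchor offsets are drawn from (default 9e5, inside
#'   the 1 Mb flank). Widening it beyond the flank makes only a fraction of
#'   a neighbourhood's anchors land inside the pair's flanks, so the
#'   effective shared count rises smoothly with `anchors_per_locus` —
#'   useful for probing the classifier's graded response.
#' @param onesided_per_locus Anchors per neighbourhood whose partner lies
#'   far away on the other genome (default 0; recycled over loci). These
#'   count towards a flank's `m1`/`m2` but never towards `m`, so with
#'   `k` corresponding and `t` one-sided anchors a planted pair's anchor
#'   proportion score is `k / (k + t)` — useful for probing the
#'   classifier's response to partial anchor sharing.
#' @param locus_span Genomic spacing between neighbourhoods (default 4 Mb,
#'   beyond the 1 Mb flank so neighbourhoods stay independent).
#' @param seed Integer seed.
#' @return List with `genes_a`, `genes_b` (gene tables), `correspondences`,
#'   `protein_pairs` (training input with `element_id`), and `lnc_pairs`
#'   (planted pairs and decoys with `label` and `k_anchors`).
#' @export
make_synteny_genomes <- function(n_loci = 60L, anchors_per_locus = 6L,
                                 proteins_per_locus = 3L, noise_anchors = 50L,
                                 anchor_spread = 9e5, onesided_per_locus = 0L,
                                 locus_span = 4e6, seed = 1L) {
  set.seed(seed)
  k_anchor <- rep_len(anchors_per_locus, n_loci)
  k_protein <- rep_len(proteins_per_locus, n_loci)
  k_onesided <- rep_len(onesided_per_locus, n_loci)
  genes_a <- list(); genes_b <- list(); corr <- list(); prot_pairs <- list()
  lnc_a <- character(n_loci); lnc_b <- character(n_loci)
  for (i in seq_len(n_loci)) {
    c_a <- i * locus_span
    c_b <- i * locus_span + round(runif(1, -2e5, 2e5))
    # lncRNA pair at the neighbourhood centre
    lnc_a[i] <- sprintf("lncA%03d", i)
    lnc_b[i] <- sprintf("lncB%03d", i)
    # orientation is conserved across the alignment for a syntenic pair
    strand_i <- sample(c("+", "-"), 1)
    genes_a[[length(genes_a) + 1L]] <- tibble(
      gene_id = lnc_a[i], chrom = "chrA1", start = c_a, end = c_a + 2000,
      strand = strand_i, type = "lncRNA")
    genes_b[[length(genes_b) + 1L]] <- tibble(
      gene_id = lnc_b[i], chrom = "chrB1", start = c_b, end = c_b + 2000,
      strand = strand_i, type = "lncRNA")
    # protein homolog pairs in the shared flank
    for (p in seq_len(k_protein[i])) {
      off <- round(runif(1, -9e5, 9e5))
      pa <- sprintf("protA%03d_%d", i, p)
      pb <- sprintf("protB%03d_%d", i, p)
      eid <- sprintf("P%03d_%d", i, p)
      genes_a[[length(genes_a) + 1L]] <- tibble(
        gene_id = pa, chrom = "chrA1", start = c_a + off, end = c_a + off + 5000,
        strand = "+", type = "protein_coding")
      genes_b[[length(genes_b) + 1L]] <- tibble(
        gene_id = pb, chrom = "chrB1", start = c_b + off, end = c_b + off + 5000,
        strand = "+", type = "protein_coding")
      corr[[length(corr) + 1L]] <- tibble(
        element_id = eid, evidence = "protein",
        chrom_a = "chrA1", start_a = c_a + off, end_a = c_a + off + 5000,
        chrom_b = "chrB1", start_b = c_b + off, end_b = c_b + off + 5000)
      prot_pairs[[length(prot_pairs) + 1L]] <- tibble(
        gene_a = pa, gene_b = pb, element_id = eid)
    }
    # corresponding anchors in the shared flank
    if (k_anchor[i] > 0) {
      for (a in seq_len(k_anchor[i])) {
        off <- round(runif(1, -anchor_spread, anchor_spread))
        corr[[length(corr) + 1L]] <- tibble(
          element_id = sprintf("A%03d_%d", i, a), evidence = "anchor",
          chrom_a = "chrA1", start_a = c_a + off, end_a = c_a + off + 500,
          chrom_b = "chrB1", start_b = c_b + off, end_b = c_b + off + 500)
      }
    }
    # one-sided anchors: in this neighbourhood's flank on one genome only,
    # with the partner locus far outside every flank on the other genome
    if (k_onesided[i] > 0) {
      far <- (n_loci + 5) * locus_span
      for (a in seq_len(k_onesided[i])) {
        off_a <- round(runif(1, -9e5, 9e5))
        off_b <- round(runif(1, -9e5, 9e5))
        corr[[length(corr) + 1L]] <- tibble(
          element_id = sprintf("OA%03d_%d", i, a), evidence = "anchor",
          chrom_a = "chrA1", start_a = c_a + off_a, end_a = c_a + off_a + 500,
          chrom_b = "chrB1", start_b = far + a * 2000, end_b = far + a * 2000 + 500)
        corr[[length(corr) + 1L]] <- tibble(
          element_id = sprintf("OB%03d_%d", i, a), evidence = "anchor",
          chrom_a = "chrA1", start_a = far + a * 2000, end_a = far + a * 2000 + 500,
          chrom_b = "chrB1", start_b = c_b + off_b, end_b = c_b + off_b + 500)
      }
    }
  }
  # one-sided noise anchors: far ends of each genome, no shared neighbourhood
  span_max <- (n_loci + 2) * locus_span
  for (j in seq_len(noise_anchors)) {
    pa <- round(runif(1, 0, span_max))
    pb <- round(runif(1, 0, span_max))
    corr[[length(corr) + 1L]] <- tibble(
      element_id = sprintf("N%03d", j), evidence = "anchor",
      chrom_a = "chrA1", start_a = pa, end_a = pa + 500,
      chrom_b = "chrB2", start_b = pb, end_b = pb + 500)
  }
  planted <- tibble(gene_a = lnc_a, gene_b = lnc_b, label = 1L,
                    k_anchors = k_anchor, k_proteins = k_protein)
  shift <- sample(2:(n_loci - 2), 1)
  decoys <- tibble(gene_a = lnc_a,
                   gene_b = lnc_b[((seq_len(n_loci) + shift - 1L) %% n_loci) + 1L],
                   label = 0L, k_anchors = 0L, k_proteins = 0L)
  list(genes_a = bind_rows(genes_a), genes_b = bind_rows(genes_b),
       correspondences = bind_rows(corr),
       protein_pairs = bind_rows(prot_pairs),
       lnc_pairs = bind_rows(planted, decoys))
}

#' Simulate a paired-crRNA knockout screen count table
#'
#' Negative-binomial counts per crRNA pair per timepoint. Planted depleted
#' genes decay log-linearly (`depletion_effect` log2 units per day) while
#' null genes and the AAVS1-background control rows stay flat in
#' expectation.
#'
#' @param n_genes Number of target genes (default 2000).
#' @param pairs_per_gene crRNA pairs per gene (default 3).
#' @param n_controls Control (AAVS1) crRNA pairs (default 100).
#' @param days Screening timepoints (default days 0, 15, 30, 45).
#' @param frac_depleted Fraction of genes given the depletion trend
#'   (default 0.05).
#' @param depletion_effect Log2 change per day for depleted genes
#'   (default -0.05, i.e. about -2.25 log2 fold at day 45).
#' @param base_mean Baseline negative-binomial mean (default 500).
#' @param nb_size Negative-binomial size/dispersion parameter (default 20).
#' @param seed Integer seed.
#' @return List with `screen_table` (tibble: `pair_id`, `gene_id`,
#'   `control`, one count column `d<day>` per timepoint) and `truth`
#'   (tibble `gene_id`, `depleted`).
#' @export
make_screen <- function(n_genes = 2000L, pairs_per_gene = 3L,
                        n_controls = 100L, days = c(0, 15, 30, 45),
                        frac_depleted = 0.05, depletion_effect = -0.05,
                        base_mean = 500, nb_size = 20, seed = 1L) {
  set.seed(seed)
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  n_depleted <- round(frac_depleted * n_genes)
  depleted <- sample(gene_ids, n_depleted)
  rows <- tibble(
    gene_id = rep(gene_ids, each = pairs_per_gene),
    pair_id = sprintf("%s_p%d", rep(gene_ids, each = pairs_per_gene),
                      rep(seq_len(pairs_per_gene), n_genes)),
    control = FALSE
  )
  ctrl <- tibble(
    gene_id = "AAVS1",
    pair_id = sprintf("AAVS1_p%03d", seq_len(n_controls)),
    control = TRUE
  )
  tab <- bind_rows(rows, ctrl)
  effect <- ifelse(tab$gene_id %in% depleted, depletion_effect, 0)
  for (d in days) {
    mu <- base_mean * 2^(effect * d)
    tab[[sprintf("d%d", d)]] <- rnbinom(nrow(tab), mu = mu, size = nb_size)
  }
  list(screen_table = tab,
       truth = tibble(gene_id = gene_ids, depleted = gene_ids %in% depleted))
}
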