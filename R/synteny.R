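# Classify correspondence elements into strand-oriented flank regions of a
# gene: "u" (upstream), "d" (downstream) or NA (outside the flanks or on
# another chromosome). An element is placed by its midpoint.
#' @noRd
lnx_flank_label <- function(gene, chrom, start, end, flank_bp) {
  mid <- (start + end) / 2
  fwd <- identical(gene$strand, "+")
  up <- if (fwd) c(gene$start - flank_bp, gene$start) else c(gene$end, gene$end + flank_bp)
  dn <- if (fwd) c(gene$end, gene$end + flank_bp) else c(gene$start - flank_bp, gene$start)
  label <- rep(NA_character_, length(mid))
  same <- chrom == gene$chrom
  label[same & mid >= up[1] & mid < up[2]] <- "u"
  label[same & mid >= dn[1] & mid < dn[2]] <- "d"
  label
}

#' Count correspondence elements in the flanks of a candidate gene pair
#'
#' For each evidence class (genomic `anchor`, `protein` homolog) and each
#' region (upstream `u`, downstream `d` and their union `f`), counts the
#' elements near gene A (`m1`), near gene B (`m2`) and the one-to-one
#' corresponding elements falling in the same-labelled region on both sides
#' (`m`). Regions are strand-oriented and elements are placed by midpoint.
#'
#' @param gene_a,gene_b One-row tibbles (or lists) with `chrom`, `start`,
#'   `end`, `strand` on the two assemblies.
#' @param correspondences Tibble of one-to-one elements with columns
#'   `element_id`, `evidence` (`anchor`/`protein`), `chrom_a`, `start_a`,
#'   `end_a`, `chrom_b`, `start_b`, `end_b`.
#' @param flank_bp Flank size in bp (default 1e6, i.e. 1 Mb).
#' @return Tibble with one row per evidence x region: `evidence`, `region`,
#'   `m1`, `m2`, `m`.
#' @export
flank_counts <- function(gene_a, gene_b, correspondences, flank_bp = 1e6) {
  la <- lnx_flank_label(gene_a, correspondences$chrom_a,
                        correspondences$start_a, correspondences$end_a, flank_bp)
  lb <- lnx_flank_label(gene_b, correspondences$chrom_b,
                        correspondences$start_b, correspondences$end_b, flank_bp)
  out <- tidyr::expand_grid(evidence = c("anchor", "protein"),
                            region = c("u", "d"))
  counts <- pmap(out, function(evidence, region) {
    ev <- correspondences$evidence == evidence
    tibble(m1 = sum(ev & la == region, na.rm = TRUE),
           m2 = sum(ev & lb == region, na.rm = TRUE),
           m = sum(ev & la == region & lb == region, na.rm = TRUE))
  })
  ud <- bind_cols(out, bind_rows(counts))
  f <- ud |>
    group_by(.data$evidence) |>
    summarise(region = "f", m1 = sum(.data$m1), m2 = sum(.data$m2),
              m = sum(.data$m), .groups = "drop")
  bind_rows(ud, f) |> arrange(.data$evidence, match(.data$region, c("u", "d", "f")))
}

#' Proportion scores from flank counts
#'
#' Per evidence and region, `proportion = m / min(m1, m2)`, defined as 0
#' when `min(m1, m2) = 0` (an empty flank carries no synteny evidence).
#'
#' @param counts Output of [flank_counts()].
#' @return The input with a `proportion` column added.
#' @export
proportion_scores <- function(counts) {
  counts |>
    mutate(proportion = if_else(pmin(.data$m1, .data$m2) > 0,
                                .data$m / pmin(.data$m1, .data$m2), 0))
}

#' Twelve synteny features for candidate gene pairs
#'
#' The six proportion scores and six matched counts (`m_u`, `m_d`, `m_f`
#' for anchors and for protein homologs) used by the synteny classifier.
#'
#' @param pairs Tibble with `gene_a`, `gene_b` (ids into the gene tables).
#' @param genes_a,genes_b Gene tables with `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (gene-level spans).
#' @param correspondences See [flank_counts()].
#' @param flank_bp Flank size in bp.
#' @param drop_element Optional character vector of `element_id`s excluded
#'   from the correspondence evidence per pair (a list-column `drop_element`
#'   in `pairs` overrides it); used to keep a training pair's own
#'   correspondence out of its features.
#' @return `pairs` with 12 feature columns
#'   `<evidence>_prop_<r>` / `<evidence>_m_<r>` for r in u, d, f.
#' @export
synteny_features <- function(pairs, genes_a, genes_b, correspondences,
                             flank_bp = 1e6, drop_element = NULL) {
  ga <- genes_a[match(pairs$gene_a, genes_a$gene_id), ]
  gb <- genes_b[match(pairs$gene_b, genes_b$gene_id), ]
  if (anyNA(ga$chrom) || anyNA(gb$chrom)) {
    abort("Some pair members are missing from the gene tables.")
  }
  drops <- if ("drop_element" %in% names(pairs)) {
    pairs$drop_element
  } else {
    rep(list(drop_element), nrow(pairs))
  }
  feats <- map(seq_len(nrow(pairs)), function(i) {
    co <- correspondences
    if (!is.null(drops[[i]])) co <- filter(co, !.data$element_id %in% drops[[i]])
    fc <- proportion_scores(flank_counts(ga[i, ], gb[i, ], co, flank_bp))
    vals <- c(fc$proportion, fc$m)
    names(vals) <- c(paste0(fc$evidence, "_prop_", fc$region),
                     paste0(fc$evidence, "_m_", fc$region))
    as_tibble(as.list(vals))
  })
  bind_cols(select(pairs, !any_of("drop_element")), bind_rows(feats))
}

#' Build a synteny training set from one-to-one protein homolog pairs
#'
#' Positives are the protein homolog pairs themselves (each pair's own
#' correspondence element is removed before its features are computed, so a
#' pair never sees itself as evidence); negatives are uniformly sampled
#' non-homologous gene pairs.
#'
#' @param protein_pairs Tibble with `gene_a`, `gene_b` and `element_id`
#'   (the pair's own entry in `correspondences`, or `NA`).
#' @param genes_a,genes_b Gene tables (see [synteny_features()]).
#' @param correspondences Correspondence table (see [flank_counts()]).
#' @param n_negative_ratio Negatives per positive (default 1).
#' @param flank_bp Flank size in bp.
#' @param seed Integer seed for negative sampling.
#' @return Tibble of feature rows with a `label` column (1 = homolog pair,
#'   0 = random pair).
#' @export
build_training_set <- function(protein_pairs, genes_a, genes_b, correspondences,
                               n_negative_ratio = 1, flank_bp = 1e6, seed = 1L) {
  if (nrow(protein_pairs) < 20) {
    abort("Need at least 20 one-to-one protein homolog pairs to train.")
  }
  pos <- protein_pairs |>
    mutate(drop_element = as.list(.data$element_id)) |>
    select("gene_a", "gene_b", "drop_element")
  pos_feats <- synteny_features(pos, genes_a, genes_b, correspondences,
                                flank_bp = flank_bp) |>
    mutate(label = 1L)
  set.seed(seed)
  n_neg <- ceiling(nrow(protein_pairs) * n_negative_ratio)
  known <- paste(protein_pairs$gene_a, protein_pairs$gene_b)
  neg <- tibble(gene_a = character(), gene_b = character())
  while (nrow(neg) < n_neg) {
    cand <- tibble(
      gene_a = sample(genes_a$gene_id, n_neg, replace = TRUE),
      gene_b = sample(genes_b$gene_id, n_neg, replace = TRUE)
    ) |>
      filter(!paste(.data$gene_a, .data$gene_b) %in% known)
    neg <- distinct(bind_rows(neg, cand))
  }
  neg <- head(neg, n_neg)
  neg_feats <- synteny_features(neg, genes_a, genes_b, correspondences,
                                flank_bp = flank_bp) |>
    mutate(label = 0L)
  bind_rows(pos_feats, neg_feats)
}

#' Train the synteny random-forest classifier
#'
#' @param training Output of [build_training_set()] (12 feature columns plus
#'   `label`).
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @return A `synteny_model` wrapping the fitted random forest.
#' @export
train_synteny_model <- function(training, n_trees = 500L, seed = 1L) {
  feat_cols <- grep("^(anchor|protein)_(prop|m)_[udf]$", names(training),
                    value = TRUE)
  if (length(feat_cols) != 12) abort("Training table must carry the 12 features.")
  if (length(unique(training$label)) < 2) {
    abort("Training labels are single-class; cannot train.")
  }
  x <- as.data.frame(training[feat_cols])
  if (any(!is.finite(as.matrix(x)))) abort("Non-finite feature values.")
  y <- factor(training$label, levels = c(0, 1))
  set.seed(seed)
  forest <- randomForest::randomForest(x = x, y = y, ntree = n_trees)
  structure(list(forest = forest, features = feat_cols, n_trees = n_trees,
                 seed = seed),
            class = "synteny_model")
}

#' @export
print.synteny_model <- function(x, ...) {
  cat(sprintf("<synteny_model> random forest, %d trees, OOB error %.3f\n",
              x$n_trees, x$forest$err.rate[x$n_trees, "OOB"]))
  invisible(x)
}

#' Score candidate lncRNA pairs with the synteny classifier
#'
#' @param model A `synteny_model`.
#' @param features Feature tibble from [synteny_features()].
#' @param threshold Probability cut-off for nominating a candidate
#'   (default 0.5).
#' @return `features` with `synteny_prob` and `candidate` columns.
#' @export
predict_syntenic <- function(model, features, threshold = 0.5) {
  stopifnot(inherits(model, "synteny_model"))
  x <- as.data.frame(features[model$features])
  prob <- predict(model$forest, newdata = x, type = "prob")[, "1"]
  features |>
    mutate(synteny_prob = unname(prob),
           candidate = .data$synteny_prob >= threshold)
}
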