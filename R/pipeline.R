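#' Assemble a validated pipeline configuration
#'
#' Collects every tunable the end-to-end run uses, so a run can be
#' reproduced from its emitted config alone. The `"paper"` profile uses the
#' full permutation counts (100000 MPSS pairs, 1000 GPS shuffles); the
#' default `"test"` profile scales them down (2000 / 200) for desk-scale
#' runtimes.
#'
#' @param sequences_a,sequences_b Named character vectors of lncRNA
#'   sequences for the two species, or paths to FASTA files.
#' @param motif_library List of [pwm()] objects or a path to a MEME
#'   minimal-format file.
#' @param candidates Optional tibble `query_id`, `target_id` restricting
#'   the scored pairs (default: all cross-species pairs).
#' @param p_threshold Motif-scan p-value threshold.
#' @param n_perm_mpss,n_shuffle_gps Permutation counts for the two nulls.
#' @param alpha Significance level for calling.
#' @param mpss_ratio Per-query MPSS ratio threshold.
#' @param seed Integer seed governing every random draw.
#' @param out_dir Optional output directory for result tables + manifest.
#' @param profile `"test"` (default) or `"paper"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sequences_a, sequences_b, motif_library,
                            candidates = NULL, p_threshold = 1e-4,
                            n_perm_mpss = NULL, n_shuffle_gps = NULL,
                            alpha = 0.05, mpss_ratio = 0.8, seed = 1L,
                            out_dir = NULL, profile = c("test", "paper")) {
  profile <- match.arg(profile)
  defaults <- if (profile == "paper") c(1e5, 1000) else c(2000, 200)
  if (missing(motif_library) || is.null(motif_library)) {
    abort("Config field `motif_library` is missing.")
  }
  if (is.character(motif_library)) {
    if (length(motif_library) != 1 || !file.exists(motif_library)) {
      abort("Config field `motif_library`: file not found.")
    }
    motif_library <- read_meme_motifs(motif_library)
  }
  load_seqs <- function(x, field) {
    if (is.character(x) && length(x) == 1 && is.null(names(x))) {
      if (!file.exists(x)) abort(sprintf("Config field `%s`: file not found.", field))
      read_fasta(x)
    } else {
      if (is.null(names(x))) abort(sprintf("Config field `%s` needs named sequences.", field))
      x
    }
  }
  structure(list(
    sequences_a = load_seqs(sequences_a, "sequences_a"),
    sequences_b = load_seqs(sequences_b, "sequences_b"),
    motif_library = motif_library,
    candidates = candidates,
    p_threshold = p_threshold,
    n_perm_mpss = n_perm_mpss %||% defaults[1],
    n_shuffle_gps = n_shuffle_gps %||% defaults[2],
    alpha = alpha, mpss_ratio = mpss_ratio,
    seed = as.integer(seed), out_dir = out_dir, profile = profile
  ), class = "pipeline_config")
}

#' Run the homology pipeline end to end
#'
#' Scans both sequence sets against the motif library, clusters matches
#' into block profiles, builds the shared cross-species MPSS null, scores
#' every candidate pair (MPSS, GPS, both permutation p-values), calls
#' coPARSE homologs and extracts homologous regions. Deterministic under
#' the config seed. When `out_dir` is set, the stage tables are written as
#' TSV with a JSON manifest of file checksums and the resolved config.
#'
#' @param config A [pipeline_config()].
#' @return List with `matches_a`, `matches_b`, `profiles_a`, `profiles_b`,
#'   `calls` (the scored + called candidate tibble) and `regions`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }
  matches_a <- stage("scan", scan_motif_library(config$motif_library,
                                                config$sequences_a,
                                                config$p_threshold))
  matches_b <- stage("scan", scan_motif_library(config$motif_library,
                                                config$sequences_b,
                                                config$p_threshold))
  profiles_a <- stage("blocks", block_profiles(matches_a, nchar(config$sequences_a)))
  profiles_b <- stage("blocks", block_profiles(matches_b, nchar(config$sequences_b)))
  null <- stage("null_mpss", null_mpss(profiles_a, profiles_b,
                                       n_perm = config$n_perm_mpss,
                                       seed = lnx_substream_seed(config$seed, 1L)))
  cand <- config$candidates %||%
    tidyr::expand_grid(query_id = names(config$sequences_a),
                       target_id = names(config$sequences_b))
  scored <- stage("score", {
    rows <- pmap(cand, function(query_id, target_id, ...) {
      al <- align_blocks(profiles_a[[query_id]], profiles_b[[target_id]])
      p_gps <- null_gps(al, n_shuffle = config$n_shuffle_gps,
                        seed = lnx_substream_seed(config$seed, 2L))
      tibble(query_id = query_id, target_id = target_id,
             mpss = al$mpss, gps = al$gps,
             n_pairs = nrow(al$pairs),
             p_mpss = mpss_p_value(null, al$mpss),
             p_gps = p_gps, alignment = list(al))
    })
    bind_rows(rows)
  })
  calls <- stage("call", call_homologs(scored, alpha = config$alpha,
                                       ratio = config$mpss_ratio))
  regions <- stage("regions", {
    hom <- filter(calls, .data$verdict == "coPARSE")
    bind_rows(pmap(hom, function(query_id, target_id, alignment, ...) {
      homologous_region(
        alignment,
        filter(matches_a, .data$seq_id == query_id),
        filter(matches_b, .data$seq_id == target_id)
      ) |> mutate(query_id = query_id, target_id = target_id)
    }))
  })
  result <- list(matches_a = matches_a, matches_b = matches_b,
                 profiles_a = profiles_a, profiles_b = profiles_b,
                 calls = select(calls, !"alignment"), regions = regions)
  if (!is.null(config$out_dir)) {
    stage("write", lnx_write_results(result, config))
  }
  result
}

#' @noRd
lnx_write_results <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matches_a = "matches_a.tsv", matches_b = "matches_b.tsv",
             calls = "calls.tsv", regions = "regions.tsv")
  for (nm in names(paths)) {
    readr::write_tsv(result[[nm]], file.path(config$out_dir, paths[[nm]]),
                     progress = FALSE)
  }
  files <- file.path(config$out_dir, paths)
  manifest <- list(
    config = config[c("p_threshold", "n_perm_mpss", "n_shuffle_gps", "alpha",
                      "mpss_ratio", "seed", "profile")],
    n_sequences = c(a = length(config$sequences_a), b = length(config$sequences_b)),
    n_motifs = length(config$motif_library),
    files = as.list(setNames(unname(tools::md5sum(files)), names(paths))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(config$out_dir)
}
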