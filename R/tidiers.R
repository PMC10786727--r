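#' Tidy a block alignment into one row per aligned pair
#'
#' @param x A `block_alignment` from [align_blocks()].
#' @param ... Unused.
#' @return Tibble with the aligned block indices, their similarity, spans
#'   and centres in both transcripts.
#' @method tidy block_alignment
#' @export
tidy.block_alignment <- function(x, ...) {
  a <- x$profile_a
  b <- x$profile_b
  x$pairs |>
    mutate(start_a = a$start[.data$idx_a], end_a = a$end[.data$idx_a],
           center_a = a$center[.data$idx_a],
           start_b = b$start[.data$idx_b], end_b = b$end[.data$idx_b],
           center_b = b$center[.data$idx_b])
}

#' One-row summary of a block alignment
#'
#' @inheritParams tidy.block_alignment
#' @return Tibble with `mpss`, `gps`, `n_pairs`, and the block counts of
#'   the two profiles.
#' @method glance block_alignment
#' @export
glance.block_alignment <- function(x, ...) {
  tibble(mpss = x$mpss, gps = x$gps, n_pairs = nrow(x$pairs),
         n_blocks_a = nrow(x$profile_a), n_blocks_b = nrow(x$profile_b))
}

#' Per-feature importance of a synteny classifier
#'
#' @param x A `synteny_model` from [train_synteny_model()].
#' @param ... Unused.
#' @return Tibble `feature`, `importance` (mean decrease in Gini), sorted
#'   decreasing.
#' @method tidy synteny_model
#' @export
tidy.synteny_model <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble(feature = rownames(imp), importance = unname(imp[, 1])) |>
    arrange(desc(.data$importance))
}

#' One-row summary of a synteny classifier
#'
#' @inheritParams tidy.synteny_model
#' @return Tibble with tree count, out-of-bag error and class errors.
#' @method glance synteny_model
#' @export
glance.synteny_model <- function(x, ...) {
  er <- x$forest$err.rate[x$n_trees, ]
  tibble(n_trees = x$n_trees, oob_error = unname(er["OOB"]),
         class_error_0 = unname(er["0"]), class_error_1 = unname(er["1"]))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
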