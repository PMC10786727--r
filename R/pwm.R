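#' Construct a position weight matrix (PWM) object
#'
#' A `pwm` holds the per-position base probabilities of one RBP-binding
#' motif in one species. Rows are motif positions, columns the bases
#' `A,C,G,T`. Rows are regularised with a pseudocount and renormalised so
#' each sums to 1 (within 1e-6); this keeps log-odds scores finite.
#'
#' @param matrix Numeric matrix, width x 4, rows approximately summing to 1.
#' @param motif_id Motif identifier (unique within a library).
#' @param rbp_name RBP the motif belongs to. Motifs of one RBP form one
#'   *motif class* for block counting.
#' @param species Species label (free text).
#' @param background Background base probabilities (length 4, sums to 1).
#' @param pseudocount Positive regularisation constant added to every cell
#'   when log-odds scores are computed (default 1e-3); the stored
#'   probabilities are kept as given (row-renormalised only), so file
#'   round-trips are exact.
#' @return An object of class `pwm`.
#' @export
#' @examples
#' m <- matrix(c(0.97, 0.01, 0.01, 0.01,
#'               0.01, 0.97, 0.01, 0.01,
#'               0.01, 0.01, 0.97, 0.01,
#'               0.01, 0.01, 0.01, 0.97), 4, 4, byrow = TRUE)
#' p <- pwm(m, motif_id = "M1", rbp_name = "RBP1")
#' pwm_consensus(p)
pwm <- function(matrix, motif_id, rbp_name = motif_id, species = NA_character_,
                background = rep(0.25, 4), pseudocount = 1e-3) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L) abort("PWM matrix must have 4 columns (A,C,G,T).")
  if (nrow(matrix) < 1L) abort("PWM matrix must have at least one row.")
  if (any(matrix < 0) || any(!is.finite(matrix))) {
    abort("PWM matrix cells must be finite and non-negative.")
  }
  rs <- rowSums(matrix)
  if (any(abs(rs - 1) > 0.01)) {
    abort(sprintf("PWM row sums deviate from 1 by more than 0.01 (motif %s).",
                  motif_id))
  }
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-6) {
    abort("`background` must be 4 probabilities summing to 1.")
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    abort("`pseudocount` must be a positive number.")
  }
  m <- matrix / rowSums(matrix)
  colnames(m) <- LNX_BASES
  rownames(m) <- NULL
  structure(
    list(motif_id = as.character(motif_id),
         rbp_name = as.character(rbp_name),
         species = as.character(species),
         matrix = m,
         background = as.numeric(background),
         pseudocount = pseudocount),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (RBP %s, species %s), width %d, consensus %s\n",
              x$motif_id, x$rbp_name, x$species, pwm_width(x), pwm_consensus(x)))
  invisible(x)
}

#' @rdname pwm
#' @param x A `pwm`.
#' @export
pwm_width <- function(x) nrow(x$matrix)

#' @rdname pwm
#' @export
pwm_consensus <- function(x) {
  paste(LNX_BASES[apply(x$matrix, 1, which.max)], collapse = "")
}

#' Mean information content of a PWM, in bits per column
#'
#' @param x A `pwm`.
#' @return Mean over columns of `sum(p * log2(p / background))`.
#' @export
pwm_information <- function(x) {
  m <- (x$matrix + x$pseudocount) / (1 + 4 * x$pseudocount)
  ic <- vapply(seq_len(pwm_width(x)), function(i) {
    p <- m[i, ]
    sum(p * log2(p / x$background))
  }, numeric(1))
  mean(ic)
}

# Log-odds score matrix in bits. The pseudocount regularisation is applied
# here (not to the stored probabilities) so zero cells stay scoreable and
# file round-trips are exact.
#' @noRd
pwm_logodds <- function(x) {
  m <- (x$matrix + x$pseudocount) / (1 + 4 * x$pseudocount)
  log2(m / rep(x$background, each = nrow(m)))
}

#' Summarise a motif library as a tibble
#'
#' @param pwms List of `pwm` objects.
#' @return A tibble with one row per motif: id, RBP, species, width,
#'   consensus and mean information content.
#' @export
tidy_pwm_library <- function(pwms) {
  tibble(
    motif_id = map_chr(pwms, "motif_id"),
    rbp_name = map_chr(pwms, "rbp_name"),
    species = map_chr(pwms, "species"),
    width = map_int(pwms, pwm_width),
    consensus = map_chr(pwms, pwm_consensus),
    information = map_dbl(pwms, pwm_information)
  )
}
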