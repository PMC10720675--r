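#' Dice overlap coefficient between two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`. Two empty masks agree perfectly on absence and
#' score 1 (flagged via the `"both_empty"` attribute so callers can exclude
#' such sections from averages).
#'
#' @param a,b logical/binary matrices of identical dimensions.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("dice: mask dimensions differ")
  a <- a > 0; b <- b > 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(structure(1.0, both_empty = TRUE))
  2 * sum(a & b) / (sa + sb)
}

#' Pairwise annotator agreement by Dice
#'
#' For each annotated section, Dice is computed for every unordered pair of
#' annotators; pair means are averaged over sections, and the summary mean
#' averages over pairs and sections with a standard error taken over
#' section-level means (sections, not pixels, are the replication unit).
#'
#' @param annotations tibble with columns `ln_id`, `annotator_id` and `mask`
#'   (list column of binary matrices; one shared frame per `ln_id`).
#' @return object of class `nm_concordance`: list with `pairs` (tibble
#'   `ln_id`, `a`, `b`, `dice`), `matrix` (annotator x annotator mean Dice,
#'   1 on the diagonal), `mean`, `se`, `n_sections`.
#' @export
pairwise_dice <- function(annotations) {
  stopifnot(all(c("ln_id", "annotator_id", "mask") %in% names(annotations)))
  annotators <- sort(unique(annotations$annotator_id))
  if (length(annotators) < 2L) stop("pairwise agreement needs >= 2 annotators")
  pairs <- list()
  for (ln in unique(annotations$ln_id)) {
    sub <- annotations[annotations$ln_id == ln, ]
    ids <- sub$annotator_id
    cmb <- utils::combn(seq_len(nrow(sub)), 2L)
    for (j in seq_len(ncol(cmb))) {
      i1 <- cmb[1, j]; i2 <- cmb[2, j]
      pairs[[length(pairs) + 1L]] <- tibble::tibble(
        ln_id = ln, a = ids[i1], b = ids[i2],
        dice = as.numeric(dice(sub$mask[[i1]], sub$mask[[i2]])))
    }
  }
  pairs <- dplyr::bind_rows(pairs)
  mat <- matrix(1, length(annotators), length(annotators),
                dimnames = list(annotators, annotators))
  pm <- dplyr::summarise(dplyr::group_by(pairs, .data$a, .data$b),
                         dice = mean(.data$dice), .groups = "drop")
  for (j in seq_len(nrow(pm))) {
    mat[pm$a[j], pm$b[j]] <- pm$dice[j]
    mat[pm$b[j], pm$a[j]] <- pm$dice[j]
  }
  ln_means <- dplyr::summarise(dplyr::group_by(pairs, .data$ln_id),
                               dice = mean(.data$dice), .groups = "drop")
  structure(list(pairs = pairs, matrix = mat,
                 mean = mean(pairs$dice),
                 se = stats::sd(ln_means$dice) / sqrt(nrow(ln_means)),
                 n_sections = nrow(ln_means)),
            class = "nm_concordance")
}

#' @export
print.nm_concordance <- function(x, ...) {
  cat(sprintf("<nm_concordance: %d sections, mean pairwise Dice %.3f (SE %.3f)>\n",
              x$n_sections, x$mean, x$se))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Consensus map across annotators
#'
#' Per-pixel count of how many annotators marked the pixel.
#'
#' @param masks list of binary matrices in a shared frame.
#' @return integer matrix with values in `0..length(masks)` and attribute
#'   `n_annotators`.
#' @export
consensus_map <- function(masks) {
  stopifnot(length(masks) >= 1L)
  counts <- Reduce(`+`, lapply(masks, function(m) (m > 0) * 1L))
  structure(counts, n_annotators = length(masks))
}

#' Dice of a model mask against a consensus level
#'
#' The reference mask at level `k` contains pixels marked by at least `k`
#' annotators; references are nested decreasing in `k`.
#'
#' @param model_mask binary matrix.
#' @param cmap consensus counts from [consensus_map()].
#' @param k consensus level, `1 <= k <= n_annotators`.
#' @return Dice coefficient.
#' @export
model_vs_consensus <- function(model_mask, cmap, k) {
  n <- attr(cmap, "n_annotators") %||% max(cmap)
  if (k < 1 || k > n) stop(sprintf("consensus level k = %s out of range 1..%d", k, n))
  as.numeric(dice(model_mask, cmap >= k))
}
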