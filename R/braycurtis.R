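#' Bray-Curtis dissimilarity
#'
#' Quantitative dissimilarity between two abundance vectors over an aligned
#' taxon set:
#' \deqn{d(x, y) = 1 - \frac{2\sum_i \min(x_i, y_i)}{\sum_i (x_i + y_i)}.}
#' It reflects both composition and proportional density. A pair of all-zero
#' vectors carries no compositional information and returns `NA`; a zero
#' vector against a non-zero one is maximally dissimilar (1).
#'
#' @param x,y Non-negative abundance vectors of equal length. If both are
#'   named, names must match (taxon alignment is the caller's contract).
#' @return Dissimilarity in `[0, 1]`, or `NA` for a both-zero pair.
#' @examples
#' bray_curtis(c(6, 4, 0), c(3, 4, 3))  # 0.30
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (!is.null(names(x)) && !is.null(names(y)) && !identical(names(x), names(y))) {
    abort("taxon labels of `x` and `y` do not align.")
  }
  if (any(x < 0) || any(y < 0)) abort("abundances must be >= 0.")
  tot <- sum(x + y)
  if (tot == 0) return(NA_real_)
  1 - 2 * sum(pmin(x, y)) / tot
}

#' Bray-Curtis dissimilarity matrix
#'
#' @param mat Samples-by-taxa abundance matrix (row names = sample labels).
#' @return A symmetric matrix of Bray-Curtis dissimilarities with zero
#'   diagonal; both-zero sample pairs are `NA`.
#' @export
bray_curtis_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) abort("abundances must be >= 0.")
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  rs <- rowSums(mat)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- rs[i] + rs[j]
      d[i, j] <- d[j, i] <- if (tot == 0) NA_real_ else {
        1 - 2 * sum(pmin(mat[i, ], mat[j, ])) / tot
      }
    }
  }
  d
}
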