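#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats rnorm rpois rlnorm rchisq runif sd var setNames
#' @importFrom stats coef dnorm quantile uniroot as.dist hclust
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All simulators funnel through this so that
# (scenario, seed) fully determines every stochastic output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a reproducible child seed from a parent seed and a stream index,
# staying inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * stream) %% 2147483647L)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

# log(mean(exp(x))) along rows of a matrix, numerically stable.
row_log_mean_exp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowMeans(exp(m - mx)))
}

row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1L)
}
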