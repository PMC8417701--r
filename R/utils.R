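#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Index of the element of `haystack` nearest to each value of `needle`
#'
#' `haystack` must be sorted increasing. Ties break toward the earlier sample.
#' @noRd
nearest_index <- function(needle, haystack) {
  n <- length(haystack)
  lo <- findInterval(needle, haystack, all.inside = FALSE)
  lo <- pmax(pmin(lo, n), 1L)
  hi <- pmin(lo + 1L, n)
  pick_hi <- abs(haystack[hi] - needle) < abs(haystack[lo] - needle)
  ifelse(pick_hi, hi, lo)
}

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a bounded child seed from a master seed and a label
#' @noRd
child_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  # deterministic string hash folded into [0, 2^28)
  h <- 0
  for (cp in utf8ToInt(parts)) h <- (h * 131 + cp) %% 268435456
  as.integer(h)
}

#' Stratified fold assignment
#'
#' Returns an integer vector of fold ids (1..k) with class proportions
#' balanced across folds. Requires every class to have >= k members only
#' when `strict`.
#' @noRd
stratified_folds <- function(y, k, seed = NULL) {
  assign_fold <- function(idx) {
    n <- length(idx)
    f <- rep_len(seq_len(k), n)
    f[sample.int(n)]
  }
  run <- function() {
    folds <- integer(length(y))
    for (cl in levels(factor(y))) {
      idx <- which(y == cl)
      folds[idx] <- assign_fold(idx)
    }
    folds
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Fit/apply column standardization (z-score); constant columns pass through
#' @noRd
standardizer_fit <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  list(center = mu, scale = s)
}

#' @noRd
standardizer_apply <- function(std, x) {
  scale(x, center = std$center, scale = std$scale)[, , drop = FALSE]
}
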