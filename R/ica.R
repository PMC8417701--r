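#' Symmetric FastICA decomposition
#'
#' Fixed-point independent component analysis with the logcosh contrast
#' and symmetric orthogonalization, on whitened data. Used to isolate
#' ocular components for removal; exported because it is generally useful
#' for inspecting the decomposition.
#'
#' @param x numeric matrix, samples x channels.
#' @param n_comp number of components (default: all channels).
#' @param max_iter,tol iteration controls.
#' @return List with `S` (samples x components source estimates), `A`
#'   (mixing matrix, channels x components, in centered-data space),
#'   `center`, and `converged`.
#' @export
fast_ica <- function(x, n_comp = ncol(x), max_iter = 100, tol = 1e-3) {
  x <- as.matrix(x)
  n <- nrow(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  cv <- crossprod(xc) / (n - 1)
  ed <- eigen(cv, symmetric = TRUE)
  keep <- which(ed$values > max(ed$values) * 1e-9)[seq_len(min(n_comp, ncol(x)))]
  keep <- keep[!is.na(keep)]
  K <- ed$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(ed$values[keep]), length(keep))
  z <- xc %*% K                                  # whitened, n x m
  m <- ncol(z)
  W <- with_seed(42, matrix(rnorm(m * m), m, m))
  orth <- function(w) {
    s <- svd(w)
    s$u %*% t(s$v)
  }
  W <- orth(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    wz <- z %*% t(W)                             # n x m projections
    g <- tanh(wz)
    gp <- 1 - g^2
    W1 <- crossprod(g, z) / n - diag(colMeans(gp), m) %*% W
    W1 <- orth(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  S <- z %*% t(W)
  # unmixing in channel space is U = K t(W); mixing A satisfies x_c ~ S t(A)
  A <- t(MASS::ginv(K %*% t(W)))
  list(S = S, A = A, center = ctr, converged = converged)
}
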