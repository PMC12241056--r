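#' Principal component decomposition of a double-centered matrix
#'
#' Decomposes the residual (double-centered log) matrix `C` by singular value
#' decomposition into regional covariance pattern components: unit-norm tract
#' loading vectors (right singular vectors) and per-participant subject
#' scores (`C` projected onto the loadings). The eigenvalue of component `c`
#' is the variance of its score column, `d_c^2 / (n - 1)`, identical to the
#' eigenvalues of the tract-by-tract residual covariance matrix
#' `t(C) %*% C / (n - 1)`. Components are ordered by decreasing eigenvalue
#' and only components above numerical rank are retained; after
#' double-centering the rank is at most `min(n - 1, p - 1)`.
#'
#' Sign convention: each loading vector is oriented so its largest-magnitude
#' entry is positive. The fitness-facing orientation of the combined pattern
#' is fixed later, in [ssm_fit()].
#'
#' @param centered Numeric matrix with zero row and column means (from
#'   [log_double_center()]).
#' @param tol Relative tolerance on singular values for rank determination.
#' @return Object of class `ssm_decomposition`: `loadings` (tracts x
#'   components, orthonormal columns), `scores` (participants x components,
#'   orthogonal columns with zero mean), `eigenvalues`, `rank`. An all-zero
#'   input yields an empty (zero-component) decomposition.
#' @export
ssm_decompose <- function(centered, tol = 1e-10) {
  stopifnot(is.matrix(centered), is.numeric(centered))
  n <- nrow(centered); p <- ncol(centered)
  if (max(abs(rowMeans(centered))) > 1e-8 ||
      max(abs(colMeans(centered))) > 1e-8)
    stop("input is not double-centered: row/column means are not zero")
  sv <- svd(centered)
  thresh <- max(sv$d[1] * tol, .Machine$double.eps * max(n, p))
  r <- sum(sv$d > thresh)
  if (r == 0L) {
    return(structure(list(
      loadings = matrix(0, p, 0, dimnames = list(colnames(centered), NULL)),
      scores = matrix(0, n, 0, dimnames = list(rownames(centered), NULL)),
      eigenvalues = numeric(0), rank = 0L, n = n),
      class = "ssm_decomposition"))
  }
  V <- sv$v[, seq_len(r), drop = FALSE]
  S <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
  # deterministic orientation: largest |loading| entry positive
  for (c in seq_len(r)) {
    j <- which.max(abs(V[, c]))
    if (V[j, c] < 0) { V[, c] <- -V[, c]; S[, c] <- -S[, c] }
  }
  cn <- paste0("PC", seq_len(r))
  dimnames(V) <- list(colnames(centered), cn)
  dimnames(S) <- list(rownames(centered), cn)
  structure(list(loadings = V, scores = S,
                 eigenvalues = setNames(sv$d[seq_len(r)]^2 / (n - 1), cn),
                 rank = r, n = n),
            class = "ssm_decomposition")
}

#' @export
print.ssm_decomposition <- function(x, ...) {
  cat("SSM decomposition:", x$rank, "components,",
      nrow(x$scores), "participants x", nrow(x$loadings), "tracts\n")
  if (x$rank) {
    ev <- x$eigenvalues
    cat("  variance explained (top 5):",
        paste0(sprintf("%.1f%%", 100 * head(ev, 5) / sum(ev)),
               collapse = " "), "\n")
  }
  invisible(x)
}
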