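#' Log transform and double mean-centering
#'
#' The first step of the Scaled Subprofile Model: each metric value is
#' natural-log transformed, then row (participant) means, column (tract)
#' means and the grand mean are removed,
#' \deqn{C_{ij} = L_{ij} - \bar L_{i.} - \bar L_{.j} + \bar L_{..}}
#' leaving a residual matrix whose every row mean and column mean is zero.
#' Double-centering annihilates any additive row + column structure on the
#' log scale — in particular a global multiplicative scaling factor per
#' participant and the group mean regional profile — so only the
#' participant-by-tract interaction (the covariance pattern structure)
#' survives.
#'
#' @param x Strictly positive numeric matrix, participants in rows, tracts in
#'   columns.
#' @return List of class `ssm_centering`:
#'   \describe{
#'     \item{centered}{the double-centered log matrix `C`;}
#'     \item{row_means}{per-participant mean of the log matrix;}
#'     \item{column_means}{per-tract mean of the log matrix (the group mean
#'       log profile), used to score new participants;}
#'     \item{grand_mean}{overall mean of the log matrix.}
#'   }
#' @export
#' @examples
#' M <- matrix(exp(rnorm(20)), 5, 4)
#' ctr <- log_double_center(M)
#' max(abs(rowMeans(ctr$centered)))   # ~ 0
log_double_center <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  bad <- which(!(x > 0), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "non-positive value at participant %s, tract %s: log transform undefined",
      if (is.null(rownames(x))) i else rownames(x)[i],
      if (is.null(colnames(x))) j else colnames(x)[j]))
  }
  L <- log(x)
  rm <- rowMeans(L)
  cm <- colMeans(L)
  gm <- mean(L)
  C <- L - rm - rep(cm - gm, each = nrow(L))
  dimnames(C) <- dimnames(x)
  structure(list(centered = C, row_means = rm, column_means = cm,
                 grand_mean = gm),
            class = "ssm_centering")
}

# hot-path variant for resampling loops: takes an already-logged matrix,
# returns the centered matrix only
.double_center <- function(L) {
  L - rowMeans(L) - rep(colMeans(L) - mean(L), each = nrow(L))
}
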