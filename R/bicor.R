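#' Biweight midcorrelation
#'
#' Robust correlation based on the median and the median absolute deviation
#' (MAD, without consistency scaling). Each observation is centered at the
#' vector's median and downweighted by Tukey's biweight
#' \eqn{w_i = (1 - u_i^2)^2 \, 1[|u_i| < 1]} with
#' \eqn{u_i = (x_i - \mathrm{med}\,x) / (9\,\mathrm{MAD}\,x)}, so that gross
#' outliers (beyond nine MADs) get zero weight; the correlation is the
#' normalized cross-product of the weighted, centered vectors. If a vector's
#' MAD is zero (heavily tied data) that vector falls back to mean/SD
#' (Pearson-style) centering, recorded in the `"fallback"` attribute.
#'
#' @param x,y numeric vectors of equal length >= 4, neither constant.
#' @return Correlation in `[-1, 1]`; attribute `"fallback"` is a logical pair
#'   indicating a zero-MAD Pearson fallback for `x` and `y`.
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- x + rnorm(50, sd = 0.3)
#' bicor(x, y)
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 4) stop("need at least 4 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  a <- .bicor_center(x)
  b <- .bicor_center(y)
  r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  r <- max(-1, min(1, r))
  attr(r, "fallback") <- c(x = attr(a, "fallback"), y = attr(b, "fallback"))
  r
}

# median/MAD biweight centering of one vector; Pearson-style fallback on
# zero MAD. Returns centered weighted values with a "fallback" flag.
.bicor_center <- function(x) {
  m <- stats::median(x)
  mad0 <- stats::median(abs(x - m))
  if (mad0 == 0) {
    out <- x - mean(x)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  u <- (x - m) / (9 * mad0)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  out <- (x - m) * w
  attr(out, "fallback") <- FALSE
  out
}

# rows of X biweight-centered and scaled to unit L2 norm, so that
# tcrossprod() of the result is the bicor matrix. Errors on constant rows.
.bicor_rows <- function(X) {
  const <- apply(X, 1L, function(r) max(r) == min(r))
  if (any(const))
    stop("constant gene(s): ", paste(rownames(X)[const], collapse = ", "))
  A <- t(apply(X, 1L, function(r) {
    a <- .bicor_center(r)
    a / sqrt(sum(a^2))
  }))
  dimnames(A) <- dimnames(X)
  A
}

#' All-pairs correlation matrix of gene profiles
#'
#' @param X numeric matrix, genes in rows, samples in columns (>= 4).
#' @param method `"bicor"` (default) or `"pearson"`.
#' @return Symmetric genes x genes correlation matrix with unit diagonal.
#' @export
cor_matrix <- function(X, method = c("bicor", "pearson")) {
  method <- match.arg(method)
  if (ncol(X) < 4) stop("need at least 4 samples")
  if (anyNA(X)) stop("missing values not allowed; run qc_filter first")
  if (method == "pearson") {
    C <- stats::cor(t(X))
  } else {
    A <- .bicor_rows(X)
    C <- tcrossprod(A)
  }
  C[C > 1] <- 1
  C[C < -1] <- -1
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C
}

#' Unsigned co-expression similarity matrix
#'
#' \eqn{S_{ij} = |\mathrm{cor}(i, j)|}: the absolute correlation of every
#' gene pair, so positively and negatively co-regulated pairs are treated
#' alike (unsigned network).
#'
#' @param expr a complete [coex_expr] with >= 4 samples and no constant genes.
#' @param method correlation flavor, `"bicor"` (default) or `"pearson"`.
#' @return Symmetric matrix in `[0, 1]` with unit diagonal and attribute
#'   `"method"`.
#' @export
similarity_matrix <- function(expr, method = c("bicor", "pearson")) {
  method <- match.arg(method)
  S <- abs(cor_matrix(expr$values, method))
  diag(S) <- 1
  attr(S, "method") <- method
  S
}
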