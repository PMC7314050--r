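#' Soft-threshold adjacency matrix
#'
#' Raises the similarity matrix elementwise to the power `beta`
#' (\eqn{a_{ij} = S_{ij}^\beta}), keeping the network weighted while
#' suppressing weak correlations. The diagonal is set to 1 but is excluded
#' from all connectivity sums.
#'
#' @param S symmetric similarity matrix with entries in `[0, 1]`.
#' @param beta positive integer soft-threshold power.
#' @return Adjacency matrix, same shape as `S`.
#' @export
adjacency_matrix <- function(S, beta) {
  if (length(beta) != 1 || beta < 1) stop("'beta' must be >= 1")
  A <- S^beta
  diag(A) <- 1
  A
}

#' Network connectivity (weighted degree)
#'
#' @param A adjacency matrix.
#' @return Vector \eqn{k_i = \sum_{j \ne i} a_{ij}}.
#' @export
connectivity <- function(A) {
  rowSums(A) - diag(A)
}

#' Scale-free topology fit index
#'
#' Bins the connectivity distribution into `n_bins` equal-width bins, drops
#' empty bins, and regresses log10(frequency) on log10(mean connectivity).
#' Returns the signed fit index \eqn{R^2_{signed} = -\mathrm{sign}(slope)
#' \cdot R^2}: positive (approaching 1) for the negative log-log slope a
#' scale-free degree distribution shows.
#'
#' @param x adjacency matrix, or directly a vector of connectivities.
#' @param n_bins number of equal-width connectivity bins (default 10).
#' @return List with `r2_signed`, `slope`, and the `bins` data.frame.
#' @export
scale_free_fit <- function(x, n_bins = 10) {
  k <- if (is.matrix(x)) connectivity(x) else x
  k <- k[k > 0]
  if (length(k) < n_bins)
    stop("need at least ", n_bins, " genes with positive connectivity")
  if (max(k) == min(k))
    stop("insufficient degree spread: all connectivities equal")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  cnt <- tabulate(bin, nbins = n_bins)
  keep <- cnt > 0
  if (sum(keep) < 3) stop("insufficient degree spread: fewer than 3 non-empty bins")
  mean_k <- vapply(which(keep), function(b) mean(k[as.integer(bin) == b]),
                   numeric(1))
  freq <- cnt[keep] / length(k)
  fit <- stats::lm(log10(freq) ~ log10(mean_k))
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  list(r2_signed = -sign(slope) * r2, slope = slope,
       bins = data.frame(mean_k = mean_k, freq = freq))
}

#' Soft-threshold selection by the scale-free topology criterion
#'
#' Scans candidate powers in ascending order and returns the smallest `beta`
#' whose signed fit index reaches `r2_target` (the lowest power at which
#' network topology is scale-free). If none qualifies, the power maximizing
#' the fit index is returned with `warning_flag = TRUE`.
#'
#' @param S similarity matrix.
#' @param beta_grid ascending positive integers to scan (default `1:20`).
#' @param r2_target signed-R2 threshold (default 0.9).
#' @param n_bins connectivity bins passed to [scale_free_fit()].
#' @return List with `beta`, `warning_flag`, and `scan`: a data.frame of
#'   `beta`, `r2_signed`, `slope`, `mean_k`, `median_k`, `max_k` per power.
#' @export
pick_soft_threshold <- function(S, beta_grid = 1:20, r2_target = 0.9,
                                n_bins = 10) {
  if (!length(beta_grid) || is.unsorted(beta_grid))
    stop("'beta_grid' must be non-empty and ascending")
  scan <- data.frame(beta = beta_grid, r2_signed = NA_real_,
                     slope = NA_real_, mean_k = NA_real_,
                     median_k = NA_real_, max_k = NA_real_)
  for (i in seq_along(beta_grid)) {
    A <- adjacency_matrix(S, beta_grid[i])
    k <- connectivity(A)
    scan$mean_k[i] <- mean(k)
    scan$median_k[i] <- stats::median(k)
    scan$max_k[i] <- max(k)
    fit <- tryCatch(scale_free_fit(k, n_bins), error = function(e) NULL)
    if (!is.null(fit)) {
      scan$r2_signed[i] <- fit$r2_signed
      scan$slope[i] <- fit$slope
    }
  }
  ok <- which(!is.na(scan$r2_signed) & scan$r2_signed >= r2_target)
  if (length(ok)) {
    list(beta = beta_grid[ok[1]], warning_flag = FALSE, scan = scan)
  } else {
    best <- if (all(is.na(scan$r2_signed))) 1L else which.max(scan$r2_signed)
    list(beta = beta_grid[best], warning_flag = TRUE, scan = scan)
  }
}

#' Topological overlap matrix
#'
#' \deqn{TOM_{ij} = \frac{\ell_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}}
#' with \eqn{\ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and unit diagonal:
#' two genes overlap strongly when they are directly connected and share
#' neighbors. `1 - TOM` is the clustering dissimilarity.
#'
#' @param A symmetric adjacency matrix with entries in `[0, 1]`.
#' @return TOM matrix in `[0, 1]`, symmetric, unit diagonal.
#' @export
topological_overlap <- function(A) {
  if (!isSymmetric(unname(A), tol = 1e-10)) stop("adjacency must be symmetric")
  A0 <- A
  diag(A0) <- 0
  L <- A0 %*% A0           # l_ij: u = i, j terms vanish since diag(A0) = 0
  k <- rowSums(A0)
  kmin <- outer(k, k, pmin)
  TOM <- (L + A0) / (kmin + 1 - A0)
  TOM[kmin + 1 - A0 == 0] <- 0   # isolated pair guard
  diag(TOM) <- 1
  TOM
}

#' Build a weighted co-expression network
#'
#' Convenience wrapper: similarity -> soft-threshold selection (unless `beta`
#' is given) -> adjacency -> TOM -> dissimilarity.
#'
#' @param expr a complete [coex_expr].
#' @param method correlation flavor for [similarity_matrix()].
#' @param beta fixed soft power, or `NULL` to select by
#'   [pick_soft_threshold()].
#' @param beta_grid,r2_target,n_bins passed to [pick_soft_threshold()].
#' @return Object of class `gene_network`: list with `gene_ids`, `adjacency`,
#'   `tom`, `dissimilarity`, `beta`, `method`, `scan` (or `NULL`),
#'   `beta_warning`.
#' @export
build_network <- function(expr, method = c("bicor", "pearson"), beta = NULL,
                          beta_grid = 1:20, r2_target = 0.9, n_bins = 10) {
  method <- match.arg(method)
  S <- similarity_matrix(expr, method)
  scan <- NULL
  warn <- FALSE
  if (is.null(beta)) {
    pick <- pick_soft_threshold(S, beta_grid, r2_target, n_bins)
    beta <- pick$beta
    scan <- pick$scan
    warn <- pick$warning_flag
  }
  A <- adjacency_matrix(S, beta)
  TOM <- topological_overlap(A)
  structure(list(gene_ids = rownames(expr$values), adjacency = A, tom = TOM,
                 dissimilarity = 1 - TOM, beta = beta, method = method,
                 scan = scan, beta_warning = warn),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, %s similarity, beta = %d%s\n",
              length(x$gene_ids), x$method, x$beta,
              if (isTRUE(x$beta_warning)) " (fit target not reached)" else ""))
  invisible(x)
}
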