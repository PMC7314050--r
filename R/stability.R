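#' Module stability by half-sample resampling of intramodular connectivity
#'
#' For each resample, a fraction of the samples is drawn without replacement,
#' the similarity (same correlation method) and adjacency (same `beta`) are
#' rebuilt on the subsample, and each gene's intramodular connectivity
#' (sum of adjacency to same-module genes) is recomputed. Per module, the
#' resampled connectivity vector is correlated (Pearson) with the full-data
#' one over that module's genes; the mean and SD of this connectivity
#' correlation across resamples summarize reproducibility. Module membership
#' is frozen at the full-data partition throughout: only the connectivity is
#' re-estimated, so module matching across resamples stays well-defined. A
#' module is called stable when its mean connectivity correlation exceeds
#' `threshold` (default 0.7).
#'
#' Each resample draws from its own seed (`seed + r`), so results are
#' bit-reproducible and independent of execution order.
#'
#' @param expr a complete [coex_expr].
#' @param partition a `module_partition`; label 0 is ignored.
#' @param beta soft-threshold power used for the full network.
#' @param n_resamples number of resamples (default 1000).
#' @param fraction fraction of samples per resample (default 0.5);
#'   `floor(fraction * n)` must be >= 4. `fraction = 1` reproduces the full
#'   network in every resample.
#' @param threshold stability call threshold on the mean correlation.
#' @param seed master seed.
#' @param method correlation flavor, as in [similarity_matrix()].
#' @return Object of class `stability_report`: data.frame `report` with
#'   columns `module`, `n_genes`, `mean_corr`, `sd_corr`, `n_resamples`,
#'   `stable`, plus the run settings. Modules with fewer than 3 genes are
#'   reported as `NA` with a warning.
#' @export
resample_connectivity_stability <- function(expr, partition, beta,
                                            n_resamples = 1000,
                                            fraction = 0.5, threshold = 0.7,
                                            seed = 1,
                                            method = c("bicor", "pearson")) {
  method <- match.arg(method)
  if (n_resamples < 1) stop("'n_resamples' must be >= 1")
  X <- expr$values
  n <- ncol(X)
  nsub <- floor(fraction * n)
  if (nsub < 4) stop("floor(fraction * n_samples) must be >= 4")
  labs <- sort(setdiff(unique(partition$labels), 0L))
  genes_by_mod <- lapply(labs, function(l)
    names(partition$labels)[partition$labels == l])
  small <- vapply(genes_by_mod, length, integer(1)) < 3
  if (any(small))
    warning("module(s) with < 3 genes reported as NA: ",
            paste(labs[small], collapse = ", "))

  kwithin <- function(A) {
    out <- lapply(genes_by_mod, function(g) {
      B <- A[g, g, drop = FALSE]
      rowSums(B) - diag(B)
    })
    out
  }
  A_full <- adjacency_matrix(similarity_matrix(expr, method), beta)
  kw_full <- kwithin(A_full)

  corrs <- matrix(NA_real_, n_resamples, length(labs))
  for (r in seq_len(n_resamples)) {
    set.seed(seed + r)
    idx <- sort(sample.int(n, nsub))  # keep original sample order
    sub <- coex_expr(X[, idx, drop = FALSE], expr$batch[idx])
    A <- adjacency_matrix(similarity_matrix(sub, method), beta)
    kw <- kwithin(A)
    for (m in seq_along(labs)) {
      if (small[m]) next
      # cor() of a vector with itself is 1 by definition; bypass its
      # floating-point round-trip so identity resamples are exact
      corrs[r, m] <- if (identical(kw_full[[m]], kw[[m]])) 1
                     else stats::cor(kw_full[[m]], kw[[m]])
    }
  }
  report <- data.frame(
    module = labs,
    n_genes = vapply(genes_by_mod, length, integer(1)),
    mean_corr = colMeans(corrs),
    sd_corr = apply(corrs, 2, stats::sd),
    n_resamples = n_resamples,
    stringsAsFactors = FALSE)
  report$stable <- !is.na(report$mean_corr) & report$mean_corr > threshold
  structure(list(report = report, fraction = fraction, threshold = threshold,
                 seed = seed, beta = beta, method = method),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability_report: %d modules, %d resamples at fraction %.2f (beta %d)\n",
              nrow(x$report), x$report$n_resamples[1], x$fraction, x$beta))
  print(x$report, row.names = FALSE)
  invisible(x)
}
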