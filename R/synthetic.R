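#' Generate a synthetic expression compendium with planted structure
#'
#' Emulates the statistical shape of a multi-experiment microarray
#' compendium: each module is driven by a latent per-sample factor (standard
#' normal); gene `g` of module `m` with loading \eqn{\ell_g} has profile
#' \eqn{\ell_g f_m + \sigma \sqrt{1 - \ell_g^2}\, \epsilon}, so with
#' `noise_sd = 1` the population gene-factor correlation equals the loading.
#' Background genes are pure noise. The first gene of each module is the
#' planted hub (loading `hub_loading`, strictly above all co-members); the
#' second is a planted regulator ("TF") at loading `tf_loading`; `n_decoy_tfs`
#' background genes are designated decoy TFs. A fraction of cells can be
#' multiplied by `outlier_scale` to emulate gross outliers (stressing the
#' robust correlation). Samples are split into `n_batches` label-only
#' batches (no batch shift is injected). When `factor_cor` is given, the
#' first two module factors are constructed with exactly that sample
#' correlation (Gram-Schmidt), to exercise the eigengene-merging rule under
#' a known planted condition.
#'
#' @param n_modules number of planted modules (default 5).
#' @param module_sizes integer vector of module sizes (default 40 each).
#' @param n_background pure-noise genes (default 100).
#' @param n_samples samples (default 60, >= 8).
#' @param loading_range range of non-hub loadings (default `c(0.8, 0.95)`).
#' @param hub_loading hub loading (default 0.98; must exceed
#'   `max(loading_range)` and `tf_loading`).
#' @param tf_loading planted-regulator loading (default 0.9).
#' @param n_decoy_tfs decoy TFs among background genes (default 5).
#' @param noise_sd noise scale multiplier (default 1).
#' @param outlier_frac fraction of cells made outliers (default 0).
#' @param outlier_scale multiplier applied to outlier cells (default 10).
#' @param n_batches number of sample batches (default 3).
#' @param factor_cor optional exact sample correlation between factors 1
#'   and 2.
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @return List with `expr` (a [coex_expr]) and `truth`: planted labels
#'   (named integer, 0 = background), `loadings`, `factors` (modules x
#'   samples), `hubs`, `tfs` (data.frame `tf`, `module`), `decoy_tfs`, and
#'   the generating configuration.
#' @export
generate_dataset <- function(n_modules = 5,
                             module_sizes = rep(40L, n_modules),
                             n_background = 100, n_samples = 60,
                             loading_range = c(0.8, 0.95),
                             hub_loading = 0.98, tf_loading = 0.9,
                             n_decoy_tfs = min(5L, n_background),
                             noise_sd = 1,
                             outlier_frac = 0, outlier_scale = 10,
                             n_batches = 3, factor_cor = NULL, seed = 1) {
  if (length(module_sizes) != n_modules) stop("one size per module required")
  if (any(module_sizes < 2)) stop("module sizes must be >= 2")
  if (n_samples < 8) stop("need at least 8 samples")
  if (hub_loading <= max(loading_range) || hub_loading <= tf_loading)
    stop("'hub_loading' must exceed max(loading_range) and 'tf_loading'")
  if (n_decoy_tfs > n_background) stop("more decoy TFs than background genes")
  set.seed(seed)

  F <- matrix(stats::rnorm(n_modules * n_samples), n_modules, n_samples)
  if (!is.null(factor_cor)) {
    if (n_modules < 2) stop("'factor_cor' needs >= 2 modules")
    u <- as.vector(scale(F[1, ]))
    r <- stats::residuals(stats::lm(F[2, ] ~ u))
    v <- as.vector(scale(r))
    F[2, ] <- factor_cor * u + sqrt(1 - factor_cor^2) * v
  }

  n_genes <- sum(module_sizes) + n_background
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  labels <- integer(n_genes)
  loadings <- rep(NA_real_, n_genes)
  X <- matrix(NA_real_, n_genes, n_samples)
  at <- 0L
  hubs <- character(n_modules)
  tfs <- character(n_modules)
  for (m in seq_len(n_modules)) {
    sz <- module_sizes[m]
    idx <- at + seq_len(sz)
    l <- stats::runif(sz, loading_range[1], loading_range[2])
    l[1] <- hub_loading
    if (sz >= 2) l[2] <- tf_loading
    eps <- matrix(stats::rnorm(sz * n_samples), sz, n_samples)
    X[idx, ] <- l %o% F[m, ] + noise_sd * sqrt(1 - l^2) * eps
    labels[idx] <- m
    loadings[idx] <- l
    hubs[m] <- gene_ids[idx[1]]
    tfs[m] <- gene_ids[idx[min(2, sz)]]
    at <- at + sz
  }
  if (n_background > 0) {
    idx <- at + seq_len(n_background)
    X[idx, ] <- matrix(stats::rnorm(n_background * n_samples),
                       n_background, n_samples)
  }
  if (outlier_frac > 0) {
    cells <- sample.int(length(X), round(outlier_frac * length(X)))
    X[cells] <- X[cells] * outlier_scale
  }
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  dimnames(X) <- list(gene_ids, sample_ids)
  # contiguous, roughly equal batches (labels only, no injected shift)
  batch <- paste0("batch", sort(rep_len(seq_len(n_batches), n_samples)))
  names(labels) <- gene_ids
  names(loadings) <- gene_ids
  rownames(F) <- as.character(seq_len(n_modules))
  colnames(F) <- sample_ids
  decoys <- if (n_decoy_tfs > 0)
    gene_ids[sum(module_sizes) + seq_len(n_decoy_tfs)] else character(0)
  truth <- list(labels = labels, loadings = loadings, factors = F,
                hubs = stats::setNames(hubs, as.character(seq_len(n_modules))),
                tfs = data.frame(tf = tfs, module = seq_len(n_modules),
                                 target_loading = tf_loading,
                                 stringsAsFactors = FALSE),
                decoy_tfs = decoys, noise_sd = noise_sd,
                outlier_frac = outlier_frac, outlier_scale = outlier_scale,
                factor_cor = factor_cor, seed = seed)
  list(expr = coex_expr(X, batch), truth = truth)
}

#' Planted partition of a synthetic dataset
#'
#' @param truth the `truth` element of [generate_dataset()].
#' @param min_size minimum module size to record (metadata only).
#' @return A `module_partition` carrying the planted labels.
#' @export
truth_partition <- function(truth, min_size = 2) {
  structure(list(labels = truth$labels, min_size = min_size,
                 merge_history = list(), colors = NULL),
            class = "module_partition")
}

#' Generate a trait gene list with a planted module overlap
#'
#' Emulates a differential-expression gene list: exactly `overlap_count`
#' genes come from `target_module`, the rest are drawn uniformly from
#' non-module genes.
#'
#' @param truth the `truth` element of [generate_dataset()].
#' @param list_size total list size.
#' @param target_module planted module label.
#' @param overlap_count genes shared with the target module
#'   (`<= min(list_size, module size)`).
#' @param seed RNG seed.
#' @return List with `label`, `genes`, `target_module`, `overlap_count`.
#' @export
generate_trait_lists <- function(truth, list_size, target_module,
                                 overlap_count, seed = 1) {
  members <- names(truth$labels)[truth$labels == target_module]
  others <- names(truth$labels)[truth$labels != target_module]
  if (overlap_count > min(list_size, length(members)))
    stop("infeasible overlap: overlap_count exceeds list or module size")
  if (list_size - overlap_count > length(others))
    stop("infeasible list size: not enough non-module genes")
  set.seed(seed)
  genes <- c(sample(members, overlap_count),
             sample(others, list_size - overlap_count))
  list(label = sprintf("trait_module%s_k%d", target_module, overlap_count),
       genes = genes, target_module = target_module,
       overlap_count = overlap_count)
}
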