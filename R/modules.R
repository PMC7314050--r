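#' Average-linkage clustering of the TOM dissimilarity
#'
#' @param diss symmetric dissimilarity matrix (zero diagonal, entries in
#'   `[0, 1]`), typically `1 - TOM`.
#' @return An [stats::hclust] dendrogram (average linkage).
#' @export
cluster_genes <- function(diss) {
  if (!isSymmetric(unname(diss), tol = 1e-10))
    stop("dissimilarity must be symmetric")
  if (any(abs(diag(diss)) > 1e-12)) stop("dissimilarity diagonal must be zero")
  stats::hclust(stats::as.dist(diss), method = "average")
}

# leaves under a node of an hclust tree (node > 0: merge row, < 0: leaf)
.tree_leaves <- function(merge, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (nd < 0) out <- c(out, -nd)
    else stack <- c(stack, merge[nd, 1], merge[nd, 2])
  }
  out
}

#' Dynamic hybrid tree cut
#'
#' Two-stage module detection on an average-linkage dendrogram of the TOM
#' dissimilarity. Stage one finds branches: the tree is first cut at
#' `max_cut_height` times its maximum merge height, and each resulting
#' component is recursively split wherever the joining height of two
#' sub-branches (each of size >= `min_cluster_size`) clears their internal
#' merge heights by a gap controlled by `deep_split` (0 = most conservative,
#' 4 = most aggressive); small late-attaching offshoots are trimmed from a
#' branch under the same gap rule. Stage two (the PAM-like stage) assigns
#' each unlabeled gene to the cluster with smallest average dissimilarity,
#' provided that distance is below the cluster's own mean internal
#' dissimilarity; genes failing this stay unassigned (label 0, "grey").
#'
#' This is an independent implementation of the dynamic hybrid idea; it is
#' validated by planted-structure recovery, not by bit-identity with any
#' particular reference. See [cut_static()] for the plain fixed-height
#' fallback.
#'
#' @param dend an [stats::hclust] tree from [cluster_genes()].
#' @param diss the dissimilarity matrix the tree was built from.
#' @param min_cluster_size smallest allowed module (default 20 genes).
#' @param deep_split split aggressiveness, integer 0..4 (default 2).
#' @param pam_stage run the assignment stage (default `TRUE`).
#' @param max_cut_height top cut as a fraction of the maximum merge height
#'   (default 0.99).
#' @return A `module_partition`: list with `labels` (named integer vector,
#'   0 = unassigned), `min_size`, `merge_history` (empty), `colors` (`NULL`
#'   until [assign_colors()]).
#' @export
cut_dynamic <- function(dend, diss, min_cluster_size = 20, deep_split = 2,
                        pam_stage = TRUE, max_cut_height = 0.99) {
  if (min_cluster_size < 2) stop("'min_cluster_size' must be >= 2")
  if (!deep_split %in% 0:4) stop("'deep_split' must be an integer in 0..4")
  n <- length(dend$order)
  gene_ids <- dend$labels
  if (is.null(gene_ids)) gene_ids <- as.character(seq_len(n))
  merge <- dend$merge
  h <- dend$height
  cut_h <- max_cut_height * max(h)
  # minimum separating gap on the absolute dissimilarity-height scale:
  # larger deep_split tolerates smaller gaps, hence splits more aggressively
  gap_min <- c(0.30, 0.20, 0.125, 0.075, 0.025)[deep_split + 1]

  # per-node subtree size
  sz <- integer(n - 1)
  for (i in seq_len(n - 1)) {
    l <- merge[i, 1]; r <- merge[i, 2]
    sz[i] <- (if (l < 0) 1L else sz[l]) + (if (r < 0) 1L else sz[r])
  }
  node_size <- function(nd) if (nd < 0) 1L else sz[nd]
  node_top <- function(nd) if (nd < 0) 0 else h[nd]

  # component roots: subtrees below the top cut are candidate branches, but
  # two sibling subtrees whose join clears neither's internal structure by
  # gap_min are not genuinely separate and are joined back (this keeps a
  # flat, homogeneous tree in one piece instead of shattering it at the top)
  comp_root <- vector("list", n - 1)
  child_roots <- function(nd) {
    if (nd < 0 || h[nd] <= cut_h) list(nd) else comp_root[[nd]]
  }
  for (i in which(h > cut_h)) {   # heights ascend, so children come first
    L <- child_roots(merge[i, 1])
    R <- child_roots(merge[i, 2])
    join <- length(L) == 1 && length(R) == 1 &&
      (h[i] - node_top(L[[1]])) < gap_min &&
      (h[i] - node_top(R[[1]])) < gap_min
    comp_root[[i]] <- if (join) list(i) else c(L, R)
  }
  roots <- if (max(h) > cut_h) comp_root[[n - 1L]] else list(n - 1L)
  clusters <- list()
  unassigned <- integer(0)

  emit <- function(nd) clusters[[length(clusters) + 1L]] <<-
    .tree_leaves(merge, nd)
  split_node <- function(root) {
    stack <- root
    while (length(stack)) {
      nd <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (nd < 0 || node_size(nd) < min_cluster_size) {
        # defensive; callers only push nodes of size >= min_cluster_size
        unassigned <<- c(unassigned, .tree_leaves(merge, nd))
        next
      }
      l <- merge[nd, 1]; r <- merge[nd, 2]
      sl <- node_size(l); sr <- node_size(r)
      if (sl >= min_cluster_size && sr >= min_cluster_size &&
          (h[nd] - max(node_top(l), node_top(r))) >= gap_min) {
        stack <- c(stack, l, r)
      } else if (xor(sl >= min_cluster_size, sr >= min_cluster_size)) {
        big <- if (sl >= min_cluster_size) l else r
        small <- if (sl >= min_cluster_size) r else l
        if ((h[nd] - node_top(big)) >= gap_min) {
          unassigned <<- c(unassigned, .tree_leaves(merge, small))
          stack <- c(stack, big)
        } else emit(nd)
      } else emit(nd)
    }
  }

  for (root in roots) {
    if (node_size(root) < min_cluster_size)
      unassigned <- c(unassigned, .tree_leaves(merge, root))
    else split_node(root)
  }

  labels <- integer(n)
  names(labels) <- gene_ids
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i

  if (pam_stage && length(clusters)) {
    radius <- vapply(clusters, function(m) {
      d <- diss[m, m]
      sum(d) / (length(m) * (length(m) - 1))
    }, numeric(1))
    for (g in which(labels == 0)) {
      d <- vapply(clusters, function(m) mean(diss[g, m]), numeric(1))
      best <- which.min(d)
      if (d[best] < radius[best]) labels[g] <- best
    }
  }
  .relabel_partition(labels, min_cluster_size)
}

#' Fixed-height tree cut (fallback mode)
#'
#' Plain `cutree` at a fixed height followed by the minimum-size filter;
#' clusters below `min_cluster_size` are unassigned. Provided as a
#' transparent baseline for debugging the dynamic cut.
#'
#' @inheritParams cut_dynamic
#' @param cut_height absolute cut height.
#' @return A `module_partition`.
#' @export
cut_static <- function(dend, cut_height, min_cluster_size = 20) {
  if (min_cluster_size < 2) stop("'min_cluster_size' must be >= 2")
  grp <- stats::cutree(dend, h = cut_height)
  tab <- table(grp)
  labels <- ifelse(tab[as.character(grp)] >= min_cluster_size, grp, 0L)
  names(labels) <- names(grp)
  .relabel_partition(labels, min_cluster_size)
}

# canonical relabeling: modules numbered by decreasing size, ties broken by
# the lexicographically smallest member gene ID
.relabel_partition <- function(labels, min_size, merge_history = list()) {
  nm <- names(labels)
  labs <- setdiff(unique(labels), 0L)
  if (length(labs)) {
    size <- vapply(labs, function(l) sum(labels == l), integer(1))
    first <- vapply(labs, function(l) min(nm[labels == l]), character(1))
    ord <- order(-size, first)
    new <- integer(max(labs))
    new[labs[ord]] <- seq_along(labs)
    labels <- as.integer(ifelse(labels == 0L, 0L, new[pmax(labels, 1L)]))
  } else {
    labels <- as.integer(labels)
  }
  names(labels) <- nm
  structure(list(labels = labels, min_size = min_size,
                 merge_history = merge_history, colors = NULL),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  tab <- table(x$labels[x$labels > 0])
  cat(sprintf("module_partition: %d modules, %d assigned / %d genes (min size %d)\n",
              length(tab), sum(x$labels > 0), length(x$labels), x$min_size))
  invisible(x)
}

#' Module sizes
#' @param partition a `module_partition`.
#' @return Named integer vector of module sizes (labels > 0).
#' @export
module_sizes <- function(partition) {
  lab <- partition$labels[partition$labels > 0]
  tab <- table(factor(lab, levels = sort(unique(lab))))
  stats::setNames(as.integer(tab), names(tab))
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its genes'
#' z-scored expression: a unit-norm per-sample summary profile. The sign is
#' fixed so each eigengene correlates non-negatively with its module's mean
#' z-scored profile; the fraction of module variance it explains is reported.
#' Single-gene modules return the gene's standardized profile (variance
#' explained 1) with a warning.
#'
#' @param expr a complete [coex_expr].
#' @param partition a `module_partition`; label 0 (unassigned) is skipped.
#' @return Object of class `module_eigengenes`: list with `eigengenes`
#'   (module x sample matrix, rownames are module labels), `var_explained`,
#'   `module_labels`.
#' @export
module_eigengenes <- function(expr, partition) {
  labs <- sort(setdiff(unique(partition$labels), 0L))
  if (!length(labs)) stop("partition has no labeled modules")
  X <- expr$values
  E <- matrix(NA_real_, length(labs), ncol(X),
              dimnames = list(as.character(labs), colnames(X)))
  ve <- stats::setNames(numeric(length(labs)), as.character(labs))
  for (i in seq_along(labs)) {
    genes <- names(partition$labels)[partition$labels == labs[i]]
    Z <- t(scale(t(X[genes, , drop = FALSE])))
    if (length(genes) == 1L) {
      warning("module ", labs[i], " has a single gene")
      v <- Z[1, ] / sqrt(sum(Z[1, ]^2))
      ve[i] <- 1
    } else {
      sv <- svd(Z, nu = 0, nv = 1)
      v <- sv$v[, 1]
      ve[i] <- sv$d[1]^2 / sum(sv$d^2)
      m <- colMeans(Z)
      if (stats::sd(m) > 0 && stats::cor(v, m) < 0) v <- -v
    }
    E[i, ] <- v
  }
  structure(list(eigengenes = E, var_explained = ve, module_labels = labs),
            class = "module_eigengenes")
}

#' Merge modules with correlated eigengenes
#'
#' Eigengenes are clustered by average linkage on the dissimilarity
#' `1 - cor(ME_i, ME_j)`; all modules within a branch below `cut_height`
#' (default 0.2, i.e. eigengene correlation above 0.8) are fused, the fused
#' module inherits the label of its largest constituent, eigengenes are
#' recomputed, and the procedure iterates until no pair of eigengenes is
#' closer than `cut_height`.
#'
#' @param expr a complete [coex_expr].
#' @param partition pre-merge `module_partition`.
#' @param MEs optional pre-computed [module_eigengenes()] for `partition`.
#' @param cut_height merge height on the `1 - cor` scale, in `(0, 1)`.
#' @return List with `partition` (merge history appended, labels renumbered
#'   by size) and `eigengenes` (recomputed post-merge).
#' @export
merge_modules <- function(expr, partition, MEs = NULL, cut_height = 0.2) {
  if (cut_height <= 0 || cut_height >= 1) stop("'cut_height' must be in (0,1)")
  labels <- partition$labels
  history <- partition$merge_history
  if (is.null(MEs)) MEs <- module_eigengenes(expr, .as_partition(labels, partition))
  repeat {
    labs <- sort(setdiff(unique(labels), 0L))
    if (length(labs) < 2) break
    C <- stats::cor(t(MEs$eigengenes))
    d <- 1 - C
    if (min(d[upper.tri(d)]) >= cut_height) break
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    grp <- stats::cutree(hc, h = cut_height)
    sizes <- table(factor(labels, levels = labs))
    newlab <- labels
    for (g in unique(grp)) {
      members <- labs[grp == g]
      if (length(members) < 2) next
      keep <- members[which.max(sizes[as.character(members)])]
      history[[length(history) + 1L]] <- list(fused = members, into = keep)
      newlab[labels %in% members] <- keep
    }
    if (identical(newlab, labels)) break
    labels <- newlab
    MEs <- module_eigengenes(expr, .as_partition(labels, partition))
  }
  part <- .relabel_partition(labels, partition$min_size, history)
  list(partition = part, eigengenes = module_eigengenes(expr, part))
}

.as_partition <- function(labels, template) {
  structure(list(labels = labels, min_size = template$min_size,
                 merge_history = template$merge_history, colors = NULL),
            class = "module_partition")
}

# canonical module color sequence (largest module first); extended with
# module_N when exhausted
.module_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

#' Assign canonical color names to modules
#'
#' Modules sorted by decreasing size (ties: lexicographically smaller member
#' gene set first) receive names from the canonical color sequence
#' (turquoise, blue, brown, ...); unassigned genes are "grey". Since
#' [cut_dynamic()] and [merge_modules()] already number labels in this
#' canonical order, color assignment is a pure function of sizes and member
#' IDs.
#'
#' @param partition a `module_partition`.
#' @return The partition with `colors` filled in: a named character map from
#'   label (as character) to color, including `"0" = "grey"`.
#' @export
assign_colors <- function(partition) {
  labs <- sort(setdiff(unique(partition$labels), 0L))
  cols <- character(length(labs))
  if (length(labs) > length(.module_palette))
    cols <- c(.module_palette,
              paste0("module_", seq(length(.module_palette) + 1, length(labs))))
  else cols <- .module_palette[seq_along(labs)]
  partition$colors <- stats::setNames(c("grey", cols), c("0", as.character(labs)))
  partition
}

#' Per-gene module colors
#' @param partition a `module_partition` after [assign_colors()].
#' @return Named character vector, one color per gene.
#' @export
module_colors <- function(partition) {
  if (is.null(partition$colors)) partition <- assign_colors(partition)
  stats::setNames(unname(partition$colors[as.character(partition$labels)]),
                  names(partition$labels))
}

#' Module membership (kME)
#'
#' Signed correlation of each gene's expression profile with each module
#' eigengene. A gene's own-module kME measures how central it is to its
#' module.
#'
#' @param expr a complete [coex_expr].
#' @param MEs a [module_eigengenes()] object.
#' @return Genes x modules matrix of correlations.
#' @export
module_membership <- function(expr, MEs) {
  kme <- stats::cor(t(expr$values), t(MEs$eigengenes))
  colnames(kme) <- rownames(MEs$eigengenes)
  kme
}

#' Eigengene-based inter-module graph
#'
#' Edges connect module pairs whose eigengene correlation (absolute value)
#' reaches `edge_threshold`, weighted by that correlation.
#'
#' @param MEs a [module_eigengenes()] object with >= 2 modules.
#' @param edge_threshold minimum `|cor|` for an edge (default 0: complete
#'   weighted graph).
#' @return List of class `module_graph`: `edges` (data.frame `module1`,
#'   `module2`, `weight`), `degree` (named integer), `n_modules`.
#' @export
module_graph <- function(MEs, edge_threshold = 0) {
  E <- MEs$eigengenes
  if (nrow(E) < 2) stop("need at least 2 modules")
  C <- abs(stats::cor(t(E)))
  ids <- rownames(E)
  pairs <- which(upper.tri(C) & C >= edge_threshold, arr.ind = TRUE)
  edges <- data.frame(module1 = ids[pairs[, 1]], module2 = ids[pairs[, 2]],
                      weight = C[pairs], stringsAsFactors = FALSE)
  deg <- stats::setNames(integer(length(ids)), ids)
  for (m in ids) deg[m] <- sum(edges$module1 == m) + sum(edges$module2 == m)
  structure(list(edges = edges, degree = deg, n_modules = length(ids)),
            class = "module_graph")
}
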