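#' Intramodular connectivity table
#'
#' Per gene: `kTotal` (weighted degree over the whole network), `kWithin`
#' (sum of adjacency to genes of the same module; for unassigned genes this
#' is computed within the unassigned set and flagged), and optionally `kME`
#' (signed correlation with the own-module eigengene).
#'
#' @param network a `gene_network` from [build_network()].
#' @param partition a `module_partition` over the same genes.
#' @param kme optional genes x modules matrix from [module_membership()];
#'   when supplied, each gene's own-module column is extracted.
#' @return data.frame with columns `gene_id`, `module`, `kTotal`, `kWithin`,
#'   `kME` (NA when `kme` not given), `in_module` (FALSE for label 0).
#' @export
intramodular_connectivity <- function(network, partition, kme = NULL) {
  A <- network$adjacency
  genes <- network$gene_ids
  lab <- partition$labels[genes]
  ktotal <- connectivity(A)
  kwithin <- numeric(length(genes))
  names(kwithin) <- genes
  for (l in unique(lab)) {
    g <- genes[lab == l]
    B <- A[g, g, drop = FALSE]
    kwithin[g] <- rowSums(B) - diag(B)
  }
  kme_own <- rep(NA_real_, length(genes))
  if (!is.null(kme)) {
    for (i in seq_along(genes)) {
      l <- as.character(lab[i])
      if (lab[i] > 0 && l %in% colnames(kme))
        kme_own[i] <- kme[genes[i], l]
    }
  }
  data.frame(gene_id = genes, module = as.integer(lab),
             kTotal = unname(ktotal), kWithin = unname(kwithin),
             kME = kme_own, in_module = lab > 0,
             stringsAsFactors = FALSE)
}

#' Select the top hub gene of each module
#'
#' The hub is the gene maximizing intramodular connectivity (`kWithin`)
#' among module genes whose module membership exceeds `kme_min` (default
#' 0.8); ties break by higher `kTotal`, then by lexicographic gene ID. If no
#' gene of a module reaches `kme_min`, the plain `kWithin` maximum is taken
#' and flagged.
#'
#' @param conn connectivity table from [intramodular_connectivity()] (with
#'   `kME` filled in).
#' @param partition the matching `module_partition`.
#' @param kme_min minimum own-module kME for hub eligibility.
#' @return data.frame with one row per module: `module`, `hub`, `kWithin`,
#'   `kTotal`, `kME`, `kme_relaxed` (TRUE when the kME floor was waived).
#' @export
select_hub <- function(conn, partition, kme_min = 0.8) {
  labs <- sort(setdiff(unique(partition$labels), 0L))
  if (!length(labs)) stop("no labeled modules")
  rows <- lapply(labs, function(l) {
    sub <- conn[conn$module == l, , drop = FALSE]
    if (!nrow(sub)) stop("empty module ", l)
    eligible <- !is.na(sub$kME) & sub$kME > kme_min
    relaxed <- !any(eligible)
    if (relaxed) {
      warning("module ", l, ": no gene reaches kME > ", kme_min,
              "; taking argmax kWithin")
      eligible <- rep(TRUE, nrow(sub))
    }
    sub <- sub[eligible, , drop = FALSE]
    sub <- sub[order(-sub$kWithin, -sub$kTotal, sub$gene_id), , drop = FALSE]
    data.frame(module = l, hub = sub$gene_id[1], kWithin = sub$kWithin[1],
               kTotal = sub$kTotal[1], kME = sub$kME[1],
               kme_relaxed = relaxed, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Hypergeometric enrichment and depletion p-values
#'
#' Upper-tail (enrichment) and lower-tail (depletion) probabilities of the
#' observed overlap `k` between a set of size `K` and a draw of size `n`
#' from a universe of size `N`:
#' \deqn{p_{enrich} = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} /
#'   \binom{N}{n}}
#'
#' @param k observed overlap.
#' @param K set (module) size.
#' @param n draw (gene list) size.
#' @param N universe size.
#' @return List with `p_enrich` and `p_deplete`.
#' @export
hyper_test <- function(k, K, n, N) {
  if (k > min(K, n) || K > N || n > N) stop("inconsistent hypergeometric counts")
  list(p_enrich = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
       p_deplete = stats::phyper(k, K, N - K, n))
}

#' Associate modules with a trait gene list
#'
#' Tests each labeled module for over-representation of a gene list (e.g.
#' differentially expressed genes from a stress experiment) by the
#' hypergeometric distribution over the network's gene universe. List
#' members outside the universe are discarded (and reported). The
#' unassigned/grey set is excluded by default.
#'
#' @param partition a `module_partition`.
#' @param gene_list character vector of gene IDs (or a list with elements
#'   `label` and `genes`).
#' @param universe character vector of gene IDs; defaults to all genes of
#'   the partition.
#' @param alpha significance level on the enrichment p (default 0.05).
#' @param include_grey also test label 0 (default `FALSE`).
#' @return data.frame per module: `module`, `module_size`, `list_size`,
#'   `universe_size`, `overlap`, `p_enrich`, `p_deplete`, `significant`;
#'   attribute `"discarded"` holds list members outside the universe.
#' @export
module_set_association <- function(partition, gene_list,
                                   universe = names(partition$labels),
                                   alpha = 0.05, include_grey = FALSE) {
  if (is.list(gene_list) && !is.null(gene_list$genes))
    gene_list <- gene_list$genes
  if (!length(universe)) stop("empty universe")
  discarded <- setdiff(gene_list, universe)
  gene_list <- intersect(gene_list, universe)
  if (!length(gene_list)) stop("gene list empty after universe intersection")
  N <- length(universe)
  n <- length(gene_list)
  labs <- sort(setdiff(unique(partition$labels), if (include_grey) NULL else 0L))
  rows <- lapply(labs, function(l) {
    members <- intersect(names(partition$labels)[partition$labels == l],
                         universe)
    k <- length(intersect(members, gene_list))
    p <- hyper_test(k, length(members), n, N)
    data.frame(module = l, module_size = length(members), list_size = n,
               universe_size = N, overlap = k, p_enrich = p$p_enrich,
               p_deplete = p$p_deplete,
               significant = p$p_enrich <= alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "discarded") <- discarded
  out
}

#' Two-sided hypergeometric term enrichment
#'
#' Tests each annotation term for over- and under-representation in a gene
#' set relative to the universe's term frequencies, with optional
#' Benjamini-Hochberg adjustment of the enrichment p-values. Terms
#' annotating no universe gene are skipped (with a message).
#'
#' @param gene_set character vector of gene IDs.
#' @param annotation_map data.frame with columns `gene_id`, `term_id` (and
#'   optionally `term_name`), one row per gene/term pair.
#' @param universe character vector of gene IDs.
#' @param alpha significance level.
#' @param correction `"none"` (raw p, mirroring common practice) or `"BH"`;
#'   the adjusted column is always reported.
#' @return data.frame per term: `term_id`, `term_name`, `term_size`,
#'   `overlap`, `set_size`, `p_enrich`, `p_deplete`, `p_adj_BH`,
#'   `significant` (on the column `correction` selects), sorted by
#'   `p_enrich` then term ID.
#' @export
term_enrichment <- function(gene_set, annotation_map, universe,
                            alpha = 0.05, correction = c("none", "BH")) {
  correction <- match.arg(correction)
  if (!all(c("gene_id", "term_id") %in% names(annotation_map)))
    stop("annotation_map needs columns gene_id and term_id")
  ann <- annotation_map[annotation_map$gene_id %in% universe, , drop = FALSE]
  gene_set <- intersect(gene_set, universe)
  if (!any(ann$gene_id %in% gene_set))
    stop("annotation map covers no gene of the set")
  skipped <- setdiff(unique(annotation_map$term_id), unique(ann$term_id))
  if (length(skipped))
    message("skipping term(s) with no universe gene: ",
            paste(skipped, collapse = ", "))
  N <- length(universe)
  n <- length(gene_set)
  terms <- sort(unique(ann$term_id))
  rows <- lapply(terms, function(tm) {
    tg <- unique(ann$gene_id[ann$term_id == tm])
    k <- length(intersect(tg, gene_set))
    p <- hyper_test(k, length(tg), n, N)
    nm <- if ("term_name" %in% names(ann))
      ann$term_name[ann$term_id == tm][1] else NA_character_
    data.frame(term_id = tm, term_name = nm, term_size = length(tg),
               overlap = k, set_size = n, p_enrich = p$p_enrich,
               p_deplete = p$p_deplete, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj_BH <- stats::p.adjust(out$p_enrich, method = "BH")
  pcol <- if (correction == "BH") out$p_adj_BH else out$p_enrich
  out$significant <- pcol <= alpha
  out[order(out$p_enrich, out$term_id), , drop = FALSE]
}

#' Rank transcription factors by correlation with module hubs
#'
#' Each TF's expression profile is scored by its biweight midcorrelation
#' with the hub gene of a module: by default the TF's host module, or a
#' fixed module of interest via `against_module`. TFs are ranked within each
#' module by descending absolute score and assigned a strength category:
#' high (`|score| >= 0.8`), moderate (`0.5 <= |score| < 0.8`), low
#' (`< 0.5`).
#'
#' @param expr a complete [coex_expr].
#' @param tf_ids character vector of TF gene IDs.
#' @param partition a `module_partition`.
#' @param hubs hub table from [select_hub()].
#' @param against_module optional single module label: rank all TFs against
#'   that module's hub instead of their host modules.
#' @return List with `ranking` (data.frame `tf`, `module`, `hub`, `score`,
#'   `rank`, `category`) and `unmapped` (TFs absent from the matrix or
#'   without a hubbed module).
#' @export
rank_tfs <- function(expr, tf_ids, partition, hubs, against_module = NULL) {
  genes <- rownames(expr$values)
  unmapped <- setdiff(tf_ids, genes)
  tf_ids <- intersect(tf_ids, genes)
  if (is.null(against_module)) {
    mod <- partition$labels[tf_ids]
    keep <- mod %in% hubs$module
    unmapped <- c(unmapped, tf_ids[!keep])
    tf_ids <- tf_ids[keep]
    mod <- mod[keep]
  } else {
    if (!against_module %in% hubs$module)
      stop("no hub for module ", against_module)
    mod <- rep(as.integer(against_module), length(tf_ids))
  }
  if (!length(tf_ids))
    return(list(ranking = data.frame(), unmapped = unmapped))
  score <- vapply(seq_along(tf_ids), function(i) {
    hub <- hubs$hub[hubs$module == mod[i]]
    as.numeric(bicor(expr$values[tf_ids[i], ], expr$values[hub, ]))
  }, numeric(1))
  rk <- data.frame(tf = tf_ids, module = as.integer(mod),
                   hub = hubs$hub[match(mod, hubs$module)], score = score,
                   stringsAsFactors = FALSE)
  rk <- rk[order(rk$module, -abs(rk$score), rk$tf), , drop = FALSE]
  # rows are already sorted by (module, -|score|, tf): rank = position,
  # ties resolved deterministically by TF ID
  rk$rank <- stats::ave(seq_len(nrow(rk)), rk$module, FUN = seq_along)
  rk$category <- cut(abs(rk$score), c(-Inf, 0.5, 0.8, Inf),
                     labels = c("low", "moderate", "high"), right = FALSE)
  rownames(rk) <- NULL
  list(ranking = rk, unmapped = unmapped)
}

#' Topological first neighbors of a gene
#'
#' All genes whose topological overlap with `gene` exceeds `tom_min`,
#' excluding the gene itself; optionally restricted to the gene's own
#' module.
#'
#' @param gene gene ID.
#' @param network a `gene_network`.
#' @param tom_min TOM threshold (default 0.01).
#' @param partition optional `module_partition`; when given, neighbors are
#'   restricted to `gene`'s module.
#' @return Character vector of neighbor gene IDs.
#' @export
first_neighbors <- function(gene, network, tom_min = 0.01, partition = NULL) {
  if (!gene %in% network$gene_ids) stop("unknown gene: ", gene)
  tomrow <- network$tom[gene, ]
  nb <- names(tomrow)[tomrow > tom_min]
  nb <- setdiff(nb, gene)
  if (!is.null(partition))
    nb <- nb[partition$labels[nb] == partition$labels[gene]]
  nb
}

#' Guilt-by-association annotation of a (hypothetical) hub gene
#'
#' Collects the hub's close topological neighbors (TOM above `tom_min`),
#' runs [term_enrichment()] on them, and assigns the significant term with
#' the smallest enrichment p as the hub's predicted function. Ties break by
#' lexicographic term ID (and are flagged); an empty neighborhood or no
#' significant term yields `"unassigned"`.
#'
#' @param hub hub gene ID.
#' @param network a `gene_network`.
#' @param annotation_map as in [term_enrichment()].
#' @param universe gene universe for the enrichment test.
#' @param tom_min neighbor threshold (default 0.01).
#' @param alpha significance level (default 0.05).
#' @return List of class `hub_annotation`: `hub`, `neighbors`, `enrichment`
#'   (full table or `NULL`), `top_term` (term ID or `"unassigned"`),
#'   `tie` flag.
#' @export
annotate_hypothetical_hub <- function(hub, network, annotation_map, universe,
                                      tom_min = 0.01, alpha = 0.05) {
  nb <- first_neighbors(hub, network, tom_min)
  if (!length(nb)) {
    warning("empty neighborhood for hub ", hub, "; unassigned")
    return(structure(list(hub = hub, neighbors = character(0),
                          enrichment = NULL, top_term = "unassigned",
                          tie = FALSE), class = "hub_annotation"))
  }
  if (!any(annotation_map$gene_id %in% intersect(nb, universe))) {
    warning("no annotated gene among the neighbors of hub ", hub,
            "; unassigned")
    return(structure(list(hub = hub, neighbors = nb, enrichment = NULL,
                          top_term = "unassigned", tie = FALSE),
                     class = "hub_annotation"))
  }
  enr <- term_enrichment(nb, annotation_map, universe, alpha)
  sig <- enr[enr$p_enrich <= alpha, , drop = FALSE]
  if (!nrow(sig)) {
    top <- "unassigned"; tie <- FALSE
  } else {
    best <- sig[sig$p_enrich == min(sig$p_enrich), , drop = FALSE]
    tie <- nrow(best) > 1
    if (tie) message("tie on top term for hub ", hub, "; lexicographic break")
    top <- sort(best$term_id)[1]
  }
  structure(list(hub = hub, neighbors = nb, enrichment = enr,
                 top_term = top, tie = tie), class = "hub_annotation")
}
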