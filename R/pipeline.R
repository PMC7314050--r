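# TSV conventions: UTF-8, tab-separated, header row, no quoting, no rownames
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain gene-list file
#'
#' One gene ID per line; an optional second tab-separated column carries a
#' direction tag (e.g. `up`/`down`).
#'
#' @param path file path.
#' @param label list label (defaults to the file name).
#' @return List with `label`, `genes`, `direction` (or `NULL`).
#' @export
read_gene_list <- function(path, label = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  f <- strsplit(lines, "\t", fixed = TRUE)
  genes <- vapply(f, `[`, character(1), 1)
  if (anyDuplicated(genes)) stop("duplicate IDs in gene list ", path)
  dir <- vapply(f, function(x) if (length(x) > 1) x[2] else NA_character_,
                character(1))
  list(label = label, genes = genes,
       direction = if (all(is.na(dir))) NULL else dir)
}

#' Read a gene-to-term annotation map
#'
#' Tab-separated, one row per gene/term pair:
#' `gene_id<TAB>term_id[<TAB>term_name]`, no header.
#'
#' @param path file path.
#' @return data.frame with columns `gene_id`, `term_id`, `term_name`.
#' @export
read_annotation_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("annotation map needs >= 2 tab-separated columns")
  names(df)[1:2] <- c("gene_id", "term_id")
  df$term_name <- if (ncol(df) >= 3) ifelse(nzchar(df[[3]]), df[[3]],
                                            df$term_id) else df$term_id
  df[, c("gene_id", "term_id", "term_name")]
}

#' Export the network around modules in Cytoscape edge/node format
#'
#' Writes the standard Cytoscape import dialect: an edge file with columns
#' `fromNode`, `toNode`, `weight` (the TOM), `direction` (`"undirected"`),
#' `fromAltName`, `toAltName`, one row per unordered gene pair with TOM at
#' least `weight_min`; and a node file with `nodeName`, `altName`,
#' `moduleColor`.
#'
#' @param network a `gene_network`.
#' @param partition a `module_partition` (colored via [assign_colors()] if
#'   not already).
#' @param weight_min TOM threshold in `[0, 1)`.
#' @param edge_file,node_file output paths.
#' @param annotation_map optional data.frame with `gene_id` and `term_name`
#'   (or `alt_name`) used for the alt-name columns; `"NA"` otherwise.
#' @return Invisibly, a list with the edge and node data.frames.
#' @export
export_cytoscape_edges <- function(network, partition, weight_min,
                                   edge_file, node_file,
                                   annotation_map = NULL) {
  if (weight_min < 0 || weight_min >= 1) stop("'weight_min' must be in [0, 1)")
  genes <- network$gene_ids
  alt <- stats::setNames(rep("NA", length(genes)), genes)
  if (!is.null(annotation_map)) {
    cn <- if ("alt_name" %in% names(annotation_map)) "alt_name" else "term_name"
    hit <- match(genes, annotation_map$gene_id)
    alt[!is.na(hit)] <- annotation_map[[cn]][hit[!is.na(hit)]]
  }
  TOM <- network$tom
  sel <- which(upper.tri(TOM) & TOM >= weight_min, arr.ind = TRUE)
  edges <- data.frame(fromNode = genes[sel[, 1]], toNode = genes[sel[, 2]],
                      weight = TOM[sel], direction = "undirected",
                      fromAltName = unname(alt[genes[sel[, 1]]]),
                      toAltName = unname(alt[genes[sel[, 2]]]),
                      stringsAsFactors = FALSE)
  cols <- module_colors(partition)[genes]
  nodes <- data.frame(nodeName = genes, altName = unname(alt[genes]),
                      moduleColor = unname(cols), stringsAsFactors = FALSE)
  # full precision so a re-import reconstructs thresholded TOM entries exactly
  edges_out <- edges
  edges_out$weight <- sprintf("%.17g", edges$weight)
  .write_tsv(edges_out, edge_file)
  .write_tsv(nodes, node_file)
  invisible(list(edges = edges, nodes = nodes))
}

#' Export the inter-module eigengene graph as GraphML
#'
#' @param graph a [module_graph()] object.
#' @param path output GraphML path.
#' @param partition optional colored `module_partition` to translate labels
#'   into color names.
#' @return `path`, invisibly.
#' @export
export_module_graphml <- function(graph, path, partition = NULL) {
  ids <- names(graph$degree)
  name <- ids
  if (!is.null(partition) && !is.null(partition$colors))
    name <- unname(partition$colors[ids])
  g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  igraph::V(g)$color_name <- name[match(igraph::V(g)$name, ids)]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Default pipeline configuration
#'
#' Resolved settings for [run_pipeline()]. Defaults follow the package's
#' standard analysis: bicor similarity, soft-threshold grid 1..20 at fit
#' target 0.9, minimum module size 20, deep split 2, eigengene merge height
#' 0.2, half-sample stability at threshold 0.7, hub kME floor 0.8, TOM
#' neighbor floor 0.01, alpha 0.05.
#'
#' @param ... overrides of any default.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(method = "bicor", beta = NULL, beta_grid = 1:20,
              r2_target = 0.9, n_bins = 10, min_module_size = 20,
              deep_split = 2, pam_stage = TRUE, max_cut_height = 0.99,
              merge_height = 0.2, stability = TRUE,
              stability_resamples = 200, stability_fraction = 0.5,
              stability_threshold = 0.7, kme_min = 0.8, tom_min = 0.01,
              alpha = 0.05, max_missing_frac = 0.5, seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the full co-expression analysis pipeline
#'
#' Executes qc filter, similarity, soft-threshold selection, TOM,
#' clustering, dynamic cut, eigengenes, merging, color naming, connectivity
#' and hubs, optional stability resampling, and optional gene-list
#' association / TF ranking / hypothetical-hub annotation. When `out_dir`
#' is given, every intermediate table, the resolved configuration and a JSON
#' run summary are written there.
#'
#' @param expr a [coex_expr] (may contain missing values; qc is applied).
#' @param config a [pipeline_config()].
#' @param gene_lists optional list of gene lists (as from
#'   [read_gene_list()] or [generate_trait_lists()]).
#' @param tf_ids optional character vector of TF gene IDs.
#' @param annotation_map optional annotation data.frame (see
#'   [term_enrichment()]).
#' @param out_dir optional output directory.
#' @return List of class `pipeline_result` with elements `expr`, `network`,
#'   `dendrogram`, `partition_premerge`, `partition`, `eigengenes`, `kme`,
#'   `connectivity`, `hubs`, `stability`, `associations`, `tf_ranking`,
#'   `hub_annotations`, `summary`, `config`.
#' @export
run_pipeline <- function(expr, config = pipeline_config(), gene_lists = NULL,
                         tf_ids = NULL, annotation_map = NULL,
                         out_dir = NULL) {
  log_msg <- function(...) message("[coexmod] ", sprintf(...))
  log_msg("qc filter: %d genes x %d samples in", nrow(expr$values),
          ncol(expr$values))
  expr <- qc_filter(expr, config$max_missing_frac)
  log_msg("network build (%s): %d genes retained", config$method,
          nrow(expr$values))
  net <- build_network(expr, method = config$method, beta = config$beta,
                       beta_grid = config$beta_grid,
                       r2_target = config$r2_target, n_bins = config$n_bins)
  if (net$beta_warning)
    log_msg("warning: no beta reached fit target; using argmax beta = %d",
            net$beta)
  dend <- cluster_genes(net$dissimilarity)
  part0 <- cut_dynamic(dend, net$dissimilarity,
                       min_cluster_size = config$min_module_size,
                       deep_split = config$deep_split,
                       pam_stage = config$pam_stage,
                       max_cut_height = config$max_cut_height)
  n_pre <- length(setdiff(unique(part0$labels), 0L))
  log_msg("dynamic cut: %d pre-merge modules", n_pre)
  me0 <- module_eigengenes(expr, part0)
  merged <- merge_modules(expr, part0, me0, cut_height = config$merge_height)
  part <- assign_colors(merged$partition)
  mes <- merged$eigengenes
  n_post <- length(setdiff(unique(part$labels), 0L))
  log_msg("merge at height %.2f: %d modules", config$merge_height, n_post)
  kme <- module_membership(expr, mes)
  conn <- intramodular_connectivity(net, part, kme)
  hubs <- select_hub(conn, part, config$kme_min)
  stab <- NULL
  if (isTRUE(config$stability)) {
    log_msg("stability: %d resamples at fraction %.2f",
            config$stability_resamples, config$stability_fraction)
    stab <- resample_connectivity_stability(
      expr, part, net$beta, n_resamples = config$stability_resamples,
      fraction = config$stability_fraction,
      threshold = config$stability_threshold, seed = config$seed,
      method = config$method)
  }
  assoc <- NULL
  if (!is.null(gene_lists)) {
    if (!is.null(gene_lists$genes)) gene_lists <- list(gene_lists)
    assoc <- do.call(rbind, lapply(gene_lists, function(gl) {
      a <- module_set_association(part, gl, alpha = config$alpha)
      a$list_label <- if (is.list(gl)) gl$label else "list"
      a
    }))
  }
  tfr <- NULL
  if (!is.null(tf_ids)) tfr <- rank_tfs(expr, tf_ids, part, hubs)
  hub_ann <- NULL
  if (!is.null(annotation_map)) {
    hub_ann <- lapply(hubs$hub, annotate_hypothetical_hub, network = net,
                      annotation_map = annotation_map,
                      universe = rownames(expr$values),
                      tom_min = config$tom_min, alpha = config$alpha)
    names(hub_ann) <- hubs$hub
  }
  sizes <- module_sizes(part)
  summary <- list(
    n_genes = nrow(expr$values), n_samples = ncol(expr$values),
    beta = net$beta, beta_warning = net$beta_warning,
    n_modules_premerge = n_pre, n_modules_postmerge = n_post,
    module_sizes = as.list(stats::setNames(as.integer(sizes),
      unname(part$colors[names(sizes)]))),
    n_unassigned = sum(part$labels == 0),
    stable_modules = if (!is.null(stab)) sum(stab$report$stable) else NA,
    seed = config$seed)
  res <- structure(list(expr = expr, network = net, dendrogram = dend,
                        partition_premerge = part0, partition = part,
                        eigengenes = mes, kme = kme, connectivity = conn,
                        hubs = hubs, stability = stab, associations = assoc,
                        tf_ranking = tfr, hub_annotations = hub_ann,
                        summary = summary, config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  part <- res$partition
  .write_tsv(data.frame(gene_id = names(part$labels),
                        label = unname(part$labels),
                        color = unname(module_colors(part))), p("modules.tsv"))
  E <- res$eigengenes$eigengenes
  .write_tsv(data.frame(module = rownames(E), E, check.names = FALSE),
             p("eigengenes.tsv"))
  .write_tsv(res$connectivity, p("connectivity.tsv"))
  .write_tsv(res$hubs, p("hubs.tsv"))
  if (!is.null(res$network$scan)) .write_tsv(res$network$scan, p("beta_scan.tsv"))
  if (!is.null(res$stability)) {
    rep <- res$stability$report
    rep$color <- unname(part$colors[as.character(rep$module)])
    .write_tsv(rep, p("stability.tsv"))
  }
  if (!is.null(res$associations)) .write_tsv(res$associations,
                                             p("associations.tsv"))
  if (!is.null(res$tf_ranking) && nrow(res$tf_ranking$ranking))
    .write_tsv(res$tf_ranking$ranking, p("tf_ranking.tsv"))
  if (!is.null(res$hub_annotations)) {
    ann <- do.call(rbind, lapply(res$hub_annotations, function(a)
      data.frame(hub = a$hub, n_neighbors = length(a$neighbors),
                 top_term = a$top_term, stringsAsFactors = FALSE)))
    .write_tsv(ann, p("hub_annotations.tsv"))
  }
  if (nrow(E) >= 2)
    .write_tsv(module_graph(res$eigengenes)$edges, p("module_graph.tsv"))
  jsonlite::write_json(res$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  cfg <- res$config
  cfg$beta_grid <- paste(range(cfg$beta_grid), collapse = ":")
  jsonlite::write_json(unclass(cfg), p("config.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("pipeline_result: %d genes x %d samples, beta = %d, %d -> %d modules (%d genes unassigned)\n",
              s$n_genes, s$n_samples, s$beta, s$n_modules_premerge,
              s$n_modules_postmerge, s$n_unassigned))
  invisible(x)
}
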