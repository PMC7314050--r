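toy_network <- function(A, genes = sprintf("g%02d", seq_len(nrow(A)))) {
  dimnames(A) <- list(genes, genes)
  TOM <- topological_overlap(A)
  structure(list(gene_ids = genes, adjacency = A, tom = TOM,
                 dissimilarity = 1 - TOM, beta = 1, method = "bicor"),
            class = "gene_network")
}

test_that("intramodular connectivity follows its definition", {
  # 3-gene module with adjacencies 0.5 and 0.25 to the partners
  A <- diag(1, 4)
  A[1, 2] <- A[2, 1] <- 0.5
  A[1, 3] <- A[3, 1] <- 0.25
  A[2, 3] <- A[3, 2] <- 0.1
  A[1, 4] <- A[4, 1] <- 0.9
  net <- toy_network(A)
  part <- truth_partition(list(labels = setNames(c(1L, 1L, 1L, 0L),
                                                 net$gene_ids)))
  conn <- intramodular_connectivity(net, part)
  expect_equal(conn$kWithin[conn$gene_id == "g01"], 0.75)
  expect_equal(conn$kTotal[conn$gene_id == "g01"], 0.5 + 0.25 + 0.9)
  # the grey gene's kWithin is computed within the grey set and flagged
  expect_false(conn$in_module[conn$gene_id == "g04"])
  expect_equal(conn$kWithin[conn$gene_id == "g04"], 0)
  # random 30-gene network equals the double-loop oracle
  S <- random_similarity(30, 71)
  A30 <- adjacency_matrix(S, 6)
  net30 <- toy_network(A30, rownames(S))
  lab <- setNames(rep(1:3, each = 10), rownames(S))
  conn30 <- intramodular_connectivity(net30, truth_partition(list(labels = lab)))
  orc <- naive_connectivity(A30, lab)
  expect_equal(conn30$kTotal, orc$kTotal, tolerance = 1e-12)
  expect_equal(conn30$kWithin, orc$kWithin, tolerance = 1e-12)
  expect_true(all(conn30$kWithin <= conn30$kTotal + 1e-12))
})

test_that("hub selection maximizes kWithin under the kME floor with clean ties", {
  conn <- data.frame(
    gene_id = c("g2", "g1", "g3", "g4"),
    module = c(1L, 1L, 1L, 1L),
    kTotal = c(5, 5, 4, 6),
    kWithin = c(3, 3, 2.5, 2.9),
    kME = c(0.9, 0.9, 0.85, 0.7),
    stringsAsFactors = FALSE)
  part <- truth_partition(list(labels = setNames(rep(1L, 4), conn$gene_id)))
  hub <- select_hub(conn, part)
  expect_identical(hub$hub, "g1")  # tie on kWithin and kTotal: lexicographic
  # input order invariance
  hub2 <- select_hub(conn[c(3, 1, 4, 2), ], part)
  expect_identical(hub2$hub, "g1")
  # no gene reaches the floor: argmax kWithin with a warning
  conn$kME <- 0.5
  expect_warning(hub3 <- select_hub(conn, part), "kME")
  expect_identical(hub3$hub, "g1")
  expect_true(hub3$kme_relaxed)
})

test_that("planted hubs are selected from generated data", {
  hits <- 0L; total <- 0L
  for (seed in 1:10) {
    d <- generate_dataset(n_modules = 2, module_sizes = c(30, 30),
                          n_background = 20, n_samples = 60, seed = 100 + seed)
    net <- build_network(d$expr, beta = 6)
    part <- truth_partition(d$truth)
    kme <- module_membership(d$expr, module_eigengenes(d$expr, part))
    conn <- intramodular_connectivity(net, part, kme)
    hubs <- select_hub(conn, part)
    hits <- hits + sum(hubs$hub == d$truth$hubs[as.character(hubs$module)])
    total <- total + nrow(hubs)
  }
  expect_gte(hits / total, 0.95)
})

test_that("hypergeometric tail probabilities are combinatorially exact", {
  # closed-form corner: full overlap of a 5-set in a 10-universe draw of 5
  p <- hyper_test(5, 5, 5, 10)
  expect_equal(p$p_enrich, 1 / 252, tolerance = 1e-14)
  # k = 0 spans the whole support
  expect_equal(hyper_test(0, 5, 5, 10)$p_enrich, 1, tolerance = 1e-14)
  # random instances vs the choose()-sum oracle (N <= 25)
  set.seed(72)
  for (i in 1:20) {
    N <- sample(8:25, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    k <- sample(0:min(K, n), 1)
    p <- hyper_test(k, K, n, N)
    expect_equal(p$p_enrich, hyper_choose_sum(k, K, n, N), tolerance = 1e-12)
    # two-sided consistency: tails overlap in exactly P(X = k)
    expect_gte(p$p_enrich + p$p_deplete + 1e-12,
               1 + dhyper(k, K, N - K, n))
  }
  # exhaustive enumeration over all draws for tiny universes
  for (i in 1:8) {
    N <- sample(6:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hyper_test(k, K, n, N)$p_enrich,
                 hyper_enumerate(k, K, n, N), tolerance = 1e-12)
  }
  expect_error(hyper_test(6, 5, 5, 10), "inconsistent")
})

test_that("module-list association flags planted enrichment and reports discards", {
  d <- generate_dataset(n_modules = 3, module_sizes = rep(40, 3),
                        n_background = 180, seed = 73)
  part <- truth_partition(d$truth)
  gl <- generate_trait_lists(d$truth, list_size = 30, target_module = 2,
                             overlap_count = 20, seed = 74)
  res <- module_set_association(part, gl)
  expect_true(res$significant[res$module == 2])
  expect_false(any(res$significant[res$module != 2]))
  expect_identical(res$overlap[res$module == 2], 20L)
  # members outside the universe are discarded and reported
  res2 <- module_set_association(part, c(gl$genes, "NOT_A_GENE"))
  expect_identical(attr(res2, "discarded"), "NOT_A_GENE")
  expect_error(module_set_association(part, "NOT_A_GENE"), "empty")
})

test_that("association p-values are super-uniform under the null", {
  labs <- setNames(c(rep(1L, 50), rep(0L, 250)), sprintf("g%03d", 1:300))
  part <- truth_partition(list(labels = labs))
  set.seed(75)
  hits <- 0L
  for (r in 1:400) {
    gl <- sample(names(labs), 40)
    hits <- hits + module_set_association(part, gl)$significant[1]
  }
  expect_lte(hits / 400, 0.05 + 2.576 * sqrt(0.05 * 0.95 / 400))
})

test_that("term enrichment ranks a planted over-represented term first", {
  set.seed(76)
  universe <- sprintf("g%03d", 1:500)
  terms <- sprintf("T%02d", 1:20)
  ann <- data.frame(
    gene_id = sample(universe, 1500, replace = TRUE),
    term_id = sample(terms, 1500, replace = TRUE), stringsAsFactors = FALSE)
  ann <- unique(ann)
  # the test set carries term T01 at ~5x its universe frequency
  t1 <- unique(ann$gene_id[ann$term_id == "T01"])
  gene_set <- unique(c(sample(t1, min(25, length(t1))), sample(universe, 25)))
  enr <- term_enrichment(gene_set, ann, universe)
  expect_identical(enr$term_id[1], "T01")
  expect_true(enr$significant[1])
  expect_true(all(diff(enr$p_enrich) >= 0))
  expect_true(all(enr$p_adj_BH >= enr$p_enrich))
  # extreme overlap: exactly the carriers of a term reach its minimal p
  ann2 <- data.frame(gene_id = sprintf("g%03d", 1:30),
                     term_id = rep(c("TA", "TB"), each = 15),
                     stringsAsFactors = FALSE)
  uni2 <- sprintf("g%03d", 1:30)
  enr2 <- term_enrichment(sprintf("g%03d", 1:15), ann2, uni2)
  expect_equal(enr2$p_enrich[enr2$term_id == "TA"],
               hyper_choose_sum(15, 15, 15, 30), tolerance = 1e-12)
  expect_equal(enr2$p_enrich[enr2$term_id == "TB"], 1, tolerance = 1e-12)
  # terms annotating no universe gene are skipped with a message
  ann3 <- rbind(ann2, data.frame(gene_id = "zzz", term_id = "TC"))
  expect_message(term_enrichment(sprintf("g%03d", 1:15), ann3, uni2), "TC")
})

test_that("TF ranking scores, orders and categorizes against module hubs", {
  d <- generate_dataset(n_modules = 2, module_sizes = c(30, 30),
                        n_background = 30, n_samples = 60, seed = 77)
  part <- truth_partition(d$truth)
  kme <- module_membership(d$expr, module_eigengenes(d$expr, part))
  net <- build_network(d$expr, beta = 6)
  conn <- intramodular_connectivity(net, part, kme)
  hubs <- select_hub(conn, part)
  # a TF identical to the hub scores exactly 1 and ranks first
  tfr0 <- rank_tfs(d$expr, hubs$hub[1], part, hubs)
  expect_equal(tfr0$ranking$score[1], 1, tolerance = 1e-12)
  expect_identical(tfr0$ranking$rank[1], 1L)
  # planted regulator vs 5 independent-noise decoys, ranked against module 1
  tfs <- c(d$truth$tfs$tf[1], d$truth$decoy_tfs)
  tfr <- rank_tfs(d$expr, tfs, part, hubs, against_module = 1)
  expect_identical(tfr$ranking$tf[tfr$ranking$rank == 1], d$truth$tfs$tf[1])
  # an unknown TF is reported unmapped, not ranked
  tfr2 <- rank_tfs(d$expr, c("NOPE", hubs$hub[1]), part, hubs)
  expect_identical(tfr2$unmapped, "NOPE")
})

test_that("TF strength categories split high from moderate correlations", {
  # profiles constructed at fixed sample correlations with a hub profile
  set.seed(78)
  n <- 61
  hub <- rnorm(n)
  u <- as.vector(scale(hub))
  make_tf <- function(rho) {
    r <- as.vector(scale(residuals(lm(rnorm(n) ~ u))))
    rho * u + sqrt(1 - rho^2) * r
  }
  rhos <- c(0.95, 0.9, 0.85, 0.65, 0.6, 0.55)
  X <- rbind(HUB = hub, t(sapply(rhos, make_tf)))
  rownames(X) <- c("HUB", sprintf("TF%d", 1:6))
  colnames(X) <- paste0("s", seq_len(n))
  e <- coex_expr(X)
  part <- truth_partition(list(labels = setNames(rep(1L, 7), rownames(X))))
  hubs <- data.frame(module = 1L, hub = "HUB", stringsAsFactors = FALSE)
  tfr <- rank_tfs(e, sprintf("TF%d", 1:6), part, hubs)
  cats <- setNames(as.character(tfr$ranking$category), tfr$ranking$tf)
  expect_identical(sum(cats == "high"), 3L)
  expect_identical(sum(cats == "moderate"), 3L)
  expect_identical(unname(cats[c("TF1", "TF2", "TF3")]), rep("high", 3))
})

test_that("first neighbors obey thresholds, oracles and module restriction", {
  A <- matrix(0.8, 5, 5); diag(A) <- 1
  net <- toy_network(A)
  expect_length(first_neighbors("g01", net, tom_min = 0), 4)
  expect_error(first_neighbors("nope", net), "unknown gene")
  # linear-scan oracle on a random network
  S <- random_similarity(15, 79)
  net2 <- toy_network(adjacency_matrix(S, 4), rownames(S))
  for (thr in c(0.01, 0.1, 0.3)) {
    nb <- first_neighbors("g05", net2, thr)
    manual <- character(0)
    for (g in net2$gene_ids)
      if (g != "g05" && net2$tom["g05", g] > thr) manual <- c(manual, g)
    expect_setequal(nb, manual)
  }
  # restriction to the own module never adds neighbors
  lab <- setNames(rep(1:3, each = 5), net2$gene_ids)
  part <- truth_partition(list(labels = lab))
  expect_true(all(first_neighbors("g05", net2, 0.01, part) %in%
                  first_neighbors("g05", net2, 0.01)))
})

test_that("guilt-by-association annotates hubs from their TOM neighborhood", {
  d <- generate_dataset(n_modules = 2, module_sizes = c(30, 30),
                        n_background = 40, n_samples = 60, seed = 80)
  net <- build_network(d$expr, beta = 6)
  universe <- rownames(d$expr$values)
  # every module-1 gene carries term T_mod1; the rest carry scattered terms
  set.seed(81)
  m1 <- names(d$truth$labels)[d$truth$labels == 1]
  ann <- rbind(
    data.frame(gene_id = m1, term_id = "T_mod1", stringsAsFactors = FALSE),
    data.frame(gene_id = sample(universe, 60, replace = TRUE),
               term_id = sample(c("T_a", "T_b", "T_c"), 60, replace = TRUE)))
  ann <- unique(ann)
  hub <- d$truth$hubs[["1"]]
  res <- annotate_hypothetical_hub(hub, net, ann, universe, tom_min = 0.05)
  expect_identical(res$top_term, "T_mod1")
  expect_false(hub %in% res$neighbors)
  # an impossible threshold empties the neighborhood: unassigned
  expect_warning(
    res2 <- annotate_hypothetical_hub(hub, net, ann, universe, tom_min = 1),
    "empty neighborhood")
  expect_identical(res2$top_term, "unassigned")
  # exact tie between two terms breaks lexicographically and is logged:
  # g01's only close neighbors are g02..g05, split evenly across two terms
  # of equal universe frequency
  A <- matrix(0.001, 20, 20); diag(A) <- 1
  A[1, 2:5] <- A[2:5, 1] <- 0.9
  net3 <- toy_network(A)
  ann3 <- data.frame(gene_id = c("g02", "g03", "g04", "g05"),
                     term_id = c("TB", "TB", "TA", "TA"),
                     stringsAsFactors = FALSE)
  expect_message(
    res3 <- annotate_hypothetical_hub("g01", net3, ann3, net3$gene_ids,
                                      tom_min = 0.2),
    "tie")
  expect_identical(res3$top_term, "TA")
})
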