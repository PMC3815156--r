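test_that("candidate-set Venn regions equal brute-force set algebra", {
  fs <- assemble_candidate_genes(c("a", "b", "c"), c("d", "e"), "f")
  expect_equal(length(fs$union), 6)
  expect_true(all(fs$venn[c("de_as", "de_snv", "as_snv", "de_as_snv")] == 0))

  set.seed(51)
  for (r in 1:10) {
    pool <- sprintf("G%03d", 1:60)
    de <- sample(pool, 25); as_ <- sample(pool, 15); snv <- sample(pool, 20)
    fs <- assemble_candidate_genes(de, as_, snv)
    expect_equal(sum(fs$venn), length(fs$union))
    expect_equal(unname(fs$venn["de_as_snv"]),
                 length(Reduce(intersect, list(toupper(de), toupper(as_),
                                               toupper(snv)))))
    expect_equal(unname(fs$venn["de_only"]),
                 length(setdiff(toupper(de), union(toupper(as_),
                                                   toupper(snv)))))
  }
  expect_error(assemble_candidate_genes(character(0), character(0),
                                        character(0)), "empty")
})

test_that("induced network excludes linkers and isolated candidates", {
  edges <- data.frame(from = c("A", "A"), to = c("B", "X"),
                      stringsAsFactors = FALSE)
  m <- induced_network(c("A", "B", "C"), edges)
  expect_equal(m$n_nodes, 2)                  # C isolated, X a linker
  expect_equal(m$n_edges, 1)
  expect_setequal(igraph::V(m$graph)$name, c("A", "B"))

  m0 <- induced_network(c("P", "Q"), edges)
  expect_equal(m0$n_nodes, 0)
})

test_that("induced network equals brute-force subgraph computation", {
  set.seed(52)
  genes <- sprintf("N%02d", 1:30)
  edges <- t(combn(genes, 2))
  edges <- as.data.frame(edges[runif(nrow(edges)) < 0.15, ],
                         stringsAsFactors = FALSE)
  names(edges) <- c("from", "to")
  for (r in 1:10) {
    cand <- sample(genes, 12)
    m <- induced_network(cand, edges)
    inside <- edges$from %in% cand & edges$to %in% cand
    exp_edges <- sum(inside)
    exp_nodes <- length(unique(c(edges$from[inside], edges$to[inside])))
    expect_equal(m$n_edges, exp_edges)
    expect_equal(m$n_nodes, exp_nodes)
  }
})

test_that("degree statistics match hand computation and brute force", {
  star <- data.frame(from = "HUB", to = c("L1", "L2", "L3", "L4"),
                     stringsAsFactors = FALSE)
  m <- induced_network(c("HUB", paste0("L", 1:4)), star)
  st <- network_stats(m)
  expect_equal(st$table$degree[st$table$gene == "HUB"], 4L)
  expect_true(all(st$table$degree[st$table$gene != "HUB"] == 1L))
  # leaves see only the hub: neighborhood connectivity 4
  expect_true(all(st$table$neighborhood_connectivity[
    st$table$gene != "HUB"] == 4))
  expect_equal(st$table$neighborhood_connectivity[st$table$gene == "HUB"], 1)
  expect_equal(st$n_degree_ge5, 0L)

  set.seed(53)
  g <- igraph::sample_gnp(25, 0.3)
  igraph::V(g)$name <- sprintf("V%02d", 1:25)
  el <- igraph::as_edgelist(g)
  m2 <- induced_network(sprintf("V%02d", 1:25),
                        data.frame(from = el[, 1], to = el[, 2],
                                   stringsAsFactors = FALSE))
  st2 <- network_stats(m2)
  deg <- igraph::degree(g)[match(st2$table$gene, igraph::V(g)$name)]
  expect_equal(st2$table$degree, unname(as.integer(deg)))
  expect_equal(st2$n_degree_ge5, sum(deg >= 5))
})

test_that("random-draw null matches exhaustive enumeration on a tiny graph", {
  genes <- paste0("g", 1:8)
  set.seed(54)
  pairs <- t(combn(genes, 2))
  edges <- as.data.frame(pairs[runif(nrow(pairs)) < 0.35, ],
                         stringsAsFactors = FALSE)
  names(edges) <- c("from", "to")
  # independent oracle: enumerate all C(8,3) subsets and count directly
  subsets <- combn(genes, 3, simplify = FALSE)
  oracle <- t(vapply(subsets, function(s) {
    e <- sum(toupper(edges$from) %in% toupper(s) &
             toupper(edges$to) %in% toupper(s))
    inc <- unique(c(edges$from[edges$from %in% s & edges$to %in% s],
                    edges$to[edges$from %in% s & edges$to %in% s]))
    c(nodes = length(inc), edges = e)
  }, numeric(2)))
  nul <- random_network_null(genes, 3, edges, exhaustive = TRUE)
  expect_equal(nul$mean_nodes, mean(oracle[, "nodes"]))
  expect_equal(nul$mean_edges, mean(oracle[, "edges"]))
  expect_equal(nul$sd_edges, sd(oracle[, "edges"]))
  # Monte Carlo agrees within sampling error
  mc <- random_network_null(genes, 3, edges, n_draws = 400, seed = 9)
  expect_lt(abs(mc$mean_edges - nul$mean_edges),
            4 * nul$sd_edges / sqrt(400) + 0.05)
})

test_that("degenerate draws and z-score conventions", {
  genes <- paste0("g", 1:6)
  edges <- data.frame(from = c("g1", "g2"), to = c("g2", "g3"),
                      stringsAsFactors = FALSE)
  nul <- random_network_null(genes, 6, edges, n_draws = 5, seed = 1)
  expect_equal(nul$sd_nodes, 0)                       # every draw identical
  obs <- induced_network(genes, edges)
  nul2 <- random_network_null(genes, 6, edges, n_draws = 5, seed = 1,
                              observed = obs)
  expect_equal(nul2$z_nodes, 0)                       # equal, sd 0 -> 0
})

test_that("module detection separates cliques and recovers planted blocks", {
  cl1 <- t(combn(paste0("a", 1:5), 2))
  cl2 <- t(combn(paste0("b", 1:5), 2))
  edges <- data.frame(from = c(cl1[, 1], cl2[, 1]),
                      to = c(cl1[, 2], cl2[, 2]), stringsAsFactors = FALSE)
  m <- induced_network(c(paste0("a", 1:5), paste0("b", 1:5)), edges)
  mods <- detect_modules(m, seed = 2)
  expect_equal(mods$n_modules, 2)
  # one edge between two nodes -> a single module
  m1 <- induced_network(c("x", "y"),
                        data.frame(from = "x", to = "y",
                                   stringsAsFactors = FALSE))
  expect_equal(detect_modules(m1, seed = 2)$n_modules, 1)
  # determinism
  st <- small_study()
  net <- st$network
  comm_genes <- names(net$truth)[net$truth > 0]
  big <- induced_network(comm_genes, net$edges)
  mod_a <- detect_modules(big, seed = 7)
  mod_b <- detect_modules(big, seed = 7)
  expect_identical(mod_a$membership, mod_b$membership)
})

test_that("planted communities are recovered with high adjusted Rand index", {
  skip_if_not_installed("mclust")
  st <- small_study()
  net <- st$network
  comm_genes <- names(net$truth)[net$truth > 0]
  m <- induced_network(comm_genes, net$edges)
  mods <- detect_modules(m, seed = 11)
  found <- mods$membership[igraph::V(m$graph)$name]
  truth <- net$truth[igraph::V(m$graph)$name]
  ari <- mclust::adjustedRandIndex(found, truth)
  expect_gte(ari, 0.9)
})

test_that("enrichment p equals the hypergeometric construction and Fisher oracle", {
  # m = 0 spans the full upper tail
  expect_equal(fisher_enrichment(100, 20, 10, 0)$p, 1)
  # against stats::fisher.test one-sided on the same 2x2 table
  set.seed(55)
  for (r in 1:20) {
    G <- sample(50:200, 1); N <- sample(10:40, 1)
    P <- sample(5:30, 1); m <- sample(0:min(P, N), 1)
    if (G - N - P + m < 0) next
    fe <- fisher_enrichment(G, N, P, m)
    ft <- fisher.test(matrix(c(m, N - m, P - m, G - N - P + m), 2,
                             byrow = TRUE), alternative = "greater")
    expect_equal(fe$p, ft$p.value, tolerance = 1e-10)
  }
  expect_error(fisher_enrichment(10, 8, 5, 0), "negative")
})

test_that("enrichment p is monotone decreasing in m and depends only on (G,N,P,m)", {
  ps <- sapply(0:6, function(m) fisher_enrichment(1055, 244, 6, m)$p)
  expect_true(all(diff(ps) < 0))
  expect_identical(fisher_enrichment(1055, 244, 6, 4)$p,
                   fisher_enrichment(1055, 244, 6, 4)$p)
})

test_that("validation DE flags find planted shifts and stay calibrated under permutation", {
  st <- small_study()
  co <- st$cohort
  flags <- validation_de_flags(co$counts, co$groups,
                               genes = co$truth$gene)
  her2_cols <- grep("HER2", names(flags), value = TRUE)
  hit <- rowMeans(as.matrix(flags[, her2_cols])) == 1
  expect_gte(mean(hit), 0.8)
  # permuted labels: ~5% flagged per pairwise comparison
  set.seed(56)
  perm <- sample(co$groups)
  sub <- rownames(co$counts)[1:150]
  nullflags <- validation_de_flags(co$counts, perm, genes = sub)
  rate <- mean(as.matrix(nullflags[, -1]))
  expect_lt(rate, 0.10)
  expect_warning(validation_de_flags(co$counts, co$groups,
                                     genes = c(co$truth$gene[1], "NOPE")),
                 "absent")
})
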