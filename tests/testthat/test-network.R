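make_de <- function(mirnas, mrnas = character(), lncrnas = character()) {
  tibble::tibble(
    gene_id = c(mirnas, mrnas, lncrnas),
    rna_class = c(rep("mirna", length(mirnas)), rep("mrna", length(mrnas)),
                  rep("lncrna", length(lncrnas))),
    direction = "down", significant = TRUE)
}

make_corr <- function(...) {
  tibble::tibble(...)
}

make_evidence <- function(mrna = NULL, lnc = NULL) {
  structure(list(
    mirna_mrna = mrna %||% tibble::tibble(mirna_id = character(),
                                          target_id = character(),
                                          score = double()),
    mirna_lncrna = lnc %||% tibble::tibble(mirna_id = character(),
                                           target_id = character(),
                                           source = character())),
    class = "interaction_evidence")
}

test_that("spearman_edges matches hand-computed rank correlations", {
  # sum-of-squared-rank-differences oracle: rho = 1 - 6*38/(5*24) = -0.9
  x <- rbind(mir = c(1, 2, 3, 4, 5))
  y <- rbind(tg = c(5, 4, 3, 1, 2))
  # below the 10-sample minimum: pad with a second block of the same pattern
  xx <- rbind(mir = c(1:5, 11:15))
  d <- c(5, 4, 3, 1, 2)
  yy <- rbind(tg = c(d, d + 10))
  e <- spearman_edges(xx, yy, "mrna", p_max = 1)
  oracle <- function(a, b) 1 - 6 * sum((rank(a) - rank(b))^2) /
    (length(a) * (length(a)^2 - 1))
  expect_equal(e$scc, oracle(xx[1, ], yy[1, ]))
  expect_equal(cor(1:5, c(5, 4, 3, 1, 2), method = "spearman"), -0.9)

  # perfect anti-monotone map: scc = -1, retained at p < 0.05 for n >= 10
  x10 <- rbind(mir = 1:12)
  y10 <- rbind(tg = exp(-(1:12)))
  e2 <- spearman_edges(x10, y10, "mrna")
  expect_equal(e2$scc, -1)
  expect_lt(e2$p_value, 0.05)
})

test_that("null pairs are retained at about the nominal 5% rate", {
  set.seed(5)
  a <- matrix(rnorm(40 * 200), nrow = 40,
              dimnames = list(paste0("mir", 1:40), NULL))
  b <- matrix(rnorm(25 * 200), nrow = 25,
              dimnames = list(paste0("m", 1:25), NULL))
  e <- spearman_edges(a, b, "mrna")
  expect_gt(nrow(e) / 1000, 0.02)
  expect_lt(nrow(e) / 1000, 0.08)
})

test_that("constant expression vectors are skipped with a warning", {
  a <- rbind(mir1 = rnorm(20), flat = rep(1, 20))
  b <- rbind(m1 = rnorm(20))
  expect_warning(e <- spearman_edges(a, b, "mrna", p_max = 1), "constant")
  expect_false("flat" %in% e$mirna_id)
})

test_that("edge filters use strict inequalities at every threshold", {
  de <- make_de("mir1", mrnas = c("mA", "mB", "mC"), lncrnas = "lnc1")
  corr <- make_corr(
    mirna_id = "mir1",
    partner_id = c("mA", "mB", "mC", "lnc1"),
    partner_class = c("mrna", "mrna", "mrna", "lncrna"),
    scc = c(-0.31, -0.29, -0.9, -0.31),
    p_value = 0.01)
  ev <- make_evidence(
    mrna = tibble::tibble(mirna_id = "mir1",
                          target_id = c("mA", "mB", "mC"),
                          score = c(51, 99, 50)),
    lnc = tibble::tibble(mirna_id = "mir1", target_id = "lnc1",
                         source = "starbase"))
  net <- build_network(de, corr, ev)
  kept <- net$edges$partner_id
  expect_true("mA" %in% kept)    # scc -0.31 < -0.3 and score 51 > 50
  expect_false("mB" %in% kept)   # scc -0.29 fails
  expect_false("mC" %in% kept)   # score 50 fails (strict)
})

test_that("lncRNA edges pass by strong scc OR negative scc with prediction", {
  de <- make_de("mir1", mrnas = "mA", lncrnas = c("l1", "l2", "l3", "l4"))
  corr <- make_corr(
    mirna_id = "mir1",
    partner_id = c("mA", "l1", "l2", "l3", "l4"),
    partner_class = c("mrna", rep("lncrna", 4)),
    scc = c(-0.6, -0.31, -0.1, -0.1, 0.1),
    p_value = 0.01)
  ev <- make_evidence(
    mrna = tibble::tibble(mirna_id = "mir1", target_id = "mA", score = 90),
    lnc = tibble::tibble(mirna_id = rep("mir1", 2),
                         target_id = c("l2", "l4"), source = "lncbase"))
  net <- build_network(de, corr, ev)
  kept <- net$edges$partner_id[net$edges$partner_class == "lncrna"]
  expect_setequal(kept, c("l1", "l2"))  # l3 unpredicted weak, l4 positive scc
})

test_that("ceRNA closure drops miRNAs lacking either partner class", {
  de <- make_de(c("mir1", "mir2"), mrnas = c("mA", "mB"), lncrnas = "l1")
  corr <- make_corr(
    mirna_id = c("mir1", "mir1", "mir2"),
    partner_id = c("mA", "l1", "mB"),
    partner_class = c("mrna", "lncrna", "mrna"),
    scc = -0.6, p_value = 0.001)
  ev <- make_evidence(
    mrna = tibble::tibble(mirna_id = c("mir1", "mir2"),
                          target_id = c("mA", "mB"), score = 90),
    lnc = tibble::tibble(mirna_id = "mir1", target_id = "l1",
                         source = "starbase"))
  net <- build_network(de, corr, ev)
  expect_false("mir2" %in% net$nodes$id)  # no lncRNA partner
  expect_true(all(c("mir1", "mA", "l1") %in% net$nodes$id))
  net_open <- build_network(de, corr, ev, cerna_closure = FALSE)
  expect_true("mir2" %in% net_open$nodes$id)
})

test_that("an empty post-filter network returns a status, not an error", {
  de <- make_de("mir1", mrnas = "mA")
  corr <- make_corr(mirna_id = "mir1", partner_id = "mA",
                    partner_class = "mrna", scc = -0.1, p_value = 0.01)
  net <- build_network(de, corr, make_evidence())
  expect_s3_class(net, "gcpmir_network")
  expect_equal(net$status, "empty_network")
  expect_equal(nrow(net$edges), 0)
})

test_that("relaxing the scc threshold never removes an edge", {
  sim <- generate_cohort(recovery_config(seed = 31))
  ev <- generate_evidence(sim$truth, recovery_config(seed = 31))
  de <- de_screen(sim$cohort)
  nrm <- normalized_classes(sim$cohort)
  sig <- function(cls) {
    g <- de$gene_id[de$significant & de$rna_class == cls]
    nrm[[cls]][intersect(g, rownames(nrm[[cls]])), , drop = FALSE]
  }
  corr <- dplyr::bind_rows(
    spearman_edges(sig("mirna"), sig("mrna"), "mrna"),
    spearman_edges(sig("mirna"), sig("lncrna"), "lncrna"))
  strict <- build_network(de, corr, ev,
                          network_thresholds(scc_mrna = -0.3,
                                             scc_lncrna = -0.3))
  loose <- build_network(de, corr, ev,
                         network_thresholds(scc_mrna = -0.2,
                                            scc_lncrna = -0.2))
  key <- function(n) paste(n$edges$mirna_id, n$edges$partner_id)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("every edge touches exactly one miRNA (bipartite by construction)", {
  sim <- generate_cohort(recovery_config(seed = 32))
  ev <- generate_evidence(sim$truth, recovery_config(seed = 32))
  de <- de_screen(sim$cohort)
  nrm <- normalized_classes(sim$cohort)
  sig <- function(cls) {
    g <- de$gene_id[de$significant & de$rna_class == cls]
    nrm[[cls]][intersect(g, rownames(nrm[[cls]])), , drop = FALSE]
  }
  corr <- dplyr::bind_rows(
    spearman_edges(sig("mirna"), sig("mrna"), "mrna"),
    spearman_edges(sig("mirna"), sig("lncrna"), "lncrna"))
  net <- build_network(de, corr, ev)
  cls <- setNames(net$nodes$class, net$nodes$id)
  expect_true(all(cls[net$edges$mirna_id] == "mirna"))
  expect_true(all(cls[net$edges$partner_id] != "mirna"))
})

test_that("topology matches closed forms on star and path graphs", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("c", "a", "b", "d", "e")
  t1 <- compute_topology(star)
  ctr <- t1[t1$node_id == "c", ]
  expect_equal(ctr$degree, 4)
  expect_equal(ctr$L, 4)
  expect_equal(ctr$closeness, 1.0)
  expect_equal(ctr$betweenness, 1.0)
  leaf <- t1[t1$node_id == "a", ]
  expect_equal(leaf$degree, 1)
  expect_equal(leaf$L, 1 + 2 * 3)
  expect_equal(leaf$betweenness, 0)

  path <- igraph::make_graph(~ a - b, b - c)
  t2 <- compute_topology(path)
  b <- t2[t2$node_id == "b", ]
  expect_equal(b$degree, 2); expect_equal(b$L, 2)
  expect_equal(b$closeness, 1.0); expect_equal(b$betweenness, 1.0)
  a <- t2[t2$node_id == "a", ]
  expect_equal(a$degree, 1); expect_equal(a$L, 3)
  expect_equal(a$closeness, 2 / 3); expect_equal(a$betweenness, 0)
})

test_that("topology matches the brute-force oracle on random graphs", {
  set.seed(14)
  for (i in 1:15) {
    n <- sample(5:25, 1)
    adj <- random_adjacency(n, runif(1, 0.08, 0.4))
    got <- compute_topology(igraph_from_adj(adj))
    want <- oracle_topology(adj)
    got <- got[match(want$node_id, got$node_id), ]
    expect_equal(got$degree, want$degree)
    expect_equal(got$L, want$L)
    expect_equal(got$closeness, want$closeness)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-10)
    expect_equal(got$singleton, want$singleton)
  }
})

test_that("singleton components are flagged with undefined topology", {
  g <- igraph::make_graph(~ a - b) + igraph::vertices("lonely")
  tp <- compute_topology(g)
  lone <- tp[tp$node_id == "lonely", ]
  expect_true(lone$singleton)
  expect_true(is.na(lone$closeness))
})
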