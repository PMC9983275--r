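# Progression miRNA-mediated (ceRNA) network: Spearman screening, the
# four-step rule-based edge filter, and per-node topology metrics.

#' Spearman correlation screen between miRNAs and partner genes
#'
#' Scores every miRNA x partner pair by Spearman's rank correlation (average
#' ranks for ties) over the shared samples, with a two-sided p-value from the
#' t approximation. Pairs failing `p < p_max` are dropped; constant expression
#' vectors are skipped with a warning.
#'
#' @param expr_mirna,expr_partner genes-x-samples matrices on identical
#'   sample columns (normalized counts; the statistic is rank-based).
#' @param partner_class `"mrna"` or `"lncrna"`, recorded per edge.
#' @param p_max retention threshold on the correlation p-value (strict `<`).
#' @return tibble: `mirna_id`, `partner_id`, `partner_class`, `scc`,
#'   `p_value`.
#' @export
spearman_edges <- function(expr_mirna, expr_partner,
                           partner_class = c("mrna", "lncrna"),
                           p_max = 0.05) {
  partner_class <- match.arg(partner_class)
  a <- as.matrix(expr_mirna); b <- as.matrix(expr_partner)
  if (ncol(a) != ncol(b)) stop("sample columns must match")
  n <- ncol(a)
  if (n < 10) stop("need >= 10 shared samples")
  const_a <- apply(a, 1, function(x) stats::sd(x) == 0)
  const_b <- apply(b, 1, function(x) stats::sd(x) == 0)
  if (any(const_a) || any(const_b)) {
    warning(sum(const_a) + sum(const_b),
            " constant expression vector(s) skipped")
    a <- a[!const_a, , drop = FALSE]; b <- b[!const_b, , drop = FALSE]
  }
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble::tibble(mirna_id = character(), partner_id = character(),
                          partner_class = character(), scc = double(),
                          p_value = double()))
  }
  rho <- stats::cor(t(a), t(b), method = "spearman")
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  out <- tibble::tibble(
    mirna_id = rep(rownames(a) %||% as.character(seq_len(nrow(a))),
                   times = nrow(b)),
    partner_id = rep(rownames(b) %||% as.character(seq_len(nrow(b))),
                     each = nrow(a)),
    partner_class = partner_class,
    scc = as.vector(rho),
    p_value = as.vector(p))
  dplyr::filter(out, .data$p_value < p_max)
}

#' Edge-filter thresholds for network construction
#'
#' @param scc_mrna miRNA-mRNA edges need Spearman strictly below this.
#' @param scc_lncrna miRNA-lncRNA edges pass outright below this ...
#' @param scc_lncrna_pred ... or below this (default 0) when also predicted
#'   by at least one lncRNA-interaction database source.
#' @param score_min miRNA-mRNA edges need a prediction score strictly above
#'   this (miRDB-style 0-100 scale).
#' @param p_max correlation p-value retention threshold (strict `<`).
#' @return named list of thresholds.
#' @export
network_thresholds <- function(scc_mrna = -0.3, scc_lncrna = -0.3,
                               scc_lncrna_pred = 0, score_min = 50,
                               p_max = 0.05) {
  list(scc_mrna = scc_mrna, scc_lncrna = scc_lncrna,
       scc_lncrna_pred = scc_lncrna_pred, score_min = score_min,
       p_max = p_max)
}

#' Build the progression miRNA-mediated network
#'
#' Four-step construction. (1) Keep correlation pairs with `p < p_max`
#' between differential miRNAs and differential partners. (2) Keep a
#' miRNA-mRNA edge iff `scc < scc_mrna` AND its best prediction score is
#' `> score_min`. (3) Keep a miRNA-lncRNA edge iff `scc < scc_lncrna`, OR
#' `scc < scc_lncrna_pred` and the pair is predicted by at least one database
#' source. (4) ceRNA closure: retain only miRNAs incident to at least one
#' mRNA edge and at least one lncRNA edge, with their incident edges;
#' isolated nodes are removed. All inequalities are strict.
#'
#' @param de tibble from [test_differential()]/[de_screen()]; only rows with
#'   `significant == TRUE` define the node universe.
#' @param corr correlation edges from [spearman_edges()] (both classes bound
#'   together is fine).
#' @param evidence `interaction_evidence` (see [generate_evidence()]): tibbles
#'   `mirna_mrna` (`mirna_id`, `target_id`, `score`) and `mirna_lncrna`
#'   (`mirna_id`, `target_id`).
#' @param thresholds a [network_thresholds()] list.
#' @param cerna_closure apply step (4); disable to inspect the pre-closure
#'   network.
#' @return object of class `gcpmir_network`: `nodes` (tibble `id`, `class`,
#'   `de_direction`), `edges` (tibble `mirna_id`, `partner_id`,
#'   `partner_class`, `scc`, `p_value`, `evidence`), `graph` (igraph,
#'   undirected), `status` (`"ok"` or `"empty_network"`).
#' @export
build_network <- function(de, corr, evidence,
                          thresholds = network_thresholds(),
                          cerna_closure = TRUE) {
  th <- thresholds
  de_sig <- dplyr::filter(de, .data$significant)
  de_mirna <- de_sig$gene_id[de_sig$rna_class == "mirna"]
  corr <- dplyr::filter(corr,
                        .data$mirna_id %in% de_mirna,
                        .data$partner_id %in% de_sig$gene_id,
                        .data$p_value < th$p_max)

  ev_mrna <- if (nrow(evidence$mirna_mrna) == 0) {
    tibble::tibble(mirna_id = character(), target_id = character(),
                   score = double())
  } else {
    evidence$mirna_mrna |>
      dplyr::group_by(.data$mirna_id, .data$target_id) |>
      dplyr::summarise(score = max(.data$score), .groups = "drop")
  }
  mrna_edges <- corr |>
    dplyr::filter(.data$partner_class == "mrna", .data$scc < th$scc_mrna) |>
    dplyr::inner_join(ev_mrna,
                      by = c(mirna_id = "mirna_id", partner_id = "target_id")) |>
    dplyr::filter(.data$score > th$score_min) |>
    dplyr::mutate(evidence = sprintf("mirdb:%.0f", .data$score)) |>
    dplyr::select(-"score")

  ev_lnc <- dplyr::distinct(evidence$mirna_lncrna,
                            .data$mirna_id, .data$target_id)
  lnc_edges <- corr |>
    dplyr::filter(.data$partner_class == "lncrna") |>
    dplyr::left_join(dplyr::mutate(ev_lnc, predicted = TRUE),
                     by = c(mirna_id = "mirna_id", partner_id = "target_id")) |>
    dplyr::mutate(predicted = !is.na(.data$predicted)) |>
    dplyr::filter(.data$scc < th$scc_lncrna |
                    (.data$scc < th$scc_lncrna_pred & .data$predicted)) |>
    dplyr::mutate(evidence = dplyr::if_else(.data$predicted, "lncdb", "")) |>
    dplyr::select(-"predicted")

  edges <- dplyr::bind_rows(mrna_edges, lnc_edges)
  if (cerna_closure && nrow(edges) > 0) {
    keep_mirnas <- intersect(
      unique(edges$mirna_id[edges$partner_class == "mrna"]),
      unique(edges$mirna_id[edges$partner_class == "lncrna"]))
    edges <- dplyr::filter(edges, .data$mirna_id %in% keep_mirnas)
  }
  if (nrow(edges) == 0) {
    return(structure(list(nodes = tibble::tibble(id = character(),
                                                 class = character(),
                                                 de_direction = character()),
                          edges = edges, graph = igraph::make_empty_graph(0),
                          status = "empty_network"),
                     class = "gcpmir_network"))
  }
  node_ids <- unique(c(edges$mirna_id, edges$partner_id))
  nodes <- tibble::tibble(id = node_ids) |>
    dplyr::left_join(
      dplyr::select(de_sig, id = "gene_id", class = "rna_class",
                    de_direction = "direction"),
      by = "id")
  graph <- igraph::graph_from_data_frame(
    dplyr::transmute(edges, from = .data$mirna_id, to = .data$partner_id,
                     scc = .data$scc, evidence = .data$evidence),
    directed = FALSE,
    vertices = as.data.frame(nodes))
  net <- structure(list(nodes = nodes, edges = edges, graph = graph,
                        status = "ok"),
                   class = "gcpmir_network")
  .assert_mirna_bipartite(net)
  net
}

.assert_mirna_bipartite <- function(net) {
  cls <- stats::setNames(net$nodes$class, net$nodes$id)
  bad <- cls[net$edges$mirna_id] != "mirna" |
    cls[net$edges$partner_id] == "mirna"
  if (any(bad)) stop("internal error: edge not anchored on exactly one miRNA")
  invisible(TRUE)
}

#' Node topology: degree, path length, closeness, betweenness
#'
#' Unweighted undirected shortest paths within each connected component.
#' For a node in a component of `n_c` nodes: `L` is the sum of BFS distances
#' to the other `n_c - 1` nodes, closeness `C = (n_c - 1) / L`, and
#' betweenness `B` is pair-dependency betweenness normalized by
#' `(n_c - 1)(n_c - 2) / 2`. Singleton components have no defined topology and
#' are flagged and excluded from downstream scoring.
#'
#' @param net a `gcpmir_network` or any igraph graph.
#' @return tibble: `node_id`, `component`, `n_component`, `degree`, `L`
#'   (total shortest-path length), `closeness`, `betweenness`, `singleton`.
#' @export
compute_topology <- function(net) {
  g <- if (inherits(net, "gcpmir_network")) net$graph else net
  stopifnot(inherits(g, "igraph"))
  if (igraph::vcount(g) < 1) {
    return(tibble::tibble(node_id = character(), component = integer(),
                          n_component = integer(), degree = integer(),
                          L = double(), closeness = double(),
                          betweenness = double(), singleton = logical()))
  }
  comp <- igraph::components(g)
  nc <- comp$csize[comp$membership]
  d <- igraph::distances(g)
  d[!is.finite(d)] <- 0  # cross-component distances do not enter L
  L <- rowSums(d)
  btw_raw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  denom <- (nc - 1) * (nc - 2) / 2
  ids <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  tibble::tibble(
    node_id = ids,
    component = unname(comp$membership),
    n_component = as.integer(nc),
    degree = unname(igraph::degree(g)),
    L = unname(L),
    closeness = ifelse(nc > 1, (nc - 1) / L, NA_real_),
    betweenness = ifelse(denom > 0, unname(btw_raw) / denom,
                         ifelse(nc > 1, 0, NA_real_)),
    singleton = nc == 1)
}

#' @export
print.gcpmir_network <- function(x, ...) {
  if (x$status == "empty_network") {
    cat("<gcpmir_network> empty (no edge survived the filters)\n")
    return(invisible(x))
  }
  tab <- table(x$nodes$class)
  cat("<gcpmir_network> ",
      paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = ", "),
      " nodes; ",
      sum(x$edges$partner_class == "mrna"), " miRNA-mRNA and ",
      sum(x$edges$partner_class == "lncrna"), " miRNA-lncRNA edges\n",
      sep = "")
  invisible(x)
}
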