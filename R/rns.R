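# RNs gene prioritization: SVM-RFE expression ranking combined with network
# topology, RNs = degree * Rs / L.

#' Rank genes by SVM recursive feature elimination
#'
#' Repeatedly fits a linear-kernel SVM on the current feature set and removes
#' the `step` features with the smallest squared weight; the elimination order
#' reversed is the rank (rank 1 = eliminated last = most discriminative). The
#' score is `Rs = n_features - rank + 1`, so with `step = 1` the Rs values are
#' a permutation of `1..n`. Expression is log2(x+1)-transformed and per-gene
#' standardized before fitting (disable with `transform = FALSE`); constant
#' genes are eliminated first.
#'
#' @param expr genes-x-samples matrix (counts or normalized counts).
#' @param labels two-class factor/character over samples.
#' @param cost SVM regularization constant.
#' @param step features removed per iteration (within a removed chunk, ranks
#'   follow the within-chunk weight order).
#' @param transform apply log2(x+1) + per-gene z-scoring.
#' @return tibble: `gene_id`, `rfe_rank`, `Rs`, `weight2` (squared weight at
#'   elimination time).
#' @export
svm_rfe_rank <- function(expr, labels, cost = 1, step = 1, transform = TRUE) {
  x <- as.matrix(expr)
  y <- as.factor(labels)
  if (nlevels(y) != 2) stop("labels must have exactly two classes")
  if (nrow(x) < 2) stop("need >= 2 genes")
  if (length(y) != ncol(x)) stop("labels must match samples")
  if (transform) x <- log2(x + 1)
  sds <- apply(x, 1, stats::sd)
  const <- sds == 0
  if (transform) {
    x[!const, ] <- (x[!const, , drop = FALSE] -
                      rowMeans(x[!const, , drop = FALSE])) / sds[!const]
  }
  genes <- rownames(x) %||% as.character(seq_len(nrow(x)))
  rownames(x) <- genes
  n <- length(genes)
  elim <- character(0); elim_w2 <- numeric(0)
  # constant genes carry no signal: out first, arbitrary but fixed order
  if (any(const)) {
    elim <- genes[const]
    elim_w2 <- rep(0, sum(const))
  }
  remaining <- setdiff(genes, elim)
  while (length(remaining) > 1) {
    fit <- e1071::svm(x = t(x[remaining, , drop = FALSE]), y = y,
                      kernel = "linear", cost = cost, scale = FALSE)
    w <- crossprod(fit$coefs, fit$SV)[1, ]
    w2 <- stats::setNames(w^2, remaining)
    k <- min(step, length(remaining) - 1)
    drop_now <- names(sort(w2))[seq_len(k)]
    elim <- c(elim, drop_now)
    elim_w2 <- c(elim_w2, unname(w2[drop_now]))
    remaining <- setdiff(remaining, drop_now)
  }
  elim <- c(elim, remaining)
  elim_w2 <- c(elim_w2, NA_real_)
  rank <- stats::setNames(rev(seq_len(n)), elim)  # eliminated last -> rank 1
  tibble::tibble(gene_id = elim, rfe_rank = unname(rank[elim]),
                 Rs = n - unname(rank[elim]) + 1,
                 weight2 = elim_w2) |>
    dplyr::arrange(.data$rfe_rank)
}

#' RNs prioritization score
#'
#' Combines topology and expression ranking: `RNs = K * Rs / L`, with `K` the
#' node degree, `L` its total shortest-path length to the other nodes of its
#' component, and `Rs` the SVM-RFE score. Genes missing from the network (or
#' sitting in singleton components) are excluded with a warning.
#'
#' @param topology tibble from [compute_topology()].
#' @param ranking tibble from [svm_rfe_rank()].
#' @return tibble of class `rns_table`: `gene_id`, `degree`, `L`,
#'   `closeness`, `betweenness`, `Rs`, `RNs`, sorted by descending `RNs`.
#' @export
rns_scores <- function(topology, ranking) {
  missing <- setdiff(ranking$gene_id, topology$node_id)
  if (length(missing) > 0) {
    warning(length(missing), " ranked gene(s) missing from the network; excluded")
  }
  tab <- dplyr::inner_join(ranking,
                           dplyr::rename(topology, gene_id = "node_id"),
                           by = "gene_id")
  singles <- tab$singleton
  if (any(singles)) {
    warning(sum(singles), " singleton node(s) have undefined topology; excluded")
    tab <- tab[!singles, ]
  }
  stopifnot(all(tab$L > 0))
  out <- tab |>
    dplyr::transmute(gene_id = .data$gene_id, degree = .data$degree,
                     L = .data$L, closeness = .data$closeness,
                     betweenness = .data$betweenness, Rs = .data$Rs,
                     RNs = .data$degree * .data$Rs / .data$L) |>
    dplyr::arrange(dplyr::desc(.data$RNs), dplyr::desc(.data$degree),
                   .data$gene_id)
  class(out) <- c("rns_table", class(out))
  out
}

#' Top-ranked genes by RNs
#'
#' @param rns an `rns_table` (or any tibble with `gene_id`, `RNs`, `degree`).
#' @param k how many genes.
#' @param exclude gene ids to remove before ranking (e.g. an already
#'   established marker held out of the module).
#' @return character vector of `k` gene ids ordered by descending RNs, ties
#'   broken by higher degree then lexicographic id.
#' @export
top_genes <- function(rns, k, exclude = character()) {
  tab <- rns |>
    dplyr::filter(!.data$gene_id %in% exclude) |>
    dplyr::arrange(dplyr::desc(.data$RNs), dplyr::desc(.data$degree),
                   .data$gene_id)
  if (k > nrow(tab)) stop("k exceeds the number of available genes")
  tab$gene_id[seq_len(k)]
}

#' Invert a printed RNs table back to integer (L, Rs)
#'
#' Reference prioritization tables print, per node, the degree `K`, the
#' closeness `C` and the score `RNs`, each rounded to 3 decimals. Under the
#' convention `C = (N - 1) / L` the integer total path length `L` is
#' recoverable by enumeration (all `L` whose closeness rounds to the printed
#' value), and `Rs = RNs * L / K` must then be near an integer. This is the
#' consistency oracle used to validate the conventions against published
#' tables.
#'
#' @param tbl data frame with columns `name`, `degree`, `closeness`, `rns`.
#' @param n_nodes number of nodes `N` of the (connected) network.
#' @param tol_int how close `Rs` must be to an integer to accept an `L`.
#' @return tibble: `name`, `L` (integer), `Rs` (integer), `rns_check`
#'   (forward recomputation `K * Rs / L` rounded to 3 decimals),
#'   `closeness_check`.
#' @export
invert_rns_table <- function(tbl, n_nodes, tol_int = 0.2) {
  purrr::pmap_dfr(
    dplyr::select(tbl, "name", "degree", "closeness", "rns"),
    function(name, degree, closeness, rns) {
      L_all <- seq.int(n_nodes - 1, ceiling((n_nodes - 1) / 0.1))
      L_cand <- L_all[round((n_nodes - 1) / L_all, 3) == closeness]
      rs <- rns * L_cand / degree
      ok <- abs(rs - round(rs)) < tol_int
      if (!any(ok)) {
        stop("no integer-consistent (L, Rs) for node ", name)
      }
      best <- L_cand[ok][which.min(abs(rs[ok] - round(rs[ok])))]
      rs_best <- as.integer(round(rns * best / degree))
      tibble::tibble(
        name = name, L = as.integer(best), Rs = rs_best,
        rns_check = round(degree * rs_best / best, 3),
        closeness_check = round((n_nodes - 1) / best, 3))
    })
}

#' Worked-example prioritization table
#'
#' The ten top-RNs nodes of a 155-node gastric-cancer progression network
#' (seven miR-200/miR-183-family miRNAs, one additional miRNA and the two
#' lncRNAs H19 and CLLU1), as printed to three decimals. Used throughout the
#' documentation and tests as the reference for the closeness convention and
#' the RNs arithmetic.
#'
#' @return tibble: `name`, `family`, `degree`, `betweenness`, `closeness`,
#'   `rns`.
#' @export
reference_rns_example <- function() {
  path <- system.file("extdata", "reference_top10_rns.tsv",
                      package = "mirmodnet", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @export
print.rns_table <- function(x, ...) {
  cat("<rns_table> ", nrow(x), " genes; top: ",
      paste(utils::head(x$gene_id, 3), collapse = ", "), "\n", sep = "")
  NextMethod()
}
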