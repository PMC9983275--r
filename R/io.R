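# Readers/writers for the pipeline's plain-text interchange formats:
# expression and annotation TSVs, evidence TSVs, networks as GraphML + TSV,
# models and manifests as JSON.

#' Write an expression cohort to a directory
#'
#' Expression matrices go to `<class>_counts.tsv` (genes in rows, first
#' column `gene_id`, remaining columns the sample ids), annotations to
#' `annotations.tsv`.
#'
#' @param cohort an `expression_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (cls in names(cohort$counts)) {
    p <- file.path(dir, paste0(cls, "_counts.tsv"))
    write_expression(cohort$counts[[cls]], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "annotations.tsv")
  readr::write_tsv(cohort$samples, p)
  invisible(c(paths, p))
}

#' @rdname write_cohort
#' @param mat genes-x-samples matrix.
#' @param path output TSV path.
#' @export
write_expression <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a genes-x-samples expression TSV
#'
#' @param path TSV with a `gene_id` first column and one column per sample.
#' @return numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

#' Write/read interaction evidence tables
#'
#' One TSV with columns `mirna_id`, `target_id`, `score`, `source`; mRNA
#' evidence carries a numeric score and source `"mirdb"`, lncRNA evidence a
#' missing score and its database source.
#'
#' @param evidence an `interaction_evidence`.
#' @param path TSV path.
#' @return invisibly, `path` / the `interaction_evidence`.
#' @export
write_evidence <- function(evidence, path) {
  tab <- dplyr::bind_rows(
    dplyr::mutate(evidence$mirna_mrna, source = "mirdb"),
    dplyr::mutate(evidence$mirna_lncrna, score = NA_real_))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_evidence
#' @export
read_evidence <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  structure(
    list(mirna_mrna = tab |>
           dplyr::filter(.data$source == "mirdb") |>
           dplyr::select("mirna_id", "target_id", "score"),
         mirna_lncrna = tab |>
           dplyr::filter(.data$source != "mirdb") |>
           dplyr::select("mirna_id", "target_id", "source")),
    class = "interaction_evidence")
}

#' Write a network as GraphML plus edge/topology TSVs
#'
#' @param net a `gcpmir_network`.
#' @param dir output directory.
#' @param topology optional [compute_topology()] result to write alongside.
#' @return invisibly, the paths written.
#' @export
write_network <- function(net, dir, topology = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("network.graphml", "edges.tsv"))
  igraph::write_graph(net$graph, paths[1], format = "graphml")
  readr::write_tsv(net$edges, paths[2])
  if (!is.null(topology)) {
    p <- file.path(dir, "topology.tsv")
    readr::write_tsv(topology, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
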