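# Family-anchored module extraction and its expression-level validation.

#' Extract the family-mediated progression module
#'
#' Given prioritized miRNAs/lncRNAs and a family assignment, the module is the
#' selected genes plus every network mRNA adjacent to at least one member of
#' each miRNA family; edges are the network edges induced on the members.
#'
#' @param net a `gcpmir_network` from [build_network()].
#' @param selected character vector of prioritized genes (miRNAs and lncRNAs)
#'   present in the network.
#' @param family_map named character vector mapping each selected miRNA to its
#'   family label (e.g. `c("miR-429" = "miR-200")`).
#' @param min_edges_per_family how many edges to each family an mRNA needs
#'   (default 1: "interacts with members from both families").
#' @return object of class `progression_module`: tibbles `mirnas` (`gene_id`,
#'   `family`), `lncrnas`, `mrnas` (`gene_id`, plus per-family edge counts),
#'   and `edges` (the induced subset of network edges).
#' @export
extract_module <- function(net, selected, family_map,
                           min_edges_per_family = 1L) {
  stopifnot(inherits(net, "gcpmir_network"))
  if (net$status != "ok") stop("cannot extract a module from an empty network")
  missing <- setdiff(selected, net$nodes$id)
  if (length(missing) > 0) {
    stop("selected genes absent from the network: ",
         paste(missing, collapse = ", "))
  }
  cls <- stats::setNames(net$nodes$class, net$nodes$id)
  sel_mirnas <- selected[cls[selected] == "mirna"]
  sel_lncrnas <- selected[cls[selected] == "lncrna"]
  fam <- family_map[sel_mirnas]
  if (any(is.na(fam))) {
    stop("family_map must cover every selected miRNA")
  }
  families <- unique(fam)
  if (length(families) < 2) {
    stop("module rule needs at least two miRNA families with selected members")
  }
  # per-mRNA edge counts to each family among the selected miRNAs
  mrna_edges <- net$edges |>
    dplyr::filter(.data$partner_class == "mrna",
                  .data$mirna_id %in% sel_mirnas) |>
    dplyr::mutate(family = unname(fam[.data$mirna_id]))
  fam_counts <- mrna_edges |>
    dplyr::count(.data$partner_id, .data$family) |>
    tidyr::pivot_wider(names_from = "family", values_from = "n",
                       values_fill = 0L)
  for (f in setdiff(families, names(fam_counts))) fam_counts[[f]] <- 0L
  if (nrow(fam_counts) == 0) {
    fam_counts <- tibble::tibble(partner_id = character())
    for (f in families) fam_counts[[f]] <- integer(0)
  }
  qualifies <- fam_counts[
    rowSums(as.matrix(fam_counts[families]) >= min_edges_per_family) ==
      length(families), ]
  mrnas <- qualifies$partner_id
  members <- c(sel_mirnas, sel_lncrnas, mrnas)
  edges <- net$edges |>
    dplyr::filter(.data$mirna_id %in% members, .data$partner_id %in% members)
  mod <- structure(
    list(mirnas = tibble::tibble(gene_id = sel_mirnas,
                                 family = unname(fam)),
         lncrnas = tibble::tibble(gene_id = sel_lncrnas),
         mrnas = dplyr::rename(qualifies, gene_id = "partner_id"),
         edges = edges),
    class = "progression_module")
  .assert_module_closure(mod, min_edges_per_family)
  mod
}

.assert_module_closure <- function(mod, min_edges_per_family = 1L) {
  members <- module_genes(mod)
  stopifnot(all(mod$edges$mirna_id %in% members),
            all(mod$edges$partner_id %in% members))
  for (m in mod$mrnas$gene_id) {
    fams <- mod$mirnas$family[match(
      mod$edges$mirna_id[mod$edges$partner_id == m], mod$mirnas$gene_id)]
    cnt <- table(factor(fams, levels = unique(mod$mirnas$family)))
    stopifnot(all(cnt >= min_edges_per_family))
  }
  invisible(TRUE)
}

#' All member genes of a module
#' @param mod a `progression_module`.
#' @return character vector of gene ids (miRNAs, lncRNAs, mRNAs).
#' @export
module_genes <- function(mod) {
  c(mod$mirnas$gene_id, mod$lncrnas$gene_id, mod$mrnas$gene_id)
}

#' Validate a module on an independent expression set
#'
#' Recomputes, on a validation cohort, (i) the Spearman correlation of every
#' module edge, flagging "green" edges (scc < -0.5 and p < 0.05, both strict),
#' and (ii) two-sided Wilcoxon rank-sum group comparisons per module gene for
#' each requested contrast (e.g. tumor vs normal, early vs late stage).
#'
#' @param mod a `progression_module`.
#' @param expr genes-x-samples matrix of validation expression covering the
#'   module genes (any monotone scale; statistics are rank-based).
#' @param sample_info tibble with one row per column of `expr` holding the
#'   contrast columns.
#' @param contrasts character vector of `sample_info` column names; each must
#'   be two-level.
#' @param correlate_on optional logical/character filter choosing the samples
#'   used for the edge correlations (e.g. tumor samples only); default all.
#' @param green_scc,green_p the green-link rule thresholds.
#' @return list of class `module_validation`: `edges` (per-edge `scc`, `p`,
#'   `green`), `group_tests` (gene x contrast Wilcoxon W and p), `missing`
#'   (module genes absent from `expr`).
#' @export
validate_module <- function(mod, expr, sample_info, contrasts,
                            correlate_on = NULL,
                            green_scc = -0.5, green_p = 0.05) {
  genes <- module_genes(mod)
  missing <- setdiff(genes, rownames(expr))
  present <- setdiff(genes, missing)
  expr <- as.matrix(expr)
  stopifnot(ncol(expr) == nrow(sample_info))
  keep <- if (is.null(correlate_on)) rep(TRUE, ncol(expr)) else correlate_on
  edges <- mod$edges |>
    dplyr::mutate(available = .data$mirna_id %in% present &
                    .data$partner_id %in% present)
  res <- purrr::pmap_dfr(edges, function(mirna_id, partner_id, available, ...) {
    if (!available) {
      return(tibble::tibble(scc = NA_real_, p_value = NA_real_, green = NA))
    }
    ct <- suppressWarnings(stats::cor.test(
      expr[mirna_id, keep], expr[partner_id, keep],
      method = "spearman", exact = FALSE))
    tibble::tibble(scc = unname(ct$estimate), p_value = ct$p.value,
                   green = unname(ct$estimate) < green_scc &
                     ct$p.value < green_p)
  })
  edge_report <- dplyr::bind_cols(
    dplyr::select(edges, "mirna_id", "partner_id", "partner_class"), res)

  group_tests <- purrr::map_dfr(contrasts, function(cn) {
    lab <- as.factor(sample_info[[cn]])
    if (nlevels(lab) != 2) stop("contrast ", cn, " is not two-level")
    purrr::map_dfr(present, function(g) {
      x <- expr[g, lab == levels(lab)[2]]
      y <- expr[g, lab == levels(lab)[1]]
      wt <- suppressWarnings(stats::wilcox.test(x, y))
      tibble::tibble(gene_id = g, contrast = cn,
                     W = unname(wt$statistic), p_value = wt$p.value)
    })
  })
  structure(list(edges = edge_report, group_tests = group_tests,
                 missing = missing),
            class = "module_validation")
}

#' @export
print.progression_module <- function(x, ...) {
  cat("<progression_module> ", nrow(x$mirnas), " miRNAs (",
      paste(unique(x$mirnas$family), collapse = " + "), "), ",
      nrow(x$lncrnas), " lncRNAs, ", nrow(x$mrnas), " mRNAs; ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}
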