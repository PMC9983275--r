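# End-to-end orchestration: simulate (optional) -> differential screen ->
# network -> RNs prioritization -> module -> survival/associations ->
# subset classifier, with a reproducibility manifest.

#' Pipeline configuration
#'
#' All stage thresholds and seeds in one flat, YAML-serializable list.
#'
#' @param alpha adjusted-p cutoff of the differential screen.
#' @param de_method `"nbwald"` or `"wilcoxon"`.
#' @param scc_mrna,scc_lncrna,scc_lncrna_pred,score_min,p_max network
#'   thresholds, see [network_thresholds()].
#' @param cerna_closure apply the ceRNA closure (step 4).
#' @param top_k how many prioritized genes seed the module.
#' @param exclude gene ids excluded from the top-k selection.
#' @param green_scc,green_p module-validation green-link rule.
#' @param split_ratio,cutoff survival-stage options ([split_cohort()],
#'   [fit_cox()]).
#' @param categories clinical columns for the association tables.
#' @param svm_kernel,svm_cost classifier configuration.
#' @param max_panel classifier panel capped at this many module genes.
#' @param max_subset_size optional cap on enumerated subset sizes.
#' @param seed master seed (simulation uses it; the split uses `seed + 1`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.05, de_method = "nbwald",
                            scc_mrna = -0.3, scc_lncrna = -0.3,
                            scc_lncrna_pred = 0, score_min = 50,
                            p_max = 0.05, cerna_closure = TRUE,
                            top_k = 10, exclude = character(),
                            green_scc = -0.5, green_p = 0.05,
                            split_ratio = 0.7, cutoff = "median",
                            categories = c("age_group", "gender", "grade"),
                            svm_kernel = "linear", svm_cost = 1,
                            max_panel = 14, max_subset_size = NULL,
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(alpha > 0, alpha < 1, scc_mrna <= 0, score_min >= 0,
            split_ratio > 0, split_ratio < 1, top_k >= 1, max_panel >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Round-trip a pipeline config through YAML
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @return `write_config` returns `path`; `read_config` the config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the discovery pipeline end to end
#'
#' Executes (optionally) the cohort simulation, the differential screen, the
#' rule-based network construction, RNs prioritization, family-module
#' extraction and validation, Cox risk stratification with association tables,
#' and the exhaustive subset classifier. An empty network halts the downstream
#' stages with status `"empty_network"` (partial outputs are kept).
#'
#' @param config a [pipeline_config()].
#' @param cohort optional `expression_cohort`; simulated from `sim_config`
#'   when absent.
#' @param evidence optional `interaction_evidence`; simulated when absent.
#' @param sim_config a [simulate_config()] used when cohort/evidence are
#'   simulated; its seed is overridden by `config$seed`.
#' @param family_map named character vector miRNA -> family for module
#'   extraction; when absent and the cohort was simulated, the planted family
#'   assignment is used (families are nomenclature knowledge, not inference).
#' @param outdir optional directory: all stage outputs plus a JSON manifest
#'   (config, seeds, file hashes) are written there.
#' @return list of class `pipeline_result` with elements `status`, `de`,
#'   `network`, `topology`, `rns`, `top`, `module`, `validation`, `split`,
#'   `risk_model`, `stratification`, `associations`, `classifier`, `truth`
#'   (when simulated), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         evidence = NULL, sim_config = NULL,
                         family_map = NULL, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (is.null(cohort)) {
    sim_config <- sim_config %||% simulate_config()
    sim_config$seed <- config$seed
    sim <- generate_cohort(sim_config)
    cohort <- sim$cohort
    truth <- sim$truth
  }
  if (is.null(evidence)) {
    if (is.null(truth) || is.null(sim_config)) {
      stop("evidence must be supplied for a non-simulated cohort")
    }
    evidence <- generate_evidence(truth, sim_config)
  }
  if (is.null(family_map) && !is.null(truth)) {
    family_map <- stats::setNames(truth$module$mirnas$family,
                                  truth$module$mirnas$gene_id)
  }
  res <- list(status = "ok", truth = truth, config = config)

  # differential screen + normalized expression per class
  norm <- lapply(cohort$counts, function(m) normalize_counts(m)$normalized)
  res$de <- de_screen(cohort, alpha = config$alpha, method = config$de_method)
  de_sig <- dplyr::filter(res$de, .data$significant)

  # correlation screen on DE genes, pooled tumor samples
  th <- network_thresholds(scc_mrna = config$scc_mrna,
                           scc_lncrna = config$scc_lncrna,
                           scc_lncrna_pred = config$scc_lncrna_pred,
                           score_min = config$score_min, p_max = config$p_max)
  pick <- function(cls) {
    g <- intersect(de_sig$gene_id[de_sig$rna_class == cls],
                   rownames(norm[[cls]]))
    norm[[cls]][g, , drop = FALSE]
  }
  corr <- dplyr::bind_rows(
    if (nrow(pick("mirna")) && nrow(pick("mrna")))
      spearman_edges(pick("mirna"), pick("mrna"), "mrna", p_max = th$p_max),
    if (nrow(pick("mirna")) && nrow(pick("lncrna")))
      spearman_edges(pick("mirna"), pick("lncrna"), "lncrna",
                     p_max = th$p_max))
  res$network <- build_network(res$de, corr, evidence, thresholds = th,
                               cerna_closure = config$cerna_closure)
  if (res$network$status != "ok") {
    res$status <- "empty_network"
    if (!is.null(outdir)) res$manifest <- .write_bundle(res, cohort, outdir)
    return(structure(res, class = "pipeline_result"))
  }

  # prioritization
  res$topology <- compute_topology(res$network)
  expr_all <- do.call(rbind, norm)
  rownames(expr_all) <- unlist(lapply(norm, rownames), use.names = FALSE)
  net_expr <- expr_all[res$network$nodes$id, , drop = FALSE]
  ranking <- svm_rfe_rank(net_expr, cohort$samples$group)
  res$rns <- rns_scores(res$topology, ranking)
  res$top <- top_genes(res$rns, k = min(config$top_k, nrow(res$rns)),
                       exclude = config$exclude)

  # module extraction + validation on the same cohort's tumor samples
  cls_of <- stats::setNames(res$network$nodes$class, res$network$nodes$id)
  sel <- res$top[cls_of[res$top] %in% c("mirna", "lncrna")]
  sel_mirnas <- sel[cls_of[sel] == "mirna"]
  fams <- unique(family_map[intersect(sel_mirnas, names(family_map))])
  # the module rule needs both families represented among the selected
  # miRNAs; if the top-k misses one, walk down the ranking to the
  # highest-RNs member of each missing family
  if (length(stats::na.omit(fams)) < 2) {
    for (g in setdiff(res$rns$gene_id, res$top)) {
      if (isTRUE(cls_of[g] == "mirna") && g %in% names(family_map) &&
          !(family_map[[g]] %in% fams)) {
        sel <- c(sel, g)
        sel_mirnas <- c(sel_mirnas, g)
        fams <- unique(c(fams, family_map[[g]]))
      }
      if (length(stats::na.omit(fams)) >= 2) break
    }
  }
  if (length(stats::na.omit(fams)) >= 2) {
    res$module <- extract_module(res$network, sel, family_map)
    res$validation <- validate_module(
      res$module, expr_all, cohort$samples, contrasts = "group",
      green_scc = config$green_scc, green_p = config$green_p)
  } else {
    res$module <- NULL
    res$status <- "module_rule_undefined"
  }

  if (!is.null(res$module)) {
    # survival stage on the module miRNAs
    res$split <- split_cohort(cohort$samples$sample_id,
                              ratio = config$split_ratio,
                              seed = config$seed + 1L)
    idx_tr <- match(res$split$train, cohort$samples$sample_id)
    idx_te <- match(res$split$test, cohort$samples$sample_id)
    mir_expr <- norm$mirna[res$module$mirnas$gene_id, , drop = FALSE]
    res$risk_model <- fit_cox(mir_expr[, idx_tr, drop = FALSE],
                              time = cohort$samples$survival_time[idx_tr],
                              event = cohort$samples$event[idx_tr],
                              cutoff = config$cutoff)
    res$stratification <- list(
      train = risk_stratify(res$risk_model, mir_expr[, idx_tr, drop = FALSE],
                            time = cohort$samples$survival_time[idx_tr],
                            event = cohort$samples$event[idx_tr]),
      test = risk_stratify(res$risk_model, mir_expr[, idx_te, drop = FALSE],
                           time = cohort$samples$survival_time[idx_te],
                           event = cohort$samples$event[idx_te]),
      whole = risk_stratify(res$risk_model, mir_expr,
                            time = cohort$samples$survival_time,
                            event = cohort$samples$event))
    cats <- intersect(config$categories, names(cohort$samples))
    if (length(cats) > 0) {
      res$associations <- association_table(
        expr_all, cohort$samples,
        genes = intersect(module_genes(res$module), rownames(expr_all)),
        categories = cats)
    }

    # exhaustive subset classifier on the module panel
    panel <- module_genes(res$module)
    if (length(panel) > config$max_panel) {
      keep <- res$rns$gene_id[res$rns$gene_id %in% panel]
      panel <- utils::head(c(keep, setdiff(panel, keep)), config$max_panel)
    }
    res$classifier <- search_combinations(
      expr_all[panel, idx_tr, drop = FALSE],
      expr_all[panel, idx_te, drop = FALSE],
      cohort$samples$group[idx_tr], cohort$samples$group[idx_te],
      genes = panel, kernel = config$svm_kernel, cost = config$svm_cost,
      max_size = config$max_subset_size)
  }

  if (!is.null(outdir)) res$manifest <- .write_bundle(res, cohort, outdir)
  structure(res, class = "pipeline_result")
}

.write_bundle <- function(res, cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohort, file.path(outdir, "cohort"))
  readr::write_tsv(res$de, file.path(outdir, "de_results.tsv"))
  if (!is.null(res$network) && res$network$status == "ok") {
    write_network(res$network, file.path(outdir, "network"), res$topology)
    readr::write_tsv(res$rns, file.path(outdir, "rns_table.tsv"))
  }
  if (!is.null(res$module)) {
    jsonlite::write_json(
      list(mirnas = res$module$mirnas, lncrnas = res$module$lncrnas,
           mrnas = res$module$mrnas),
      file.path(outdir, "module.json"))
    readr::write_tsv(res$module$edges, file.path(outdir, "module_edges.tsv"))
    readr::write_tsv(res$validation$edges,
                     file.path(outdir, "validation_edges.tsv"))
    jsonlite::write_json(
      list(genes = res$risk_model$genes,
           coefficients = res$risk_model$coefficients,
           hr = res$risk_model$hr, cutoff = res$risk_model$cutoff),
      file.path(outdir, "risk_model.json"), auto_unbox = TRUE, digits = NA)
    readr::write_tsv(res$stratification$whole$scores,
                     file.path(outdir, "risk_scores.tsv"))
    if (!is.null(res$associations)) {
      readr::write_tsv(res$associations, file.path(outdir, "associations.tsv"))
    }
    readr::write_tsv(
      dplyr::mutate(res$classifier$results,
                    subset = vapply(.data$subset, paste, "", collapse = ",")),
      file.path(outdir, "classifier_subsets.tsv"))
    readr::write_tsv(res$classifier$best$roc,
                     file.path(outdir, "best_subset_roc.tsv"))
  }
  files <- setdiff(list.files(outdir, recursive = TRUE, full.names = TRUE),
                   file.path(outdir, "manifest.json"))
  manifest <- list(
    package = "mirmodnet",
    version = as.character(utils::packageVersion("mirmodnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    status = res$status,
    seed = res$config$seed,
    config = unclass(res$config),
    hashes = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> status:", x$status, "\n")
  if (!is.null(x$de)) {
    cat("  DE genes:", sum(x$de$significant), "of", nrow(x$de), "\n")
  }
  if (!is.null(x$network)) print(x$network)
  if (!is.null(x$module)) print(x$module)
  if (!is.null(x$stratification)) {
    cat(sprintf("  log-rank p (train/test/whole): %.4g / %.4g / %.4g\n",
                x$stratification$train$logrank$p,
                x$stratification$test$logrank$p,
                x$stratification$whole$logrank$p))
  }
  if (!is.null(x$classifier)) print(x$classifier)
  invisible(x)
}
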