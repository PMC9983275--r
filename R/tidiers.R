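# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @rdname tidiers
#' @param x a fitted `mirmodnet` object.
#' @param ... unused.
tidy.risk_model <- function(x, ...) x$hr

#' @export
#' @rdname tidiers
glance.risk_model <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, n_genes = length(x$genes),
                 cutoff = x$cutoff,
                 concordance = unname(x$fit$concordance["concordance"]))
}

#' @export
#' @rdname tidiers
tidy.risk_stratification <- function(x, ...) x$scores

#' @export
#' @rdname tidiers
glance.risk_stratification <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$scores),
    n_high = sum(x$scores$group == "high"),
    n_low = sum(x$scores$group == "low"),
    cutoff = x$cutoff,
    logrank_chisq = if (is.null(x$logrank)) NA_real_ else x$logrank$chisq,
    logrank_p = if (is.null(x$logrank)) NA_real_ else x$logrank$p)
}

#' @export
#' @rdname tidiers
tidy.gcpmir_network <- function(x, ...) x$edges

#' @export
#' @rdname tidiers
glance.gcpmir_network <- function(x, ...) {
  tab <- table(factor(x$nodes$class, levels = c("mirna", "mrna", "lncrna")))
  tibble::tibble(
    status = x$status,
    n_mirna = as.integer(tab["mirna"]), n_mrna = as.integer(tab["mrna"]),
    n_lncrna = as.integer(tab["lncrna"]),
    n_edges_mrna = sum(x$edges$partner_class == "mrna"),
    n_edges_lncrna = sum(x$edges$partner_class == "lncrna"))
}

#' @export
#' @rdname tidiers
tidy.subset_search <- function(x, ...) {
  dplyr::mutate(x$results,
                subset = vapply(.data$subset, paste, "", collapse = ","))
}

#' @export
#' @rdname tidiers
glance.subset_search <- function(x, ...) {
  tibble::tibble(n_subsets = nrow(x$results), best_auc = x$best$auc,
                 best_size = length(x$best$genes),
                 best_genes = paste(x$best$genes, collapse = ","))
}

#' @export
#' @rdname tidiers
tidy.module_validation <- function(x, ...) x$edges

#' Tidiers for mirmodnet objects
#'
#' `tidy()` returns the per-term/per-edge/per-sample table of an object;
#' `glance()` a one-row summary.
#'
#' @name tidiers
NULL
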