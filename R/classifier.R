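# Progression classifier: seeded cohort splitting, hand-built ROC/AUC
# (Mann-Whitney identity), and exhaustive gene-subset SVM search.

#' Split sample ids into training and test cohorts
#'
#' Seeded simple random split: `|train| = round(ratio * n)`, partition is
#' disjoint and exhaustive.
#'
#' @param sample_ids character vector of ids.
#' @param ratio training fraction in (0, 1).
#' @param seed integer RNG seed.
#' @return list with `train` and `test` id vectors.
#' @export
split_cohort <- function(sample_ids, ratio = 0.7, seed = 1L) {
  n <- length(sample_ids)
  if (n < 2) stop("need >= 2 samples to split")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  set.seed(seed)
  n_train <- round(ratio * n)
  train <- sort(sample(sample_ids, n_train))
  list(train = train, test = sort(setdiff(sample_ids, train)))
}

#' ROC curve and AUC from continuous scores
#'
#' AUC is computed by the Mann-Whitney identity, `U / (n1 * n0)` with ties
#' contributing 1/2; the ROC polyline is built by sweeping the score
#' thresholds, and its trapezoidal area equals the Mann-Whitney AUC.
#'
#' @param scores numeric decision values (larger = more positive-like).
#' @param labels two-level factor/logical/0-1; the second factor level (or
#'   `TRUE`/1) is the positive class.
#' @return list of class `roc_result`: `auc`, `roc` tibble
#'   (`threshold`, `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- .as_positive(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # average ranks handle ties with the 1/2 convention
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) sum(scores[pos] >= t) / n1, 1.0),
    fpr = vapply(thr, function(t) sum(scores[!pos] >= t) / n0, 1.0))
  structure(list(auc = auc, roc = roc, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

.as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- as.factor(labels)
  if (nlevels(f) != 2) stop("labels must be two-level")
  f == levels(f)[2]
}

#' Trapezoidal area under a stored ROC polyline
#'
#' Independent of the Mann-Whitney route; the two must agree exactly.
#'
#' @param roc tibble with `fpr`, `tpr` sorted by decreasing threshold.
#' @return numeric area.
#' @export
roc_trapezoid <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Fit a linear SVM on standardized training expression, return test decision
# values oriented so larger = more likely positive (second label level).
.svm_decision <- function(train_x, train_y, test_x, kernel = "linear",
                          cost = 1) {
  ctr <- colMeans(train_x)
  sds <- apply(train_x, 2, stats::sd)
  sds[sds == 0] <- 1
  tr <- sweep(sweep(train_x, 2, ctr), 2, sds, "/")
  te <- sweep(sweep(test_x, 2, ctr), 2, sds, "/")
  fit <- e1071::svm(x = tr, y = train_y, kernel = kernel, cost = cost,
                    scale = FALSE, decision.values = TRUE)
  dv <- attr(stats::predict(fit, te, decision.values = TRUE),
             "decision.values")
  # e1071 orients decision values toward the first class of the colname pair
  lev <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
  s <- as.numeric(dv[, 1])
  if (lev[1] == levels(train_y)[2]) s else -s
}

#' Exhaustive gene-subset SVM search
#'
#' Trains one SVM per non-empty subset of `genes` on the training cohort
#' (features log2(x+1)-transformed, then standardized on the training data)
#' and scores the test cohort by decision values; each subset's ROC/AUC is
#' computed with [roc_auc()]. Results are ranked by AUC, ties broken by
#' smaller subset size then lexicographic gene list.
#'
#' @param train_expr,test_expr genes-x-samples matrices of normalized counts.
#' @param train_labels,test_labels two-level group labels (second level =
#'   positive class, e.g. late stage).
#' @param genes gene panel to enumerate (at most 20).
#' @param kernel,cost SVM configuration (linear kernel, C = 1 by default).
#' @param max_size optional cap on subset size.
#' @param transform apply log2(x+1) before standardization.
#' @return object of class `subset_search`: `results` tibble (`subset`
#'   list-column, `size`, `auc`) ranked best first, and `best` (list:
#'   `genes`, `auc`, `roc` tibble of the top subset).
#' @export
search_combinations <- function(train_expr, test_expr, train_labels,
                                test_labels, genes, kernel = "linear",
                                cost = 1, max_size = NULL, transform = TRUE) {
  if (length(genes) > 20) stop("exhaustive search capped at 20 genes")
  stopifnot(all(genes %in% rownames(train_expr)),
            all(genes %in% rownames(test_expr)))
  ytr <- as.factor(train_labels); yte <- as.factor(test_labels)
  if (nlevels(ytr) != 2) stop("training labels must be two-level")
  if (length(unique(yte[!is.na(yte)])) != 2) {
    stop("AUC undefined: test cohort has a single class")
  }
  yte <- factor(yte, levels = levels(ytr))
  tr <- t(as.matrix(train_expr[genes, , drop = FALSE]))
  te <- t(as.matrix(test_expr[genes, , drop = FALSE]))
  if (transform) { tr <- log2(tr + 1); te <- log2(te + 1) }
  sizes <- seq_len(if (is.null(max_size)) length(genes) else
    min(max_size, length(genes)))
  subsets <- unlist(lapply(sizes, function(k) {
    utils::combn(genes, k, simplify = FALSE)
  }), recursive = FALSE)
  auc <- vapply(subsets, function(s) {
    dv <- .svm_decision(tr[, s, drop = FALSE], ytr, te[, s, drop = FALSE],
                        kernel = kernel, cost = cost)
    roc_auc(dv, yte)$auc
  }, 1.0)
  results <- tibble::tibble(
    subset = subsets, size = lengths(subsets), auc = auc,
    subset_key = vapply(subsets, function(s) paste(sort(s), collapse = ","),
                        "")) |>
    dplyr::arrange(dplyr::desc(.data$auc), .data$size, .data$subset_key) |>
    dplyr::select(-"subset_key")
  best_genes <- results$subset[[1]]
  best_dv <- .svm_decision(tr[, best_genes, drop = FALSE], ytr,
                           te[, best_genes, drop = FALSE],
                           kernel = kernel, cost = cost)
  best_roc <- roc_auc(best_dv, yte)
  structure(list(results = results,
                 best = list(genes = best_genes, auc = best_roc$auc,
                             roc = best_roc$roc)),
            class = "subset_search")
}

#' @export
print.subset_search <- function(x, ...) {
  cat("<subset_search> ", nrow(x$results), " subsets; best AUC = ",
      sprintf("%.3f", x$best$auc), " with {",
      paste(x$best$genes, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC = ", sprintf("%.4f", x$auc), " (", x$n_pos,
      " pos / ", x$n_neg, " neg)\n", sep = "")
  invisible(x)
}
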