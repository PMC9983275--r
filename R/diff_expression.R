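# Differential-expression screen: median-of-ratios normalization and a
# pluggable two-group test (NB Wald with method-of-moments dispersion by
# default, Wilcoxon rank-sum as alternative), BH-adjusted per RNA class.

#' Median-of-ratios size-factor normalization
#'
#' Each sample's size factor is the median, over reference genes, of the ratio
#' of its count to the gene's geometric mean across samples. Reference genes
#' are those with positive counts in every sample; with
#' `pseudo_reference = TRUE` the reference is instead every gene whose
#' geometric mean over positive counts is positive (useful for sparse data).
#'
#' @param counts non-negative genes-x-samples matrix, at least 2 samples.
#' @param pseudo_reference fall back to a positive-count geometric mean when
#'   no gene is expressed in all samples.
#' @return list with `normalized` (matrix, counts / size factor) and
#'   `size_factors` (named numeric, positive).
#' @export
normalize_counts <- function(counts, pseudo_reference = FALSE) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!pseudo_reference) {
    ref <- rowSums(counts > 0) == ncol(counts)
    if (!any(ref)) {
      stop("no gene has positive counts in every sample; ",
           "rerun with `pseudo_reference = TRUE`")
    }
    logmeans <- rowMeans(log(counts[ref, , drop = FALSE]))
    sf <- apply(counts[ref, , drop = FALSE], 2, function(cl) {
      exp(stats::median(log(cl) - logmeans))
    })
  } else {
    lc <- log(counts)
    lc[!is.finite(lc)] <- NA
    logmeans <- rowMeans(lc, na.rm = TRUE)
    ok <- is.finite(logmeans)
    if (!any(ok)) stop("all genes are all-zero; cannot normalize")
    sf <- apply(counts[ok, , drop = FALSE], 2, function(cl) {
      r <- log(cl) - logmeans[ok]
      exp(stats::median(r[is.finite(r)]))
    })
  }
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("degenerate size factors")
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
}

#' Two-group differential-expression test
#'
#' Screens each gene for a difference between two sample groups (reference
#' level first; fold changes are `group2 vs group1`, e.g. late vs early
#' stage). The default engine is a negative-binomial Wald test on normalized
#' counts with a per-gene method-of-moments dispersion; `method = "wilcoxon"`
#' uses the rank-sum test instead (constant genes get p = 1). P-values are
#' Benjamini-Hochberg adjusted within the supplied gene set, which callers
#' should keep to one RNA class at a time.
#'
#' @param norm_matrix genes-x-samples matrix of normalized counts.
#' @param group_labels factor/character of length `ncol(norm_matrix)` with
#'   exactly two levels; the second level is the numerator of fold changes.
#' @param alpha adjusted-p significance cutoff for the `significant` flag.
#' @param method `"nbwald"` (default) or `"wilcoxon"`.
#' @param rna_class optional label copied into the result.
#' @return tibble: `gene_id`, `rna_class`, `base_mean`, `log2_fold_change`,
#'   `p_value`, `adjusted_p`, `direction` (`up` iff lfc > 0), `significant`.
#' @export
test_differential <- function(norm_matrix, group_labels, alpha = 0.05,
                              method = c("nbwald", "wilcoxon"),
                              rna_class = NA_character_) {
  method <- match.arg(method)
  m <- as.matrix(norm_matrix)
  g <- as.factor(group_labels)
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (any(table(g) < 2)) stop("each group needs >= 2 samples")
  if (length(g) != ncol(m)) stop("labels must match columns")
  i1 <- g == levels(g)[1]; i2 <- g == levels(g)[2]
  m1 <- rowMeans(m[, i1, drop = FALSE]); m2 <- rowMeans(m[, i2, drop = FALSE])
  lfc <- log2((m2 + 0.5) / (m1 + 0.5))
  p <- switch(method,
    nbwald = .nb_wald_p(m, i1, i2, m1, m2),
    wilcoxon = apply(m, 1, function(x) {
      if (stats::sd(x) == 0) return(1)
      suppressWarnings(stats::wilcox.test(x[i2], x[i1])$p.value)
    }))
  p[is.na(p)] <- 1
  tibble::tibble(
    gene_id = rownames(m) %||% as.character(seq_len(nrow(m))),
    rna_class = rna_class,
    base_mean = rowMeans(m),
    log2_fold_change = unname(lfc),
    p_value = unname(p),
    adjusted_p = stats::p.adjust(p, method = "BH"),
    direction = ifelse(lfc > 0, "up", "down"),
    significant = stats::p.adjust(p, method = "BH") < alpha
  )
}

# NB Wald on the log-mean difference; dispersion by method of moments, pooled
# within groups so a true group effect does not inflate it.
.nb_wald_p <- function(m, i1, i2, m1, m2) {
  n1 <- sum(i1); n2 <- sum(i2)
  v1 <- apply(m[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(m[, i2, drop = FALSE], 1, stats::var)
  # var = mu + alpha mu^2  =>  alpha = (var - mu) / mu^2, floored at 0
  pool_v <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  pool_m <- (n1 * m1 + n2 * m2) / (n1 + n2)
  alpha_mm <- pmax(0, (pool_v - pool_m) / pmax(pool_m, 1e-8)^2)
  # delta method on log2 mean with +0.5 stabilizer
  se2 <- ((m1 + alpha_mm * m1^2) / (n1 * (m1 + 0.5)^2) +
          (m2 + alpha_mm * m2^2) / (n2 * (m2 + 0.5)^2)) / log(2)^2
  lfc <- log2((m2 + 0.5) / (m1 + 0.5))
  z <- ifelse(se2 > 0, lfc / sqrt(se2), 0)
  2 * stats::pnorm(-abs(z))
}

#' Differential screen across the three RNA classes
#'
#' Runs [normalize_counts()] + [test_differential()] per RNA class of an
#' expression cohort, adjusting p-values within each class separately.
#'
#' @param cohort `expression_cohort` (see [generate_cohort()]) or a named list
#'   of count matrices plus a `samples` tibble with a `group` column.
#' @inheritParams test_differential
#' @param pseudo_reference passed to [normalize_counts()].
#' @return tibble of per-gene results over all classes (see
#'   [test_differential()]).
#' @export
de_screen <- function(cohort, alpha = 0.05, method = c("nbwald", "wilcoxon"),
                      pseudo_reference = FALSE) {
  method <- match.arg(method)
  purrr::map_dfr(names(cohort$counts), function(cls) {
    nrm <- normalize_counts(cohort$counts[[cls]],
                            pseudo_reference = pseudo_reference)
    test_differential(nrm$normalized, cohort$samples$group, alpha = alpha,
                      method = method, rna_class = cls)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
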