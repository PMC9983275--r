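# Cox risk-score model, risk-group stratification with Kaplan-Meier /
# log-rank, and clinicopathological chi-square association tables.

#' Fit a multivariable Cox risk model on gene expression
#'
#' Expression is put on the model scale (log2(x+1), then per-gene z-scoring
#' with center/scale learned here and stored in the model so test cohorts can
#' be scored reproducibly) and fitted with Efron tie handling. The risk score
#' of a patient is the linear predictor `sum(beta_i * x_i)`; the stratification
#' cutoff defaults to the median training risk score.
#'
#' @param expr genes-x-samples matrix of normalized counts (training cohort).
#' @param time,event survival time (> 0) and event indicator (0/1) per sample.
#' @param genes genes to include; default all rows of `expr`.
#' @param cutoff `"median"` (default), `"mean"`, or a number: the risk-score
#'   cutoff separating high- from low-risk patients.
#' @param min_events minimum number of observed events required.
#' @return object of class `risk_model`: `genes`, `coefficients`, `hr` with
#'   95% CI, `cutoff`, `scale` (transform descriptor), `fit` (the `coxph`
#'   object), `n`, `n_events`.
#' @export
fit_cox <- function(expr, time, event, genes = rownames(expr),
                    cutoff = "median", min_events = 10L) {
  expr <- as.matrix(expr)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0) {
    stop("genes absent from expression: ", paste(missing, collapse = ", "))
  }
  stopifnot(length(time) == ncol(expr), length(event) == ncol(expr),
            all(time > 0), all(event %in% c(0, 1)))
  if (sum(event) < min_events) {
    stop("need >= ", min_events, " events; got ", sum(event))
  }
  x <- log2(expr[genes, , drop = FALSE] + 1)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance gene(s): ",
            paste(genes[sds == 0], collapse = ", "))
    genes <- genes[sds > 0]
    if (length(genes) == 0) stop("no gene with variance left to fit")
    x <- x[genes, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  ctr <- rowMeans(x)
  z <- (x - ctr) / sds
  df <- as.data.frame(t(z))
  names(df) <- make.names(genes)
  df$.time <- time; df$.event <- event
  fit <- survival::coxph(
    survival::Surv(.time, .event) ~ .,
    data = df, ties = "efron")
  beta <- stats::coef(fit)
  if (any(is.na(beta)) || !is.null(fit$fail)) {
    stop("Cox model did not converge: ",
         paste(genes[is.na(beta)], collapse = ", "))
  }
  ci <- stats::confint(fit)
  scores <- as.numeric(crossprod(beta, z[genes, , drop = FALSE]))
  cut_val <- switch(as.character(cutoff[1]),
                    median = stats::median(scores),
                    mean = mean(scores),
                    as.numeric(cutoff))
  if (!is.finite(cut_val)) stop("cutoff is not finite")
  structure(
    list(genes = genes,
         coefficients = stats::setNames(unname(beta), genes),
         hr = tibble::tibble(
           gene_id = genes, beta = unname(beta),
           se = sqrt(diag(fit$var)),
           hr = exp(unname(beta)),
           hr_low = exp(ci[, 1]), hr_high = exp(ci[, 2]),
           p_value = summary(fit)$coefficients[, "Pr(>|z|)"]),
         cutoff = cut_val,
         scale = list(transform = "log2(x+1), per-gene z-score",
                      center = ctr, sd = sds),
         fit = fit, n = ncol(expr), n_events = sum(event)),
    class = "risk_model")
}

#' Risk score of samples under a fitted model
#'
#' @param model a `risk_model`.
#' @param expr genes-x-samples matrix. With `rescale = TRUE` (default) raw
#'   normalized counts are put on the model scale using the transform stored
#'   at fit time; with `rescale = FALSE` `expr` is taken to be on the model
#'   scale already and the score is the bare linear combination
#'   `sum(beta_i * x_i)` (exactly linear in `expr`).
#' @return numeric vector of per-sample risk scores.
#' @export
risk_score <- function(model, expr, rescale = TRUE) {
  expr <- as.matrix(expr)
  missing <- setdiff(model$genes, rownames(expr))
  if (length(missing) > 0) {
    stop("expression lacks model gene(s): ", paste(missing, collapse = ", "))
  }
  x <- expr[model$genes, , drop = FALSE]
  if (rescale) {
    x <- (log2(x + 1) - model$scale$center) / model$scale$sd
  }
  as.numeric(crossprod(model$coefficients, x))
}

#' Stratify a cohort into risk groups and compare survival
#'
#' Scores each sample, assigns `high` iff score > cutoff, and (when survival
#' data are supplied) computes Kaplan-Meier product-limit curves per group and
#' the two-group log-rank test (chi-square, 1 df).
#'
#' @inheritParams risk_score
#' @param time,event optional survival data for the scored samples.
#' @return object of class `risk_stratification`: `scores` tibble
#'   (`sample_id`, `score`, `group`), `km` tibble (`group`, `time`,
#'   `survival`, `n_risk`, `n_event`), `logrank` list (`chisq`, `df`, `p`),
#'   `cutoff`.
#' @export
risk_stratify <- function(model, expr, time = NULL, event = NULL,
                          rescale = TRUE) {
  s <- risk_score(model, expr, rescale = rescale)
  ids <- colnames(expr) %||% as.character(seq_along(s))
  grp <- factor(ifelse(s > model$cutoff, "high", "low"),
                levels = c("low", "high"))
  km <- NULL; logrank <- NULL
  if (!is.null(time)) {
    stopifnot(length(time) == length(s), length(event) == length(s))
    sf <- survival::survfit(survival::Surv(time, event) ~ grp)
    strata_lab <- sub("^grp=", "", rep(names(sf$strata), sf$strata))
    km <- tibble::tibble(group = strata_lab, time = sf$time,
                         survival = sf$surv, n_risk = sf$n.risk,
                         n_event = sf$n.event)
    if (nlevels(droplevels(grp)) == 2) {
      sd2 <- survival::survdiff(survival::Surv(time, event) ~ grp)
      logrank <- list(chisq = sd2$chisq, df = 1,
                      p = stats::pchisq(sd2$chisq, df = 1, lower.tail = FALSE))
    }
  }
  structure(list(scores = tibble::tibble(sample_id = ids, score = s,
                                         group = grp),
                 km = km, logrank = logrank, cutoff = model$cutoff),
            class = "risk_stratification")
}

#' Chi-square association of gene expression with a clinical category
#'
#' Dichotomizes expression into High/Low at the median (or a supplied rule),
#' tabulates levels x High/Low, and applies Pearson's chi-square test -- with
#' Yates continuity correction for 2x2 tables, uncorrected otherwise. A
#' warning recommends an exact test when any expected cell is below 1.
#'
#' @param gene_expr numeric expression across patients.
#' @param clinical_category factor/character with >= 2 levels.
#' @param dichotomize `"median"` or a function mapping expression to a
#'   logical High indicator.
#' @return list of class `chisq_association`: `table` (levels x High/Low),
#'   `statistic`, `df`, `p_value`, `low_expected` flag.
#' @export
chi_square_association <- function(gene_expr, clinical_category,
                                   dichotomize = "median") {
  lab <- as.factor(clinical_category)
  if (nlevels(lab) < 2) stop("clinical category needs >= 2 levels")
  high <- if (is.function(dichotomize)) {
    dichotomize(gene_expr)
  } else {
    gene_expr > stats::median(gene_expr)
  }
  tab <- table(lab, factor(ifelse(high, "High", "Low"),
                           levels = c("High", "Low")))
  res <- chi_square_table(tab)
  structure(c(list(table = tab), res), class = "chisq_association")
}

#' Chi-square test on a pre-tabulated contingency table
#'
#' @param tab a matrix/table of counts (r x c). Yates continuity correction is
#'   applied iff the table is 2x2.
#' @return list: `statistic`, `df`, `p_value`, `low_expected`.
#' @export
chi_square_table <- function(tab) {
  tab <- as.matrix(tab)
  ct <- suppressWarnings(
    stats::chisq.test(tab, correct = all(dim(tab) == c(2, 2))))
  low <- any(ct$expected < 1)
  if (low) {
    warning("expected cell count < 1; consider an exact test")
  }
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, low_expected = low)
}

#' Association table of module genes vs clinical categories
#'
#' Runs [chi_square_association()] for every gene x category combination,
#' mirroring the usual clinicopathological association tables.
#'
#' @param expr genes-x-samples matrix (normalized counts).
#' @param samples tibble of per-sample annotations.
#' @param genes genes to tabulate (rows of `expr`).
#' @param categories column names of `samples` to test against.
#' @return tibble: `gene_id`, `category`, `statistic`, `df`, `p_value`,
#'   `low_expected`.
#' @export
association_table <- function(expr, samples, genes, categories) {
  stopifnot(all(genes %in% rownames(expr)),
            all(categories %in% names(samples)))
  tidyr::expand_grid(gene_id = genes, category = categories) |>
    dplyr::mutate(res = purrr::map2(.data$gene_id, .data$category, function(g, cat) {
      a <- chi_square_association(expr[g, ], samples[[cat]])
      tibble::tibble(statistic = a$statistic, df = a$df,
                     p_value = a$p_value, low_expected = a$low_expected)
    })) |>
    tidyr::unnest("res")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model> ", length(x$genes), " genes, n = ", x$n, " (",
      x$n_events, " events); cutoff = ", signif(x$cutoff, 5), "\n", sep = "")
  terms <- sprintf("(%.4f x %s)", x$coefficients, x$genes)
  cat("  risk score =", paste(terms, collapse = " + "), "\n")
  invisible(x)
}

#' @export
print.risk_stratification <- function(x, ...) {
  cat("<risk_stratification> ", nrow(x$scores), " samples: ",
      sum(x$scores$group == "high"), " high / ",
      sum(x$scores$group == "low"), " low risk", sep = "")
  if (!is.null(x$logrank)) {
    cat(sprintf("; log-rank chisq = %.3f, p = %.4g",
                x$logrank$chisq, x$logrank$p))
  }
  cat("\n")
  invisible(x)
}
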