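test_that("cohort split has the documented sizes and is deterministic", {
  ids <- sprintf("S%03d", 1:257)
  sp <- split_cohort(ids, ratio = 0.7, seed = 3)
  expect_equal(length(sp$train), 180)
  expect_equal(length(sp$test), 77)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, split_cohort(ids, ratio = 0.7, seed = 3))
  expect_false(identical(sp, split_cohort(ids, ratio = 0.7, seed = 4)))
  sp2 <- split_cohort(letters[1:10], ratio = 0.5, seed = 1)
  expect_equal(lengths(sp2), c(train = 5, test = 5))
  expect_error(split_cohort("a", 0.5), ">= 2")
  expect_error(split_cohort(letters, 1.2), "ratio")
})

test_that("AUC matches brute-force pair counting on worked examples", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(c(0.9, 0.3, 0.8, 0.1), c(1, 0, 1, 0))$auc, 1.0)
  # swap one positive/negative pair: 3 of 4 pairs correctly ordered + ...
  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  # one discordant pair out of four: 3/4
  s <- c(0.9, 0.3, 0.8, 0.1); y <- c(1, 1, 0, 0)
  expect_equal(roc_auc(s, y)$auc, brute(s, y))
  expect_equal(roc_auc(s, y)$auc, 0.75)
  # all ties: AUC = 1/2
  expect_equal(roc_auc(rep(1, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  # random instances, with ties
  set.seed(11)
  for (i in 1:20) {
    s <- sample(seq(0, 1, 0.1), 30, replace = TRUE)
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y)$auc, brute(s, y))
  }
})

test_that("trapezoidal ROC area equals the Mann-Whitney AUC exactly", {
  set.seed(12)
  for (i in 1:20) {
    s <- round(rnorm(40), 1)  # coarse scores force ties
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    r <- roc_auc(s, y)
    expect_equal(roc_trapezoid(r$roc), r$auc, tolerance = 1e-12)
    expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)
    expect_equal(max(r$roc$fpr), 1); expect_equal(max(r$roc$tpr), 1)
    expect_true(all(diff(r$roc$fpr) >= 0))
    expect_true(all(diff(r$roc$tpr) >= 0))
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(13)
  s <- rnorm(50); y <- rbinom(50, 1, 0.5)
  expect_equal(roc_auc(exp(s), y)$auc, roc_auc(s, y)$auc)
  expect_equal(roc_auc(rank(s), y)$auc, roc_auc(s, y)$auc)
})

test_that("hand-built AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  s <- round(rnorm(80), 1); y <- rbinom(80, 1, 0.5)
  ref <- suppressMessages(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(roc_auc(s, y)$auc, as.numeric(ref))
})

test_that("single-class test cohorts are rejected", {
  tr <- matrix(rnorm(2 * 20), 2, dimnames = list(c("a", "b"), NULL))
  te <- matrix(rnorm(2 * 10), 2, dimnames = list(c("a", "b"), NULL))
  expect_error(
    search_combinations(tr, te, rep(c("E", "L"), 10), rep("E", 10),
                        genes = c("a", "b")),
    "single class")
  expect_error(roc_auc(rnorm(5), rep(1, 5)), "two-level|both classes")
})

test_that("subset search ranks the planted signal first and sizes the grid", {
  set.seed(15)
  n <- 120
  labels <- rep(c("ESGC", "LSGC"), each = n / 2)
  mu <- matrix(80, 5, n, dimnames = list(paste0("g", 1:5), NULL))
  mu[1:2, labels == "LSGC"] <- 80 * 6  # g1, g2 strongly separating
  expr <- matrix(rnbinom(5 * n, mu = mu, size = 1 / 0.2), 5,
                 dimnames = list(paste0("g", 1:5), NULL))
  sp <- split_cohort(colnames(expr) <- as.character(1:n), 0.6, seed = 2)
  idx <- as.integer(sp$train); idx_te <- as.integer(sp$test)
  res <- search_combinations(expr[, idx], expr[, idx_te],
                             labels[idx], labels[idx_te],
                             genes = paste0("g", 1:5))
  expect_equal(nrow(res$results), 2^5 - 1)
  expect_true(all(c("g1", "g2") %in% res$results$subset[[1]]) ||
                res$results$auc[1] > 0.95)
  expect_equal(res$best$auc, res$results$auc[1])
  expect_equal(roc_trapezoid(res$best$roc), res$best$auc, tolerance = 1e-12)
  # max_size caps the enumeration
  res2 <- search_combinations(expr[, idx], expr[, idx_te],
                              labels[idx], labels[idx_te],
                              genes = paste0("g", 1:5), max_size = 2)
  expect_equal(nrow(res2$results), 5 + 10)
})

test_that("a perfectly separating single gene reaches AUC 1", {
  n <- 60
  labels <- rep(c("ESGC", "LSGC"), each = n / 2)
  expr <- rbind(sep = c(rpois(n / 2, 10), 500 + rpois(n / 2, 10)),
                noise = rpois(n, 50))
  res <- search_combinations(expr, expr, labels, labels,
                             genes = c("sep", "noise"))
  one_gene <- res$results[vapply(res$results$subset, identical, TRUE, "sep"), ]
  expect_equal(one_gene$auc, 1.0)
})

test_that("label permutation centers the best-subset AUC near chance", {
  set.seed(16)
  n <- 154  # 77-scale test cohort after a 50/50 split
  expr <- matrix(rnbinom(8 * n, mu = 100, size = 1 / 0.3), 8,
                 dimnames = list(paste0("g", 1:8), NULL))
  aucs <- vapply(1:6, function(i) {
    labels <- sample(rep(c("ESGC", "LSGC"), each = n / 2))
    idx <- 1:(n / 2); idx_te <- (n / 2 + 1):n
    best <- search_combinations(expr[, idx], expr[, idx_te],
                                labels[idx], labels[idx_te],
                                genes = paste0("g", 1:8),
                                max_size = 3)$best$auc
    best
  }, 1.0)
  # the max over many null subsets sits above 0.5 but stays near chance
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("planted multi-gene signals are recovered by the exhaustive search", {
  hits <- vapply(1:6, function(s) {
    set.seed(700 + s)
    n <- 260
    labels <- rep(c("ESGC", "LSGC"), each = n / 2)
    genes <- paste0("g", 1:10)
    mu <- matrix(90, 10, n, dimnames = list(genes, NULL))
    mu[1:6, labels == "LSGC"] <- 90 * 2^0.6  # six moderate planted signals
    expr <- matrix(rnbinom(10 * n, mu = mu, size = 1 / 0.35), 10,
                   dimnames = list(genes, NULL))
    sp <- sample(n, round(0.7 * n))
    res <- search_combinations(expr[, sp], expr[, -sp],
                               labels[sp], labels[-sp], genes = genes)
    sum(paste0("g", 1:6) %in% res$results$subset[[1]]) >= 4
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})
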