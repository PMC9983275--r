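sim_surv <- function(n, beta, seed, shape = 1.2, scale = 1500) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  t_event <- scale * (-log(runif(n)) / exp(beta * x))^(1 / shape)
  cens <- runif(n, 200, 4000)
  list(x = x, time = pmax(1, pmin(t_event, cens)),
       event = as.integer(t_event <= cens))
}

test_that("Cox coefficient bias is under 10% at n = 1000", {
  err <- vapply(1:10, function(s) {
    d <- sim_surv(1000, log(2), seed = 100 + s)
    df <- data.frame(x = d$x)
    fit <- survival::coxph(survival::Surv(d$time, d$event) ~ x, data = df,
                           ties = "efron")
    coef(fit)[["x"]]
  }, 1.0)
  expect_lt(abs(mean(err) - log(2)), 0.1 * log(2))
  # and the packaged fit agrees with coxph on the same standardized data
  d <- sim_surv(400, log(2), seed = 77)
  expr <- rbind(g1 = round(50 * (1 + d$x) + rpois(400, 3)))
  ours <- fit_cox(expr, d$time, d$event)
  z <- (log2(expr["g1", ] + 1) - ours$scale$center[["g1"]]) /
    ours$scale$sd[["g1"]]
  ref <- survival::coxph(survival::Surv(d$time, d$event) ~ z, ties = "efron")
  expect_equal(unname(ours$coefficients), unname(coef(ref)), tolerance = 1e-8)
})

test_that("confidence intervals cover a null coefficient about 95% of the time", {
  cover <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    n <- 150
    t_event <- 1500 * (-log(runif(n)))^(1 / 1.2)
    cens <- runif(n, 200, 4000)
    expr <- rbind(g1 = rnbinom(n, mu = 100, size = 2))
    fit <- fit_cox(expr, pmax(1, pmin(t_event, cens)),
                   as.integer(t_event <= cens))
    fit$hr$hr_low[1] <= 1 && 1 <= fit$hr$hr_high[1]
  }, TRUE)
  expect_gte(mean(cover), 0.85)
})

test_that("degenerate expression is rejected or dropped with a warning", {
  d <- sim_surv(100, 0, seed = 5)
  flat <- rbind(g1 = rep(7, 100))
  expect_error(suppressWarnings(fit_cox(flat, d$time, d$event)), "variance")
  two <- rbind(g1 = rep(7, 100), g2 = rpois(100, 50))
  expect_warning(fit <- fit_cox(two, d$time, d$event), "zero-variance")
  expect_equal(fit$genes, "g2")
})

test_that("risk scores are linear and respect the cutoff rule", {
  d <- sim_surv(200, log(2), seed = 9)
  expr <- rbind(g1 = round(100 * 2^d$x + rpois(200, 5)),
                g2 = rnbinom(200, mu = 80, size = 2))
  fit <- fit_cox(expr, d$time, d$event)
  # linear-combination route: score(a * x) = a * score(x) on the model scale
  z <- matrix(rnorm(2 * 10), nrow = 2,
              dimnames = list(c("g1", "g2"), NULL))
  expect_equal(risk_score(fit, 3 * z, rescale = FALSE),
               3 * risk_score(fit, z, rescale = FALSE))
  expect_equal(risk_score(fit, matrix(0, 2, 4,
                                      dimnames = list(c("g1", "g2"), NULL)),
                          rescale = FALSE),
               rep(0, 4))
  # stratification: high iff score > cutoff; median cutoff splits evenly
  st <- risk_stratify(fit, expr, d$time, d$event)
  expect_equal(sum(st$scores$group == "high"),
               sum(st$scores$score > fit$cutoff))
  expect_lte(abs(sum(st$scores$group == "high") - 100), 2)
  # missing gene: hard error
  expect_error(risk_score(fit, expr[1, , drop = FALSE]), "lacks")
})

test_that("mean and numeric cutoffs are honored", {
  d <- sim_surv(150, log(2), seed = 10)
  expr <- rbind(g1 = round(100 * 2^d$x + rpois(150, 5)),
                g2 = rnbinom(150, mu = 80, size = 2))
  f_mean <- fit_cox(expr, d$time, d$event, cutoff = "mean")
  f_num <- fit_cox(expr, d$time, d$event, cutoff = 0.25)
  s <- risk_score(f_mean, expr)
  expect_equal(f_mean$cutoff, mean(s))
  expect_equal(f_num$cutoff, 0.25)
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(4)
  d <- sim_surv(120, log(3), seed = 12)
  expr <- rbind(g1 = round(60 * 2^d$x) + rpois(120, 3),
                g2 = rnbinom(120, mu = 50, size = 2))
  fit <- fit_cox(expr, d$time, d$event)
  tt <- sort(sample(1:500, 60))  # distinct uncensored times
  st <- risk_stratify(fit, expr[, 1:60], time = tt, event = rep(1, 60))
  for (grp in unique(st$km$group)) {
    k <- st$km[st$km$group == grp, ]
    n_g <- k$n_risk[1]
    emp <- vapply(k$time, function(t0) mean(tt[st$scores$group == grp] > t0),
                  1.0)
    expect_equal(k$survival, emp, tolerance = 1e-10)
    expect_true(all(diff(k$survival) <= 1e-12))
  }
  expect_equal(st$km$survival[1] <= 1, TRUE)
})

test_that("log-rank p is invariant under group-label swap", {
  d <- sim_surv(200, log(2.5), seed = 15)
  g <- factor(ifelse(d$x == 1, "high", "low"), levels = c("low", "high"))
  s1 <- survival::survdiff(survival::Surv(d$time, d$event) ~ g)
  g2 <- factor(ifelse(d$x == 1, "low", "high"), levels = c("low", "high"))
  s2 <- survival::survdiff(survival::Surv(d$time, d$event) ~ g2)
  expect_equal(s1$chisq, s2$chisq)
})

test_that("strong planted hazard separates risk groups by log-rank", {
  ps <- vapply(1:5, function(s) {
    cfg <- simulate_config(
      seed = 500 + s,
      hazard_coefficients = setNames(rep(0.6, 7),
                                     unlist(default_module_spec()$families)))
    sim <- generate_cohort(cfg)
    mir <- normalize_counts(sim$cohort$counts$mirna)$normalized
    genes <- sim$truth$module$mirnas$gene_id
    fit <- fit_cox(mir[genes, ], sim$cohort$samples$survival_time,
                   sim$cohort$samples$event)
    st <- risk_stratify(fit, mir[genes, ],
                        sim$cohort$samples$survival_time,
                        sim$cohort$samples$event)
    st$logrank$p
  }, 1.0)
  expect_gte(mean(ps < 0.05), 0.9)
})

test_that("chi-square association reproduces the hand-computed 2x2 example", {
  tab <- matrix(c(36, 53, 101, 67), nrow = 2, byrow = TRUE)
  res <- chi_square_table(tab)
  expect_equal(res$statistic, 8.2702, tolerance = 1e-4)
  expect_equal(round(res$p_value, 3), 0.004)
  expect_equal(res$df, 1)
})

test_that("chi-square associations are calibrated and detect confounding", {
  set.seed(20)
  p_null <- replicate(400, {
    expr <- rnorm(120)
    cat <- sample(c("A", "B"), 120, replace = TRUE)
    chi_square_association(expr, cat)$p_value
  })
  expect_gt(mean(p_null < 0.05), 0.02)
  expect_lt(mean(p_null < 0.05), 0.08)
  # perfectly confounded: High <=> level A
  expr <- c(rnorm(50, 10), rnorm(50, -10))
  cat <- rep(c("A", "B"), each = 50)
  res <- chi_square_association(expr, cat)
  expect_lt(res$p_value, 1e-15)
  # >2 levels: uncorrected Pearson, df = r - 1
  res3 <- chi_square_association(rnorm(90), rep(c("A", "B", "C"), 30))
  expect_equal(res3$df, 2)
})

test_that("association_table flags the planted clinical links", {
  sim <- generate_cohort(simulate_config(seed = 50))
  nrm <- normalized_classes(sim$cohort)
  expr <- do.call(rbind, nrm)
  genes <- sim$truth$module$mirnas$gene_id
  tab <- association_table(expr, sim$cohort$samples, genes,
                           c("age_group", "gender", "grade"))
  by_cat <- split(tab$p_value, tab$category)
  # linked categories should show far smaller p than the null one on average
  expect_lt(median(by_cat$age_group), median(by_cat$gender))
})
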