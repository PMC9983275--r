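# Synthetic cohort generator: NB counts with Gaussian-copula dependence,
# planted stage effects, miRNA-target anti-correlation, family co-expression,
# proportional-hazards survival and plantable clinical associations.

#' Describe the planted miRNA families and their targets
#'
#' A module specification names two (or more) miRNA families, the lncRNA and
#' mRNA targets they regulate, and the strength of the planted dependence.
#' Dependence is injected through shared Gaussian latent factors: miRNAs of a
#' family load on a family factor (plus a module-wide factor shared across
#' families), and each target is anti-coupled to the standardized mean latent
#' of its regulators with rank correlation `rho_plant`.
#'
#' @param families named list of character vectors; each element is a family
#'   (e.g. `famA`) listing its member miRNA ids.
#' @param targets data frame with columns `target_id`, `class`
#'   (`"mrna"`/`"lncrna"`) and a list-column `regulators` of miRNA id vectors.
#' @param rho_plant target Spearman correlation (in `[-1, 0]`) between each
#'   target and the standardized mean latent of its regulators.
#' @param family_cor extra within-family latent correlation on top of
#'   `module_cor`.
#' @param module_cor latent correlation shared by all module miRNAs across
#'   families (the two families are positively co-expressed).
#' @param mirna_lfc,target_lfc planted log2 fold changes (late vs early stage)
#'   for module miRNAs and their targets.
#' @return a list of class `module_spec`.
#' @export
module_spec <- function(families,
                        targets,
                        rho_plant = -0.6,
                        family_cor = 0.35,
                        module_cor = 0.35,
                        mirna_lfc = -1,
                        target_lfc = 1) {
  stopifnot(is.list(families), length(families) >= 1L)
  targets <- tibble::as_tibble(targets)
  stopifnot(all(c("target_id", "class", "regulators") %in% names(targets)))
  if (rho_plant > 0) {
    stop("`rho_plant` must be <= 0: the planted miRNA-target dependence is negative.")
  }
  stopifnot(rho_plant >= -1, family_cor >= 0, module_cor >= 0,
            family_cor + module_cor < 1)
  all_mirnas <- unlist(families, use.names = FALSE)
  if (anyDuplicated(all_mirnas)) stop("a miRNA cannot belong to two families")
  bad <- setdiff(unlist(targets$regulators), all_mirnas)
  if (length(bad) > 0) {
    stop("regulators not in any family: ", paste(bad, collapse = ", "))
  }
  structure(
    list(families = families, targets = targets, rho_plant = rho_plant,
         family_cor = family_cor, module_cor = module_cor,
         mirna_lfc = mirna_lfc, target_lfc = target_lfc),
    class = "module_spec"
  )
}

#' Default planted module: two miRNA families with shared targets
#'
#' Mirrors the structure the pipeline is designed to recover: a five-member
#' and a two-member miRNA family, two lncRNAs and five mRNAs regulated by both
#' families (the module proper), plus six decoy mRNAs regulated by a single
#' family which the both-family extraction rule must exclude.
#'
#' @inheritParams module_spec
#' @return a `module_spec`.
#' @export
default_module_spec <- function(rho_plant = -0.6, family_cor = 0.35,
                                module_cor = 0.35, mirna_lfc = -1,
                                target_lfc = 1) {
  famA <- paste0("mir-A", 1:5)
  famB <- paste0("mir-B", 1:2)
  both <- c(famA, famB)
  targets <- tibble::tibble(
    target_id  = c("lnc-M1", "lnc-M2", paste0("m-M", 1:5), paste0("m-S", 1:6)),
    class      = c("lncrna", "lncrna", rep("mrna", 11)),
    regulators = c(list(both, both), rep(list(both), 5),
                   rep(list(famA), 3), rep(list(famB), 3))
  )
  module_spec(families = list(famA = famA, famB = famB), targets = targets,
              rho_plant = rho_plant, family_cor = family_cor,
              module_cor = module_cor, mirna_lfc = mirna_lfc,
              target_lfc = target_lfc)
}

#' Simulation configuration
#'
#' Bundles every knob of the cohort generator. Defaults emulate the kind of
#' two-arm tumor cohort the pipeline targets: 129 early-stage and 128
#' late-stage samples, negative-binomial counts around log-normal gene
#' baselines with per-sample depth variation, a planted two-family module
#' (see [default_module_spec()]), sparse background differential expression,
#' Weibull survival whose log-hazard is a linear predictor of the module
#' miRNAs, and clinical categories thresholded from gene-linked latents.
#'
#' @param n_early,n_late samples per stage group (early = ESGC, late = LSGC).
#' @param n_mirna,n_mrna,n_lncrna total genes per RNA class (module genes
#'   included).
#' @param module a [module_spec()].
#' @param de_background list(frac, lfc): fraction of non-module genes per
#'   class given a +/-`lfc` stage effect (sign alternating).
#' @param nb_dispersion NB dispersion alpha (var = mu + alpha mu^2), global.
#' @param depth_sd log-normal sd of per-sample sequencing-depth factors.
#' @param evidence_sensitivity probability a planted regulator-target pair is
#'   present in the prediction-evidence table.
#' @param evidence_specificity probability a non-pair is absent from it.
#' @param survival_baseline list(shape, scale) of the Weibull baseline, days.
#' @param hazard_coefficients named numeric, log-hazard per standard deviation
#'   of log2 module-miRNA expression; default 0.35 for every module miRNA.
#' @param censor_range administrative censoring drawn uniformly (days).
#' @param clinical list of clinical-category specs; each a list with `name`,
#'   `probs` (level proportions), optional `linked` (miRNA ids) and
#'   `strength` in [0, 1) controlling the planted association.
#' @param seed integer; the same seed yields bit-identical cohorts.
#' @return a list of class `sim_config`.
#' @export
simulate_config <- function(n_early = 129L, n_late = 128L,
                            n_mirna = 120L, n_mrna = 1000L, n_lncrna = 100L,
                            module = default_module_spec(),
                            de_background = list(frac = 0.05, lfc = 1),
                            nb_dispersion = 0.4,
                            depth_sd = 0.25,
                            evidence_sensitivity = 0.9,
                            evidence_specificity = 0.995,
                            survival_baseline = list(shape = 1.2, scale = 1800),
                            hazard_coefficients = NULL,
                            censor_range = c(365, 2920),
                            clinical = default_clinical_spec(),
                            seed = 1L) {
  counts <- c(n_early = n_early, n_late = n_late, n_mirna = n_mirna,
              n_mrna = n_mrna, n_lncrna = n_lncrna)
  if (any(counts < 1)) stop("all cohort and gene counts must be >= 1")
  stopifnot(inherits(module, "module_spec"),
            nb_dispersion > 0, depth_sd >= 0,
            evidence_sensitivity >= 0, evidence_sensitivity <= 1,
            evidence_specificity >= 0, evidence_specificity <= 1,
            survival_baseline$shape > 0, survival_baseline$scale > 0)
  mirnas <- unlist(module$families, use.names = FALSE)
  if (is.null(hazard_coefficients)) {
    hazard_coefficients <- stats::setNames(rep(0.35, length(mirnas)), mirnas)
  }
  if (is.null(names(hazard_coefficients)) ||
      !all(names(hazard_coefficients) %in% mirnas)) {
    stop("`hazard_coefficients` must be named by module miRNAs")
  }
  n_cls <- c(mirna = n_mirna, mrna = n_mrna, lncrna = n_lncrna)
  need <- table(factor(
    c(rep("mirna", length(mirnas)), module$targets$class),
    levels = names(n_cls)))
  if (any(n_cls < as.integer(need))) {
    stop("class sizes too small to hold the planted module genes")
  }
  structure(
    list(n_early = as.integer(n_early), n_late = as.integer(n_late),
         n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
         n_lncrna = as.integer(n_lncrna),
         module = module, de_background = de_background,
         nb_dispersion = nb_dispersion, depth_sd = depth_sd,
         evidence_sensitivity = evidence_sensitivity,
         evidence_specificity = evidence_specificity,
         survival_baseline = survival_baseline,
         hazard_coefficients = hazard_coefficients,
         censor_range = censor_range, clinical = clinical,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default clinical-category specification
#'
#' Two planted associations (age group and histological grade linked to the
#' module miRNAs) and one null category (gender), so association tables have
#' both signal and calibration rows.
#'
#' @return list of category specs for [simulate_config()].
#' @export
default_clinical_spec <- function() {
  list(
    list(name = "age_group", levels = c("<=60", ">60"),
         probs = c(0.35, 0.65), linked = TRUE, strength = 0.4),
    list(name = "gender", levels = c("female", "male"),
         probs = c(0.4, 0.6), linked = FALSE, strength = 0),
    list(name = "grade", levels = c("G1", "G2", "G3"),
         probs = c(0.05, 0.3, 0.65), linked = TRUE, strength = 0.35)
  )
}

# Spearman -> Pearson correlation of the underlying Gaussian copula.
rho_to_latent <- function(rho_s) 2 * sin(pi * rho_s / 6)
latent_to_rho <- function(rho_l) (6 / pi) * asin(rho_l / 2)

# Latent covariance between two module miRNAs implied by the factor model.
.mirna_latent_cov <- function(id1, id2, fam_of, spec) {
  if (id1 == id2) return(1)
  v <- spec$module_cor
  if (fam_of[[id1]] == fam_of[[id2]]) v <- v + spec$family_cor
  v
}

#' Generate a synthetic expression cohort with ground truth
#'
#' Draws NB(mu, dispersion) counts around log-normal gene baselines through a
#' Gaussian copula. Module miRNAs share family/module latent factors (positive
#' co-expression); each planted target is anti-coupled to the standardized
#' mean latent of its regulators so its rank correlation with that mean is
#' approximately `rho_plant`. Planted differential genes have their mean
#' multiplied by `2^lfc` in the late-stage group. Survival times are Weibull
#' with log-hazard equal to the hazard coefficients times standardized log2
#' module-miRNA expression; clinical categories are thresholded gene-linked
#' latents.
#'
#' @param config a [simulate_config()] object.
#' @return list with `cohort` (class `expression_cohort`: `counts` = named
#'   list of genes-x-samples integer matrices, `samples` = tibble of
#'   annotations) and `truth` (class `ground_truth`: planted DE table, planted
#'   regulator-target edges, per-pair expected Spearman, module membership,
#'   hazard coefficients).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  spec <- config$module
  n <- config$n_early + config$n_late
  late <- rep(c(0L, 1L), c(config$n_early, config$n_late))
  sample_ids <- sprintf("S%03d", seq_len(n))

  ids <- list(
    mirna  = .gene_ids(unlist(spec$families, use.names = FALSE),
                       config$n_mirna, "mir"),
    mrna   = .gene_ids(spec$targets$target_id[spec$targets$class == "mrna"],
                       config$n_mrna, "m"),
    lncrna = .gene_ids(spec$targets$target_id[spec$targets$class == "lncrna"],
                       config$n_lncrna, "lnc")
  )
  fam_of <- stats::setNames(
    rep(names(spec$families), lengths(spec$families)),
    unlist(spec$families, use.names = FALSE))
  module_mirnas <- names(fam_of)

  # --- latent Gaussian layer -------------------------------------------------
  z <- list()
  fac_module <- stats::rnorm(n)
  fac_family <- lapply(spec$families, function(.) stats::rnorm(n))
  vM <- spec$module_cor; vF <- spec$family_cor
  for (m in module_mirnas) {
    z[[m]] <- sqrt(vM) * fac_module +
      sqrt(vF) * fac_family[[fam_of[[m]]]] +
      sqrt(1 - vM - vF) * stats::rnorm(n)
  }
  rho_l <- rho_to_latent(spec$rho_plant)
  couplings <- vector("list", nrow(spec$targets))
  for (i in seq_len(nrow(spec$targets))) {
    tg <- spec$targets$target_id[i]
    regs <- spec$targets$regulators[[i]]
    # analytic sd of the mean regulator latent under the factor model
    cv <- outer(regs, regs,
                Vectorize(function(a, b) .mirna_latent_cov(a, b, fam_of, spec)))
    sd_mean <- sqrt(sum(cv)) / length(regs)
    z_reg <- rowMeans(do.call(cbind, z[regs])) / sd_mean
    z[[tg]] <- rho_l * z_reg + sqrt(max(0, 1 - rho_l^2)) * stats::rnorm(n)
    # implied per-pair latent correlation with each individual regulator
    w <- colSums(cv) / (length(regs) * sd_mean)  # corr(z_reg, z_m)
    couplings[[i]] <- tibble::tibble(
      mirna_id = regs, target_id = tg,
      rho_latent = rho_l * w,
      rho_spearman = latent_to_rho(rho_l * w))
  }
  couplings <- dplyr::bind_rows(couplings)

  # --- per-gene baselines and planted effects --------------------------------
  base_meanlog <- c(mirna = 5.5, mrna = 4.5, lncrna = 3.0)
  base_sdlog <- 1.2
  lfc <- de <- list()
  for (cls in names(ids)) {
    g <- ids[[cls]]
    l <- stats::setNames(numeric(length(g)), g)
    planted <- intersect(g, c(module_mirnas, spec$targets$target_id))
    if (cls == "mirna") l[intersect(planted, module_mirnas)] <- spec$mirna_lfc
    l[intersect(planted, spec$targets$target_id)] <- spec$target_lfc
    bg_pool <- setdiff(g, planted)
    n_bg <- round(config$de_background$frac * length(bg_pool))
    if (n_bg > 0) {
      bg <- sample(bg_pool, n_bg)
      l[bg] <- config$de_background$lfc *
        rep_len(c(1, -1), n_bg)
    }
    lfc[[cls]] <- l
    de[[cls]] <- tibble::tibble(gene_id = names(l)[l != 0], rna_class = cls,
                                lfc = unname(l[l != 0]))
  }

  # --- copula -> NB counts ---------------------------------------------------
  depth <- exp(stats::rnorm(n, 0, config$depth_sd))
  size <- 1 / config$nb_dispersion
  counts <- list()
  for (cls in names(ids)) {
    g <- ids[[cls]]
    base <- exp(stats::rnorm(length(g), base_meanlog[[cls]], base_sdlog))
    mu <- outer(base, depth) * 2^(outer(lfc[[cls]], late))
    zmat <- matrix(stats::rnorm(length(g) * n), nrow = length(g),
                   dimnames = list(g, sample_ids))
    for (pg in intersect(g, names(z))) zmat[pg, ] <- z[[pg]]
    u <- stats::pnorm(zmat)
    u[u > 1 - 1e-12] <- 1 - 1e-12  # keep quantiles finite
    cm <- matrix(stats::qnbinom(u, size = size, mu = mu), nrow = length(g),
                 dimnames = list(g, sample_ids))
    storage.mode(cm) <- "integer"
    counts[[cls]] <- cm
  }

  # --- survival --------------------------------------------------------------
  hc <- config$hazard_coefficients
  expr_h <- log2(counts$mirna[names(hc), , drop = FALSE] + 1)
  zexpr <- t(apply(expr_h, 1, function(r) {
    s <- stats::sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  lp <- as.numeric(crossprod(as.matrix(hc), zexpr))
  shp <- config$survival_baseline$shape
  scl <- config$survival_baseline$scale
  t_event <- scl * (-log(stats::runif(n)) / exp(lp))^(1 / shp)
  t_cens <- stats::runif(n, config$censor_range[1], config$censor_range[2])
  surv_time <- pmax(1, round(pmin(t_event, t_cens)))
  event <- as.integer(t_event <= t_cens)

  # --- clinical categories ---------------------------------------------------
  mod_latent <- scale(Reduce(`+`, z[module_mirnas]))[, 1]
  samples <- tibble::tibble(
    sample_id = sample_ids,
    group = factor(ifelse(late == 1, "LSGC", "ESGC"),
                   levels = c("ESGC", "LSGC")),
    survival_time = as.numeric(surv_time),
    event = event)
  for (cat in config$clinical) {
    s <- if (isTRUE(cat$linked)) cat$strength else 0
    latent <- s * mod_latent + sqrt(1 - s^2) * stats::rnorm(n)
    cuts <- stats::qnorm(cumsum(cat$probs))
    cuts <- c(-Inf, cuts[-length(cuts)], Inf)
    samples[[cat$name]] <- factor(
      cat$levels[findInterval(latent, cuts, rightmost.closed = TRUE)],
      levels = cat$levels)
  }

  cohort <- structure(list(counts = counts, samples = samples),
                      class = "expression_cohort")
  edges <- couplings |>
    dplyr::left_join(
      dplyr::select(spec$targets, "target_id", target_class = "class"),
      by = "target_id") |>
    dplyr::select("mirna_id", "target_id", "target_class")
  module_mrnas <- spec$targets |>
    dplyr::filter(.data$class == "mrna",
                  purrr::map_lgl(.data$regulators, function(r) {
                    length(unique(fam_of[r])) == length(spec$families)
                  })) |>
    dplyr::pull("target_id")
  truth <- structure(
    list(de = dplyr::bind_rows(de),
         edges = edges,
         couplings = couplings,
         module = list(
           mirnas = tibble::tibble(gene_id = module_mirnas,
                                   family = unname(fam_of[module_mirnas])),
           lncrnas = spec$targets$target_id[spec$targets$class == "lncrna"],
           mrnas = module_mrnas),
         hazard = tibble::tibble(gene_id = names(hc), beta = unname(hc))),
    class = "ground_truth")
  list(cohort = cohort, truth = truth)
}

.gene_ids <- function(planted, n_total, prefix) {
  if (length(planted) > n_total) stop("class too small for planted genes")
  c(planted, sprintf("%s-%04d", prefix, seq_len(n_total - length(planted))))
}

#' Generate interaction-prediction evidence tables
#'
#' Emulates target-prediction databases: every planted regulator-target pair
#' enters the evidence with probability `evidence_sensitivity` (mRNA targets
#' get a prediction score drawn uniform(51, 100), i.e. above the usual
#' score-50 filter); every non-pair enters with probability
#' `1 - evidence_specificity` (scores uniform(0, 100)). lncRNA evidence is
#' boolean with a random database source tag.
#'
#' @param truth `ground_truth` from [generate_cohort()].
#' @param config the same [simulate_config()].
#' @param gene_ids optional list with `mirna`, `mrna`, `lncrna` id vectors
#'   defining the non-edge universe; defaults to the ids the config implies.
#' @return list of class `interaction_evidence` with tibbles `mirna_mrna`
#'   (`mirna_id`, `target_id`, `score`) and `mirna_lncrna`
#'   (`mirna_id`, `target_id`, `source`).
#' @export
generate_evidence <- function(truth, config, gene_ids = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 1000003L)
  spec <- config$module
  if (is.null(gene_ids)) {
    gene_ids <- list(
      mirna = .gene_ids(unlist(spec$families, use.names = FALSE),
                        config$n_mirna, "mir"),
      mrna = .gene_ids(spec$targets$target_id[spec$targets$class == "mrna"],
                       config$n_mrna, "m"),
      lncrna = .gene_ids(spec$targets$target_id[spec$targets$class == "lncrna"],
                         config$n_lncrna, "lnc"))
  }
  sens <- config$evidence_sensitivity
  spec_p <- config$evidence_specificity
  one_class <- function(target_class) {
    planted <- truth$edges[truth$edges$target_class == target_class, ]
    keep <- stats::runif(nrow(planted)) < sens
    tp <- planted[keep, c("mirna_id", "target_id")]
    # sample false positives from the non-edge universe
    uni_t <- gene_ids[[target_class]]
    n_pairs <- length(gene_ids$mirna) * length(uni_t)
    n_fp <- stats::rbinom(1, n_pairs - nrow(planted), 1 - spec_p)
    fp <- tibble::tibble(mirna_id = character(), target_id = character())
    if (n_fp > 0) {
      key_planted <- paste(planted$mirna_id, planted$target_id)
      got <- character(0)
      while (length(got) < n_fp) {
        cand <- paste(sample(gene_ids$mirna, n_fp * 2, replace = TRUE),
                      sample(uni_t, n_fp * 2, replace = TRUE))
        got <- utils::head(unique(c(got, setdiff(cand, key_planted))), n_fp)
      }
      parts <- strsplit(got, " ", fixed = TRUE)
      fp <- tibble::tibble(mirna_id = vapply(parts, `[`, "", 1),
                           target_id = vapply(parts, `[`, "", 2))
    }
    list(tp = tp, fp = fp)
  }
  mr <- one_class("mrna")
  mrna_tab <- dplyr::bind_rows(
    dplyr::mutate(mr$tp, score = stats::runif(dplyr::n(), 51, 100)),
    dplyr::mutate(mr$fp, score = stats::runif(dplyr::n(), 0, 100)))
  ln <- one_class("lncrna")
  lnc_tab <- dplyr::bind_rows(ln$tp, ln$fp)
  lnc_tab$source <- if (nrow(lnc_tab) > 0) {
    sample(c("starbase", "lncbase"), nrow(lnc_tab), replace = TRUE)
  } else character(0)
  structure(list(mirna_mrna = mrna_tab, mirna_lncrna = lnc_tab),
            class = "interaction_evidence")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat("<expression_cohort> ", ncol(x$counts$mirna), " samples (",
      sum(x$samples$group == "ESGC"), " ESGC / ",
      sum(x$samples$group == "LSGC"), " LSGC); genes: ",
      paste(sprintf("%s=%d", names(x$counts),
                    vapply(x$counts, nrow, 1L)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", nrow(x$de), " planted DE genes, ",
      nrow(x$edges), " planted regulator-target edges; module: ",
      nrow(x$module$mirnas), " miRNAs / ", length(x$module$lncrnas),
      " lncRNAs / ", length(x$module$mrnas), " mRNAs\n", sep = "")
  invisible(x)
}
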