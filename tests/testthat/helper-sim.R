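# Small simulation configs reused across tests.

# one miRNA per family, one single-regulator target each: the pairwise
# planted Spearman equals rho_plant exactly
pairwise_module <- function(rho_plant, n_targets_per_family = 1) {
  tg <- tibble::tibble(
    target_id = c(sprintf("tgtX-%d", seq_len(n_targets_per_family)),
                  sprintf("tgtY-%d", seq_len(n_targets_per_family))),
    class = "mrna",
    regulators = c(rep(list("mir-X1"), n_targets_per_family),
                   rep(list("mir-Y1"), n_targets_per_family)))
  module_spec(families = list(famA = "mir-X1", famB = "mir-Y1"),
              targets = tg, rho_plant = rho_plant,
              mirna_lfc = 0, target_lfc = 0)
}

small_config <- function(seed, rho_plant = -0.6, n_per_group = 100,
                         module = NULL, ...) {
  simulate_config(
    n_early = n_per_group, n_late = n_per_group,
    n_mirna = 60, n_mrna = 300, n_lncrna = 30,
    module = module %||% pairwise_module(rho_plant),
    de_background = list(frac = 0, lfc = 0),
    seed = seed, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strong planted structure + generous samples: network recovery configs
recovery_config <- function(seed, sens = 1, spec_p = 1) {
  simulate_config(
    n_early = 110, n_late = 110,
    n_mirna = 40, n_mrna = 150, n_lncrna = 20,
    module = default_module_spec(rho_plant = -0.75, family_cor = 0.4,
                                 module_cor = 0.4),
    de_background = list(frac = 0.05, lfc = 1),
    evidence_sensitivity = sens, evidence_specificity = spec_p,
    seed = seed)
}

normalized_classes <- function(cohort) {
  lapply(cohort$counts, function(m) normalize_counts(m)$normalized)
}
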