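# End-to-end cohort pipeline: simulate a cohort of neurons from named
# presets (with across-neuron parameter heterogeneity), extract features,
# screen outliers, and run the group comparison.

#' Simulate a cohort of current-clamp recordings
#'
#' One recording per neuron. Neuron-to-neuron heterogeneity is introduced by
#' jittering the AHP increment `b_ahp` (truncated Gaussian, SD `b_ahp_sd`)
#' and applying a mild coefficient of variation to `g_l` and `c_m`. The
#' default `b_ahp_sd` is calibrated so the induced SD of measured AHP is
#' about 1.5 mV.
#'
#' @param groups Named integer vector of group sizes, names being preset
#'   names (or a list of `list(label, preset, n)` for custom labels).
#' @param seed Integer RNG seed.
#' @param b_ahp_sd Across-neuron SD of `b_ahp`, nS.
#' @param param_cv Coefficient of variation applied to `g_l` and `c_m`.
#' @param protocol A [step_protocol()].
#' @param ground_truth Compute per-neuron ground truth (see
#'   [simulate_current_clamp()]); disable for large power sweeps.
#' @return List of simulation results (each as from
#'   [simulate_current_clamp()]), with per-neuron group labels.
#' @export
simulate_intrinsic_cohort <- function(groups = c(young = 10, old = 12),
                                      seed = 0, b_ahp_sd = PRESET_B_AHP_SD,
                                      param_cv = 0.05,
                                      protocol = step_protocol(),
                                      ground_truth = TRUE) {
  if (is.numeric(groups))
    groups <- lapply(seq_along(groups), function(i)
      list(label = names(groups)[i], preset = names(groups)[i],
           n = groups[[i]]))
  set.seed(seed)
  out <- list()
  for (g in groups) {
    base <- neuron_presets(g$preset)
    for (j in seq_len(g$n)) {
      p <- base
      p$b_ahp <- max(0, rnorm(1, base$b_ahp, b_ahp_sd))
      p$g_l <- base$g_l * max(0.5, rnorm(1, 1, param_cv))
      p$c_m <- base$c_m * max(0.5, rnorm(1, 1, param_cv))
      cell_seed <- sample.int(.Machine$integer.max, 1)
      sim <- simulate_current_clamp(p, protocol, seed = cell_seed,
                                    cell_id = sprintf("%s_%02d", g$label, j),
                                    group = g$label,
                                    ground_truth = ground_truth)
      out[[length(out) + 1L]] <- sim
    }
  }
  out
}

#' Run the intrinsic-excitability group comparison end to end
#'
#' Simulates (or takes) a cohort of recordings, extracts the selected
#' features per neuron, removes QC-excluded cells, applies Grubbs outlier
#' screening per group, and runs the one-way ANOVA with Tukey post hoc on
#' the AHP magnitude.
#'
#' @param cohort Either the output of [simulate_intrinsic_cohort()] or a
#'   list of [recording()]s.
#' @param feature Feature column to test (default `"ahp_mv"`).
#' @param alpha Grubbs screening level.
#' @param features Feature families passed to [extract_all()].
#' @return List with `features` (per-cell table), `screen` (Grubbs report),
#'   `anova` ([one_way_anova()] result) and `tukey` ([tukey_hsd()] result).
#' @export
run_excitability_pipeline <- function(cohort, feature = "ahp_mv",
                                      alpha = 0.05, features = "ahp") {
  recs <- lapply(cohort, function(x)
    if (inherits(x, "recording")) x else x$recording)
  feats <- do.call(rbind, lapply(recs, extract_all, features = features))
  usable <- feats[!feats$excluded & !is.na(feats[[feature]]), , drop = FALSE]
  screened <- apply_grubbs(usable, feature, alpha = alpha)
  list(features = feats,
       screen = attr(screened, "screen"),
       anova = one_way_anova(screened, feature),
       tukey = tukey_hsd(screened, feature))
}
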