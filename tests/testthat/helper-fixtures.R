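# Small configs and hand-built tables shared across tests.

tiny_config <- function(metabolites = c("spermidine", "acetoacetate"),
                        effects = NULL, noise_cv = 0, seed = 42, ...) {
  simulation_config(
    metabolites = metabolites, effects = effects, noise_cv = noise_cv,
    standard_noise_cv = if (noise_cv == 0) 0 else 0.02,
    experiment_cv = if (noise_cv == 0) 0 else 0.05,
    seed = seed, ...
  )
}

# Minimal hand-built peak table: helper takes rows of
# (metabolite, condition, compartment, timepoint, replicate, experiment, area)
# and appends one standard row per sample.
manual_peaks <- function(rows, spike = 100, standard_id = "lamivudine") {
  tab <- dplyr::mutate(
    rows,
    sample_id = paste("E", experiment, condition, compartment,
                      timepoint_h, "r", replicate, sep = "_")
  )
  std <- dplyr::distinct(
    tab, sample_id, condition, compartment, timepoint_h, replicate,
    experiment
  )
  std$metabolite_id <- standard_id
  std$area <- spike
  out <- dplyr::bind_rows(tab, std)
  validate_peak_table(out, standard_id = standard_id)
}

expected_signature_directions <- function() {
  sig <- metr_signature_effects()
  stats::setNames(ifelse(sig$anchor_end < sig$anchor_start, "down", "up"),
                  sig$metabolite_id)
}

# TRUE when one simulated dataset's 48 h fingerprint contains every
# signature metabolite with its injected direction.
signature_recovered <- function(fp) {
  want <- expected_signature_directions()
  idx <- match(names(want), fp$metabolite_id)
  !anyNA(idx) && all(fp$direction[idx] == want)
}
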