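#' Configuration for a simulated LC/MS metabolite profiling study
#'
#' Builds and validates the configuration object consumed by
#' [simulate_experiment()]. The default design mirrors a methionine
#' restriction time course in cultured cells: two conditions (`met_plus`,
#' `met_minus`), two compartments (`cells` = pellet, `media` = supernatant),
#' five timepoints (24--120 h in 24 h steps), three replicates per condition
#' and four independent experiments, with a constant external-standard spike
#' in every sample and fresh-medium reference samples per experiment.
#'
#' Measurement noise is multiplicative log-normal on peak areas (areas are
#' positive and MS intensity noise is CV-stable); the log-normal factors are
#' mean-one so that configured effects are recovered in expectation.
#' Condition effects are specified as anchor relative levels (percent of
#' control) at the first and last timepoints and interpolated log-linearly
#' in between, giving smooth monotone trajectories.
#'
#' @param metabolites Character vector of metabolite ids, or an annotation
#'   tibble with a `metabolite_id` column (e.g. [metabolite_catalog()]).
#' @param baseline Named numeric vector of baseline peak areas (> 0) per
#'   metabolite; unnamed scalar recycles. Default: deterministic spread of
#'   area magnitudes across the catalog.
#' @param standard_id Id of the spiked external standard (default
#'   `"lamivudine"`); must not collide with a metabolite id.
#' @param spike External-standard spike area (> 0).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise on metabolite areas (fraction, >= 0).
#' @param standard_noise_cv CV of the standard's own area (fraction, >= 0).
#' @param experiment_cv CV of a per-(experiment, metabolite) baseline
#'   perturbation, making cross-experiment averaging non-trivial.
#' @param effects Tibble with columns `metabolite_id`, `condition`,
#'   `compartment`, `anchor_start`, `anchor_end`: relative level in percent
#'   of control at the first and last timepoint. Unlisted combinations
#'   default to 100 at all times (no effect); `met_plus` defaults to 100.
#' @param timepoints Strictly increasing numeric vector of sampling times in
#'   hours.
#' @param replicates Replicates per condition x compartment x timepoint per
#'   experiment (>= 1).
#' @param experiments Number of independent experiments (>= 1).
#' @param seed Integer random seed.
#' @return A validated `sim_config` list.
#' @seealso [metr_signature_config()] for a ready-made methionine
#'   restriction signature.
#' @export
simulation_config <- function(metabolites = metabolite_catalog(),
                              baseline = NULL,
                              standard_id = "lamivudine",
                              spike = 1000,
                              noise_cv = 0.1,
                              standard_noise_cv = 0.02,
                              experiment_cv = 0.05,
                              effects = NULL,
                              timepoints = c(24, 48, 72, 96, 120),
                              replicates = 3,
                              experiments = 4,
                              seed = 1L) {
  if (is.data.frame(metabolites)) {
    metabolites <- unique(metabolites$metabolite_id)
  }
  metabolites <- as.character(metabolites)
  if (length(metabolites) == 0 || anyNA(metabolites)) {
    abort("invalid config field `metabolites`: need at least one non-NA id")
  }
  if (anyDuplicated(metabolites)) {
    metabolites <- unique(metabolites)
  }
  if (standard_id %in% metabolites) {
    abort("invalid config field `standard_id`: collides with a metabolite id")
  }
  if (is.null(baseline)) {
    # deterministic spread over ~2 orders of magnitude, keyed to catalog order
    baseline <- stats::setNames(
      100 * 1.6^(seq_along(metabolites) %% 8), metabolites
    )
  } else if (length(baseline) == 1 && is.null(names(baseline))) {
    baseline <- stats::setNames(rep(baseline, length(metabolites)), metabolites)
  }
  if (!all(metabolites %in% names(baseline))) {
    abort("invalid config field `baseline`: missing values for some metabolites")
  }
  baseline <- baseline[metabolites]
  check_pos <- function(x, field, strict = TRUE) {
    bad <- !is.finite(x) | (if (strict) x <= 0 else x < 0)
    if (any(bad)) {
      abort(sprintf(
        "invalid config field `%s`: must be %s", field,
        if (strict) "strictly positive" else "non-negative"
      ))
    }
  }
  check_pos(baseline, "baseline")
  check_pos(spike, "spike")
  check_pos(noise_cv, "noise_cv", strict = FALSE)
  check_pos(standard_noise_cv, "standard_noise_cv", strict = FALSE)
  check_pos(experiment_cv, "experiment_cv", strict = FALSE)
  if (length(timepoints) < 1 || any(diff(timepoints) <= 0)) {
    abort("invalid config field `timepoints`: must be strictly increasing")
  }
  if (replicates < 1) abort("invalid config field `replicates`: must be >= 1")
  if (experiments < 1) abort("invalid config field `experiments`: must be >= 1")

  effects <- validate_effects(effects, metabolites)

  structure(
    list(
      metabolites = metabolites, baseline = baseline,
      standard_id = standard_id, spike = spike,
      noise_cv = noise_cv, standard_noise_cv = standard_noise_cv,
      experiment_cv = experiment_cv, effects = effects,
      conditions = .cond_levels, compartments = .comp_levels,
      timepoints = timepoints, replicates = as.integer(replicates),
      experiments = as.integer(experiments), seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

validate_effects <- function(effects, metabolites) {
  if (is.null(effects)) {
    return(tibble(
      metabolite_id = character(), condition = character(),
      compartment = character(), anchor_start = numeric(),
      anchor_end = numeric()
    ))
  }
  effects <- as_tibble(effects)
  needed <- c("metabolite_id", "condition", "compartment",
              "anchor_start", "anchor_end")
  missing_cols <- setdiff(needed, names(effects))
  if (length(missing_cols)) {
    abort(paste0("invalid config field `effects`: missing column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(effects$metabolite_id %in% metabolites)) {
    abort("invalid config field `effects`: unknown metabolite id")
  }
  if (!all(effects$condition %in% .cond_levels)) {
    abort("invalid config field `effects`: condition must be met_plus/met_minus")
  }
  if (!all(effects$compartment %in% .comp_levels)) {
    abort("invalid config field `effects`: compartment must be cells/media")
  }
  if (any(!is.finite(effects$anchor_start) | effects$anchor_start <= 0) ||
      any(!is.finite(effects$anchor_end) | effects$anchor_end <= 0)) {
    abort("invalid config field `effects`: anchors must be strictly positive")
  }
  effects
}

#' Default methionine-restriction signature configuration
#'
#' A [simulation_config()] whose injected condition effects follow the
#' directions characteristic of methionine restriction in L929 fibroblast
#' pellets: metabolites whose synthesis draws on methionine or its sulphur
#' (spermidine, creatine, carnitine, GSSG, homocysteine, homoserine, SAH)
#' fall, as does pantothenate; the products SAM and creatinine rise, as do
#' acetoacetate (lipid catabolism) and UDP-glucose (carbohydrate storage);
#' ATP and ADP both fall by the last day, ATP more steeply so the ADP/ATP
#' ratio rises. The magnitudes are package defaults, not measured values:
#' they are sized so that at the default design (3 replicates x 4
#' experiments) and 10% measurement CV every component separates at 48 h
#' with per-component power above 0.998 (pooled t, alpha 0.05), i.e. the
#' signature is reliably recoverable under its own stated noise level.
#'
#' @param ... Passed on to [simulation_config()] (e.g. `noise_cv`, `seed`).
#' @return A `sim_config` with the signature `effects` table attached.
#' @export
metr_signature_config <- function(...) {
  simulation_config(effects = metr_signature_effects(), ...)
}

#' Injected effect table of the methionine-restriction signature
#'
#' @return Tibble of `met_minus` cell-pellet anchors (percent of control at
#'   24 h and 120 h) used by [metr_signature_config()].
#' @export
metr_signature_effects <- function() {
  tibble::tribble(
    ~metabolite_id, ~anchor_start, ~anchor_end,
    "spermidine",     100,  30,
    "creatine",       100,  35,
    "carnitine",      100,  35,
    "GSSG",           100,  30,
    "homocysteine",   100,  30,
    "homoserine",     100,  35,
    "SAH",            100,  35,
    "pantothenate",   100,  20,
    "acetoacetate",   100, 300,
    "SAM",            100, 250,
    "creatinine",     100, 250,
    "UDP-glucose",    100, 250,
    "ATP",            100,  20,
    "ADP",            100,  40
  ) |>
    mutate(condition = "met_minus", compartment = "cells", .before = 1) |>
    select("metabolite_id", "condition", "compartment",
           "anchor_start", "anchor_end")
}

# True relative level (fraction of control) for every metabolite x condition
# x compartment x timepoint; log-linear interpolation between the anchors.
effect_grid <- function(config) {
  grid <- tidyr::expand_grid(
    metabolite_id = config$metabolites,
    condition = config$conditions,
    compartment = config$compartments,
    timepoint_h = config$timepoints
  )
  t0 <- config$timepoints[1]
  t1 <- config$timepoints[length(config$timepoints)]
  span <- if (t1 > t0) t1 - t0 else 1
  grid |>
    left_join(config$effects,
              by = c("metabolite_id", "condition", "compartment")) |>
    mutate(
      anchor_start = coalesce(.data$anchor_start, 100),
      anchor_end = coalesce(.data$anchor_end, 100),
      effect = .data$anchor_start / 100 *
        (.data$anchor_end / .data$anchor_start)^((.data$timepoint_h - t0) / span)
    ) |>
    select(-"anchor_start", -"anchor_end")
}

#' Simulate a full multi-experiment peak-area table
#'
#' Generates one long-format peak table covering the whole design of
#' `config`: for every experiment, condition, compartment, timepoint and
#' replicate, one area per metabolite plus one external-standard row, and a
#' set of fresh-medium reference samples (condition `medium_control`,
#' timepoint 0) per experiment that anchor the media percent scale
#' downstream. Areas are
#' `baseline x experiment_factor x effect(condition, compartment, t) x exp(eps)`
#' with mean-one log-normal `exp(eps)`; the standard is
#' `spike x exp(eps_std)`. The generating effect levels are returned
#' alongside as ground truth.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return A `metr_sim` list: `peaks` (tibble with columns `metabolite_id`,
#'   `sample_id`, `condition`, `compartment`, `timepoint_h`, `replicate`,
#'   `experiment`, `area`), `truth` (tibble with the true `effect_percent`
#'   per metabolite x condition x compartment x timepoint), and `config`.
#' @examples
#' sim <- simulate_experiment(simulation_config(
#'   metabolites = c("spermidine", "ATP"), noise_cv = 0, seed = 7
#' ))
#' head(sim$peaks)
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by simulation_config()")
  }
  set.seed(config$seed)
  n_met <- length(config$metabolites)

  # per-(experiment, metabolite) baseline perturbation
  sig_e <- lognormal_sigma(config$experiment_cv)
  exp_factor <- matrix(
    exp(stats::rnorm(config$experiments * n_met, -sig_e^2 / 2, sig_e)),
    nrow = config$experiments, ncol = n_met,
    dimnames = list(NULL, config$metabolites)
  )

  samples <- tidyr::expand_grid(
    experiment = seq_len(config$experiments),
    condition = config$conditions,
    compartment = config$compartments,
    timepoint_h = config$timepoints,
    replicate = seq_len(config$replicates)
  )
  refs <- tidyr::expand_grid(
    experiment = seq_len(config$experiments),
    condition = .medium_control,
    compartment = "media",
    timepoint_h = 0,
    replicate = seq_len(config$replicates)
  )
  samples <- bind_rows(samples, refs) |>
    mutate(sample_id = sprintf(
      "E%d_%s_%s_t%03d_r%d", .data$experiment, .data$condition,
      .data$compartment, .data$timepoint_h, .data$replicate
    ))

  eff <- effect_grid(config)
  rows <- tidyr::expand_grid(samples, metabolite_id = config$metabolites) |>
    left_join(eff, by = c("metabolite_id", "condition", "compartment",
                          "timepoint_h")) |>
    mutate(effect = coalesce(.data$effect, 1)) # medium_control: no effect

  sig <- lognormal_sigma(config$noise_cv)
  noise <- exp(stats::rnorm(nrow(rows), -sig^2 / 2, sig))
  rows <- rows |>
    mutate(
      area = config$baseline[.data$metabolite_id] *
        exp_factor[cbind(.data$experiment,
                         match(.data$metabolite_id, config$metabolites))] *
        .data$effect * noise
    )

  sig_s <- lognormal_sigma(config$standard_noise_cv)
  std <- samples |>
    mutate(
      metabolite_id = config$standard_id,
      area = config$spike *
        exp(stats::rnorm(nrow(samples), -sig_s^2 / 2, sig_s))
    )

  cols <- c("metabolite_id", "sample_id", "condition", "compartment",
            "timepoint_h", "replicate", "experiment", "area")
  peaks <- bind_rows(select(rows, all_of(cols)), select(std, all_of(cols))) |>
    arrange(.data$experiment, .data$condition, .data$compartment,
            .data$timepoint_h, .data$replicate, .data$metabolite_id)

  truth <- eff |>
    mutate(effect_percent = 100 * .data$effect) |>
    select(-"effect")

  structure(list(peaks = peaks, truth = truth, config = config),
            class = "metr_sim")
}

lognormal_sigma <- function(cv) sqrt(log(1 + cv^2))

#' @export
print.metr_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated LC/MS study: %d metabolites (+ standard '%s'), %d experiments, %d samples\n",
    length(x$config$metabolites), x$config$standard_id,
    x$config$experiments, length(unique(x$peaks$sample_id))
  ))
  invisible(x)
}

#' Configuration for a simulated crystal-violet plate
#'
#' @param means Named numeric vector of true mean OD-595 per group
#'   (non-negative); names are the group labels.
#' @param sd Additive OD noise standard deviation (>= 0), scalar or one per
#'   group.
#' @param wells Wells per group (>= 1).
#' @param seed Integer random seed.
#' @return A validated `plate_config` list.
#' @export
plate_config <- function(means, sd = 0, wells = 3, seed = 1L) {
  if (is.null(names(means)) || any(!nzchar(names(means)))) {
    abort("invalid config field `means`: must be a named vector of group ODs")
  }
  if (any(!is.finite(means) | means < 0)) {
    abort("invalid config field `means`: ODs must be non-negative")
  }
  if (any(!is.finite(sd) | sd < 0)) {
    abort("invalid config field `sd`: must be non-negative")
  }
  if (wells < 1) abort("invalid config field `wells`: must be >= 1")
  sd <- rep_len(sd, length(means))
  structure(
    list(means = means, sd = sd, wells = as.integer(wells),
         seed = as.integer(seed)),
    class = "plate_config"
  )
}

#' Simulate crystal-violet OD-595 readings
#'
#' Draws `wells` normal readings per group around the configured true means
#' (truncated at zero; ODs cannot be negative). The true means are attached
#' as the `truth` attribute.
#'
#' @param config A `plate_config`.
#' @return Tibble with columns `well`, `group`, `od595`.
#' @examples
#' simulate_plate(plate_config(c(untreated = 0.6, met_minus = 0.3), sd = 0))
#' @export
simulate_plate <- function(config) {
  if (!inherits(config, "plate_config")) {
    abort("`config` must be created by plate_config()")
  }
  set.seed(config$seed)
  groups <- names(config$means)
  out <- tibble(
    group = rep(groups, each = config$wells),
    well = paste0(rep(groups, each = config$wells), "_",
                  rep(seq_len(config$wells), length(groups)))
  ) |>
    mutate(od595 = pmax(0, stats::rnorm(
      dplyr::n(),
      mean = rep(config$means, each = config$wells),
      sd = rep(config$sd, each = config$wells)
    ))) |>
    select("well", "group", "od595")
  attr(out, "truth") <- config$means
  out
}
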