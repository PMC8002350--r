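#' Normalize peak areas against the external standard
#'
#' Divides every metabolite area by the area of the external standard in the
#' same sample, cancelling sample-to-sample differences in injection and
#' ionization efficiency. Standard rows are dropped from the output.
#'
#' @param peaks Validated peak table (see [read_peak_table()]).
#' @param standard_id External-standard metabolite id; defaults to the id
#'   recorded on the table.
#' @return The peak table with an added `value = area / standard area`
#'   column and the standard rows removed.
#' @examples
#' sim <- simulate_experiment(simulation_config(
#'   metabolites = "serine", noise_cv = 0, experiment_cv = 0,
#'   standard_noise_cv = 0
#' ))
#' head(normalize_to_standard(sim$peaks))
#' @export
normalize_to_standard <- function(peaks,
                                  standard_id = attr(peaks, "standard_id") %||%
                                    "lamivudine") {
  peaks <- validate_peak_table(peaks, standard_id = standard_id)
  std <- peaks |>
    filter(.data$metabolite_id == standard_id) |>
    select("sample_id", std_area = "area")
  peaks |>
    filter(.data$metabolite_id != standard_id) |>
    left_join(std, by = "sample_id") |>
    mutate(value = .data$area / .data$std_area) |>
    select(-"std_area")
}

#' Mean, standard deviation and n of a replicate group
#'
#' @param values Numeric vector of (typically triplicate) measurements.
#' @return List with `mean`, `sd` (sample SD, `NA` when n < 2) and `n`.
#' @examples
#' summarize_replicates(c(1, 2, 3)) # mean 2, sd 1
#' @export
summarize_replicates <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("empty replicate group")
  list(
    mean = mean(values),
    sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
    n = length(values)
  )
}

#' Percent conversion against the control-medium baseline
#'
#' Supernatant (media) values are expressed relative to the measurement of
#' the fresh control medium, which defines 100%. Values above 100 indicate
#' net secretion into the medium, values below 100 net consumption.
#'
#' @param values Numeric standard-normalized abundances.
#' @param reference Control-medium reference value (> 0).
#' @return `100 * values / reference`; if the reference is missing, zero or
#'   non-finite, `NA`s are returned with a warning (the metabolite cannot be
#'   placed on the media percent scale).
#' @export
percent_convert_media <- function(values, reference) {
  if (length(reference) != 1 || is.na(reference) || !is.finite(reference) ||
      reference <= 0) {
    warn("control-medium reference missing or non-positive; values excluded")
    return(rep(NA_real_, length(values)))
  }
  # divide first so a value equal to its reference is exactly 100
  100 * (values / reference)
}

#' Percent conversion against the series maximum (cell pellets)
#'
#' Pellet values have no external 100% anchor, so the highest value in the
#' test series (one metabolite, both conditions, all timepoints, within one
#' experiment) is defined as 100% and everything else scaled to it. Exactly
#' one element (or every tie at the maximum) maps to 100.
#'
#' @param values Numeric standard-normalized abundances forming one test
#'   series.
#' @return `100 * values / max(values)`; an all-zero series returns zeros
#'   with a warning.
#' @examples
#' percent_convert_cells(c(2, 4, 8)) # 25 50 100
#' @export
percent_convert_cells <- function(values) {
  if (length(values) == 0) abort("empty test series")
  m <- max(values, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) {
    warn("all-zero test series; percents set to 0")
    return(rep(0, length(values)))
  }
  100 * (values / m)
}

#' Average per-experiment percents and round for presentation
#'
#' Cross-experiment summarization keeps the unrounded mean for all further
#' statistics; the rounded integer (half away from zero, so 84.5 becomes
#' 85) is for heat-map display only.
#'
#' @param percents Numeric vector of per-experiment percent values for one
#'   metabolite x condition x compartment x timepoint cell.
#' @return List with `mean` (unrounded), `rounded` (integer), `sd` across
#'   experiments (`NA` when n < 2) and `n`.
#' @export
average_experiments <- function(percents) {
  s <- summarize_replicates(percents)
  list(mean = s$mean, rounded = as.integer(round_half_away(s$mean)),
       sd = s$sd, n = s$n)
}

#' Run the full value-generation pipeline on a peak table
#'
#' Implements the standard workflow for multi-experiment LC/MS time courses:
#' (1) normalize all areas against the external standard per sample;
#' (2) average replicates (mean, sample SD, n) per metabolite x condition x
#' compartment x timepoint within each experiment; (3) convert to percent
#' with the compartment-appropriate baseline --- media: the fresh
#' control-medium measurement of the same experiment defines 100%; cells:
#' the highest replicate-mean in the test series (one metabolite, both
#' conditions, all timepoints, one experiment) defines 100%; (4) average the
#' per-experiment percents across experiments. Missing (metabolite, sample)
#' peaks are treated as zero areas (MS dropouts are absences, not errors).
#' Rounding happens only in [heatmap_matrix()]; all statistics use unrounded
#' values.
#'
#' @param peaks Peak table (tibble, `metr_sim`, or path handled by the
#'   caller). Fresh-medium reference samples are rows with condition
#'   `"medium_control"`; they are required whenever media-compartment rows
#'   are present, unless `media_reference` supplies the baseline directly.
#' @param standard_id External-standard id.
#' @param order `"anchor_then_average"` (default): percent-convert within
#'   each experiment, then average percents across experiments.
#'   `"average_then_anchor"`: average standard-normalized values across
#'   experiments first, then apply the percent baselines once.
#' @param media_reference Optional tibble (`metabolite_id`, `experiment`,
#'   `reference`) overriding the control-medium baseline; normally derived
#'   from the `medium_control` rows.
#' @return A `metr_series` object with tibbles `summary` (percent mean, SD
#'   across experiments, n), `per_experiment`, `per_replicate` (unrounded
#'   replicate-level percents used for differential testing) and
#'   `media_reference`.
#' @examples
#' sim <- simulate_experiment(metr_signature_config(noise_cv = 0.05))
#' series <- normalize_series(sim$peaks)
#' series
#' @export
normalize_series <- function(peaks,
                             standard_id = attr(peaks, "standard_id") %||%
                               "lamivudine",
                             order = c("anchor_then_average",
                                       "average_then_anchor"),
                             media_reference = NULL) {
  order <- match.arg(order)
  if (inherits(peaks, "metr_sim")) peaks <- peaks$peaks
  values <- normalize_to_standard(peaks, standard_id = standard_id)

  # complete the metabolite x sample grid: missing peaks are "not detected"
  samples <- distinct(values, .data$sample_id, .data$condition,
                      .data$compartment, .data$timepoint_h,
                      .data$replicate, .data$experiment)
  values <- tidyr::expand_grid(
    metabolite_id = unique(values$metabolite_id), samples
  ) |>
    left_join(
      select(values, "metabolite_id", "sample_id", "value"),
      by = c("metabolite_id", "sample_id")
    ) |>
    mutate(detected = !is.na(.data$value),
           value = coalesce(.data$value, 0))

  refs <- values |> filter(.data$condition == .medium_control)
  main <- values |> filter(.data$condition != .medium_control)

  if (is.null(media_reference)) {
    media_reference <- refs |>
      summarise(reference = mean(.data$value),
                .by = c("metabolite_id", "experiment"))
  } else {
    media_reference <- as_tibble(media_reference)
  }
  if (any(main$compartment == "media") && nrow(media_reference) == 0) {
    abort(paste0(
      "media-compartment rows present but no control-medium reference: ",
      "add 'medium_control' samples or pass `media_reference`"
    ))
  }

  rep_summary <- main |>
    summarise(
      mean_value = mean(.data$value),
      sd_value = if (dplyr::n() >= 2) stats::sd(.data$value) else NA_real_,
      n_replicates = dplyr::n(),
      .by = c("metabolite_id", "condition", "compartment", "timepoint_h",
              "experiment")
    )

  if (order == "anchor_then_average") {
    divisors <- series_divisors(rep_summary, media_reference,
                                by_experiment = TRUE)
    per_experiment <- rep_summary |>
      left_join(divisors, by = c("metabolite_id", "compartment",
                                 "experiment")) |>
      mutate(percent = 100 * (.data$mean_value / .data$divisor),
             percent_sd = 100 * (.data$sd_value / .data$divisor))
    summary <- per_experiment |>
      summarise(
        percent_mean = mean(.data$percent),
        percent_sd = if (dplyr::n() >= 2) stats::sd(.data$percent)
                     else NA_real_,
        n_experiments = sum(!is.na(.data$percent)),
        .by = c("metabolite_id", "condition", "compartment", "timepoint_h")
      )
    per_replicate <- main |>
      left_join(divisors, by = c("metabolite_id", "compartment",
                                 "experiment")) |>
      mutate(percent = 100 * (.data$value / .data$divisor)) |>
      select("metabolite_id", "condition", "compartment", "timepoint_h",
             "replicate", "experiment", "percent", "detected")
  } else {
    avg <- rep_summary |>
      summarise(mean_value = mean(.data$mean_value),
                n_experiments = dplyr::n(),
                .by = c("metabolite_id", "condition", "compartment",
                        "timepoint_h"))
    ref_overall <- media_reference |>
      summarise(reference = mean(.data$reference), .by = "metabolite_id")
    divisors <- series_divisors(
      rename(avg, value_for_anchor = "mean_value"), ref_overall,
      by_experiment = FALSE
    )
    summary <- avg |>
      left_join(divisors, by = c("metabolite_id", "compartment")) |>
      mutate(percent_mean = 100 * (.data$mean_value / .data$divisor),
             percent_sd = NA_real_) |>
      select("metabolite_id", "condition", "compartment", "timepoint_h",
             "percent_mean", "percent_sd", "n_experiments")
    per_experiment <- rep_summary |>
      left_join(divisors, by = c("metabolite_id", "compartment")) |>
      mutate(percent = 100 * (.data$mean_value / .data$divisor),
             percent_sd = 100 * (.data$sd_value / .data$divisor))
    per_replicate <- main |>
      left_join(divisors, by = c("metabolite_id", "compartment")) |>
      mutate(percent = 100 * (.data$value / .data$divisor)) |>
      select("metabolite_id", "condition", "compartment", "timepoint_h",
             "replicate", "experiment", "percent", "detected")
  }

  excluded <- unique(summary$metabolite_id[is.na(summary$percent_mean)])
  if (length(excluded)) {
    warn(paste0(
      "metabolite(s) without a positive control-medium reference excluded ",
      "from the media percent scale: ", paste(excluded, collapse = ", ")
    ))
  }

  structure(
    list(
      summary = arrange(summary, .data$metabolite_id, .data$condition,
                        .data$compartment, .data$timepoint_h),
      per_experiment = per_experiment,
      per_replicate = per_replicate,
      media_reference = media_reference,
      standard_id = standard_id,
      order = order
    ),
    class = "metr_series"
  )
}

# Percent divisors per metabolite (x experiment): media = control-medium
# reference; cells = maximum of the test series.
series_divisors <- function(summaries, media_reference, by_experiment) {
  value_col <- intersect(c("mean_value", "value_for_anchor"),
                         names(summaries))[1]
  keys <- c("metabolite_id", "compartment",
            if (by_experiment) "experiment")
  cells <- summaries |>
    filter(.data$compartment == "cells") |>
    summarise(divisor = {
      v <- .data[[value_col]]
      v <- v[is.finite(v)]
      if (length(v) == 0 || max(v) <= 0) NA_real_ else max(v)
    }, .by = all_of(keys))
  media <- summaries |>
    filter(.data$compartment == "media") |>
    distinct(!!!rlang::syms(keys)) |>
    left_join(media_reference,
              by = intersect(names(media_reference), keys)) |>
    mutate(divisor = ifelse(!is.na(.data$reference) & .data$reference > 0,
                            .data$reference, NA_real_)) |>
    select(all_of(keys), "divisor")
  bind_rows(cells, media)
}

#' @export
print.metr_series <- function(x, ...) {
  cat(sprintf(
    "Normalized metabolite series (%s): %d metabolites, %d conditions, %d timepoints\n",
    x$order, length(unique(x$summary$metabolite_id)),
    length(unique(x$summary$condition)),
    length(unique(x$summary$timepoint_h))
  ))
  print(x$summary, ...)
  invisible(x)
}

#' Rounded integer percent matrix for heat-map display
#'
#' @param series A `metr_series` from [normalize_series()].
#' @param compartment `"cells"` or `"media"`.
#' @param rounded Round half away from zero to integers (default); set
#'   `FALSE` for the unrounded matrix.
#' @return Matrix with metabolites as rows and `condition_timepoint`
#'   columns, timepoints ascending within condition.
#' @export
heatmap_matrix <- function(series, compartment = c("cells", "media"),
                           rounded = TRUE) {
  stopifnot(inherits(series, "metr_series"))
  compartment <- match.arg(compartment)
  sub <- series$summary |>
    filter(.data$compartment == !!compartment) |>
    mutate(condition = factor(.data$condition, levels = .cond_levels)) |>
    arrange(.data$condition, .data$timepoint_h) |>
    mutate(col = paste0(.data$condition, "_", .data$timepoint_h, "h"))
  wide <- sub |>
    select("metabolite_id", "col", "percent_mean") |>
    tidyr::pivot_wider(names_from = "col", values_from = "percent_mean")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$metabolite_id
  if (rounded) {
    m[] <- round_half_away(m)
    storage.mode(m) <- "integer"
  }
  m
}
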