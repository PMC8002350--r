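#' Summed relative mass of a metabolite class
#'
#' Beyond single metabolites, the summed relative masses of all metabolites
#' belonging to one pathway or class (TCA cycle, amino acids, purines, ...)
#' indicate the overall regulation of that pathway. Member abundances are
#' summed on the standard-normalized scale per sample (equivalently, member
#' areas are summed before standard normalization) and the sum is then
#' percent-converted with the same compartment rule as single metabolites:
#' in media the control-medium sum defines 100%, in pellets the
#' per-experiment series maximum of the sum defines 100%. Methionine never
#' contributes to an amino-acid aggregate (`amino_acid`, `essential`,
#' `branched`): it is the restricted variable, not a readout.
#'
#' @param peaks Peak table or `metr_sim`.
#' @param annotation Long annotation tibble (`metabolite_id`, `class`), e.g.
#'   [metabolite_catalog()] or [read_annotation()].
#' @param class Class or subgroup label to aggregate.
#' @param standard_id External-standard id.
#' @param method `"sum_then_percent"` (default): sum member abundances, then
#'   percent-convert the sum. `"mean_of_percents"`: percent-convert each
#'   member first, then average member percents.
#' @param order Passed to [normalize_series()].
#' @return A `class_summary` list: `class`, `members` used, `summary` tibble
#'   (percent mean/SD/n per condition x compartment x timepoint) and
#'   `per_experiment` (including the pre-percent `sum_value` when
#'   `method = "sum_then_percent"`).
#' @examples
#' sim <- simulate_experiment(metr_signature_config(noise_cv = 0))
#' cs <- class_sum(sim, metabolite_catalog(), "tca_cycle")
#' head(cs$summary)
#' @export
class_sum <- function(peaks, annotation, class,
                      standard_id = "lamivudine",
                      method = c("sum_then_percent", "mean_of_percents"),
                      order = "anchor_then_average") {
  method <- match.arg(method)
  if (inherits(peaks, "metr_sim")) {
    standard_id <- peaks$config$standard_id
    peaks <- peaks$peaks
  }
  standard_id <- attr(peaks, "standard_id") %||% standard_id
  annotation <- as_tibble(annotation)
  label <- class

  members <- annotation$metabolite_id[annotation$class == label]
  if (label %in% c("amino_acid", "essential", "branched")) {
    members <- setdiff(members, "methionine")
  }
  members <- intersect(members, unique(peaks$metabolite_id))
  if (length(members) == 0) {
    avail <- sort(unique(
      annotation$class[annotation$metabolite_id %in% peaks$metabolite_id]
    ))
    abort(paste0(
      "class '", label, "' has no members in the data; available classes: ",
      paste(avail, collapse = ", ")
    ))
  }

  if (method == "sum_then_percent") {
    keep <- peaks |>
      filter(.data$metabolite_id %in% c(members, standard_id))
    summed <- keep |>
      filter(.data$metabolite_id != standard_id) |>
      summarise(
        area = sum(.data$area),
        .by = c("sample_id", "condition", "compartment", "timepoint_h",
                "replicate", "experiment")
      ) |>
      mutate(metabolite_id = label)
    mini <- bind_rows(
      summed,
      filter(keep, .data$metabolite_id == standard_id)
    )
    series <- normalize_series(mini, standard_id = standard_id,
                               order = order)
    summary <- series$summary |>
      rename(class = "metabolite_id") |>
      mutate(n_members = length(members))
    per_experiment <- series$per_experiment |>
      rename(class = "metabolite_id", sum_value = "mean_value")
  } else {
    series <- normalize_series(peaks, standard_id = standard_id,
                               order = order)
    summary <- series$summary |>
      filter(.data$metabolite_id %in% members) |>
      summarise(
        percent_mean = mean(.data$percent_mean),
        percent_sd = stats::sd(.data$percent_mean),
        n_experiments = min(.data$n_experiments),
        .by = c("condition", "compartment", "timepoint_h")
      ) |>
      mutate(class = label, n_members = length(members))
    per_experiment <- series$per_experiment |>
      filter(.data$metabolite_id %in% members) |>
      summarise(percent = mean(.data$percent),
                .by = c("condition", "compartment", "timepoint_h",
                        "experiment")) |>
      mutate(class = label)
  }

  structure(
    list(class = label, members = members, method = method,
         summary = summary, per_experiment = per_experiment),
    class = "class_summary"
  )
}

#' Summed relative mass of a metabolite subgroup
#'
#' Identical machinery to [class_sum()], applied to cross-cutting subgroup
#' labels such as `essential`, `branched` or `s_containing`.
#'
#' @inheritParams class_sum
#' @param subgroup Subgroup label.
#' @return A `class_summary`; see [class_sum()].
#' @export
subgroup_sum <- function(peaks, annotation, subgroup, ...) {
  class_sum(peaks, annotation, class = subgroup, ...)
}

#' Aggregate several classes at once
#'
#' @inheritParams class_sum
#' @param classes Character vector of labels, or `"all"` for every label
#'   present in both annotation and data.
#' @return Tibble binding the `summary` components of each class.
#' @export
aggregate_classes <- function(peaks, annotation, classes = "all", ...) {
  annotation <- as_tibble(annotation)
  ids <- if (inherits(peaks, "metr_sim")) peaks$config$metabolites
         else unique(peaks$metabolite_id)
  if (identical(classes, "all")) {
    classes <- sort(unique(
      annotation$class[annotation$metabolite_id %in% ids]
    ))
  }
  bind_rows(lapply(classes, function(cl) {
    class_sum(peaks, annotation, cl, ...)$summary
  }))
}

#' @export
print.class_summary <- function(x, ...) {
  cat(sprintf("Class summary '%s' (%s; %d members)\n",
              x$class, x$method, length(x$members)))
  print(x$summary, ...)
  invisible(x)
}
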