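#' Two-sample differential test between Met+ and Met- groups
#'
#' Unpaired two-sample t test (pooled variance by default, Welch behind the
#' flag) on unrounded replicate-level percents; two-sided p. Direction is
#' the sign of `mean(met_minus) - mean(met_plus)`: `"up"` means higher
#' under methionine restriction. Degenerate zero-variance groups follow a
#' no-effect convention: identical groups give p = 1; perfectly separated
#' constant groups give p = 0.
#'
#' @param met_plus,met_minus Numeric measurement vectors for the control
#'   and methionine-restricted group.
#' @param var_equal Pooled-variance t (default `TRUE`); `FALSE` for Welch.
#' @return List with `t`, `df`, `p`, `direction` (`"up"`/`"down"`/`"none"`),
#'   `estimate` (`mean(met_minus) - mean(met_plus)`), `n` (per group) and
#'   `testable` (`FALSE`, with `p = NA`, when either group has n < 2).
#' @examples
#' differential_test(c(10, 11, 12), c(20, 21, 22)) # t ~ -12.25, p < 0.001
#' @export
differential_test <- function(met_plus, met_minus, var_equal = TRUE) {
  x <- met_plus[!is.na(met_plus)]
  y <- met_minus[!is.na(met_minus)]
  est <- mean(y) - mean(x)
  direction <- if (isTRUE(est > 0)) "up" else if (isTRUE(est < 0)) "down"
               else "none"
  if (length(x) < 2 || length(y) < 2) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                direction = direction, estimate = est,
                n = c(length(x), length(y)), testable = FALSE))
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # zero-variance convention: t.test() refuses constant data
    if (est == 0) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                  direction = "none", estimate = 0,
                  n = c(length(x), length(y)), testable = TRUE))
    }
    return(list(t = -sign(est) * Inf, df = length(x) + length(y) - 2, p = 0,
                direction = direction, estimate = est,
                n = c(length(x), length(y)), testable = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), direction = direction, estimate = est,
       n = c(length(x), length(y)), testable = TRUE)
}

#' Build the differential metabolic fingerprint at a reference timepoint
#'
#' Tests every metabolite for a Met+ vs Met- difference at one timepoint
#' and compartment, on the unrounded replicate-level percents pooled across
#' experiments, and collects the significant ones (p < alpha) with their
#' direction and magnitude (difference of averaged percents,
#' Met- minus Met+). Entries are ordered by |magnitude|, largest first.
#' The canonical fingerprint of methionine restriction uses the
#' intracellular (cells) compartment at 48 h, the earliest time at which
#' the profile is clearly defined.
#'
#' @param series A `metr_series` from [normalize_series()].
#' @param timepoint Reference timepoint in hours (default 48).
#' @param alpha Significance level (default 0.05; entries require p <
#'   alpha).
#' @param compartment `"cells"` (default) or `"media"`.
#' @param adjust `"none"` (default; raw p values) or `"BH"` for
#'   Benjamini-Hochberg.
#' @param var_equal Passed to [differential_test()].
#' @return A `metr_fingerprint`: tibble with columns `metabolite_id`,
#'   `direction`, `magnitude`, `p_value`, `n_met_plus`, `n_met_minus`, and
#'   attributes `timepoint`, `alpha`, `compartment`, `adjust`.
#' @examples
#' sim <- simulate_experiment(metr_signature_config(noise_cv = 0.05))
#' fp <- build_fingerprint(normalize_series(sim))
#' fp
#' @export
build_fingerprint <- function(series, timepoint = 48, alpha = 0.05,
                              compartment = c("cells", "media"),
                              adjust = c("none", "BH"),
                              var_equal = TRUE) {
  stopifnot(inherits(series, "metr_series"))
  compartment <- match.arg(compartment)
  adjust <- match.arg(adjust)
  avail <- sort(unique(series$per_replicate$timepoint_h))
  if (!timepoint %in% avail) {
    abort(sprintf("timepoint %s h not in series; available: %s",
                  format(timepoint), paste(avail, collapse = ", ")))
  }

  reps <- series$per_replicate |>
    filter(.data$timepoint_h == timepoint,
           .data$compartment == !!compartment)
  means <- series$summary |>
    filter(.data$timepoint_h == timepoint,
           .data$compartment == !!compartment) |>
    select("metabolite_id", "condition", "percent_mean") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = "percent_mean")

  tests <- reps |>
    tidyr::nest(.by = "metabolite_id") |>
    mutate(res = lapply(.data$data, function(d) {
      tt <- differential_test(
        d$percent[d$condition == "met_plus"],
        d$percent[d$condition == "met_minus"],
        var_equal = var_equal
      )
      tibble(p_value = tt$p, direction = tt$direction,
             n_met_plus = tt$n[1], n_met_minus = tt$n[2],
             testable = tt$testable)
    })) |>
    select(-"data") |>
    tidyr::unnest("res") |>
    left_join(means, by = "metabolite_id") |>
    mutate(magnitude = .data$met_minus - .data$met_plus)

  if (adjust == "BH") {
    tests$p_value <- stats::p.adjust(tests$p_value, method = "BH")
  }
  entries <- tests |>
    filter(.data$testable, !is.na(.data$p_value), .data$p_value < alpha) |>
    arrange(desc(abs(.data$magnitude))) |>
    select("metabolite_id", "direction", "magnitude", "p_value",
           "n_met_plus", "n_met_minus")

  structure(entries, class = c("metr_fingerprint", class(entries)),
            timepoint = timepoint, alpha = alpha,
            compartment = compartment, adjust = adjust)
}

#' @export
print.metr_fingerprint <- function(x, ...) {
  cat(sprintf(
    "Metabolic fingerprint at %s h (%s, alpha %s): %d differential metabolite(s)\n",
    format(attr(x, "timepoint")), attr(x, "compartment"),
    format(attr(x, "alpha")), nrow(x)
  ))
  NextMethod()
  invisible(x)
}

#' Directional profile of a normalized series
#'
#' Extracts the Met- vs Met+ direction per metabolite at one timepoint and
#' compartment, the form consumed by [match_score()] when screening a
#' candidate low-energy-metabolism inducer against the restriction
#' fingerprint.
#'
#' @inheritParams build_fingerprint
#' @return Tibble with columns `metabolite_id` and `direction`.
#' @export
direction_profile <- function(series, timepoint = 48,
                              compartment = c("cells", "media")) {
  stopifnot(inherits(series, "metr_series"))
  compartment <- match.arg(compartment)
  series$summary |>
    filter(.data$timepoint_h == timepoint,
           .data$compartment == !!compartment) |>
    select("metabolite_id", "condition", "percent_mean") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = "percent_mean") |>
    mutate(direction = dplyr::case_when(
      .data$met_minus > .data$met_plus ~ "up",
      .data$met_minus < .data$met_plus ~ "down",
      .default = "none"
    )) |>
    select("metabolite_id", "direction")
}

#' Score a candidate profile against the restriction fingerprint
#'
#' A candidate compound's potential as a low-energy-metabolism inducer is
#' assessed by the number of directional matches among the differentially
#' synthesized metabolites of the fingerprint. The score is the fraction of
#' evaluable fingerprint entries whose direction the new profile
#' reproduces; fingerprint metabolites absent from the profile are not
#' evaluable and are reported, not penalized.
#'
#' @param profile Tibble with `metabolite_id` and `direction` columns (see
#'   [direction_profile()]), a named character vector of directions, or
#'   another `metr_fingerprint`.
#' @param fingerprint A non-empty `metr_fingerprint`.
#' @return List with `score` in `[0, 1]`, `n_matched`, `n_evaluable`, and
#'   `not_evaluable` (fingerprint metabolites the profile does not cover).
#' @examples
#' sim <- simulate_experiment(metr_signature_config(noise_cv = 0.05))
#' series <- normalize_series(sim)
#' fp <- build_fingerprint(series)
#' match_score(direction_profile(series), fp)$score # 1 by construction
#' @export
match_score <- function(profile, fingerprint) {
  stopifnot(inherits(fingerprint, "metr_fingerprint"))
  if (nrow(fingerprint) == 0) {
    abort("empty fingerprint: nothing to match against")
  }
  if (inherits(profile, "metr_fingerprint") || is.data.frame(profile)) {
    dirs <- stats::setNames(profile$direction, profile$metabolite_id)
  } else {
    dirs <- profile
  }
  observed <- dirs[match(fingerprint$metabolite_id, names(dirs))]
  evaluable <- !is.na(observed) & observed %in% c("up", "down")
  matched <- evaluable & observed == fingerprint$direction
  n_eval <- sum(evaluable)
  if (n_eval == 0) {
    warn("no fingerprint metabolite is evaluable in the profile")
    return(list(score = NA_real_, n_matched = 0L, n_evaluable = 0L,
                not_evaluable = fingerprint$metabolite_id))
  }
  list(
    score = sum(matched) / n_eval,
    n_matched = sum(matched),
    n_evaluable = n_eval,
    not_evaluable = fingerprint$metabolite_id[!evaluable]
  )
}

#' Expected component directions of the low-energy-metabolism footprint
#'
#' Under methionine restriction, acetoacetate rises (lipid catabolism),
#' creatine, spermidine and GSSG fall (methionine/sulphur-dependent
#' synthesis), and the ADP/ATP ratio rises as energy charge drops (the
#' ratio is the AMP-kinase input; both nucleotides fall, ATP more
#' steeply). The ratio direction is configurable because assays
#' report it both ways round.
#'
#' @return Named character vector of expected directions.
#' @export
lem_expected_directions <- function() {
  c(acetoacetate = "up", creatine = "down", spermidine = "down",
    GSSG = "down", adp_atp_ratio = "up")
}

#' Five-component low-energy-metabolism footprint score
#'
#' The combination of acetoacetate, creatine, spermidine, GSSG and the
#' ADP/ATP ratio is a small panel suitable for rapid "fast tracking" of
#' low-energy metabolism without full MS profiling. Each component's
#' observed Met- vs Met+ direction is compared with the expected direction;
#' the score is the concordant fraction of evaluable components. Components
#' missing from the data are excluded from the denominator and flagged.
#'
#' @param x A `metr_series`, or a measured panel: tibble with columns
#'   `component` (using `adp_atp_ratio` for the ratio) and `direction`.
#' @param timepoint,compartment Where to read directions from a series
#'   (defaults: 48 h, cells).
#' @param expected Named direction vector (default
#'   [lem_expected_directions()]).
#' @return A `metr_footprint`: list with `components` tibble (`component`,
#'   `observed`, `expected`, `evaluable`, `concordant`), `score` =
#'   concordant / evaluable, and `n_evaluable`.
#' @examples
#' sim <- simulate_experiment(metr_signature_config(noise_cv = 0.05))
#' footprint_score(normalize_series(sim))
#' @export
footprint_score <- function(x, timepoint = 48,
                            compartment = c("cells", "media"),
                            expected = lem_expected_directions()) {
  compartment <- match.arg(compartment)
  comps <- names(expected)
  if (inherits(x, "metr_series")) {
    wide <- x$summary |>
      filter(.data$timepoint_h == timepoint,
             .data$compartment == !!compartment) |>
      select("metabolite_id", "condition", "percent_mean") |>
      tidyr::pivot_wider(names_from = "condition",
                         values_from = "percent_mean")
    get_pct <- function(id, cond) {
      i <- match(id, wide$metabolite_id)
      if (is.na(i) || !cond %in% names(wide)) NA_real_ else wide[[cond]][i]
    }
    observed <- vapply(comps, function(cc) {
      if (cc == "adp_atp_ratio") {
        rp <- get_pct("ADP", "met_plus") / get_pct("ATP", "met_plus")
        rm_ <- get_pct("ADP", "met_minus") / get_pct("ATP", "met_minus")
        d <- rm_ - rp
      } else {
        d <- get_pct(cc, "met_minus") - get_pct(cc, "met_plus")
      }
      if (is.na(d) || !is.finite(d)) NA_character_
      else if (d > 0) "up" else if (d < 0) "down" else "none"
    }, character(1))
  } else {
    panel <- as_tibble(x)
    if (!all(c("component", "direction") %in% names(panel))) {
      abort("measured panel needs `component` and `direction` columns")
    }
    observed <- panel$direction[match(comps, panel$component)]
  }

  components <- tibble(
    component = comps,
    observed = unname(observed),
    expected = unname(expected)
  ) |>
    mutate(
      evaluable = !is.na(.data$observed) &
        .data$observed %in% c("up", "down"),
      concordant = .data$evaluable & .data$observed == .data$expected
    )
  n_eval <- sum(components$evaluable)
  if (n_eval == 0) {
    abort("no footprint component is evaluable in the input")
  }
  structure(
    list(components = components,
         score = sum(components$concordant) / n_eval,
         n_evaluable = n_eval),
    class = "metr_footprint"
  )
}

#' @export
print.metr_footprint <- function(x, ...) {
  cat(sprintf("LEM footprint score: %.2f (%d/%d components concordant)\n",
              x$score, sum(x$components$concordant), x$n_evaluable))
  print(x$components, ...)
  invisible(x)
}

#' Serialize / read a fingerprint as JSON
#'
#' @param fingerprint A `metr_fingerprint`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_fingerprint()` returns the
#'   `metr_fingerprint`.
#' @export
write_fingerprint <- function(fingerprint, path) {
  stopifnot(inherits(fingerprint, "metr_fingerprint"))
  payload <- list(
    timepoint = attr(fingerprint, "timepoint"),
    alpha = attr(fingerprint, "alpha"),
    compartment = attr(fingerprint, "compartment"),
    adjust = attr(fingerprint, "adjust"),
    entries = as.data.frame(fingerprint)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fingerprint
#' @export
read_fingerprint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- as_tibble(payload$entries)
  structure(entries, class = c("metr_fingerprint", class(entries)),
            timepoint = payload$timepoint, alpha = payload$alpha,
            compartment = payload$compartment, adjust = payload$adjust)
}
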