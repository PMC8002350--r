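#' Relative cell number (RCN) from crystal-violet absorbance
#'
#' Crystal-violet OD-595 readings of stimulated wells (CVS) are normalized
#' to the mean of the untreated control wells (CVC):
#' `RCN (%) = 100 * CVS / mean(CVC)`. The control thus sits at 100% by
#' construction and `inhibition = 100 - mean(RCN)`. RCN is computed per
#' well and then summarized, which leaves group means identical to
#' normalizing the group mean directly.
#'
#' @param stimulated Numeric OD-595 values of the stimulated wells.
#' @param control Numeric OD-595 values of the untreated control wells;
#'   their mean must be positive.
#' @param var_equal Passed to [compare_groups()] for the test against
#'   control.
#' @return An `rcn_result` list: per-well `rcn`, group `mean`, `sd`, `n`,
#'   `inhibition`, and `test` (t, df, p, tier vs the control wells' own
#'   RCN).
#' @examples
#' rcn(c(0.3, 0.31, 0.29), c(0.6, 0.61, 0.59)) # ~50% RCN
#' @export
rcn <- function(stimulated, control, var_equal = TRUE) {
  control <- control[!is.na(control)]
  stimulated <- stimulated[!is.na(stimulated)]
  if (length(control) == 0 || mean(control) <= 0) {
    abort("control group mean OD must be positive")
  }
  cvc <- mean(control)
  vals <- 100 * stimulated / cvc
  ctrl_vals <- 100 * control / cvc
  s <- summarize_replicates(vals)
  structure(
    list(
      rcn = vals, mean = s$mean, sd = s$sd, n = s$n,
      inhibition = 100 - s$mean,
      control = list(rcn = ctrl_vals, mean = 100, n = length(control)),
      test = compare_groups(ctrl_vals, vals, var_equal = var_equal)
    ),
    class = "rcn_result"
  )
}

#' @export
print.rcn_result <- function(x, ...) {
  cat(sprintf("RCN %.1f%% (SD %s, n %d); inhibition %.1f%%; p %s [%s]\n",
              x$mean, ifelse(is.na(x$sd), "-", sprintf("%.1f", x$sd)),
              x$n, x$inhibition,
              ifelse(is.na(x$test$p), "-", format.pval(x$test$p)),
              x$test$tier))
  invisible(x)
}

#' Compare two well groups by unpaired t test with significance tiers
#'
#' @param a,b Numeric vectors (e.g. RCN values of two groups).
#' @param var_equal Pooled-variance t (default); `FALSE` for Welch.
#' @return List with `t`, `df`, `p`, `tier` and `testable`. Tiers:
#'   `"***"` for p <= 0.001, `"**"` for p <= 0.01 (conventional extension),
#'   `"*"` for p < 0.05, `"ns"` otherwise.
#' @export
compare_groups <- function(a, b, var_equal = TRUE) {
  tt <- differential_test(a, b, var_equal = var_equal)
  list(t = tt$t, df = tt$df, p = tt$p, tier = significance_tier(tt$p),
       testable = tt$testable)
}

#' Map a p value to its significance tier
#'
#' @param p Numeric p value(s).
#' @return `"***"` (p <= 0.001), `"**"` (p <= 0.01), `"*"` (p < 0.05) or
#'   `"ns"`; `NA` stays `NA`.
#' @export
significance_tier <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p < 0.05 ~ "*",
    .default = "ns"
  )
}

#' Summarize a whole crystal-violet plate
#'
#' Computes RCN for every group on the plate against the designated
#' untreated control group.
#'
#' @param plate Tibble with columns `well`, `group`, `od595` (as produced
#'   by [simulate_plate()]).
#' @param control Label of the untreated control group (default
#'   `"untreated"`).
#' @param var_equal Passed to [rcn()].
#' @return Tibble with one row per group: `rcn_mean`, `rcn_sd`, `n`,
#'   `inhibition`, `t`, `df`, `p`, `tier` (test columns `NA` for the
#'   control row).
#' @export
proliferation_summary <- function(plate, control = "untreated",
                                  var_equal = TRUE) {
  plate <- as_tibble(plate)
  if (!all(c("group", "od595") %in% names(plate))) {
    abort("plate needs `group` and `od595` columns")
  }
  if (!control %in% plate$group) {
    abort(sprintf("control group '%s' not found on the plate", control))
  }
  ctrl_od <- plate$od595[plate$group == control]
  groups <- unique(plate$group)
  bind_rows(lapply(groups, function(g) {
    r <- rcn(plate$od595[plate$group == g], ctrl_od, var_equal = var_equal)
    is_ctrl <- identical(g, control)
    tibble(
      group = g, rcn_mean = r$mean, rcn_sd = r$sd, n = r$n,
      inhibition = r$inhibition,
      t = if (is_ctrl) NA_real_ else r$test$t,
      df = if (is_ctrl) NA_real_ else r$test$df,
      p = if (is_ctrl) NA_real_ else r$test$p,
      tier = if (is_ctrl) NA_character_ else r$test$tier
    )
  }))
}
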