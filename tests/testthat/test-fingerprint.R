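test_that("pooled t test matches the textbook oracle on the worked example", {
  tt <- differential_test(c(10, 11, 12), c(20, 21, 22))
  # sp^2 = 1, se = sqrt(2/3), t = -10 / se = -sqrt(150)
  expect_equal(tt$t, -sqrt(150), tolerance = 1e-12)
  expect_equal(tt$df, 4)
  expect_lt(tt$p, 0.001)
  expect_equal(tt$direction, "up")
  expect_equal(tt$estimate, 10)
})

test_that("swapping groups flips direction but preserves p", {
  a <- c(3.1, 4.0, 2.8, 3.5)
  b <- c(5.2, 4.9, 5.8)
  ab <- differential_test(a, b)
  ba <- differential_test(b, a)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$direction, "up")
  expect_equal(ba$direction, "down")
})

test_that("degenerate groups follow the stated conventions", {
  same <- differential_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$p, 1)
  expect_equal(same$direction, "none")
  split <- differential_test(c(5, 5), c(7, 7))
  expect_equal(split$p, 0)
  expect_equal(split$direction, "up")
  tiny <- differential_test(5, c(6, 7))
  expect_false(tiny$testable)
  expect_true(is.na(tiny$p))
})

test_that("Welch flag relaxes the equal-variance assumption", {
  a <- c(10, 10.1, 9.9, 10.2)
  b <- c(15, 25, 5, 18)
  pooled <- differential_test(a, b)
  welch <- differential_test(a, b, var_equal = FALSE)
  expect_lt(welch$df, pooled$df)
})

test_that("zero-noise fingerprint contains exactly the injected effect", {
  eff <- tibble::tibble(
    metabolite_id = "spermidine", condition = "met_minus",
    compartment = "cells", anchor_start = 100, anchor_end = 30
  )
  sim <- simulate_experiment(tiny_config(
    metabolites = c("spermidine", "serine", "glycine"), effects = eff
  ))
  series <- normalize_series(sim)
  fp <- build_fingerprint(series, timepoint = 48)
  expect_equal(fp$metabolite_id, "spermidine")
  expect_equal(fp$direction, "down")
  expect_equal(build_fingerprint(series, alpha = 0)$metabolite_id,
               character(0))
  expect_error(build_fingerprint(series, timepoint = 36), "available")
})

test_that("fingerprint entries are ordered by absolute magnitude", {
  sim <- simulate_experiment(metr_signature_config(noise_cv = 0.05,
                                                   seed = 61))
  fp <- build_fingerprint(normalize_series(sim))
  expect_true(all(diff(abs(fp$magnitude)) <= 0))
  expect_true(all(fp$p_value < attr(fp, "alpha")))
  expect_true(all(ifelse(fp$magnitude > 0, "up", "down") == fp$direction))
  expect_false(anyDuplicated(fp$metabolite_id) > 0)
})

test_that("Benjamini-Hochberg adjustment never reports smaller p values", {
  sim <- simulate_experiment(metr_signature_config(noise_cv = 0.1,
                                                   seed = 62))
  series <- normalize_series(sim)
  raw <- build_fingerprint(series)
  bh <- build_fingerprint(series, adjust = "BH")
  shared <- intersect(raw$metabolite_id, bh$metabolite_id)
  expect_gte(length(shared), 1)
  expect_true(all(
    bh$p_value[match(shared, bh$metabolite_id)] >=
      raw$p_value[match(shared, raw$metabolite_id)]
  ))
})

test_that("match score counts directional concordance over evaluable entries", {
  sim <- simulate_experiment(metr_signature_config(noise_cv = 0.05,
                                                   seed = 63))
  series <- normalize_series(sim)
  fp <- build_fingerprint(series)
  expect_gte(nrow(fp), 10)

  expect_equal(match_score(fp, fp)$score, 1)
  self <- direction_profile(series)
  expect_equal(match_score(self, fp)$score, 1)

  inverted <- stats::setNames(
    ifelse(fp$direction == "up", "down", "up"), fp$metabolite_id
  )
  expect_equal(match_score(inverted, fp)$score, 0)

  ten <- fp$metabolite_id[1:10]
  partial <- stats::setNames(
    ifelse(seq_len(10) <= 6, fp$direction[1:10],
           ifelse(fp$direction[1:10] == "up", "down", "up")), ten
  )
  ms <- match_score(partial, fp[fp$metabolite_id %in% ten, ])
  expect_equal(ms$score, 0.6)

  missing_some <- stats::setNames(fp$direction[1:5], fp$metabolite_id[1:5])
  ms2 <- match_score(missing_some, fp)
  expect_equal(ms2$score, 1)
  expect_setequal(ms2$not_evaluable,
                  fp$metabolite_id[-(1:5)])

  empty <- fp[0, ]
  expect_error(match_score(self, empty), "empty fingerprint")
})

test_that("footprint score counts concordant components out of five", {
  panel <- tibble::tibble(
    component = c("acetoacetate", "creatine", "spermidine", "GSSG",
                  "adp_atp_ratio"),
    direction = c("up", "down", "down", "down", "up")
  )
  expect_equal(footprint_score(panel)$score, 1)

  inverted <- dplyr::mutate(
    panel, direction = ifelse(direction == "up", "down", "up")
  )
  expect_equal(footprint_score(inverted)$score, 0)

  three <- panel
  three$direction[4:5] <- c("up", "down") # two discordant
  expect_equal(footprint_score(three)$score, 0.6)

  # component order must not matter
  shuffled <- three[c(4, 2, 5, 1, 3), ]
  expect_equal(footprint_score(shuffled)$score, 0.6)

  # a missing component shrinks the denominator and is flagged
  four <- panel[-1, ]
  fs <- footprint_score(four)
  expect_equal(fs$n_evaluable, 4)
  expect_equal(fs$score, 1)
  expect_false(
    fs$components$evaluable[fs$components$component == "acetoacetate"]
  )

  none <- dplyr::mutate(panel, direction = NA_character_)
  expect_error(footprint_score(none), "no footprint component")
})

test_that("the signature simulation yields a fully concordant footprint", {
  sim <- simulate_experiment(metr_signature_config(noise_cv = 0.05,
                                                   seed = 64))
  fs <- footprint_score(normalize_series(sim))
  expect_equal(fs$score, 1)
  expect_equal(fs$n_evaluable, 5)
  expect_true(fs$score %in% seq(0, 1, by = 0.2))
})

test_that("fingerprints survive a JSON round trip", {
  sim <- simulate_experiment(metr_signature_config(noise_cv = 0.05,
                                                   seed = 65))
  fp <- build_fingerprint(normalize_series(sim))
  path <- withr::local_tempfile(fileext = ".json")
  write_fingerprint(fp, path)
  back <- read_fingerprint(path)
  expect_equal(as.data.frame(back), as.data.frame(fp))
  expect_equal(attr(back, "timepoint"), attr(fp, "timepoint"))
  expect_equal(attr(back, "alpha"), attr(fp, "alpha"))
})

test_that("power rises with effect size and replication", {
  detect_freq <- function(anchor_end, replicates, seeds) {
    eff <- tibble::tibble(
      metabolite_id = "m1", condition = "met_minus",
      compartment = "cells", anchor_start = 100, anchor_end = anchor_end
    )
    hits <- vapply(seeds, function(s) {
      sim <- simulate_experiment(simulation_config(
        metabolites = "m1", effects = eff, noise_cv = 0.15,
        replicates = replicates, experiments = 2, seed = s
      ))
      fp <- build_fingerprint(normalize_series(sim), timepoint = 120)
      "m1" %in% fp$metabolite_id
    }, logical(1))
    mean(hits)
  }
  seeds <- 7000 + 1:25
  weak <- detect_freq(85, 3, seeds)
  strong <- detect_freq(40, 3, seeds)
  more_reps <- detect_freq(85, 10, seeds)
  expect_gte(strong, weak)
  expect_gte(more_reps, weak)
  expect_gte(strong, 0.9)
})

test_that("percent estimates converge to configured anchors with replication", {
  eff <- tibble::tibble(
    metabolite_id = "m1", condition = "met_minus", compartment = "media",
    anchor_start = 100, anchor_end = 150
  )
  sim <- simulate_experiment(simulation_config(
    metabolites = "m1", effects = eff, noise_cv = 0.1,
    replicates = 40, experiments = 4, seed = 71
  ))
  series <- normalize_series(sim)
  est <- series$summary |>
    dplyr::filter(condition == "met_minus", compartment == "media",
                  timepoint_h == 120)
  per_exp <- series$per_experiment |>
    dplyr::filter(condition == "met_minus", compartment == "media",
                  timepoint_h == 120)
  se <- stats::sd(per_exp$percent) / sqrt(nrow(per_exp))
  expect_lt(abs(est$percent_mean - 150), 3 * se + 1e-9)
})
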