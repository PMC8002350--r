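test_that("a singleton class reproduces the metabolite's own percents", {
  sim <- simulate_experiment(tiny_config(
    metabolites = c("citrate", "serine"), noise_cv = 0.1, seed = 51
  ))
  ann <- tibble::tibble(metabolite_id = "citrate", class = "tca_cycle")
  cs <- class_sum(sim, ann, "tca_cycle")
  single <- normalize_series(sim)$summary |>
    dplyr::filter(metabolite_id == "citrate")
  joined <- dplyr::left_join(
    cs$summary, single,
    by = c("condition", "compartment", "timepoint_h")
  )
  expect_equal(joined$percent_mean.x, joined$percent_mean.y,
               tolerance = 1e-12)
})

test_that("pre-percent class sums are additive to machine precision", {
  sim <- simulate_experiment(metr_signature_config(noise_cv = 0.1,
                                                   seed = 52))
  ann <- metabolite_catalog()
  cs <- class_sum(sim, ann, "purine")
  members <- cs$members
  per_met <- normalize_series(sim)$per_experiment |>
    dplyr::filter(metabolite_id %in% members) |>
    dplyr::summarise(total = sum(mean_value),
                     .by = c(condition, compartment, timepoint_h,
                             experiment))
  joined <- dplyr::left_join(
    cs$per_experiment, per_met,
    by = c("condition", "compartment", "timepoint_h", "experiment")
  )
  expect_equal(joined$sum_value, joined$total, tolerance = 1e-12)
})

test_that("subgroups are subsets: branched sum never exceeds amino-acid sum", {
  sim <- simulate_experiment(metr_signature_config(noise_cv = 0.1,
                                                   seed = 53))
  ann <- metabolite_catalog()
  aa <- class_sum(sim, ann, "amino_acid")$per_experiment
  br <- subgroup_sum(sim, ann, "branched")$per_experiment
  expect_setequal(
    subgroup_sum(sim, ann, "branched")$members,
    c("leucine", "isoleucine", "valine")
  )
  joined <- dplyr::left_join(
    br, aa, by = c("condition", "compartment", "timepoint_h", "experiment"),
    suffix = c("_br", "_aa")
  )
  expect_true(all(joined$sum_value_br <= joined$sum_value_aa + 1e-12))
})

test_that("methionine never contributes to amino-acid aggregates", {
  sim <- simulate_experiment(simulation_config(
    metabolites = c("methionine", "valine", "leucine"), noise_cv = 0,
    standard_noise_cv = 0, experiment_cv = 0, seed = 54
  ))
  ann <- metabolite_catalog()
  base <- class_sum(sim, ann, "amino_acid")
  expect_false("methionine" %in% base$members)
  boosted <- sim$peaks
  is_met <- boosted$metabolite_id == "methionine"
  boosted$area[is_met] <- boosted$area[is_met] * 10
  again <- class_sum(validate_peak_table(boosted), ann, "amino_acid")
  expect_equal(again$summary$percent_mean, base$summary$percent_mean)
})

test_that("zero-abundance members leave the class summary unchanged", {
  rows <- tidyr::expand_grid(
    metabolite_id = c("citrate", "malate"),
    condition = c("met_plus", "met_minus"), compartment = "cells",
    timepoint_h = c(24, 48), replicate = 1:2, experiment = 1:2
  )
  rows$area <- 10 * seq_len(nrow(rows)) %% 7 + 1
  rows$area[rows$metabolite_id == "malate"] <- 0
  peaks <- manual_peaks(rows)
  ann <- metabolite_catalog()
  with_zero <- class_sum(peaks, ann, "tca_cycle")
  only_citrate <- class_sum(
    validate_peak_table(peaks[peaks$metabolite_id != "malate", ]),
    ann, "tca_cycle"
  )
  expect_equal(with_zero$summary$percent_mean,
               only_citrate$summary$percent_mean)
})

test_that("raising a member's abundance cannot lower the class percent in media", {
  rows <- tidyr::expand_grid(
    metabolite_id = c("citrate", "malate"),
    condition = c("met_plus", "met_minus", "medium_control"),
    compartment = "media", replicate = 1:2, experiment = 1L
  )
  rows$timepoint_h <- ifelse(rows$condition == "medium_control", 0, 24)
  rows$area <- 10
  peaks <- manual_peaks(rows)
  ann <- metabolite_catalog()
  before <- class_sum(peaks, ann, "tca_cycle")$summary
  bumped <- peaks
  sel <- bumped$metabolite_id == "malate" & bumped$condition == "met_minus"
  bumped$area[sel] <- 25
  after <- class_sum(validate_peak_table(bumped), ann, "tca_cycle")$summary
  key <- after$condition == "met_minus"
  expect_true(all(after$percent_mean[key] >= before$percent_mean[key]))
  expect_equal(after$percent_mean[after$condition == "met_plus"],
               before$percent_mean[before$condition == "met_plus"])
})

test_that("media class sums scale on the control-medium sum", {
  # members sum to 2.0 in the control medium and 2.4 at 24 h -> 120%
  rows <- tibble::tibble(
    metabolite_id = rep(c("citrate", "malate"), 2),
    condition = rep(c("medium_control", "met_minus"), each = 2),
    compartment = "media",
    timepoint_h = rep(c(0, 24), each = 2),
    replicate = 1L, experiment = 1L,
    area = c(120, 80, 150, 90) # ratios 1.2+0.8 = 2.0; 1.5+0.9 = 2.4
  )
  peaks <- manual_peaks(rows, spike = 100)
  cs <- class_sum(peaks, metabolite_catalog(), "tca_cycle")
  expect_equal(cs$summary$percent_mean, 120)
})

test_that("unknown or absent classes fail listing what is available", {
  sim <- simulate_experiment(tiny_config(metabolites = c("citrate")))
  expect_error(class_sum(sim, metabolite_catalog(), "pyrimidine"),
               "available classes")
})

test_that("the s_containing subgroup only admits sulphur compounds", {
  sulphur <- c("methionine", "cysteine", "homocysteine", "taurine", "SAM",
               "SAH", "GSH", "GSSG")
  cat <- metabolite_catalog()
  expect_setequal(cat$metabolite_id[cat$class == "s_containing"], sulphur)
})

test_that("aggregate_classes binds one summary per requested class", {
  sim <- simulate_experiment(metr_signature_config(noise_cv = 0.05,
                                                   seed = 55))
  agg <- aggregate_classes(sim, metabolite_catalog(),
                           classes = c("tca_cycle", "purine"))
  expect_setequal(unique(agg$class), c("tca_cycle", "purine"))
  expect_equal(nrow(agg), 2 * 2 * 2 * 5) # class x condition x compartment x t
})
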