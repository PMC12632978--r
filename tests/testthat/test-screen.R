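test_that("screen generation is reproducible from the seed and well behaved", {
  p <- toy_screen_parts(seed = 3)
  s1 <- generate_screen(p$lib, p$truth, p$reg, p$panel, p$donors, p$plan)
  s2 <- generate_screen(p$lib, p$truth, p$reg, p$panel, p$donors, p$plan)
  expect_identical(s1, s2)
  expect_true(all(s1$mfi > 0))
  expect_true(all(s1$dose_nM[s1$condition == "unstimulated_control"] == 0))
  # controls: 3 replicates per donor x cell x pathway
  ctrl <- s1[s1$condition == "unstimulated_control", ]
  expect_true(all(table(ctrl$donor_id, ctrl$cell_type, ctrl$pathway) == 3))
  # single-binder records exist for every binder
  sb <- s1[s1$condition == "single_binder_control", ]
  expect_setequal(unique(sb$construct_id),
                  paste0("SB__", p$reg$binders$binder_id))
  # a different noise seed changes wells but not the population mean (MC error)
  plan2 <- screen_plan(seed = 33)
  s3 <- generate_screen(p$lib, p$truth, p$reg, p$panel, p$donors, plan2)
  expect_false(identical(s1$mfi, s3$mfi))
  c1 <- s1$mfi[s1$condition == "unstimulated_control"]
  c3 <- s3$mfi[s3$condition == "unstimulated_control"]
  expect_equal(mean(c1), mean(c3), tolerance = 0.05)
})

test_that("an all-inactive screen is statistically indistinguishable from its controls", {
  reg <- default_registry(); lib <- enumerate_library(reg)
  panel <- u937_panel()
  truth <- make_ground_truth(lib, reg, panel,
                             p_active = c(.default = 0), seed = 5)
  expect_true(all(truth$mechanism == "inactive"))
  expect_true(all(truth$efficacy == 0))
  donors <- donor_profiles(3, colnames(panel$density), seed = 5)
  s <- generate_screen(lib, truth, reg, panel, donors, screen_plan(seed = 5))
  set.seed(6)
  stim <- sample(s$mfi[s$condition == "stimulated"], 500)
  ctrl <- s$mfi[s$condition == "unstimulated_control"]
  expect_gt(suppressWarnings(stats::ks.test(stim, ctrl)$p.value), 0.01)
})

test_that("ground truth is planted only where it is detectable", {
  reg <- default_registry(); lib <- enumerate_library(reg)
  truth <- make_ground_truth(lib, reg, default_cell_panel(), seed = 9)
  expect_setequal(truth$construct_id, lib$construct_id)
  expect_true(all(truth$efficacy[truth$mechanism == "inactive"] == 0))
  expect_true(all(truth$efficacy[truth$mechanism != "inactive"] > 0))
  # active constructs always carry weight on a measured pathway
  act <- truth[truth$mechanism != "inactive", ]
  wmeas <- rowSums(act[, c("w_pSTAT1", "w_pSTAT3", "w_pSTAT5", "w_pSTAT6")])
  expect_true(all(wmeas > 0))
  # a pairing of two non-STAT receptors can never be active
  zero <- lib$construct_id[lib$receptor_a == "EGFR" & lib$receptor_b == "HER2"]
  expect_true(all(truth$mechanism[truth$construct_id %in% zero] == "inactive"))
  expect_error(generate_screen(lib, truth[-1, ], reg, default_cell_panel(),
                               donor_profiles(2, colnames(default_cell_panel()$density)),
                               screen_plan()),
               "missing construct")
})

test_that("receptor knockout zeroes one density, idempotently", {
  panel <- toy_panel()
  ko <- apply_knockout(panel, "alpha", "gcommon")
  expect_equal(ko$density["alpha", "gcommon"], 0)
  expect_equal(ko$density["beta", "gcommon"], panel$density["beta", "gcommon"])
  expect_identical(apply_knockout(ko, "alpha", "gcommon"), ko)
  expect_error(apply_knockout(panel, "alpha", "IL7Ra"), "unknown receptor")
  # bridging signal dies with the knocked-out arm
  expect_equal(ternary_signal(250, 5, 20, ko$density["alpha", "gcommon"],
                              ko$density["alpha", "IL4Ra"], emax = 3), 0)
})

test_that("dose series reflect the planted mechanism", {
  p <- toy_screen_parts(seed = 11, p_active = c(.default = 1))
  doses <- c(0, 1, 4, 16, 64, 250, 1000, 4000)
  tern_id <- p$truth$construct_id[p$truth$mechanism == "ternary"][1]
  row <- p$lib[p$lib$construct_id == tern_id, ]
  ds <- generate_dose_series(row, p$truth, doses, p$reg, seed = 2)
  expect_equal(nrow(ds), length(doses))
  expect_equal(ds$response[1], 100, tolerance = 0.35)
  # plateau within the tested range: last two mean responses nearly equal
  amp <- max(ds$response) - min(ds$response)
  expect_lt(abs(ds$response[8] - ds$response[7]), 0.25 * amp)
  # inactive series: flat at baseline
  p0 <- toy_screen_parts(seed = 11, p_active = c(.default = 0))
  ds0 <- generate_dose_series(p0$lib[1, ], p0$truth, doses, p0$reg, seed = 2)
  expect_lt(diff(range(ds0$response)), 100 * 0.6)
  expect_error(generate_dose_series(row, p$truth, c(0, 1, 10), p$reg), "4 doses")
  expect_error(generate_dose_series(row, p$truth, c(1, 10, 100, 1000), p$reg),
               "include 0")
})
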