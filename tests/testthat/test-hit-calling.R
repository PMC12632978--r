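mini_table <- function(mfi, condition = NULL, donor = "d1") {
  n <- length(mfi)
  if (is.null(condition))
    condition <- c(rep("unstimulated_control", 3), rep("stimulated", n - 3))
  data.frame(construct_id = paste0("c", seq_len(n)), donor_id = donor,
             cell_type = "x", pathway = "pSTAT5", dose_nM = 250,
             replicate = 1L, condition = condition, mfi = mfi,
             stringsAsFactors = FALSE)
}

test_that("0-1 normalization maps stratum extremes to 0 and 1", {
  tab <- mini_table(c(100, 150, 200), condition = rep("stimulated", 3))
  norm <- normalize_01(tab, transform = "identity")
  expect_equal(norm$normalized_score, c(0, 0.5, 1))
  expect_warning(norm0 <- normalize_01(mini_table(rep(7, 3),
                                                  condition = rep("stimulated", 3)),
                                       transform = "identity"),
                 "constant")
  expect_equal(norm0$normalized_score, c(0, 0, 0))
  # affine invariance of the raw intensities within a stratum
  tab2 <- tab; tab2$mfi <- 3.7 * tab2$mfi + 42
  expect_equal(normalize_01(tab2, transform = "identity")$normalized_score,
               norm$normalized_score)
  # on the default log scale, scale factors cancel entirely
  tab3 <- tab; tab3$mfi <- 55 * tab3$mfi
  expect_equal(normalize_01(tab3)$normalized_score,
               normalize_01(tab)$normalized_score)
})

test_that("mean + k x SEM call has exact boundary behaviour", {
  cs <- data.frame(mean = 0.2, sem = 0.05, n = 3)
  expect_true(call_signal(0.2 + 6.01 * 0.05, cs, k = 6))
  expect_false(call_signal(0.2 + 5.99 * 0.05, cs, k = 6))
  expect_false(call_signal(0.2, cs, k = 6))
  expect_error(call_signal(0.5, data.frame(mean = 0.2, sem = 0.05, n = 1)),
               "n < 2")
})

test_that("null false-positive rate of the 6xSEM rule matches the t2 closed form", {
  # analytic reduction: with 3 controls, (x - xbar) / (s * sqrt(4/3)) ~ t2,
  # and the threshold 6 * s / sqrt(3) sits at t = 3
  closed_form <- stats::pt(3, df = 2, lower.tail = FALSE)
  expect_equal(closed_form, 0.0477, tolerance = 1e-3)
  set.seed(77); n <- 2e4
  for (noise_scale in c(1, 100)) {
    ctrl <- matrix(stats::rnorm(3 * n, sd = noise_scale), n, 3)
    s <- sqrt((rowSums(ctrl^2) - 3 * rowMeans(ctrl)^2) / 2)
    cs <- data.frame(mean = rowMeans(ctrl), sem = s / sqrt(3), n = 3)
    fpr <- mean(call_signal(stats::rnorm(n, sd = noise_scale), cs, k = 6))
    expect_equal(fpr, closed_form, tolerance = 0.2)
    expect_lt(abs(fpr - closed_form), 0.01)
  }
})

test_that("adaptive cutoff escalates for weak positive controls, monotonically", {
  cs <- data.frame(mean = 0.05, sem = 0.02, n = 3)
  expect_equal(adaptive_cutoff(cs, positive_control_scores = 0.8), 6)
  expect_equal(adaptive_cutoff(cs, positive_control_scores = 0.1, gamma = 1.5), 9)
  expect_warning(k0 <- adaptive_cutoff(cs, numeric(0)), "no positive controls")
  expect_equal(k0, 6)
  ks <- vapply(seq(0.9, 0.06, by = -0.04), function(eff)
    adaptive_cutoff(cs, positive_control_scores = cs$mean + eff), numeric(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("donor reproducibility needs at least two of three donors", {
  expect_true(reproducibility(c(TRUE, TRUE, FALSE)))
  expect_false(reproducibility(c(TRUE, FALSE, FALSE)))
  expect_false(reproducibility(c(FALSE, FALSE, FALSE)))
  expect_true(reproducibility(c(TRUE, TRUE, TRUE), min_donors = 3))
})

test_that("activation rates hit their trivial bounds", {
  p <- toy_screen_parts(seed = 21, p_active = c(.default = 0))
  s <- generate_screen(p$lib, p$truth, p$reg, p$panel, p$donors, p$plan)
  hits <- call_hits(s)
  rates <- activation_rate_by_receptor(hits, p$lib)
  expect_true(all(rates < 0.2))
  # force every construct strongly active: all rates 1
  t1 <- p$truth; t1$mechanism <- "ternary"; t1$efficacy <- 8
  for (w in paste0("w_", c("pSTAT1", "pSTAT3", "pSTAT4", "pSTAT5", "pSTAT6")))
    t1[[w]] <- 1
  pan <- p$panel; pan$density[pan$density == 0] <- 1000
  s1 <- generate_screen(p$lib, t1, p$reg, pan, p$donors, p$plan)
  r1 <- activation_rate_by_receptor(call_hits(s1), p$lib)
  expect_equal(unname(r1), rep(1, length(r1)))
  # single-binder rows are scored but never counted toward rates
  h1 <- call_hits(s1)
  expect_true(any(h1$condition == "single_binder_control"))
  expect_false(any(startsWith(names(r1), "SB__")))
})

test_that("a planted gamma-common activation rate is recovered within five points", {
  reg <- default_registry(); lib <- enumerate_library(reg)
  panel <- u937_panel()
  truth <- make_ground_truth(lib, reg, panel, seed = 7)
  gid <- lib$construct_id[lib$receptor_a == "gcommon" | lib$receptor_b == "gcommon"]
  planted <- mean(truth$mechanism[match(gid, truth$construct_id)] != "inactive")
  expect_equal(planted, 0.42, tolerance = 0.02)
  donors <- donor_profiles(3, colnames(panel$density), seed = 7)
  s <- generate_screen(lib, truth, reg, panel, donors, screen_plan(seed = 7))
  rates <- activation_rate_by_receptor(call_hits(s), lib)
  expect_lt(abs(rates[["gcommon"]] - planted), 0.05)
})
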