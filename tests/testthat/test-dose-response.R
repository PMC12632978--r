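hill_curve <- function(d, e0, emax, ec50, h) {
  e0 + (emax - e0) * ifelse(d == 0, 0, d^h / (d^h + ec50^h))
}

test_that("noiseless Hill parameters are recovered within one percent", {
  d <- c(0, 1, 3, 10, 30, 100, 300, 1000)
  series <- data.frame(dose_nM = d,
                       response = hill_curve(d, e0 = 1, emax = 5, ec50 = 10,
                                             h = 1))
  fit <- fit_hill(series)
  expect_true(fit$converged)
  p <- coef(fit)
  expect_equal(unname(p["e0"]), 1, tolerance = 0.01)
  expect_equal(unname(p["emax"]), 5, tolerance = 0.01)
  expect_equal(unname(p["ec50_nM"]), 10, tolerance = 0.01)
  expect_equal(unname(p["hill"]), 1, tolerance = 0.01)
  expect_equal(unname(predict(fit, 0)), unname(p["e0"]))
  expect_equal(fitted(fit) + residuals(fit), series$response)
  expect_output(print(fit), "Hill fit")
})

test_that("a flat series fits with near-zero amplitude", {
  series <- data.frame(dose_nM = c(0, 1, 10, 100, 1000),
                       response = c(2.0, 2.01, 1.99, 2.0, 2.01))
  p <- coef(fit_hill(series))
  expect_lt(abs(p["emax"] - p["e0"]), 0.1)
})

test_that("rescaling dose units rescales the EC50 and nothing else", {
  d <- c(0, 0.5, 2, 8, 32, 128, 512)
  r <- hill_curve(d, 1, 4, 7, 1.3)
  p1 <- coef(fit_hill(data.frame(dose_nM = d, response = r)))
  p2 <- coef(fit_hill(data.frame(dose_nM = d * 1000, response = r)))
  expect_equal(unname(p2["ec50_nM"] / p1["ec50_nM"]), 1000, tolerance = 0.02)
  expect_equal(unname(p1[c("e0", "emax", "hill")]),
               unname(p2[c("e0", "emax", "hill")]), tolerance = 0.02)
})

test_that("series invariants are enforced", {
  expect_error(fit_hill(data.frame(dose_nM = c(0, 1, 10),
                                   response = c(1, 2, 3))), "4 doses")
  expect_error(fit_hill(data.frame(dose_nM = c(0, 10, 5, 20),
                                   response = 1:4)), "increasing")
})

test_that("classification separates the three mechanisms on generated series", {
  reg <- default_registry(); lib <- enumerate_library(reg)
  panel <- u937_panel()
  truth <- make_ground_truth(lib, reg, panel, seed = 5)
  doses <- c(0, 0.4, 1.6, 6.4, 25, 100, 400, 1600, 6400)
  nf <- control_noise_floor()
  # strongest representative of each mechanism
  strongest <- function(mech) {
    t <- truth[truth$mechanism == mech, ]
    t$construct_id[which.max(t$efficacy)]
  }
  for (case in list(c("ternary", "saturable"),
                    c("clustering", "non_saturating"))) {
    id <- strongest(case[1])
    s <- generate_dose_series(lib[lib$construct_id == id, ], truth, doses,
                              reg, seed = 31)
    mc <- classify_dose_response(s[, c("dose_nM", "response")], nf)
    expect_equal(mc$label, case[2])
  }
  # pure noise at a 3-sd floor is no_signal
  id0 <- truth$construct_id[truth$mechanism == "inactive"][1]
  s0 <- generate_dose_series(lib[lib$construct_id == id0, ], truth, doses,
                             reg, seed = 31)
  mc0 <- classify_dose_response(s0[, c("dose_nM", "response")], nf)
  expect_equal(mc0$label, "no_signal")
})

test_that("classification is invariant to affine response rescaling", {
  reg <- default_registry(); lib <- enumerate_library(reg)
  truth <- make_ground_truth(lib, reg, u937_panel(), seed = 5)
  doses <- c(0, 0.4, 1.6, 6.4, 25, 100, 400, 1600, 6400)
  nf <- control_noise_floor()
  ids <- c(truth$construct_id[truth$mechanism == "ternary"][1:2],
           truth$construct_id[truth$mechanism == "clustering"][1:2],
           truth$construct_id[truth$mechanism == "inactive"][1:2])
  for (id in ids) {
    s <- generate_dose_series(lib[lib$construct_id == id, ], truth, doses,
                              reg, seed = 13)[, c("dose_nM", "response")]
    lab1 <- classify_dose_response(s, nf)$label
    s2 <- s; s2$response <- 2.5 * s$response + 40
    lab2 <- classify_dose_response(s2, 2.5 * nf)$label
    expect_equal(lab2, lab1)
  }
})

test_that("classify_series_table returns one labelled fit per construct", {
  reg <- default_registry(); lib <- enumerate_library(reg)
  truth <- make_ground_truth(lib, reg, u937_panel(), seed = 5)
  doses <- c(0, 1, 5, 25, 125, 625, 3125)
  ids <- truth$construct_id[truth$mechanism == "ternary"][1:3]
  series <- do.call(rbind, lapply(ids, function(id)
    generate_dose_series(lib[lib$construct_id == id, ], truth, doses, reg,
                         seed = 17)))
  out <- classify_series_table(series, noise_floor = control_noise_floor())
  expect_equal(nrow(out), 3)
  expect_setequal(out$construct_id, ids)
  expect_true(all(out$label %in% c("saturable", "non_saturating", "no_signal")))
  expect_true(all(out$ec50_nM[out$label == "saturable"] > 0))
})
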