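test_that("initial rate is the OLS slope over the low-conversion window", {
  # exactly linear data: slope recovered with zero standard error
  a <- rate_assay(time_h = 1:5 / 10, product_mM = 2 * (1:5) / 10,
                  enzyme = 0.01, substrate0 = 10)
  ir <- initial_rate(a)
  expect_equal(ir$rate, 2)
  expect_lt(ir$se, 1e-12)
  expect_equal(ir$n_used, 5L)
})

test_that("points beyond the conversion limit are excluded from the fit", {
  # curved series crossing 20% conversion: estimate must change when the
  # window is widened to include the late points
  k <- 5; E <- 0.05; S0 <- 10
  t <- c(0.05, 0.1, 0.15, 0.2, 0.4, 0.8, 1.6)
  p <- S0 * (1 - exp(-k * E * t))
  a <- rate_assay(t, p, enzyme = E, substrate0 = S0)
  narrow <- initial_rate(a, conversion_limit = 0.20)
  wide <- initial_rate(a, conversion_limit = 0.99)
  expect_lt(narrow$n_used, wide$n_used)
  expect_false(isTRUE(all.equal(narrow$rate, wide$rate)))
  expect_error(initial_rate(rate_assay(c(1, 2, 3), c(3, 5, 7),
                                       enzyme = 1, substrate0 = 10),
                            conversion_limit = 0.25),
               "insufficient data")
})

test_that("noiseless synthetic assays recover the rate constant within 2%", {
  k_true <- 10; E <- 0.01; S0 <- 10
  assays <- generate_initial_rate_dataset(k_true, E, S0, n_points = 6,
                                          n_replicates = 3,
                                          noise = noise_model(0, 0, seed = 1))
  est <- fit_rate_constant(assays)
  expect_lt(abs(est$k - k_true) / k_true, 0.02)
  expect_equal(est$sd, 0)
  expect_identical(est$n_replicates, 3L)
})

test_that("second-order constant arithmetic and replicate aggregation", {
  est <- second_order_constant(1, enzyme = 0.001, substrate0 = 10)
  expect_equal(est$k, 100)
  est3 <- second_order_constant(c(2, 2, 2), enzyme = 0.01, substrate0 = 10)
  expect_equal(est3$sd, 0)
  expect_identical(est3$n_replicates, 3L)
  expect_error(second_order_constant(numeric(), 1, 1), "at least one")
  expect_error(second_order_constant(1, 0, 10), "enzyme")
})

test_that("replicate scatter behaves like iid normal constants", {
  # with 3 replicates the +/- 3 sd interval has the exact t_2 coverage
  # ceiling of 96.5%; curvature bias (~1% of k) lowers it a little.
  # 300 seeded repeats: expect coverage in a band around that.
  k_true <- 10; E <- 0.01; S0 <- 10
  cov <- vapply(1:300, function(i) {
    assays <- generate_initial_rate_dataset(
      k_true, E, S0, n_points = 5, n_replicates = 3,
      noise = noise_model(cv = 0.03, floor = 0.01, seed = i))
    est <- fit_rate_constant(assays)
    abs(est$k - k_true) <= 3 * est$sd
  }, logical(1))
  expect_gt(mean(cov), 0.88)
  expect_lt(mean(cov), 0.99)
})

test_that("stereochemistry table derives E^S and K_eq with strict flags", {
  est <- data.frame(
    label = c("II^S", "II^S", "II^R", "II^R", "I^S", "I^S", "I^R", "I^R"),
    direction = c("OD", "RA", "OD", "RA", "OD", "RA", "OD", "RA"),
    k = c(2, 4, 0.1, 0.2, 10, 1, 0, 0))
  tab <- stereochemistry_table(est)
  ii <- tab$compounds[tab$compounds$family == "II", ]
  expect_equal(ii$E_S_OD, 20)
  expect_equal(ii$E_S_RA, 20)
  expect_false(ii$strict_OD)
  i_ <- tab$compounds[tab$compounds$family == "I", ]
  expect_true(is.infinite(i_$E_S_OD) && i_$strict_OD)
  expect_true(is.infinite(i_$E_S_RA) && i_$strict_RA)
  expect_true(is.na(tab$reactions$K_eq[tab$reactions$label == "I^R"]))
  expect_equal(tab$reactions$K_eq[tab$reactions$label == "II^S"], 0.5)
  # equal-K_eq enantiomer pair
  expect_equal(tab$reactions$K_eq[tab$reactions$label == "II^S"],
               tab$reactions$K_eq[tab$reactions$label == "II^R"])
  expect_error(stereochemistry_table(
    data.frame(label = "II^R", direction = "OD", k = 1)),
    "missing for: II\\^R")
  expect_error(stereochemistry_table(
    data.frame(label = c("II^S", "II^S"), direction = c("OD", "OD"),
               k = c(1, 2))), "duplicated")
})

test_that("a 20-fold enantiomeric ratio is recovered from generated assays", {
  E <- 0.01; S0 <- 10
  k_S <- 8; k_R <- k_S / 20
  rows <- do.call(rbind, lapply(
    list(c("II^S", "OD", k_S), c("II^S", "RA", 2 * k_S),
         c("II^R", "OD", k_R), c("II^R", "RA", 2 * k_R)),
    function(spec_row) {
      k_true <- as.numeric(spec_row[3])
      assays <- generate_initial_rate_dataset(
        k_true, E, S0, n_points = 6, n_replicates = 3,
        noise = noise_model(0, 0, seed = 7))
      est <- fit_rate_constant(assays)
      data.frame(label = spec_row[1], direction = spec_row[2], k = est$k)
    }))
  tab <- stereochemistry_table(rows)
  expect_equal(tab$compounds$E_S_OD, 20, tolerance = 1e-6)
  expect_equal(tab$compounds$E_S_RA, 20, tolerance = 1e-6)
})
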